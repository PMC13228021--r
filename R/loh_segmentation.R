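#' Classify site zygosity by the 90% read-support rule
#'
#' A site is homozygous when its alternate read support is at or above the
#' threshold, or at or below the mirrored threshold (a reference-matching
#' homozygous site has support near 0, so the rule is applied two-sidedly);
#' heterozygous otherwise. The boundary is inclusive: support exactly at
#' the threshold is homozygous.
#'
#' @param sites Variant data frame (see [read_variant_table()]).
#' @param threshold Homozygosity threshold on read support (default 0.90).
#' @param min_depth Minimum total depth; shallower sites are dropped
#'   (default 10).
#' @return Data frame `chrom`, `pos`, `support`, `state` (`homozygous` /
#'   `heterozygous`), sorted by `(chrom, pos)`.
#' @export
classify_zygosity <- function(sites, threshold = 0.90, min_depth = 10L) {
  stopifnot(threshold > 0.5, threshold <= 1)
  total <- sites$ref_depth + sites$alt_depth
  if (any(total == 0L)) stop("zero-depth site; pre-filter the input")
  sites <- sites[total >= min_depth, , drop = FALSE]
  total <- sites$ref_depth + sites$alt_depth
  support <- sites$alt_depth / total
  # two-sided rule on the major-allele direction; comparing the mirrored
  # support against the one threshold avoids 1 - threshold rounding at
  # the inclusive boundary
  hom <- pmax(support, 1 - support) >= threshold
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    support = support,
                    state = ifelse(hom, "homozygous", "heterozygous"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# A tolerant run over a 0/1 homozygosity vector is an interval whose
# endpoints are homozygous, contains no two adjacent heterozygous calls,
# and whose heterozygous count is <= max_het_rate * interval size.
# Segments are the maximal tolerant runs (not contained in a larger one).
tolerant_runs <- function(hom, max_het_rate) {
  n <- length(hom)
  if (n == 0L) return(matrix(integer(0), ncol = 2L))
  runs <- matrix(integer(0), ncol = 2L)
  hom_idx <- which(hom)
  if (length(hom_idx) == 0L) return(runs)
  for (i in hom_idx) {
    het <- 0L
    best_j <- NA_integer_
    j <- i
    while (j <= n) {
      if (!hom[j]) {
        if (j < n && !hom[j + 1L]) break   # adjacent hets: no j beyond works
        het <- het + 1L
      } else if (het <= max_het_rate * (j - i + 1L)) {
        best_j <- j
      }
      j <- j + 1L
    }
    if (!is.na(best_j)) runs <- rbind(runs, c(i, best_j))
  }
  if (nrow(runs) <= 1L) return(runs)
  # drop runs contained in another
  keep <- vapply(seq_len(nrow(runs)), function(k) {
    !any(runs[, 1L] <= runs[k, 1L] & runs[, 2L] >= runs[k, 2L] &
           (runs[, 1L] < runs[k, 1L] | runs[, 2L] > runs[k, 2L]))
  }, TRUE)
  unique(runs[keep, , drop = FALSE])
}

#' Segment runs of homozygous calls
#'
#' Finds, per chromosome, maximal runs of homozygous zygosity calls that
#' tolerate isolated heterozygous interruptions (never two in a row) up to
#' a rate cap, and keeps runs with at least `min_sites` member sites. The
#' segment span is first to last member site, reported 0-based half-open.
#'
#' @param calls Zygosity calls from [classify_zygosity()].
#' @param min_sites Minimum sites per segment (default 10).
#' @param max_het_rate Tolerated heterozygous-interruption rate within a
#'   segment (default 1/50).
#' @return Data frame `chrom`, `start`, `end`, `n_sites`, `mean_support`
#'   (mean major-direction support over member sites), `class` (NA;
#'   set by [classify_loh_segments()]).
#' @export
segment_homozygous_runs <- function(calls, min_sites = 10L,
                                    max_het_rate = 1 / 50) {
  segs <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    cc <- cc[order(cc$pos), , drop = FALSE]
    runs <- tolerant_runs(cc$state == "homozygous", max_het_rate)
    for (k in seq_len(nrow(runs))) {
      i0 <- runs[k, 1L]; i1 <- runs[k, 2L]
      if (i1 - i0 + 1L < min_sites) next
      sup <- cc$support[i0:i1]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = cc$pos[i0] - 1L, end = cc$pos[i1],
        n_sites = i1 - i0 + 1L,
        mean_support = mean(pmax(sup, 1 - sup)),
        class = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      mean_support = numeric(), class = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Per-chromosome assessed spans
#'
#' The interval from the first to the last assessed SNV per chromosome;
#' the denominator for homozygosity fractions and the frame for
#' terminal/UPD classification.
#'
#' @param calls Zygosity calls from [classify_zygosity()].
#' @return Data frame `chrom`, `first_pos`, `last_pos`, `n_sites`.
#' @export
assessed_spans <- function(calls) {
  out <- do.call(rbind, lapply(split(calls$pos, calls$chrom), range))
  data.frame(chrom = rownames(out), first_pos = out[, 1L],
             last_pos = out[, 2L],
             n_sites = as.vector(table(calls$chrom)[rownames(out)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify LOH segments as interstitial, terminal or UPD
#'
#' Positional taxonomy of LOH: a segment covering at least `upd_fraction`
#' of a chromosome's assessed sites is uniparental disomy (UPD,
#' whole-chromosome homozygosity from a segregation error); a segment
#' reaching within `terminal_margin_sites` assessed sites of either
#' chromosome end is terminal (single-crossover signature); anything else
#' is interstitial (gene conversion / double crossover).
#'
#' @param segments Segments from [segment_homozygous_runs()].
#' @param calls The zygosity calls the segments were built from.
#' @param layout A [genome_layout()] (chromosome names are validated
#'   against it).
#' @param terminal_margin_sites Assessed-site margin for the terminal call
#'   (default 3).
#' @param upd_fraction Assessed-site coverage for the UPD call
#'   (default 0.95).
#' @return The segments with `class` filled in.
#' @export
classify_loh_segments <- function(segments, calls, layout,
                                  terminal_margin_sites = 3L,
                                  upd_fraction = 0.95) {
  if (nrow(segments) == 0L) return(segments)
  unknown <- setdiff(unique(segments$chrom), layout$chrom)
  if (length(unknown) > 0L) {
    stop("segment on unknown chromosome: ", unknown[1L])
  }
  for (k in seq_len(nrow(segments))) {
    ch <- segments$chrom[k]
    pos <- sort(calls$pos[calls$chrom == ch])
    n <- length(pos)
    n_before <- sum(pos < segments$start[k] + 1L)
    n_after <- sum(pos > segments$end[k])
    segments$class[k] <- if (segments$n_sites[k] >= upd_fraction * n) {
      "upd"
    } else if (n_before < terminal_margin_sites ||
               n_after < terminal_margin_sites) {
      "terminal"
    } else {
      "interstitial"
    }
  }
  segments
}

#' Length-weighted genome homozygosity fraction
#'
#' Total LOH segment length divided by the total assessed span length
#' (first-to-last assessed SNV per chromosome), in \[0, 1\].
#'
#' @param segments Classified or unclassified LOH segments.
#' @param spans Assessed spans from [assessed_spans()].
#' @return A fraction, or NA when no sites were assessed.
#' @export
homozygosity_fraction <- function(segments, spans) {
  denom <- sum(as.numeric(spans$last_pos - spans$first_pos + 1L))
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  min(1, sum(as.numeric(segments$end - segments$start)) / denom)
}

tz_overlap <- function(chrom_i, start, end, layout, arm_fraction = 0.20) {
  L <- layout$length[chrom_i]
  cen <- layout$centromere[chrom_i]
  lz_end <- cen * arm_fraction                   # left zone: [0, lz_end)
  rz_start <- L - (L - cen) * arm_fraction       # right zone: [rz_start, L)
  inzone <- pmax(0, pmin(end, lz_end) - start) +
    pmax(0, end - pmax(start, rz_start))
  total <- sum(end - start)
  if (total == 0) return(NA_real_)
  sum(inzone) / total
}

terminal_zone_overlap <- function(segments, layout, arm_fraction = 0.20) {
  tz_overlap(match(segments$chrom, layout$chrom), segments$start,
             segments$end, layout, arm_fraction)
}

#' Genome-wide LOH positional pattern statistic
#'
#' Mitotic LOH concentrates at telomere-proximal regions while
#' meiosis-associated LOH is distributed more evenly along chromosomes.
#' The statistic is the fraction of total LOH length lying in the terminal
#' `arm_fraction` (default 20%) of chromosome arms (arms defined by the
#' centromere). Its null distribution is obtained by re-placing each
#' segment uniformly along its chromosome, length preserved. The pattern
#' is `fully-homozygous` when the genome homozygosity fraction is >= 0.99;
#' `mitotic-dominated` when the statistic exceeds the null's 95th
#' percentile; `meiotic-dominated` when it lies within the null's central
#' 90%; `undetermined` otherwise or with fewer than 3 segments.
#'
#' @param segments Classified LOH segments.
#' @param layout A [genome_layout()].
#' @param spans Assessed spans (for the homozygosity fraction).
#' @param n_permutations Null draws (default 1000).
#' @param arm_fraction Terminal arm fraction defining the telomeric zone
#'   (default 0.20).
#' @param seed Optional seed for the permutation null.
#' @param strain Strain id carried into the report.
#' @return A list of class `loh_pattern`: `strain`, `hom_fraction`,
#'   `terminal_fraction` (the statistic), `pattern`, `p_value`
#'   (permutation upper-tail p).
#' @export
loh_pattern_statistic <- function(segments, layout, spans,
                                  n_permutations = 1000L,
                                  arm_fraction = 0.20, seed = NULL,
                                  strain = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  hom_frac <- homozygosity_fraction(segments, spans)
  res <- list(strain = strain, hom_fraction = hom_frac,
              terminal_fraction = NA_real_, pattern = "undetermined",
              p_value = NA_real_)
  class(res) <- "loh_pattern"
  if (!is.na(hom_frac) && hom_frac >= 0.99) {
    res$pattern <- "fully-homozygous"
    res$terminal_fraction <- terminal_zone_overlap(segments, layout,
                                                   arm_fraction)
    return(res)
  }
  if (nrow(segments) < 3L) return(res)
  stat <- terminal_zone_overlap(segments, layout, arm_fraction)
  res$terminal_fraction <- stat
  chrom_i <- match(segments$chrom, layout$chrom)
  lens <- segments$end - segments$start
  chrom_len <- layout$length[chrom_i]
  null <- vapply(seq_len(n_permutations), function(...) {
    starts <- floor(stats::runif(nrow(segments)) * (chrom_len - lens))
    tz_overlap(chrom_i, starts, starts + lens, layout, arm_fraction)
  }, 0)
  res$p_value <- (1 + sum(null >= stat)) / (1 + n_permutations)
  q95 <- stats::quantile(null, 0.95, names = FALSE)
  q05 <- stats::quantile(null, 0.05, names = FALSE)
  res$pattern <- if (stat > q95) {
    "mitotic-dominated"
  } else if (stat >= q05) {
    "meiotic-dominated"
  } else {
    "undetermined"
  }
  res
}

#' @export
print.loh_pattern <- function(x, ...) {
  cat("LOH pattern:", x$pattern,
      sprintf("(homozygosity %.1f%%, terminal-zone fraction %s, p = %s)\n",
              100 * x$hom_fraction,
              ifelse(is.na(x$terminal_fraction), "NA",
                     sprintf("%.2f", x$terminal_fraction)),
              ifelse(is.na(x$p_value), "NA",
                     sprintf("%.3f", x$p_value))))
  invisible(x)
}
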
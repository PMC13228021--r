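# copy-number estimates round half-up at exactly x.5 (base round() is
# round-half-even, which would split ties between adjacent copy states)
round_half_up <- function(x) floor(x + 0.5)

#' Call whole-chromosome copy number from windowed coverage
#'
#' Per chromosome the copy number is `round(median(norm_ratio) x
#' baseline_ploidy)`; the chromosome is called aneuploid (trisomy-like
#' gain or monosomy-like loss) only when at least `support_fraction` of
#' its windows individually round to the same non-baseline copy number.
#' Mixed or subclonal coverage levels therefore surface as euploid calls
#' with a low support fraction rather than as discrete aneuploidies.
#'
#' @param windows Coverage data frame (see [read_coverage_table()]).
#' @param baseline_ploidy Strain baseline ploidy (2, 3 or 4).
#' @param support_fraction Window agreement needed to call aneuploidy
#'   (default 0.8).
#' @param deny_chroms Chromosomes excluded from calling (e.g. rDNA or
#'   mitochondrial contigs with depth artifacts).
#' @return Data frame `chrom`, `copy_number`, `state` (`euploid`,
#'   `trisomy_like_gain`, `monosomy_like_loss`), `support` (fraction of
#'   windows backing the reported copy number), `n_windows`. Chromosomes
#'   with fewer than 3 windows are skipped with a warning.
#' @export
call_chromosome_copies <- function(windows, baseline_ploidy,
                                   support_fraction = 0.8,
                                   deny_chroms = character(0)) {
  stopifnot(baseline_ploidy %in% c(2L, 3L, 4L))
  windows <- windows[!windows$chrom %in% deny_chroms, , drop = FALSE]
  chroms <- unique(windows$chrom)
  rows <- lapply(chroms, function(ch) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (nrow(w) < 3L) {
      warning("chromosome ", ch, " has < 3 windows; call skipped")
      return(NULL)
    }
    cn <- round_half_up(stats::median(w$norm_ratio) * baseline_ploidy)
    win_cn <- round_half_up(w$norm_ratio * baseline_ploidy)
    support <- mean(win_cn == cn)
    if (cn != baseline_ploidy && support >= support_fraction) {
      state <- if (cn > baseline_ploidy) "trisomy_like_gain"
               else "monosomy_like_loss"
    } else {
      state <- "euploid"
      cn <- baseline_ploidy
      support <- mean(win_cn == baseline_ploidy)
    }
    data.frame(chrom = ch, copy_number = cn, state = state,
               support = support, n_windows = nrow(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), copy_number = integer(),
                      state = character(), support = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Classify a segment as terminal or interstitial
#'
#' A segment is terminal when it starts within `terminal_margin` bp of the
#' left chromosome end or ends within `terminal_margin` bp of the right
#' end; otherwise interstitial.
#'
#' @param chrom,start,end Segment coordinates (0-based half-open).
#' @param layout A [genome_layout()].
#' @param terminal_margin Margin in bp (default 2000, i.e. two default
#'   coverage windows).
#' @return `"terminal"` or `"interstitial"`.
#' @export
classify_segment_position <- function(chrom, start, end, layout,
                                      terminal_margin = 2000L) {
  i <- match(chrom, layout$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  L <- layout$length[i]
  if (start < 0 || end > L || end <= start) {
    stop("segment outside chromosome bounds: ", chrom, ":", start, "-", end)
  }
  if (start < terminal_margin || end > L - terminal_margin) {
    "terminal"
  } else {
    "interstitial"
  }
}

#' Detect segmental duplications and deletions
#'
#' Scans each chromosome for maximal runs of consecutive windows whose
#' normalized depth deviates from the chromosome's called level by at
#' least `ratio_margin / baseline_ploidy` in a consistent direction; runs
#' of at least `min_windows` become segments. Segment copy number is
#' `round(run median x baseline_ploidy)` and the positional class
#' (terminal vs interstitial) is combined with the deviation direction
#' into the four rearrangement classes.
#'
#' @param windows Coverage data frame.
#' @param chrom_calls Result of [call_chromosome_copies()].
#' @param layout A [genome_layout()].
#' @param baseline_ploidy Strain baseline ploidy.
#' @param min_windows Minimum run length (default 3).
#' @param ratio_margin Deviation threshold in units of one copy at the
#'   baseline ploidy (default 0.3).
#' @param terminal_margin Margin for the positional class (default 2000
#'   bp).
#' @return Data frame `chrom`, `start`, `end`, `copy_number`, `class`
#'   (`interstitial_deletion`, `interstitial_duplication`,
#'   `terminal_deletion`, `terminal_duplication`), `n_windows`.
#' @export
detect_segmental_cnv <- function(windows, chrom_calls, layout,
                                 baseline_ploidy, min_windows = 3L,
                                 ratio_margin = 0.3,
                                 terminal_margin = 2000L) {
  stopifnot(min_windows >= 2L)
  thr <- ratio_margin / baseline_ploidy
  segs <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    call <- chrom_calls[chrom_calls$chrom == ch, , drop = FALSE]
    level_cn <- if (nrow(call) == 1L) call$copy_number else baseline_ploidy
    level <- level_cn / baseline_ploidy
    dev <- w$norm_ratio - level
    dir <- ifelse(dev >= thr, 1L, ifelse(dev <= -thr, -1L, 0L))
    r <- rle(dir)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L || r$lengths[k] < min_windows) next
      i0 <- starts[k]; i1 <- stops[k]
      cn <- round_half_up(stats::median(w$norm_ratio[i0:i1]) *
                            baseline_ploidy)
      pos <- classify_segment_position(ch, w$start[i0], w$end[i1], layout,
                                       terminal_margin)
      kind <- if (r$values[k] > 0L) "duplication" else "deletion"
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start = w$start[i0], end = w$end[i1],
        copy_number = cn, class = paste(pos, kind, sep = "_"),
        n_windows = i1 - i0 + 1L, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), copy_number = integer(),
                      class = character(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Annotate segment breakpoints with nearby repeat features
#'
#' Rearrangement breakpoints in yeast are typically associated with
#' repetitive elements (LTRs, Ty transposons, mating-type loci). Each
#' segment boundary is labeled with the class of any annotated repeat
#' within `flank` bp (overlap counts as distance 0).
#'
#' @param segments CNV segment data frame.
#' @param repeats Data frame `chrom`, `start`, `end`, `class` with class
#'   in `LTR`, `Ty`, `mating_locus`, `other` (BED-style records).
#' @param flank Maximum breakpoint-to-feature distance in bp
#'   (default 1000, one default window).
#' @return The segments with added `start_repeat` and `end_repeat` columns
#'   (`"none"` where no feature is near) and an attached
#'   `attr(, "repeat_fraction")`: the fraction of breakpoints that are
#'   repeat-associated.
#' @export
annotate_breakpoint_repeats <- function(segments, repeats, flank = 1000L) {
  label_at <- function(chrom, bp) {
    r <- repeats[repeats$chrom == chrom, , drop = FALSE]
    if (nrow(r) == 0L) return("none")
    dist <- pmax(r$start - bp, bp - r$end, 0L)
    near <- which(dist <= flank)
    if (length(near) == 0L) return("none")
    r$class[near[which.min(dist[near])]]
  }
  segments$start_repeat <- mapply(label_at, segments$chrom, segments$start,
                                  USE.NAMES = FALSE)
  segments$end_repeat <- mapply(label_at, segments$chrom, segments$end,
                                USE.NAMES = FALSE)
  lab <- c(segments$start_repeat, segments$end_repeat)
  attr(segments, "repeat_fraction") <-
    if (length(lab) > 0L) mean(lab != "none") else NA_real_
  segments
}
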
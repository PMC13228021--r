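is_indel <- function(ref, alt) nchar(ref) > 1L | nchar(alt) > 1L

#' Pairwise SNV distance between two strains
#'
#' Counts the SNV records (chrom, pos, alt) present in exactly one of the
#' two strains: the size of the symmetric difference. InDels (either
#' allele longer than 1 bp) are excluded. Zygosity is ignored — a shared
#' position with different alternate alleles counts twice.
#'
#' @param sites_a,sites_b Variant data frames.
#' @return Integer count.
#' @export
pairwise_snv_distance <- function(sites_a, sites_b) {
  key <- function(s) {
    s <- s[!is_indel(s$ref, s$alt), , drop = FALSE]
    unique(paste(s$chrom, s$pos, s$alt, sep = ":"))
  }
  a <- key(sites_a)
  b <- key(sites_b)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Divergence time from an SNV difference count
#'
#' Converts the number of SNV differences between two strains into years
#' since divergence, assuming a constant per-division SNV accumulation
#' rate and generation time:
#' `years = snv_difference / mu * generation_hours / 8760`.
#' The count is taken as-is (no division between the two lineages), with
#' 8,760 h per 365-day year.
#'
#' @param snv_difference Non-negative SNV difference count.
#' @param mu SNVs per genome per cell division (default 5e-3).
#' @param generation_hours Generation time in hours (default 2).
#' @return Divergence time in years.
#' @export
divergence_time <- function(snv_difference, mu = 5e-3,
                            generation_hours = 2) {
  stopifnot(mu > 0, generation_hours > 0)
  if (any(snv_difference < 0)) stop("negative SNV difference")
  snv_difference / mu * generation_hours / 8760
}

#' Annotation tallies for one strain
#'
#' Summarizes effect annotations over a strain's variant records: the
#' coding fraction of SNVs, synonymous and missense counts and their
#' ratio, frameshift InDel count (computed natively from allele lengths:
#' length difference not divisible by 3, restricted to coding InDels),
#' start/stop gain-loss count, and the repeat-context InDel fraction when
#' a `context` column is present. Records without an annotation are
#' counted as `other` and reported via a message.
#'
#' @param sites Variant data frame with an `annotation` column using the
#'   labels `synonymous`, `missense`, `frameshift`,
#'   `start_stop_gain_loss`, `noncoding`, `other`. Coding labels are all
#'   but `noncoding`/`other`.
#' @param strain Strain id.
#' @return A one-row data frame with the tallies; `syn_missense_ratio` is
#'   NA when there are no missense variants.
#' @export
annotation_tallies <- function(sites, strain = NA_character_) {
  ann <- sites$annotation
  n_missing <- sum(is.na(ann))
  if (n_missing > 0L) {
    message(n_missing, " unannotated record(s) counted as 'other'")
    ann[is.na(ann)] <- "other"
  }
  indel <- is_indel(sites$ref, sites$alt)
  snv_ann <- ann[!indel]
  coding_labels <- c("synonymous", "missense", "frameshift",
                     "start_stop_gain_loss")
  n_snv <- length(snv_ann)
  n_syn <- sum(snv_ann == "synonymous")
  n_mis <- sum(snv_ann == "missense")
  len_diff <- abs(nchar(sites$alt) - nchar(sites$ref))
  coding_indel <- indel & ann %in% coding_labels
  n_frameshift <- sum(coding_indel & (len_diff %% 3L != 0L))
  ctx <- sites$context
  repeat_fraction <- if (!is.null(ctx) && any(indel)) {
    mean(ctx[indel] %in% c("mononucleotide_repeat", "microsatellite"))
  } else {
    NA_real_
  }
  data.frame(
    strain = strain,
    n_snv = n_snv,
    coding_fraction = if (n_snv > 0L) {
      mean(snv_ann %in% coding_labels)
    } else NA_real_,
    synonymous = n_syn,
    missense = n_mis,
    syn_missense_ratio = if (n_mis > 0L) n_syn / n_mis else NA_real_,
    frameshift_indels = n_frameshift,
    start_stop_gain_loss = sum(ann == "start_stop_gain_loss"),
    repeat_context_indel_fraction = repeat_fraction,
    stringsAsFactors = FALSE
  )
}

#' Classify the repeat context of an InDel
#'
#' Replication slippage makes InDels cluster at short repeats. An InDel is
#' in `mononucleotide_repeat` context when it lies within a single-base
#' run of length >= 4 (counting the event's own inserted/deleted bases);
#' in `microsatellite` context when it lies within >= 3 tandem units of a
#' 2-6 bp motif; otherwise `non_repeat`. Mononucleotide context takes
#' precedence.
#'
#' @param ref,alt Reference and alternate alleles (VCF-style, anchored on
#'   the base before the event).
#' @param window Reference sequence window of at least 21 bp centered on
#'   the InDel anchor position.
#' @param anchor_offset 1-based position of the anchor base within
#'   `window` (default the center).
#' @return One of `"mononucleotide_repeat"`, `"microsatellite"`,
#'   `"non_repeat"`.
#' @export
indel_repeat_context <- function(ref, alt, window,
                                 anchor_offset = (nchar(window) + 1L) %/% 2L) {
  if (nchar(window) < 21L) stop("reference window must be >= 21 bp")
  if (!is_indel(ref, alt)) stop("not an InDel")
  if (nchar(ref) > 1L && nchar(alt) > 1L) stop("complex InDel not supported")
  event <- if (nchar(ref) > nchar(alt)) {
    substr(ref, nchar(alt) + 1L, nchar(ref))     # deleted bases
  } else {
    substr(alt, nchar(ref) + 1L, nchar(alt))     # inserted bases
  }
  # neighborhood with the event bases present, so they count toward
  # run/unit lengths; for a deletion this reconstructs the reference
  # window, for an insertion it applies the insertion after the anchor
  left <- substr(window, 1L, anchor_offset)
  right <- substr(window, anchor_offset + nchar(ref) - nchar(alt) + 1L,
                  nchar(window))
  neigh <- paste0(left, event, right)
  ev_start <- nchar(left) + 1L
  ev_end <- nchar(left) + nchar(event)
  if (mono_run_length(neigh, ev_start, ev_end) >= 4L) {
    return("mononucleotide_repeat")
  }
  for (u in 2L:6L) {
    if (tandem_units(neigh, ev_start, ev_end, u) >= 3L) {
      return("microsatellite")
    }
  }
  "non_repeat"
}

# length of the maximal single-base run covering positions s..e
mono_run_length <- function(seq, s, e) {
  chars <- strsplit(seq, "")[[1L]]
  if (length(unique(chars[s:e])) != 1L) return(0L)
  b <- chars[s]
  i <- s
  while (i > 1L && chars[i - 1L] == b) i <- i - 1L
  j <- e
  while (j < length(chars) && chars[j + 1L] == b) j <- j + 1L
  j - i + 1L
}

# number of tandem copies of a u-bp unit in the maximal u-periodic tract
# [a, b] containing positions s..e; a tract satisfies
# chars[k] == chars[k + u] for every k in [a, b - u]
tandem_units <- function(seq, s, e, u) {
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  if (n < 2L * u) return(0L)
  periodic <- chars[seq_len(n - u)] == chars[seq_len(n - u) + u]
  if (e - u >= s && !all(periodic[s:(e - u)])) return(0L)
  a <- s
  b <- e
  while (a > 1L && (a - 1L + u > b || periodic[a - 1L])) a <- a - 1L
  while (b < n && (b + 1L - u < a || periodic[b + 1L - u])) b <- b + 1L
  (b - a + 1L) %/% u
}
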
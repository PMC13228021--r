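#' Collect heterozygous-site allele fractions
#'
#' Extracts alternate-allele read-support fractions from a variant table,
#' keeping sites with total depth at least `min_depth` whose support lies
#' strictly inside the heterozygous band. The band (default 0.10-0.90)
#' excludes homozygous sites per the 90% read-support rule and its mirror
#' on the reference side.
#'
#' @param sites Variant data frame (see [read_variant_table()]).
#' @param min_depth Minimum total depth (default 10).
#' @param band Numeric length-2 `(low, high)` fraction band
#'   (default `c(0.10, 0.90)`).
#' @param exclude_chroms Chromosomes to drop before collection (e.g.
#'   aneuploid chromosomes from a prior copy-number analysis).
#' @return Data frame with columns `fraction` and `depth`.
#' @export
collect_het_fractions <- function(sites, min_depth = 10L,
                                  band = c(0.10, 0.90),
                                  exclude_chroms = character(0)) {
  stopifnot(min_depth >= 1, length(band) == 2L,
            band[1L] >= 0, band[1L] < band[2L], band[2L] <= 1)
  if (length(exclude_chroms) > 0L) {
    sites <- sites[!sites$chrom %in% exclude_chroms, , drop = FALSE]
  }
  total <- sites$ref_depth + sites$alt_depth
  keep <- total >= min_depth
  frac <- sites$alt_depth / total
  keep <- keep & frac > band[1L] & frac < band[2L]
  data.frame(fraction = frac[keep], depth = total[keep])
}

# log-likelihood of alt counts under a uniform-weight mixture of
# Binomial(depth, a/c), a = 1..c-1
mixture_loglik <- function(alt, depth, c) {
  comps <- seq_len(c - 1L) / c
  ll <- vapply(comps, function(p) {
    stats::dbinom(alt, depth, p, log = TRUE)
  }, numeric(length(alt)))
  ll <- matrix(ll, nrow = length(alt))
  m <- apply(ll, 1L, max)
  sum(m + log(rowSums(exp(ll - m)) / (c - 1L)))
}

#' Fit ploidy from heterozygous allele fractions
#'
#' Models alternate read counts at heterozygous sites as a uniform-weight
#' mixture of `Binomial(depth, a/c)` components, `a = 1..c-1`, for each
#' candidate ploidy `c` in {2, 3, 4}: a diploid concentrates support at
#' 50%, a triploid at 33%/66%, a tetraploid at 25%/50%/75%. Candidates are
#' scored by log-likelihood penalized for component count
#' (`(c-1) * log(n)`); the best-scoring candidate wins, ties broken toward
#' smaller ploidy. The tetraploid a=2 component coincides with the diploid
#' mode, so tetraploid discrimination rests on the 25%/75% components; the
#' per-candidate scores are returned so borderline fits are visible.
#'
#' @param fractions Data frame from [collect_het_fractions()], or a
#'   numeric vector of fractions (then `depths` is required).
#' @param depths Total depths matched to `fractions` when the latter is a
#'   bare numeric vector.
#' @param min_sites Minimum usable sites; below it the call is
#'   `undetermined` (default 200).
#' @param strain Strain id carried into the result.
#' @return A list of class `ploidy_call`: `strain`, `ploidy` (integer or
#'   NA for undetermined), `n_sites`, and `scores` (named, per candidate).
#' @export
fit_ploidy <- function(fractions, depths = NULL, min_sites = 200L,
                       strain = NA_character_) {
  if (is.data.frame(fractions)) {
    depths <- fractions$depth
    fractions <- fractions$fraction
  }
  stopifnot(length(fractions) == length(depths))
  n <- length(fractions)
  candidates <- c(2L, 3L, 4L)
  if (n < min_sites) {
    return(structure(list(strain = strain, ploidy = NA_integer_,
                          n_sites = n,
                          scores = stats::setNames(rep(NA_real_, 3L),
                                                   paste0("score_", candidates))),
                     class = "ploidy_call"))
  }
  alt <- as.integer(round(fractions * depths))
  scores <- vapply(candidates, function(c) {
    mixture_loglik(alt, depths, c) - (c - 1L) * log(n)
  }, 0)
  names(scores) <- paste0("score_", candidates)
  best <- candidates[which.max(scores)]   # which.max takes first = smallest c
  structure(list(strain = strain, ploidy = best, n_sites = n,
                 scores = scores),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  p <- if (is.na(x$ploidy)) "undetermined" else x$ploidy
  cat("ploidy call:", p, "(", x$n_sites, "het sites )\n")
  if (!all(is.na(x$scores))) {
    print(round(x$scores, 2))
  }
  invisible(x)
}

#' Infer ploidy for one strain end to end
#'
#' Convenience wrapper: collects in-band heterozygous fractions and fits
#' the candidate ploidies.
#'
#' @inheritParams collect_het_fractions
#' @inheritParams fit_ploidy
#' @return A `ploidy_call`.
#' @export
infer_ploidy <- function(sites, min_depth = 10L, band = c(0.10, 0.90),
                         exclude_chroms = character(0), min_sites = 200L,
                         strain = NA_character_) {
  hf <- collect_het_fractions(sites, min_depth = min_depth, band = band,
                              exclude_chroms = exclude_chroms)
  fit_ploidy(hf, min_sites = min_sites, strain = strain)
}
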
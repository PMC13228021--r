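#' Relative biomass under stress
#'
#' Stress tolerance quantified as the ratio of biomass (optical density)
#' under a stress condition to biomass under the control condition.
#'
#' @param stress Biomass under stress (OD).
#' @param control Biomass under the control condition (OD), > 0.
#' @return The dimensionless ratio.
#' @export
relative_biomass <- function(stress, control) {
  if (any(control <= 0)) stop("control biomass must be positive")
  stress / control
}

#' Cluster stress conditions (or strains) hierarchically
#'
#' Agglomerative clustering of the phenotype-matrix columns with
#' correlation distance (1 - Pearson r) or Euclidean distance and average
#' or complete linkage. `stats::hclust` is deterministic given the input
#' column order, which serves as the tie-break.
#'
#' @param m Phenotype matrix (strains x conditions).
#' @param linkage `"average"` (default) or `"complete"`.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param cut_height Optional dendrogram cut height for flat clusters;
#'   when NULL no flat clusters are produced.
#' @param k Optional flat cluster count (alternative to `cut_height`).
#' @return List with `hclust` (the dendrogram), `order` (column order)
#'   and `clusters` (named integer vector, NULL unless a cut was
#'   requested).
#' @export
cluster_conditions <- function(m, linkage = c("average", "complete"),
                               distance = c("correlation", "euclidean"),
                               cut_height = NULL, k = NULL) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (ncol(m) < 2L) stop("need at least 2 conditions to cluster")
  if (distance == "correlation") {
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant column under correlation distance: ",
           colnames(m)[which(sds == 0)[1L]])
    }
    d <- stats::as.dist(1 - stats::cor(m))
  } else {
    d <- stats::dist(t(m))
  }
  hc <- stats::hclust(d, method = linkage)
  clusters <- NULL
  if (!is.null(cut_height)) {
    clusters <- stats::cutree(hc, h = cut_height)
  } else if (!is.null(k)) {
    clusters <- stats::cutree(hc, k = k)
  }
  list(hclust = hc, order = colnames(m)[hc$order], clusters = clusters)
}

#' Length of the fermentation period from CO2 loss
#'
#' The fermentation period ends at the first time point whose CO2-loss
#' increment over the preceding interval falls below `epsilon` (the
#' plateau), falling back to the last sampled time when no plateau is
#' reached.
#'
#' @param series Per-strain data frame (`time`, `co2_loss`) from
#'   [read_fermentation_series()].
#' @param epsilon Plateau increment threshold in g/100 mL (default 0.05).
#' @return Duration in hours.
#' @export
fermentation_period <- function(series, epsilon = 0.05) {
  t <- series$time
  inc <- diff(series$co2_loss)
  flat <- which(inc < epsilon)
  if (length(flat) > 0L) t[flat[1L] + 1L] else t[length(t)]
}

#' Fermentation rate as midpoint ethanol titer
#'
#' The rate proxy is the ethanol titer at the midpoint of the
#' fermentation period, linearly interpolated between the two sampled
#' ethanol time points spanning the midpoint.
#'
#' @param series Per-strain data frame (`time`, `ethanol`; NA ethanol
#'   entries are ignored).
#' @param duration Total fermentation period in hours; when NULL it is
#'   derived from the CO2 plateau via [fermentation_period()].
#' @return Ethanol titer (g/L) at `duration / 2`.
#' @export
fermentation_rate <- function(series, duration = NULL) {
  eth <- series[!is.na(series$ethanol), , drop = FALSE]
  if (nrow(eth) < 2L) stop("need at least 2 ethanol time points")
  if (is.null(duration)) duration <- fermentation_period(series)
  mid <- duration / 2
  if (mid < min(eth$time) || mid > max(eth$time)) {
    stop("midpoint ", mid, " h outside the sampled ethanol range")
  }
  stats::approx(eth$time, eth$ethanol, xout = mid, ties = "ordered")$y
}

#' Sugar-to-product conversion efficiency
#'
#' @param produced Product formed (g/L), e.g. ethanol or glycerol.
#' @param consumed Sugar consumed (g/L), > 0.
#' @return Grams of product per gram of sugar.
#' @export
conversion_efficiency <- function(produced, consumed) {
  if (any(consumed <= 0)) stop("sugar consumed must be positive")
  produced / consumed
}

#' Correlate stress tolerance with a fermentation metric
#'
#' Pearson correlation of a per-strain fermentation metric (e.g. midpoint
#' ethanol titer, final titer, byproduct concentration) against each
#' condition column of the phenotype matrix. Strains missing either value
#' are dropped pairwise (counts reported); an optional permutation test
#' (shuffling the metric across strains) yields per-condition p-values.
#'
#' @param m Phenotype matrix (strains x conditions, rownames = strains).
#' @param metric Named numeric vector of the fermentation metric
#'   (names = strains).
#' @param n_permutations Permutation count for p-values (0 = skip;
#'   default 0).
#' @param adjust If TRUE, Benjamini-Hochberg-adjust the permutation
#'   p-values (default FALSE: raw r values are the primary output).
#' @param seed Optional seed for the permutation test.
#' @return Data frame `condition`, `r`, `n_used`, and `p` /`p_adj` when
#'   permutations were requested. Zero-variance conditions report
#'   `r = NA`.
#' @export
tolerance_fermentation_correlation <- function(m, metric,
                                               n_permutations = 0L,
                                               adjust = FALSE,
                                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  common <- intersect(rownames(m), names(metric))
  if (length(common) < 3L) stop("need at least 3 strains with both values")
  dropped <- nrow(m) - length(common)
  if (dropped > 0L) message(dropped, " strain(s) without metric dropped")
  m <- m[common, , drop = FALSE]
  v <- metric[common]
  rows <- lapply(colnames(m), function(cond) {
    x <- m[, cond]
    ok <- !is.na(x) & !is.na(v)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(v[ok]) == 0) {
      return(data.frame(condition = cond, r = NA_real_, n_used = sum(ok),
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    r <- stats::cor(x[ok], v[ok])
    p <- NA_real_
    if (n_permutations > 0L) {
      null <- vapply(seq_len(n_permutations), function(...) {
        stats::cor(x[ok], sample(v[ok]))
      }, 0)
      p <- (1 + sum(abs(null) >= abs(r))) / (1 + n_permutations)
    }
    data.frame(condition = cond, r = r, n_used = sum(ok), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (n_permutations == 0L) out$p <- NULL
  else if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
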
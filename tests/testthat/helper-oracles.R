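# Independent brute-force oracles. These re-derive the same definitions as
# the package from first principles, without sharing code paths.

# Needleman-Wunsch identity: plain-R DP with the same scoring and the same
# traceback tie-break (diagonal, then up, then left)
nw_identity_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  dp <- matrix(0, n + 1, m + 1)
  dp[1, ] <- gap * (0:m)
  dp[, 1] <- gap * (0:n)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (x[i] == y[j]) match else mismatch
      dp[i + 1, j + 1] <- max(dp[i, j] + s, dp[i, j + 1] + gap,
                              dp[i + 1, j] + gap)
    }
  }
  i <- n; j <- m; matches <- 0; columns <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        dp[i + 1, j + 1] ==
          dp[i, j] + (if (x[i] == y[j]) match else mismatch)) {
      if (x[i] == y[j]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && dp[i + 1, j + 1] == dp[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    columns <- columns + 1
  }
  100 * matches / columns
}

# maximal tolerant runs: enumerate every interval, test the definition
# directly, drop intervals contained in a larger valid one
tolerant_runs_oracle <- function(hom, max_het_rate) {
  n <- length(hom)
  valid <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!hom[i] || !hom[j]) next
      inside <- hom[i:j]
      het_idx <- which(!inside)
      if (length(het_idx) > 1 && any(diff(het_idx) == 1)) next
      if (length(het_idx) > max_het_rate * (j - i + 1)) next
      valid[[length(valid) + 1]] <- c(i, j)
    }
  }
  if (length(valid) == 0) return(matrix(integer(0), ncol = 2))
  v <- do.call(rbind, valid)
  keep <- vapply(seq_len(nrow(v)), function(k) {
    !any(v[, 1] <= v[k, 1] & v[, 2] >= v[k, 2] &
           (v[, 1] < v[k, 1] | v[, 2] > v[k, 2]))
  }, TRUE)
  v[keep, , drop = FALSE]
}

# symmetric-difference size over hashed SNV records
snv_distance_oracle <- function(a, b) {
  h <- function(s) {
    snv <- nchar(s$ref) == 1 & nchar(s$alt) == 1
    unique(paste(s$chrom[snv], s$pos[snv], s$alt[snv]))
  }
  length(union(h(a), h(b))) - length(intersect(h(a), h(b)))
}
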
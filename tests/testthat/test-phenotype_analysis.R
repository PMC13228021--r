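test_that("relative biomass is the stress/control ratio and scale-invariant", {
  expect_equal(relative_biomass(0.6, 1.2), 0.5)
  expect_equal(relative_biomass(1.2, 1.2), 1.0)
  expect_error(relative_biomass(0.5, 0), "positive")
  set.seed(30)
  for (k in 1:10) {
    s <- runif(1, 0.1, 2); ctrl <- runif(1, 0.5, 2); a <- runif(1, 0.1, 10)
    expect_equal(relative_biomass(a * s, a * ctrl),
                 relative_biomass(s, ctrl))
  }
})

block_matrix <- function(n_strains = 41, block1 = 4, block2 = 4,
                         within_r = 0.9) {
  load1 <- rnorm(n_strains)
  load2 <- rnorm(n_strains)
  w <- sqrt(within_r)
  cols <- cbind(
    sapply(seq_len(block1), function(i) w * load1 +
             sqrt(1 - within_r) * rnorm(n_strains)),
    sapply(seq_len(block2), function(i) w * load2 +
             sqrt(1 - within_r) * rnorm(n_strains)))
  colnames(cols) <- c(paste0("a", seq_len(block1)),
                      paste0("b", seq_len(block2)))
  rownames(cols) <- paste0("F", seq_len(n_strains))
  cols + 2  # keep entries positive like relative biomass
}

test_that("identical condition columns merge first at distance zero", {
  set.seed(31)
  m <- block_matrix()
  m <- cbind(m, dup = m[, "a1"])
  cl <- cluster_conditions(m)
  h <- cl$hclust
  first <- sort(h$labels[-h$merge[1, ]])
  expect_equal(first, c("a1", "dup"))
  expect_equal(h$height[1], 0, tolerance = 1e-12)
})

test_that("planted condition blocks are recovered as flat clusters", {
  set.seed(32)
  ok <- 0L
  for (r in 1:40) {
    m <- block_matrix()
    cl <- cluster_conditions(m, k = 2)$clusters
    same_a <- length(unique(cl[paste0("a", 1:4)])) == 1
    same_b <- length(unique(cl[paste0("b", 1:4)])) == 1
    split <- cl[["a1"]] != cl[["b1"]]
    if (same_a && same_b && split) ok <- ok + 1L
  }
  expect_gte(ok / 40, 0.95)
})

test_that("degenerate clustering inputs are rejected", {
  m <- block_matrix()
  expect_error(cluster_conditions(m[, 1, drop = FALSE]), "at least 2")
  m[, "a2"] <- 1
  expect_error(cluster_conditions(m), "a2")
})

test_that("fermentation rate interpolates the midpoint ethanol titer", {
  s <- data.frame(time = c(0, 96), co2_loss = c(0, 8),
                  ethanol = c(0, 100))
  expect_equal(fermentation_rate(s, duration = 96), 50)
  s2 <- data.frame(time = c(0, 48, 96), co2_loss = c(0, 6, 8),
                   ethanol = c(0, 70, 100))
  expect_equal(fermentation_rate(s2, duration = 96), 70)
  s3 <- data.frame(time = 48, co2_loss = 4, ethanol = 55)
  expect_error(fermentation_rate(s3, duration = 96), "at least 2")
  s4 <- data.frame(time = c(60, 96), co2_loss = c(5, 8),
                   ethanol = c(80, 100))
  expect_error(fermentation_rate(s4, duration = 96), "outside")
})

test_that("the fermentation period ends at the CO2 plateau", {
  s <- data.frame(time = seq(0, 96, 8),
                  co2_loss = c(0, 1, 2.5, 4, 5, 5.8, 6.4, 6.8, 6.82,
                               6.83, 6.84, 6.85, 6.86),
                  ethanol = NA)
  expect_equal(fermentation_period(s), 64)
  ramp <- data.frame(time = seq(0, 96, 8),
                     co2_loss = seq(0, 12, 1), ethanol = NA)
  expect_equal(fermentation_period(ramp), 96)
})

test_that("conversion efficiency reproduces the published bounds", {
  expect_equal(conversion_efficiency(96, 200), 0.48)
  expect_equal(conversion_efficiency(84, 200), 0.42)
  expect_equal(conversion_efficiency(0, 200), 0)
  expect_error(conversion_efficiency(10, 0), "positive")
})

test_that("tolerance-fermentation correlation handles exact and degenerate cases", {
  set.seed(33)
  m <- block_matrix()
  metric <- m[, "a1"]
  out <- tolerance_fermentation_correlation(m, metric)
  expect_equal(out$r[out$condition == "a1"], 1.0)
  out2 <- tolerance_fermentation_correlation(m, -metric)
  expect_equal(out2$r[out2$condition == "a1"], -1.0)
  m2 <- cbind(m, flat = 1)
  out3 <- suppressMessages(tolerance_fermentation_correlation(m2, metric))
  expect_true(is.na(out3$r[out3$condition == "flat"]))
})

test_that("Pearson r is affine-invariant and sign-flips under negation", {
  set.seed(34)
  m <- block_matrix()
  v <- rnorm(41) + m[, "b2"]
  names(v) <- rownames(m)
  base <- tolerance_fermentation_correlation(m, v)$r
  scaled <- tolerance_fermentation_correlation(m, 3 * v + 7)$r
  expect_equal(scaled, base)
  flipped <- tolerance_fermentation_correlation(m, -v)$r
  expect_equal(flipped, -base)
})

test_that("a planted correlation of 0.4 over 41 strains is estimated well", {
  set.seed(35)
  hits <- 0L
  for (r in 1:50) {
    z <- rnorm(41)
    x <- sqrt(0.4) * z + sqrt(0.6) * rnorm(41)
    y <- sqrt(0.4) * z + sqrt(0.6) * rnorm(41)
    m <- matrix(x + 3, ncol = 1,
                dimnames = list(paste0("F", 1:41), "cond"))
    names(y) <- rownames(m)
    est <- tolerance_fermentation_correlation(m, y)$r
    if (abs(est - 0.4) <= 0.25) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.85)
})

test_that("permutation p-values flag a strong association", {
  set.seed(36)
  m <- block_matrix()
  v <- m[, "a1"] + rnorm(41, sd = 0.1)
  names(v) <- rownames(m)
  out <- tolerance_fermentation_correlation(m, v, n_permutations = 500L,
                                            seed = 1)
  expect_lt(out$p[out$condition == "a1"], 0.01)
  out_adj <- tolerance_fermentation_correlation(m, v,
                                                n_permutations = 200L,
                                                adjust = TRUE, seed = 2)
  expect_true(all(out_adj$p_adj >= out_adj$p, na.rm = TRUE))
})
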
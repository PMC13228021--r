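lay <- tiny_layout()

site <- function(support, depth = 10000L) {
  alt <- as.integer(round(support * depth))
  data.frame(chrom = "chrA", pos = 100L, ref = "A", alt = "G",
             ref_depth = depth - alt, alt_depth = alt,
             annotation = NA_character_, stringsAsFactors = FALSE)
}

test_that("the 90% rule is inclusive and two-sided", {
  expect_equal(classify_zygosity(site(0.95))$state, "homozygous")
  expect_equal(classify_zygosity(site(0.90))$state, "homozygous")
  expect_equal(classify_zygosity(site(0.8999))$state, "heterozygous")
  expect_equal(classify_zygosity(site(0.50))$state, "heterozygous")
  expect_equal(classify_zygosity(site(0.10))$state, "homozygous")
  expect_equal(classify_zygosity(site(0.1001))$state, "heterozygous")
})

test_that("zygosity is symmetric under support -> 1 - support", {
  set.seed(8)
  for (s in runif(50)) {
    expect_equal(classify_zygosity(site(s))$state,
                 classify_zygosity(site(1 - s))$state)
  }
})

test_that("zero-depth sites are an error and shallow sites are dropped", {
  s <- site(0.5)
  s$ref_depth <- 0L; s$alt_depth <- 0L
  expect_error(classify_zygosity(s), "zero-depth")
  s2 <- site(0.5, depth = 4L)
  expect_equal(nrow(classify_zygosity(s2, min_depth = 10L)), 0L)
})

test_that("homozygous runs segment with tolerated isolated interruptions", {
  pure <- calls_from_hom(rep(TRUE, 100))
  seg <- segment_homozygous_runs(pure)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_sites, 100L)

  short <- calls_from_hom(rep(TRUE, 9))
  expect_equal(nrow(segment_homozygous_runs(short)), 0L)

  interrupted <- calls_from_hom(c(rep(TRUE, 50), FALSE, rep(TRUE, 50)))
  seg2 <- segment_homozygous_runs(interrupted)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$n_sites, 101L)
})

test_that("segmentation matches the brute-force tolerant-run enumerator", {
  set.seed(77)
  for (rep in 1:100) {
    hom <- runif(sample(20:60, 1)) < 0.75
    calls <- calls_from_hom(hom)
    got <- segment_homozygous_runs(calls, min_sites = 1L)
    want <- tolerant_runs_oracle(hom, 1 / 50)
    want <- want[order(want[, 1]), , drop = FALSE]
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, (want[, 1] * 300L) - 1L)  # pos = index * 300
    expect_equal(got$end, want[, 2] * 300L)
  }
})

test_that("positional classes separate interstitial, terminal and UPD", {
  hom <- c(rep(FALSE, 5), rep(TRUE, 20), rep(FALSE, 40),
           rep(TRUE, 15), rep(FALSE, 2))
  calls <- calls_from_hom(hom, chrom = "chrA", spacing = 1000L)
  calls$pos <- calls$pos  # spans most of chrA
  segs <- segment_homozygous_runs(calls)
  segs <- classify_loh_segments(segs, calls, lay)
  expect_equal(segs$class, c("interstitial", "terminal"))

  upd_calls <- calls_from_hom(rep(TRUE, 80), chrom = "chrB", spacing = 700L)
  upd_seg <- classify_loh_segments(segment_homozygous_runs(upd_calls),
                                   upd_calls, lay)
  expect_equal(upd_seg$class, "upd")

  expect_error(classify_loh_segments(
    data.frame(chrom = "chrZZ", start = 0L, end = 10L, n_sites = 10L,
               mean_support = 1, class = NA_character_),
    upd_calls, lay), "unknown")
})

test_that("planted LOH tracts of all three classes are recovered", {
  cfg <- simulation_config()
  n_ok <- 0L; n_total <- 0L
  for (r in 1:6) {
    loh <- data.frame(
      chrom = c("chrII", "chrIV", "chrV"),
      start = c(30000L, 0L, 0L),
      end = c(34000L + r * 3000L, 8000L + r * 1000L,
              cfg$layout$length[cfg$layout$chrom == "chrV"]),
      class = c("interstitial", "terminal", "upd"))
    sim <- simulate_strain(cfg, strain_spec(paste0("L", r), ploidy = 2L,
                                            loh = loh), seed = 300L + r)
    z <- classify_zygosity(sim$variants)
    segs <- classify_loh_segments(segment_homozygous_runs(z), z, cfg$layout)
    for (k in seq_len(nrow(loh))) {
      n_total <- n_total + 1L
      hit <- segs[segs$chrom == loh$chrom[k] &
                    segs$end > loh$start[k] & segs$start < loh$end[k], ]
      if (nrow(hit) == 1L && hit$class == loh$class[k]) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_total, 0.95)
})

test_that("homozygosity fraction is length-weighted and bounded", {
  spans <- data.frame(chrom = "chrA", first_pos = 1L, last_pos = 100000L,
                      n_sites = 300L)
  seg <- data.frame(chrom = "chrA", start = 0L, end = 50000L,
                    n_sites = 150L, mean_support = 1, class = "terminal")
  expect_equal(homozygosity_fraction(seg, spans), 0.5, tolerance = 1e-4)
  expect_equal(homozygosity_fraction(seg[0, ], spans), 0)
  expect_true(is.na(homozygosity_fraction(seg, spans[0, ])))
})

test_that("homozygosity fraction grows with planted tract length", {
  cfg <- simulation_config()
  fracs <- vapply(1:4, function(k) {
    loh <- data.frame(chrom = "chrIV", start = 10000L,
                      end = 10000L + k * 25000L, class = "interstitial")
    sim <- simulate_strain(cfg, strain_spec("lad", ploidy = 2L, loh = loh),
                           seed = 55L)
    z <- classify_zygosity(sim$variants)
    homozygosity_fraction(segment_homozygous_runs(z), assessed_spans(z))
  }, 0)
  expect_true(all(diff(fracs) > 0))
})

test_that("positional statistic separates telomeric from uniform placement", {
  set.seed(12)
  spans <- data.frame(chrom = lay$chrom, first_pos = 1L,
                      last_pos = lay$length, n_sites = 100L)
  telo <- data.frame(chrom = rep(lay$chrom, 2),
                     start = c(rep(0L, 3), lay$length - 2000L),
                     end = c(rep(2000L, 3), lay$length),
                     n_sites = 20L, mean_support = 1,
                     class = "terminal", stringsAsFactors = FALSE)
  pat <- loh_pattern_statistic(telo, lay, spans, seed = 1)
  expect_equal(pat$pattern, "mitotic-dominated")
  expect_lt(pat$p_value, 0.05)

  unif <- data.frame(chrom = rep(lay$chrom[1], 6),
                     start = s <- as.integer(seq(5000, 80000, length.out = 6)),
                     end = s + 3000L, n_sites = 20L, mean_support = 1,
                     class = "interstitial", stringsAsFactors = FALSE)
  pat2 <- loh_pattern_statistic(unif, lay, spans, seed = 2)
  expect_equal(pat2$pattern, "meiotic-dominated")
})

test_that("an almost fully homozygous genome is reported as such", {
  spans <- data.frame(chrom = lay$chrom, first_pos = 1L,
                      last_pos = lay$length, n_sites = 100L)
  full <- data.frame(chrom = lay$chrom, start = 0L, end = lay$length,
                     n_sites = 100L, mean_support = 1, class = "upd",
                     stringsAsFactors = FALSE)
  pat <- loh_pattern_statistic(full, lay, spans)
  expect_equal(pat$pattern, "fully-homozygous")
  expect_gte(pat$hom_fraction, 0.99)
})

test_that("mitotic-dominated false-positive rate on uniform placement is low", {
  set.seed(400)
  fp <- 0L
  spans <- data.frame(chrom = lay$chrom, first_pos = 1L,
                      last_pos = lay$length, n_sites = 100L)
  for (r in 1:200) {
    n_seg <- sample(4:10, 1)
    chrom <- sample(lay$chrom, n_seg, replace = TRUE)
    len <- sample(1000:5000, n_seg, replace = TRUE)
    maxs <- lay$length[match(chrom, lay$chrom)] - len
    start <- as.integer(floor(runif(n_seg) * maxs))
    segs <- data.frame(chrom = chrom, start = start, end = start + len,
                       n_sites = 10L, mean_support = 1,
                       class = "interstitial", stringsAsFactors = FALSE)
    pat <- loh_pattern_statistic(segs, lay, spans, n_permutations = 200L)
    if (pat$pattern == "mitotic-dominated") fp <- fp + 1L
  }
  expect_lte(fp / 200, 0.07)
})
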
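lay <- tiny_layout()

test_that("whole-chromosome copy calls follow median normalized depth", {
  # chrA (the largest chromosome) anchors the genome-wide median
  w <- normalize_coverage(flat_windows(lay, ratio = c(1.0, 1.5, 0.5)))
  calls <- call_chromosome_copies(w, baseline_ploidy = 2L)
  expect_equal(calls$state[calls$chrom == "chrA"], "euploid")
  expect_equal(calls$copy_number[calls$chrom == "chrB"], 3)
  expect_equal(calls$state[calls$chrom == "chrB"], "trisomy_like_gain")
  expect_equal(calls$copy_number[calls$chrom == "chrC"], 1)
  expect_equal(calls$state[calls$chrom == "chrC"], "monosomy_like_loss")
})

test_that("chromosomes with too few windows are skipped with a warning", {
  w <- normalize_coverage(data.frame(
    chrom = c(rep("chrA", 5), "chrB", "chrB"),
    start = c(seq(0, 4000, 1000), 0, 1000),
    end = c(seq(1000, 5000, 1000), 1000, 2000),
    depth = 50))
  expect_warning(calls <- call_chromosome_copies(w, 2L), "chrB")
  expect_false("chrB" %in% calls$chrom)
})

test_that("low window agreement is reported euploid, not called", {
  # chrA alternates between 2 and 4 copies (a mixed/subclonal state whose
  # median rounds to 3); chrB and chrC anchor the median
  w <- flat_windows(lay, ratio = 1)
  on_a <- which(w$chrom == "chrA")
  w$depth[on_a[seq(1, length(on_a), 2)]] <- 100
  w <- normalize_coverage(w)
  calls <- call_chromosome_copies(w, 2L)
  a <- calls[calls$chrom == "chrA", ]
  expect_equal(a$state, "euploid")
  expect_lt(a$support, 0.8)
})

test_that("planted segmental CNVs are recovered within one window", {
  cfg <- simulation_config()
  cnv <- data.frame(chrom = c("chrIII", "chrX", "chrX"),
                    start = c(0L, 20000L, 40000L),
                    end = c(12000L, 24000L, 45000L),
                    delta = c(1L, -1L, -1L))
  sim <- simulate_strain(cfg, strain_spec("cnv", ploidy = 2L, cnv = cnv),
                         seed = 21L)
  calls <- call_chromosome_copies(sim$coverage, 2L)
  segs <- detect_segmental_cnv(sim$coverage, calls, cfg$layout, 2L)
  expect_equal(nrow(segs), 3L)
  for (k in seq_len(nrow(cnv))) {
    hit <- segs[segs$chrom == cnv$chrom[k] &
                  abs(segs$start - cnv$start[k]) <= 1000 &
                  abs(segs$end - cnv$end[k]) <= 1000, ]
    expect_equal(nrow(hit), 1L, label = paste("segment", k, "recovered"))
  }
  expect_equal(segs$class[segs$start == 0L], "terminal_duplication")
  expect_setequal(segs$class[segs$chrom == "chrX"],
                  "interstitial_deletion")
})

test_that("a flat genome yields no segments", {
  w <- normalize_coverage(flat_windows(lay))
  calls <- call_chromosome_copies(w, 2L)
  expect_equal(nrow(detect_segmental_cnv(w, calls, lay, 2L)), 0L)
})

test_that("positional classification distinguishes terminal from interstitial", {
  big <- genome_layout("chr1", 1000000L, 400000L)
  expect_equal(classify_segment_position("chr1", 0L, 12000L, big), "terminal")
  expect_equal(classify_segment_position("chr1", 300000L, 310000L, big),
               "interstitial")
  expect_equal(classify_segment_position("chr1", 988000L, 1000000L, big),
               "terminal")
  expect_error(classify_segment_position("chr1", 990000L, 1090000L, big),
               "outside")
  expect_error(classify_segment_position("chrNope", 0L, 10L, big), "unknown")
})

test_that("breakpoints are labeled with nearby repeat features", {
  segs <- data.frame(chrom = "chrA", start = 10000L, end = 20000L,
                     class = "interstitial_duplication",
                     stringsAsFactors = FALSE)
  reps <- data.frame(chrom = "chrA",
                     start = c(9990L, 50000L),
                     end = c(9995L, 50100L),
                     class = c("LTR", "Ty"), stringsAsFactors = FALSE)
  ann <- annotate_breakpoint_repeats(segs, reps, flank = 1000L)
  expect_equal(ann$start_repeat, "LTR")
  expect_equal(ann$end_repeat, "none")
  expect_equal(attr(ann, "repeat_fraction"), 0.5)

  # breakpoints placed exactly at repeat coordinates are all associated
  reps2 <- data.frame(chrom = "chrA", start = c(10000L, 20000L),
                      end = c(10300L, 20300L), class = c("Ty", "LTR"),
                      stringsAsFactors = FALSE)
  ann2 <- annotate_breakpoint_repeats(segs, reps2, flank = 1000L)
  expect_equal(attr(ann2, "repeat_fraction"), 1.0)
})

test_that("doubling raw depth changes no call (normalization invariance)", {
  cfg <- simulation_config()
  sim <- simulate_strain(cfg, strain_spec(
    "inv", ploidy = 2L,
    aneuploidy = data.frame(chrom = "chrI", delta = 1L),
    cnv = data.frame(chrom = "chrX", start = 0L, end = 8000L, delta = 1L)),
    seed = 13L)
  w <- sim$coverage
  w2 <- w
  w2$depth <- w2$depth * 2
  w2 <- normalize_coverage(w2[c("chrom", "start", "end", "depth")])
  c1 <- call_chromosome_copies(w, 2L)
  c2 <- call_chromosome_copies(w2, 2L)
  expect_equal(c1, c2)
  s1 <- detect_segmental_cnv(w, c1, cfg$layout, 2L)
  s2 <- detect_segmental_cnv(w2, c2, cfg$layout, 2L)
  expect_equal(s1, s2)
})
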
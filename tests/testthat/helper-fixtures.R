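# Shared fixtures built in code.

tiny_layout <- function() {
  genome_layout(chrom = c("chrA", "chrB", "chrC"),
                length = c(100000L, 60000L, 40000L),
                centromere = c(40000L, 20000L, 15000L))
}

# coverage windows at a constant norm level with optional per-chromosome
# copy ratios
flat_windows <- function(layout, width = 1000L, ratio = 1) {
  ratio <- rep_len(ratio, nrow(layout))
  do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    starts <- seq.int(0L, layout$length[i] - 1L, by = width)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + width, layout$length[i]),
               depth = 50 * ratio[i], stringsAsFactors = FALSE)
  }))
}

# zygosity-call frame from a logical homozygosity vector on one chromosome
calls_from_hom <- function(hom, chrom = "chrA", spacing = 300L) {
  data.frame(chrom = chrom, pos = seq_along(hom) * spacing,
             support = ifelse(hom, 0.98, 0.5),
             state = ifelse(hom, "homozygous", "heterozygous"),
             stringsAsFactors = FALSE)
}

random_variant_table <- function(n, chroms = c("chrA", "chrB")) {
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(1e5, n)
  ref <- sample(bases, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    pos = pos,
    ref = ref,
    alt = vapply(ref, function(b) sample(setdiff(bases, b), 1), ""),
    ref_depth = sample.int(100L, n),
    alt_depth = sample.int(100L, n),
    annotation = sample(c("synonymous", "missense", "noncoding"), n,
                        replace = TRUE),
    stringsAsFactors = FALSE
  )
}
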
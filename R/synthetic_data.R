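#' Default scaled Saccharomyces cerevisiae genome layout
#'
#' The 16 nuclear chromosomes with real relative lengths and centromere
#' positions, scaled (default 1/10, ~1.2 Mb total) so that full-pipeline
#' simulations run in seconds while size-dependent phenomena (small
#' chromosomes being most often aneuploid, arm-length asymmetry around
#' centromeres) remain representable.
#'
#' @param scale Linear scale factor applied to real chromosome coordinates.
#' @return A [genome_layout()].
#' @export
yeast_layout <- function(scale = 0.1) {
  len_kb <- c(230, 813, 316, 1532, 577, 270, 1091, 562,
              439, 746, 667, 1078, 924, 784, 1091, 948)
  cen_kb <- c(151, 238, 114, 450, 152, 148, 497, 105,
              355, 436, 440, 151, 268, 629, 327, 556)
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
             "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")
  genome_layout(
    chrom = paste0("chr", roman),
    length = as.integer(round(len_kb * 1000 * scale)),
    centromere = as.integer(round(cen_kb * 1000 * scale))
  )
}

#' Simulation configuration
#'
#' Bundles the genome layout and sampling parameters shared by all strains
#' of a simulated collection.
#'
#' @param layout Genome layout; default [yeast_layout()].
#' @param het_density Heterozygous SNVs per bp (default 1/300).
#' @param mean_depth Mean sequencing depth at baseline copy number
#'   (default 80).
#' @param window Coverage window width in bp (default 1000 at simulation
#'   scale, i.e. 10 kb at real scale).
#' @param read_length Read length used to convert window depth into a
#'   Poisson read count (default 100).
#' @param residual_error Residual alternate-allele error rate at homozygous
#'   sites: support is sampled at `1 - residual_error` (alt-homozygous) or
#'   `residual_error` (ref-homozygous) rather than 1 or 0, so the 90%
#'   zygosity rule is exercised non-trivially (default 0.005).
#' @param coding_fraction Fraction of SNVs labeled as coding
#'   (default 0.65).
#' @param syn_missense_ratio Ratio of synonymous to missense labels among
#'   coding SNVs (default 1.8).
#' @param indel_repeat_fraction Fraction of planted InDels placed in repeat
#'   context (default 0.82).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(layout = yeast_layout(),
                              het_density = 1 / 300,
                              mean_depth = 80,
                              window = 1000L,
                              read_length = 100L,
                              residual_error = 0.005,
                              coding_fraction = 0.65,
                              syn_missense_ratio = 1.8,
                              indel_repeat_fraction = 0.82) {
  stopifnot(het_density > 0, mean_depth > 0, window >= 1,
            residual_error >= 0, residual_error < 0.5,
            indel_repeat_fraction >= 0, indel_repeat_fraction <= 1)
  structure(list(layout = layout, het_density = het_density,
                 mean_depth = mean_depth, window = as.integer(window),
                 read_length = as.integer(read_length),
                 residual_error = residual_error,
                 coding_fraction = coding_fraction,
                 syn_missense_ratio = syn_missense_ratio,
                 indel_repeat_fraction = indel_repeat_fraction),
            class = "simulation_config")
}

#' Sample alternate-allele read support at heterozygous sites
#'
#' The sampling model behind every simulated heterozygous site: a site
#' carrying `alt_copies` alternate copies out of `total_copies` homologs,
#' sequenced to `depth` reads, yields
#' `alt_depth ~ Binomial(depth, alt_copies / total_copies)`. In a diploid
#' the expected support is 50%; in a triploid, 1/3 or 2/3 depending on
#' dosage.
#'
#' @param n Number of sites.
#' @param depth Read depth per site (scalar or vector of length `n`).
#' @param alt_copies Alternate-allele copy count.
#' @param total_copies Total copy count (local copy number).
#' @return Data frame with columns `depth`, `alt_depth`, `support`.
#' @export
simulate_het_support <- function(n, depth, alt_copies, total_copies) {
  stopifnot(n >= 0, alt_copies >= 1, alt_copies < total_copies)
  depth <- rep_len(depth, n)
  alt <- stats::rbinom(n, depth, alt_copies / total_copies)
  data.frame(depth = depth, alt_depth = alt, support = alt / depth)
}

#' Modal read-support percentage over sites
#'
#' Histograms support fractions into 1%-wide bins centered on integer
#' percentages (nearest-percent rounding) and returns the modal bin; ties
#' resolve to the smallest percentage. In a triploid the heterozygous
#' modes sit at the 33%/67% bins, in a diploid at 50%.
#'
#' @param support Numeric vector of alt-support fractions in \[0, 1\].
#' @return Integer percent of the modal bin.
#' @export
modal_support_percent <- function(support) {
  pct <- round(100 * support)
  tab <- table(pct)
  as.integer(names(tab)[which.max(tab)])
}

#' Specify one simulated strain
#'
#' @param id Strain identifier.
#' @param ploidy Baseline ploidy, one of 2, 3, 4.
#' @param aneuploidy Data frame `chrom`, `delta` (whole-chromosome copy
#'   changes; +1 trisomy-like, -1 monosomy-like), or NULL.
#' @param loh Data frame `chrom`, `start`, `end`, `class`
#'   (`interstitial`, `terminal` or `upd`), 0-based half-open, or NULL.
#'   `upd` tracts must span the whole chromosome.
#' @param cnv Data frame `chrom`, `start`, `end`, `delta` (segmental copy
#'   changes), or NULL.
#' @param n_hgt Number of horizontally acquired genes to plant on extra
#'   contigs (default 0).
#' @param hgt_identity Nucleotide identity of planted HGT genes to their
#'   reference ORFs (default 0.8).
#' @param n_indels Number of InDels to plant (default 0; requires a
#'   reference sequence, generated on demand).
#' @return A list of class `strain_spec`.
#' @export
strain_spec <- function(id, ploidy = 2L, aneuploidy = NULL, loh = NULL,
                        cnv = NULL, n_hgt = 0L, hgt_identity = 0.8,
                        n_indels = 0L) {
  if (!ploidy %in% c(2L, 3L, 4L)) stop("ploidy must be 2, 3 or 4")
  structure(list(id = id, ploidy = as.integer(ploidy),
                 aneuploidy = aneuploidy, loh = loh, cnv = cnv,
                 n_hgt = as.integer(n_hgt), hgt_identity = hgt_identity,
                 n_indels = as.integer(n_indels)),
            class = "strain_spec")
}

check_tracts <- function(tr, layout, what) {
  if (is.null(tr) || nrow(tr) == 0L) return(invisible())
  i <- match(tr$chrom, layout$chrom)
  if (anyNA(i)) stop(what, " on unknown chromosome")
  if (any(tr$start < 0 | tr$end > layout$length[i] | tr$end <= tr$start)) {
    stop(what, " tract outside chromosome bounds")
  }
  invisible()
}

local_copy_number <- function(pos, chrom_copies, cnv, chrom) {
  cn <- rep.int(chrom_copies, length(pos))
  if (!is.null(cnv) && nrow(cnv) > 0L) {
    here <- cnv[cnv$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(here))) {
      inside <- pos >= here$start[k] & pos < here$end[k]
      cn[inside] <- cn[inside] + here$delta[k]
    }
  }
  pmax(cn, 0L)
}

#' Simulate one strain
#'
#' Emits the variant table, coverage windows, optional extra contigs and a
#' ground-truth record for a strain with known ploidy, aneuploidies, LOH
#' tracts, segmental CNVs and HGT genes.
#'
#' Sampling model: per-site depth ~ Poisson(mean depth x local copy number /
#' baseline ploidy); at a heterozygous site with `a` alternate copies of `c`
#' total, alt_depth ~ Binomial(depth, a/c); sites inside LOH tracts are
#' homozygous and sample support at `1 - residual_error` (or
#' `residual_error` when the retained allele is the reference). Window
#' depths are Poisson read counts scaled by local copy number. Every truth
#' tract is guaranteed to overlap at least one emitted site.
#'
#' @param config A [simulation_config()].
#' @param spec A [strain_spec()].
#' @param reference_orfs Named character vector of reference ORF sequences
#'   (required when `spec$n_hgt > 0`); see [random_orf_set()].
#' @param seed Optional integer seed; with a fixed seed the simulation is
#'   bit-reproducible.
#' @return A list with elements `variants` (data frame as from
#'   [read_variant_table()]), `coverage` (data frame as from
#'   [read_coverage_table()]), `contigs` (named character vector, possibly
#'   empty), and `truth` (ploidy, chromosome copies, tracts, HGT genes,
#'   per-site allele configuration).
#' @export
simulate_strain <- function(config, spec, reference_orfs = NULL, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(spec, "strain_spec"))
  if (!is.null(seed)) set.seed(seed)
  layout <- config$layout
  check_tracts(spec$loh, layout, "LOH")
  check_tracts(spec$cnv, layout, "CNV")
  if (!is.null(spec$loh) && nrow(spec$loh) > 0L) {
    bad <- !spec$loh$class %in% c("interstitial", "terminal", "upd")
    if (any(bad)) stop("unknown LOH class: ", spec$loh$class[bad][1L])
  }

  chrom_copies <- stats::setNames(rep.int(spec$ploidy, nrow(layout)),
                                  layout$chrom)
  if (!is.null(spec$aneuploidy) && nrow(spec$aneuploidy) > 0L) {
    i <- match(spec$aneuploidy$chrom, layout$chrom)
    if (anyNA(i)) stop("aneuploidy on unknown chromosome")
    chrom_copies[i] <- chrom_copies[i] + spec$aneuploidy$delta
    if (any(chrom_copies < 1L)) stop("aneuploidy drives copy number below 1")
  }

  var_list <- vector("list", nrow(layout))
  truth_sites <- vector("list", nrow(layout))
  cov_list <- vector("list", nrow(layout))
  for (ci in seq_len(nrow(layout))) {
    ch <- layout$chrom[ci]
    L <- layout$length[ci]
    n_sites <- max(1L, round(L * config$het_density))
    pos <- sort(sample.int(L, n_sites))          # 0-based positions
    # guarantee every planted tract overlaps at least one site
    for (tr in list(spec$loh, spec$cnv)) {
      if (is.null(tr) || nrow(tr) == 0L) next
      here <- tr[tr$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(here))) {
        if (!any(pos >= here$start[k] & pos < here$end[k])) {
          pos <- sort(c(pos, here$start[k] +
                          sample.int(here$end[k] - here$start[k], 1L) - 1L))
        }
      }
    }
    n_sites <- length(pos)
    cn <- local_copy_number(pos, chrom_copies[ci], spec$cnv, ch)
    in_loh <- rep(FALSE, n_sites)
    if (!is.null(spec$loh) && nrow(spec$loh) > 0L) {
      here <- spec$loh[spec$loh$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(here))) {
        in_loh <- in_loh | (pos >= here$start[k] & pos < here$end[k])
      }
    }
    hom <- in_loh | cn < 2L
    alt_copies <- integer(n_sites)
    p <- numeric(n_sites)
    if (any(!hom)) {
      a <- vapply(cn[!hom], function(c) sample.int(c - 1L, 1L), 0L)
      alt_copies[!hom] <- a
      p[!hom] <- a / cn[!hom]
    }
    if (any(hom)) {
      alt_hom <- stats::runif(sum(hom)) < 0.5
      alt_copies[hom] <- ifelse(alt_hom, cn[hom], 0L)
      p[hom] <- ifelse(alt_hom, 1 - config$residual_error,
                       config$residual_error)
    }
    depth <- stats::rpois(n_sites, config$mean_depth * cn / spec$ploidy)
    alt_d <- stats::rbinom(n_sites, depth, p)
    base <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    altb <- vapply(base, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
    var_list[[ci]] <- data.frame(
      chrom = ch, pos = pos + 1L, ref = base, alt = altb,
      ref_depth = depth - alt_d, alt_depth = alt_d,
      annotation = NA_character_, stringsAsFactors = FALSE
    )
    truth_sites[[ci]] <- data.frame(
      chrom = ch, pos = pos + 1L, alt_copies = alt_copies, total_copies = cn,
      zygosity = ifelse(hom, "homozygous", "heterozygous"),
      stringsAsFactors = FALSE
    )
    # coverage windows
    starts <- seq.int(0L, L - 1L, by = config$window)
    ends <- pmin(starts + config$window, L)
    mid <- (starts + ends) %/% 2L
    wcn <- local_copy_number(mid, chrom_copies[ci], spec$cnv, ch)
    lambda <- config$mean_depth * wcn / spec$ploidy *
      (ends - starts) / config$read_length
    reads <- stats::rpois(length(starts), lambda)
    cov_list[[ci]] <- data.frame(
      chrom = ch, start = starts, end = ends,
      depth = reads * config$read_length / (ends - starts),
      stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, var_list)
  variants <- annotate_snv_labels(variants, config)
  coverage <- normalize_coverage(do.call(rbind, cov_list))

  contigs <- character(0)
  hgt_truth <- data.frame(gene_id = character(), ref_id = character(),
                          identity = numeric(), stringsAsFactors = FALSE)
  if (spec$n_hgt > 0L) {
    if (is.null(reference_orfs)) {
      stop("reference_orfs required to plant HGT genes")
    }
    hgt <- plant_hgt_contig(reference_orfs, identity = spec$hgt_identity,
                            n_genes = spec$n_hgt, telomeric_end = TRUE,
                            motif = attr(layout, "telomere_motif"),
                            contig_id = paste0(spec$id, "_hgt"))
    contigs <- hgt$contig
    hgt_truth <- hgt$truth[c("gene_id", "ref_id", "identity")]
  }

  indels <- NULL
  if (spec$n_indels > 0L) {
    genome <- random_genome(layout)
    indels <- plant_indels(genome, n = spec$n_indels,
                           repeat_fraction = config$indel_repeat_fraction)
  }

  list(
    variants = variants,
    coverage = coverage,
    contigs = contigs,
    indels = indels,
    truth = list(
      strain = spec$id,
      ploidy = spec$ploidy,
      chrom_copies = chrom_copies,
      loh = if (is.null(spec$loh)) data.frame() else spec$loh,
      cnv = if (is.null(spec$cnv)) data.frame() else spec$cnv,
      hgt = hgt_truth,
      sites = do.call(rbind, truth_sites)
    )
  )
}

# deterministic label counts, random assignment of which sites get which
annotate_snv_labels <- function(variants, config) {
  n <- nrow(variants)
  n_coding <- round(n * config$coding_fraction)
  r <- config$syn_missense_ratio
  n_syn <- round(n_coding * r / (1 + r))
  n_mis <- n_coding - n_syn
  lab <- c(rep("synonymous", n_syn), rep("missense", n_mis),
           rep("noncoding", n - n_coding))
  variants$annotation <- sample(lab)
  variants
}

#' Generate a random reference ORF set
#'
#' @param n Number of ORFs.
#' @param lengths ORF lengths in bp (recycled); default 900.
#' @return Named character vector (`ORF0001`, ...).
#' @export
random_orf_set <- function(n, lengths = 900L) {
  lengths <- rep_len(as.integer(lengths), n)
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  stats::setNames(seqs, sprintf("ORF%04d", seq_len(n)))
}

#' Generate random genome sequences for a layout
#'
#' @param layout A [genome_layout()].
#' @return Named character vector of chromosome sequences.
#' @export
random_genome <- function(layout) {
  stats::setNames(vapply(layout$length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, ""), layout$chrom)
}

mutate_to_identity <- function(seq, identity) {
  L <- nchar(seq)
  n_sub <- round((1 - identity) * L)
  if (identity < 1 && n_sub < 1L) {
    stop("requested identity incompatible with ORF length: ",
         "fewer than 1 substitutable site")
  }
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  at <- sample.int(L, n_sub)
  chars[at] <- vapply(chars[at], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, "")
  paste(chars, collapse = "")
}

#' Plant a contig of horizontally acquired genes
#'
#' Builds a synthetic contig carrying mutated copies of reference ORFs at a
#' controlled nucleotide identity (substitutions placed uniformly at
#' random, no indels), optionally terminated by tandem telomere repeats so
#' the contig is recognizably chromosome-end located, and optionally
#' flanked on both sides by near-identical copies of one native gene (the
#' flanking-duplication signature of some transferred fragments).
#'
#' @param reference_orfs Named character vector of reference ORFs.
#' @param identity Target global identity of planted genes to their
#'   references, in \[0, 1\]. Realized identity is within one percentage
#'   point of the request.
#' @param n_genes Number of genes to plant (sampled without replacement
#'   from the reference set).
#' @param telomeric_end If TRUE, appends tandem telomere-motif copies at
#'   the right contig end.
#' @param motif Telomere motif used when `telomeric_end`.
#' @param motif_copies Number of tandem motif copies appended (default 10).
#' @param flank_gene Optional reference ORF id; an exact copy is placed on
#'   both sides of the planted genes.
#' @param spacer Length of random spacer sequence between genes
#'   (default 200).
#' @param contig_id Contig name.
#' @return A list with `contig` (named character vector of length 1),
#'   `orfs` (named character vector of planted gene sequences), and
#'   `truth` (data frame `gene_id`, `ref_id`, `identity`, `start`, `end`
#'   giving 0-based half-open coordinates on the contig).
#' @export
plant_hgt_contig <- function(reference_orfs, identity, n_genes,
                             telomeric_end = FALSE,
                             motif = "TGTGGGTGTGGTG", motif_copies = 10L,
                             flank_gene = NULL, spacer = 200L,
                             contig_id = "hgt_contig") {
  stopifnot(identity >= 0, identity <= 1, n_genes >= 1,
            n_genes <= length(reference_orfs))
  pick <- sample(names(reference_orfs), n_genes)
  genes <- character(0)
  ids <- character(0)
  refs <- character(0)
  idents <- numeric(0)
  if (!is.null(flank_gene)) {
    stopifnot(flank_gene %in% names(reference_orfs))
    genes <- c(genes, reference_orfs[[flank_gene]])
    ids <- c(ids, paste0(contig_id, "_g", length(ids) + 1L))
    refs <- c(refs, flank_gene)
    idents <- c(idents, 1)
  }
  for (ref_id in pick) {
    mut <- mutate_to_identity(reference_orfs[[ref_id]], identity)
    genes <- c(genes, mut)
    ids <- c(ids, paste0(contig_id, "_g", length(ids) + 1L))
    refs <- c(refs, ref_id)
    idents <- c(idents,
                1 - round((1 - identity) * nchar(mut)) / nchar(mut))
  }
  if (!is.null(flank_gene)) {
    genes <- c(genes, reference_orfs[[flank_gene]])
    ids <- c(ids, paste0(contig_id, "_g", length(ids) + 1L))
    refs <- c(refs, flank_gene)
    idents <- c(idents, 1)
  }
  rand <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = "")
  seq <- rand(spacer)
  starts <- integer(length(genes))
  ends <- integer(length(genes))
  for (k in seq_along(genes)) {
    starts[k] <- nchar(seq)
    seq <- paste0(seq, genes[k])
    ends[k] <- nchar(seq)
    seq <- paste0(seq, rand(spacer))
  }
  if (telomeric_end) {
    seq <- paste0(seq, strrep(motif, motif_copies))
  }
  list(
    contig = stats::setNames(seq, contig_id),
    orfs = stats::setNames(genes, ids),
    truth = data.frame(gene_id = ids, ref_id = refs, identity = idents,
                       start = starts, end = ends, stringsAsFactors = FALSE)
  )
}

find_repeat_loci <- function(seq) {
  mono <- gregexpr("A{4,}|C{4,}|G{4,}|T{4,}", seq)[[1L]]
  units <- c("AC", "AG", "AT", "CA", "CG", "CT",
             "GA", "GC", "GT", "TA", "TC", "TG")
  pat <- paste0("(", units, "){3,}", collapse = "|")
  micro <- gregexpr(pat, seq)[[1L]]
  take <- function(m, ctx) {
    if (m[1L] == -1L) return(NULL)
    data.frame(start = as.integer(m),
               len = attr(m, "match.length"), context = ctx)
  }
  rbind(take(mono, "mononucleotide_repeat"), take(micro, "microsatellite"))
}

# conservative screen: window must contain no single-base run >= 3 and no
# tandem of any 2-6 bp unit repeated >= 2 times, so the planted event can
# never create a qualifying repeat
is_clean_window <- function(win) {
  if (grepl("A{3,}|C{3,}|G{3,}|T{3,}", win)) return(FALSE)
  !grepl("(.{2,6})\\1", win, perl = TRUE)
}

#' Plant InDels with controlled repeat-context fraction
#'
#' Places a deterministic number (`round(repeat_fraction * n)`) of InDels
#' inside mononucleotide runs (length >= 4) or dinucleotide microsatellites
#' (>= 3 units) found in the reference, and the remainder at positions
#' screened to be repeat-free; the ground-truth context of each event is
#' recorded. Repeat-context events delete or insert one repeat unit;
#' non-repeat events are 1-bp insertions or deletions.
#'
#' @param genome Named character vector of reference chromosome sequences.
#' @param n Number of InDels.
#' @param repeat_fraction Fraction placed in repeat context, in \[0, 1\].
#' @return Data frame `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `context` (truth label), `type` (`insertion`/`deletion`).
#' @export
plant_indels <- function(genome, n, repeat_fraction = 0.82) {
  stopifnot(repeat_fraction >= 0, repeat_fraction <= 1, n >= 0)
  n_rep <- round(n * repeat_fraction)
  n_non <- n - n_rep
  loci <- do.call(rbind, lapply(names(genome), function(ch) {
    df <- find_repeat_loci(genome[[ch]])
    if (is.null(df)) return(NULL)
    df$chrom <- ch
    # keep loci with room for a centered context window
    df[df$start > 12L & df$start + df$len < nchar(genome[[ch]]) - 12L, ,
       drop = FALSE]
  }))
  if (n_rep > 0L && (is.null(loci) || nrow(loci) < n_rep)) {
    stop("insufficient repeat loci in reference; use a larger genome")
  }
  out <- vector("list", n)
  k <- 0L
  if (n_rep > 0L) {
    pick <- loci[sample.int(nrow(loci), n_rep), , drop = FALSE]
    for (i in seq_len(n_rep)) {
      ch <- pick$chrom[i]
      s <- pick$start[i]
      ctx <- pick$context[i]
      unit_len <- if (ctx == "mononucleotide_repeat") 1L else 2L
      del <- stats::runif(1) < 0.5
      # anchor base just before the event, VCF-style representation;
      # the unit is read at the anchor so it matches the reference exactly
      anchor_pos <- s + sample.int(pick$len[i] - unit_len, 1L) - 1L
      anchor <- substr(genome[[ch]], anchor_pos, anchor_pos)
      unit <- substr(genome[[ch]], anchor_pos + 1L, anchor_pos + unit_len)
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = ch, pos = anchor_pos,
        ref = if (del) paste0(anchor, unit) else anchor,
        alt = if (del) anchor else paste0(anchor, unit),
        context = ctx, type = if (del) "deletion" else "insertion",
        stringsAsFactors = FALSE
      )
    }
  }
  tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 50000L) stop("could not place non-repeat InDels")
    ch <- sample(names(genome), 1L)
    L <- nchar(genome[[ch]])
    p <- sample.int(L - 22L, 1L) + 10L
    win <- substr(genome[[ch]], p - 10L, p + 10L)
    if (!is_clean_window(win)) next
    anchor <- substr(genome[[ch]], p, p)
    del <- stats::runif(1) < 0.5
    nxt <- substr(genome[[ch]], p + 1L, p + 1L)
    ins_base <- sample(setdiff(c("A", "C", "G", "T"),
                               c(anchor, nxt)), 1L)
    k <- k + 1L
    out[[k]] <- data.frame(
      chrom = ch, pos = p,
      ref = if (del) paste0(anchor, nxt) else anchor,
      alt = if (del) anchor else paste0(anchor, ins_base),
      context = "non_repeat", type = if (del) "deletion" else "insertion",
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), context = character(),
                     type = character(), stringsAsFactors = FALSE)
  }
  df
}

#' Write a simulated strain to disk
#'
#' Emits `<strain>.variants.tsv`, `<strain>.coverage.bed`,
#' `<strain>.contigs.fasta` (when contigs exist) and `<strain>.truth.json`
#' under `out_dir`.
#'
#' @param sim Result of [simulate_strain()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_strain <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- sim$truth$strain
  paths <- c(
    variants = file.path(out_dir, paste0(id, ".variants.tsv")),
    coverage = file.path(out_dir, paste0(id, ".coverage.bed")),
    truth = file.path(out_dir, paste0(id, ".truth.json"))
  )
  write_variant_table(sim$variants, paths[["variants"]])
  write_coverage_table(sim$coverage, paths[["coverage"]])
  if (length(sim$contigs) > 0L) {
    paths[["contigs"]] <- file.path(out_dir, paste0(id, ".contigs.fasta"))
    write_fasta(sim$contigs, paths[["contigs"]])
  }
  truth <- sim$truth
  truth$chrom_copies <- as.list(truth$chrom_copies)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       dataframe = "columns", digits = NA)
  invisible(paths)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
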
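#' Global-alignment percent identity of two sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2,
#' end gaps penalized); identity is the number of matching columns
#' divided by the total alignment columns, times 100. Gap columns count
#' toward the denominator, making this stricter than local (BLAST-style)
#' identity. Ambiguous traceback steps resolve diagonal first, then a gap
#' in the reference, then a gap in the query.
#'
#' @param query,reference Non-empty nucleotide strings.
#' @return Percent identity in \[0, 100\].
#' @export
percent_identity <- function(query, reference) {
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("empty sequence")
  }
  .nw_identity(query, reference)$identity
}

kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
}

#' Flag additional genes against a reference ORF set
#'
#' Matches each query ORF to its best reference ORF by global percent
#' identity and flags it "additional" when the best identity is at or
#' below the threshold (the rule is inclusive: exactly 85% is
#' additional) or when no reference shares enough k-mers to be a
#' candidate (identity recorded as 0). Candidate references are
#' pre-filtered by shared k-mer count so the dynamic programming runs
#' only on plausible pairs; identity ties resolve to the
#' lexicographically smallest reference id.
#'
#' @param query_orfs Named character vector of query ORF sequences.
#' @param reference_orfs Named character vector of reference ORFs.
#' @param threshold Additional-gene identity threshold in percent
#'   (default 85).
#' @param k K-mer size for the candidate pre-filter (default 15).
#' @param min_shared_kmers Minimum shared k-mers to become a candidate
#'   (default 5).
#' @return Data frame `query`, `reference` (NA when no candidate),
#'   `identity`, `additional`.
#' @export
flag_additional_genes <- function(query_orfs, reference_orfs,
                                  threshold = 85, k = 15L,
                                  min_shared_kmers = 5L) {
  if (length(reference_orfs) == 0L) {
    warning("empty reference ORF set: all queries flagged additional")
    return(data.frame(query = names(query_orfs),
                      reference = NA_character_, identity = 0,
                      additional = TRUE, stringsAsFactors = FALSE))
  }
  ref_ids <- sort(names(reference_orfs))
  ref_kmers <- lapply(reference_orfs[ref_ids], kmer_set, k = k)
  rows <- lapply(names(query_orfs), function(qid) {
    q <- query_orfs[[qid]]
    qk <- kmer_set(q, k)
    shared <- vapply(ref_kmers, function(rk) sum(qk %in% rk), 0L)
    cand <- ref_ids[shared >= min_shared_kmers]
    if (length(cand) == 0L) {
      return(data.frame(query = qid, reference = NA_character_,
                        identity = 0, additional = TRUE,
                        stringsAsFactors = FALSE))
    }
    ident <- vapply(cand, function(rid) {
      percent_identity(q, reference_orfs[[rid]])
    }, 0)
    best <- which.max(ident)          # cand is sorted: first max wins ties
    data.frame(query = qid, reference = cand[best],
               identity = ident[best],
               additional = ident[best] <= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# fraction of positions in x matching the motif tiled from its start
motif_conservation <- function(x, motif) {
  tiled <- strrep(motif, ceiling(nchar(x) / nchar(motif)))
  tiled <- substr(tiled, 1L, nchar(x))
  a <- strsplit(x, "")[[1L]]
  b <- strsplit(tiled, "")[[1L]]
  mean(a == b)
}

#' Detect telomeric repeats at contig ends
#'
#' Scans both terminal windows of a contig for at least `min_copies`
#' tandem copies of the telomere motif, tolerating up to 10% base
#' divergence over the tandem stretch. Contigs carrying such an array at
#' an end were located at a chromosome end in the source genome.
#'
#' @param contig Contig sequence.
#' @param motif Telomere repeat motif.
#' @param min_copies Minimum tandem copies (default 8).
#' @param window Terminal window size in bp (default 500); shorter
#'   contigs are scanned whole.
#' @param min_conservation Minimum per-base motif conservation of the
#'   tandem stretch (default 0.90).
#' @return One of `"left"`, `"right"`, `"both"`, `"none"`.
#' @export
detect_telomeric_end <- function(contig, motif, min_copies = 8L,
                                 window = 500L, min_conservation = 0.90) {
  stopifnot(nchar(motif) > 0L)
  L <- nchar(contig)
  span <- min_copies * nchar(motif)
  scan <- function(region) {
    rl <- nchar(region)
    if (rl < span) return(FALSE)
    for (off in seq_len(rl - span + 1L)) {
      x <- substr(region, off, off + span - 1L)
      if (motif_conservation(x, motif) >= min_conservation) return(TRUE)
    }
    FALSE
  }
  w <- min(window, L)
  left <- scan(substr(contig, 1L, w))
  right <- scan(substr(contig, L - w + 1L, L))
  if (left && right) "both" else if (left) "left" else if (right) "right"
  else "none"
}

#' Detect an HGT fragment flanked by a duplicated native gene
#'
#' Some transferred fragments integrate between two copies of the same
#' native gene. Given the gene order along a contig and its gene matches,
#' the flag is set when a run of additional genes is bounded on both
#' sides by non-additional matches to the same reference gene.
#'
#' @param matches [flag_additional_genes()] result ordered by gene
#'   position along the contig.
#' @return List with `flanked` (logical) and `flanking_gene` (reference
#'   id or NA).
#' @export
detect_flanking_duplication <- function(matches) {
  n <- nrow(matches)
  add <- matches$additional
  if (n < 3L || !any(add)) {
    return(list(flanked = FALSE, flanking_gene = NA_character_))
  }
  r <- rle(add)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- stops[k]
    if (i0 == 1L || i1 == n) next
    left <- matches$reference[i0 - 1L]
    right <- matches$reference[i1 + 1L]
    if (!is.na(left) && !is.na(right) && left == right) {
      return(list(flanked = TRUE, flanking_gene = left))
    }
  }
  list(flanked = FALSE, flanking_gene = NA_character_)
}

#' Per-contig report of additional genes and telomeric ends
#'
#' @param contigs Named character vector of contig sequences.
#' @param contig_genes Data frame `gene_id`, `contig`, `start` giving each
#'   predicted ORF's contig and position (used for gene order).
#' @param matches [flag_additional_genes()] result for all gene ids.
#' @param motif Telomere motif.
#' @param ... Passed to [detect_telomeric_end()].
#' @return Data frame `contig`, `length`, `telomeric_end`, `n_genes`,
#'   `n_additional`, `flanked_by_duplication`, `flanking_gene`.
#' @export
contig_report <- function(contigs, contig_genes, matches, motif, ...) {
  rows <- lapply(names(contigs), function(cid) {
    genes <- contig_genes[contig_genes$contig == cid, , drop = FALSE]
    genes <- genes[order(genes$start), , drop = FALSE]
    m <- matches[match(genes$gene_id, matches$query), , drop = FALSE]
    fl <- detect_flanking_duplication(m)
    data.frame(
      contig = cid, length = nchar(contigs[[cid]]),
      telomeric_end = detect_telomeric_end(contigs[[cid]], motif, ...),
      n_genes = nrow(genes), n_additional = sum(m$additional),
      flanked_by_duplication = fl$flanked,
      flanking_gene = fl$flanking_gene, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
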
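#' Read a per-site variant table
#'
#' Reads biallelic variant records with per-allele read depths from either a
#' plain TSV (`chrom pos ref alt ref_depth alt_depth [annotation]`, no
#' header) or a minimal VCF ("vcf-subset": `CHROM POS ID REF ALT QUAL FILTER
#' INFO FORMAT sample`, with an `AD` field carrying comma-separated
#' per-allele depths). Positions are 1-based in both dialects.
#'
#' Multi-allelic VCF rows are split into biallelic records keeping, per
#' record, the reference allele and one alternate allele with its depth; the
#' two most-supported alleles at a site determine the record retained when
#' depths must be collapsed downstream. Records whose total depth is zero
#' are dropped and counted (see the `dropped` attribute).
#'
#' @param path Path to the variant file.
#' @param dialect `"tsv"` or `"vcf-subset"`.
#' @param layout Optional genome layout (see [genome_layout()]); when
#'   supplied, records on chromosomes absent from the layout raise an error.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ref_depth`, `alt_depth`, `annotation` (NA when absent), sorted by
#'   `(chrom, pos)`. The number of zero-depth records removed is attached as
#'   `attr(, "dropped")`.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf-subset"),
                               layout = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "tsv") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0L) {
      df <- empty_variant_table()
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      nf <- lengths(parts)
      bad <- which(nf < 6L)
      if (length(bad) > 0L) {
        stop("malformed variant row at line ", bad[1L], ": expected >= 6 fields")
      }
      df <- data.frame(
        chrom = vapply(parts, `[`, "", 1L),
        pos = as.integer(vapply(parts, `[`, "", 2L)),
        ref = vapply(parts, `[`, "", 3L),
        alt = vapply(parts, `[`, "", 4L),
        ref_depth = as.integer(vapply(parts, `[`, "", 5L)),
        alt_depth = as.integer(vapply(parts, `[`, "", 6L)),
        annotation = vapply(parts, function(p) {
          if (length(p) >= 7L) p[[7L]] else NA_character_
        }, ""),
        stringsAsFactors = FALSE
      )
      if (anyNA(df$pos) || anyNA(df$ref_depth) || anyNA(df$alt_depth)) {
        stop("malformed variant row at line ",
             which(is.na(df$pos) | is.na(df$ref_depth) | is.na(df$alt_depth))[1L],
             ": non-numeric position or depth")
      }
    }
  } else {
    df <- parse_vcf_subset(path)
  }
  if (!is.null(layout)) {
    unknown <- setdiff(unique(df$chrom), layout$chrom)
    if (length(unknown) > 0L) {
      stop("unknown chromosome(s) not in layout: ",
           paste(unknown, collapse = ", "))
    }
  }
  keep <- (df$ref_depth + df$alt_depth) > 0L
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " zero-depth variant record(s) dropped")
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "dropped") <- dropped
  df
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), ref_depth = integer(), alt_depth = integer(),
             annotation = character(), stringsAsFactors = FALSE)
}

parse_vcf_subset <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0L) return(empty_variant_table())
  out <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 10L) {
      stop("malformed VCF row at line ", i, ": expected >= 10 fields")
    }
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    ad_i <- match("AD", fmt)
    if (is.na(ad_i)) stop("malformed VCF row at line ", i, ": no AD field")
    sample <- strsplit(f[10L], ":", fixed = TRUE)[[1L]]
    ad <- as.integer(strsplit(sample[ad_i], ",", fixed = TRUE)[[1L]])
    if (anyNA(ad) || length(ad) != length(alts) + 1L) {
      stop("malformed VCF row at line ", i, ": AD does not match alleles")
    }
    # split multi-allelic rows: one biallelic record per alternate allele
    out[[k]] <- data.frame(
      chrom = f[1L], pos = as.integer(f[2L]), ref = f[4L], alt = alts,
      ref_depth = ad[1L], alt_depth = ad[-1L],
      annotation = NA_character_, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Write a variant table as TSV
#'
#' Inverse of [read_variant_table()] for the `"tsv"` dialect.
#'
#' @param variants Variant `data.frame` as returned by [read_variant_table()].
#' @param path Output path.
#' @export
write_variant_table <- function(variants, path) {
  df <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  ann <- ifelse(is.na(df$annotation), ".", df$annotation)
  lines <- paste(df$chrom, df$pos, df$ref, df$alt, df$ref_depth,
                 df$alt_depth, ann, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a windowed coverage table
#'
#' Reads a BED-like TSV (`chrom start end depth`, 0-based half-open, no
#' header) and fills `norm_ratio = depth / genome-wide median depth`.
#'
#' @param path Path to the coverage file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `depth`,
#'   `norm_ratio`, sorted by `(chrom, start)`.
#' @export
read_coverage_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      depth = numeric(), norm_ratio = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4L)) {
    stop("malformed coverage row at line ", which(lengths(parts) < 4L)[1L])
  }
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    depth = as.numeric(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  normalize_coverage(df)
}

#' Normalize and validate coverage windows
#'
#' Sorts windows, checks the per-chromosome non-overlap invariant and
#' computes `norm_ratio` against the genome-wide median depth.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `depth`.
#' @return The sorted data frame with a `norm_ratio` column.
#' @export
normalize_coverage <- function(df) {
  if (any(df$end <= df$start)) stop("coverage window with end <= start")
  if (any(df$depth < 0)) stop("negative depth")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    w <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(w) > 1L && any(w$start[-1L] < w$end[-nrow(w)])) {
      stop("overlapping coverage windows on ", ch)
    }
  }
  df$norm_ratio <- df$depth / stats::median(df$depth)
  rownames(df) <- NULL
  df
}

#' Write a coverage table as BED-like TSV
#'
#' @param windows Coverage `data.frame` (`chrom`, `start`, `end`, `depth`).
#' @param path Output path.
#' @export
write_coverage_table <- function(windows, path) {
  df <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  writeLines(paste(df$chrom, df$start, df$end,
                   format(df$depth, trim = TRUE, scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

#' Write genomic segments as BED
#'
#' Writes LOH or CNV segments as 0-based half-open BED with the segment
#' class in column 4. The output round-trips losslessly through
#' [read_segments_bed()].
#'
#' @param segments Data frame with columns `chrom`, `start`, `end`, `class`.
#' @param path Output path.
#' @export
write_segments_bed <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tclass", con)
  if (nrow(segments) > 0L) {
    df <- segments[order(segments$chrom, segments$start), , drop = FALSE]
    writeLines(paste(df$chrom, df$start, df$end, df$class, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a segments BED written by [write_segments_bed()]
#'
#' @param path Path to the BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, `class`.
#' @export
read_segments_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    class = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Construct a genome layout
#'
#' A genome layout records per-chromosome length and centromere position
#' plus the telomere repeat motif; positional LOH/CNV classes and the
#' simulator both require it.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Integer chromosome lengths (bp), all positive.
#' @param centromere Centromere positions (bp), strictly inside each
#'   chromosome.
#' @param telomere_motif Telomere repeat motif (default the budding-yeast
#'   TG1-3-type repeat).
#' @return A `data.frame` of class `genome_layout` with the motif stored as
#'   an attribute.
#' @export
genome_layout <- function(chrom, length, centromere,
                          telomere_motif = "TGTGGGTGTGGTG") {
  stopifnot(length(chrom) == length(length),
            length(chrom) == length(centromere))
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (any(centromere <= 0 | centromere >= length)) {
    stop("centromere must lie strictly inside the chromosome")
  }
  df <- data.frame(chrom = as.character(chrom), length = as.integer(length),
                   centromere = as.integer(centromere),
                   stringsAsFactors = FALSE)
  attr(df, "telomere_motif") <- telomere_motif
  class(df) <- c("genome_layout", "data.frame")
  df
}

#' Read a genome layout TSV
#'
#' Expects columns `chrom length centromere` (no header); an optional
#' comment line `#telomere_motif=<motif>` sets the motif.
#'
#' @param path Path to the layout TSV.
#' @return A `genome_layout`.
#' @export
read_genome_layout <- function(path) {
  lines <- readLines(path)
  motif <- "TGTGGGTGTGGTG"
  m <- grep("^#telomere_motif=", lines, value = TRUE)
  if (length(m) > 0L) motif <- sub("^#telomere_motif=", "", m[1L])
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genome_layout(
    chrom = vapply(parts, `[`, "", 1L),
    length = as.integer(vapply(parts, `[`, "", 2L)),
    centromere = as.integer(vapply(parts, `[`, "", 3L)),
    telomere_motif = motif
  )
}

#' Write a genome layout TSV
#'
#' @param layout A `genome_layout`.
#' @param path Output path.
#' @export
write_genome_layout <- function(layout, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#telomere_motif=", attr(layout, "telomere_motif")), con)
  writeLines(paste(layout$chrom, layout$length, layout$centromere, sep = "\t"),
             con)
  invisible(path)
}

#' Read a strains-by-conditions phenotype matrix
#'
#' TSV with a header row of condition names and strain ids in the first
#' column; entries are relative-biomass ratios (dimensionless, >= 0).
#'
#' @param path Path to the TSV.
#' @return A numeric matrix (strains in rows, conditions in columns).
#' @export
read_phenotype_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  m <- as.matrix(df)
  if (any(m < 0, na.rm = TRUE)) stop("negative relative-biomass entry")
  m
}

#' Write a phenotype matrix TSV
#'
#' @param m Numeric matrix (strains x conditions).
#' @param path Output path.
#' @export
write_phenotype_matrix <- function(m, path) {
  df <- data.frame(strain = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fermentation time series
#'
#' Long-format TSV with header `strain time co2_loss ethanol`; `time` in
#' hours, `co2_loss` cumulative (g/100 mL), `ethanol` the titer (g/L) at
#' that time (NA allowed where not sampled).
#'
#' @param path Path to the TSV.
#' @return A list of per-strain data frames (`time`, `co2_loss`, `ethanol`),
#'   each sorted by time.
#' @export
read_fermentation_series <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("strain", "time", "co2_loss") %in% names(df)))
  if (is.null(df$ethanol)) df$ethanol <- NA_real_
  out <- split(df[c("time", "co2_loss", "ethanol")], df$strain)
  lapply(out, function(s) {
    s <- s[order(s$time), , drop = FALSE]
    if (is.unsorted(s$co2_loss)) stop("CO2 loss must be non-decreasing")
    rownames(s) <- NULL
    s
  })
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Values that parse as numbers are returned numeric.
#'
#' @param path Path to the config file.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line: ",
                                   lines[which(lengths(kv) != 3L)[1L]])
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(out) <- keys
  out
}
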
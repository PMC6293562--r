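#' Read a GFF3 gene annotation
#'
#' Parses gene features and contig sizes from a GFF3 file. Contig lengths are
#' taken from `##sequence-region` pragmas; alternatively a contig table can be
#' supplied. GFF3 1-based inclusive coordinates are converted to the package's
#' internal 0-based half-open convention (`start - 1`, `end`), and the TSS is
#' derived from strand (`start` for `+`, `end - 1` for `-`, internal
#' coordinates).
#'
#' @param path Path to a GFF3 file.
#' @param contigs Optional tibble with columns `contig`, `length` (and
#'   optionally `is_control`) overriding/supplementing sequence-region
#'   pragmas.
#' @param feature_type GFF3 `type` values treated as genes (default
#'   `"gene"`).
#' @return A [genome_annotation()] (with empty repeat table).
#' @export
read_gff3 <- function(path, contigs = NULL, feature_type = "gene") {
  lines <- readLines(path)
  ctg <- tibble(contig = character(), length = integer(), is_control = logical())

  sr <- grep("^##sequence-region", lines)
  for (i in sr) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 4) abort(sprintf("line %d: malformed ##sequence-region pragma", i))
    ctg <- dplyr::bind_rows(ctg, tibble(contig = f[2],
                                        length = as.integer(f[4]),
                                        is_control = FALSE))
  }
  if (!is.null(contigs)) {
    contigs <- as_tibble(contigs)
    if (!"is_control" %in% names(contigs)) contigs$is_control <- FALSE
    ctg <- dplyr::bind_rows(contigs, ctg[!ctg$contig %in% contigs$contig, ])
  }
  if (nrow(ctg) == 0) abort("no contig lengths: need ##sequence-region pragmas or a `contigs` table")

  feat <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  recs <- vector("list", length(feat))
  for (k in seq_along(feat)) {
    i <- feat[k]
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 9) abort(sprintf("line %d: expected 9 tab-separated GFF3 columns", i))
    if (!f[3] %in% feature_type) next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1)) abort(sprintf("line %d: non-integer coordinates", i))
    id <- sub(".*ID=([^;]+).*", "\\1", f[9])
    if (identical(id, f[9]) && !grepl("ID=", f[9])) {
      abort(sprintf("line %d: gene feature without ID attribute", i))
    }
    recs[[k]] <- tibble(gene_id = id, contig = f[1],
                        start = start1 - 1L, end = end1, strand = f[7],
                        .line = i)
  }
  genes <- dplyr::bind_rows(recs)
  if (nrow(genes) > 0) {
    clen <- ctg$length[match(genes$contig, ctg$contig)]
    bad <- which(is.na(clen) | genes$end > clen)
    if (length(bad)) {
      abort(sprintf("line %d: gene '%s' extends past its contig (or contig unknown)",
                    genes$.line[bad[1]], genes$gene_id[bad[1]]))
    }
    genes$.line <- NULL
  } else {
    genes <- NULL
  }
  genome_annotation(ctg, genes)
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_gff3()]: emits `##sequence-region` pragmas for every
#' contig and one `gene` line per gene, converting internal 0-based half-open
#' coordinates back to GFF3's 1-based inclusive convention.
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  with(annotation$contigs,
       writeLines(sprintf("##sequence-region %s 1 %d", contig, length), con))
  g <- annotation$genes
  if (nrow(g)) {
    writeLines(sprintf("%s\tchromdev\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, g$start + 1L, g$end, g$strand, g$gene_id), con)
  }
  invisible(path)
}

#' Read a BED interval file
#'
#' Reads 3+ column BED; coordinates are 0-based half-open and preserved
#' verbatim. A fourth column, if present, is kept as `label`.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `contig`, `start`, `end` (and `label` when the
#'   file has a name column). Empty files yield an empty tibble.
#' @export
read_bed <- function(path) {
  empty <- tibble(contig = character(), start = integer(), end = integer())
  if (file.size(path) == 0) return(empty)
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0) return(empty)
  if (ncol(x) < 3) abort("BED needs at least 3 columns")
  out <- tibble(contig = as.character(x[[1]]),
                start = x[[2]], end = x[[3]])
  if (!is.numeric(out$start) || !is.numeric(out$end) ||
      any(out$start != floor(out$start)) || any(out$end != floor(out$end))) {
    abort("BED coordinates must be integers")
  }
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  if (any(out$start >= out$end)) {
    abort(sprintf("BED record %d: start >= end", which(out$start >= out$end)[1]))
  }
  if (ncol(x) >= 4) out$label <- as.character(x[[4]])
  out
}

#' Write intervals to BED
#'
#' @param x Tibble with columns `contig`, `start`, `end` and optionally
#'   `label` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("contig", "start", "end", intersect("label", names(x)))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a per-cytosine methylation report
#'
#' Reads a cytosine-report-style TSV (the Bismark dialect): one row per
#' cytosine with columns contig, position (1-based), strand, methylated read
#' count, unmethylated read count, trinucleotide context. Records are returned
#' in file order with no aggregation; zero-coverage rows are retained (they
#' are filtered at calling time).
#'
#' @param path Path to the TSV (no header).
#' @return Tibble with columns `contig`, `pos` (1-based), `strand`,
#'   `meth_count`, `unmeth_count`, `context`.
#' @export
read_cytosine_report <- function(path) {
  x <- readr::read_tsv(path,
                       col_names = c("contig", "pos", "strand",
                                     "meth_count", "unmeth_count", "context"),
                       col_types = "ciciic", progress = FALSE)
  if (any(x$meth_count < 0 | x$unmeth_count < 0)) abort("negative counts in cytosine report")
  if (any(x$pos < 1)) abort("cytosine positions are 1-based; pos must be >= 1")
  x
}

#' Write a per-cytosine methylation report
#'
#' @param x Tibble as returned by [read_cytosine_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(x, path) {
  readr::write_tsv(
    x[, c("contig", "pos", "strand", "meth_count", "unmeth_count", "context")],
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene-by-sample count table with sample metadata
#'
#' Reads a counts TSV (first column `gene_id`, one column per sample, plus a
#' `length` column of gene lengths in bp unless `gene_lengths` is supplied)
#' and a sample sheet (columns `sample_id`, `genotype`, `replicate`), and
#' returns the tidy long form used throughout the package.
#'
#' @param path Counts TSV path.
#' @param samples Sample sheet: a tibble or a path to a TSV with columns
#'   `sample_id`, `genotype`, `replicate`.
#' @param gene_lengths Optional tibble (`gene_id`, `length`) when the counts
#'   file has no `length` column.
#' @return A tibble with one row per gene x sample: `gene_id`, `gene_length`,
#'   `sample_id`, `genotype`, `replicate`, `count`.
#' @export
read_count_table <- function(path, samples, gene_lengths = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(x)[1] != "gene_id") names(x)[1] <- "gene_id"
  if (anyDuplicated(x$gene_id)) abort("duplicate gene ids in count table")
  if ("length" %in% names(x)) {
    len <- x[, c("gene_id", "length")]
    x$length <- NULL
  } else if (!is.null(gene_lengths)) {
    len <- as_tibble(gene_lengths)[, c("gene_id", "length")]
  } else {
    abort("gene lengths required: `length` column or `gene_lengths` table")
  }
  if (any(len$length <= 0)) abort("gene lengths must be > 0")
  if (is.character(samples)) {
    samples <- readr::read_tsv(samples, show_col_types = FALSE, progress = FALSE)
  }
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "genotype", "replicate") %in% names(samples))) {
    abort("sample sheet needs columns sample_id, genotype, replicate")
  }
  sample_cols <- setdiff(names(x), "gene_id")
  missing <- setdiff(sample_cols, samples$sample_id)
  if (length(missing)) {
    abort(paste0("samples without metadata: ", paste(missing, collapse = ", ")))
  }
  vals <- as.matrix(x[, sample_cols])
  if (any(is.na(vals)) || any(vals != floor(vals)) || any(vals < 0)) {
    abort("counts must be non-negative integers")
  }
  long <- tidyr::pivot_longer(x, -"gene_id",
                              names_to = "sample_id", values_to = "count")
  long$count <- as.integer(long$count)
  long |>
    dplyr::left_join(len, by = "gene_id") |>
    dplyr::rename(gene_length = "length") |>
    dplyr::left_join(samples[, c("sample_id", "genotype", "replicate")],
                     by = "sample_id") |>
    dplyr::select("gene_id", "gene_length", "sample_id", "genotype",
                  "replicate", "count")
}

#' Write a tidy count table to counts TSV + sample sheet
#'
#' @param counts Tidy counts as returned by [read_count_table()].
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_count_table <- function(counts, counts_path, samples_path) {
  wide <- counts |>
    dplyr::select("gene_id", length = "gene_length", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, counts_path, progress = FALSE)
  samp <- dplyr::distinct(counts, .data$sample_id, .data$genotype, .data$replicate)
  readr::write_tsv(samp, samples_path, progress = FALSE)
  invisible(counts_path)
}

#' Write an occupancy track as bedGraph
#'
#' Run-length compresses the per-base track into 0-based half-open bedGraph
#' lines. Zero-valued runs are emitted explicitly so output is a deterministic
#' function of the track and files diff cleanly.
#'
#' @param track An [occupancy_track()].
#' @param path Output path.
#' @param append Append to an existing file (for multi-contig output).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, append = FALSE) {
  stopifnot(inherits(track, "occupancy_track"))
  v <- as.numeric(track)
  if (any(!is.finite(v))) abort("track values must be finite")
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- sprintf("%s\t%d\t%d\t%s", attr(track, "contig"),
                   starts, ends, format(r$values, trim = TRUE, scientific = FALSE))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path.
#' @return Tibble with columns `contig`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("contig", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}
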
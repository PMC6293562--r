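#' Assemble and validate a genome annotation
#'
#' Bundles the coordinate backbone shared by all downstream analyses: contig
#' sizes, gene models with strand-aware transcription start sites (TSSs), and
#' repeat intervals. All coordinates are held internally as 0-based half-open
#' intervals; conversion to and from 1-based formats (GFF3, cytosine reports)
#' happens only in the readers and writers.
#'
#' @param contigs Tibble with columns `contig`, `length` (bp) and logical
#'   `is_control` flagging the designated unmethylated control contig (e.g.
#'   mitochondrial DNA used for bisulfite conversion-rate estimation).
#' @param genes Tibble with columns `gene_id`, `contig`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"` or `"-"`). A `tss` column is
#'   computed if absent: `start` on the plus strand, `end - 1` on the minus
#'   strand.
#' @param repeats Tibble with columns `contig`, `start`, `end`, `label`
#'   (0-based half-open). May be empty.
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `contigs`, `genes` and `repeats`, each a validated tibble.
#' @export
genome_annotation <- function(contigs, genes = NULL, repeats = NULL) {
  contigs <- as_tibble(contigs)
  if (!all(c("contig", "length") %in% names(contigs))) {
    abort("`contigs` needs columns `contig` and `length`.")
  }
  if (!"is_control" %in% names(contigs)) contigs$is_control <- FALSE
  if (anyDuplicated(contigs$contig)) abort("contig names must be unique")
  if (any(contigs$length <= 0)) abort("contig lengths must be > 0")

  if (is.null(genes)) {
    genes <- tibble(gene_id = character(), contig = character(),
                    start = integer(), end = integer(),
                    strand = character(), tss = integer())
  }
  genes <- as_tibble(genes)
  if (nrow(genes) == 0) {
    genes <- tibble(gene_id = character(), contig = character(),
                    start = integer(), end = integer(),
                    strand = character(), tss = integer())
  }
  if (nrow(genes) > 0) {
    if (anyDuplicated(genes$gene_id)) abort("gene ids must be unique")
    if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
    if (!"tss" %in% names(genes)) {
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    }
    clen <- contigs$length[match(genes$contig, contigs$contig)]
    if (anyNA(clen)) abort("gene on unknown contig")
    bad <- genes$start < 0 | genes$start >= genes$end | genes$end > clen
    if (any(bad)) {
      abort(sprintf("gene '%s' has invalid coordinates for its contig",
                    genes$gene_id[which(bad)[1]]))
    }
    if (any(genes$tss < genes$start | genes$tss >= genes$end)) {
      abort("tss must lie within [start, end)")
    }
  }

  if (is.null(repeats)) {
    repeats <- tibble(contig = character(), start = integer(),
                      end = integer(), label = character())
  }
  repeats <- as_tibble(repeats)
  if (nrow(repeats) == 0) {
    repeats <- tibble(contig = character(), start = integer(),
                      end = integer(), label = character())
  }
  if (nrow(repeats) > 0) {
    if (!"label" %in% names(repeats)) repeats$label <- "repeat"
    if (any(repeats$start >= repeats$end)) abort("repeat start must be < end")
    if (!all(repeats$contig %in% contigs$contig)) abort("repeat on unknown contig")
  }

  structure(
    list(contigs = contigs,
         genes = genes[, c("gene_id", "contig", "start", "end", "strand", "tss")],
         repeats = repeats[, c("contig", "start", "end", "label")]),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  ctrl <- x$contigs$contig[x$contigs$is_control]
  cat(sprintf(
    "<genome_annotation> %d contigs (%s bp), %d genes, %d repeats%s\n",
    nrow(x$contigs), format(sum(x$contigs$length), big.mark = ","),
    nrow(x$genes), nrow(x$repeats),
    if (length(ctrl)) paste0(", control contig: ", paste(ctrl, collapse = ",")) else ""
  ))
  invisible(x)
}

#' Map genomic positions to gene-body, upstream and repeat features
#'
#' Builds the feature index used for methylation aggregation: each gene
#' contributes one gene-body interval (its full primary-transcript span) and
#' one upstream interval of `upstream_len` bp on the TSS side of the gene,
#' truncated at contig edges; each annotated repeat contributes one repeat
#' interval. Memberships may overlap — a position inside both a gene and a
#' repeat belongs to both features, and each feature instance is tallied
#' independently downstream.
#'
#' @param annotation A [genome_annotation()].
#' @param upstream_len Width of the upstream window in bp (default 500).
#' @param stranded If `TRUE` (default) the upstream window sits upstream of
#'   the TSS side of the gene (`[start - upstream_len, start)` for plus-strand
#'   genes, `[end, end + upstream_len)` for minus-strand genes). `FALSE`
#'   ignores strand and always uses the left side.
#'
#' @return A tibble of feature intervals with columns `feature_id`,
#'   `feature_class` (`"gene_body"`, `"upstream"` or `"repeat"`), `contig`,
#'   `start`, `end` (0-based half-open). Upstream windows fully truncated to
#'   zero width are dropped.
#' @export
assign_feature_classes <- function(annotation, upstream_len = 500L, stranded = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (upstream_len <= 0) abort("`upstream_len` must be > 0")
  upstream_len <- as.integer(upstream_len)
  g <- annotation$genes
  clen <- annotation$contigs$length[match(g$contig, annotation$contigs$contig)]

  body <- tibble(feature_id = g$gene_id, feature_class = "gene_body",
                 contig = g$contig, start = g$start, end = g$end)

  left <- if (stranded) g$strand == "+" else rep(TRUE, nrow(g))
  up_start <- ifelse(left, pmax(0L, g$start - upstream_len), g$end)
  up_end <- ifelse(left, g$start, pmin(clen, g$end + upstream_len))
  upstream <- tibble(feature_id = g$gene_id, feature_class = "upstream",
                     contig = g$contig,
                     start = as.integer(up_start), end = as.integer(up_end))
  upstream <- upstream[upstream$end > upstream$start, , drop = FALSE]

  r <- annotation$repeats
  reps <- tibble(
    feature_id = if (nrow(r)) paste0(r$label, "_", seq_len(nrow(r))) else character(),
    feature_class = rep("repeat", nrow(r)),
    contig = r$contig, start = r$start, end = r$end
  )

  dplyr::bind_rows(body, upstream, reps)
}
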
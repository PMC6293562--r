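#' Compute RPKM from a tidy count table
#'
#' RPKM (reads per kilobase per million counted reads) for every gene x
#' sample cell: `1e9 * count / (gene_length * library_size)`, where the
#' library size is the per-sample sum of counted reads. RPKM reflects the
#' overall expression level of a gene and is the measure used to stratify
#' genes into weakly and strongly expressed classes.
#'
#' @param counts Tidy count table (columns `gene_id`, `gene_length`,
#'   `sample_id`, `genotype`, `replicate`, `count`), as produced by
#'   [read_count_table()] or [simulate_counts()].
#' @return The input tibble with `library_size` and `rpkm` columns added.
#' @export
compute_rpkm <- function(counts) {
  out <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(library_size = sum(as.numeric(.data$count))) |>
    dplyr::ungroup()
  if (any(out$library_size == 0)) abort("zero library size")
  dplyr::mutate(out,
                rpkm = 1e9 * .data$count / (.data$gene_length * .data$library_size))
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed as the median, over genes with
#' a nonzero count in every sample, of the ratio of the gene's count in that
#' sample to the gene's geometric mean across samples.
#'
#' @inheritParams compute_rpkm
#' @return Tibble with columns `sample_id`, `size_factor`.
#' @export
size_factors <- function(counts) {
  wide <- counts |>
    dplyr::select("gene_id", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  m <- as.matrix(wide[, -1])
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) abort("no gene has nonzero counts in all samples")
  lg <- log(m[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - geo)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Per-gene log2 fold change and MA coordinates
#'
#' Normalizes counts by size factors, then computes for every gene the log2
#' ratio of the mutant group mean to the wild-type group mean (with a
#' pseudocount on both means) and the MA x-coordinate (mean normalized count
#' over all samples in the two groups).
#'
#' @inheritParams compute_rpkm
#' @param sf Size factors from [size_factors()]; computed if `NULL`.
#' @param group_mut,group_wt Genotype labels selecting the two groups.
#' @param pseudocount Value added to both group means before taking the
#'   ratio (default 0.5).
#' @return Tibble with columns `gene_id`, `base_mean`, `log2fc`.
#' @export
log2_fold_change <- function(counts, sf = NULL, group_mut = "mutant",
                             group_wt = "wt", pseudocount = 0.5) {
  sub <- dplyr::filter(counts, .data$genotype %in% c(group_mut, group_wt))
  if (!all(c(group_mut, group_wt) %in% sub$genotype)) {
    abort("both groups must be present in `counts`")
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  if (is.null(sf)) sf <- size_factors(counts)
  sub <- sub |>
    dplyr::left_join(sf, by = "sample_id") |>
    dplyr::mutate(norm = .data$count / .data$size_factor)
  out <- sub |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      base_mean = mean(.data$norm),
      mean_mut = mean(.data$norm[.data$genotype == group_mut]),
      mean_wt = mean(.data$norm[.data$genotype == group_wt]),
      .groups = "drop")
  if (pseudocount == 0 && any(out$mean_mut == 0 | out$mean_wt == 0)) {
    abort("zero group mean with pseudocount 0; use a positive pseudocount")
  }
  out |>
    dplyr::mutate(log2fc = log2((.data$mean_mut + pseudocount) /
                                  (.data$mean_wt + pseudocount))) |>
    dplyr::select("gene_id", "base_mean", "log2fc")
}

#' Classify genes by wild-type RPKM
#'
#' Genes are stratified by their mean RPKM across wild-type samples:
#' strictly below `low_max` is `"low"`, strictly above `high_min` is
#' `"high"`, everything else (including the boundary values) `"neither"`.
#'
#' @param rpkm Output of [compute_rpkm()].
#' @param wt_genotype Genotype label identifying wild-type samples.
#' @param low_max,high_min Class thresholds (defaults 1 and 5).
#' @return Tibble with columns `gene_id`, `wt_rpkm`, `class`.
#' @export
classify_by_wt_rpkm <- function(rpkm, wt_genotype = "wt",
                                low_max = 1, high_min = 5) {
  if (low_max > high_min) abort("`low_max` must be <= `high_min`")
  rpkm |>
    dplyr::filter(.data$genotype == wt_genotype) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(wt_rpkm = mean(.data$rpkm), .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$wt_rpkm < low_max ~ "low",
      .data$wt_rpkm > high_min ~ "high",
      TRUE ~ "neither"))
}

# Five-number boxplot summary with the 1.5 x IQR whisker rule; quartiles by
# linear interpolation between order statistics.
boxplot_summary <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  tibble(n = length(x), median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         whisker_lo = min(x[x >= q[1] - 1.5 * iqr]),
         whisker_hi = max(x[x <= q[3] + 1.5 * iqr]))
}

#' Fold-change distribution summaries per expression class
#'
#' Boxplot statistics (n, median, quartiles, IQR, 1.5 x IQR whiskers) of the
#' per-gene log2 fold changes within each expression class — the numbers
#' behind class-stratified fold-change boxplots.
#'
#' @param fc Output of [log2_fold_change()].
#' @param classes Output of [classify_by_wt_rpkm()] (columns `gene_id`,
#'   `class`).
#' @param which_classes Classes to summarise (default all present).
#' @param gene_subset Optional character vector restricting the analysis to a
#'   supplied gene list (e.g. significantly differential genes); default all
#'   genes.
#' @return Tibble with one row per class: `class`, `n`, `median`, `q1`,
#'   `q3`, `iqr`, `whisker_lo`, `whisker_hi`.
#' @export
fold_change_distribution <- function(fc, classes, which_classes = NULL,
                                     gene_subset = NULL) {
  x <- dplyr::inner_join(fc, classes[, c("gene_id", "class")], by = "gene_id")
  if (!is.null(gene_subset)) x <- dplyr::filter(x, .data$gene_id %in% gene_subset)
  if (!is.null(which_classes)) {
    x <- dplyr::filter(x, .data$class %in% which_classes)
    if (!all(which_classes %in% x$class)) abort("empty expression class")
  }
  if (nrow(x) == 0) abort("no genes left to summarise")
  x |>
    dplyr::group_by(.data$class) |>
    dplyr::reframe(boxplot_summary(.data$log2fc))
}

#' Spearman correlation and clustering of samples
#'
#' Restricts to genes with a nonzero RPKM in every sample, log2-transforms,
#' computes the sample x sample Spearman correlation matrix (ties receive
#' average ranks), and clusters samples by average-linkage hierarchical
#' clustering on the distance `1 - rho`. Samples are ordered lexicographically
#' before clustering so leaf order is deterministic.
#'
#' @param rpkm Output of [compute_rpkm()].
#' @return An object of class `sample_correlation`: list with `correlation`
#'   (matrix), `leaf_order` (character), `hclust`, and `n_genes` used.
#' @export
sample_correlation_clustering <- function(rpkm) {
  wide <- rpkm |>
    dplyr::select("gene_id", "sample_id", "rpkm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpkm")
  m <- as.matrix(wide[, -1])
  if (ncol(m) < 2) abort("need at least 2 samples")
  m <- m[, order(colnames(m)), drop = FALSE]
  m <- m[rowSums(m > 0) == ncol(m), , drop = FALSE]
  if (nrow(m) < 2) abort("fewer than 2 genes with RPKM > 0 in all samples")
  rho <- cor(log2(m), method = "spearman")
  hc <- hclust(as.dist(1 - rho), method = "average")
  structure(list(correlation = rho, leaf_order = colnames(rho)[hc$order],
                 hclust = hc, n_genes = nrow(m)),
            class = "sample_correlation")
}

#' @export
print.sample_correlation <- function(x, ...) {
  cat(sprintf("<sample_correlation> %d samples over %d genes; leaf order: %s\n",
              ncol(x$correlation), x$n_genes,
              paste(x$leaf_order, collapse = " ")))
  invisible(x)
}

#' @describeIn sample_correlation_clustering Tidy the correlation matrix into
#'   long form (`sample_a`, `sample_b`, `rho`).
#' @param x A `sample_correlation` object.
#' @param ... Unused.
#' @export
tidy.sample_correlation <- function(x, ...) {
  as_tibble(as.data.frame.table(x$correlation, responseName = "rho",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(sample_a = "Var1", sample_b = "Var2")
}

#' @describeIn sample_correlation_clustering One-row summary (sample count,
#'   genes used, min/mean off-diagonal correlation).
#' @export
glance.sample_correlation <- function(x, ...) {
  off <- x$correlation[lower.tri(x$correlation)]
  tibble(n_samples = ncol(x$correlation), n_genes = x$n_genes,
         min_rho = min(off), mean_rho = mean(off))
}

#' @describeIn sample_correlation_clustering Heatmap of the correlation
#'   matrix with samples in dendrogram leaf order.
#' @param object A `sample_correlation` object.
#' @export
autoplot.sample_correlation <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(sample_a = factor(.data$sample_a, levels = object$leaf_order),
                  sample_b = factor(.data$sample_b, levels = object$leaf_order))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_a, .data$sample_b,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Spearman\nrho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplot of fold-change distributions by expression class
#'
#' Draws the class-stratified log2 fold-change boxplots (median, quartile
#' box, 1.5 x IQR whiskers, no outliers) with a reference line at 0.
#'
#' @param fc Output of [log2_fold_change()].
#' @param classes Output of [classify_by_wt_rpkm()].
#' @param which_classes Classes to draw (default `c("low", "high")`).
#' @return A ggplot object.
#' @export
plot_fold_change_classes <- function(fc, classes,
                                     which_classes = c("low", "high")) {
  s <- fold_change_distribution(fc, classes, which_classes = which_classes)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$class)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_lo,
                                        ymax = .data$whisker_hi), width = 0.2) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_hi),
      stat = "identity", width = 0.5) +
    ggplot2::geom_hline(yintercept = 0, colour = "red") +
    ggplot2::labs(x = "wild-type RPKM class", y = "log2 fold change") +
    ggplot2::theme_classic()
}
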
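#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' Pools all reads over cytosines on the designated control contig (a
#' known-unmethylated sequence such as mitochondrial DNA) and reports the
#' percentage converted: `100 * sum(unmeth) / sum(meth + unmeth)`. This is a
#' micro-average over reads, not a mean of per-cytosine rates.
#'
#' @param cytosines Cytosine report tibble ([read_cytosine_report()] /
#'   [simulate_cytosine_report()]).
#' @param control_contig Name of the control contig, or a
#'   [genome_annotation()] whose flagged control contig is used.
#' @return Conversion rate as a percentage (scalar).
#' @export
estimate_conversion_rate <- function(cytosines, control_contig) {
  if (inherits(control_contig, "genome_annotation")) {
    ctg <- control_contig$contigs
    control_contig <- ctg$contig[ctg$is_control]
    if (length(control_contig) != 1) abort("annotation must flag exactly one control contig")
  }
  x <- cytosines[cytosines$contig == control_contig, , drop = FALSE]
  total <- sum(x$meth_count) + sum(x$unmeth_count)
  if (total == 0) abort("no coverage on the control contig")
  100 * sum(x$unmeth_count) / total
}

#' Call methylated cytosines
#'
#' Applies the at-least-5-percent rule: a covered cytosine is methylated when
#' its methylated-read fraction is at least `min_fraction` (inclusive, per
#' "at least") and its coverage is at least `min_coverage`. Zero-coverage
#' records are dropped from the output.
#'
#' @param cytosines Cytosine report tibble.
#' @param min_fraction Minimum methylated fraction (default 0.05).
#' @param min_coverage Minimum read coverage (default 1; no coverage filter
#'   beyond being observed).
#' @param context Optional subset of contexts (`"CG"`, `"CHG"`, `"CHH"`);
#'   default all.
#' @return Tibble of covered cytosines with added columns `coverage`,
#'   `fraction`, `is_methylated`.
#' @export
call_methylated <- function(cytosines, min_fraction = 0.05, min_coverage = 1,
                            context = NULL) {
  if (min_fraction <= 0 || min_fraction > 1) abort("`min_fraction` must be in (0, 1]")
  if (min_coverage < 1) abort("`min_coverage` must be >= 1")
  x <- cytosines
  if (!is.null(context)) x <- x[x$context %in% context, , drop = FALSE]
  x <- dplyr::mutate(x, coverage = .data$meth_count + .data$unmeth_count)
  x <- x[x$coverage > 0, , drop = FALSE]
  dplyr::mutate(x,
                fraction = .data$meth_count / .data$coverage,
                is_methylated = .data$coverage >= min_coverage &
                  .data$fraction >= min_fraction)
}

#' Aggregate methylation calls over annotated features
#'
#' For every feature instance (gene body, upstream window, repeat) counts the
#' covered cytosines lying inside it and the subset called methylated, and
#' reports the percentage methylated. Both strands are counted
#' independently; a position inside overlapping features contributes to each
#' of them. Features containing no covered cytosine are excluded and counted
#' in the `n_excluded` attribute.
#'
#' @param calls Output of [call_methylated()].
#' @param features Feature intervals from [assign_feature_classes()].
#' @param contig_lengths Optional tibble (`contig`, `length`) for coordinate
#'   validation.
#' @return Tibble with columns `feature_id`, `feature_class`, `n_covered`,
#'   `n_methylated`, `percent_methylated`, with attribute `n_excluded`.
#' @export
aggregate_by_feature <- function(calls, features, contig_lengths = NULL) {
  if (!is.null(contig_lengths)) {
    L <- contig_lengths$length[match(calls$contig, contig_lengths$contig)]
    if (any(is.na(L)) || any(calls$pos > L)) {
      abort("cytosine position beyond contig length: coordinate mismatch")
    }
  }
  pieces <- purrr::map_dfr(unique(features$contig), function(ctg) {
    fc <- features[features$contig == ctg, , drop = FALSE]
    cc <- calls[calls$contig == ctg, , drop = FALSE]
    if (nrow(cc) == 0 || nrow(fc) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = fc$start + 1L, end = fc$end),
      IRanges::IRanges(start = cc$pos, width = 1L))
    if (length(hits) == 0) return(NULL)
    tibble(feature_id = fc$feature_id[S4Vectors::queryHits(hits)],
           feature_class = fc$feature_class[S4Vectors::queryHits(hits)],
           is_methylated = cc$is_methylated[S4Vectors::subjectHits(hits)])
  })
  if (nrow(pieces) == 0) {
    out <- tibble(feature_id = character(), feature_class = character(),
                  n_covered = integer(), n_methylated = integer(),
                  percent_methylated = numeric())
    attr(out, "n_excluded") <- nrow(dplyr::distinct(features, .data$feature_id,
                                                    .data$feature_class))
    return(out)
  }
  out <- pieces |>
    dplyr::group_by(.data$feature_id, .data$feature_class) |>
    dplyr::summarise(n_covered = dplyr::n(),
                     n_methylated = sum(.data$is_methylated),
                     .groups = "drop") |>
    dplyr::mutate(percent_methylated = 100 * .data$n_methylated / .data$n_covered)
  n_total <- nrow(dplyr::distinct(features, .data$feature_id, .data$feature_class))
  attr(out, "n_excluded") <- n_total - nrow(out)
  out
}

# Two-sample t by the textbook formulas; handles the degenerate zero-variance
# case with the documented p = 0 / p = 1 convention.
t_two_sample <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    warn("zero-variance t-test input; returning p = 0")
    return(list(t = sign(m1 - m2) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
}

#' Compare per-feature methylation between genotypes
#'
#' For each feature class present in both genotypes, runs a two-sample
#' Student's t-test (pooled variance by default, Welch optional) on the
#' per-feature percentages of methylated cytosines, and computes boxplot
#' summaries for both genotypes.
#'
#' @param wt,mut Per-feature tables from [aggregate_by_feature()] for the two
#'   genotypes.
#' @param var_equal Pooled-variance Student's t (`TRUE`, default) or Welch.
#' @return An object of class `genotype_comparison`: tibble with one row per
#'   feature class (`feature_class`, `n_wt`, `n_mut`, `mean_wt`, `mean_mut`,
#'   `mean_diff`, `median_wt`, `median_mut`, `t`, `df`, `p`, `degenerate`)
#'   plus a `summaries` attribute holding both genotypes' full boxplot
#'   statistics.
#' @export
compare_genotypes <- function(wt, mut, var_equal = TRUE) {
  classes_wt <- unique(wt$feature_class)
  classes_mut <- unique(mut$feature_class)
  skipped <- union(setdiff(classes_wt, classes_mut), setdiff(classes_mut, classes_wt))
  if (length(skipped)) {
    warn(paste0("feature class absent in one genotype, skipped: ",
                paste(skipped, collapse = ", ")))
  }
  shared <- intersect(classes_wt, classes_mut)
  rows <- purrr::map_dfr(shared, function(cl) {
    x <- wt$percent_methylated[wt$feature_class == cl]
    y <- mut$percent_methylated[mut$feature_class == cl]
    if (length(x) < 2 || length(y) < 2) abort("need >= 2 features per class per genotype")
    tt <- t_two_sample(x, y, var_equal = var_equal)
    tibble(feature_class = cl, n_wt = length(x), n_mut = length(y),
           mean_wt = mean(x), mean_mut = mean(y),
           mean_diff = mean(y) - mean(x),
           median_wt = median(x), median_mut = median(y),
           t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate)
  })
  summaries <- dplyr::bind_rows(
    wt |> dplyr::group_by(feature_class = .data$feature_class) |>
      dplyr::reframe(genotype = "wt", boxplot_summary(.data$percent_methylated)),
    mut |> dplyr::group_by(feature_class = .data$feature_class) |>
      dplyr::reframe(genotype = "mutant", boxplot_summary(.data$percent_methylated)))
  structure(rows, class = c("genotype_comparison", class(rows)),
            summaries = summaries)
}

#' @describeIn compare_genotypes Tidy per-class test results (drops
#'   attributes).
#' @param x A `genotype_comparison`.
#' @param ... Unused.
#' @export
tidy.genotype_comparison <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @describeIn compare_genotypes One-row overview: classes tested, minimum
#'   p, and whether methylation is lower in the mutant in every class.
#' @export
glance.genotype_comparison <- function(x, ...) {
  tibble(n_classes = nrow(x), min_p = min(x$p),
         all_lower_in_mutant = all(x$mean_diff < 0))
}

#' @describeIn compare_genotypes Side-by-side boxplots per feature class and
#'   genotype (outliers omitted).
#' @param object A `genotype_comparison`.
#' @export
autoplot.genotype_comparison <- function(object, ...) {
  s <- attr(object, "summaries")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$feature_class, fill = .data$genotype)) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_lo, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_hi),
      stat = "identity", position = ggplot2::position_dodge(width = 0.8),
      width = 0.6) +
    ggplot2::labs(x = NULL, y = "% methylated cytosines", fill = NULL) +
    ggplot2::theme_classic()
}

#' Feature methylation stratified by expression class
#'
#' Restricts the gene-linked feature intervals (gene bodies or upstream
#' windows) to the genes of each expression class and aggregates methylation
#' calls within each stratum, producing per-class tables ready for
#' [compare_genotypes()].
#'
#' @param calls Output of [call_methylated()].
#' @param features Feature intervals from [assign_feature_classes()].
#' @param classes Tibble (`gene_id`, `class`) from [classify_by_wt_rpkm()].
#' @param region `"gene_body"` or `"upstream"`.
#' @param which_classes Expression classes to keep (default
#'   `c("low", "high")`).
#' @return Named list (one per expression class) of
#'   [aggregate_by_feature()] tables.
#' @export
methylation_by_expression_class <- function(calls, features, classes,
                                            region = c("gene_body", "upstream"),
                                            which_classes = c("low", "high")) {
  region <- match.arg(region)
  out <- lapply(which_classes, function(cl) {
    ids <- classes$gene_id[classes$class == cl]
    if (length(ids) == 0) abort(sprintf("expression class '%s' is empty", cl))
    f <- features[features$feature_class == region &
                    features$feature_id %in% ids, , drop = FALSE]
    aggregate_by_feature(calls, f)
  })
  names(out) <- which_classes
  out
}
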
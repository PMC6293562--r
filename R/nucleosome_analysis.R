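#' Construct an occupancy track
#'
#' A per-base, non-negative vector over one contig, tagged with how it was
#' derived (`footprint_coverage` for occupancy metaplots,
#' `smoothed_midpoint_density` for dyad calling).
#'
#' @param values Numeric vector, one value per base (index 1 = base 0).
#' @param contig Contig name.
#' @param mode Track mode tag.
#' @return An `occupancy_track` (numeric vector with attributes).
#' @export
occupancy_track <- function(values,
                            contig,
                            mode = c("footprint_coverage",
                                     "smoothed_midpoint_density",
                                     "midpoint_density")) {
  mode <- match.arg(mode)
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("track values must be finite and >= 0")
  }
  structure(as.numeric(values), contig = contig, mode = mode,
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("<occupancy_track> %s, %d bp, mode=%s, total=%.4g\n",
              attr(x, "contig"), length(x), attr(x, "mode"), sum(x)))
  invisible(x)
}

#' Per-base occupancy from MNase fragments
#'
#' Two modes: `footprint_coverage` counts, at every base, the fragments whose
#' footprint covers it (start <= base < end) — the quantity plotted as
#' nucleosome occupancy; `smoothed_midpoint_density` counts fragment
#' midpoints `floor((start + end) / 2)` per base and applies Gaussian
#' smoothing — the localized signal used for dyad calling. Fragments
#' extending beyond the contig are clipped; the number clipped is recorded in
#' the `n_clipped` attribute with a warning.
#'
#' @param fragments Tibble with columns `contig`, `start`, `end` (0-based
#'   half-open).
#' @param contig Contig to compute the track for.
#' @param contig_length Contig length in bp.
#' @param mode `"footprint_coverage"` (default) or
#'   `"smoothed_midpoint_density"`.
#' @param sigma_bp Smoothing bandwidth for the midpoint mode.
#' @return An [occupancy_track()].
#' @export
occupancy_from_fragments <- function(fragments, contig, contig_length,
                                     mode = c("footprint_coverage",
                                              "smoothed_midpoint_density"),
                                     sigma_bp = 20) {
  mode <- match.arg(mode)
  L <- as.integer(contig_length)
  fr <- fragments[fragments$contig == contig, , drop = FALSE]
  n_clipped <- sum(fr$start < 0 | fr$end > L)
  if (n_clipped > 0) {
    warn(sprintf("%d fragments extend beyond %s and were clipped", n_clipped, contig))
  }
  st <- pmax(0L, fr$start)
  en <- pmin(L, fr$end)
  ok <- st < en
  st <- st[ok]; en <- en[ok]
  if (mode == "footprint_coverage") {
    add <- tabulate(st + 1L, nbins = L + 1L)
    sub <- tabulate(en + 1L, nbins = L + 1L)
    v <- cumsum(add - sub)[seq_len(L)]
    out <- occupancy_track(v, contig, "footprint_coverage")
  } else {
    mid <- (st + en) %/% 2L
    v <- tabulate(mid + 1L, nbins = L)
    out <- smooth_track(occupancy_track(v, contig, "midpoint_density"),
                        sigma_bp = sigma_bp)
  }
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Gaussian smoothing of an occupancy track
#'
#' Discrete convolution with a normalized Gaussian kernel truncated at plus
#' or minus four bandwidths, using reflective boundaries so total track mass
#' is conserved.
#'
#' @param track An [occupancy_track()].
#' @param sigma_bp Kernel bandwidth in bp (> 0).
#' @return A smoothed `occupancy_track` with mode
#'   `"smoothed_midpoint_density"`.
#' @export
smooth_track <- function(track, sigma_bp = 20) {
  stopifnot(inherits(track, "occupancy_track"), sigma_bp > 0)
  v <- as.numeric(track)
  L <- length(v)
  half <- ceiling(4 * sigma_bp)
  kern <- stats::dnorm(seq(-half, half), sd = sigma_bp)
  kern <- kern / sum(kern)
  # reflective extension; index folding handles kernels wider than the track
  idx <- seq(1L - half, L + half)
  fold <- ((idx - 1L) %% (2L * L))
  fold <- ifelse(fold >= L, 2L * L - 1L - fold, fold) + 1L
  ext <- v[fold]
  sm <- stats::filter(ext, kern, sides = 2)
  out <- as.numeric(sm)[half + seq_len(L)]
  out[out < 0] <- 0  # guard tiny negative fp noise
  occupancy_track(out, attr(track, "contig"), "smoothed_midpoint_density")
}

# Plateau-aware local maxima of a numeric vector; returns the (rounded)
# center index of each maximal run that is strictly above its neighbours.
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(r$values)
  if (n == 1) return(integer(0))
  left <- c(-Inf, r$values[-n])
  right <- c(r$values[-1], -Inf)
  is_max <- r$values > left & r$values > right & r$values > 0
  as.integer(round((starts[is_max] + ends[is_max]) / 2))
}

#' Call nucleosome positions from a smoothed midpoint-density track
#'
#' A simplified positioning caller: candidate dyads are local maxima of the
#' smoothed midpoint density at or above `min_height`; two candidates closer
#' than `merge_dist` are merged into a single `MainPeak:doublet` at their
#' height-weighted center; a secondary peak lying `shoulder_dist` bp from a
#' taller `MainPeak` with relative height inside `shoulder_rel` is labelled
#' `Shoulder` and promotes its partner to `MainPeak+Shoulder`; all remaining
#' peaks are `MainPeak`. Downstream analyses consume only the dyad positions
#' and these category labels.
#'
#' @param track A smoothed midpoint-density [occupancy_track()].
#' @param min_height Minimum peak height; default 0.25 times the track mean
#'   over its nonzero region.
#' @param merge_dist Doublet merge distance in bp (default 110). Use 0 to
#'   disable merging.
#' @param shoulder_dist Length-2 range (bp) in which a secondary peak counts
#'   as a shoulder (default 75-150, left-closed right-open). `NULL` disables
#'   shoulder labelling.
#' @param shoulder_rel Length-2 relative-height band for shoulders (default
#'   0.4-0.8, left-closed right-open).
#' @param footprint_bp Footprint used to derive call start/end from the dyad.
#' @return Tibble of calls sorted by dyad: `contig`, `dyad`, `start`, `end`,
#'   `category`, `height`. Empty for an all-zero track.
#' @export
call_nucleosomes <- function(track, min_height = NULL, merge_dist = 110,
                             shoulder_dist = c(75, 150),
                             shoulder_rel = c(0.4, 0.8),
                             footprint_bp = 147L) {
  stopifnot(inherits(track, "occupancy_track"))
  v <- as.numeric(track)
  empty <- tibble(contig = character(), dyad = integer(), start = integer(),
                  end = integer(), category = character(), height = numeric())
  if (all(v == 0)) return(empty)
  if (is.null(min_height)) min_height <- 0.25 * mean(v[v > 0])

  idx <- local_maxima(v)
  idx <- idx[v[idx] >= min_height]
  if (length(idx) == 0) return(empty)
  pos <- idx - 1L  # 0-based dyads
  h <- v[idx]
  cat_lab <- rep("MainPeak", length(pos))

  if (merge_dist > 0 && length(pos) > 1) {
    mpos <- numeric(0); mh <- numeric(0); mcat <- character(0)
    cur_pos <- pos[1]; cur_h <- h[1]; cur_n <- 1L
    for (i in seq_along(pos)[-1]) {
      if (pos[i] - cur_pos < merge_dist) {
        cur_pos <- (cur_pos * cur_h + pos[i] * h[i]) / (cur_h + h[i])
        cur_h <- max(cur_h, h[i])
        cur_n <- cur_n + 1L
      } else {
        mpos <- c(mpos, cur_pos); mh <- c(mh, cur_h)
        mcat <- c(mcat, if (cur_n > 1) "MainPeak:doublet" else "MainPeak")
        cur_pos <- pos[i]; cur_h <- h[i]; cur_n <- 1L
      }
    }
    mpos <- c(mpos, cur_pos); mh <- c(mh, cur_h)
    mcat <- c(mcat, if (cur_n > 1) "MainPeak:doublet" else "MainPeak")
    pos <- as.integer(round(mpos)); h <- mh; cat_lab <- mcat
  }

  if (!is.null(shoulder_dist) && length(pos) > 1) {
    for (i in seq_len(length(pos) - 1L)) {
      j <- i + 1L
      d <- pos[j] - pos[i]
      if (d >= shoulder_dist[1] && d < shoulder_dist[2]) {
        lo <- if (h[i] <= h[j]) i else j
        hi <- if (h[i] <= h[j]) j else i
        rel <- h[lo] / h[hi]
        if (rel >= shoulder_rel[1] && rel < shoulder_rel[2] &&
            cat_lab[hi] == "MainPeak" && cat_lab[lo] == "MainPeak") {
          cat_lab[hi] <- "MainPeak+Shoulder"
          cat_lab[lo] <- "Shoulder"
        }
      }
    }
  }

  L <- length(v)
  half <- as.integer(footprint_bp) %/% 2L
  tibble(contig = attr(track, "contig"), dyad = pos,
         start = pmax(0L, pos - half),
         end = pmin(L, pos + (as.integer(footprint_bp) - half)),
         category = cat_lab, height = h) |>
    dplyr::arrange(.data$dyad)
}

#' Call nucleosomes genome-wide from a fragment table
#'
#' Convenience pipeline: for each contig, builds the smoothed
#' midpoint-density track and runs [call_nucleosomes()].
#'
#' @param fragments Fragment tibble (`contig`, `start`, `end`).
#' @param annotation A [genome_annotation()] supplying contig lengths.
#' @param sigma_bp Smoothing bandwidth.
#' @param ... Passed to [call_nucleosomes()].
#' @return Tibble of calls over all contigs.
#' @export
call_nucleosomes_genome <- function(fragments, annotation, sigma_bp = 20, ...) {
  purrr::map_dfr(seq_len(nrow(annotation$contigs)), function(ci) {
    contig <- annotation$contigs$contig[ci]
    if (!any(fragments$contig == contig)) return(NULL)
    tr <- occupancy_from_fragments(fragments, contig,
                                   annotation$contigs$length[ci],
                                   mode = "smoothed_midpoint_density",
                                   sigma_bp = sigma_bp)
    call_nucleosomes(tr, ...)
  })
}

#' Histogram of adjacent nucleosome-call distances
#'
#' Distances between consecutive called dyads on the same contig, optionally
#' restricted to `MainPeak` calls before pairing. Distances are binned to the
#' nearest multiple of `bin_bp` (left-closed bins centered on multiples of
#' the bin width); the histogram mode is the center of the maximal bin, ties
#' broken toward the smaller distance. The mode of this distribution is the
#' nucleosome repeat length (footprint plus typical linker).
#'
#' @param calls Call tibble from [call_nucleosomes()] (any number of
#'   contigs).
#' @param filter `"all"` pairs every consecutive call irrespective of
#'   category; `"mainpeak"` first drops non-MainPeak calls.
#' @param bin_bp Histogram bin width in bp (default 5).
#' @return An object of class `distance_histogram`: list with `distances`,
#'   `bins` (tibble `center`, `count`), `mode` (NA when fewer than two
#'   retained calls), `bin_bp`, `n_pairs`.
#' @export
adjacent_distances <- function(calls, filter = c("all", "mainpeak"), bin_bp = 5) {
  filter <- match.arg(filter)
  x <- calls
  if (filter == "mainpeak") x <- x[x$category == "MainPeak", , drop = FALSE]
  d <- x |>
    dplyr::group_by(.data$contig) |>
    dplyr::arrange(.data$dyad, .by_group = TRUE) |>
    dplyr::summarise(d = list(diff(.data$dyad)), .groups = "drop") |>
    dplyr::pull(d) |>
    unlist()
  d <- as.numeric(d %||% numeric(0))
  if (length(d) == 0) {
    return(structure(list(distances = numeric(0),
                          bins = tibble(center = numeric(0), count = integer(0)),
                          mode = NA_real_, bin_bp = bin_bp, n_pairs = 0L),
                     class = "distance_histogram"))
  }
  k <- round(d / bin_bp)
  tab <- table(k)
  centers <- as.numeric(names(tab)) * bin_bp
  counts <- as.integer(tab)
  o <- order(centers)
  bins <- tibble(center = centers[o], count = counts[o])
  mode <- bins$center[which(bins$count == max(bins$count))[1]]
  structure(list(distances = d, bins = bins, mode = mode,
                 bin_bp = bin_bp, n_pairs = length(d)),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("<distance_histogram> %d adjacent pairs, bin %g bp, mode %s bp\n",
              x$n_pairs, x$bin_bp,
              if (is.na(x$mode)) "NA" else format(x$mode)))
  invisible(x)
}

#' @describeIn adjacent_distances Bar plot of the distance histogram with
#'   the mode marked.
#' @param object A `distance_histogram`.
#' @param ... Unused.
#' @export
autoplot.distance_histogram <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(.data$center, .data$count)) +
    ggplot2::geom_col(width = object$bin_bp * 0.9) +
    ggplot2::geom_vline(xintercept = object$mode, linetype = 2, colour = "red") +
    ggplot2::labs(x = "adjacent dyad distance (bp)", y = "pairs") +
    ggplot2::theme_classic()
}

#' TSS metaplot of normalized nucleosome occupancy
#'
#' For every classified gene, extracts footprint occupancy over a window
#' around the TSS (orientation flipped for minus-strand genes so downstream
#' of the TSS is always to the right), rescales the window so its maximum is
#' 1 (removing per-gene coverage differences), bins positions, and averages
#' within each expression class. Genes whose window leaves the contig or
#' contains no signal are excluded and counted.
#'
#' @param tracks A single footprint-coverage [occupancy_track()] or a list of
#'   them (named by contig, or using their `contig` attributes).
#' @param genes Gene tibble from a [genome_annotation()] (`gene_id`,
#'   `contig`, `strand`, `tss`).
#' @param classes Tibble (`gene_id`, `class`) from [classify_by_wt_rpkm()].
#' @param window_bp Half-window around the TSS (default 1000).
#' @param bin_bp Position bin width (default 10).
#' @return An object of class `tss_metaplot`: a tibble with columns
#'   `position` (bin center relative to the TSS; negative = upstream),
#'   `class`, `mean_occupancy` (in \[0, 1\]) and `n_genes`, with attributes
#'   `excluded_window` and `excluded_zero`.
#' @export
tss_metaplot <- function(tracks, genes, classes, window_bp = 1000, bin_bp = 10) {
  if (inherits(tracks, "occupancy_track")) tracks <- list(tracks)
  nm <- names(tracks) %||% vapply(tracks, function(t) attr(t, "contig"), "")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) names(tracks) <- nm
  g <- dplyr::inner_join(genes, classes[, c("gene_id", "class")], by = "gene_id")
  window_bp <- as.integer(window_bp)
  nb <- (2L * window_bp) %/% as.integer(bin_bp)
  centers <- -window_bp + (seq_len(nb) - 0.5) * bin_bp

  excluded_window <- 0L; excluded_zero <- 0L
  rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    tr <- tracks[[g$contig[i]]]
    if (is.null(tr)) { excluded_window <- excluded_window + 1L; next }
    L <- length(tr)
    tss <- g$tss[i]
    if (g$strand[i] == "+") {
      a <- tss - window_bp; b <- tss + window_bp - 1L
      if (a < 0 || b >= L) { excluded_window <- excluded_window + 1L; next }
      w <- as.numeric(tr)[(a + 1L):(b + 1L)]
    } else {
      a <- tss - window_bp + 1L; b <- tss + window_bp
      if (a < 0 || b >= L) { excluded_window <- excluded_window + 1L; next }
      w <- rev(as.numeric(tr)[(a + 1L):(b + 1L)])
    }
    mx <- max(w)
    if (mx == 0) { excluded_zero <- excluded_zero + 1L; next }
    w <- w / mx
    binned <- colMeans(matrix(w, nrow = bin_bp, ncol = nb))
    rows[[i]] <- tibble(class = g$class[i], position = centers, value = binned)
  }
  prof <- dplyr::bind_rows(rows)
  if (nrow(prof) == 0) abort("no gene had a usable TSS window")
  out <- prof |>
    dplyr::group_by(.data$class, .data$position) |>
    dplyr::summarise(mean_occupancy = mean(.data$value),
                     n_genes = dplyr::n(), .groups = "drop")
  structure(out, class = c("tss_metaplot", class(out)),
            excluded_window = excluded_window, excluded_zero = excluded_zero,
            window_bp = window_bp, bin_bp = bin_bp)
}

#' @describeIn tss_metaplot Class-average occupancy profiles around the TSS.
#' @param object A `tss_metaplot`.
#' @param ... Unused.
#' @export
autoplot.tss_metaplot <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$mean_occupancy,
                                       colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mean normalized occupancy", colour = "RPKM class") +
    ggplot2::theme_classic()
}

#' Locate and size the nucleosome-depleted region
#'
#' From a class-average metaplot, finds the position of minimal occupancy
#' upstream of the TSS and the width of the contiguous span around that
#' minimum where occupancy stays below `threshold` times the maximum of the
#' upstream flank. NDR width grows with expression class in fungal
#' chromatin, which this metric quantifies.
#'
#' @param metaplot A [tss_metaplot()].
#' @param classes Classes to measure (default all in the metaplot).
#' @param threshold Depletion threshold as a fraction of the upstream-flank
#'   maximum (default 0.5).
#' @return Tibble with columns `class`, `ndr_min_pos` (bp relative to TSS)
#'   and `ndr_width` (bp; 0 for profiles that never dip below threshold).
#' @export
ndr_metrics <- function(metaplot, classes = NULL, threshold = 0.5) {
  cls <- classes %||% unique(metaplot$class)
  bin <- attr(metaplot, "bin_bp")
  purrr::map_dfr(cls, function(cl) {
    p <- metaplot[metaplot$class == cl, , drop = FALSE]
    p <- p[order(p$position), , drop = FALSE]
    up <- p$position < 0
    if (!any(up)) abort("metaplot has no upstream coverage")
    i_min <- which(up)[which.min(p$mean_occupancy[up])]
    thr <- threshold * max(p$mean_occupancy[up])
    if (p$mean_occupancy[i_min] >= thr) {
      return(tibble(class = cl, ndr_min_pos = p$position[i_min], ndr_width = 0))
    }
    lo <- i_min
    while (lo > 1 && p$mean_occupancy[lo - 1] < thr) lo <- lo - 1
    hi <- i_min
    while (hi < nrow(p) && p$mean_occupancy[hi + 1] < thr) hi <- hi + 1
    tibble(class = cl, ndr_min_pos = p$position[i_min],
           ndr_width = (hi - lo + 1) * bin)
  })
}
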
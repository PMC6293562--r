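test_that("footprint coverage matches a per-base brute-force counter", {
  fr1 <- tibble::tibble(contig = "c", start = 0L, end = 147L)
  tr <- occupancy_from_fragments(fr1, "c", 200L)
  expect_equal(as.numeric(tr), c(rep(1, 147), rep(0, 53)))
  expect_equal(sum(tr), 147)  # conservation: sum = total fragment length

  set.seed(7)
  n <- 200
  st <- sample.int(9800, n) - 1L
  fr <- tibble::tibble(contig = "c", start = st,
                       end = st + sample(50:200, n, replace = TRUE))
  tr <- occupancy_from_fragments(fr, "c", 10000L)
  brute <- vapply(0:9999, function(b) sum(fr$start <= b & b < fr$end), numeric(1))
  expect_equal(as.numeric(tr), brute)
  expect_equal(sum(tr), sum(fr$end - fr$start))

  expect_warning(
    occupancy_from_fragments(tibble::tibble(contig = "c", start = 9950L, end = 10100L),
                             "c", 10000L), "clipped")
})

test_that("Gaussian smoothing conserves mass and preserves shape limits", {
  delta <- occupancy_track(c(rep(0, 500), 1, rep(0, 499)), "c", "midpoint_density")
  sm <- smooth_track(delta, sigma_bp = 20)
  expect_equal(which.max(sm), 501L)  # peak stays at the delta
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  # symmetric around the peak
  expect_equal(as.numeric(sm)[501 + 1:80], as.numeric(sm)[501 - 1:80])

  const <- occupancy_track(rep(3, 400), "c", "midpoint_density")
  expect_equal(as.numeric(smooth_track(const)), rep(3, 400), tolerance = 1e-9)

  set.seed(12)
  v <- rpois(2000, 1)
  sm2 <- smooth_track(occupancy_track(v, "c", "midpoint_density"), sigma_bp = 35)
  expect_equal(sum(sm2), sum(v), tolerance = 1e-6 * sum(v))
})

test_that("the caller recovers isolated peaks exactly and merges doublets", {
  mk <- function(pos, L = 2000) {
    v <- numeric(L); v[pos + 1] <- 1
    smooth_track(occupancy_track(v, "c", "midpoint_density"), sigma_bp = 20)
  }
  calls <- call_nucleosomes(mk(c(100L, 280L, 460L)))
  expect_equal(calls$dyad, c(100L, 280L, 460L))
  expect_equal(calls$category, rep("MainPeak", 3))

  dbl <- call_nucleosomes(mk(c(100L, 160L)))
  expect_equal(nrow(dbl), 1L)
  expect_equal(dbl$category, "MainPeak:doublet")
  expect_equal(dbl$dyad, 130L)  # equal heights -> midpoint

  expect_equal(nrow(call_nucleosomes(
    occupancy_track(rep(0, 100), "c", "smoothed_midpoint_density"))), 0L)
})

test_that("candidate peaks equal brute-force local maxima on short tracks", {
  set.seed(3)
  for (i in 1:5) {
    v <- rpois(2000, 0.02)
    sm <- smooth_track(occupancy_track(v, "c", "midpoint_density"), sigma_bp = 15)
    calls <- call_nucleosomes(sm, min_height = 1e-9, merge_dist = 0,
                              shoulder_dist = NULL)
    # plateau-aware enumeration: a maximal run strictly above its neighbours
    # counts once, at its center
    x <- as.numeric(sm)
    brute <- integer(0)
    i <- 1L
    while (i <= length(x)) {
      j <- i
      while (j < length(x) && x[j + 1] == x[i]) j <- j + 1L
      left <- if (i == 1L) -Inf else x[i - 1L]
      right <- if (j == length(x)) -Inf else x[j + 1L]
      if (x[i] > left && x[i] > right && x[i] > 0) {
        brute <- c(brute, as.integer(round((i + j) / 2)) - 1L)
      }
      i <- j + 1L
    }
    expect_equal(calls$dyad, brute)
  }
})

test_that("shoulder heuristics label secondary peaks in the relative-height band", {
  v <- numeric(1500)
  v[401] <- 1; v[521] <- 0.6  # 120 bp apart, relative height 0.6
  sm <- smooth_track(occupancy_track(v, "c", "midpoint_density"), sigma_bp = 15)
  calls <- call_nucleosomes(sm)
  expect_setequal(calls$category, c("MainPeak+Shoulder", "Shoulder"))
  expect_equal(calls$category[which.max(calls$height)], "MainPeak+Shoulder")
})

test_that("adjacent distances pair consecutive calls within contigs only", {
  calls <- tibble::tibble(contig = "c1", dyad = c(100L, 280L, 460L),
                          start = 0L, end = 0L, category = "MainPeak", height = 1)
  h <- adjacent_distances(calls)
  expect_equal(h$distances, c(180, 180))
  expect_equal(h$mode, 180)
  expect_equal(h$n_pairs, 2L)

  two <- dplyr::bind_rows(calls,
                          dplyr::mutate(calls, contig = "c2", dyad = dyad + 7L))
  expect_equal(adjacent_distances(two)$n_pairs, 4L)  # no cross-contig pairs

  # MainPeak-only filtering drops other categories before pairing
  calls$category <- c("MainPeak", "Shoulder", "MainPeak")
  hmp <- adjacent_distances(calls, filter = "mainpeak")
  expect_equal(hmp$distances, 360)

  expect_true(is.na(adjacent_distances(calls[1, ])$mode))
})

test_that("the full pipeline recovers simulated dyads and repeat length", {
  cfg <- sim_config(seed = 19, n_contigs = 1L, contig_length = 1.3e6,
                    n_genes = 350L, n_repeats = 0L)
  ann <- build_genome(cfg)
  mn <- simulate_mnase_fragments(ann, cfg)
  calls <- call_nucleosomes_genome(mn$fragments, ann)

  dy <- sort(calls$dyad)
  near <- function(x) {
    i <- findInterval(x, dy)
    pmin(abs(x - dy[pmax(i, 1)]), abs(dy[pmin(i + 1, length(dy))] - x))
  }
  expect_gte(mean(near(mn$truth$dyad) <= 20), 0.90)

  h <- adjacent_distances(calls, bin_bp = 5)
  expect_lte(abs(h$mode - 180), 5)  # footprint 147 + linker 33, within one bin
})

test_that("TSS metaplots are max-normalized, mirror-symmetric, and bounded", {
  # one plus-strand gene with a simple stepped track: window max rescaled to 1
  v <- numeric(4000); v[2001:2300] <- 4; v[1001:1500] <- 1
  tr <- occupancy_track(v, "c")
  genes <- tibble::tibble(gene_id = "g1", contig = "c", start = 2000L,
                          end = 3000L, strand = "+", tss = 2000L)
  cls <- tibble::tibble(gene_id = "g1", class = "high")
  mp <- tss_metaplot(tr, genes, cls)
  expect_equal(max(mp$mean_occupancy), 1)
  expect_true(all(mp$mean_occupancy >= 0 & mp$mean_occupancy <= 1))

  # a minus-strand gene over the mirrored track gives the identical profile
  vm <- rev(v)
  genes_m <- tibble::tibble(gene_id = "g1", contig = "c", start = 1000L,
                            end = 2000L, strand = "-", tss = 1999L)
  mp_m <- tss_metaplot(occupancy_track(vm, "c"), genes_m, cls)
  expect_equal(mp_m$mean_occupancy, mp$mean_occupancy)

  # scaling the track leaves the normalized metaplot unchanged
  mp_s <- tss_metaplot(occupancy_track(v * 10, "c"), genes, cls)
  expect_equal(mp_s$mean_occupancy, mp$mean_occupancy)

  # gene whose window leaves the contig is excluded and counted
  genes2 <- dplyr::bind_rows(genes,
                             tibble::tibble(gene_id = "g2", contig = "c",
                                            start = 300L, end = 1300L,
                                            strand = "+", tss = 300L))
  cls2 <- dplyr::bind_rows(cls, tibble::tibble(gene_id = "g2", class = "high"))
  mp2 <- tss_metaplot(tr, genes2, cls2)
  expect_equal(attr(mp2, "excluded_window"), 1L)
})

test_that("NDR metrics find the upstream dip and its width", {
  # V-shaped profile: flanks 1.0, dip 0.2 at -95
  pos <- seq(-995, 995, by = 10)
  val <- pmin(1, 0.2 + abs(pos + 95) / 200)
  toy <- structure(tibble::tibble(position = pos, class = "low",
                                  mean_occupancy = val, n_genes = 10L),
                   class = c("tss_metaplot", "tbl_df", "tbl", "data.frame"),
                   bin_bp = 10, window_bp = 1000)
  m <- ndr_metrics(toy)
  expect_equal(m$ndr_min_pos, -95)  # bin center at the dip
  expect_gt(m$ndr_width, 0)

  flat <- toy
  flat$mean_occupancy <- 0.7
  expect_equal(ndr_metrics(flat)$ndr_width, 0)
})

test_that("NDR width grows with simulated expression class", {
  cfg <- sim_config(seed = 23, n_contigs = 1L, contig_length = 1.3e6,
                    n_genes = 350L, n_repeats = 0L)
  ann <- build_genome(cfg)
  cls <- tibble::tibble(gene_id = ann$genes$gene_id,
                        class = rep_len(c("low", "high"), nrow(ann$genes)))
  mn <- simulate_mnase_fragments(ann, cfg, classes = cls)
  mp <- tss_metaplot(coverage_tracks(mn$fragments, ann), ann$genes, cls)
  m <- ndr_metrics(mp)
  expect_true(all(m$ndr_min_pos < 0))  # depletion sits upstream of the TSS
  expect_gt(m$ndr_width[m$class == "high"], m$ndr_width[m$class == "low"])
})
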
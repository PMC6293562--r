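test_that("generators are exactly reproducible from the root seed", {
  cfg <- small_config(seed = 21)
  a1 <- build_genome(cfg); a2 <- build_genome(cfg)
  expect_identical(a1, a2)

  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_gff3(a1, p1); write_gff3(a2, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical output
  write_bed(a1$repeats, p1); write_bed(a2$repeats, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_identical(simulate_counts(a1, cfg), simulate_counts(a1, cfg))
  expect_identical(simulate_mnase_fragments(a1, cfg), simulate_mnase_fragments(a1, cfg))
  expect_identical(simulate_cytosine_report(a1, cfg), simulate_cytosine_report(a1, cfg))
})

test_that("per-generator substreams are independent of other parameters", {
  cfg1 <- small_config(seed = 8)
  cfg2 <- small_config(seed = 8, fragments_per_nucleosome = 5)  # MNase-only change
  ann <- build_genome(cfg1)
  expect_identical(build_genome(cfg2), ann)
  expect_identical(simulate_counts(ann, cfg1), simulate_counts(ann, cfg2))
  expect_identical(simulate_cytosine_report(ann, cfg1),
                   simulate_cytosine_report(ann, cfg2))
})

test_that("genome placement respects contig bounds and gene spacing", {
  cfg <- small_config(seed = 4)
  ann <- build_genome(cfg)
  g <- ann$genes
  clen <- ann$contigs$length[match(g$contig, ann$contigs$contig)]
  expect_true(all(g$start >= 0 & g$end <= clen))
  for (ctg in unique(g$contig)) {
    s <- g[g$contig == ctg, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1) {
      expect_true(all(s$start[-1] - s$end[-nrow(s)] >= 500))  # room for upstream windows
    }
    # brute-force overlap check against repeats as well
    occ <- integer(cfg$contig_length)
    for (i in seq_len(nrow(s))) occ[(s$start[i] + 1):s$end[i]] <- occ[(s$start[i] + 1):s$end[i]] + 1L
    r <- ann$repeats[ann$repeats$contig == ctg, ]
    for (i in seq_len(nrow(r))) occ[(r$start[i] + 1):r$end[i]] <- occ[(r$start[i] + 1):r$end[i]] + 1L
    expect_true(all(occ <= 1L))
  }
  expect_true(ann$contigs$is_control[nrow(ann$contigs)])

  ann0 <- build_genome(small_config(n_genes = 0L, n_repeats = 0L))
  expect_equal(nrow(ann0$genes), 0L)
  expect_equal(nrow(ann0$contigs), 3L)

  expect_error(build_genome(small_config(n_genes = 500L)), "cannot fit")
})

test_that("simulated counts have the configured first and second moments", {
  # all genes share mu = 100; dispersion 0 is the Poisson limit
  cfg <- sim_config(seed = 13, n_contigs = 2L, contig_length = 3e6,
                    n_genes = 1500L, count_mean_range = c(100, 100),
                    nb_dispersion = 0, p_effect = 0, n_repeats = 0L)
  ann <- build_genome(cfg)
  sim <- simulate_counts(ann, cfg)
  x <- sim$counts$count  # 6000 draws from Poisson(100)
  expect_gt(length(x), 1e4 / 2)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 100), 3 * se)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)  # variance ~ mean

  expect_true(all(sim$truth$log2_effect == 0))  # p_effect = 0

  # with NB dispersion, variance tracks mu + phi mu^2
  cfg2 <- sim_config(seed = 13, n_contigs = 2L, contig_length = 3e6,
                     n_genes = 1500L, count_mean_range = c(100, 100),
                     nb_dispersion = 0.2, p_effect = 0, n_repeats = 0L)
  x2 <- simulate_counts(ann, cfg2)$counts$count
  expect_lt(abs(var(x2) / (100 + 0.2 * 100^2) - 1), 0.15)
})

test_that("mutant effect hits only low-baseline genes at rate p_effect", {
  cfg <- small_config(seed = 2, count_mean_range = c(0.2, 5e4), n_genes = 80L)
  sim <- simulate_counts(build_genome(cfg), cfg)
  tr <- sim$truth
  expect_true(all(tr$log2_effect[tr$true_class != "low"] == 0))
  expect_true(all(tr$log2_effect %in% c(0, cfg$mutant_low_effect)))
})

test_that("noise-free fragments are exact footprints at the true spacing", {
  cfg <- small_config(seed = 5, dyad_jitter_sd = 0, length_jitter = 0L,
                      background_frag_per_kb = 0)
  ann <- build_genome(cfg)
  mn <- simulate_mnase_fragments(ann, cfg)
  expect_true(all(mn$fragments$end - mn$fragments$start == 147L))

  # fixed linker: every adjacent dyad distance within an array = footprint + linker
  d <- mn$truth |>
    dplyr::filter(kind == "array") |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(d = list(abs(diff(dyad))), .groups = "drop") |>
    dplyr::pull(d) |>
    unlist()
  expect_true(all(d == 147 + 33))
})

test_that("fragment midpoints stay within four jitter sds of a true dyad", {
  cfg <- sim_config(seed = 17, n_contigs = 2L, contig_length = 1.2e6,
                    n_genes = 600L, n_repeats = 0L, background_frag_per_kb = 0)
  ann <- build_genome(cfg)
  mn <- simulate_mnase_fragments(ann, cfg)
  nearest_dyad_dist <- function(m, dy) {
    dy <- sort(dy)
    i <- findInterval(m, dy)
    pmin(abs(m - dy[pmax(i, 1)]), abs(dy[pmin(i + 1, length(dy))] - m))
  }
  ok <- unlist(lapply(unique(mn$fragments$contig), function(ctg) {
    fr <- mn$fragments[mn$fragments$contig == ctg, ]
    mid <- (fr$start + fr$end) %/% 2L
    # +1 bp allowance for midpoint rounding
    nearest_dyad_dist(mid, mn$truth$dyad[mn$truth$contig == ctg]) <=
      4 * cfg$dyad_jitter_sd + 1
  }))
  expect_gte(mean(ok), 0.9999)
})

test_that("cytosine simulation honours its rate formula in the limits", {
  ann <- build_genome(small_config())
  # perfect conversion, zero true rate -> no methylated reads anywhere
  cfg0 <- small_config(conversion_probability = 1,
                       meth_rate = c("repeat" = 0, gene_body = 0,
                                     upstream = 0, background = 0))
  cx0 <- simulate_cytosine_report(ann, cfg0)$cytosines
  expect_true(all(cx0$meth_count == 0))

  # fully methylated sites read methylated regardless of conversion
  cfg1 <- small_config(conversion_probability = 0.8,
                       meth_rate = c("repeat" = 1, gene_body = 1,
                                     upstream = 1, background = 1))
  cx1 <- simulate_cytosine_report(ann, cfg1)$cytosines
  nuclear <- cx1$contig != "contig_control"
  expect_equal(sum(cx1$unmeth_count[nuclear]), 0L)

  # control contig stays unmethylated up to conversion error
  cfg <- small_config(seed = 9)
  cx <- simulate_cytosine_report(ann, cfg)$cytosines
  ctl <- cx[cx$contig == "contig_control", ]
  n <- sum(ctl$meth_count + ctl$unmeth_count)
  p <- 1 - cfg$conversion_probability
  frac <- sum(ctl$meth_count) / n
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("mirrored genomes give statistically identical metaplots", {
  cfg <- sim_config(seed = 6, n_contigs = 1L, contig_length = 1.2e6,
                    n_genes = 300L, n_repeats = 0L)
  ann <- build_genome(cfg)
  L <- ann$contigs$length[1]
  gm <- ann$genes
  mirror <- tibble::tibble(
    gene_id = gm$gene_id, contig = gm$contig,
    start = L - gm$end, end = L - gm$start,
    strand = ifelse(gm$strand == "+", "-", "+"))
  ann_m <- genome_annotation(ann$contigs, mirror)

  classes <- tibble::tibble(gene_id = gm$gene_id, class = "neither")
  mp1 <- tss_metaplot(coverage_tracks(simulate_mnase_fragments(ann, cfg)$fragments, ann),
                      ann$genes, classes)
  mp2 <- tss_metaplot(coverage_tracks(simulate_mnase_fragments(ann_m, cfg)$fragments, ann_m),
                      ann_m$genes, classes)
  j <- dplyr::inner_join(as.data.frame(mp1), as.data.frame(mp2),
                         by = c("class", "position"))
  expect_lt(max(abs(j$mean_occupancy.x - j$mean_occupancy.y)), 0.05)
})

test_that("flat config files parse and reject unknown keys", {
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("seed = 99", "n_genes = 10", "# comment",
               "count_mean_range = 2,50000",
               "ndr_width = low:120,neither:200,high:300"), p)
  cfg <- read_sim_config(p)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$n_genes, 10)
  expect_equal(unname(cfg$ndr_width["high"]), 300)

  writeLines("not_a_key = 1", p)
  expect_error(read_sim_config(p), "unknown config key")
})
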
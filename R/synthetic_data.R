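#' Simulation configuration
#'
#' Collects every tunable parameter of the synthetic-data generators into one
#' validated object. Defaults describe a small fungal-like genome and the
#' canonical chromatin constants: a 147 bp nucleosome footprint with a fixed
#' 33 bp linker (so the default nucleosome repeat length is 180 bp, the
#' spacing at which adjacent-dyad distance distributions in fungal MNase data
#' peak), a bisulfite conversion probability of 0.99, and a mutant genotype
#' that both upregulates a random half of the weakly expressed genes by one
#' log2 unit and scales all methylation rates by 0.6.
#'
#' A single root `seed` fixes every generator exactly; each generator draws
#' from its own derived substream, so regenerating one data type never
#' perturbs the others.
#'
#' @param seed Integer root seed.
#' @param n_contigs,contig_length Number and size (bp) of nuclear contigs.
#' @param control_contig_length Size of the appended unmethylated control
#'   contig (mitochondrial stand-in; no genes or repeats are placed on it).
#' @param n_genes Total genes, spread evenly over nuclear contigs.
#' @param gene_length_mean,gene_length_sd Gene length distribution (bp).
#' @param gene_gap_range Intergenic gap range (bp) between placed genes; the
#'   lower bound keeps room for 500 bp upstream windows.
#' @param n_repeats,repeat_length Repeat intervals placed in the
#'   repeat-dedicated tail of each contig (bp).
#' @param gene_region_frac Fraction of each nuclear contig reserved for genes;
#'   repeats go in the remainder.
#' @param count_mean_range Per-gene baseline mean counts drawn log-uniformly
#'   over this range.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param n_replicates Replicates per genotype.
#' @param mutant_low_effect Log2 expression shift applied in the mutant.
#' @param p_effect Probability that a low-baseline gene receives the shift.
#' @param low_rpkm_threshold,high_rpkm_threshold Baseline-RPKM class bounds
#'   (strict `<` / `>`).
#' @param footprint_bp Nucleosome footprint (bp).
#' @param linker_bp Linker length: a single value for fixed spacing or a
#'   length-2 range for per-gap uniform draws.
#' @param dyad_jitter_sd Gaussian sd (bp) of fragment-midpoint jitter around
#'   the true dyad.
#' @param length_jitter Fragment lengths are footprint_bp plus a uniform
#'   integer in `[-length_jitter, length_jitter]`.
#' @param fragments_per_nucleosome Poisson mean fragments emitted per
#'   nucleosome.
#' @param plus_one_offset Offset (bp) added to the +1 dyad position
#'   `tss + footprint/2`.
#' @param n_upstream_nucleosomes Phased nucleosomes placed upstream of the
#'   nucleosome-depleted region (NDR).
#' @param ndr_width Named vector of NDR widths (bp) per expression class
#'   (`low`, `neither`, `high`); wider NDRs for more strongly expressed genes.
#' @param background_frag_per_kb Poisson rate of unstructured background
#'   fragments per kb of contig.
#' @param meth_rate Named vector of true methylation rates per feature class
#'   (`repeat`, `gene_body`, `upstream`, `background`).
#' @param mutant_rate_multiplier Factor applied to all methylation rates in
#'   the mutant genotype.
#' @param conversion_probability Bisulfite conversion probability; an
#'   unmethylated cytosine reads as methylated with probability
#'   `1 - conversion_probability`.
#' @param coverage_mean Poisson mean read coverage per cytosine.
#' @param cytosine_density Cytosine sites per bp.
#'
#' @return A `sim_config` object (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 4L, contig_length = 2e6,
                       control_contig_length = 1e5,
                       n_genes = 2000L,
                       gene_length_mean = 1500, gene_length_sd = 300,
                       gene_gap_range = c(600, 1800),
                       n_repeats = 200L, repeat_length = 1000,
                       gene_region_frac = 0.8,
                       count_mean_range = c(2, 5e4),
                       nb_dispersion = 0.05,
                       n_replicates = 2L,
                       mutant_low_effect = 1,
                       p_effect = 0.5,
                       low_rpkm_threshold = 1, high_rpkm_threshold = 5,
                       footprint_bp = 147L,
                       linker_bp = 33L,
                       dyad_jitter_sd = 10,
                       length_jitter = 10L,
                       fragments_per_nucleosome = 30,
                       plus_one_offset = 0L,
                       n_upstream_nucleosomes = 3L,
                       ndr_width = c(low = 120, neither = 200, high = 300),
                       background_frag_per_kb = 1,
                       meth_rate = c("repeat" = 0.2, gene_body = 0.02,
                                     upstream = 0.03, background = 0.01),
                       mutant_rate_multiplier = 0.6,
                       conversion_probability = 0.99,
                       coverage_mean = 20,
                       cytosine_density = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$footprint_bp > 0, cfg$n_contigs >= 1,
            cfg$contig_length > 0, cfg$nb_dispersion >= 0,
            length(cfg$linker_bp) %in% 1:2)
  probs <- c(cfg$p_effect, cfg$conversion_probability,
             cfg$mutant_rate_multiplier, unname(cfg$meth_rate))
  if (any(probs < 0 | probs > 1)) abort("probabilities/rates must be in [0, 1]")
  if (!all(c("repeat", "gene_body", "upstream", "background") %in% names(cfg$meth_rate))) {
    abort("`meth_rate` needs entries repeat, gene_body, upstream, background")
  }
  if (!all(c("low", "neither", "high") %in% names(cfg$ndr_width))) {
    abort("`ndr_width` needs entries low, neither, high")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Read a flat key = value simulation config file
#'
#' Parses a plain-text configuration with one `key = value` pair per line
#' (`#` comments allowed). Scalar values are numeric; ranges are
#' comma-separated (`count_mean_range = 2,50000`); named vectors use
#' `name:value` pairs (`ndr_width = low:120,neither:200,high:300`). Unknown
#' keys are an error.
#'
#' @param path Config file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  known <- names(formals(sim_config))
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% known) abort(sprintf("unknown config key: '%s'", key))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (any(grepl(":", parts, fixed = TRUE))) {
      nm <- sub(":.*", "", parts)
      v <- as.numeric(sub(".*:", "", parts))
      args[[key]] <- setNames(v, nm)
    } else {
      args[[key]] <- as.numeric(parts)
    }
  }
  do.call(sim_config, args)
}

# Derive a deterministic per-generator substream seed from the root seed.
substream <- function(config, offset) {
  (as.numeric(config$seed) * 7919 + offset * 104729) %% 2147483647
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes along each nuclear contig with intergenic
#' gaps at least as wide as the default upstream window, fills a dedicated
#' tail region of each contig with repeat intervals, and appends an
#' unmethylated control contig carrying no features. Output is byte-exactly
#' reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return A [genome_annotation()].
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(substream(config, 1), {
    L <- config$contig_length
    gene_region <- floor(config$gene_region_frac * L)
    per_contig <- diff(round(seq(0, config$n_genes, length.out = config$n_contigs + 1)))
    reps_per_contig <- diff(round(seq(0, config$n_repeats, length.out = config$n_contigs + 1)))

    genes <- list(); repeats <- list()
    for (ci in seq_len(config$n_contigs)) {
      contig <- sprintf("contig_%d", ci)
      ng <- per_contig[ci]
      if (ng > 0) {
        lens <- pmax(300L, as.integer(round(rnorm(ng, config$gene_length_mean,
                                                  config$gene_length_sd))))
        gaps <- as.integer(round(runif(ng, config$gene_gap_range[1],
                                       config$gene_gap_range[2])))
        need <- sum(lens) + sum(gaps)
        if (need > gene_region) {
          abort(sprintf(
            "cannot fit %d genes on %s: need %d bp, gene region is %d bp",
            ng, contig, need, gene_region))
        }
        starts <- cumsum(gaps) + cumsum(c(0L, lens[-ng]))
        genes[[ci]] <- tibble(
          gene_id = sprintf("g_%d_%03d", ci, seq_len(ng)),
          contig = contig,
          start = starts, end = starts + lens,
          strand = sample(c("+", "-"), ng, replace = TRUE))
      }
      nr <- reps_per_contig[ci]
      if (nr > 0) {
        rl <- as.integer(config$repeat_length)
        rgap <- 100L
        need <- nr * (rl + rgap)
        if (need > L - gene_region) {
          abort(sprintf(
            "cannot fit %d repeats on %s: need %d bp, repeat region is %d bp",
            nr, contig, need, L - gene_region))
        }
        rstart <- gene_region + rgap + (seq_len(nr) - 1L) * (rl + rgap)
        repeats[[ci]] <- tibble(contig = contig, start = as.integer(rstart),
                                end = as.integer(rstart + rl),
                                label = sprintf("rep_%d_%03d", ci, seq_len(nr)))
      }
    }
    contigs <- tibble(
      contig = c(sprintf("contig_%d", seq_len(config$n_contigs)), "contig_control"),
      length = as.integer(c(rep(L, config$n_contigs), config$control_contig_length)),
      is_control = c(rep(FALSE, config$n_contigs), TRUE))
    genome_annotation(contigs, dplyr::bind_rows(genes), dplyr::bind_rows(repeats))
  })
}

#' Simulate an RNA-seq count table with a low-expression mutant effect
#'
#' Draws per-gene baseline means log-uniformly, then negative-binomial counts
#' for each replicate of a wild-type and a mutant genotype. In the mutant,
#' genes whose baseline RPKM falls below `low_rpkm_threshold` receive a
#' `mutant_low_effect` log2 shift with probability `p_effect`; all other
#' genes are unchanged. Baseline RPKM is computed from the expected library
#' size, so the ground-truth expression class is noise-free.
#'
#' @param annotation A [genome_annotation()] (gene ids and lengths are used).
#' @param config A [sim_config()].
#' @return A list with `counts` (tidy gene x sample tibble as from
#'   [read_count_table()]) and `truth` (per-gene tibble: `gene_id`,
#'   `mu`, `true_rpkm`, `true_class`, `log2_effect`).
#' @export
simulate_counts <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"), inherits(config, "sim_config"))
  g <- annotation$genes
  if (nrow(g) == 0) abort("annotation has no genes")
  withr::with_seed(substream(config, 2), {
    n <- nrow(g)
    lr <- log(config$count_mean_range)
    mu <- exp(runif(n, lr[1], lr[2]))
    len <- g$end - g$start
    true_rpkm <- 1e9 * mu / (len * sum(mu))
    true_class <- dplyr::case_when(
      true_rpkm < config$low_rpkm_threshold ~ "low",
      true_rpkm > config$high_rpkm_threshold ~ "high",
      TRUE ~ "neither")
    hit <- true_class == "low" & runif(n) < config$p_effect
    delta <- ifelse(hit, config$mutant_low_effect, 0)

    samples <- tidyr::expand_grid(genotype = c("wt", "mutant"),
                                  replicate = seq_len(config$n_replicates)) |>
      dplyr::mutate(sample_id = paste0(.data$genotype, "_", .data$replicate))
    draw <- function(mu_s) {
      if (config$nb_dispersion == 0) rpois(n, mu_s)
      else rnbinom(n, size = 1 / config$nb_dispersion, mu = mu_s)
    }
    counts <- purrr::pmap_dfr(samples, function(genotype, replicate, sample_id) {
      mu_s <- if (genotype == "mutant") mu * 2^delta else mu
      tibble(gene_id = g$gene_id, gene_length = len,
             sample_id = sample_id, genotype = genotype,
             replicate = as.integer(replicate),
             count = as.integer(draw(mu_s)))
    })
    list(counts = counts,
         truth = tibble(gene_id = g$gene_id, mu = mu, true_rpkm = true_rpkm,
                        true_class = true_class, log2_effect = delta))
  })
}

#' Simulate MNase fragments with phased nucleosome arrays and NDRs
#'
#' For every gene, places a +1 nucleosome dyad at `tss + footprint/2 +
#' plus_one_offset` (mirrored for minus-strand genes) and continues a phased
#' array spaced `footprint + linker` into the gene body; keeps a hard
#' nucleosome-depleted exclusion zone of class-dependent width immediately
#' upstream of the TSS; and places `n_upstream_nucleosomes` phased dyads
#' beyond the NDR. Each dyad emits a Poisson number of unstranded fragments
#' whose midpoints jitter around the dyad and whose lengths jitter around the
#' footprint; a uniform low-rate background is added on every contig.
#' Both genotypes are simulated from identical parameters (differing only in
#' their random substream), reflecting chromatin structure unaffected by the
#' mutation.
#'
#' @param annotation A [genome_annotation()].
#' @param config A [sim_config()].
#' @param genotype `"wt"` or `"mutant"` (selects the random substream).
#' @param classes Optional tibble (`gene_id`, `class`) of expression classes
#'   controlling per-gene NDR width; genes without a class (or `NULL`) use
#'   class `"neither"`.
#' @return A list with `fragments` (tibble `contig`, `start`, `end`; BED
#'   convention) and `truth` (tibble `gene_id`, `contig`, `dyad`, `kind`).
#' @export
simulate_mnase_fragments <- function(annotation, config, genotype = "wt",
                                     classes = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"), inherits(config, "sim_config"))
  genotype <- match.arg(genotype, c("wt", "mutant"))
  g <- annotation$genes
  cls <- rep("neither", nrow(g))
  if (!is.null(classes)) {
    m <- match(g$gene_id, classes$gene_id)
    cls[!is.na(m)] <- classes$class[m[!is.na(m)]]
  }
  fp <- as.integer(config$footprint_bp)
  half <- fp %/% 2L
  clen <- annotation$contigs$length[match(g$contig, annotation$contigs$contig)]

  withr::with_seed(substream(config, if (genotype == "wt") 3 else 4), {
    draw_linker <- function(k) {
      lb <- config$linker_bp
      if (length(lb) == 1) rep(as.integer(lb), k)
      else as.integer(round(runif(k, lb[1], lb[2])))
    }
    truth <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
      s <- if (g$strand[i] == "+") 1L else -1L
      tss <- g$tss[i]
      span <- g$end[i] - g$start[i]
      n_down <- max(1L, (span - fp) %/% (fp + as.integer(mean(config$linker_bp))) + 1L)
      link <- draw_linker(n_down - 1L)
      down <- tss + s * (half + as.integer(config$plus_one_offset)) +
        s * cumsum(c(0L, link + fp))
      ndr <- config$ndr_width[[cls[i]]]
      n_up <- config$n_upstream_nucleosomes
      up <- integer(0)
      if (n_up > 0) {
        link_u <- draw_linker(n_up - 1L)
        up <- tss - s * (as.integer(ndr) + half) - s * cumsum(c(0L, link_u + fp))
      }
      d <- c(rev(up), down)
      kind <- c(rep("upstream", length(up)), rep("array", length(down)))
      keep <- d >= half & d < clen[i] - half
      tibble(gene_id = g$gene_id[i], contig = g$contig[i],
             dyad = as.integer(d[keep]), kind = kind[keep])
    })
    nf <- rpois(nrow(truth), config$fragments_per_nucleosome)
    dy <- rep(truth$dyad, nf)
    ctg <- rep(truth$contig, nf)
    total <- length(dy)
    mid <- as.integer(round(dy + rnorm(total, 0, config$dyad_jitter_sd)))
    jl <- as.integer(config$length_jitter)
    lens <- fp + (if (jl > 0) sample(seq(-jl, jl), total, replace = TRUE)
                  else rep(0L, total))
    fr <- tibble(contig = ctg, start = mid - lens %/% 2L,
                 end = mid - lens %/% 2L + lens)

    bg <- purrr::map_dfr(seq_len(nrow(annotation$contigs)), function(ci) {
      L <- annotation$contigs$length[ci]
      nb <- rpois(1, config$background_frag_per_kb * L / 1000)
      st <- as.integer(floor(runif(nb, 0, max(1, L - fp))))
      tibble(contig = annotation$contigs$contig[ci], start = st, end = st + fp)
    })
    fr <- dplyr::bind_rows(fr, bg)
    L_all <- annotation$contigs$length[match(fr$contig, annotation$contigs$contig)]
    fr <- fr[fr$start >= 0 & fr$end <= L_all, , drop = FALSE]
    fr <- dplyr::arrange(fr, .data$contig, .data$start, .data$end)
    list(fragments = fr, truth = truth)
  })
}

#' Simulate a per-cytosine bisulfite report
#'
#' Scatters cytosine sites uniformly at the configured density, assigns each
#' a true methylation rate by feature class (precedence: repeat > gene body >
#' upstream > background; the control contig is fully unmethylated), and
#' draws Poisson coverage and binomial methylated counts. Incomplete
#' bisulfite conversion appears as false methylation on unmethylated
#' cytosines: the observed methylation probability is
#' `r + (1 - r) * (1 - conversion_probability)`. In the mutant genotype all
#' true rates are scaled by `mutant_rate_multiplier`.
#'
#' @inheritParams simulate_mnase_fragments
#' @return A list with `cytosines` (tibble `contig`, `pos` 1-based, `strand`,
#'   `meth_count`, `unmeth_count`, `context`) and `truth` (tibble `contig`,
#'   `pos`, `feature_class`, `true_rate`).
#' @export
simulate_cytosine_report <- function(annotation, config, genotype = "wt") {
  stopifnot(inherits(annotation, "genome_annotation"), inherits(config, "sim_config"))
  genotype <- match.arg(genotype, c("wt", "mutant"))
  feats <- assign_feature_classes(annotation, upstream_len = 500L)

  withr::with_seed(substream(config, if (genotype == "wt") 5 else 6), {
    out <- purrr::map_dfr(seq_len(nrow(annotation$contigs)), function(ci) {
      contig <- annotation$contigs$contig[ci]
      L <- annotation$contigs$length[ci]
      ns <- round(config$cytosine_density * L)
      pos <- sort(sample.int(L, min(ns, L)))  # 1-based
      fc <- feats[feats$contig == contig, , drop = FALSE]
      class <- rep("background", length(pos))
      for (cl in c("upstream", "gene_body", "repeat")) {  # ascending precedence
        iv <- fc[fc$feature_class == cl, , drop = FALSE]
        if (nrow(iv)) {
          hit <- IRanges::overlapsAny(
            IRanges::IRanges(start = pos, width = 1L),
            IRanges::IRanges(start = iv$start + 1L, end = iv$end))
          class[hit] <- cl
        }
      }
      r <- unname(config$meth_rate[class])
      if (annotation$contigs$is_control[ci]) r[] <- 0
      if (genotype == "mutant") r <- r * config$mutant_rate_multiplier
      p_obs <- r + (1 - r) * (1 - config$conversion_probability)
      cov <- rpois(length(pos), config$coverage_mean)
      meth <- rbinom(length(pos), cov, p_obs)
      tibble(contig = contig, pos = pos,
             strand = sample(c("+", "-"), length(pos), replace = TRUE),
             meth_count = meth, unmeth_count = cov - meth,
             context = sample(c("CG", "CHG", "CHH"), length(pos),
                              replace = TRUE, prob = c(0.25, 0.25, 0.5)),
             feature_class = class, true_rate = r)
    })
    list(cytosines = out[, c("contig", "pos", "strand", "meth_count",
                             "unmeth_count", "context")],
         truth = out[, c("contig", "pos", "feature_class", "true_rate")])
  })
}
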
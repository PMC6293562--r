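# Scaled-down simulation configs used across tests.

small_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, n_contigs = 2L, contig_length = 2e5,
                   n_genes = 60L, n_repeats = 20L,
                   control_contig_length = 2e4, cytosine_density = 0.05)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Footprint-coverage tracks for every contig of an annotation.
coverage_tracks <- function(fragments, annotation) {
  tr <- lapply(seq_len(nrow(annotation$contigs)), function(ci) {
    occupancy_from_fragments(fragments, annotation$contigs$contig[ci],
                             annotation$contigs$length[ci],
                             mode = "footprint_coverage")
  })
  names(tr) <- annotation$contigs$contig
  tr
}

# Minimal tidy count table from a gene x sample matrix.
toy_counts <- function(m, gene_length = 1000L,
                       genotype = sub("_.*", "", colnames(m))) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    tibble::tibble(gene_id = rownames(m),
                   gene_length = rep_len(gene_length, nrow(m)),
                   sample_id = colnames(m)[j],
                   genotype = genotype[j],
                   replicate = j,
                   count = as.integer(m[, j]))
  })
}
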
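# Shared fixtures, built in code. Expensive objects are cached per test
# session so multiple test files can reuse one small simulation.

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

tiny_build <- function() {
  genome_build(c("chrA", "chrB", "spk"), c(2e5, 1.5e5, 2e4),
               spike_contigs = "spk")
}

# small but classification-grade synthetic study
tiny_config <- function(...) {
  sim_config(n_genes = 60, n_chrom = 2, chrom_length = 3e5,
             min_tss_spacing = 3000,
             depth_groseq = 50000, depth_chip = 120000,
             depth_polii = 90000, contacts_per_chrom = 3e6, ...)
}

tiny_sim <- function() {
  cached_fixture("tiny_sim", simulate_truth_genome(tiny_config()))
}

# a fragment_set from bare coordinates on tiny_build
make_frags <- function(chrom, start, end, strand = "+",
                       assay = "test", condition = "Ctrl",
                       replicate = "rep1", build = tiny_build()) {
  fragment_set(data.frame(chrom = chrom, start = start, end = end,
                          strand = strand, assay = assay,
                          condition = condition, replicate = replicate,
                          stringsAsFactors = FALSE), build)
}

# a count_matrix from a bare matrix, two conditions split evenly
make_cm <- function(counts, conditions = NULL, lengths = NULL) {
  n <- ncol(counts)
  if (is.null(conditions))
    conditions <- rep(c("A", "B"), each = n / 2)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(n))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  meta <- data.frame(sample_id = colnames(counts), condition = conditions,
                     replicate = paste0("r", stats::ave(seq_len(n),
                                                        conditions,
                                                        FUN = seq_along)),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta, lengths)
}
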
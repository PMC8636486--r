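#' Transcripts-per-million from a count matrix
#'
#' `TPM_g = 1e6 * (count_g / length_g) / sum_g(count_g / length_g)` per
#' sample. Columns with no counts at all stay all-zero (no
#' normalization); otherwise each column sums to one million.
#'
#' @param cm a [count_matrix()] with feature lengths.
#' @return numeric matrix of TPM values (features x samples) with the
#'   feature lengths kept as attribute `lengths`.
#' @export
compute_tpm <- function(cm) {
  if (is.null(cm$lengths)) stop("count matrix has no feature lengths")
  if (any(cm$lengths <= 0)) stop("feature length must be > 0")
  rate <- cm$counts / cm$lengths
  tot <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm[, tot == 0] <- 0
  attr(tpm, "lengths") <- cm$lengths
  tpm
}

#' Maternally deposited genes from unfertilized-egg TPM
#'
#' A gene is maternal iff its TPM exceeds `threshold` (strictly) in at
#' least `min_reps` replicate samples.
#'
#' @param tpm_unfertilized TPM matrix (genes x replicate samples).
#' @param threshold TPM cutoff (strict `>`).
#' @param min_reps minimal number of qualifying replicates.
#' @return character vector of maternal gene ids.
#' @export
maternal_set <- function(tpm_unfertilized, threshold = 5, min_reps = 3) {
  n_ok <- rowSums(tpm_unfertilized > threshold)
  rownames(tpm_unfertilized)[n_ok >= min_reps]
}

#' Maternal / zygotic / maternal-zygotic origin classification
#'
#' Partitions the gene universe: `zygotic` = active but not maternal,
#' `maternal` = maternal but not active, `maternal_zygotic` = both,
#' `silent` = neither.
#'
#' @param genes character vector: the gene universe.
#' @param maternal character vector of maternally deposited genes.
#' @param zygotically_active character vector of genes with active
#'   promoters at ZGA.
#' @return data frame with `gene_id` and `origin`.
#' @export
origin_classify <- function(genes, maternal, zygotically_active) {
  m <- genes %in% maternal
  a <- genes %in% zygotically_active
  origin <- ifelse(a & m, "maternal_zygotic",
            ifelse(a, "zygotic",
            ifelse(m, "maternal", "silent")))
  data.frame(gene_id = genes, origin = origin, stringsAsFactors = FALSE)
}

#' Zelda zygotic target genes
#'
#' The intersection of four conditions: expressed in control embryos
#' (TPM above `threshold`), Zelda-dependent, zygotically expressed
#' (origin strictly `zygotic`) and active at ZGA. The embryo TPM filter
#' uses the mean across replicates by default; set
#' `per_replicate = TRUE` to require `TPM > threshold` in at least
#' `min_reps` individual replicates instead.
#'
#' @param tpm_ctrl_embryos TPM matrix of control embryo samples.
#' @param zld_dependent character vector of Zelda-dependent genes.
#' @param origin data frame from [origin_classify()].
#' @param active character vector of active genes.
#' @param threshold TPM cutoff (strict `>`).
#' @param per_replicate,min_reps alternative per-replicate filter.
#' @return character vector of Zelda zygotic target gene ids.
#' @export
zelda_zygotic_targets <- function(tpm_ctrl_embryos, zld_dependent, origin,
                                  active, threshold = 5,
                                  per_replicate = FALSE, min_reps = 3) {
  expressed <- if (per_replicate)
    rownames(tpm_ctrl_embryos)[rowSums(tpm_ctrl_embryos > threshold) >=
                               min_reps]
  else
    rownames(tpm_ctrl_embryos)[rowMeans(tpm_ctrl_embryos) > threshold]
  zygotic <- origin$gene_id[origin$origin == "zygotic"]
  Reduce(intersect, list(expressed, zld_dependent, zygotic, active))
}
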
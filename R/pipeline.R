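#' Combine fragment sets
#'
#' Row-binds fragment sets that share a genome build.
#'
#' @param ... [fragment_set()] objects.
#' @return a [fragment_set()].
#' @export
combine_fragments <- function(...) {
  sets <- list(...)
  build <- attr(sets[[1]], "build")
  fragment_set(do.call(rbind, lapply(sets, as.data.frame)), build)
}

# tiny FNV-1a hash for the config echo (no external digest dependency)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full promoter-classification pipeline on synthetic data
#'
#' Executes every stage in dependency order on data generated from one
#' [sim_config()]: nascent-transcription simulation, strand-specific
#' peak calling and promoter-activity assignment; differential Pol II
#' occupancy in a Zelda knockdown to call Zelda-dependent promoters;
#' H2A.Z dyad calling and +1/-1 classification of the Zelda-independent
#' active promoters; maternal/zygotic origin and Zelda zygotic targets
#' from RNA-seq TPM; per-class differential nascent transcription in a
#' chaperone knockdown (reference-set size factors); RELACS double-ratio
#' H2A.Z quantification over active promoters; and Hi-C insulation
#' profiles with boundary distances per class. All thresholds default to
#' the pipeline's standard rule set and can be overridden via
#' `thresholds`.
#'
#' @param config a [sim_config()].
#' @param thresholds named list overriding any of the rule thresholds
#'   (see `zga_thresholds()` defaults).
#' @return object of class `zga_run`: `classification` (per-promoter
#'   table with rule provenance), `summary` (class counts/fractions and
#'   group statistics), plus intermediate results and the planted truth.
#' @export
run_zga_pipeline <- function(config = sim_config(), thresholds = list()) {
  th <- utils::modifyList(zga_thresholds(), thresholds)
  sim <- simulate_truth_genome(config)
  promoters <- select_unique_promoters(sim$transcripts,
                                       window = th$activity_dist)

  ## -- promoter activity from nascent transcription ----------------------
  gro_ctrl <- simulate_groseq(sim, config, "Ctrl")
  cov <- strand_coverage(gro_ctrl, extsize = th$extsize)
  peaks <- call_peaks(cov, q_max = th$peak_q)
  act <- assign_activity(promoters, peaks, max_dist = th$activity_dist)
  active_ids <- act$promoter_id[act$active]
  active <- promoters[promoters$promoter_id %in% active_ids, ]

  ## -- Zelda dependence from differential Pol II occupancy ---------------
  polii <- simulate_chip(sim, config, "PolII",
                         conditions = c("Ctrl", "ZldKD"))
  tc <- transcript_counts_fpkm(polii, sim$transcripts,
                               min_span = th$min_span,
                               min_sum = th$min_sum)
  sf_all <- reference_size_factors(tc$counts, rownames(tc$counts$counts))
  diff_zld <- nb_differential(tc$counts, sf_all, min_mean = th$min_mean)
  zld_tx <- call_zld_dependent(diff_zld, lfc_max = th$zld_lfc,
                               fdr_max = th$zld_fdr)
  zld_ids <- active$promoter_id[active$transcript_id %in% zld_tx]

  ## -- H2A.Z promoter classification -------------------------------------
  h2az <- simulate_chip(sim, config, "H2A.Z",
                        conditions = c("Ctrl", "DomKD"))
  h2az_ctrl <- h2az[h2az$condition == "Ctrl", ]
  h2az_ctrl <- fragment_set(as.data.frame(h2az_ctrl), sim$build)
  h2az_f <- filter_fragment_length(h2az_ctrl, th$fraglen_lo, th$fraglen_hi)
  dyads <- call_dyads(h2az_f)
  flanks <- assign_flanking_all(active, dyads, r1_max = th$r1_max,
                                r2_max = th$r2_max, r2_diff = th$r2_diff)
  h2az_cls <- classify_h2az(active, flanks, zld_dependent = zld_ids)

  ## -- maternal / zygotic origin and Zelda zygotic targets ---------------
  unfert <- simulate_rnaseq_counts(sim, config, "unfertilized")
  tpm_unf <- compute_tpm(unfert)
  maternal <- maternal_set(tpm_unf, threshold = th$tpm_min,
                           min_reps = th$tpm_reps)
  active_genes <- unique(active$gene_id)
  origin <- origin_classify(sim$truth$gene_id, maternal, active_genes)
  embryo <- simulate_rnaseq_counts(sim, config, "embryo")
  tpm_emb <- compute_tpm(embryo)
  zld_genes <- unique(active$gene_id[active$promoter_id %in% zld_ids])
  zz_targets <- zelda_zygotic_targets(tpm_emb, zld_genes, origin,
                                      active_genes,
                                      threshold = th$tpm_min)

  ## -- per-promoter class labels -----------------------------------------
  cls <- data.frame(promoters,
                    active = promoters$promoter_id %in% active_ids,
                    stringsAsFactors = FALSE)
  cls$zld_dependent <- cls$promoter_id %in% zld_ids
  cls$h2az_label <- h2az_cls$label[match(cls$promoter_id,
                                         h2az_cls$promoter_id)]
  cls$group <- ifelse(!cls$active, "inactive",
               ifelse(cls$zld_dependent, "zld", cls$h2az_label))
  cls$group[cls$group == "H2AZ_POS"] <- "h2az_pos"
  cls$group[cls$group == "H2AZ_NEG_MINUS1"] <- "h2az_neg_minus1"
  cls$group[cls$group == "H2AZ_NEG_NONE"] <- "h2az_neg_none"
  cls$origin <- origin$origin[match(cls$gene_id, origin$gene_id)]
  cls$zelda_zygotic_target <- cls$gene_id %in% zz_targets
  cls$supporting_peak <- act$supporting_peak[match(cls$promoter_id,
                                                   act$promoter_id)]
  cls$distance_to_summit <- act$distance_to_summit[match(cls$promoter_id,
                                                         act$promoter_id)]
  cls$plus1_rule <- flanks$plus1_rule[match(cls$promoter_id,
                                            flanks$promoter_id)]
  cls$minus1_rule <- flanks$minus1_rule[match(cls$promoter_id,
                                              flanks$promoter_id)]

  ## -- differential nascent transcription in the chaperone KD ------------
  gro_kd <- simulate_groseq(sim, config, "DomKD")
  gro_all <- combine_fragments(gro_ctrl, gro_kd)
  gc <- transcript_counts_fpkm(gro_all, sim$transcripts,
                               min_span = th$min_span,
                               min_sum = th$min_sum, stranded = TRUE)
  ref_tx <- sim$truth$transcript_id[sim$truth$gene_id %in% zz_targets]
  ref_tx <- intersect(ref_tx, rownames(gc$counts$counts))
  sf_gro <- if (length(ref_tx) >= 5)
    reference_size_factors(gc$counts, ref_tx)
  else reference_size_factors(gc$counts, rownames(gc$counts$counts))
  diff_kd <- nb_differential(gc$counts, sf_gro, min_mean = th$min_mean)
  cls$logFC_kd <- diff_kd$logFC[match(cls$transcript_id,
                                      diff_kd$feature_id)]

  ## -- RELACS double-ratio H2A.Z quantification ---------------------------
  ip_counts <- count_promoter_fragments(h2az, active,
                                        flank = th$relacs_flank)
  input <- simulate_chip(sim, config, "input",
                         conditions = c("Ctrl", "DomKD"))
  input_counts <- count_promoter_fragments(input, active,
                                           flank = th$relacs_flank)
  relacs <- relacs_double_ratio(ip_counts, input_counts)

  ## -- Hi-C insulation -----------------------------------------------------
  contacts <- simulate_contacts(sim, config)
  tracks <- do.call(rbind, lapply(contacts, function(cm)
    insulation_score(balance_matrix(cm),
                     min_depth = th$ins_min_depth,
                     max_depth = th$ins_max_depth, step = th$ins_step)))
  rownames(tracks) <- NULL
  boundaries <- call_boundaries(tracks, delta = th$boundary_delta)
  act_cls <- cls[cls$active, ]
  bdist <- boundary_distance(act_cls, boundaries)
  bs <- unique(tracks$end - tracks$start)[1]
  tss_bin_score <- tracks$score[match(paste(act_cls$chrom,
                                            floor(act_cls$tss / bs)),
                                      paste(tracks$chrom, tracks$bin))]

  ## -- summary -------------------------------------------------------------
  groups <- c("zld", "h2az_pos", "h2az_neg_minus1", "h2az_neg_none")
  per_class <- lapply(groups, function(g) {
    sel <- act_cls$group == g
    list(n_promoters = sum(sel),
         n_genes = length(unique(act_cls$gene_id[sel])),
         fraction_of_active = sum(sel) / nrow(act_cls),
         median_logFC_kd = stats::median(act_cls$logFC_kd[sel],
                                         na.rm = TRUE),
         median_tss_insulation = stats::median(tss_bin_score[sel],
                                               na.rm = TRUE),
         median_boundary_distance = stats::median(bdist[sel], na.rm = TRUE))
  })
  names(per_class) <- groups
  summary <- list(
    n_promoters_total = nrow(cls),
    n_active = nrow(act_cls),
    n_active_genes = length(unique(act_cls$gene_id)),
    n_maternal = length(maternal),
    n_zelda_zygotic_targets = length(zz_targets),
    h2az_pos_fraction_of_active_genes =
      length(unique(act_cls$gene_id[act_cls$group == "h2az_pos"])) /
      length(unique(act_cls$gene_id)),
    relacs_factor = relacs$factor,
    per_class = per_class,
    seed = config$seed,
    config_hash = .config_hash(unclass(config)),
    version = as.character(utils::packageVersion("zgakit")))
  structure(list(classification = cls, summary = summary, truth = sim$truth,
                 peaks = peaks, dyads = dyads, diff_zld = diff_zld,
                 diff_kd = diff_kd, relacs = relacs,
                 insulation = tracks, boundaries = boundaries,
                 config = config, thresholds = th),
            class = "zga_run")
}

#' Standard rule thresholds of the pipeline
#'
#' All classification thresholds in one place: peak calling (extension
#' 100 bp, q 0.05), activity distance (150 nt), nucleosome rules
#' (350/600/80 nt), fragment-length window (130-200 bp), TPM rule
#' (> 5 in >= 3), differential rules (logFC < -1, FDR < 0.01, span
#' >= 125 nt, sum > 10, mean >= 10), RELACS window (+/-400 nt),
#' bin-level rules (500 nt bins, mean > 25) and insulation parameters
#' (20-100 kb windows, 2 kb step, delta 0.01).
#'
#' @return named list of defaults.
#' @export
zga_thresholds <- function() {
  list(extsize = 100, peak_q = 0.05, activity_dist = 150,
       r1_max = 350, r2_max = 600, r2_diff = 80,
       fraglen_lo = 130, fraglen_hi = 200,
       tpm_min = 5, tpm_reps = 3,
       zld_lfc = -1, zld_fdr = 0.01,
       min_span = 125, min_sum = 10, min_mean = 10,
       relacs_flank = 400, bin_size = 500, bin_min_mean = 25,
       ins_min_depth = 20000, ins_max_depth = 100000, ins_step = 2000,
       boundary_delta = 0.01,
       ipms_padj = 0.05, ipms_fc = 1.5)
}

#' @export
print.zga_run <- function(x, ...) {
  s <- x$summary
  cat("zga_run (seed ", s$seed, ", config ", s$config_hash, ")\n", sep = "")
  cat(sprintf("  %d promoters, %d active (%d genes)\n",
              s$n_promoters_total, s$n_active, s$n_active_genes))
  for (g in names(s$per_class))
    cat(sprintf("  %-16s %4d promoters (%.1f%% of active), median logFC(KD) %+.2f\n",
                g, s$per_class[[g]]$n_promoters,
                100 * s$per_class[[g]]$fraction_of_active,
                s$per_class[[g]]$median_logFC_kd))
  cat(sprintf("  RELACS promoter H2A.Z factor (KD/Ctrl): %.3f\n",
              s$relacs_factor))
  invisible(x)
}

#' Compare a pipeline run against its planted truth
#'
#' Computes, per class, the recovered fraction of active promoters, the
#' planted fraction and the one-vs-rest balanced accuracy over the set
#' of truly active promoters, plus the balanced accuracy of the
#' activity call itself over all promoters.
#'
#' @param run a `zga_run`.
#' @return list: `activity_balanced_accuracy`, `class_balanced_accuracy`
#'   (named, per class), `fraction_recovered`, `fraction_planted`,
#'   `max_fraction_error`.
#' @export
evaluate_against_truth <- function(run) {
  cls <- run$classification
  truth <- run$truth[match(cls$gene_id, run$truth$gene_id), ]
  bal_acc <- function(pred, ref) {
    sens <- if (any(ref)) mean(pred[ref]) else NA_real_
    spec <- if (any(!ref)) mean(!pred[!ref]) else NA_real_
    mean(c(sens, spec), na.rm = TRUE)
  }
  act_ba <- bal_acc(cls$active, truth$active)
  groups <- c("zld", "h2az_pos", "h2az_neg_minus1", "h2az_neg_none")
  on <- truth$active  # classes are defined over active promoters
  cls_ba <- vapply(groups, function(g)
    bal_acc(cls$group[on] == g, truth$class[on] == g), numeric(1))
  frac_rec <- vapply(groups, function(g)
    sum(cls$group == g & cls$active) / max(sum(cls$active), 1), numeric(1))
  frac_planted <- vapply(groups, function(g)
    sum(truth$class == g) / sum(truth$active), numeric(1))
  list(activity_balanced_accuracy = act_ba,
       class_balanced_accuracy = cls_ba,
       fraction_recovered = frac_rec,
       fraction_planted = frac_planted,
       max_fraction_error = max(abs(frac_rec - frac_planted)))
}

#' Write a machine-readable run report
#'
#' Serializes the run summary as JSON with stable keys (all counts
#' integers, config hash included) and an optional plain-text rendering.
#'
#' @param run a `zga_run`.
#' @param path output path for the JSON; `NULL` returns the JSON string.
#' @param text_path optional path for a human-readable summary.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_report <- function(run, path = NULL, text_path = NULL) {
  s <- run$summary
  json <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(run); sink()
    close(con)
  }
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
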
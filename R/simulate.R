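#' Configuration for the synthetic embryo-genomics generator
#'
#' Bundles every tunable of the toy-data generator: genome geometry,
#' class fractions, sequencing depths, nucleosome phasing, the knockdown
#' depletion factor, spike-in share, contact decay and boundary strength,
#' and the proteomics effect/dropout model. Defaults describe a 2 x 1 Mb
#' toy genome with 400 genes and a few hundred thousand fragments per
#' assay — minutes of compute on one CPU.
#'
#' One RNG stream per assay is derived from `seed`, so adding an assay
#' never perturbs another assay's data.
#'
#' @param seed master integer seed.
#' @param n_chrom,chrom_length,spike_length genome geometry (bp).
#' @param n_genes number of genes; `min_tss_spacing` the minimum pairwise
#'   TSS distance (bp); `gene_length` a length-2 range (bp).
#' @param frac_active fraction of genes transcriptionally active at ZGA.
#' @param frac_zld_of_active fraction of active promoters that are
#'   Zelda-dependent.
#' @param frac_h2az_pos_of_zldindep fraction of Zld-independent active
#'   promoters carrying H2A.Z on the +1 nucleosome.
#' @param frac_minus1_of_h2azneg fraction of H2A.Z-negative promoters
#'   carrying H2A.Z only on the -1 nucleosome.
#' @param frac_maternal fraction of genes with maternally deposited RNA.
#' @param plus1_offset,minus1_offset planted dyad offsets (bp, signed,
#'   strand-aware).
#' @param phasing_sd Gaussian sd of fragment dyads around planted
#'   positions (bp).
#' @param kd_depletion multiplier in (0, 1] applied to H2A.Z fragment
#'   rates at planted nucleosomes in the DomKD condition.
#' @param lfc_kd named numeric: planted log2 fold change of nascent
#'   transcription / Pol II in DomKD per promoter class
#'   (`zld`, `h2az_pos`, `h2az_neg_minus1`, `h2az_neg_none`).
#' @param zld_lfc planted log2 fold change of Pol II occupancy at
#'   Zld-dependent promoters in the ZldKD condition.
#' @param depth_groseq,depth_chip,depth_polii expected fragments per
#'   sample (main genome).
#' @param n_reps_groseq,n_reps_chip,n_reps_polii,n_reps_rnaseq_unfert,n_reps_rnaseq_embryo
#'   replicate counts (Pol II uses three so the differential occupancy
#'   test retains power at its strict FDR cutoff).
#' @param chip_signal_share share of a ChIP sample's main-genome
#'   fragments that come from planted promoter nucleosomes (the rest is a
#'   uniform genomic background standing in for non-promoter chromatin).
#' @param nfr_halfwidth half-width (bp) of the nucleosome-free region
#'   around active TSSs: chromatin background fragments of nucleosomal
#'   assays are excluded from these zones (input libraries are not).
#' @param groseq_signal_share share of GRO-seq fragments from active
#'   promoters (rest uniform background).
#' @param spike_fraction expected fraction of each ChIP sample made of
#'   spike-contig fragments.
#' @param frag_length ChIP/MNase fragment length range (bp), filtered
#'   downstream to 130-200.
#' @param bin_size_hic,contact_decay,boundary_attenuation,contacts_per_chrom
#'   Hi-C simulation: bin size (bp), distance-decay exponent, attenuation
#'   multiplier for pairs spanning a planted boundary, expected total
#'   contacts per chromosome (deep, as in merged replicate matrices, so
#'   insulation noise stays well below the boundary prominence cutoff).
#' @param mu_maternal_per_kb,mu_embryo_per_kb,rnaseq_dispersion,background_count_mean
#'   RNA-seq count model.
#' @param n_proteins,frac_enriched_proteins,protein_log2fc,protein_sd,
#'   protein_base_mean,protein_base_sd,censor_quantile,n_contaminants
#'   proteomics model: planted bait enrichment, log-intensity noise and
#'   missing-not-at-random censoring below a low-intensity quantile.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2, chrom_length = 1e6, spike_length = 5e4,
                       n_genes = 400, min_tss_spacing = 3000,
                       gene_length = c(1500, 4000),
                       frac_active = 0.6,
                       frac_zld_of_active = 0.10,
                       frac_h2az_pos_of_zldindep = 0.697,
                       frac_minus1_of_h2azneg = 0.26,
                       frac_maternal = 0.5,
                       plus1_offset = 120, minus1_offset = -180,
                       phasing_sd = 20,
                       kd_depletion = 0.5,
                       lfc_kd = c(zld = 0, h2az_pos = -1.2,
                                  h2az_neg_minus1 = -0.5,
                                  h2az_neg_none = -0.2),
                       zld_lfc = -2,
                       depth_groseq = 150000, depth_chip = 300000,
                       depth_polii = 300000, nfr_halfwidth = 520,
                       n_reps_groseq = 3, n_reps_chip = 2,
                       n_reps_polii = 3,
                       n_reps_rnaseq_unfert = 4, n_reps_rnaseq_embryo = 3,
                       chip_signal_share = 0.10,
                       groseq_signal_share = 0.9,
                       spike_fraction = 0.05,
                       frag_length = c(100, 220),
                       bin_size_hic = 2000, contact_decay = 1.0,
                       boundary_attenuation = 0.2,
                       contacts_per_chrom = 2e7,
                       mu_maternal_per_kb = 100, mu_embryo_per_kb = 50,
                       rnaseq_dispersion = 0.05,
                       background_count_mean = 0.05,
                       n_proteins = 800, frac_enriched_proteins = 0.04,
                       protein_log2fc = 2, protein_sd = 0.3,
                       protein_base_mean = 25, protein_base_sd = 2,
                       censor_quantile = 0.10, n_contaminants = 20) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_genes > 0, chrom_length > 0, n_chrom >= 1,
              depth_groseq > 0, depth_chip > 0, depth_polii > 0,
              kd_depletion > 0, kd_depletion <= 1,
              frac_active >= 0, frac_active <= 1,
              frac_zld_of_active + 0 <= 1,
              spike_fraction >= 0, spike_fraction < 1,
              phasing_sd > 0, bin_size_hic > 0, contact_decay > 0,
              boundary_attenuation > 0, boundary_attenuation <= 1)
  })
  structure(cfg, class = "sim_config")
}

# Fixed per-assay RNG stream offsets; keeps assays independent of each
# other under one master seed.
.stream <- function(config, offset) {
  set.seed((as.integer(config$seed) + offset) %% .Machine$integer.max)
}

.round_count <- function(n, frac) as.integer(round(n * frac))

#' Simulate a toy genome with planted promoter classes
#'
#' Places genes on the main chromosomes at guaranteed minimum TSS
#' spacing, draws class labels per the configured fractions
#' (deterministic rounded class sizes, random membership), and plants
#' per-class chromatin features: +1/-1 H2A.Z dyad offsets, knockdown
#' log2 fold changes, maternal deposition and a TAD boundary near each
#' Zelda-dependent TSS.
#'
#' @param config a [sim_config()].
#' @return list with `build` (a [genome_build()]), `transcripts`
#'   (a [transcript_units()] table, one transcript per gene) and `truth`
#'   (data frame of planted labels per gene).
#' @export
simulate_truth_genome <- function(config) {
  .stream(config, 0L)
  chroms <- paste0("chrS", seq_len(config$n_chrom))
  build <- genome_build(c(chroms, "spike_1"),
                        c(rep(config$chrom_length, config$n_chrom),
                          config$spike_length),
                        spike_contigs = "spike_1")
  # evenly sized slots per chromosome guarantee the minimum TSS spacing
  per <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
  slot <- floor(config$chrom_length / max(per))
  jit <- floor((slot - config$min_tss_spacing) / 2)
  if (jit < 0)
    stop("genome too small for ", config$n_genes,
         " genes at minimum TSS spacing ", config$min_tss_spacing)
  rows <- list()
  g <- 0L
  for (ci in seq_len(config$n_chrom)) {
    n <- per[ci]
    if (n == 0) next
    centers <- floor(slot / 2) + slot * (seq_len(n) - 1L)
    tss <- centers + if (jit > 0) sample(-jit:jit, n, replace = TRUE) else 0L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- sample(config$gene_length[1]:config$gene_length[2], n,
                  replace = TRUE)
    start <- ifelse(strand == "+", tss, tss - len + 1L)
    end <- ifelse(strand == "+", tss + len, tss + 1L)
    start <- pmax(start, 0L)
    end <- pmin(end, config$chrom_length)
    ids <- sprintf("g%04d", g + seq_len(n))
    rows[[ci]] <- data.frame(
      transcript_id = paste0(ids, ".t1"), gene_id = ids,
      chrom = chroms[ci], strand = strand,
      start = as.integer(start), end = as.integer(end),
      stringsAsFactors = FALSE)
    g <- g + n
  }
  tx <- transcript_units(do.call(rbind, rows), build)

  n <- nrow(tx)
  active <- rep(FALSE, n)
  active[sample.int(n, .round_count(n, config$frac_active))] <- TRUE
  idx_active <- which(active)
  zld <- rep(FALSE, n)
  zld[sample(idx_active,
             .round_count(length(idx_active), config$frac_zld_of_active))] <- TRUE
  idx_indep <- which(active & !zld)
  h2az_pos <- rep(FALSE, n)
  h2az_pos[sample(idx_indep,
                  .round_count(length(idx_indep),
                               config$frac_h2az_pos_of_zldindep))] <- TRUE
  idx_neg <- which(active & !zld & !h2az_pos)
  minus1_only <- rep(FALSE, n)
  minus1_only[sample(idx_neg,
                     .round_count(length(idx_neg),
                                  config$frac_minus1_of_h2azneg))] <- TRUE
  maternal <- rep(FALSE, n)
  maternal[sample.int(n, .round_count(n, config$frac_maternal))] <- TRUE

  class_lab <- ifelse(!active, "inactive",
               ifelse(zld, "zld",
               ifelse(h2az_pos, "h2az_pos",
               ifelse(minus1_only, "h2az_neg_minus1", "h2az_neg_none"))))
  lfc <- ifelse(class_lab %in% names(config$lfc_kd),
                config$lfc_kd[class_lab], 0)
  truth <- data.frame(
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    chrom = tx$chrom, strand = tx$strand, tss = tx$tss,
    active = active, zld_dependent = zld,
    class = class_lab,
    h2az_plus1 = ifelse(h2az_pos, config$plus1_offset, NA_real_),
    h2az_minus1 = ifelse(h2az_pos | minus1_only, config$minus1_offset,
                         NA_real_),
    maternal = maternal,
    planted_logFC_kd = as.numeric(lfc),
    boundary_near_tss = zld,
    stringsAsFactors = FALSE)
  list(build = build, transcripts = tx, truth = truth)
}

#' Write / read the planted truth table
#' @param truth,path data frame from [simulate_truth_genome()]; file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}

# uniform background fragments over the main chromosomes
.background_frags <- function(build, n, len_range, stranded = TRUE) {
  chroms <- main_chromosomes(build)
  lens <- build$length[chroms]
  ch <- sample(chroms, n, replace = TRUE, prob = lens)
  pos <- floor(stats::runif(n) * (build$length[ch] - max(len_range)))
  flen <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  data.frame(chrom = ch, start = pos, end = pos + flen,
             strand = if (stranded) sample(c("+", "-"), n, replace = TRUE)
                      else "+",
             stringsAsFactors = FALSE)
}

#' Simulate nascent-transcription (GRO-seq) fragments
#'
#' Active promoters emit sense-strand fragments whose 5' ends fall from
#' the TSS into the gene body (a promoter-proximal exponential component
#' plus a uniform gene-body component) over a uniform Poisson background
#' on both strands. Inactive promoters emit background only.
#'
#' @param sim output of [simulate_truth_genome()].
#' @param config a [sim_config()].
#' @param condition condition label; in "DomKD" each gene's rate is
#'   scaled by its planted log2 fold change.
#' @return a [fragment_set()] (assay "GROseq").
#' @export
simulate_groseq <- function(sim, config, condition = "Ctrl") {
  .stream(config, 11L + (condition != "Ctrl") * 2L)
  truth <- sim$truth; tx <- sim$transcripts
  read_len <- 30L
  out <- vector("list", config$n_reps_groseq)
  idx <- which(truth$active)
  glen <- tx$end - tx$start
  w <- rep(1, length(idx))
  if (condition != "Ctrl") w <- w * 2^truth$planted_logFC_kd[idx]
  for (r in seq_len(config$n_reps_groseq)) {
    n_sig <- if (length(idx)) stats::rpois(1, config$depth_groseq *
                               config$groseq_signal_share * mean(w)) else 0L
    n_bg <- stats::rpois(1, config$depth_groseq *
                              (1 - config$groseq_signal_share))
    if (n_sig > 0) {
      gi <- idx[sample.int(length(idx), n_sig, replace = TRUE, prob = w)]
      prox <- stats::runif(n_sig) < 0.6
      off <- ifelse(prox, stats::rexp(n_sig, 1 / 40),
                    stats::runif(n_sig) * (glen[gi] - read_len))
      off <- pmin(pmax(floor(off), 0), glen[gi] - read_len)
      p5 <- ifelse(tx$strand[gi] == "+", tx$tss[gi] + off, tx$tss[gi] - off)
      start <- ifelse(tx$strand[gi] == "+", p5, p5 - read_len + 1)
      sig <- data.frame(chrom = tx$chrom[gi], start = start,
                        end = start + read_len, strand = tx$strand[gi],
                        stringsAsFactors = FALSE)
    } else {
      sig <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
    }
    bg <- .background_frags(sim$build, n_bg, c(read_len, read_len))
    d <- rbind(sig, bg)
    d$assay <- "GROseq"; d$condition <- condition
    d$replicate <- paste0("rep", r)
    out[[r]] <- d
  }
  fragment_set(do.call(rbind, out), sim$build)
}

# planted nucleosome positions (genomic bp) for the chromatin assays
.planted_dyads <- function(truth) {
  plus <- truth[!is.na(truth$h2az_plus1), ]
  minus <- truth[!is.na(truth$h2az_minus1), ]
  data.frame(
    chrom = c(plus$chrom, minus$chrom),
    pos = c(ifelse(plus$strand == "+", plus$tss + plus$h2az_plus1,
                   plus$tss - plus$h2az_plus1),
            ifelse(minus$strand == "+", minus$tss + minus$h2az_minus1,
                   minus$tss - minus$h2az_minus1)),
    gene_id = c(plus$gene_id, minus$gene_id),
    stringsAsFactors = FALSE)
}

#' Simulate chromatin-assay fragments (H2A.Z / MNase / PolII / input)
#'
#' H2A.Z and MNase fragments are nucleosome-sized with dyads Gaussian
#' around the planted +1/-1 positions; in condition "DomKD" the H2A.Z
#' fragment rate at planted nucleosomes is multiplied by the configured
#' depletion factor (MNase occupancy is unchanged - the nucleosome stays,
#' the variant is exchanged). Pol II fragments track active gene bodies,
#' scaled in knockdown conditions by the planted per-gene log2 fold
#' change ("DomKD") or by `zld_lfc` at Zelda-dependent genes ("ZldKD").
#' The input assay has a uniform fragment rate and no nucleosome
#' structure. Every sample additionally emits spike-contig fragments at
#' its configured spike fraction.
#'
#' @param sim output of [simulate_truth_genome()].
#' @param config a [sim_config()].
#' @param assay one of "H2A.Z", "MNase", "PolII", "input".
#' @param conditions condition labels to simulate.
#' @param n_reps replicates per condition (defaults to the assay's
#'   configured replicate count).
#' @param spike_fraction expected spike-in read share per sample
#'   (recycled across samples).
#' @return a [fragment_set()].
#' @export
simulate_chip <- function(sim, config, assay,
                          conditions = c("Ctrl", "DomKD"),
                          n_reps = if (assay == "PolII")
                            config$n_reps_polii else config$n_reps_chip,
                          spike_fraction = config$spike_fraction) {
  offs <- c("H2A.Z" = 21L, "MNase" = 22L, "PolII" = 23L, "input" = 24L)
  if (!assay %in% names(offs)) stop("unknown assay: ", assay)
  .stream(config, offs[[assay]])
  truth <- sim$truth; tx <- sim$transcripts; build <- sim$build
  dyads <- .planted_dyads(truth)
  spike_fraction <- rep_len(spike_fraction, length(conditions) * n_reps)
  lr <- config$frag_length
  out <- list(); k <- 0L
  for (cond in conditions) for (r in seq_len(n_reps)) {
    k <- k + 1L
    if (assay %in% c("H2A.Z", "MNase")) {
      sig_rate <- config$depth_chip * config$chip_signal_share
      if (assay == "H2A.Z" && cond == "DomKD")
        sig_rate <- sig_rate * config$kd_depletion
      bg_rate <- config$depth_chip * (1 - config$chip_signal_share)
      n_sig <- if (nrow(dyads)) stats::rpois(1, sig_rate) else 0L
      n_bg <- stats::rpois(1, bg_rate)
      di <- sample.int(max(nrow(dyads), 1), n_sig, replace = TRUE)
      dy <- round(dyads$pos[di] + stats::rnorm(n_sig, 0, config$phasing_sd))
      flen <- sample(lr[1]:lr[2], n_sig, replace = TRUE)
      start <- dy - floor(flen / 2)
      sig <- data.frame(chrom = dyads$chrom[di], start = start,
                        end = start + flen,
                        strand = sample(c("+", "-"), n_sig, replace = TRUE),
                        stringsAsFactors = FALSE)
      bg <- .background_frags(build, n_bg, lr)
      # nucleosome-free regions: chromatin background stays out of
      # active-promoter windows
      act <- truth[truth$active, ]
      if (nrow(act)) {
        bmid <- (bg$start + bg$end - 1) / 2
        bgr <- GenomicRanges::GRanges(bg$chrom,
                                      IRanges::IRanges(bmid + 1, width = 1))
        wgr <- GenomicRanges::GRanges(
          act$chrom,
          IRanges::IRanges(pmax(act$tss - config$nfr_halfwidth, 0) + 1,
                           act$tss + config$nfr_halfwidth + 1))
        bg <- bg[GenomicRanges::countOverlaps(bgr, wgr) == 0, ]
      }
      d <- rbind(sig, bg)
    } else if (assay == "PolII") {
      idx <- which(truth$active)
      w <- rep(1, length(idx))
      if (cond == "DomKD") w <- w * 2^truth$planted_logFC_kd[idx]
      if (cond == "ZldKD")
        w <- w * ifelse(truth$zld_dependent[idx], 2^config$zld_lfc, 1)
      mean_rate <- config$depth_polii * 0.9 * mean(w)
      n_sig <- if (length(idx)) stats::rpois(1, mean_rate) else 0L
      n_bg <- stats::rpois(1, config$depth_polii * 0.1)
      gi <- idx[sample.int(length(idx), n_sig, replace = TRUE, prob = w)]
      glen <- tx$end[gi] - tx$start[gi]
      flen <- 200L
      pos <- tx$start[gi] + floor(stats::runif(n_sig) *
                                  pmax(glen - flen, 1))
      sig <- data.frame(chrom = tx$chrom[gi], start = pos, end = pos + flen,
                        strand = sample(c("+", "-"), n_sig, replace = TRUE),
                        stringsAsFactors = FALSE)
      d <- rbind(sig, .background_frags(build, n_bg, c(flen, flen)))
    } else {  # input
      n_bg <- stats::rpois(1, config$depth_chip)
      d <- .background_frags(build, n_bg, lr)
    }
    sf <- spike_fraction[k]
    n_spike <- stats::rpois(1, nrow(d) * sf / (1 - sf))
    if (n_spike > 0 && length(build$spike)) {
      slen <- build$length[build$spike[1]]
      flen <- sample(lr[1]:lr[2], n_spike, replace = TRUE)
      pos <- floor(stats::runif(n_spike) * (slen - max(lr)))
      d <- rbind(d, data.frame(chrom = build$spike[1], start = pos,
                               end = pos + flen,
                               strand = sample(c("+", "-"), n_spike,
                                               replace = TRUE),
                               stringsAsFactors = FALSE))
    }
    d$assay <- assay; d$condition <- cond; d$replicate <- paste0("rep", r)
    out[[k]] <- d
  }
  fragment_set(do.call(rbind, out), build)
}

#' Simulate RNA-seq gene counts
#'
#' Unfertilized-egg samples give maternal genes high negative-binomial
#' counts and everything else a near-zero Poisson background; embryo
#' samples additionally express the active (zygotic) genes.
#'
#' @param sim output of [simulate_truth_genome()].
#' @param config a [sim_config()].
#' @param sample_kind "unfertilized" or "embryo".
#' @param condition condition label for the sample metadata.
#' @return a [count_matrix()] with gene lengths attached.
#' @export
simulate_rnaseq_counts <- function(sim, config,
                                   sample_kind = c("unfertilized", "embryo"),
                                   condition = "Ctrl") {
  sample_kind <- match.arg(sample_kind)
  .stream(config, if (sample_kind == "unfertilized") 31L else 32L)
  truth <- sim$truth; tx <- sim$transcripts
  n_reps <- if (sample_kind == "unfertilized") config$n_reps_rnaseq_unfert
            else config$n_reps_rnaseq_embryo
  len_kb <- (tx$end - tx$start) / 1000
  mu <- rep(config$background_count_mean, nrow(tx))
  if (sample_kind == "unfertilized") {
    mu[truth$maternal] <- config$mu_maternal_per_kb * len_kb[truth$maternal]
  } else {
    mu[truth$maternal] <- config$mu_maternal_per_kb * len_kb[truth$maternal]
    expr <- truth$active
    mu[expr] <- mu[expr] + config$mu_embryo_per_kb * len_kb[expr]
  }
  size <- 1 / config$rnaseq_dispersion
  counts <- sapply(seq_len(n_reps), function(r)
    ifelse(mu > 1,
           stats::rnbinom(length(mu), mu = mu, size = size),
           stats::rpois(length(mu), mu)))
  rownames(counts) <- truth$gene_id
  sid <- paste0(sample_kind, "_", condition, "_rep", seq_len(n_reps))
  colnames(counts) <- sid
  meta <- data.frame(sample_id = sid, condition = condition,
                     replicate = paste0("rep", seq_len(n_reps)),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta,
               lengths = stats::setNames(tx$end - tx$start, truth$gene_id))
}

#' Simulate distance-decay contact matrices with planted boundaries
#'
#' Expected counts follow `|i - j|^(-decay)`, multiplied by the
#' attenuation factor once per planted boundary a bin pair spans, then
#' Poisson sampled and symmetrized. Boundaries are planted at the bins of
#' TSSs flagged `boundary_near_tss` in the truth table.
#'
#' @param sim output of [simulate_truth_genome()].
#' @param config a [sim_config()].
#' @return named list of [contact_matrix()] per main chromosome, with
#'   attribute `boundaries`: per chromosome, the planted boundary bins.
#' @export
simulate_contacts <- function(sim, config) {
  .stream(config, 41L)
  truth <- sim$truth
  bs <- config$bin_size_hic
  res <- list(); planted <- list()
  for (ch in main_chromosomes(sim$build)) {
    n <- ceiling(sim$build$length[ch] / bs)
    b <- sort(unique(floor(truth$tss[truth$boundary_near_tss &
                                     truth$chrom == ch] / bs)))
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- ifelse(d == 0, 1, d^(-config$contact_decay))
    if (length(b)) {
      # boundary between bins b-1 and b (0-based): crossings per pair
      cum <- stats::stepfun(b, c(0, seq_along(b)))(seq_len(n) - 1L)
      ncross <- abs(outer(cum, cum, "-"))
      w <- w * config$boundary_attenuation^ncross
    }
    ut <- upper.tri(w, diag = TRUE)
    scale <- config$contacts_per_chrom / sum(w[ut])
    m <- matrix(0, n, n)
    m[ut] <- stats::rpois(sum(ut), w[ut] * scale)
    m <- m + t(m) - diag(diag(m))
    res[[ch]] <- contact_matrix(ch, bs, m)
    planted[[ch]] <- b
  }
  attr(res, "boundaries") <- planted
  res
}

#' Simulate a label-free proteomics intensity table
#'
#' Per-protein baseline log2 intensities are normal; a planted fraction
#' of proteins is enriched in the bait group by a configured log2 fold
#' change; per-measurement noise is normal; values below a low-intensity
#' quantile are censored to missing (missing-not-at-random); contaminant,
#' decoy and site-only rows are injected and flagged.
#'
#' @param config a [sim_config()].
#' @param n_reps replicates per group.
#' @return a [protein_table()]; attribute `enriched` marks the planted
#'   proteins.
#' @export
simulate_proteomics <- function(config, n_reps = 3) {
  .stream(config, 51L)
  n <- config$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  base <- stats::rnorm(n, config$protein_base_mean, config$protein_base_sd)
  enriched <- rep(FALSE, n)
  enriched[sample.int(n, .round_count(n, config$frac_enriched_proteins))] <-
    TRUE
  groups <- rep(c("bait", "control"), each = n_reps)
  sid <- paste0(groups, "_rep", rep(seq_len(n_reps), 2))
  mu <- outer(base, rep(1, 2 * n_reps))
  mu[enriched, groups == "bait"] <- mu[enriched, groups == "bait"] +
    config$protein_log2fc
  x <- mu + stats::rnorm(length(mu), 0, config$protein_sd)
  censor <- stats::quantile(x, config$censor_quantile)
  x[x < censor] <- NA
  # flagged junk rows
  nc <- config$n_contaminants
  junk <- matrix(stats::rnorm(3 * nc * 2 * n_reps,
                              config$protein_base_mean,
                              config$protein_base_sd),
                 nrow = 3 * nc)
  x <- rbind(x, junk)
  ids <- c(ids, sprintf("CON_%03d", seq_len(nc)),
           sprintf("REV_%03d", seq_len(nc)),
           sprintf("SITE_%03d", seq_len(nc)))
  flags <- data.frame(
    contaminant = c(rep(FALSE, n), rep(TRUE, nc), rep(FALSE, 2 * nc)),
    decoy = c(rep(FALSE, n + nc), rep(TRUE, nc), rep(FALSE, nc)),
    site_only = c(rep(FALSE, n + 2 * nc), rep(TRUE, nc)))
  rownames(x) <- ids
  colnames(x) <- sid
  tab <- protein_table(x, stats::setNames(groups, sid), flags)
  attr(tab, "enriched") <- c(enriched, rep(FALSE, 3 * nc))
  tab
}
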
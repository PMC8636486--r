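#' Median-of-ratios size factors on a reference feature set
#'
#' Size factors are computed only from the given reference features
#' (e.g. a set of genes known to be unchanged between conditions):
#' per sample, the median log-ratio of its counts to the feature-wise
#' geometric mean, exponentiated and normalized to geometric mean one
#' across samples. Reference features with a zero count in any sample
#' are excluded.
#'
#' @param cm a [count_matrix()].
#' @param reference character vector of reference feature ids.
#' @return data frame: `sample_id`, `size_factor`, `source`.
#' @export
reference_size_factors <- function(cm, reference) {
  bad <- setdiff(reference, rownames(cm$counts))
  if (length(bad)) stop("reference features absent from counts: ",
                        paste(utils::head(bad, 3), collapse = ", "))
  k <- cm$counts[reference, , drop = FALSE]
  usable <- rowSums(k == 0) == 0
  if (!any(usable)) stop("no usable reference feature (all contain zeros)")
  k <- k[usable, , drop = FALSE]
  logratio <- log(k) - rowMeans(log(k))
  sf <- exp(apply(logratio, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))  # geometric mean 1
  data.frame(sample_id = colnames(cm$counts), size_factor = as.numeric(sf),
             source = "reference_set", stringsAsFactors = FALSE)
}

#' Spike-in size factors
#'
#' Per-sample scaling factors inversely proportional to the sample's
#' spike-in read share, normalized to geometric mean one. When `totals`
#' is omitted the raw spike counts are used (valid when the samples were
#' sequenced to comparable depth).
#'
#' @param spike_counts named numeric: spike-contig fragment count per
#'   sample.
#' @param totals optional named numeric of total fragments per sample;
#'   shares `spike/total` are then used instead of raw counts.
#' @return data frame: `sample_id`, `size_factor`, `source`.
#' @export
spikein_size_factors <- function(spike_counts, totals = NULL) {
  if (any(spike_counts <= 0))
    stop("zero spike-in counts in sample(s): ",
         paste(names(spike_counts)[spike_counts <= 0], collapse = ", "))
  share <- if (is.null(totals)) spike_counts
           else spike_counts / totals[names(spike_counts)]
  f <- 1 / share
  f <- f / exp(mean(log(f)))
  data.frame(sample_id = names(spike_counts), size_factor = as.numeric(f),
             source = "spike_in", stringsAsFactors = FALSE)
}

# method-of-moments NB dispersion from normalized counts, pooled
# within-condition (removes the condition signal), floored at 1e-8
.mom_dispersion <- function(norm, condition) {
  groups <- split(seq_along(condition), condition)
  ss <- 0; df <- 0
  for (g in groups) {
    if (length(g) < 2) next
    m <- rowMeans(norm[, g, drop = FALSE])
    ss <- ss + rowSums((norm[, g, drop = FALSE] - m)^2)
    df <- df + length(g) - 1
  }
  s2 <- ss / df
  mu <- rowMeans(norm)
  pmax((s2 - mu) / mu^2, 1e-8)
}

# IRLS fit of a NB GLM with log link, fixed dispersion, offset log(sf)
.nb_irls <- function(y, X, sf, alpha, max_iter = 50, tol = 1e-8) {
  off <- log(sf)
  beta <- qr.solve(X, log(pmax(y / sf, 0.5)))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- eta - off + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    new <- fit$coefficients
    if (any(!is.finite(new))) break
    delta <- max(abs(new - beta))
    beta <- new
    if (delta < tol) break
  }
  eta <- drop(X %*% beta) + off
  mu <- pmin(exp(eta), 1e12)
  w <- mu / (1 + alpha * mu)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  list(beta = beta, cov = cov, mu = mu)
}

#' Negative-binomial differential analysis
#'
#' A self-contained NB engine: features with mean raw count below
#' `min_mean` (across all samples) are removed; per-feature dispersions
#' come from a method-of-moments estimate on size-factor-normalized
#' counts pooled within condition (floored at 1e-8); a NB generalized
#' linear model with a condition covariate (plus optional replicate
#' blocking) is fitted by iteratively reweighted least squares; the
#' condition coefficient is tested with a Wald test against a
#' t reference with the model's residual degrees of freedom, and BH
#' q-values are reported.
#'
#' @param cm a [count_matrix()]; `cm$meta$condition` must have exactly
#'   two levels with at least two samples each.
#' @param size_factors data frame from [reference_size_factors()] /
#'   [spikein_size_factors()], or a named numeric; `NULL` sets all to 1.
#' @param min_mean filter threshold on the mean raw count (strict `<`
#'   removed).
#' @param block_replicate add replicate as a blocking covariate
#'   (`~ replicate + condition`).
#' @return data frame: `feature_id`, `logFC` (log2, second condition
#'   level vs first), `p`, `fdr`, `mean` (mean normalized count).
#' @export
nb_differential <- function(cm, size_factors = NULL, min_mean = 10,
                            block_replicate = FALSE) {
  counts <- cm$counts
  cond <- factor(cm$meta$condition)
  if (nlevels(cond) != 2) stop("need exactly two conditions")
  if (any(table(cond) < 2)) stop("need >= 2 samples per condition")
  sf <- if (is.null(size_factors)) rep(1, ncol(counts))
        else if (is.data.frame(size_factors))
          size_factors$size_factor[match(colnames(counts),
                                         size_factors$sample_id)]
        else size_factors[colnames(counts)]
  if (any(!is.finite(sf) | sf <= 0)) stop("invalid size factors")
  keep <- rowMeans(counts) >= min_mean
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) stop("no features pass the mean-count filter")
  norm <- sweep(counts, 2, sf, "/")
  alpha <- .mom_dispersion(norm, cond)
  X <- stats::model.matrix(
    if (block_replicate) ~ factor(cm$meta$replicate) + cond else ~ cond)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  ci <- ncol(X)  # condition coefficient is last
  df_resid <- ncol(counts) - ncol(X)
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    fit <- .nb_irls(counts[i, ], X, sf, alpha[i])
    if (is.null(fit$cov)) return(c(NA_real_, NA_real_))
    c(fit$beta[ci], sqrt(fit$cov[ci, ci]))
  }, numeric(2)))
  z <- res[, 1] / res[, 2]
  # t reference with the residual df: the plug-in variance rests on a
  # moment dispersion estimate carrying only ~df_resid df, and the
  # normal reference is visibly anticonservative at these sample sizes
  p <- 2 * stats::pt(-abs(z), df = df_resid)
  data.frame(feature_id = rownames(counts),
             logFC = res[, 1] / log(2),
             p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             mean = rowMeans(norm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call condition-dependent features from differential results
#'
#' Features with `logFC < lfc_max` AND `fdr < fdr_max` (both strict);
#' with the defaults, the rule used to call Zelda-dependent promoters
#' from differential Pol II occupancy in Zelda mutants.
#'
#' @param diff data frame from [nb_differential()].
#' @param lfc_max log2 fold-change threshold (strict `<`).
#' @param fdr_max FDR threshold (strict `<`).
#' @return character vector of feature ids.
#' @export
call_zld_dependent <- function(diff, lfc_max = -1, fdr_max = 0.01) {
  diff$feature_id[!is.na(diff$p) & diff$logFC < lfc_max &
                  diff$fdr < fdr_max]
}

#' Per-transcript fragment counts and FPKM
#'
#' A fragment overlapping k transcripts contributes one count to each
#' (occupancy-style, strand-agnostic by default). Transcripts spanning
#' fewer than `min_span` bp, and transcripts whose counts summed over
#' all samples do not exceed `min_sum`, are dropped.
#' `FPKM = 1e9 * count / (library_size * span)`, with the library size
#' the sample's total (main-genome) fragment count.
#'
#' @param fragments a [fragment_set()] (samples = condition x replicate).
#' @param transcripts a [transcript_units()] data frame.
#' @param min_span minimal transcript span, bp (strict `<` dropped).
#' @param min_sum minimal total count over all samples (strict `>` kept).
#' @param stranded count only fragments on the transcript's strand.
#' @return list: `counts` (a [count_matrix()] with transcript spans as
#'   lengths), `fpkm` (matrix), `library_sizes` (named numeric).
#' @export
transcript_counts_fpkm <- function(fragments, transcripts, min_span = 125,
                                   min_sum = 10, stranded = FALSE) {
  build <- attr(fragments, "build")
  tx <- as.data.frame(transcripts)
  span <- tx$end - tx$start
  keep_tx <- span >= min_span
  tx <- tx[keep_tx, , drop = FALSE]; span <- span[keep_tx]
  sample_id <- paste(fragments$condition, fragments$replicate, sep = "_")
  samples <- unique(sample_id)
  main <- fragments$chrom %in% main_chromosomes(build)
  txgr <- GenomicRanges::GRanges(tx$chrom,
                                 IRanges::IRanges(tx$start + 1, tx$end),
                                 strand = tx$strand)
  counts <- matrix(0L, nrow(tx), length(samples),
                   dimnames = list(tx$transcript_id, samples))
  libsize <- stats::setNames(numeric(length(samples)), samples)
  for (s in samples) {
    f <- fragments[sample_id == s & main, , drop = FALSE]
    libsize[s] <- nrow(f)
    fgr <- GenomicRanges::GRanges(f$chrom,
                                  IRanges::IRanges(f$start + 1, f$end),
                                  strand = f$strand)
    counts[, s] <- GenomicRanges::countOverlaps(
      txgr, fgr, ignore.strand = !stranded)
  }
  keep <- rowSums(counts) > min_sum
  counts <- counts[keep, , drop = FALSE]
  tx <- tx[keep, , drop = FALSE]; span <- span[keep]
  if (!nrow(tx)) stop("no transcripts pass the span/count filters")
  meta <- data.frame(
    sample_id = samples,
    condition = vapply(strsplit(samples, "_"), `[`, "", 1),
    replicate = vapply(strsplit(samples, "_"), `[`, "", 2),
    stringsAsFactors = FALSE)
  fpkm <- 1e9 * sweep(sweep(counts, 2, libsize, "/"), 1, span, "/")
  list(counts = count_matrix(counts, meta,
                             stats::setNames(span, tx$transcript_id)),
       fpkm = fpkm, library_sizes = libsize)
}

#' Count fragments in promoter windows
#'
#' Sums fragments overlapping TSS +/- `flank` windows, per sample, and
#' records each sample's main-genome library size - the inputs to the
#' RELACS double-ratio quantification.
#'
#' @param fragments a [fragment_set()].
#' @param promoters data frame with `chrom`, `tss` and an id column.
#' @param flank half-window around the TSS, bp.
#' @return a [count_matrix()] (regions x samples) with attribute
#'   `library_sizes`.
#' @export
count_promoter_fragments <- function(fragments, promoters, flank = 400) {
  build <- attr(fragments, "build")
  idcol <- if ("promoter_id" %in% names(promoters)) "promoter_id"
           else "transcript_id"
  sample_id <- paste(fragments$condition, fragments$replicate, sep = "_")
  samples <- unique(sample_id)
  main <- fragments$chrom %in% main_chromosomes(build)
  wgr <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(pmax(promoters$tss - flank, 0) + 1,
                     promoters$tss + flank + 1))
  counts <- matrix(0L, nrow(promoters), length(samples),
                   dimnames = list(promoters[[idcol]], samples))
  libsize <- stats::setNames(numeric(length(samples)), samples)
  for (s in samples) {
    f <- fragments[sample_id == s & main, , drop = FALSE]
    libsize[s] <- nrow(f)
    fgr <- GenomicRanges::GRanges(f$chrom,
                                  IRanges::IRanges(f$start + 1, f$end))
    counts[, s] <- GenomicRanges::countOverlaps(wgr, fgr)
  }
  meta <- data.frame(
    sample_id = samples,
    condition = vapply(strsplit(samples, "_"), `[`, "", 1),
    replicate = vapply(strsplit(samples, "_"), `[`, "", 2),
    stringsAsFactors = FALSE)
  cm <- count_matrix(counts, meta)
  attr(cm, "library_sizes") <- libsize
  cm
}

#' RELACS double-ratio scaling factor
#'
#' Library-size-corrected double ratio of IP and input over a region
#' set: `[(IP_KD/L) / (IP_Ctrl/L)] / [(In_KD/L) / (In_Ctrl/L)]` using
#' counts summed over regions and replicates (pooled). A factor below 1
#' means depletion in the knockdown. The per-region median factor is
#' also reported (regions with a zero term are skipped there).
#'
#' @param ip_counts,input_counts region x sample [count_matrix()]es from
#'   [count_promoter_fragments()] (with `library_sizes` attributes), for
#'   the IP and the input libraries.
#' @param ctrl,kd condition labels.
#' @return list: `factor` (pooled double ratio), `per_region_median`,
#'   `ip_ratio`, `input_ratio`.
#' @export
relacs_double_ratio <- function(ip_counts, input_counts,
                                ctrl = "Ctrl", kd = "DomKD") {
  rate <- function(cm, cond) {
    sel <- cm$meta$condition == cond
    if (!any(sel)) stop("condition absent: ", cond)
    L <- attr(cm, "library_sizes")[cm$meta$sample_id[sel]]
    k <- cm$counts[, cm$meta$sample_id[sel], drop = FALSE]
    list(pooled = sum(k) / sum(L),
         region = rowSums(k) / sum(L))
  }
  ip_c <- rate(ip_counts, ctrl); ip_k <- rate(ip_counts, kd)
  in_c <- rate(input_counts, ctrl); in_k <- rate(input_counts, kd)
  if (ip_c$pooled == 0 || in_c$pooled == 0 || in_k$pooled == 0)
    stop("zero denominator in double ratio")
  ip_ratio <- ip_k$pooled / ip_c$pooled
  input_ratio <- in_k$pooled / in_c$pooled
  ok <- ip_c$region > 0 & in_c$region > 0 & in_k$region > 0
  per_region <- (ip_k$region[ok] / ip_c$region[ok]) /
                (in_k$region[ok] / in_c$region[ok])
  list(factor = ip_ratio / input_ratio,
       per_region_median = stats::median(per_region),
       ip_ratio = ip_ratio, input_ratio = input_ratio)
}

#' Stabilized log transform and replicate averaging
#'
#' `log2(count / size_factor + pseudocount)` - a shifted-log
#' variance stabilization applied after size-factor scaling - with
#' optional averaging of replicate columns of the same condition.
#'
#' @param cm a [count_matrix()].
#' @param size_factors as in [nb_differential()]; `NULL` = all 1.
#' @param pseudocount added inside the log.
#' @param collapse_replicates average columns by condition.
#' @return numeric matrix.
#' @export
stabilized_log <- function(cm, size_factors = NULL, pseudocount = 1,
                           collapse_replicates = FALSE) {
  sf <- if (is.null(size_factors)) rep(1, ncol(cm$counts))
        else if (is.data.frame(size_factors))
          size_factors$size_factor[match(colnames(cm$counts),
                                         size_factors$sample_id)]
        else size_factors[colnames(cm$counts)]
  m <- log2(sweep(cm$counts, 2, sf, "/") + pseudocount)
  if (collapse_replicates) {
    conds <- unique(cm$meta$condition)
    m <- vapply(conds, function(cc)
      rowMeans(m[, cm$meta$condition == cc, drop = FALSE]),
      numeric(nrow(m)))
    colnames(m) <- conds
  }
  m
}

#' Genome-bin fragment counts
#'
#' Tiles the main chromosomes into fixed bins and assigns each fragment
#' to the bin containing its midpoint (each fragment counted exactly
#' once per sample). Bins whose mean count across samples is less than
#' or equal to `min_mean` are discarded.
#'
#' @param fragments a [fragment_set()].
#' @param bin bin size, bp.
#' @param min_mean discard bins with mean count `<= min_mean`.
#' @return a [count_matrix()] with feature ids `chrom:start`.
#' @export
bin_counts <- function(fragments, bin = 500, min_mean = 25) {
  build <- attr(fragments, "build")
  chroms <- main_chromosomes(build)
  nb <- ceiling(build$length[chroms] / bin)
  offset <- stats::setNames(c(0, cumsum(nb))[seq_along(chroms)], chroms)
  total_bins <- sum(nb)
  f <- fragments[fragments$chrom %in% chroms, , drop = FALSE]
  mid <- floor((f$start + f$end - 1) / 2)
  gbin <- offset[f$chrom] + pmin(floor(mid / bin), nb[f$chrom] - 1) + 1
  sample_id <- paste(f$condition, f$replicate, sep = "_")
  samples <- unique(sample_id)
  counts <- vapply(samples, function(s)
    tabulate(gbin[sample_id == s], nbins = total_bins),
    numeric(total_bins))
  ids <- unlist(lapply(chroms, function(ch)
    paste0(ch, ":", format((seq_len(nb[ch]) - 1) * bin,
                           scientific = FALSE, trim = TRUE))))
  rownames(counts) <- ids
  keep <- rowMeans(counts) > min_mean
  meta <- data.frame(
    sample_id = samples,
    condition = vapply(strsplit(samples, "_"), `[`, "", 1),
    replicate = vapply(strsplit(samples, "_"), `[`, "", 2),
    stringsAsFactors = FALSE)
  count_matrix(counts[keep, , drop = FALSE], meta)
}
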
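#' Strand-specific coverage from nascent-transcription fragments
#'
#' Each fragment's 5' end is extended `extsize` bp in the fragment's
#' strand direction (single-end pileup) and per-base coverage is
#' computed per strand, pooling all replicates of the fragment set.
#'
#' @param fragments a [fragment_set()].
#' @param extsize extension of the 5' end, bp (> 0).
#' @return list with elements `"+"` and `"-"`, each a named
#'   [IRanges::RleList]-like list of coverage Rle per chromosome, and
#'   attribute `build`.
#' @export
strand_coverage <- function(fragments, extsize = 100) {
  if (extsize <= 0) stop("extsize must be > 0")
  build <- attr(fragments, "build")
  chroms <- main_chromosomes(build)
  out <- list()
  for (s in c("+", "-")) {
    f <- fragments[fragments$strand == s & fragments$chrom %in% chroms, ]
    p5 <- if (s == "+") f$start else f$end - 1
    start <- if (s == "+") p5 else p5 - extsize + 1
    start <- pmax(start, 0)
    end <- pmin(start + extsize, build$length[f$chrom])
    keep <- end > start
    gr <- GenomicRanges::GRanges(
      f$chrom[keep],
      IRanges::IRanges(start = start[keep] + 1, end = end[keep]),
      seqlengths = build$length[chroms])
    out[[s]] <- GenomicRanges::coverage(gr)
  }
  attr(out, "build") <- build
  out
}

# candidate enriched runs (coverage > lambda) merged across small gaps
.candidate_regions <- function(rle, lambda, merge_gap) {
  ir <- IRanges::reduce(IRanges::slice(rle, lower = lambda,
                                       includeLower = FALSE,
                                       rangesOnly = TRUE),
                        min.gapwidth = merge_gap + 1L)
  ir
}

#' Call enriched regions against a local Poisson background
#'
#' A sliding-scan re-implementation of treatment-only peak calling: the
#' per-strand coverage is sliced into candidate regions (coverage above
#' the genome-wide mean, merged across gaps up to `extsize`), each
#' candidate's summit height is tested against a local background
#' `lambda_local = max(lambda_genome, lambda_1kb, lambda_10kb)` (window
#' means centered on the summit) with a Poisson upper-tail p-value, and
#' Benjamini-Hochberg q-values are computed over all candidates of both
#' strands. Regions with q <= `q_max` are returned. Summits take the
#' leftmost position of maximal coverage.
#'
#' @param coverage output of [strand_coverage()].
#' @param q_max BH q-value cutoff.
#' @param merge_gap merge candidate runs separated by at most this many
#'   bp before testing.
#' @return data frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `summit`, `qvalue`); zero rows when nothing is enriched.
#' @export
call_peaks <- function(coverage, q_max = 0.05, merge_gap = 100) {
  build <- attr(coverage, "build")
  genome_len <- sum(build$length[main_chromosomes(build)])
  cand <- list()
  for (s in c("+", "-")) {
    covs <- coverage[[s]]
    lambda_g <- sum(vapply(covs, function(r) sum(as.numeric(r)),
                           numeric(1))) / genome_len
    for (ch in names(covs)) {
      r <- covs[[ch]]
      ir <- .candidate_regions(r, lambda_g, merge_gap)
      if (!length(ir)) next
      v <- IRanges::Views(r, ir)
      height <- IRanges::viewMaxs(v)
      summit1 <- IRanges::viewWhichMaxs(v)      # leftmost max, 1-based
      x <- as.numeric(r)
      cx <- c(0, cumsum(x))
      wmean <- function(half) {
        lo <- pmax(summit1 - half, 1)
        hi <- pmin(summit1 + half, length(x))
        (cx[hi + 1] - cx[lo]) / (hi - lo + 1)
      }
      lambda_local <- pmax(lambda_g, wmean(500), wmean(5000))
      p <- stats::ppois(height - 1, lambda_local, lower.tail = FALSE)
      cand[[paste(s, ch)]] <- data.frame(
        chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
        strand = s, summit = summit1 - 1L, height = height, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character(),
                      summit = integer(), qvalue = numeric()))
  d <- do.call(rbind, cand)
  d$qvalue <- stats::p.adjust(d$p, method = "BH")
  d <- d[d$qvalue <= q_max, , drop = FALSE]
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  if (nrow(d)) {
    d$name <- sprintf("peak_%d", seq_len(nrow(d)))
    d$score <- -10 * log10(pmax(d$qvalue, 1e-300))
  } else {
    d$name <- character(0); d$score <- numeric(0)
  }
  rownames(d) <- NULL
  d[, c("chrom", "start", "end", "name", "score", "strand", "summit",
        "qvalue")]
}

#' Blacklist hyper-accessible regions
#'
#' Accessibility peaks within `merge_dist` bp of each other are merged;
#' merged regions spanning strictly more than `span_min` bp are returned
#' as a blacklist. Downstream classification drops promoters falling
#' inside blacklisted regions.
#'
#' @param atac_peaks interval data frame (`chrom`, `start`, `end`).
#' @param merge_dist merge peaks separated by up to this many bp.
#' @param span_min minimal merged span (strict) for blacklisting, bp.
#' @return data frame of blacklisted intervals (possibly zero rows).
#' @export
blacklist_hyperaccessible <- function(atac_peaks, merge_dist = 1000,
                                      span_min = 12000) {
  if (!nrow(atac_peaks))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  gr <- GenomicRanges::GRanges(atac_peaks$chrom,
                               IRanges::IRanges(atac_peaks$start + 1,
                                                atac_peaks$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = merge_dist + 1)
  keep <- GenomicRanges::width(merged) > span_min
  merged <- merged[keep]
  data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged) - 1L,
             end = GenomicRanges::end(merged),
             stringsAsFactors = FALSE)
}

#' Assign promoter activity from called peaks
#'
#' A promoter is active iff a peak on the promoter's strand has its
#' summit within `max_dist` bp (inclusive, unsigned) of the TSS. The
#' nearest qualifying peak is recorded. Promoters inside `blacklist`
#' intervals are forced inactive (flagged in the output).
#'
#' @param promoters data frame with `transcript_id` (or `promoter_id`),
#'   `chrom`, `strand`, `tss`.
#' @param peaks output of [call_peaks()].
#' @param max_dist maximal unsigned summit-TSS distance, bp.
#' @param blacklist optional interval data frame from
#'   [blacklist_hyperaccessible()].
#' @return data frame: id column, `active`, `supporting_peak`,
#'   `distance_to_summit`, `blacklisted`.
#' @export
assign_activity <- function(promoters, peaks, max_dist = 150,
                            blacklist = NULL) {
  idcol <- if ("promoter_id" %in% names(promoters)) "promoter_id"
           else "transcript_id"
  n <- nrow(promoters)
  active <- rep(FALSE, n)
  supporting <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (key in unique(paste(promoters$chrom, promoters$strand))) {
    pk <- peaks[paste(peaks$chrom, peaks$strand) == key, , drop = FALSE]
    pi <- which(paste(promoters$chrom, promoters$strand) == key)
    if (!nrow(pk) || !length(pi)) next
    s <- sort(pk$summit, index.return = TRUE)
    summit <- s$x; name <- pk$name[s$ix]
    j <- findInterval(promoters$tss[pi], summit)
    lo <- pmax(j, 1); hi <- pmin(j + 1, length(summit))
    d_lo <- abs(promoters$tss[pi] - summit[lo])
    d_hi <- abs(promoters$tss[pi] - summit[hi])
    use_lo <- j >= 1 & (j >= length(summit) | d_lo <= d_hi)
    best <- ifelse(use_lo, lo, hi)
    bestd <- ifelse(use_lo, d_lo, d_hi)
    ok <- bestd <= max_dist
    active[pi[ok]] <- TRUE
    supporting[pi[ok]] <- name[best[ok]]
    dist[pi[ok]] <- bestd[ok]
  }
  blk <- rep(FALSE, n)
  if (!is.null(blacklist) && nrow(blacklist)) {
    pgr <- GenomicRanges::GRanges(promoters$chrom,
                                  IRanges::IRanges(promoters$tss + 1,
                                                   width = 1))
    bgr <- GenomicRanges::GRanges(blacklist$chrom,
                                  IRanges::IRanges(blacklist$start + 1,
                                                   blacklist$end))
    blk <- GenomicRanges::countOverlaps(pgr, bgr) > 0
    active[blk] <- FALSE
    supporting[blk] <- NA_character_
    dist[blk] <- NA_real_
  }
  out <- data.frame(id = promoters[[idcol]], active = active,
                    supporting_peak = supporting,
                    distance_to_summit = dist, blacklisted = blk,
                    stringsAsFactors = FALSE)
  names(out)[1] <- idcol
  out
}

#' Select unique promoters
#'
#' Transcripts of the same gene whose promoter windows (TSS +/- `window`)
#' overlap on the same strand are clustered into one promoter; the
#' representative transcript is the one with the smallest FDR when
#' differential results are supplied, otherwise the most upstream TSS.
#' Promoters whose window overlaps a promoter of a *different* gene on
#' the same strand are discarded as non-unique.
#'
#' @param transcripts a [transcript_units()] data frame.
#' @param diff_results optional data frame with `transcript_id` and
#'   `fdr`.
#' @param window promoter half-window, bp.
#' @return data frame, one row per unique promoter: `promoter_id`,
#'   `gene_id`, `transcript_id` (representative), `chrom`, `strand`,
#'   `tss`, `n_transcripts`.
#' @export
select_unique_promoters <- function(transcripts, diff_results = NULL,
                                    window = 150) {
  tx <- as.data.frame(transcripts)
  fdr <- rep(NA_real_, nrow(tx))
  if (!is.null(diff_results))
    fdr <- diff_results$fdr[match(tx$transcript_id,
                                  diff_results$transcript_id)]
  # within-gene clustering by overlapping promoter windows
  ord <- order(tx$gene_id, tx$chrom, tx$strand, tx$tss)
  tx <- tx[ord, ]; fdr <- fdr[ord]
  same_prev <- c(FALSE,
                 tx$gene_id[-1] == tx$gene_id[-nrow(tx)] &
                 tx$chrom[-1] == tx$chrom[-nrow(tx)] &
                 tx$strand[-1] == tx$strand[-nrow(tx)] &
                 (tx$tss[-1] - tx$tss[-nrow(tx)]) <= 2 * window)
  cl <- cumsum(!same_prev)
  reps <- vapply(split(seq_len(nrow(tx)), cl), function(ii) {
    if (any(!is.na(fdr[ii]))) {
      ii[which.min(fdr[ii])]
    } else {
      # most upstream TSS: minimal on "+", maximal on "-"
      if (tx$strand[ii[1]] == "+") ii[which.min(tx$tss[ii])]
      else ii[which.max(tx$tss[ii])]
    }
  }, integer(1))
  prom <- data.frame(
    promoter_id = paste0(tx$gene_id[reps], "_p",
                         stats::ave(cl[reps], tx$gene_id[reps],
                                    FUN = seq_along)),
    gene_id = tx$gene_id[reps],
    transcript_id = tx$transcript_id[reps],
    chrom = tx$chrom[reps], strand = tx$strand[reps],
    tss_lo = as.numeric(tapply(tx$tss, cl, min)),
    tss_hi = as.numeric(tapply(tx$tss, cl, max)),
    tss = tx$tss[reps],
    n_transcripts = as.integer(table(cl)),
    stringsAsFactors = FALSE)
  # cross-gene uniqueness: window of the whole cluster
  gr <- GenomicRanges::GRanges(
    paste(prom$chrom, prom$strand),
    IRanges::IRanges(prom$tss_lo - window + 1, prom$tss_hi + window + 1))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  bad <- unique(S4Vectors::queryHits(hits)[
    prom$gene_id[S4Vectors::queryHits(hits)] !=
    prom$gene_id[S4Vectors::subjectHits(hits)]])
  if (length(bad)) prom <- prom[-bad, , drop = FALSE]
  rownames(prom) <- NULL
  prom[, c("promoter_id", "gene_id", "transcript_id", "chrom", "strand",
           "tss", "n_transcripts")]
}
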
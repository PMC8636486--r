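#' Filter fragments by length
#'
#' Retains fragments whose length is within `[lo, hi]` (inclusive); the
#' nucleosome-footprint window used before dyad calling.
#'
#' @param fragments a [fragment_set()].
#' @param lo,hi inclusive length bounds, bp.
#' @return the filtered [fragment_set()].
#' @export
filter_fragment_length <- function(fragments, lo = 130, hi = 200) {
  len <- fragments$end - fragments$start
  out <- fragments[len >= lo & len <= hi, , drop = FALSE]
  fragment_set(as.data.frame(out), attr(fragments, "build"))
}

# Gaussian-smoothed midpoint intensity on a 1-bp grid (FFT convolution).
.midpoint_intensity <- function(mids, chrom_len, bandwidth) {
  counts <- tabulate(pmin(pmax(floor(mids), 0), chrom_len - 1) + 1L,
                     nbins = chrom_len)
  half <- ceiling(3 * bandwidth)
  kern <- stats::dnorm(-half:half, sd = bandwidth)
  y <- stats::convolve(counts, rev(kern), type = "open")
  y[(half + 1):(half + chrom_len)]
}

#' Call nucleosome dyads from fragment midpoints
#'
#' Per replicate and chromosome, fragment midpoints are smoothed with a
#' Gaussian kernel (`bandwidth` bp sd); dyads are local maxima of the
#' smoothed intensity exceeding `min_rel_occupancy` times the chromosome
#' median intensity, kept greedily in decreasing occupancy subject to a
#' minimum pairwise separation. Fragments should be length-filtered
#' first (see [filter_fragment_length()]).
#'
#' @param fragments a [fragment_set()] (one assay; replicates are
#'   processed separately; spike contigs are skipped).
#' @param bandwidth Gaussian kernel sd, bp.
#' @param min_separation minimum dyad spacing, bp.
#' @param min_rel_occupancy occupancy threshold relative to the
#'   chromosome median intensity.
#' @return data frame of dyad calls: `replicate`, `chrom`, `pos`,
#'   `occupancy`, sorted by position within replicate/chromosome.
#' @export
call_dyads <- function(fragments, bandwidth = 30, min_separation = 120,
                       min_rel_occupancy = 2.0) {
  build <- attr(fragments, "build")
  out <- list()
  for (rep in unique(fragments$replicate)) {
    for (ch in main_chromosomes(build)) {
      f <- fragments[fragments$replicate == rep & fragments$chrom == ch, ]
      if (!nrow(f)) next
      mids <- (f$start + f$end - 1) / 2
      y <- .midpoint_intensity(mids, as.integer(build$length[ch]), bandwidth)
      # floor against FFT round-off ripples on sparse chromosomes
      thr <- max(min_rel_occupancy * stats::median(y), 1e-9 * max(y))
      n <- length(y)
      # leftmost position of each local maximum
      is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                         y[2:(n - 1)] >= y[3:n], FALSE)
      cand <- which(is_max & y > thr & y > 0)
      if (!length(cand)) next
      ord <- cand[order(-y[cand], cand)]
      kept <- numeric(0)
      for (p in ord) {
        if (!length(kept) || min(abs(kept - p)) >= min_separation)
          kept <- c(kept, p)
      }
      kept <- sort(kept)
      out[[paste(rep, ch)]] <- data.frame(
        replicate = rep, chrom = ch, pos = kept - 1L,
        occupancy = y[kept], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(replicate = character(), chrom = character(),
                      pos = numeric(), occupancy = numeric()))
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

# nearest dyad (by unsigned offset, ties to leftmost genomic position)
# among dyads of one replicate satisfying the direction filter
.nearest_dyad <- function(pos_sorted, tss, strand, direction, max_abs) {
  if (!length(pos_sorted)) return(NULL)
  off <- strand_offset(pos_sorted, tss, strand)
  keep <- if (direction == "downstream") off >= 0 else off < 0
  keep <- keep & abs(off) <= max_abs
  if (!any(keep)) return(NULL)
  p <- pos_sorted[keep]; o <- abs(off[keep])
  best <- which(o == min(o))
  c(pos = min(p[best]), dist = min(o))
}

#' Assign a flanking (+1 or -1) nucleosome to a promoter
#'
#' Two replicate-consistency rules, evaluated in order and combined by
#' OR: rule 1 accepts the nearest dyad within `r1_max` bp of the TSS in
#' *either* replicate; rule 2 accepts when *both* replicates have a dyad
#' within `r2_max` bp and the two dyad centers differ by strictly less
#' than `r2_diff` bp, the reported position being their midpoint. Only
#' dyads on the requested side of the TSS count (downstream: signed
#' offset >= 0; upstream: offset < 0); distances are unsigned.
#'
#' @param tss,strand,chrom promoter TSS (bp), strand and chromosome.
#' @param calls_rep1,calls_rep2 dyad-call data frames (see
#'   [call_dyads()]), one replicate each.
#' @param direction "downstream" (+1) or "upstream" (-1).
#' @param r1_max,r2_max,r2_diff rule thresholds, bp.
#' @return `NULL` if no assignment, else a list with `pos` (genomic bp)
#'   and `rule` ("r1_single" or "r2_both").
#' @export
assign_flanking <- function(tss, strand, chrom, calls_rep1, calls_rep2,
                            direction = c("downstream", "upstream"),
                            r1_max = 350, r2_max = 600, r2_diff = 80) {
  direction <- match.arg(direction)
  p1 <- sort(calls_rep1$pos[calls_rep1$chrom == chrom])
  p2 <- sort(calls_rep2$pos[calls_rep2$chrom == chrom])
  # rule 1: either replicate within r1_max
  n1 <- .nearest_dyad(p1, tss, strand, direction, r1_max)
  n2 <- .nearest_dyad(p2, tss, strand, direction, r1_max)
  if (!is.null(n1) || !is.null(n2)) {
    cand <- rbind(n1, n2)
    best <- cand[order(cand[, "dist"], cand[, "pos"]), , drop = FALSE][1, ]
    return(list(pos = unname(best["pos"]), rule = "r1_single"))
  }
  # rule 2: both replicates within r2_max, centers closer than r2_diff
  m1 <- .nearest_dyad(p1, tss, strand, direction, r2_max)
  m2 <- .nearest_dyad(p2, tss, strand, direction, r2_max)
  if (!is.null(m1) && !is.null(m2) &&
      abs(m1["pos"] - m2["pos"]) < r2_diff) {
    return(list(pos = unname((m1["pos"] + m2["pos"]) / 2),
                rule = "r2_both"))
  }
  NULL
}

#' Assign +1 and -1 nucleosomes to a set of promoters
#'
#' Vectorized driver for [assign_flanking()] over a promoter table and a
#' two-replicate dyad-call set.
#'
#' @param promoters data frame with `chrom`, `strand`, `tss` and an id
#'   column (`promoter_id` or `transcript_id`).
#' @param dyads dyad calls from [call_dyads()] containing exactly two
#'   replicates.
#' @inheritParams assign_flanking
#' @return data frame: id, `plus1_pos`, `plus1_rule`, `minus1_pos`,
#'   `minus1_rule` (NA where no rule fired).
#' @export
assign_flanking_all <- function(promoters, dyads, r1_max = 350,
                                r2_max = 600, r2_diff = 80) {
  reps <- unique(dyads$replicate)
  if (length(reps) != 2) stop("need exactly two replicates, got ",
                              length(reps))
  c1 <- dyads[dyads$replicate == reps[1], ]
  c2 <- dyads[dyads$replicate == reps[2], ]
  idcol <- if ("promoter_id" %in% names(promoters)) "promoter_id"
           else "transcript_id"
  n <- nrow(promoters)
  res <- data.frame(id = promoters[[idcol]],
                    plus1_pos = rep(NA_real_, n),
                    plus1_rule = NA_character_,
                    minus1_pos = NA_real_, minus1_rule = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    up <- assign_flanking(promoters$tss[i], promoters$strand[i],
                          promoters$chrom[i], c1, c2, "downstream",
                          r1_max, r2_max, r2_diff)
    dn <- assign_flanking(promoters$tss[i], promoters$strand[i],
                          promoters$chrom[i], c1, c2, "upstream",
                          r1_max, r2_max, r2_diff)
    if (!is.null(up)) {
      res$plus1_pos[i] <- up$pos; res$plus1_rule[i] <- up$rule
    }
    if (!is.null(dn)) {
      res$minus1_pos[i] <- dn$pos; res$minus1_rule[i] <- dn$rule
    }
  }
  names(res)[1] <- idcol
  res
}

#' Classify promoters by H2A.Z nucleosome occupancy
#'
#' A promoter is `H2AZ_POS` iff a +1 nucleosome was assigned;
#' otherwise `H2AZ_NEG_MINUS1` iff a -1 nucleosome was assigned;
#' otherwise `H2AZ_NEG_NONE`. The three labels partition the
#' Zelda-independent active promoters; Zelda-dependent promoters are
#' excluded from the partition (flagged `excluded`) but their flank
#' calls are retained for reporting.
#'
#' @param promoters promoter table with an id column.
#' @param flanks output of [assign_flanking_all()].
#' @param zld_dependent optional character vector of promoter ids to
#'   exclude from the partition.
#' @return data frame: id, `label`, `rule` (provenance of the label's
#'   nucleosome call), `excluded`.
#' @export
classify_h2az <- function(promoters, flanks, zld_dependent = character()) {
  idcol <- names(flanks)[1]
  label <- ifelse(!is.na(flanks$plus1_pos), "H2AZ_POS",
           ifelse(!is.na(flanks$minus1_pos), "H2AZ_NEG_MINUS1",
                  "H2AZ_NEG_NONE"))
  rule <- ifelse(!is.na(flanks$plus1_pos), flanks$plus1_rule,
          ifelse(!is.na(flanks$minus1_pos), flanks$minus1_rule, "none"))
  data.frame(id = flanks[[idcol]], label = label, rule = rule,
             excluded = flanks[[idcol]] %in% zld_dependent,
             stringsAsFactors = FALSE) |>
    stats::setNames(c(idcol, "label", "rule", "excluded"))
}
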
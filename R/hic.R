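#' Bin contact pairs into a contact matrix
#'
#' Assigns intra-chromosomal contact pairs to `(bin_i, bin_j)` at the
#' requested resolution; inter-chromosomal pairs are discarded. The
#' result is symmetric.
#'
#' @param pairs data frame with `chrom1`, `pos1`, `chrom2`, `pos2` (bp).
#' @param build a [genome_build()].
#' @param bin_size bin size, bp.
#' @return named list of [contact_matrix()] per main chromosome.
#' @export
bin_contacts <- function(pairs, build, bin_size = 2000) {
  out <- list()
  intra <- pairs$chrom1 == pairs$chrom2
  for (ch in main_chromosomes(build)) {
    n <- ceiling(build$length[ch] / bin_size)
    sel <- intra & pairs$chrom1 == ch
    m <- matrix(0, n, n)
    if (any(sel)) {
      i <- pmin(floor(pairs$pos1[sel] / bin_size), n - 1) + 1
      j <- pmin(floor(pairs$pos2[sel] / bin_size), n - 1) + 1
      for (k in seq_along(i)) {
        m[i[k], j[k]] <- m[i[k], j[k]] + 1
        if (i[k] != j[k]) m[j[k], i[k]] <- m[j[k], i[k]] + 1
      }
    }
    out[[ch]] <- contact_matrix(ch, bin_size, m)
  }
  out
}

#' Balance a contact matrix by iterative correction
#'
#' Finds per-bin weights such that the balanced matrix
#' `w_i * w_j * count(i,j)` has equal row sums over covered bins
#' (the matrix-scaling fixed point also targeted by KR balancing).
#' Bins with zero marginal are masked (weight NA) and excluded.
#'
#' @param cm a [contact_matrix()].
#' @param tol convergence tolerance on the maximum relative deviation of
#'   covered row sums from their mean.
#' @param max_iter maximum iterations; non-convergence is an error
#'   reporting the residual.
#' @return the [contact_matrix()] with `weights` filled in.
#' @export
balance_matrix <- function(cm, tol = 1e-5, max_iter = 500) {
  m <- cm$counts
  n <- nrow(m)
  covered <- rowSums(m) > 0
  w <- ifelse(covered, 1, NA_real_)
  if (!any(covered)) { cm$weights <- w; return(cm) }
  mc <- m[covered, covered, drop = FALSE]
  b <- rep(1, nrow(mc))
  resid <- Inf
  for (it in seq_len(max_iter)) {
    s <- drop(mc %*% b) * b
    rel <- s / mean(s)
    resid <- max(abs(rel - 1))
    if (resid < tol) break
    b <- b / sqrt(rel)
  }
  if (resid >= tol)
    stop(sprintf("balancing did not converge in %d iterations (residual %.3g)",
                 max_iter, resid))
  # normalize so the mean balanced row sum is 1
  s <- drop(mc %*% b) * b
  b <- b / sqrt(mean(s))
  w[covered] <- b
  cm$weights <- w
  cm
}

# rectangle sum over a matrix with NAs: returns sums and counts of
# finite entries for rows [r1,r2] x cols [c1,c2] (vectorized over bins)
.sat <- function(m) {
  z <- m; z[!is.finite(z)] <- 0
  cnt <- matrix(as.numeric(is.finite(m)), nrow(m))
  pad <- function(x) {
    s <- apply(x, 2, cumsum)     # down rows
    s <- t(apply(s, 1, cumsum))  # then across columns
    rbind(0, cbind(0, s))
  }
  list(sum = pad(z), cnt = pad(cnt))
}

.rect <- function(sat, r1, r2, c1, c2) {
  sat[cbind(r2 + 1, c2 + 1)] - sat[cbind(r1, c2 + 1)] -
    sat[cbind(r2 + 1, c1)] + sat[cbind(r1, c1)]
}

#' Multi-depth insulation score
#'
#' For each bin `i` and each window size `w` from `min_depth` to
#' `max_depth` in steps of `step` (bp, converted to bins), the diamond
#' mean is the mean of balanced counts over
#' `[i-w, i-1] x [i+1, i+w]`. Each per-window track is log2-normalized
#' to its chromosome mean over covered bins (0 = average insulation;
#' lower = more insulated), and the final score is the unweighted mean
#' across window sizes. Bins within the maximum window of a chromosome
#' edge, and bins whose diamonds contain no covered cells, are flagged
#' uncovered (score NA).
#'
#' @param cm a balanced [contact_matrix()] (see [balance_matrix()]).
#' @param min_depth,max_depth,step window range, bp.
#' @return data frame: `chrom`, `bin` (0-based), `start`, `end`,
#'   `score`, `covered`.
#' @export
insulation_score <- function(cm, min_depth = 20000, max_depth = 100000,
                             step = 2000) {
  n <- nrow(cm$counts)
  bs <- cm$bin_size
  ws <- unique(pmax(1L, as.integer(round(
    seq(min_depth, max_depth, by = step) / bs))))
  bm <- balanced_counts(cm)
  max_w <- max(ws)
  edge_ok <- seq_len(n) - max_w >= 1 & seq_len(n) + max_w <= n
  if (2 * max_w >= n)
    return(data.frame(chrom = cm$chrom, bin = seq_len(n) - 1L,
                      start = (seq_len(n) - 1L) * bs,
                      end = pmin(seq_len(n) * bs, n * bs),
                      score = NA_real_, covered = FALSE))
  sat <- .sat(bm)
  per_w <- matrix(NA_real_, n, length(ws))
  idx <- which(edge_ok)
  for (k in seq_along(ws)) {
    w <- ws[k]
    s <- .rect(sat$sum, idx - w, idx - 1, idx + 1, idx + w)
    m <- .rect(sat$cnt, idx - w, idx - 1, idx + 1, idx + w)
    dia <- ifelse(m > 0, s / m, NA_real_)
    mu <- mean(dia[dia > 0], na.rm = TRUE)
    per_w[idx, k] <- ifelse(!is.na(dia) & dia > 0, log2(dia / mu),
                            NA_real_)
  }
  score <- rowMeans(per_w)
  covered <- edge_ok & is.finite(score)
  score[!covered] <- NA_real_
  data.frame(chrom = cm$chrom, bin = seq_len(n) - 1L,
             start = (seq_len(n) - 1L) * bs,
             end = pmin(seq_len(n) * bs, n * bs),
             score = score, covered = covered,
             stringsAsFactors = FALSE)
}

#' Call insulation boundaries
#'
#' A boundary is a local minimum of the insulation score whose value
#' lies at least `delta` below both flanking local maxima (the maxima
#' between it and the neighboring minima, or the ends of the covered
#' segment). Plateaus count once, at their leftmost bin.
#'
#' @param track insulation track from [insulation_score()] (one or more
#'   chromosomes row-bound).
#' @param delta minimal prominence.
#' @return data frame: `chrom`, `bin`, `start`, `end`, `score`,
#'   `prominence`.
#' @export
call_boundaries <- function(track, delta = 0.01) {
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    seg <- cumsum(c(TRUE, diff(tr$covered) != 0) )
    for (sg in unique(seg[tr$covered])) {
      rows <- which(seg == sg & tr$covered)
      y <- tr$score[rows]
      if (length(y) < 3) next
      # leftmost bins of local-minimum plateaus
      ny <- length(y)
      lmin <- which(c(FALSE, y[2:(ny - 1)] < y[1:(ny - 2)] &
                             y[2:(ny - 1)] <= y[3:ny], FALSE))
      if (!length(lmin)) next
      keep <- logical(length(lmin)); prom <- numeric(length(lmin))
      bounds <- c(1, lmin, ny)
      for (q in seq_along(lmin)) {
        i <- lmin[q]
        lmax <- max(y[bounds[q]:i])
        rmax <- max(y[i:bounds[q + 2]])
        prom[q] <- min(lmax, rmax) - y[i]
        keep[q] <- prom[q] >= delta
      }
      if (!any(keep)) next
      r <- rows[lmin[keep]]
      out[[paste(ch, sg)]] <- data.frame(
        chrom = ch, bin = tr$bin[r], start = tr$start[r], end = tr$end[r],
        score = tr$score[r], prominence = prom[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), bin = integer(),
                      start = numeric(), end = numeric(),
                      score = numeric(), prominence = numeric()))
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d[order(d$chrom, d$bin), ]
}

#' Insulation profiles over TSS groups
#'
#' Extracts each TSS's strand-oriented insulation window and reports the
#' per-group pointwise median and standard error; uncovered bins are
#' excluded pointwise.
#'
#' @param track insulation track from [insulation_score()].
#' @param tss_groups data frame with `chrom`, `tss`, `strand`, `group`.
#' @param flank half-window around the TSS, bp.
#' @return data frame: `group`, `rel_bin` (bins, negative = upstream),
#'   `median`, `se`, `n`.
#' @export
profile_over_groups <- function(track, tss_groups, flank = 20000) {
  bs <- unique(track$end - track$start)[1]
  fb <- floor(flank / bs)
  rel <- -fb:fb
  score_by_chrom <- split(track, track$chrom)
  rows <- list()
  for (g in unique(tss_groups$group)) {
    sel <- tss_groups[tss_groups$group == g, ]
    prof <- matrix(NA_real_, nrow(sel), length(rel))
    for (i in seq_len(nrow(sel))) {
      tr <- score_by_chrom[[sel$chrom[i]]]
      if (is.null(tr)) next
      b <- floor(sel$tss[i] / bs)
      ix <- b + rel
      ok <- ix >= 0 & ix < nrow(tr)
      v <- rep(NA_real_, length(rel))
      v[ok] <- tr$score[match(ix[ok], tr$bin)]
      if (sel$strand[i] == "-") v <- rev(v)
      prof[i, ] <- v
    }
    med <- apply(prof, 2, stats::median, na.rm = TRUE)
    nn <- colSums(is.finite(prof))
    se <- apply(prof, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
    rows[[g]] <- data.frame(group = g, rel_bin = rel, median = med,
                            se = se, n = nn, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

#' Distance from TSSs to the nearest insulation boundary
#'
#' @param tss_set data frame with `chrom`, `tss`.
#' @param boundaries data frame from [call_boundaries()].
#' @return numeric vector of unsigned distances (bp) to the nearest
#'   boundary bin center; NA when the chromosome has no boundary.
#' @export
boundary_distance <- function(tss_set, boundaries) {
  centers <- (boundaries$start + boundaries$end) / 2
  vapply(seq_len(nrow(tss_set)), function(i) {
    cc <- centers[boundaries$chrom == tss_set$chrom[i]]
    if (!length(cc)) return(NA_real_)
    min(abs(cc - tss_set$tss[i]))
  }, numeric(1))
}

#' Difference of two insulation tracks
#'
#' `a - b` per bin where both tracks are covered; uncovered anywhere ->
#' uncovered in the output (non-covered regions are skipped, never
#' treated as zero).
#'
#' @param track_a,track_b insulation tracks over the same bins.
#' @return a track data frame with the difference in `score`.
#' @export
insulation_difference <- function(track_a, track_b) {
  key_a <- paste(track_a$chrom, track_a$bin)
  key_b <- paste(track_b$chrom, track_b$bin)
  j <- match(key_a, key_b)
  out <- track_a
  cov <- track_a$covered & !is.na(j) & track_b$covered[j]
  out$score <- ifelse(cov, track_a$score - track_b$score[j], NA_real_)
  out$covered <- cov
  out
}
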
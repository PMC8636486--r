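#' Protein log-intensity table
#'
#' Container for label-free IP-MS quantification: a proteins x samples
#' matrix of log2 intensities (NA = missing), a bait/control group per
#' sample and contaminant/decoy/site-only flags per protein.
#'
#' @param intensities numeric matrix, rownames = protein ids, NA for
#'   missing values.
#' @param groups named character ("bait"/"control") per sample.
#' @param flags data frame with logical columns `contaminant`, `decoy`,
#'   `site_only` (one row per protein); defaults to all-FALSE.
#' @return object of class `protein_table`.
#' @export
protein_table <- function(intensities, groups, flags = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    stop("intensities must have protein rownames")
  if (!all(colnames(intensities) %in% names(groups)))
    stop("groups must cover every sample")
  groups <- groups[colnames(intensities)]
  if (!all(groups %in% c("bait", "control")))
    stop("groups must be 'bait' or 'control'")
  if (length(unique(groups)) < 2) stop("need both groups")
  if (is.null(flags))
    flags <- data.frame(contaminant = rep(FALSE, nrow(intensities)),
                        decoy = FALSE, site_only = FALSE)
  structure(list(intensities = intensities, groups = groups,
                 flags = flags),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat("protein_table:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples (",
      sum(x$groups == "bait"), "bait /", sum(x$groups == "control"),
      "control );", sum(is.na(x$intensities)), "missing values\n")
  invisible(x)
}

#' Filter a protein table
#'
#' Removes contaminant, decoy and site-only entries, then keeps proteins
#' with at least `min_valid` non-missing quantitation values in the bait
#' group OR in the control group.
#'
#' @param tab a [protein_table()].
#' @param min_valid minimal valid values in any one group.
#' @return the filtered [protein_table()].
#' @export
filter_proteins <- function(tab, min_valid = 2) {
  keep <- !(tab$flags$contaminant | tab$flags$decoy | tab$flags$site_only)
  x <- tab$intensities[keep, , drop = FALSE]
  nb <- rowSums(!is.na(x[, tab$groups == "bait", drop = FALSE]))
  nc <- rowSums(!is.na(x[, tab$groups == "control", drop = FALSE]))
  ok <- nb >= min_valid | nc >= min_valid
  protein_table(x[ok, , drop = FALSE], tab$groups,
                tab$flags[keep, , drop = FALSE][ok, , drop = FALSE])
}

#' Median-center log intensities
#'
#' Shifts each sample's observed log-intensities so its median equals
#' the grand median over all observed values. Missing values are
#' untouched.
#'
#' @param tab a [protein_table()].
#' @return the normalized [protein_table()].
#' @export
normalize_log <- function(tab) {
  x <- tab$intensities
  grand <- stats::median(x, na.rm = TRUE)
  meds <- apply(x, 2, stats::median, na.rm = TRUE)
  tab$intensities <- sweep(x, 2, meds - grand, "-")
  tab
}

#' Impute missing values from a down-shifted normal
#'
#' Per sample, missing values are drawn from
#' `Normal(mu_s - downshift * sigma_s, (width * sigma_s)^2)` where
#' `mu_s` and `sigma_s` are the sample's observed mean and sd — the
#' standard treatment of missing-not-at-random dropout in label-free
#' proteomics. Observed values are never altered.
#'
#' @param tab a [protein_table()].
#' @param width imputation sd as a fraction of the sample sd.
#' @param downshift shift of the imputation mean, in sample sds.
#' @param seed integer seed; identical seeds give identical imputations.
#' @return the completed [protein_table()].
#' @export
impute_shifted_normal <- function(tab, width = 0.5, downshift = 1.8,
                                  seed = 1L) {
  set.seed(seed)
  x <- tab$intensities
  for (s in colnames(x)) {
    obs <- x[, s][!is.na(x[, s])]
    if (length(obs) < 2)
      stop("sample ", s, " has fewer than 2 observed values")
    mu <- mean(obs); sdv <- stats::sd(obs)
    miss <- is.na(x[, s])
    x[miss, s] <- stats::rnorm(sum(miss), mu - downshift * sdv,
                               width * sdv)
  }
  tab$intensities <- x
  tab
}

# solve trigamma(y) = x by Newton iteration (monotone decreasing)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per protein, the pooled within-group variance `s^2` (d residual df)
#' is shrunk toward a prior `s0^2` with prior df `d0`, both estimated by
#' moments on the log residual variances; the moderated statistic uses
#' the posterior variance `(d0 s0^2 + d s^2) / (d0 + d)` and a t
#' reference with `d0 + d` degrees of freedom. P-values are adjusted by
#' Benjamini-Yekutieli.
#'
#' @param tab a complete [protein_table()] (no missing values; see
#'   [impute_shifted_normal()]).
#' @return data frame: `protein_id`, `log2FC` (bait - control),
#'   `t`, `p`, `padj`, plus the estimated `d0` and `s0` as attributes.
#' @export
moderated_ttest <- function(tab) {
  x <- tab$intensities
  if (anyNA(x)) stop("table contains missing values; impute first")
  b <- tab$groups == "bait"; c_ <- !b
  n1 <- sum(b); n2 <- sum(c_)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(x[, b, drop = FALSE])
  m2 <- rowMeans(x[, c_, drop = FALSE])
  ss <- rowSums((x[, b, drop = FALSE] - m1)^2) +
        rowSums((x[, c_, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- pmax(ss / d, 1e-12)
  # moments of log variances: E log s^2 = log s0^2 + digamma(d/2) - log(d/2)
  # (+0 under the prior), Var log s^2 = trigamma(d/2) + trigamma(d0/2)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ve <- stats::var(e)
  excess <- ve - trigamma(d / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigamma_inverse(excess)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- if (is.infinite(d0)) rep(s0_2, length(s2))
          else (d0 * s0_2 + d * s2) / (d0 + d)
  tstat <- (m1 - m2) / sqrt(post * (1 / n1 + 1 / n2))
  df_t <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_t)
  out <- data.frame(protein_id = rownames(x), log2FC = m1 - m2,
                    t = tstat, p = p,
                    padj = stats::p.adjust(p, method = "BY"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s0") <- sqrt(s0_2)
  out
}

#' Call enriched proteins
#'
#' Enriched iff `padj <= padj_max` AND `|log2FC| >= log2(fc_min)`
#' (a fold change of at least +/-50% with the defaults). The direction
#' of the change is recorded.
#'
#' @param stats data frame from [moderated_ttest()].
#' @param padj_max adjusted p-value cutoff (inclusive).
#' @param fc_min minimal fold change (linear scale, inclusive).
#' @return `stats` with added logical `enriched` and `direction`
#'   ("up"/"down"/NA).
#' @export
call_enriched <- function(stats, padj_max = 0.05, fc_min = 1.5) {
  hit <- stats$padj <= padj_max & abs(stats$log2FC) >= log2(fc_min)
  stats$enriched <- hit
  stats$direction <- ifelse(hit, ifelse(stats$log2FC > 0, "up", "down"),
                            NA_character_)
  stats
}
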
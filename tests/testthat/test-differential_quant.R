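test_that("reference size factors are median-of-ratios on the reference only", {
  set.seed(2)
  base <- matrix(rpois(200 * 4, 50), 200,
                 dimnames = list(paste0("f", 1:200), paste0("s", 1:4)))
  cm <- make_cm(base)
  ref <- paste0("f", 1:50)
  sf0 <- reference_size_factors(cm, ref)
  # identical marginal law -> factors near 1
  expect_equal(sf0$size_factor, rep(1, 4), tolerance = 0.1)
  # doubling one sample doubles its factor exactly, relative to the
  # others (size factors are defined up to a common scale)
  cm2 <- cm; cm2$counts[, 2] <- cm$counts[, 2] * 2
  sf2 <- reference_size_factors(cm2, ref)
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1],
               2 * sf0$size_factor[2] / sf0$size_factor[1])
  expect_equal(sf2$size_factor[3] / sf2$size_factor[1],
               sf0$size_factor[3] / sf0$size_factor[1])
  # a 10x change confined to non-reference features leaves factors alone
  cm3 <- cm; cm3$counts[100:200, 3] <- cm3$counts[100:200, 3] * 10
  sf3 <- reference_size_factors(cm3, ref)
  expect_equal(sf3$size_factor, sf0$size_factor)
  expect_error(reference_size_factors(cm, "nope"), "absent")
  # all-zero-containing reference is unusable
  cmz <- cm; cmz$counts[1:50, 1] <- 0
  expect_error(reference_size_factors(cmz, ref), "no usable reference")
})

test_that("reference size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  k <- matrix(rnbinom(300 * 6, mu = 80, size = 10), 300,
              dimnames = list(paste0("f", 1:300), paste0("s", 1:6)))
  cm <- make_cm(k)
  ref <- paste0("f", 1:100)
  ours <- reference_size_factors(cm, ref)$size_factor
  theirs <- DESeq2::estimateSizeFactorsForMatrix(
    k, controlGenes = rownames(k) %in% ref)
  # same median-of-ratios statistic up to a common rescaling
  expect_equal(unname(ours / theirs), rep(unname(ours[1] / theirs[1]), 6),
               tolerance = 1e-8)
})

test_that("NB differential is calibrated on a simulated null", {
  set.seed(42)
  n <- 2000
  counts <- matrix(rnbinom(n * 6, mu = 100, size = 1 / 0.05), n,
                   dimnames = list(paste0("f", 1:n), paste0("s", 1:6)))
  d <- nb_differential(make_cm(counts), NULL)
  frac <- mean(d$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  ks <- suppressWarnings(stats::ks.test(d$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("NB differential recovers a planted log2 fold change", {
  set.seed(43)
  n <- 400
  mu <- matrix(100, n, 6)
  mu[1:100, 4:6] <- 100 * 2^-2   # planted logFC -2
  counts <- matrix(rnbinom(n * 6, mu = mu, size = 1 / 0.05), n,
                   dimnames = list(paste0("f", 1:n), paste0("s", 1:6)))
  d <- nb_differential(make_cm(counts), NULL)
  est <- mean(d$logFC[d$feature_id %in% paste0("f", 1:100)])
  expect_lt(abs(est - (-2)), 0.3)
  # low-count features are removed by the mean filter
  counts2 <- counts
  counts2["f200", ] <- c(8, 8, 8, 8, 8, 8)
  d2 <- nb_differential(make_cm(counts2), NULL, min_mean = 10)
  expect_false("f200" %in% d2$feature_id)
  expect_error(nb_differential(make_cm(counts,
                                       conditions = rep("A", 6)), NULL),
               "two conditions")
})

test_that("NB logFC estimates agree with edgeR on shared input", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  n <- 200
  mu <- matrix(150, n, 6)
  mu[1:40, 4:6] <- 150 * 2^-1.5
  counts <- matrix(rnbinom(n * 6, mu = mu, size = 1 / 0.05), n,
                   dimnames = list(paste0("f", 1:n), paste0("s", 1:6)))
  d <- nb_differential(make_cm(counts), NULL)
  grp <- factor(rep(c("A", "B"), each = 3))
  y <- edgeR::DGEList(counts, group = grp)
  y$samples$norm.factors <- 1
  y <- edgeR::estimateDisp(y, model.matrix(~grp))
  fit <- edgeR::glmFit(y, model.matrix(~grp))
  lrt <- edgeR::glmLRT(fit)
  ref <- lrt$table[d$feature_id, "logFC"]
  expect_gt(stats::cor(d$logFC, ref), 0.99)
  # closed-form check: for a plain two-group design the fitted logFC
  # tracks the normalized group-mean ratio
  cf <- log2(rowMeans(counts[d$feature_id, 4:6]) /
             rowMeans(counts[d$feature_id, 1:3]))
  expect_lt(stats::median(abs(d$logFC - cf)), 0.05)
  # both routes rank the same features on top
  top_ours <- d$feature_id[order(d$p)][1:40]
  top_edger <- d$feature_id[order(lrt$table[d$feature_id, "PValue"])][1:40]
  expect_gt(length(intersect(top_ours, top_edger)) / 40, 0.8)
})

test_that("condition-dependence calls use strict logFC and FDR cutoffs", {
  d <- data.frame(feature_id = c("a", "b", "c", "d"),
                  logFC = c(-1.5, -0.5, -1.5, -1.0),
                  p = c(1e-4, 1e-4, 1e-3, 1e-5),
                  fdr = c(0.001, 0.001, 0.02, 0.001))
  expect_identical(call_zld_dependent(d), "a")  # b: logFC, c: fdr, d: -1 not < -1
})

test_that("transcript counting is occupancy-style with span and sum filters", {
  gb <- tiny_build()
  tx <- transcript_units(data.frame(
    transcript_id = c("iso1", "iso2", "short", "quiet"),
    gene_id = c("g1", "g1", "g2", "g3"),
    chrom = "chrA", strand = "+",
    start = c(1000, 1500, 30000, 60000),
    end = c(5000, 6000, 30124, 64000)), gb)
  start <- c(rep(2000, 20), rep(60500, 5), rep(61000, 5))
  f <- make_frags("chrA", start, start + 100, "+",
                  condition = "Ctrl", replicate = "rep1")
  res <- transcript_counts_fpkm(f, tx, min_sum = 10)
  # a fragment overlapping both isoforms increments both
  expect_equal(res$counts$counts["iso1", 1], 20)
  expect_equal(res$counts$counts["iso2", 1], 20)
  # span 124 < 125 dropped before counting
  expect_false("short" %in% rownames(res$counts$counts))
  # sum exactly 10 dropped (strict "more than 10")
  expect_false("quiet" %in% rownames(res$counts$counts))
  # FPKM closed form: 1e9 * count / (libsize * span)
  expect_equal(res$fpkm["iso1", 1],
               1e9 * 20 / (res$library_sizes[[1]] * 4000))
})

test_that("FPKM is invariant under uniform duplication of the fragments", {
  gb <- tiny_build()
  tx <- transcript_units(data.frame(
    transcript_id = "t1", gene_id = "g1", chrom = "chrA", strand = "+",
    start = 1000, end = 5000), gb)
  start <- rep(seq(1200, 4000, by = 100), 2)
  f1 <- make_frags("chrA", start, start + 80)
  f2 <- make_frags("chrA", rep(start, 2), rep(start + 80, 2))
  r1 <- transcript_counts_fpkm(f1, tx, min_sum = 0)
  r2 <- transcript_counts_fpkm(f2, tx, min_sum = 0)
  expect_equal(r1$fpkm, r2$fpkm)
})

test_that("RELACS double ratio recovers planted depletion and ignores depth", {
  cfg <- tiny_config(kd_depletion = 0.5)
  sim <- cached_fixture("tiny_sim_kd", simulate_truth_genome(cfg))
  h2az <- cached_fixture("tiny_h2az_kd",
                         simulate_chip(sim, cfg, "H2A.Z",
                                       conditions = c("Ctrl", "DomKD")))
  input <- cached_fixture("tiny_input_kd",
                          simulate_chip(sim, cfg, "input",
                                        conditions = c("Ctrl", "DomKD")))
  prom <- select_unique_promoters(sim$transcripts)
  act <- prom[prom$gene_id %in% sim$truth$gene_id[sim$truth$active], ]
  ip <- count_promoter_fragments(h2az, act)
  inp <- count_promoter_fragments(input, act)
  r <- relacs_double_ratio(ip, inp)
  expect_lt(abs(r$factor - 0.5), 0.05)
  expect_lt(abs(r$input_ratio - 1), 0.05)
  # doubling a condition's sequencing depth leaves the factor unchanged
  ip2 <- ip
  ctrl_cols <- ip$meta$condition == "Ctrl"
  ip2$counts[, ctrl_cols] <- ip$counts[, ctrl_cols] * 2
  attr(ip2, "library_sizes")[ctrl_cols] <-
    attr(ip, "library_sizes")[ctrl_cols] * 2
  r2 <- relacs_double_ratio(ip2, inp)
  expect_equal(r2$factor, r$factor)
  # no change anywhere -> factor 1
  r3 <- relacs_double_ratio(inp, inp)
  expect_equal(r3$factor, 1)
})

test_that("spike-in size factors invert the spike share", {
  sc <- c(a = 100, b = 100, c = 100)
  f <- spikein_size_factors(sc)
  expect_equal(f$size_factor, rep(1, 3))
  # 2x spike reads -> half the factor, relative to the others
  f2 <- spikein_size_factors(c(a = 100, b = 200, c = 100))
  expect_equal(f2$size_factor[2] / f2$size_factor[1], 0.5)
  expect_error(spikein_size_factors(c(a = 0, b = 10)), "zero spike")
  # with totals, the share (not raw count) is inverted
  f3 <- spikein_size_factors(c(a = 100, b = 100),
                             totals = c(a = 1000, b = 2000))
  expect_equal(f3$size_factor[2] / f3$size_factor[1], 2)
})

test_that("stabilized log transform and replicate averaging are exact", {
  counts <- rbind(x = c(0, 7, 3, 5), y = c(7, 7, 1, 1))
  colnames(counts) <- c("A_r1", "A_r2", "B_r1", "B_r2")
  cm <- make_cm(counts, conditions = c("A", "A", "B", "B"))
  m <- stabilized_log(cm, NULL)
  expect_equal(m["x", "A_r1"], 0)       # count 0 -> log2(1) = 0
  expect_equal(m["x", "A_r2"], 3)       # count 7, sf 1 -> log2(8) = 3
  collapsed <- stabilized_log(cm, NULL, collapse_replicates = TRUE)
  expect_equal(collapsed["y", "A"], 3)  # replicate mean of (3, 3)
  expect_equal(collapsed["x", "B"], (2 + log2(6)) / 2)
  # size factors divide before the log
  m2 <- stabilized_log(cm, c(A_r1 = 1, A_r2 = 7, B_r1 = 1, B_r2 = 1))
  expect_equal(m2["x", "A_r2"], 1)      # log2(7/7 + 1)
})

test_that("bin counting assigns by midpoint and applies the <= 25 filter", {
  # 26 fragments in one bin, 25 in another, single sample
  s1 <- rep(100, 26); s2 <- rep(700, 25)
  f <- make_frags("chrA", c(s1, s2), c(s1, s2) + 80)
  bc <- bin_counts(f, bin = 500, min_mean = 25)
  expect_identical(rownames(bc$counts), "chrA:0")
  expect_equal(bc$counts[1, 1], 26)
  # a fragment spanning two bins lands in its midpoint's bin
  f2 <- make_frags("chrA", rep(480, 26), rep(560, 26))  # midpoint 519.5
  bc2 <- bin_counts(f2, bin = 500, min_mean = 25)
  expect_identical(rownames(bc2$counts), "chrA:500")
})
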
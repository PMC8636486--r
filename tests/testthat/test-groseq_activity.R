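test_that("strand coverage extends 5' ends in the strand direction", {
  f <- make_frags("chrA", c(1000, 1000), c(1030, 1030), c("+", "-"))
  cov <- strand_coverage(f, extsize = 100)
  plus <- as.numeric(cov[["+"]][["chrA"]])
  minus <- as.numeric(cov[["-"]][["chrA"]])
  # "+" fragment: 5' at 1000, covers [1000, 1100)
  expect_equal(which(plus == 1), 1001:1100)
  expect_equal(sum(plus), 100)
  # "-" fragment: 5' at end-1 = 1029, covers (929, 1029]
  expect_equal(which(minus == 1), 931:1030)
  # overlap accumulates
  f2 <- make_frags("chrA", c(1000, 1050), c(1030, 1080), "+")
  cov2 <- strand_coverage(f2, extsize = 100)
  expect_equal(max(as.numeric(cov2[["+"]][["chrA"]])), 2)
  expect_error(strand_coverage(f, extsize = 0), "extsize")
})

test_that("flat coverage yields no peaks; an enriched region yields one", {
  # flat lambda = 2: fragments tiled every 50 bp with 100 bp extension
  starts <- seq(0, 2e5 - 100, by = 50)
  flat <- make_frags("chrA", starts, starts + 30, "+")
  cov <- strand_coverage(flat)
  expect_equal(nrow(call_peaks(cov)), 0)
  # a 50-deep spike over near-zero background
  spike <- make_frags("chrA", rep(10000, 50), rep(10030, 50), "+")
  bg <- make_frags("chrA", seq(0, 2e5 - 100, by = 5000),
                   seq(0, 2e5 - 100, by = 5000) + 30, "+")
  cov2 <- strand_coverage(combine_fragments(spike, bg))
  pk <- call_peaks(cov2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$summit, 10000)
  expect_equal(pk$strand, "+")
  # Poisson tail oracle: the summit p-value matches ppois directly
  expect_lt(pk$qvalue, 1e-10)
})

test_that("peaks on opposite strands are called independently", {
  plus <- make_frags("chrA", rep(10000, 40), rep(10030, 40), "+")
  minus <- make_frags("chrA", rep(50100, 40), rep(50130, 40), "-")
  cov <- strand_coverage(combine_fragments(plus, minus))
  pk <- call_peaks(cov)
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$strand, c("+", "-"))
  # "-" summit: leftmost base of the (p5 - 100, p5] extension
  expect_equal(sort(pk$summit), c(10000, 50030))
})

test_that("peak calling commutes with chromosome mirroring + strand flip", {
  set.seed(9)
  L <- 2e5
  n <- 400
  start <- c(sample.int(L - 200, n), rep(30000, 60), rep(120000, 60))
  strand <- c(sample(c("+", "-"), n, TRUE), rep("+", 60), rep("-", 60))
  f <- make_frags("chrA", start, start + 30, strand)
  pk <- call_peaks(strand_coverage(f))
  # mirror: [s,e) -> [L-e, L-s), strands flipped
  fm <- make_frags("chrA", L - (start + 30), L - start,
                   ifelse(strand == "+", "-", "+"))
  pkm <- call_peaks(strand_coverage(fm))
  expect_equal(nrow(pkm), nrow(pk))
  # regions mirror exactly; summits up to plateau tie-breaking
  expect_setequal(paste(L - pkm$end, L - pkm$start),
                  paste(pk$start, pk$end))
  for (i in seq_len(nrow(pk))) {
    j <- which(L - pkm$end == pk$start[i])
    expect_lte(abs((L - 1 - pkm$summit[j]) - pk$summit[i]), 100)
  }
})

test_that("hyper-accessible blacklisting merges and applies the strict span rule", {
  # gap 900 <= 1 kb -> merged span 13000 > 12 kb -> blacklisted
  pk <- data.frame(chrom = "chrA", start = c(0, 5900), end = c(5000, 13000))
  bl <- blacklist_hyperaccessible(pk)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start, 0)
  expect_equal(bl$end, 13000)
  # merged span exactly 12000 is kept (strict "more than 12 kb")
  pk2 <- data.frame(chrom = "chrA", start = c(0, 7000), end = c(6000, 12000))
  expect_equal(nrow(blacklist_hyperaccessible(pk2)), 0)
  # gap 1001 is not merged
  pk3 <- data.frame(chrom = "chrA", start = c(0, 6001), end = c(5000, 20000))
  bl3 <- blacklist_hyperaccessible(pk3)
  expect_equal(bl3$start, 6001)
  # isolated short peak survives
  expect_equal(nrow(blacklist_hyperaccessible(
    data.frame(chrom = "chrA", start = 100, end = 600))), 0)
})

test_that("activity assignment follows the same-strand 150 nt summit rule", {
  prom <- data.frame(transcript_id = c("t1", "t2", "t3"),
                     chrom = "chrA", strand = c("+", "+", "+"),
                     tss = c(1000, 3000, 5000))
  peaks <- data.frame(chrom = "chrA",
                      start = c(1050, 3050, 5100), end = c(1150, 3150, 5250),
                      name = c("p1", "p2", "p3"), score = 1,
                      strand = c("+", "-", "+"),
                      summit = c(1100, 3100, 5151), qvalue = 0.001)
  act <- assign_activity(prom, peaks, max_dist = 150)
  expect_true(act$active[1])           # distance 100, same strand
  expect_equal(act$distance_to_summit[1], 100)
  expect_equal(act$supporting_peak[1], "p1")
  expect_false(act$active[2])          # opposite strand
  expect_false(act$active[3])          # 151 > 150
  # boundary: exactly 150 is active (inclusive)
  peaks$summit[3] <- 5150
  expect_true(assign_activity(prom, peaks)$active[3])
})

test_that("activity is monotone in the distance threshold", {
  set.seed(21)
  prom <- data.frame(transcript_id = paste0("t", 1:60), chrom = "chrA",
                     strand = sample(c("+", "-"), 60, TRUE),
                     tss = sample.int(1e5, 60))
  peaks <- data.frame(chrom = "chrA", start = 0, end = 1,
                      name = paste0("p", 1:40), score = 1,
                      strand = sample(c("+", "-"), 40, TRUE),
                      summit = sample.int(1e5, 40), qvalue = 0.01)
  peaks$start <- peaks$summit - 10; peaks$end <- peaks$summit + 10
  prev <- rep(FALSE, 60)
  for (d in c(0, 50, 150, 400, 1000)) {
    cur <- assign_activity(prom, peaks, max_dist = d)$active
    expect_true(all(cur[prev]))  # active set only grows with d
    prev <- cur
  }
})

test_that("blacklisted promoters are forced inactive", {
  prom <- data.frame(transcript_id = "t1", chrom = "chrA", strand = "+",
                     tss = 1000)
  peaks <- data.frame(chrom = "chrA", start = 950, end = 1150, name = "p1",
                      score = 1, strand = "+", summit = 1010,
                      qvalue = 1e-4)
  bl <- data.frame(chrom = "chrA", start = 0, end = 13000)
  act <- assign_activity(prom, peaks, blacklist = bl)
  expect_false(act$active)
  expect_true(act$blacklisted)
})

test_that("on null data the fraction of active promoters stays below 1%", {
  cfg <- tiny_config(frac_active = 0)
  sim <- simulate_truth_genome(cfg)
  fr <- simulate_groseq(sim, cfg)
  prom <- select_unique_promoters(sim$transcripts)
  act <- assign_activity(prom, call_peaks(strand_coverage(fr)))
  expect_lte(mean(act$active), 0.01)
})

test_that("activity recovery on planted data is essentially perfect", {
  cfg <- tiny_config()
  sim <- tiny_sim()
  fr <- cached_fixture("tiny_gro", simulate_groseq(sim, cfg))
  prom <- select_unique_promoters(sim$transcripts)
  act <- assign_activity(prom, call_peaks(strand_coverage(fr)))
  truth_active <- sim$truth$active[match(prom$gene_id, sim$truth$gene_id)]
  sens <- mean(act$active[truth_active])
  spec <- mean(!act$active[!truth_active])
  expect_gte(mean(c(sens, spec)), 0.95)
})

test_that("unique-promoter selection clusters isoforms and drops collisions", {
  gb <- tiny_build()
  tx <- transcript_units(data.frame(
    transcript_id = c("a1", "a2", "b1", "c1", "d1"),
    gene_id = c("gA", "gA", "gB", "gC", "gD"),
    chrom = "chrA", strand = c("+", "+", "+", "+", "-"),
    start = c(1000, 1000, 50000, 50080, 80000),
    end = c(3000, 4000, 52000, 52500, 81000)), gb)
  # same-TSS isoforms with differential results: min-FDR representative
  diffres <- data.frame(transcript_id = c("a1", "a2"), fdr = c(0.2, 0.001))
  sel <- select_unique_promoters(tx, diffres)
  expect_equal(sel$transcript_id[sel$gene_id == "gA"], "a2")
  # two genes with TSSs 80 bp apart on the same strand: both discarded
  expect_false(any(sel$gene_id %in% c("gB", "gC")))
  # single-isoform gene untouched
  expect_equal(sel$tss[sel$gene_id == "gD"], 80999)
  # without differential results the most upstream TSS represents
  sel2 <- select_unique_promoters(tx)
  expect_equal(sel2$transcript_id[sel2$gene_id == "gA"], "a1")
})
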
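test_that("genome_build validates its invariants", {
  expect_error(genome_build(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_build("a", 0), "positive")
  expect_error(genome_build("a", 10, spike_contigs = "b"), "subset")
  gb <- tiny_build()
  expect_identical(main_chromosomes(gb), c("chrA", "chrB"))
})

test_that("GTF loading converts 1-based closed to 0-based half-open TSSs", {
  gb <- tiny_build()
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    'chrA\tx\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";',
    'chrA\tx\ttranscript\t101\t200\t.\t-\t.\tgene_id "g2"; transcript_id "t2"; transcript_biotype "protein_coding";',
    'chrA\tx\ttranscript\t301\t400\t.\t+\t.\tgene_id "g3"; transcript_id "t3"; transcript_biotype "snoRNA";')
  writeLines(lines, gtf)
  tx <- load_annotation(gtf, gb)
  expect_identical(sort(tx$transcript_id), c("t1", "t2"))
  plus <- tx[tx$transcript_id == "t1", ]
  expect_equal(plus$start, 100)
  expect_equal(plus$end, 200)
  expect_equal(plus$tss, 100)
  minus <- tx[tx$transcript_id == "t2", ]
  expect_equal(minus$tss, 199)
  # biotype filter off keeps the snoRNA
  tx_all <- load_annotation(gtf, gb, protein_coding_only = FALSE)
  expect_true("t3" %in% tx_all$transcript_id)
})

test_that("GTF records on unknown chromosomes warn; malformed lines error", {
  gb <- tiny_build()
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrA\tx\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chrZZ\tx\ttranscript\t11\t20\t.\t+\t.\tgene_id "g9"; transcript_id "t9";'),
    gtf)
  expect_warning(tx <- load_annotation(gtf, gb), "unknown chromosome")
  expect_identical(tx$transcript_id, "t1")
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chrA\tx\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chrA\tx\ttranscript\tnot_a_number'), bad)
  expect_error(load_annotation(bad, gb), "line 2")
})

test_that("TSS derivation is an involution under strand flip + mirroring", {
  gb <- tiny_build()
  set.seed(11)
  n <- 50
  L <- 2e5
  start <- sample.int(L - 5000, n)
  df <- data.frame(transcript_id = paste0("t", 1:n),
                   gene_id = paste0("g", 1:n), chrom = "chrA",
                   strand = sample(c("+", "-"), n, TRUE),
                   start = start, end = start + sample(100:4000, n, TRUE))
  tx <- transcript_units(df, gb)
  # mirror: position p -> L - 1 - p, so [start,end) -> [L-end, L-start)
  mirrored <- data.frame(transcript_id = df$transcript_id,
                         gene_id = df$gene_id, chrom = "chrA",
                         strand = ifelse(df$strand == "+", "-", "+"),
                         start = L - tx$end, end = L - tx$start)
  mtx <- transcript_units(mirrored, gb)
  expect_equal(mtx$tss, L - 1 - tx$tss)
})

test_that("BED round trip is the identity and zero-width records fail", {
  set.seed(5)
  n <- 1000
  df <- data.frame(chrom = sample(c("chrA", "chrB"), n, TRUE),
                   start = sample.int(1e5, n),
                   name = paste0("r", 1:n),
                   score = round(stats::runif(n), 3),
                   strand = sample(c("+", "-"), n, TRUE),
                   stringsAsFactors = FALSE)
  df$end <- df$start + sample.int(500, n, replace = TRUE)
  df <- df[order(df$chrom, df$start), c("chrom", "start", "end", "name",
                                        "score", "strand")]
  rownames(df) <- NULL
  path <- tempfile(fileext = ".bed")
  write_bed(df, path)
  back <- read_bed(path)
  expect_equal(back, df)
  df$end[1] <- df$start[1]
  expect_error(write_bed(df, path), "start >= end")
})

test_that("BED q-value column survives a round trip", {
  df <- data.frame(chrom = "chrA", start = c(0, 100), end = c(50, 200),
                   name = c("p1", "p2"), score = c(1, 2),
                   strand = c("+", "-"), qvalue = c(0.01, 0.5),
                   stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_bed(df, path)
  expect_equal(read_bed(path), df)
})

test_that("bedGraph IO preserves values, merges equal neighbors, rejects overlaps", {
  df <- data.frame(chrom = "chrA", start = c(0, 100, 200, 400),
                   end = c(100, 200, 300, 500),
                   value = c(1.5, 1.5, 2.25, -0.125))
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(df, path)
  back <- read_bedgraph(path)
  # adjacent equal-value bins merged on write; values preserved
  expect_equal(back$value, c(1.5, 2.25, -0.125))
  expect_equal(back$start, c(0, 200, 400))
  expect_equal(back$end, c(200, 300, 500))
  bad <- tempfile(fileext = ".bedGraph")
  writeLines(c("chrA\t0\t100\t1", "chrA\t50\t150\t2"), bad)
  expect_error(read_bedgraph(bad), "overlapping")
})

test_that("count-matrix IO round-trips counts, zeros, lengths and metadata", {
  counts <- matrix(c(0L, 5L, 2L, 0L, 7L, 1L), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  cm <- count_matrix(counts,
                     data.frame(sample_id = c("s1", "s2"),
                                condition = c("Ctrl", "KD"),
                                replicate = c("r1", "r1")),
                     lengths = c(gA = 100, gB = 250, gC = 70))
  path <- tempfile(fileext = ".tsv")
  write_counts(cm, path)
  back <- read_counts(path)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$meta, cm$meta)
  expect_equal(back$lengths, cm$lengths)
  writeLines(c("#meta\ts1\tA\tr1", "feature_id\ts1", "g1\t-3"), path)
  expect_error(read_counts(path), "negative")
})

test_that("contact triplets symmetrize on load and validate bins", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("#chrom=chrA", "#bin_size=2000", "#n_bins=10",
               "3\t5\t7", "0\t0\t2"), path)
  cm <- read_contacts(path)
  expect_equal(cm$counts[6, 4], 7)  # count(5,3) with 0-based bins
  expect_equal(cm$counts[4, 6], 7)
  expect_equal(cm$counts[1, 1], 2)
  # round trip
  out <- tempfile(fileext = ".txt")
  write_contacts(cm, out)
  expect_equal(read_contacts(out)$counts, cm$counts)
  writeLines(c("#chrom=chrA", "#bin_size=2000", "#n_bins=10",
               "3\t12\t1"), path)
  expect_error(read_contacts(path), "beyond chromosome end")
  writeLines(c("#chrom=chrA", "#bin_size=2000", "#n_bins=10",
               "3\t5\t7", "5\t3\t9"), path)
  expect_error(read_contacts(path), "conflicting")
})

test_that("fragment table IO round-trips and validates chromosomes", {
  set.seed(3)
  start <- sample.int(1e5, 200)
  f <- make_frags(chrom = sample(c("chrA", "chrB"), 200, TRUE),
                  start = start, end = start + sample(50:200, 200, TRUE),
                  strand = sample(c("+", "-"), 200, TRUE))
  path <- tempfile(fileext = ".tsv")
  write_fragments(f, path)
  back <- read_fragments(path, tiny_build())
  expect_equal(as.data.frame(back), as.data.frame(f))
  bad <- as.data.frame(f)
  bad$chrom[1] <- "chrNOPE"
  expect_error(fragment_set(bad, tiny_build()), "unknown chromosome")
})
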
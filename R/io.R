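#' Load transcript annotation from a GTF file
#'
#' Reads a GTF (1-based, closed intervals), converts to the package's
#' 0-based half-open convention and derives the strand-aware TSS.
#' Records on chromosomes absent from `build` are dropped with a warning.
#' When a transcript biotype attribute is present and
#' `protein_coding_only = TRUE` (the default), only protein-coding
#' transcripts are retained.
#'
#' @param path path to a GTF file.
#' @param build a [genome_build()].
#' @param protein_coding_only keep only transcripts whose
#'   `transcript_biotype`/`gene_biotype` is "protein_coding" (when such an
#'   attribute exists in the file).
#' @return A [transcript_units()] data frame.
#' @export
load_annotation <- function(path, build, protein_coding_only = TRUE) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) {
      bad <- .find_malformed_gtf_line(path)
      if (!is.na(bad))
        stop("malformed GTF line ", bad, " in ", path, call. = FALSE)
      stop("failed to parse GTF ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  df <- as.data.frame(gr)
  if ("type" %in% names(df))
    df <- df[df$type %in% c("transcript", "mRNA"), , drop = FALSE]
  if (!nrow(df)) stop("no transcript records in ", path)
  biotype <- if ("transcript_biotype" %in% names(df)) df$transcript_biotype
             else if ("gene_biotype" %in% names(df)) df$gene_biotype
             else NULL
  if (protein_coding_only && !is.null(biotype)) {
    keep <- !is.na(biotype) & biotype == "protein_coding"
    df <- df[keep, , drop = FALSE]
  }
  unknown <- !(as.character(df$seqnames) %in% build$chrom)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) on unknown chromosome(s) dropped: ",
            paste(unique(as.character(df$seqnames)[unknown]), collapse = ", "))
    df <- df[!unknown, , drop = FALSE]
  }
  out <- data.frame(
    transcript_id = as.character(df$transcript_id),
    gene_id = as.character(df$gene_id),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = df$start - 1L,   # 1-based closed -> 0-based half-open
    end = df$end,
    stringsAsFactors = FALSE)
  transcript_units(out, build)
}

.find_malformed_gtf_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(l) || startsWith(l, "#")) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9 || is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5]))))
      return(i)
  }
  NA_integer_
}

#' Write transcript units as GTF
#'
#' Emits one `transcript` feature per unit, converting back to the GTF
#' 1-based closed convention, with `gene_id`, `transcript_id` and an
#' optional `transcript_biotype` attribute.
#'
#' @param tx a [transcript_units()] data frame.
#' @param path output path.
#' @param biotype biotype attribute written for every record; `NULL`
#'   omits the attribute.
#' @export
write_gtf <- function(tx, path, biotype = "protein_coding") {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   tx$gene_id, tx$transcript_id)
  if (!is.null(biotype))
    attrs <- paste0(attrs, sprintf(' transcript_biotype "%s";', biotype))
  lines <- paste(tx$chrom, "zgakit", "transcript",
                 tx$start + 1L, tx$end, ".", tx$strand, ".", attrs,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

## ---- BED6 (+ optional qvalue column) -------------------------------------

#' Read and write BED intervals
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate conversion is applied. An optional 7th column carries
#' a q-value (peak files). Zero-width records are rejected.
#'
#' @param path file path.
#' @return `read_bed`: data frame with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand` and, if present in the file, `qvalue`.
#' @export
read_bed <- function(path) {
  first <- readLines(path, n = 1L)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  extra <- if (nfield >= 7) c(qvalue = "numeric") else character()
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  if (any(IRanges::width(gr) == 0))
    stop("zero-width BED record (start == end)")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (nfield >= 7) df$qvalue <- as.numeric(gr$qvalue)
  df
}

#' @param df interval data frame (`chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`, `qvalue`).
#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  if (any(df$start >= df$end))
    stop("zero- or negative-width interval (start >= end)")
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE),
               name, format(score, trim = TRUE), strand)
  if ("qvalue" %in% names(df))
    cols <- c(cols, list(sprintf("%.6g", df$qvalue)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

## ---- bedGraph -------------------------------------------------------------

#' Read and write bedGraph tracks
#'
#' Tracks must be disjoint: overlapping intervals on read are an error.
#' On write, runs of adjacent bins with equal values are merged and
#' values serialized with fixed precision.
#'
#' @param path file path.
#' @return `read_bedgraph`: data frame `chrom`, `start`, `end`, `value`
#'   (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) > 1) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits)) stop("overlapping bedGraph intervals in ", path)
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE)
}

#' @param df data frame with `chrom`, `start`, `end`, `value`.
#' @param digits significant digits for serialized values.
#' @param merge_adjacent merge touching intervals with identical
#'   serialized value.
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(df, path, digits = 6, merge_adjacent = TRUE) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  val <- sprintf(paste0("%.", digits, "g"), df$value)
  if (merge_adjacent && nrow(df) > 1) {
    same <- c(FALSE, df$chrom[-1] == df$chrom[-nrow(df)] &
                     df$start[-1] == df$end[-nrow(df)] &
                     val[-1] == val[-nrow(df)])
    grp <- cumsum(!same)
    df <- data.frame(
      chrom = tapply(df$chrom, grp, `[`, 1),
      start = as.numeric(tapply(df$start, grp, min)),
      end = as.numeric(tapply(df$end, grp, max)),
      stringsAsFactors = FALSE)
    val <- tapply(val, grp, `[`, 1)
  }
  writeLines(paste(df$chrom,
                   format(df$start, scientific = FALSE, trim = TRUE),
                   format(df$end, scientific = FALSE, trim = TRUE),
                   val, sep = "\t"), path)
  invisible(path)
}

## ---- TSV containers -------------------------------------------------------

#' Read and write fragment tables
#'
#' Fragments travel as a TSV with header columns `chrom`, `start`, `end`,
#' `strand`, `assay`, `condition`, `replicate` (0-based half-open).
#'
#' @param path file path.
#' @param build a [genome_build()] attached to the result.
#' @return `read_fragments`: a [fragment_set()].
#' @export
read_fragments <- function(path, build) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         replicate = "character",
                                         condition = "character",
                                         assay = "character"))
  fragment_set(df, build)
}

#' @param frags a [fragment_set()].
#' @rdname read_fragments
#' @export
write_fragments <- function(frags, path) {
  utils::write.table(as.data.frame(frags)[, c("chrom", "start", "end",
                                              "strand", "assay",
                                              "condition", "replicate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write count matrices
#'
#' TSV with the feature id in the first column, one column per sample,
#' and sample metadata in `#meta` header lines
#' (`#meta<TAB>sample<TAB>condition<TAB>replicate`). An optional second
#' column `length` carries feature lengths in bp.
#'
#' @param path file path.
#' @return `read_counts`: a [count_matrix()].
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#meta\t", lines, value = TRUE)
  if (!length(metal)) stop("no #meta header lines in ", path)
  parts <- do.call(rbind, strsplit(metal, "\t", fixed = TRUE))
  meta <- data.frame(sample_id = parts[, 2], condition = parts[, 3],
                     replicate = parts[, 4], stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  lengths <- NULL
  scol <- 2L
  if (names(tab)[2] == "length") {
    lengths <- stats::setNames(as.numeric(tab[[2]]), ids)
    scol <- 3L
  }
  counts <- as.matrix(tab[, scol:ncol(tab), drop = FALSE])
  if (any(counts < 0)) stop("negative count in ", path)
  rownames(counts) <- ids
  count_matrix(counts, meta, lengths)
}

#' @param cm a [count_matrix()].
#' @rdname read_counts
#' @export
write_counts <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#meta", cm$meta$sample_id, cm$meta$condition,
                   cm$meta$replicate, sep = "\t"), con)
  tab <- data.frame(feature_id = rownames(cm$counts),
                    stringsAsFactors = FALSE)
  if (!is.null(cm$lengths)) tab$length <- cm$lengths
  tab <- cbind(tab, as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write contact matrices as bin-pair triplet text
#'
#' Triplets are `bin_i<TAB>bin_j<TAB>count` (0-based bin indices,
#' `bin_i <= bin_j`) under header lines `#chrom=`, `#bin_size=` and
#' `#n_bins=`. The matrix is symmetrized on load; duplicate pairs with
#' conflicting values and bins beyond the chromosome end are errors.
#'
#' @param path file path.
#' @return `read_contacts`: a [contact_matrix()].
#' @export
read_contacts <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    l <- grep(paste0("^#", key, "="), lines, value = TRUE)
    if (!length(l)) stop("missing #", key, "= header in ", path)
    sub(paste0("^#", key, "="), "", l[1])
  }
  chrom <- hdr("chrom")
  bin_size <- as.numeric(hdr("bin_size"))
  n_bins <- as.integer(hdr("n_bins"))
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  m <- matrix(0, n_bins, n_bins)
  if (length(body)) {
    tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                             header = FALSE)
    i <- as.integer(tab[[1]]); j <- as.integer(tab[[2]])
    v <- as.numeric(tab[[3]])
    if (any(v < 0)) stop("negative contact count in ", path)
    if (any(i < 0 | j < 0 | i >= n_bins | j >= n_bins))
      stop("bin index beyond chromosome end in ", path)
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) {
      agg <- tapply(v, key, function(x) length(unique(x)))
      if (any(agg > 1)) stop("conflicting duplicate triplet(s) in ", path)
      keep <- !duplicated(key)
      lo <- lo[keep]; hi <- hi[keep]; v <- v[keep]
    }
    m[cbind(lo + 1L, hi + 1L)] <- v
    m[cbind(hi + 1L, lo + 1L)] <- v
  }
  contact_matrix(chrom, bin_size, m)
}

#' @param cm a [contact_matrix()].
#' @rdname read_contacts
#' @export
write_contacts <- function(cm, path) {
  n <- nrow(cm$counts)
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
               arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#chrom=", cm$chrom),
               paste0("#bin_size=", format(cm$bin_size, scientific = FALSE)),
               paste0("#n_bins=", n)), con)
  if (nrow(idx))
    writeLines(paste(idx[, 1] - 1L, idx[, 2] - 1L,
                     sprintf("%.10g", cm$counts[idx]), sep = "\t"), con)
  invisible(path)
}
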
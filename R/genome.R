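#' Genome build
#'
#' A minimal description of the reference the pipeline works against: an
#' ordered set of chromosomes with lengths, plus an optional subset of
#' contigs flagged as exogenous spike-in material (e.g. a phage genome
#' added at library preparation for quantitative scaling).
#'
#' All coordinates in the package are 0-based, half-open. Annotation in
#' 1-based closed convention (GTF) is converted at the boundary by
#' [load_annotation()].
#'
#' @param chromosomes character vector of chromosome names (unique).
#' @param lengths integer vector of chromosome lengths in bp (> 0), same
#'   order as `chromosomes`.
#' @param spike_contigs character vector, subset of `chromosomes`, naming
#'   spike-in contigs. Default none.
#' @return An object of class `genome_build`: a list with elements
#'   `chrom`, `length` (named numeric) and `spike`.
#' @examples
#' gb <- genome_build(c("chr2L", "spike_lambda"), c(1e6, 48502),
#'                    spike_contigs = "spike_lambda")
#' gb
#' @export
genome_build <- function(chromosomes, lengths, spike_contigs = character()) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (length(lengths) != length(chromosomes))
    stop("lengths must match chromosomes")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!all(spike_contigs %in% chromosomes))
    stop("spike_contigs must be a subset of chromosomes")
  names(lengths) <- chromosomes
  structure(list(chrom = chromosomes, length = lengths,
                 spike = as.character(spike_contigs)),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", length(x$chrom), "contig(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  for (i in seq_along(x$chrom)) {
    cat(sprintf("  %-12s %12s bp%s\n", x$chrom[i],
                format(x$length[i], big.mark = ",", scientific = FALSE),
                if (x$chrom[i] %in% x$spike) "  [spike-in]" else ""))
  }
  invisible(x)
}

#' Main (non-spike) chromosomes of a build
#' @param build a [genome_build()].
#' @return character vector of chromosome names.
#' @export
main_chromosomes <- function(build) {
  setdiff(build$chrom, build$spike)
}

#' Transcript unit table
#'
#' Validates a data frame of transcription units and derives the
#' strand-aware TSS. Coordinates are 0-based half-open; the TSS is
#' `start` on the plus strand and `end - 1` on the minus strand.
#'
#' @param df data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` ("+"/"-"), `start`, `end` (0-based half-open).
#' @param build optional [genome_build()]; when given, records on unknown
#'   chromosomes are an error.
#' @return The validated data frame with a derived `tss` column, class
#'   `c("transcript_units", "data.frame")`.
#' @export
transcript_units <- function(df, build = NULL) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(df$start >= df$end))
    stop("start must be < end (0-based half-open)")
  if (!is.null(build) && !all(df$chrom %in% build$chrom))
    stop("unknown chromosome(s): ",
         paste(unique(setdiff(df$chrom, build$chrom)), collapse = ", "))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  stopifnot(all(df$tss >= df$start & df$tss < df$end))
  class(df) <- c("transcript_units", "data.frame")
  df
}

#' Signed offset along the direction of transcription
#'
#' "Downstream" always means increasing signed offset along the
#' transcript's strand: `pos - tss` on "+", `tss - pos` on "-".
#'
#' @param pos genomic position(s), bp.
#' @param tss TSS position(s), bp.
#' @param strand "+" or "-" (recycled).
#' @return numeric signed offsets.
#' @export
strand_offset <- function(pos, tss, strand) {
  dir <- ifelse(strand == "+", 1, -1)
  dir * (pos - tss)
}

#' Fragment set
#'
#' A table of aligned fragments (0-based half-open intervals) tagged by
#' assay, condition and replicate — the universal sequencing input to the
#' pipeline. A `genome_build` is attached so downstream operations can
#' validate coordinates and identify spike-in contigs.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `assay`, `condition`, `replicate`.
#' @param build a [genome_build()].
#' @return `df` with class `c("fragment_set","data.frame")` and attribute
#'   `build`.
#' @export
fragment_set <- function(df, build) {
  need <- c("chrom", "start", "end", "strand", "assay", "condition",
            "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!inherits(build, "genome_build")) stop("build must be a genome_build")
  if (nrow(df)) {
    if (!all(df$chrom %in% build$chrom))
      stop("fragment on unknown chromosome: ",
           paste(unique(setdiff(df$chrom, build$chrom)), collapse = ", "))
    if (any(df$start >= df$end)) stop("fragments must have start < end")
  }
  attr(df, "build") <- build
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x), "fragments;",
      "assays:", paste(unique(x$assay), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$condition), collapse = ", "),
      "| replicates:", paste(unique(x$replicate), collapse = ", "), "\n")
  invisible(x)
}

#' Count matrix with sample metadata
#'
#' Features x samples integer counts plus per-sample condition/replicate
#' labels; the input to all differential and scaling operations.
#'
#' @param counts numeric matrix (non-negative), rownames = feature ids,
#'   colnames = sample ids.
#' @param meta data frame with columns `sample_id`, `condition`,
#'   `replicate`, covering every column of `counts`.
#' @param lengths optional named numeric of feature lengths (bp).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta, lengths = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) && is.null(rownames(counts))) ||
      (ncol(counts) && is.null(colnames(counts))))
    stop("counts must have feature rownames and sample colnames")
  if (!nrow(counts) && is.null(rownames(counts)))
    rownames(counts) <- character(0)
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- c("sample_id", "condition", "replicate")
  if (!all(need %in% names(meta)))
    stop("meta must have columns sample_id, condition, replicate")
  if (!all(colnames(counts) %in% meta$sample_id))
    stop("meta must cover every sample")
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (!is.null(lengths)) {
    if (is.null(names(lengths)) || !all(rownames(counts) %in% names(lengths)))
      stop("lengths must be named and cover every feature")
    lengths <- lengths[rownames(counts)]
  }
  structure(list(counts = counts, meta = meta, lengths = lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("  conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Contact matrix
#'
#' Per-chromosome binned symmetric contact counts with optional balancing
#' weights. Stored dense; toy genomes at 2 kb resolution stay small.
#'
#' @param chrom chromosome name.
#' @param bin_size bin size in bp (> 0).
#' @param counts square symmetric numeric matrix.
#' @param weights optional numeric vector of balancing weights (NA =
#'   masked bin).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, counts, weights = NULL) {
  counts <- as.matrix(counts)
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8)))
    stop("counts must be symmetric")
  if (!is.null(weights) && length(weights) != nrow(counts))
    stop("weights length must equal number of bins")
  structure(list(chrom = chrom, bin_size = bin_size, counts = counts,
                 weights = weights),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", nrow(x$counts), "bins of",
      x$bin_size, "bp;", if (is.null(x$weights)) "unbalanced" else "balanced",
      "\n")
  invisible(x)
}

#' Balanced counts of a contact matrix
#'
#' @param cm a [contact_matrix()] with balancing weights (see [balance_matrix()]).
#' @return numeric matrix `w_i * w_j * count(i,j)`; masked bins are NA.
#' @export
balanced_counts <- function(cm) {
  if (is.null(cm$weights)) stop("contact matrix has no balancing weights")
  w <- cm$weights
  cm$counts * outer(w, w)
}
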
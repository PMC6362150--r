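#' Per-gene allelic count table
#'
#' The central data structure: one row per gene, and for every reciprocal
#' cross a pair of non-negative integer columns holding the maternal and
#' paternal allelic read counts. Internally stored as a list with a counts
#' matrix (columns interleaved `maternal_1, paternal_1, maternal_2,
#' paternal_2, ...`) and a sample annotation data.frame with factors
#' `cross` and `parent`.
#'
#' @param maternal,paternal integer matrices (genes x crosses) of maternal
#'   and paternal read counts; must have identical dimensions.
#' @param gene_id gene identifiers (defaults to rownames of `maternal`).
#' @return An object of class `allelic_counts`.
#' @export
allelic_counts <- function(maternal, paternal, gene_id = rownames(maternal)) {
  maternal <- as.matrix(maternal)
  paternal <- as.matrix(paternal)
  stopifnot(identical(dim(maternal), dim(paternal)))
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_len(nrow(maternal)))
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  if (any(maternal < 0) || any(paternal < 0))
    stop("allelic counts must be non-negative")
  k <- ncol(maternal)
  counts <- matrix(0L, nrow = nrow(maternal), ncol = 2L * k)
  counts[, 2L * seq_len(k) - 1L] <- as.integer(round(maternal))
  counts[, 2L * seq_len(k)] <- as.integer(round(paternal))
  rownames(counts) <- gene_id
  colnames(counts) <- as.vector(rbind(paste0("maternal_", seq_len(k)),
                                      paste0("paternal_", seq_len(k))))
  samples <- data.frame(
    cross = factor(rep(seq_len(k), each = 2L)),
    parent = factor(rep(c("maternal", "paternal"), k),
                    levels = c("paternal", "maternal")),
    row.names = colnames(counts)
  )
  obj <- list(counts = counts, samples = samples)
  class(obj) <- "allelic_counts"
  obj
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat(sprintf("Allelic count table: %d genes, %d crosses\n",
              nrow(x$counts), n_crosses(x)))
  print(utils::head(x$counts, 5L))
  if (nrow(x$counts) > 5L) cat("...\n")
  invisible(x)
}

#' @export
dim.allelic_counts <- function(x) dim(x$counts)

#' Number of reciprocal crosses in an allelic count table
#' @param x an [allelic_counts()] object.
#' @export
n_crosses <- function(x) ncol(x$counts) %/% 2L

#' Extract the maternal or paternal count matrix
#' @param x an [allelic_counts()] object.
#' @return integer matrix, genes x crosses.
#' @export
maternal_counts <- function(x) {
  x$counts[, x$samples$parent == "maternal", drop = FALSE]
}

#' @rdname maternal_counts
#' @export
paternal_counts <- function(x) {
  x$counts[, x$samples$parent == "paternal", drop = FALSE]
}

#' Subset an allelic count table by gene
#' @param x an [allelic_counts()] object.
#' @param i gene index, logical mask or character vector of gene ids.
#' @param ... unused.
#' @export
`[.allelic_counts` <- function(x, i, ...) {
  out <- x
  out$counts <- x$counts[i, , drop = FALSE]
  out
}

#' Swap the maternal/paternal labels of every cross
#'
#' Relabelling utility used for the reciprocal-cross symmetry checks: a
#' correct caller must swap MEG and PEG calls, flip every effect size and
#' keep p-values unchanged under this operation.
#'
#' @param x an [allelic_counts()] object.
#' @export
swap_parents <- function(x) {
  allelic_counts(paternal_counts(x), maternal_counts(x),
                 gene_id = rownames(x$counts))
}

#' Remove genes with insufficient total allelic counts
#'
#' Keeps genes whose allelic counts, summed over both parents and all
#' crosses, reach `min_total`. The default of 10 reproduces the standard
#' callable-gene filter (genes with fewer than 10 allelic reads summed
#' across the two reciprocal crosses are discarded); the boundary is
#' inclusive: a gene with exactly `min_total` reads is kept.
#'
#' @param x an [allelic_counts()] object.
#' @param min_total minimum summed count (default 10).
#' @export
filter_min_counts <- function(x, min_total = 10) {
  stopifnot(inherits(x, "allelic_counts"))
  x[rowSums(x$counts) >= min_total]
}

#' Write / read an allelic count table as TSV
#'
#' The on-disk dialect is a plain TSV with a `gene_id` column followed by
#' `maternal_<cross>`/`paternal_<cross>` pairs.
#'
#' @param x an [allelic_counts()] object.
#' @param path file path.
#' @export
write_allelic_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_allelic_counts
#' @export
read_allelic_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    stop("allelic count TSV must have a gene_id column: ", path)
  mat_cols <- grep("^maternal_", names(df), value = TRUE)
  pat_cols <- grep("^paternal_", names(df), value = TRUE)
  if (length(mat_cols) == 0L || length(mat_cols) != length(pat_cols))
    stop("allelic count TSV must have paired maternal_*/paternal_* columns: ",
         path)
  ord <- order(as.integer(sub("^maternal_", "", mat_cols)))
  m <- as.matrix(df[mat_cols[ord]])
  p <- as.matrix(df[pat_cols[order(as.integer(sub("^paternal_", "",
                                                  pat_cols)))]])
  allelic_counts(m, p, gene_id = df$gene_id)
}
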
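#' TMM normalization factors
#'
#' Trimmed Mean of M-values normalization: for each library, per-gene log2
#' expression ratios (M) against a reference library are trimmed (30% on
#' each side by M, 5% on each side by average log abundance A), averaged
#' with delta-method precision weights, and exponentiated to give a
#' composition-correction factor. Factors are rescaled so their geometric
#' mean is 1; effective library sizes are `lib_size * factor`.
#'
#' Applied to a maternal/paternal allelic count matrix from endosperm,
#' TMM leaves the maternal:paternal effective-library-size ratio of each
#' cross at approximately 2, so the expected 2:1 allelic ratio is absorbed
#' by the offsets and the GLM parent coefficient measures deviation from
#' it.
#'
#' @param counts non-negative count matrix (genes x libraries, >= 2
#'   columns).
#' @param lib_size library sizes (defaults to column sums).
#' @param logratio_trim fraction trimmed from each tail of the M values
#'   (default 0.30).
#' @param abundance_trim fraction trimmed from each tail of the A values
#'   (default 0.05).
#' @return numeric vector of normalization factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_size = colSums(counts),
                        logratio_trim = 0.30, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two libraries")
  if (any(lib_size <= 0)) stop("every library must contain reads")
  ## reference: column whose upper-quartile expression rate is closest to
  ## the mean upper quartile
  uq <- apply(counts, 2L, function(y) stats::quantile(y, 0.75)) / lib_size
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
             logratio_trim, abundance_trim)
  }, numeric(1))
  f / exp(mean(log(f)))
}

## single-pair trimmed weighted mean of M values (obs vs ref)
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  m <- log2(p_obs / p_ref)
  ## mean of logs (not log of product): keeps ties exact for the rank trim
  a <- (log2(p_obs) + log2(p_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  n <- length(m)
  if (n == 0L) return(1)
  if (max(abs(m)) < 1e-6) return(1)  # identical composition
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}
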
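## Count-test baselines: Fisher's exact test against the expected allelic
## ratio, either on counts summed over the reciprocal crosses
## ("Fisher-summed") or per cross with Stouffer-combined p-values
## ("Fisher-combined"). These are the methods most published plant
## imprinting studies used; they share the BH/classification stage with
## the GLM pipeline.

## Two-sided Fisher's exact p for the 2x2 table
## [observed maternal, observed paternal; expected maternal, expected
## paternal], where the expected column apportions the observed total at
## the null ratio (expected maternal = round(total * p0)).
fisher_expected_p <- function(maternal, paternal, null_maternal_prop) {
  total <- maternal + paternal
  exp_m <- round(total * null_maternal_prop)
  exp_p <- total - exp_m
  p <- rep(1, length(total))
  nz <- total > 0
  p[nz] <- vapply(which(nz), function(i) {
    min(1, stats::fisher.test(matrix(c(maternal[i], paternal[i],
                                       exp_m[i], exp_p[i]), nrow = 2,
                                     byrow = TRUE))$p.value)
  }, numeric(1))
  attr(p, "zero_total") <- !nz
  p
}

#' Fisher's exact test on counts summed across reciprocal crosses
#'
#' Per gene, maternal and paternal counts are summed over all crosses and
#' compared with a two-sided Fisher's exact test against an expected
#' column apportioning the same total at the null ratio. Genes with zero
#' total get p = 1 and are flagged.
#'
#' @param x an [allelic_counts()] table.
#' @param null_maternal_prop expected maternal proportion (2/3 endosperm).
#' @return data.frame with `gene_id`, `maternal`, `paternal`,
#'   `maternal_prop`, `log2_fold_effect` (log2 of the observed/expected
#'   ratio shift, 0.5-adjusted), `p_value`, `zero_total`.
#' @export
fisher_summed <- function(x, null_maternal_prop = 2 / 3) {
  stopifnot(inherits(x, "allelic_counts"))
  m <- rowSums(maternal_counts(x))
  p <- rowSums(paternal_counts(x))
  pv <- fisher_expected_p(m, p, null_maternal_prop)
  data.frame(
    gene_id = rownames(x$counts),
    maternal = m, paternal = p,
    maternal_prop = m / pmax(m + p, 1),
    log2_fold_effect = log2(((m + 0.5) / (p + 0.5)) /
                              (null_maternal_prop / (1 - null_maternal_prop))),
    p_value = as.numeric(pv),
    zero_total = attr(pv, "zero_total"),
    row.names = NULL
  )
}

#' Per-cross Fisher's exact tests against the expected ratio
#'
#' @param x an [allelic_counts()] table.
#' @param null_maternal_prop expected maternal proportion.
#' @return matrix of p-values, genes x crosses (zero-total cells get 1).
#' @export
fisher_per_cross <- function(x, null_maternal_prop = 2 / 3) {
  stopifnot(inherits(x, "allelic_counts"))
  m <- maternal_counts(x); p <- paternal_counts(x)
  out <- matrix(NA_real_, nrow(m), n_crosses(x),
                dimnames = list(rownames(x$counts),
                                paste0("cross", seq_len(n_crosses(x)))))
  for (c in seq_len(n_crosses(x)))
    out[, c] <- as.numeric(fisher_expected_p(m[, c], p[, c],
                                             null_maternal_prop))
  out
}

#' Combine p-values with Stouffer's Z method
#'
#' Each p-value is converted to a z-score `qnorm(1 - p)`; the equal-weight
#' mean `sum(z)/sqrt(k)` is transformed back to a combined p-value
#' `1 - pnorm(Z)`. Zero p-values are clipped to the smallest positive
#' double and p-values of 1 to `1 - 1e-12` so the z-scores stay finite.
#' With the default `directional = FALSE` the (two-sided) per-cross
#' p-values are combined naively, which can mask opposite-direction
#' imbalance; `directional = TRUE` signs each z-score by the maternal
#' excess of its cross before combining and returns a two-sided p.
#'
#' @param p matrix of p-values (genes x crosses) or a numeric vector for a
#'   single gene.
#' @param directional sign the z-scores by the direction of imbalance.
#' @param sign_matrix required when `directional = TRUE`: +1 where the
#'   cross shows maternal excess, -1 otherwise.
#' @return numeric vector of combined p-values.
#' @export
stouffer_combine <- function(p, directional = FALSE, sign_matrix = NULL) {
  if (is.vector(p)) p <- matrix(p, nrow = 1)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - 1e-12)
  z <- stats::qnorm(p, lower.tail = FALSE)
  if (directional) {
    if (is.null(sign_matrix)) stop("directional combination needs signs")
    ## two-sided p -> one-sided magnitude, then sign by direction
    z <- sign(sign_matrix) * stats::qnorm(p / 2, lower.tail = FALSE)
    zc <- rowSums(z) / sqrt(ncol(z))
    return(2 * stats::pnorm(abs(zc), lower.tail = FALSE))
  }
  zc <- rowSums(z) / sqrt(ncol(z))
  stats::pnorm(zc, lower.tail = FALSE)
}

#' Fisher-summed and Fisher-combined imprinting callers
#'
#' Full baseline pipelines sharing the downstream contract of
#' [imprint_test()]: they produce a per-gene p-value, BH FDR and a
#' MEG/PEG/none call.
#'
#' @param x an [allelic_counts()] table (filtered).
#' @param config a [test_config()]; only `null_maternal_prop` and
#'   `fdr_level` are used.
#' @param directional for the combined test, see [stouffer_combine()].
#' @return data.frame of class `imprinting_result`.
#' @export
fisher_summed_test <- function(x, config = test_config()) {
  fs <- fisher_summed(x, config$null_maternal_prop)
  res <- data.frame(
    gene_id = fs$gene_id, x$counts,
    maternal_prop = fs$maternal_prop,
    log2_fold_effect = fs$log2_fold_effect,
    p_value = fs$p_value,
    row.names = NULL, check.names = FALSE
  )
  res$fdr <- bh_fdr(res$p_value)
  res$call <- classify_imprinted(res, config)
  attr(res, "config") <- config
  class(res) <- c("imprinting_result", "data.frame")
  res
}

#' @rdname fisher_summed_test
#' @export
fisher_combined_test <- function(x, config = test_config(),
                                 directional = FALSE) {
  pm <- fisher_per_cross(x, config$null_maternal_prop)
  m <- maternal_counts(x); p <- paternal_counts(x)
  signs <- sign((m + 0.5) / (m + p + 1) - config$null_maternal_prop)
  pv <- stouffer_combine(pm, directional = directional,
                         sign_matrix = if (directional) signs)
  msum <- rowSums(m); psum <- rowSums(p)
  res <- data.frame(
    gene_id = rownames(x$counts), x$counts,
    maternal_prop = msum / pmax(msum + psum, 1),
    log2_fold_effect = log2(((msum + 0.5) / (psum + 0.5)) /
                              (config$null_maternal_prop /
                                 (1 - config$null_maternal_prop))),
    p_value = pv,
    row.names = NULL, check.names = FALSE
  )
  res$fdr <- bh_fdr(res$p_value)
  res$call <- classify_imprinted(res, config)
  attr(res, "config") <- config
  class(res) <- c("imprinting_result", "data.frame")
  res
}
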
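#' Configuration of the imprinting test
#'
#' @param null_maternal_prop expected maternal read proportion under no
#'   imprinting: 2/3 for triploid endosperm (2 maternal : 1 paternal
#'   genomes), 1/2 for diploid tissue.
#' @param fdr_level Benjamini-Hochberg FDR cut-off for MEG/PEG calls
#'   (default 0.05).
#' @param dispersion_mode `"tagwise"` (default, empirical-Bayes moderated
#'   per-gene), `"trended"` or `"common"`.
#' @param prior_df prior degrees of freedom of the tagwise shrinkage.
#' @param normalization `"tmm"` (default): the expected allelic ratio is
#'   absorbed by TMM-scaled effective library sizes, valid when most genes
#'   follow the null ratio; `"offset"`: the null ratio is imposed as an
#'   explicit fixed offset with per-cross library sizes, for datasets where
#'   the genome-wide assumption fails.
#' @return An object of class `test_config`.
#' @export
test_config <- function(null_maternal_prop = 2 / 3,
                        fdr_level = 0.05,
                        dispersion_mode = c("tagwise", "trended", "common"),
                        prior_df = 10,
                        normalization = c("tmm", "offset")) {
  stopifnot(null_maternal_prop > 0, null_maternal_prop < 1,
            fdr_level > 0, fdr_level < 1, prior_df > 0)
  cfg <- list(
    null_maternal_prop = null_maternal_prop,
    fdr_level = fdr_level,
    dispersion_mode = match.arg(dispersion_mode),
    prior_df = prior_df,
    normalization = match.arg(normalization)
  )
  class(cfg) <- "test_config"
  cfg
}

## paired design: blocking factor cross + tested factor parent
## (maternal coefficient last)
paired_design <- function(samples) {
  design <- stats::model.matrix(~ cross + parent, data = samples)
  colnames(design)[ncol(design)] <- "parent_maternal"
  design
}

## log-scale offsets for the chosen normalization mode
make_offsets <- function(x, config) {
  y <- x$counts
  lib <- colSums(y)
  if (config$normalization == "tmm") {
    if (any(lib == 0)) stop("a library has zero total counts")
    log(lib * tmm_factors(y, lib))
  } else {
    p0 <- config$null_maternal_prop
    cross_lib <- tapply(lib, x$samples$cross, sum)[x$samples$cross] / 2
    ifelse(x$samples$parent == "maternal",
           log(cross_lib * 2 * p0), log(cross_lib * 2 * (1 - p0)))
  }
}

#' Test allelic imbalance with a paired negative binomial GLM
#'
#' The main statistical method: allelic counts of each cross are treated
#' as paired samples in a negative binomial GLM with log link, offsets
#' equal to log effective library sizes, a blocking factor for the cross
#' and a tested factor for the parent-of-origin. After TMM normalization
#' the effective library sizes carry the expected allelic ratio (2:1 in
#' endosperm), so the likelihood-ratio test of the parent coefficient
#' detects deviation from that expectation. Dispersions are moderated
#' (tagwise by default), p-values come from a two-sided chi-squared LRT,
#' and Benjamini-Hochberg FDR plus the effect direction yield MEG/PEG
#' calls.
#'
#' @param x an [allelic_counts()] table (apply [filter_min_counts()]
#'   first).
#' @param config a [test_config()].
#' @return data.frame of class `imprinting_result` with columns `gene_id`,
#'   the input counts, `maternal_prop`, `log2_fold_effect` (log2 deviation
#'   of the maternal/paternal ratio from the null ratio), `dispersion`,
#'   `p_value`, `fdr` and `call` (`MEG`, `PEG` or `none`).
#' @export
imprint_test <- function(x, config = test_config()) {
  stopifnot(inherits(x, "allelic_counts"), inherits(config, "test_config"))
  if (n_crosses(x) < 2L)
    stop("the paired GLM needs at least two reciprocal crosses")
  y <- x$counts
  offset <- make_offsets(x, config)
  design <- paired_design(x$samples)
  disp <- estimate_dispersions(y, design, offset,
                               prior_df = config$prior_df)
  dispersion <- switch(config$dispersion_mode,
                       tagwise = disp$tagwise,
                       trended = disp$trended,
                       common = rep(disp$common, nrow(y)))
  lrt <- glm_lrt(y, design, offset, dispersion, coef = "parent_maternal")

  ## genes with an all-zero parent have a divergent coefficient; report a
  ## finite effect from a 0.5-count working adjustment (test untouched)
  m <- maternal_counts(x); p <- paternal_counts(x)
  degenerate <- rowSums(m) == 0 | rowSums(p) == 0
  if (any(degenerate)) {
    adj <- nb_glm_fit(y[degenerate, , drop = FALSE] + 0.5, design, offset,
                      dispersion[degenerate])
    lrt$log2_fold_effect[degenerate] <-
      adj$coefficients[, "parent_maternal"] / log(2)
  }

  res <- data.frame(
    gene_id = rownames(y), y,
    maternal_prop = rowSums(m) / pmax(rowSums(y), 1),
    log2_fold_effect = lrt$log2_fold_effect,
    dispersion = dispersion,
    p_value = lrt$p_value,
    row.names = NULL, check.names = FALSE
  )
  res$fdr <- bh_fdr(res$p_value)
  res$call <- classify_imprinted(res, config)
  attr(res, "config") <- config
  class(res) <- c("imprinting_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: monotone non-decreasing in p-value
#' rank and capped at 1. `NA` p-values (e.g. non-converged genes) are
#' propagated as `NA` and excluded from the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values (FDR) of the same length.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as MEG, PEG or not imprinted
#'
#' A gene is a candidate MEG when its FDR is below `config$fdr_level` and
#' its effect points to maternal excess relative to the expected ratio,
#' and a candidate PEG when the effect points to paternal excess.
#'
#' @param results data.frame with columns `fdr` and `log2_fold_effect`.
#' @param config a [test_config()].
#' @return factor with levels `none`, `MEG`, `PEG`.
#' @export
classify_imprinted <- function(results, config = test_config()) {
  call <- rep("none", nrow(results))
  sig <- !is.na(results$fdr) & results$fdr < config$fdr_level
  call[sig & results$log2_fold_effect > 0] <- "MEG"
  call[sig & results$log2_fold_effect < 0] <- "PEG"
  factor(call, levels = c("none", "MEG", "PEG"))
}

#' Write / read an imprinting result table as TSV
#'
#' @param results an `imprinting_result` data.frame.
#' @param path file path.
#' @export
write_imprinting_result <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_imprinting_result
#' @export
read_imprinting_result <- function(path) {
  res <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  res$call <- factor(res$call, levels = c("none", "MEG", "PEG"))
  class(res) <- c("imprinting_result", "data.frame")
  res
}
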
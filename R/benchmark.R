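#' Evaluate imprinting calls against the simulation truth
#'
#' Spiked genes are the true-positive group, all other genes the
#' true-negative group. A spiked gene counts as detected when it is called
#' in either direction; genes removed by the count filter are simply not
#' called (they stay in the 200-gene TPR denominator). Also reports the
#' TPR per spike-in category.
#'
#' @param called character vector of gene ids called imprinted (at the FDR
#'   cut-off), e.g. `results$gene_id[results$call != "none"]`.
#' @param truth a `sim_truth` data.frame over the full simulated gene
#'   universe.
#' @return list of class `benchmark_summary`: `n_true_positives`,
#'   `n_false_positives`, `tpr`, `fpr`, `n_spiked`, `n_null`, and
#'   `category_tpr` (named vector).
#' @export
evaluate_calls <- function(called, truth) {
  stopifnot(inherits(truth, "sim_truth"))
  unknown <- setdiff(called, truth$gene_id)
  if (length(unknown) > 0)
    stop("calls outside the simulated gene universe: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  spike <- truth$category != "null" & truth$category != "strain_bias"
  spiked_ids <- truth$gene_id[spike]
  null_ids <- truth$gene_id[!spike]
  tp <- sum(spiked_ids %in% called)
  fp <- sum(null_ids %in% called)
  cats <- unique(truth$category[spike])
  cat_tpr <- vapply(cats, function(cc) {
    ids <- truth$gene_id[truth$category == cc]
    sum(ids %in% called) / length(ids)
  }, numeric(1))
  out <- list(
    n_true_positives = tp, n_false_positives = fp,
    tpr = tp / length(spiked_ids), fpr = fp / length(null_ids),
    n_spiked = length(spiked_ids), n_null = length(null_ids),
    category_tpr = cat_tpr
  )
  class(out) <- "benchmark_summary"
  out
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("TP %d/%d (TPR %.1f%%), FP %d (FPR %.2f%%)\n",
              x$n_true_positives, x$n_spiked, 100 * x$tpr,
              x$n_false_positives, 100 * x$fpr))
  if (length(x$category_tpr))
    print(round(100 * x$category_tpr, 1))
  invisible(x)
}

#' ROC curve over all score thresholds
#'
#' Standard threshold sweep over per-gene scores (smaller = more
#' significant, e.g. p-values; genes excluded by the count filter should
#' be given score 1 so they are never called). Tied scores are grouped
#' into a single threshold. The returned points start at (0, 0) and end at
#' (1, 1) and are non-decreasing in both coordinates.
#'
#' @param scores named numeric vector, one score per gene.
#' @param truth a `sim_truth` data.frame, or a logical vector (TRUE =
#'   positive) aligned with `scores`.
#' @return list of class `roc_curve`: data.frame `points` with `fpr`,
#'   `tpr`, `threshold`, and the trapezoidal `auc`.
#' @export
roc_curve <- function(scores, truth) {
  if (inherits(truth, "sim_truth")) {
    stopifnot(!is.null(names(scores)),
              setequal(names(scores), truth$gene_id))
    pos <- truth$category[match(names(scores), truth$gene_id)] != "null"
  } else {
    pos <- as.logical(truth)
    stopifnot(length(pos) == length(scores))
  }
  np <- sum(pos); nn <- sum(!pos)
  stopifnot(np > 0, nn > 0)
  ord <- order(scores)
  s <- scores[ord]; p <- pos[ord]
  ## group ties
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  points <- data.frame(
    fpr = c(0, fp / nn), tpr = c(0, tp / np),
    threshold = c(-Inf, s[last])
  )
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  out <- list(points = points, auc = auc)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve, %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' TPR and FPR within count bins
#'
#' Divides the assessed genes into `n_bins` equally sized bins by their
#' total allelic counts (rank-based, ties at a bin boundary go to the
#' lower bin) and reports the true and false positive rate within each
#' bin. Bins with no spiked (or no null) genes get `NaN` rates and a zero
#' denominator.
#'
#' @param called character vector of called gene ids.
#' @param truth a `sim_truth` data.frame restricted to the assessed genes
#'   (the shared universe passing the count filter).
#' @param counts total allelic counts per assessed gene, aligned with
#'   `truth`.
#' @param n_bins number of bins (default 4, i.e. count quartiles).
#' @return data.frame with one row per bin: count range, numbers of spiked
#'   and null genes, `tpr`, `fpr`.
#' @export
binned_tpr <- function(called, truth, counts, n_bins = 4) {
  stopifnot(inherits(truth, "sim_truth"), length(counts) == nrow(truth))
  br <- unique(stats::quantile(counts, probs = seq(0, 1, length.out = n_bins + 1),
                               type = 1))
  bin <- cut(counts, br, include.lowest = TRUE, right = TRUE)
  spike <- truth$category != "null" & truth$category != "strain_bias"
  hit <- truth$gene_id %in% called
  do.call(rbind, lapply(seq_along(levels(bin)), function(b) {
    i <- as.integer(bin) == b
    ns <- sum(i & spike); nn <- sum(i & !spike)
    data.frame(
      bin = b, range = levels(bin)[b],
      min_count = min(counts[i]), max_count = max(counts[i]),
      n_spiked = ns, n_null = nn,
      tpr = if (ns > 0) sum(i & spike & hit) / ns else NaN,
      fpr = if (nn > 0) sum(i & !spike & hit) / nn else NaN
    )
  }))
}

#' Top-N most significant candidate genes
#'
#' Deterministic ranking by p-value, then absolute effect size, then gene
#' id; restricted to one direction and an optional maternal-fraction
#' window (e.g. >= 0.85 for candidate MEGs, <= 0.50 for candidate PEGs, as
#' used for between-study top-50 comparisons).
#'
#' @param results an `imprinting_result` data.frame.
#' @param n number of genes to return (all qualifying genes if fewer).
#' @param direction `"MEG"`, `"PEG"` or `"any"`.
#' @param min_maternal_frac,max_maternal_frac optional bounds on the
#'   observed maternal proportion.
#' @return character vector of gene ids.
#' @export
top_n <- function(results, n = 50, direction = c("any", "MEG", "PEG"),
                  min_maternal_frac = NULL, max_maternal_frac = NULL) {
  direction <- match.arg(direction)
  keep <- !is.na(results$p_value)
  if (direction == "MEG") keep <- keep & results$log2_fold_effect > 0
  if (direction == "PEG") keep <- keep & results$log2_fold_effect < 0
  if (!is.null(min_maternal_frac))
    keep <- keep & results$maternal_prop >= min_maternal_frac
  if (!is.null(max_maternal_frac))
    keep <- keep & results$maternal_prop <= max_maternal_frac
  r <- results[keep, ]
  ord <- order(r$p_value, -abs(r$log2_fold_effect), r$gene_id)
  if (n < nrow(r)) ord <- ord[seq_len(n)]
  else if (n > nrow(r))
    message("only ", nrow(r), " qualifying genes for top-", n)
  r$gene_id[ord]
}

#' Concordance between gene sets
#'
#' All Venn regions by inclusion-exclusion over exact membership, pairwise
#' Jaccard indices and the proportion of genes in each set shared with no
#' other set.
#'
#' @param sets named list of >= 2 character vectors.
#' @return list of class `concordance_summary`: `regions` (data.frame of
#'   all 2^k - 1 membership patterns with counts), `jaccard` (matrix),
#'   `non_shared` (named proportions).
#' @export
concordance <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  k <- length(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(patterns) <- names(sets)
  patterns$count <- apply(patterns, 1, function(row) {
    sum(apply(member, 1, function(m) all(m == row)))
  })
  jac <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    jac[i, j] <- jac[j, i] <-
      length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
  }
  non_shared <- vapply(seq_len(k), function(i) {
    others <- unique(unlist(sets[-i]))
    if (length(sets[[i]]) == 0) return(NaN)
    mean(!sets[[i]] %in% others)
  }, numeric(1))
  names(non_shared) <- names(sets)
  out <- list(regions = patterns, jaccard = jac, non_shared = non_shared)
  class(out) <- "concordance_summary"
  out
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Pairwise Jaccard indices:\n")
  print(round(x$jaccard, 3))
  cat("Non-shared proportion per set:\n")
  print(round(x$non_shared, 3))
  invisible(x)
}

#' Saturation analysis by count subsampling
#'
#' Binomially thins every count cell to a proportion `q` of the original
#' depth, re-runs the full pipeline (filter + test + classification) and
#' reports mean and standard error of the number of detected MEGs, PEGs
#' and callable genes over `n_reps` random subsamples per proportion.
#' Thinning at q = 1 is the identity, so those replicates reproduce the
#' full-data analysis exactly.
#'
#' @param x an unfiltered [allelic_counts()] table.
#' @param proportions subsampling proportions in (0, 1].
#' @param n_reps subsamples per proportion (default 10).
#' @param pipeline function taking a filtered [allelic_counts()] table and
#'   returning an `imprinting_result` (default: [imprint_test()] with the
#'   given `config`).
#' @param config a [test_config()] for the default pipeline.
#' @param min_total count filter re-applied after thinning.
#' @param seed master seed; each replicate uses a seed derived from it.
#' @return data.frame with one row per (proportion, statistic): means and
#'   standard errors of `n_meg`, `n_peg`, `n_callable`.
#' @export
saturation <- function(x, proportions, n_reps = 10, pipeline = NULL,
                       config = test_config(), min_total = 10, seed = 1L) {
  stopifnot(all(proportions > 0), all(proportions <= 1))
  if (is.null(pipeline)) pipeline <- function(tab) imprint_test(tab, config)
  rows <- list()
  for (qi in seq_along(proportions)) {
    q <- proportions[qi]
    reps <- matrix(NA_real_, n_reps, 3,
                   dimnames = list(NULL, c("n_meg", "n_peg", "n_callable")))
    for (r in seq_len(n_reps)) {
      set.seed(seed + 1000L * qi + r)
      thinned <- thin_counts(x, q)
      kept <- filter_min_counts(thinned, min_total)
      if (nrow(kept$counts) == 0) {
        reps[r, ] <- c(0, 0, 0)
        next
      }
      res <- pipeline(kept)
      reps[r, ] <- c(sum(res$call == "MEG"), sum(res$call == "PEG"),
                     nrow(kept$counts))
    }
    rows[[qi]] <- data.frame(
      proportion = q,
      statistic = colnames(reps),
      mean = colMeans(reps),
      se = apply(reps, 2, stats::sd) / sqrt(n_reps),
      row.names = NULL
    )
  }
  do.call(rbind, rows)
}

#' Binomial thinning of an allelic count table
#'
#' Each count cell is replaced by a Binomial(count, q) draw, emulating
#' sequencing at a fraction `q` of the original depth. `q = 1` returns the
#' table unchanged.
#'
#' @param x an [allelic_counts()] table.
#' @param q retention proportion in (0, 1].
#' @export
thin_counts <- function(x, q) {
  stopifnot(q > 0, q <= 1)
  if (q == 1) return(x)
  y <- x$counts
  thinned <- matrix(stats::rbinom(length(y), size = as.vector(y), prob = q),
                    nrow = nrow(y), dimnames = dimnames(y))
  k <- n_crosses(x)
  allelic_counts(thinned[, 2L * seq_len(k) - 1L, drop = FALSE],
                 thinned[, 2L * seq_len(k), drop = FALSE],
                 gene_id = rownames(y))
}

#' Run the full spike-in benchmark
#'
#' Simulates an allelic count table, applies the count filter, runs the
#' requested callers, and evaluates each against the simulation truth.
#' With several seeds the per-method summaries are averaged.
#'
#' @param config a [sim_config()] (its seed is overridden per run).
#' @param methods subset of `c("nbglm", "fisher-summed", "fisher-combined")`.
#' @param seeds integer vector of simulation seeds.
#' @param test_cfg a [test_config()]; its null proportion should match the
#'   simulation's.
#' @param min_total count filter threshold.
#' @return list of class `benchmark_run`: `per_seed` (data.frame of
#'   TP/FP/TPR/FPR and per-category TPRs per method and seed), `mean`
#'   (aggregated over seeds), `detected` (per seed: list of called spiked
#'   gene ids per method, for overlap analyses).
#' @export
run_benchmark <- function(config = sim_config(),
                          methods = c("nbglm", "fisher-summed",
                                      "fisher-combined"),
                          seeds = 1L,
                          test_cfg = test_config(
                            null_maternal_prop = config$null_maternal_prop),
                          min_total = config$min_total) {
  methods <- match.arg(methods, several.ok = TRUE)
  per_seed <- list()
  detected <- list()
  for (sd in seeds) {
    cfg <- config; cfg$seed <- as.integer(sd)
    sim <- simulate_imprinting(cfg)
    kept <- filter_min_counts(sim$counts, min_total)
    det <- list()
    for (m in methods) {
      res <- switch(m,
                    "nbglm" = imprint_test(kept, test_cfg),
                    "fisher-summed" = fisher_summed_test(kept, test_cfg),
                    "fisher-combined" = fisher_combined_test(kept, test_cfg))
      called <- res$gene_id[res$call != "none"]
      ev <- evaluate_calls(called, sim$truth)
      det[[m]] <- called
      per_seed[[length(per_seed) + 1L]] <- data.frame(
        seed = sd, method = m,
        n_true_positives = ev$n_true_positives,
        n_false_positives = ev$n_false_positives,
        tpr = ev$tpr, fpr = ev$fpr,
        t(100 * ev$category_tpr), check.names = FALSE
      )
    }
    detected[[as.character(sd)]] <- det
  }
  per_seed <- do.call(rbind, per_seed)
  num <- vapply(per_seed, is.numeric, logical(1)) & names(per_seed) != "seed"
  mean_tab <- stats::aggregate(per_seed[num], list(method = per_seed$method),
                               mean)
  out <- list(per_seed = per_seed, mean = mean_tab, detected = detected)
  class(out) <- "benchmark_run"
  out
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat(sprintf("Spike-in benchmark over %d seed(s)\n",
              length(unique(x$per_seed$seed))))
  print(x$mean, digits = 3)
  invisible(x)
}
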
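toy_truth <- function(n = 100, n_spike = 10, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n))
  cat <- rep("null", n)
  cat[sample(n, n_spike)] <- rep(c("strong_MEG", "strong_PEG"),
                                 length.out = n_spike)
  truth <- data.frame(gene_id = ids, category = cat,
                      true_maternal_prop = ifelse(cat == "null", 2 / 3, 0.9))
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

test_that("perfect and empty callers hit the TPR/FPR corners", {
  truth <- toy_truth()
  spiked <- truth$gene_id[truth$category != "null"]
  perfect <- evaluate_calls(spiked, truth)
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)
  nothing <- evaluate_calls(character(0), truth)
  expect_equal(nothing$tpr, 0)
  expect_equal(nothing$fpr, 0)
  expect_equal(perfect$n_true_positives +
                 (perfect$n_spiked - perfect$n_true_positives),
               perfect$n_spiked)
  expect_error(evaluate_calls("nonexistent", truth), "universe")
})

test_that("random calls recover the sampling expectation", {
  truth <- toy_truth(n = 2000, n_spike = 200, seed = 3)
  set.seed(4)
  k <- 100
  tp <- replicate(200, {
    evaluate_calls(sample(truth$gene_id, k), truth)$n_true_positives
  })
  expected <- 200 * k / 2000
  se <- sd(tp) / sqrt(length(tp))
  expect_lt(abs(mean(tp) - expected), 4 * se + 0.01)
})

test_that("ROC endpoints, symmetry and separability behave canonically", {
  truth <- toy_truth(n = 500, n_spike = 50, seed = 5)
  pos <- truth$category != "null"
  ## perfectly separating scores
  s <- ifelse(pos, 0.001, 0.9) + runif(500, 0, 1e-4)
  names(s) <- truth$gene_id
  r <- roc_curve(s, truth)
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  ## reversing the score order flips the AUC
  set.seed(6)
  s2 <- runif(500); names(s2) <- truth$gene_id
  r2 <- roc_curve(s2, truth)
  r2r <- roc_curve(1 - s2, truth)
  expect_equal(r2r$auc, 1 - r2$auc, tolerance = 1e-12)
  ## independent scores give AUC near 1/2
  expect_lt(abs(r2$auc - 0.5), 3 * sqrt((500 + 1) / (12 * 50 * 450)))
})

test_that("AUC matches the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  truth <- toy_truth(n = 300, n_spike = 40, seed = 7)
  pos <- truth$category != "null"
  s <- runif(300) - 0.3 * pos
  names(s) <- truth$gene_id
  mine <- roc_curve(s, truth)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(response = pos, predictor = s,
                                              direction = ">")))
  expect_equal(mine, as.numeric(ref), tolerance = 1e-10)
})

test_that("count-binned rates reduce to the totals with one bin", {
  run <- standard_benchmark(1)
  truth_kept <- run$sim$truth[match(rownames(run$kept$counts),
                                    run$sim$truth$gene_id), ]
  class(truth_kept) <- c("sim_truth", "data.frame")
  counts <- rowSums(run$kept$counts)
  called <- called_ids(run$nbglm)
  one <- binned_tpr(called, truth_kept, counts, n_bins = 1)
  expect_equal(one$tpr, sum(truth_kept$gene_id[truth_kept$category != "null"]
                            %in% called) /
                 sum(truth_kept$category != "null"))
  four <- binned_tpr(called, truth_kept, counts, n_bins = 4)
  expect_equal(sum(four$n_spiked), one$n_spiked)
  expect_equal(sum(four$n_null), one$n_null)
})

test_that("bins without spiked genes report NaN with zero denominators", {
  truth <- toy_truth(n = 40, n_spike = 4, seed = 8)
  spike <- truth$category != "null"
  counts <- ifelse(spike, 1000 + seq_len(40), seq_len(40))
  called <- truth$gene_id[spike]
  tab <- binned_tpr(called, truth, counts, n_bins = 4)
  expect_true(any(is.nan(tab$tpr)))
  expect_equal(tab$n_spiked[is.nan(tab$tpr)],
               rep(0L, sum(is.nan(tab$tpr))), ignore_attr = TRUE)
})

test_that("top-N ranking is deterministic and nested", {
  res <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    maternal_prop = c(0.9, 0.95, 0.2, 0.3, 0.97),
    log2_fold_effect = c(1, 2, -1.5, -0.2, 2),
    p_value = c(0.01, 0.01, 0.002, 0.5, 0.001)
  )
  ## ties on p broken by |effect| then gene_id
  expect_equal(top_n(res, 3), c("e", "c", "b"))
  expect_equal(top_n(res, 2, direction = "MEG"), c("e", "b"))
  expect_equal(top_n(res, 2, direction = "PEG",
                     max_maternal_frac = 0.5), c("c", "d"))
  expect_message(got <- top_n(res, 10, direction = "PEG"), "qualifying")
  expect_equal(got, c("c", "d"))
  run <- standard_benchmark(1)
  expect_true(all(top_n(run$nbglm, 50) %in% top_n(run$nbglm, 100)))
})

test_that("concordance matches brute-force membership tabulation", {
  expect_equal(concordance(list(a = c("x", "y"), b = c("x", "y")))
               $jaccard["a", "b"], 1)
  expect_equal(concordance(list(a = c("x"), b = c("y")))$jaccard["a", "b"], 0)
  set.seed(9)
  universe <- sprintf("g%02d", 1:40)
  sets <- list(s1 = sample(universe, 15), s2 = sample(universe, 20),
               s3 = sample(universe, 10))
  cc <- concordance(sets)
  ## brute force every region
  all_ids <- unique(unlist(sets))
  for (r in seq_len(nrow(cc$regions))) {
    pat <- unlist(cc$regions[r, names(sets)])
    n_bf <- sum(vapply(all_ids, function(g) {
      all(vapply(names(sets), function(s) (g %in% sets[[s]]) == pat[s],
                 logical(1)))
    }, logical(1)))
    expect_equal(cc$regions$count[r], n_bf)
  }
  ## inclusion-exclusion: regions partition the union
  expect_equal(sum(cc$regions$count), length(all_ids))
  j12 <- length(intersect(sets$s1, sets$s2)) /
    length(union(sets$s1, sets$s2))
  expect_equal(cc$jaccard["s1", "s2"], j12)
})

test_that("binomial thinning is exact at q = 1 and null at tiny q", {
  sim <- small_sim(seed = 91, n_genes = 400)
  expect_identical(thin_counts(sim$counts, 1)$counts, sim$counts$counts)
  set.seed(1)
  nearly_empty <- thin_counts(sim$counts, 1e-4)
  expect_equal(nrow(filter_min_counts(nearly_empty, 10)$counts), 0)
})

test_that("saturation at proportion 1 reproduces the full analysis", {
  sim <- small_sim(seed = 92, n_genes = 800)
  cfg <- test_config()
  kept <- filter_min_counts(sim$counts, 10)
  full <- imprint_test(kept, cfg)
  sat <- saturation(sim$counts, proportions = 1, n_reps = 2, config = cfg,
                    seed = 123)
  expect_equal(sat$mean[sat$statistic == "n_meg"], sum(full$call == "MEG"))
  expect_equal(sat$mean[sat$statistic == "n_peg"], sum(full$call == "PEG"))
  expect_equal(sat$mean[sat$statistic == "n_callable"], nrow(kept$counts))
  expect_equal(sat$se, rep(0, 3))
})

test_that("detected genes do not decrease with sampling depth", {
  sim <- small_sim(seed = 93, n_genes = 1200)
  sat <- saturation(sim$counts, proportions = c(0.05, 0.4, 1), n_reps = 3,
                    seed = 7)
  meg <- sat[sat$statistic == "n_meg", ]
  ## monotone within the standard errors
  expect_lte(meg$mean[1], meg$mean[3] + 2 * (meg$se[1] + meg$se[3]) + 1)
  callable <- sat[sat$statistic == "n_callable", ]
  expect_true(all(diff(callable$mean) >= 0))
})

test_that("the benchmark driver aggregates per-seed summaries", {
  cfg <- sim_config(n_genes = 1200, seed = 1,
                    spike_design = data.frame(
                      category = c("strong_MEG", "strong_PEG"),
                      n = c(15L, 15L), maternal_prop = c(0.99, 0.34)))
  bench <- run_benchmark(cfg, methods = c("nbglm", "fisher-summed"),
                         seeds = c(1, 2))
  expect_equal(nrow(bench$per_seed), 4)
  expect_equal(sort(bench$mean$method), c("fisher-summed", "nbglm"))
  expect_true(all(bench$per_seed$tpr >= 0 & bench$per_seed$tpr <= 1))
  ## strong spikes at high counts: NB-GLM should detect a decent share
  expect_gt(bench$mean$tpr[bench$mean$method == "nbglm"], 0.3)
})
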
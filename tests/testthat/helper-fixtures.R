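## Shared fixtures, all generated in code.

## Small spike-in dataset for fast pipeline tests.
small_sim <- function(seed = 7L, n_genes = 2000L, ...) {
  cfg <- sim_config(
    n_genes = n_genes,
    spike_design = data.frame(
      category = c("strong_MEG", "weak_MEG", "strong_PEG", "weak_PEG"),
      n = c(10L, 10L, 10L, 10L),
      maternal_prop = c(0.99, 0.85, 0.34, 0.48)
    ),
    seed = seed, ...
  )
  simulate_imprinting(cfg)
}

## Independent two-sided Fisher p-value by exhaustive hypergeometric
## enumeration over the 2x2 table [a, b; c, d] (fixed margins).
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  k <- max(0, c1 - (n - r1)):min(r1, c1)
  dens <- dhyper(k, c1, n - c1, r1)
  obs <- dhyper(a, c1, n - c1, r1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

## Hand-coded Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

## One standard full-scale benchmark run per seed, cached across test
## files (the NB-GLM, Fisher-summed and Fisher-combined callers all run on
## the same simulated table).
.bench_cache <- new.env(parent = emptyenv())
standard_benchmark <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  sim <- simulate_imprinting(sim_config(seed = seed))
  kept <- filter_min_counts(sim$counts, 10)
  cfg <- test_config()
  res <- list(
    sim = sim, kept = kept,
    nbglm = imprint_test(kept, cfg),
    fisher_summed = fisher_summed_test(kept, cfg),
    fisher_combined = fisher_combined_test(kept, cfg)
  )
  .bench_cache[[key]] <- res
  res
}

called_ids <- function(res) res$gene_id[res$call != "none"]
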
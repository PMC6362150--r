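#' Simulation configuration for synthetic allelic count tables
#'
#' Bundles the parameters of the spike-in simulation used to benchmark
#' imprinting callers. Total gene expression is drawn per gene from a
#' negative binomial whose log2 mean is Normal(`intercept_mean`,
#' `intercept_sd`) and whose dispersion follows `dispersion_fn`; the two
#' reciprocal crosses are simulated as two biological replicates with no
#' differential expression between them. Allelic reads are then split
#' binomially at each gene's true maternal proportion, which is
#' `null_maternal_prop` (2/3 for triploid endosperm) except for the genes
#' spiked as imprinted by `spike_design`.
#'
#' @param n_genes number of genes to simulate.
#' @param intercept_mean,intercept_sd mean and sd of the per-gene log2
#'   baseline expression.
#' @param dispersion_fn function mapping the NB mean to the NB dispersion;
#'   the default `4/mu + 0.1` is the documented default trend of the count
#'   generator the benchmark is modelled on.
#' @param n_crosses number of reciprocal crosses (paired maternal/paternal
#'   columns); at least 2.
#' @param null_maternal_prop true maternal-read proportion of non-spiked
#'   genes, in (0,1). 2/3 corresponds to the endosperm 2:1 ratio.
#' @param spike_design data.frame with columns `category`, `n`,
#'   `maternal_prop` giving, per spike-in class, how many genes to spike and
#'   their true maternal proportion. The default spikes 50 genes each of
#'   strong MEGs (0.99), weak MEGs (0.85), strong PEGs (0.34) and weak PEGs
#'   (0.48).
#' @param spike_pool `"expressed"` (default) restricts the genes eligible
#'   for spiking to those whose simulated totals pass `min_total`, so that
#'   every spiked gene is assessable by the downstream pipeline and the
#'   true-positive denominator equals the number of spiked genes;
#'   `"all"` spikes uniformly over all genes.
#' @param min_total the min-count filter the pipeline will apply (used only
#'   when `spike_pool = "expressed"`).
#' @param n_bias_genes,bias_factor optional accession-bias scenario: this
#'   many extra genes get a strain-specific expression bias of
#'   `bias_factor` (per genome copy) for the first parent's allele, giving
#'   opposite maternal-fraction shifts in the two reciprocal crosses.
#' @param seed integer seed; all randomness of the generator flows from it.
#'
#' @return An object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(n_genes = 15000,
                       intercept_mean = 2,
                       intercept_sd = 3,
                       dispersion_fn = function(mu) 4 / mu + 0.1,
                       n_crosses = 2,
                       null_maternal_prop = 2 / 3,
                       spike_design = default_spike_design(),
                       spike_pool = c("expressed", "all"),
                       min_total = 10,
                       n_bias_genes = 0,
                       bias_factor = 3,
                       seed = 1L) {
  spike_pool <- match.arg(spike_pool)
  stopifnot(
    n_genes >= 1, n_crosses >= 2,
    null_maternal_prop > 0, null_maternal_prop < 1,
    is.function(dispersion_fn),
    is.data.frame(spike_design),
    all(c("category", "n", "maternal_prop") %in% names(spike_design)),
    n_bias_genes >= 0, bias_factor > 0
  )
  if (nrow(spike_design) > 0) {
    if (any(spike_design$maternal_prop <= 0 | spike_design$maternal_prop >= 1))
      stop("spiked maternal proportions must lie in (0, 1)")
    if (anyDuplicated(spike_design$category))
      stop("spike categories must be unique")
  }
  if (sum(spike_design$n) + n_bias_genes >= n_genes)
    stop("more spiked genes than genes to simulate")
  cfg <- list(
    n_genes = as.integer(n_genes),
    intercept_mean = intercept_mean,
    intercept_sd = intercept_sd,
    dispersion_fn = dispersion_fn,
    n_crosses = as.integer(n_crosses),
    null_maternal_prop = null_maternal_prop,
    spike_design = spike_design,
    spike_pool = spike_pool,
    min_total = as.integer(min_total),
    n_bias_genes = as.integer(n_bias_genes),
    bias_factor = bias_factor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default spike-in design: 50 genes each of four imprinting classes
#'
#' @return data.frame with columns `category`, `n`, `maternal_prop`.
#' @export
default_spike_design <- function() {
  data.frame(
    category = c("strong_MEG", "weak_MEG", "strong_PEG", "weak_PEG"),
    n = c(50L, 50L, 50L, 50L),
    maternal_prop = c(0.99, 0.85, 0.34, 0.48),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Spike-in simulation config\n")
  cat(sprintf("  genes: %d, crosses: %d, seed: %d\n",
              x$n_genes, x$n_crosses, x$seed))
  cat(sprintf("  log2 baseline ~ N(%g, %g), null maternal prop %.4f\n",
              x$intercept_mean, x$intercept_sd, x$null_maternal_prop))
  cat(sprintf("  spiked genes: %d in %d categories (pool: %s)\n",
              sum(x$spike_design$n), nrow(x$spike_design), x$spike_pool))
  if (x$n_bias_genes > 0)
    cat(sprintf("  accession-bias genes: %d (factor %g)\n",
                x$n_bias_genes, x$bias_factor))
  invisible(x)
}

#' Simulate per-gene total allelic counts
#'
#' Draws, for each gene, a log2 baseline `b ~ N(intercept_mean,
#' intercept_sd)` and then, independently for each cross, a negative
#' binomial total with mean `mu = 2^b` and dispersion `dispersion_fn(mu)`
#' (variance `mu + phi * mu^2`). No differential expression between crosses
#' and no outliers are introduced; library sizes are implicitly equal.
#'
#' @param config a [sim_config()].
#' @return list with `totals` (integer matrix, genes x crosses), `mu`
#'   (true NB means) and `dispersion` (true NB dispersions).
#' @export
simulate_total_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  beta0 <- stats::rnorm(n, config$intercept_mean, config$intercept_sd)
  mu <- 2^beta0
  phi <- config$dispersion_fn(mu)
  if (any(!is.finite(phi)) || any(phi <= 0))
    stop("dispersion_fn must return finite positive dispersions")
  k <- config$n_crosses
  totals <- matrix(
    stats::rnbinom(n * k, mu = rep(mu, k), size = rep(1 / phi, k)),
    nrow = n, ncol = k,
    dimnames = list(gene_ids(n), paste0("cross", seq_len(k)))
  )
  list(totals = totals, mu = mu, dispersion = phi)
}

gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

#' Assign spike-in imprinting status
#'
#' Picks disjoint random gene sets for each spike-in category of
#' `config$spike_design` and labels every other gene `null` at the null
#' maternal proportion. With `spike_pool = "expressed"` (default) the
#' spiked genes are drawn only from genes whose simulated totals pass the
#' pipeline's min-count filter, so all of them are assessable downstream.
#' If the accession-bias scenario is enabled, an additional disjoint set of
#' genes is labelled `strain_bias`; these keep the null maternal proportion
#' on average but receive opposite per-cross allelic shifts in
#' [split_alleles()].
#'
#' @param config a [sim_config()].
#' @param totals matrix of simulated totals (needed for the expressed pool).
#' @return data.frame (`sim_truth`) with columns `gene_id`, `category`,
#'   `true_maternal_prop`.
#' @export
spike_imprinting <- function(config, totals = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  ids <- gene_ids(n)
  design <- config$spike_design
  n_spike <- sum(design$n) + config$n_bias_genes
  pool <- seq_len(n)
  if (config$spike_pool == "expressed") {
    if (is.null(totals))
      stop("totals are required to spike from the expressed pool")
    pool <- which(rowSums(totals) >= config$min_total)
    if (length(pool) < n_spike)
      stop("fewer expressed genes than genes to spike")
  }
  picked <- sample(pool, n_spike)
  category <- rep("null", n)
  prop <- rep(config$null_maternal_prop, n)
  at <- 0L
  for (i in seq_len(nrow(design))) {
    sel <- picked[at + seq_len(design$n[i])]
    category[sel] <- design$category[i]
    prop[sel] <- design$maternal_prop[i]
    at <- at + design$n[i]
  }
  if (config$n_bias_genes > 0) {
    sel <- picked[at + seq_len(config$n_bias_genes)]
    category[sel] <- "strain_bias"
  }
  truth <- data.frame(
    gene_id = ids, category = category, true_maternal_prop = prop,
    stringsAsFactors = FALSE
  )
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

#' Split total counts into maternal and paternal reads
#'
#' For each gene and cross, the maternal count is a binomial draw from the
#' total with success probability equal to the gene's true maternal
#' proportion; the paternal count is the remainder, so the two allelic
#' counts always sum exactly to the simulated total. Genes labelled
#' `strain_bias` instead use cross-dependent proportions implied by a
#' constant per-genome-copy expression bias of the first parent's allele:
#' with bias factor `k` and a maternal genome dosage `d = p0/(1-p0)`, the
#' maternal proportion is `d*k/(d*k + 1)` in odd-numbered crosses (first
#' parent is the mother) and `d/(d + k)` in even-numbered crosses.
#'
#' @param totals integer matrix of totals (genes x crosses).
#' @param truth a `sim_truth` data.frame from [spike_imprinting()].
#' @param config the [sim_config()] used to generate both.
#' @return an [allelic_counts()] object.
#' @export
split_alleles <- function(totals, truth, config) {
  stopifnot(nrow(totals) == nrow(truth))
  if (any(totals < 0) || any(totals != round(totals)))
    stop("totals must be non-negative integers")
  n <- nrow(totals)
  k <- ncol(totals)
  p <- matrix(truth$true_maternal_prop, nrow = n, ncol = k)
  bias <- truth$category == "strain_bias"
  if (any(bias)) {
    d <- config$null_maternal_prop / (1 - config$null_maternal_prop)
    kf <- config$bias_factor
    p_odd <- d * kf / (d * kf + 1)
    p_even <- d / (d + kf)
    for (c in seq_len(k))
      p[bias, c] <- if (c %% 2 == 1) p_odd else p_even
  }
  maternal <- matrix(
    stats::rbinom(n * k, size = as.vector(totals), prob = as.vector(p)),
    nrow = n, ncol = k
  )
  paternal <- totals - maternal
  allelic_counts(maternal, paternal, gene_id = rownames(totals))
}

#' Simulate a complete spike-in benchmark dataset
#'
#' Convenience wrapper running [simulate_total_counts()],
#' [spike_imprinting()] and [split_alleles()] under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (an [allelic_counts()] table), `truth`
#'   (a `sim_truth` data.frame) and `config`.
#' @export
simulate_imprinting <- function(config = sim_config()) {
  set.seed(config$seed)
  tot <- simulate_total_counts(config)
  truth <- spike_imprinting(config, tot$totals)
  counts <- split_alleles(tot$totals, truth, config)
  list(counts = counts, truth = truth, config = config)
}

#' Write / read a simulation truth table as TSV
#'
#' @param truth a `sim_truth` data.frame.
#' @param path output file.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  truth <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "category", "true_maternal_prop") %in%
                  names(truth)))
  class(truth) <- c("sim_truth", "data.frame")
  truth
}
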
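## Vectorized negative-binomial GLM engine.
##
## All genes share one design matrix (samples x coefficients), so iterative
## reweighted least squares can be run for every gene simultaneously with a
## handful of dense matrix operations per iteration; the per-gene P x P
## normal equations are solved by Gaussian elimination vectorized over
## genes. Dispersions enter as a per-gene vector (0 = Poisson limit).

## Solve A x = b for G stacked P x P SPD systems.
## A: G x (P*P) matrix, column-major per gene; b: G x P.
## Returns list(x = G x P, logdet = length-G log determinant).
batch_solve <- function(A, b, p) {
  g <- nrow(b)
  A <- matrix(A, nrow = g)  # copy
  x <- matrix(b, nrow = g)
  logdet <- numeric(g)
  idx <- function(i, j) (j - 1L) * p + i
  for (k in seq_len(p)) {
    piv <- pmax(A[, idx(k, k)], 1e-12)
    logdet <- logdet + log(piv)
    if (k < p) {
      for (i in (k + 1L):p) {
        fac <- A[, idx(i, k)] / piv
        for (j in k:p) A[, idx(i, j)] <- A[, idx(i, j)] - fac * A[, idx(k, j)]
        x[, i] <- x[, i] - fac * x[, k]
      }
    }
  }
  for (k in rev(seq_len(p))) {
    if (k < p) for (j in (k + 1L):p) x[, k] <- x[, k] - A[, idx(k, j)] * x[, j]
    x[, k] <- x[, k] / pmax(A[, idx(k, k)], 1e-12)
  }
  list(x = x, logdet = logdet)
}

## Negative binomial log-likelihood, rowwise over a G x S matrix.
## phi is per-gene (recycled across samples); phi ~ 0 uses the Poisson limit.
nb_loglik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  pois <- phi < 1e-10
  ll <- matrix(0, nrow = nrow(y), ncol = ncol(y))
  ylogmu <- y * log(mu)
  if (any(pois)) {
    ll[pois, ] <- ylogmu[pois, , drop = FALSE] - mu[pois, , drop = FALSE] -
      lgamma(y[pois, , drop = FALSE] + 1)
  }
  if (any(!pois)) {
    i <- !pois
    r <- 1 / phi[i]
    yi <- y[i, , drop = FALSE]; mi <- mu[i, , drop = FALSE]
    ll[i, ] <- lgamma(yi + r) - lgamma(r) - lgamma(yi + 1) +
      r * log(r) + ylogmu[i, , drop = FALSE] - (yi + r) * log(mi + r)
  }
  rowSums(ll)
}

## NB unit deviance summed per gene.
nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-300)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  pois <- phi < 1e-10
  dev <- matrix(0, nrow = nrow(y), ncol = ncol(y))
  if (any(pois)) {
    i <- pois
    dev[i, ] <- t1[i, , drop = FALSE] -
      (y[i, , drop = FALSE] - mu[i, , drop = FALSE])
  }
  if (any(!pois)) {
    i <- !pois
    r <- 1 / phi[i]
    yi <- y[i, , drop = FALSE]; mi <- mu[i, , drop = FALSE]
    dev[i, ] <- t1[i, , drop = FALSE] -
      (yi + r) * log((yi + r) / (mi + r))
  }
  2 * rowSums(dev)
}

#' Fit negative binomial GLMs with a shared design across genes
#'
#' Fits, for every row of `y`, a log-link negative binomial GLM with the
#' common design matrix `design`, per-sample (or per-gene-and-sample)
#' offsets, and a per-gene dispersion. Fitting is iterative reweighted
#' least squares vectorized over genes, with step halving when a step
#' would increase the deviance.
#'
#' @param y count matrix, genes x samples (non-negative; non-integer
#'   working counts are accepted).
#' @param design samples x coefficients design matrix, full rank.
#' @param offset offsets on the log scale: a length-`ncol(y)` vector or a
#'   matrix like `y`. Typically `log(effective library size)`.
#' @param dispersion NB dispersion, scalar or per-gene vector; 0 gives the
#'   Poisson limit.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return list with `coefficients` (genes x coefficients), `fitted`
#'   (means), `deviance`, `loglik`, `logdet_xwx` (log determinant of the
#'   weighted information, used for Cox-Reid adjustment) and `converged`.
#' @export
nb_glm_fit <- function(y, design, offset, dispersion,
                       maxit = 50L, tol = 1e-8) {
  y <- as.matrix(y)
  X <- as.matrix(design)
  g <- nrow(y); s <- ncol(y); p <- ncol(X)
  stopifnot(nrow(X) == s, qr(X)$rank == p, s >= p)
  off <- if (is.matrix(offset)) offset else
    matrix(offset, nrow = g, ncol = s, byrow = TRUE)
  phi <- rep_len(dispersion, g)
  ## cross-product layout for the batched normal equations
  XX <- matrix(0, nrow = s, ncol = p * p)
  for (j in seq_len(p)) for (i in seq_len(p))
    XX[, (j - 1L) * p + i] <- X[, i] * X[, j]

  mu <- pmax(y, 1 / 6)
  eta <- log(mu)
  beta <- NULL
  dev <- nb_deviance(y, mu, phi)
  converged <- rep(FALSE, g)
  res <- NULL
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - off) + (y - mu) / mu
    A <- w %*% XX
    b <- (w * z) %*% X
    res <- batch_solve(A, b, p)
    beta_new <- res$x
    if (!is.null(beta)) {
      ## step halving where the proposed step increases the deviance
      for (h in 1:12) {
        eta_new <- pmin(off + tcrossprod(beta_new, X), 700)
        dev_new <- nb_deviance(y, exp(eta_new), phi)
        bad <- dev_new > dev + 1e-6 & !converged
        if (!any(bad)) break
        beta_new[bad, ] <- (beta_new[bad, , drop = FALSE] +
                              beta[bad, , drop = FALSE]) / 2
      }
    }
    beta <- beta_new
    eta <- pmin(off + tcrossprod(beta, X), 700)
    mu <- pmax(exp(eta), 1e-300)
    dev_new <- nb_deviance(y, mu, phi)
    converged <- abs(dev_new - dev) < tol * (abs(dev_new) + 0.1)
    dev <- dev_new
    if (all(converged)) break
  }
  ## information determinant at the final fit (for Cox-Reid adjustment)
  w <- mu / (1 + phi * mu)
  res <- batch_solve(w %*% XX, matrix(0, g, p), p)
  dimnames(beta) <- list(rownames(y), colnames(X))
  list(coefficients = beta, fitted = mu, deviance = dev,
       loglik = nb_loglik(y, mu, phi), logdet_xwx = res$logdet,
       converged = converged, iterations = it)
}

## Cox-Reid adjusted profile log-likelihood per gene at dispersion phi.
cox_reid_apl <- function(y, design, offset, phi, fit = NULL) {
  if (is.null(fit)) fit <- nb_glm_fit(y, design, offset, phi)
  fit$loglik - 0.5 * fit$logdet_xwx
}

#' Estimate negative binomial dispersions with empirical-Bayes moderation
#'
#' Implements the standard three-tier scheme for designed count
#' experiments: a single common dispersion maximizing the summed Cox-Reid
#' adjusted profile likelihood (APL); a mean-dispersion trend obtained by
#' maximizing the summed APL within abundance bins and interpolating with a
#' natural spline; and per-gene (tagwise) dispersions maximizing a weighted
#' sum of the gene's own APL and the grid-averaged APL of all genes, which
#' shrinks each gene toward the trend with strength `prior_df` prior
#' degrees of freedom per residual degree of freedom.
#'
#' @param y count matrix, genes x samples.
#' @param design design matrix, samples x coefficients.
#' @param offset log-scale offsets (vector or matrix).
#' @param prior_df prior degrees of freedom for tagwise shrinkage
#'   (default 10); `Inf` returns the trend itself.
#' @param grid_length,grid_range grid of log2 dispersion offsets around the
#'   trend explored for the tagwise estimates.
#' @return list with `common`, `trended`, `tagwise` (vectors), and
#'   `abundance` (average log2 counts per million used for the trend).
#' @export
estimate_dispersions <- function(y, design, offset, prior_df = 10,
                                 grid_length = 11L, grid_range = c(-6, 6)) {
  y <- as.matrix(y)
  g <- nrow(y); s <- ncol(y); p <- ncol(design)
  df_resid <- s - p
  if (df_resid < 1L)
    stop("no residual degrees of freedom: supply replicates (>= 2 crosses) ",
         "or a fixed dispersion")
  off <- if (is.matrix(offset)) offset else
    matrix(offset, nrow = g, ncol = s, byrow = TRUE)
  lib <- exp(off[1, ])
  abundance <- log2((rowSums(y) / sum(lib)) * 1e6 + 0.25)

  apl_sum <- function(log_phi, rows = seq_len(g)) {
    sum(cox_reid_apl(y[rows, , drop = FALSE], design,
                     off[rows, , drop = FALSE], exp(log_phi)))
  }
  bounds <- log(c(1e-6, 20))
  common <- exp(stats::optimize(apl_sum, bounds, maximum = TRUE,
                                tol = 1e-3)$maximum)

  ## trend: per-abundance-bin common dispersions, spline-interpolated
  n_bins <- max(1L, min(30L, floor(g / 100L)))
  if (n_bins >= 3L) {
    ord <- order(abundance)
    bin <- cut(seq_len(g), breaks = n_bins, labels = FALSE)
    phi_bin <- ab_bin <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
      rows <- ord[bin == b]
      phi_bin[b] <- stats::optimize(apl_sum, bounds, rows = rows,
                                    maximum = TRUE, tol = 1e-3)$maximum
      ab_bin[b] <- mean(abundance[rows])
    }
    xo <- pmin(pmax(abundance, min(ab_bin)), max(ab_bin))
    trended <- exp(stats::spline(ab_bin, phi_bin, xout = xo,
                                 method = "natural")$y)
  } else {
    trended <- rep(common, g)
  }

  ## tagwise: weighted-likelihood shrinkage toward the trend
  if (is.infinite(prior_df)) {
    tagwise <- trended
  } else {
    deltas <- seq(grid_range[1], grid_range[2], length.out = grid_length)
    apl <- matrix(0, g, grid_length)
    for (k in seq_len(grid_length))
      apl[, k] <- cox_reid_apl(y, design, off, trended * 2^deltas[k])
    prior_n <- prior_df / df_resid
    score <- apl + matrix(prior_n * colMeans(apl), g, grid_length,
                          byrow = TRUE)
    tagwise <- trended * 2^interp_max(deltas, score)
  }
  list(common = common, trended = trended, tagwise = tagwise,
       abundance = abundance)
}

## Per-row quadratic-interpolated argmax of a score matrix over grid x.
interp_max <- function(x, score) {
  g <- nrow(score); n <- length(x)
  k <- max.col(score, ties.method = "first")
  inner <- k > 1L & k < n
  out <- x[k]
  if (any(inner)) {
    i <- which(inner)
    y0 <- score[cbind(i, k[i] - 1L)]
    y1 <- score[cbind(i, k[i])]
    y2 <- score[cbind(i, k[i] + 1L)]
    denom <- y0 - 2 * y1 + y2
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
    shift <- pmin(pmax(shift, -1), 1)
    h <- x[2] - x[1]
    out[i] <- x[k[i]] + shift * h
  }
  pmin(pmax(out, x[1]), x[n])
}

#' Likelihood-ratio test for one coefficient of the NB GLM
#'
#' Fits the full model and the model with the tested coefficient dropped,
#' at the same per-gene dispersions, and compares deviances against a
#' chi-squared distribution with one degree of freedom (two-sided).
#'
#' @param y count matrix, genes x samples.
#' @param design full design matrix.
#' @param offset log-scale offsets.
#' @param dispersion per-gene dispersions.
#' @param coef column name or index of the tested coefficient (default:
#'   last column).
#' @return data.frame with `log2_fold_effect` (tested coefficient in log2
#'   units), `lr_stat` and `p_value`. Genes whose full fit failed to
#'   converge get `NA` p-values.
#' @export
glm_lrt <- function(y, design, offset, dispersion, coef = ncol(design)) {
  design <- as.matrix(design)
  if (is.character(coef)) coef <- match(coef, colnames(design))
  stopifnot(!is.na(coef), coef >= 1, coef <= ncol(design))
  full <- nb_glm_fit(y, design, offset, dispersion)
  null <- nb_glm_fit(y, design[, -coef, drop = FALSE], offset, dispersion)
  stat <- pmax(null$deviance - full$deviance, 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  bad <- !full$converged
  if (any(bad)) {
    warning(sum(bad), " gene(s) did not converge; p-values set to NA")
    p[bad] <- NA_real_
  }
  data.frame(
    log2_fold_effect = full$coefficients[, coef] / log(2),
    lr_stat = stat, p_value = p,
    row.names = rownames(y)
  )
}
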
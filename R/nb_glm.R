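# Negative-binomial GLM machinery: log link, per-sample offsets, fixed
# dispersion phi (variance = mu + phi * mu^2). phi = 0 is the Poisson limit.

#' Negative binomial log-likelihood at fixed dispersion
#'
#' @param y counts
#' @param mu fitted means (> 0)
#' @param phi dispersion; `0` gives the Poisson log-likelihood
#' @return scalar log-likelihood
#' @keywords internal
#' @export
nb_loglik <- function(y, mu, phi) {
  if (phi < 1e-10) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Negative binomial deviance
#'
#' Twice the log-likelihood gap to the saturated model (`mu = y`),
#' with the `y log(y/mu)` term taken as 0 at `y = 0`.
#'
#' @inheritParams nb_loglik
#' @return scalar deviance, >= 0
#' @keywords internal
#' @export
nb_deviance <- function(y, mu, phi) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi < 1e-10) {
    d <- 2 * sum(t1 - (y - mu))
  } else {
    t2 <- (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu))
    d <- 2 * sum(t1 - t2)
  }
  max(d, 0)
}

#' Fit a negative-binomial GLM to one gene by IRLS
#'
#' Maximizes the NB log-likelihood in the coefficients at fixed dispersion
#' via iteratively reweighted least squares with step halving, so the
#' deviance is non-increasing across iterations. The model is
#' `log mu = offset + X beta`.
#'
#' @param y integer count vector (one gene across samples).
#' @param design full-rank design matrix, rows matching `y`.
#' @param offsets log effective library sizes (default 0).
#' @param dispersion NB dispersion phi >= 0.
#' @param tol convergence tolerance on the relative deviance change.
#' @param max_iter maximum IRLS iterations.
#' @param trace if TRUE, records the deviance path in `$deviance_path`.
#' @return a list of class `xdg_nbfit`: `beta`, `mu`, `dispersion`,
#'   `deviance`, `converged`, `all_zero`, `df_residual`.
#' @examples
#' y <- c(8, 12, 10, 37, 41, 44)
#' X <- cbind(1, rep(0:1, each = 3))
#' fit_nb_glm(y, X, dispersion = 0.1)$beta
#' @export
fit_nb_glm <- function(y, design, offsets = NULL, dispersion = 0,
                       tol = 1e-8, max_iter = 50, trace = FALSE) {
  design <- as.matrix(design)
  n <- length(y)
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite counts")
  if (any(y < 0)) stop("negative counts")
  if (nrow(design) != n) stop("design rows must match length(y)")
  if (is.null(offsets)) offsets <- rep(0, n)
  if (length(offsets) != n) stop("offsets must match length(y)")
  p <- ncol(design)
  if (qr(design)$rank < p) stop("design matrix is not full rank")
  phi <- dispersion
  if (all(y == 0)) {
    mu <- rep(1e-8, n)
    out <- list(beta = rep(NA_real_, p), mu = mu, dispersion = phi,
                deviance = 0, converged = TRUE, all_zero = TRUE,
                df_residual = n - p)
    class(out) <- "xdg_nbfit"
    return(out)
  }
  # start from a damped log-linear fit
  mu <- pmax(y, mean(y) / 8)
  z <- log(mu) - offsets
  beta <- qr.coef(qr(design), z)
  eta <- offsets + drop(design %*% beta)
  mu <- pmin(exp(eta), 1e12)
  dev <- nb_deviance(y, mu, phi)
  path <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offsets) + (y - mu) / mu
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(design * sw), z * sw)
    step <- beta_new - beta
    # step halving guarantees monotone deviance
    fac <- 1
    repeat {
      b <- beta + fac * step
      eta_new <- offsets + drop(design %*% b)
      mu_new <- pmin(exp(eta_new), 1e12)
      dev_new <- nb_deviance(y, mu_new, phi)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) { b <- beta; eta_new <- eta; mu_new <- mu; dev_new <- dev; break }
    }
    delta <- dev - dev_new
    beta <- b; eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (trace) path <- c(path, dev)
    if (delta >= 0 && delta < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
  }
  out <- list(beta = beta, mu = mu, dispersion = phi, deviance = dev,
              converged = converged, all_zero = FALSE, df_residual = n - p)
  if (trace) out$deviance_path <- path
  class(out) <- "xdg_nbfit"
  out
}

# Vectorized fit for cell-means designs (each row of the design selects
# exactly one level): the model separates by level, so each coefficient is
# a 1-d root found by damped Fisher scoring, simultaneously for all genes.
# Y: genes x samples; group: level index per sample; offsets per sample.
# Returns list(beta = genes x levels, mu = genes x samples).
#' @noRd
fit_cellmeans_matrix <- function(Y, group, offsets, phi, iter = 30, tol = 1e-10) {
  Y <- as.matrix(Y)
  ng <- nrow(Y); ns <- ncol(Y)
  levels_n <- max(group)
  eo <- exp(offsets)
  beta <- matrix(0, ng, levels_n)
  for (g in seq_len(levels_n)) {
    idx <- which(group == g)
    sy <- rowSums(Y[, idx, drop = FALSE])
    beta[, g] <- log(pmax(sy, 0.125) / sum(eo[idx]))  # Poisson start
  }
  if (phi >= 1e-10) {
    for (g in seq_len(levels_n)) {
      idx <- which(group == g)
      yg <- Y[, idx, drop = FALSE]
      eog <- eo[idx]
      b <- beta[, g]
      for (k in seq_len(iter)) {
        mu <- exp(b) %o% eog
        r <- 1 + phi * mu
        score <- rowSums((yg - mu) / r)
        info <- rowSums(mu / r)
        step <- score / pmax(info, 1e-12)
        step <- pmin(pmax(step, -2), 2)
        b <- b + step
        if (max(abs(step)) < tol) break
      }
      beta[, g] <- b
    }
  }
  mu <- exp(beta[, group, drop = FALSE] +
              matrix(offsets, ng, ns, byrow = TRUE))
  list(beta = beta, mu = mu)
}

#' Likelihood-ratio test of a single contrast on NB-GLM coefficients
#'
#' Fits the full model and the model constrained by `contrast' beta = 0`
#' (the design projected onto the null space of the contrast) at the same
#' fixed dispersion, and refers the deviance difference to chi-squared
#' with 1 degree of freedom.
#'
#' @inheritParams fit_nb_glm
#' @param contrast numeric vector, one entry per design column.
#' @param fit_full optional pre-computed full fit (from [fit_nb_glm()]).
#' @return list with `statistic`, `pvalue`, `log2fc` (the contrast value
#'   on the log2 scale) and the two fits.
#' @export
lrt_contrast <- function(y, design, contrast, offsets = NULL, dispersion = 0,
                         fit_full = NULL) {
  design <- as.matrix(design)
  p <- ncol(design)
  contrast <- as.numeric(contrast)
  if (length(contrast) != p) stop("contrast length must equal the number of coefficients")
  if (all(contrast == 0)) stop("contrast must be non-zero")
  if (qr(design)$rank < p) stop("design matrix is not full rank")
  if (is.null(offsets)) offsets <- rep(0, length(y))
  if (is.null(fit_full)) {
    fit_full <- fit_nb_glm(y, design, offsets, dispersion)
  }
  if (isTRUE(fit_full$all_zero)) {
    return(list(statistic = NA_real_, pvalue = NA_real_, log2fc = NA_real_,
                fit_full = fit_full, fit_reduced = NULL))
  }
  # null-space basis of the contrast: columns orthogonal to it
  Q <- qr.Q(qr(matrix(contrast, ncol = 1)), complete = TRUE)
  B <- Q[, -1, drop = FALSE]
  fit_red <- fit_nb_glm(y, design %*% B, offsets, dispersion)
  stat <- max(fit_red$deviance - fit_full$deviance, 0)
  list(statistic = stat,
       pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       log2fc = sum(contrast * fit_full$beta) / log(2),
       fit_full = fit_full, fit_reduced = fit_red)
}
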
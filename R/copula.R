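#' Latent Pearson correlation for a Gaussian copula Spearman target
#'
#' For continuous marginals coupled through a Gaussian copula, a latent
#' Pearson correlation `rho` induces the Spearman rank correlation
#' `r_s = (6/pi) asin(rho/2)`; inverting gives
#' `rho = 2 sin(pi r_s / 6)`. Applied elementwise to a matrix, with a
#' nearest positive-semidefinite repair if the transformed matrix loses
#' PSD-ness (repair is reported via a message).
#'
#' @param r_s Spearman correlation, scalar or symmetric matrix with unit
#'   diagonal; entries in \[-1, 1\].
#' @return Latent Pearson correlation of the same shape.
#' @export
calibrate_copula <- function(r_s) {
  if (any(abs(r_s) > 1)) kd_validation_error("|r_s| must be <= 1")
  rho <- 2 * sin(pi * r_s / 6)
  if (is.matrix(rho)) {
    diag(rho) <- 1
    rho <- ensure_psd(rho)
  }
  rho
}

# clip negative eigenvalues and restore the unit diagonal
ensure_psd <- function(m, eps = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 0) return(m)
  message("correlation matrix not PSD; applying nearest-PSD repair")
  v <- pmax(e$values, eps)
  r <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  (r + t(r)) / 2
}

# bivariate standard normal CDF P(X <= h, Y <= k), correlation r,
# by 1D quadrature of the conditional probability
pbinorm <- function(h, k, r) {
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
    if (h == Inf) return(stats::pnorm(k))
    if (k == Inf) return(stats::pnorm(h))
  }
  if (r >= 1 - 1e-12) return(stats::pnorm(min(h, k)))
  if (r <= -1 + 1e-12) return(max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  s <- sqrt(1 - r^2)
  stats::integrate(function(u) stats::dnorm(u) * stats::pnorm((k - r * u) / s),
                   -Inf, h, rel.tol = 1e-9)$value
}

#' Population pooled Spearman correlation of a two-group Gaussian pair
#'
#' The pooled-sample (grade) Spearman correlation of two variables whose
#' joint distribution is a two-component mixture of bivariate normals
#' sharing latent correlation `rho` but with group-specific means and
#' SDs: `r_s = 12 E[F(X) G(Y)] - 3` with `F`, `G` the pooled marginal
#' CDFs. Pooling groups with different means changes the rank
#' correlation relative to the within-group value — this function is the
#' forward model that [calibrate_pooled_copula()] inverts.
#'
#' @param rho latent within-group Pearson correlation.
#' @param mean_x,sd_x,mean_y,sd_y length-2 vectors of group marginals
#'   (group order must match `weights`).
#' @param weights group mixing proportions (summing to 1).
#' @return The population pooled Spearman correlation.
#' @export
pooled_spearman_mixture <- function(rho, mean_x, sd_x, mean_y, sd_y, weights) {
  stopifnot(length(mean_x) == 2, length(weights) == 2)
  efg <- 0
  for (g in 1:2) for (a in 1:2) for (b in 1:2) {
    c1 <- (mean_x[g] - mean_x[a]) / sd_x[a]; d1 <- sd_x[g] / sd_x[a]
    c2 <- (mean_y[g] - mean_y[b]) / sd_y[b]; d2 <- sd_y[g] / sd_y[b]
    efg <- efg + weights[g] * weights[a] * weights[b] *
      pbinorm(c1 / sqrt(1 + d1^2), c2 / sqrt(1 + d2^2),
              rho * d1 * d2 / sqrt((1 + d1^2) * (1 + d2^2)))
  }
  12 * efg - 3
}

#' Calibrate the latent correlation matrix to pooled Spearman targets
#'
#' Published correlation tables from two-group studies report the
#' pooled-sample Spearman correlation, which mixes the within-group
#' dependence with the between-group mean separation. For each variable
#' pair this routine finds, by root bisection on
#' [pooled_spearman_mixture()], the common within-group latent Pearson
#' correlation whose pooled population Spearman equals the target. An
#' unattainable target (outside the range spanned by latent correlation
#' -1..1) is clamped to the nearest boundary with a warning. The
#' assembled matrix gets a nearest-PSD repair if needed.
#'
#' @param target symmetric matrix of pooled Spearman targets, with
#'   dimnames naming the variables.
#' @param means,sds matrices (2 rows = groups, columns = variables, in
#'   `target`'s variable order) of group marginals.
#' @param weights group mixing proportions.
#' @param tol bisection tolerance on the latent correlation.
#' @return Latent Pearson correlation matrix (unit diagonal, PSD).
#' @export
calibrate_pooled_copula <- function(target, means, sds, weights, tol = 1e-5) {
  k <- ncol(target)
  rho <- diag(1, k)
  dimnames(rho) <- dimnames(target)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- function(r) pooled_spearman_mixture(r, means[, i], sds[, i],
                                             means[, j], sds[, j], weights) -
      target[i, j]
    lo <- f(-0.999); hi <- f(0.999)
    if (lo > 0 || hi < 0) {
      warning(sprintf(
        "pooled Spearman target %.3f for (%s, %s) unattainable; clamped",
        target[i, j], colnames(target)[i], colnames(target)[j]))
      rho[i, j] <- rho[j, i] <- if (lo > 0) -0.999 else 0.999
    } else {
      rho[i, j] <- rho[j, i] <- stats::uniroot(f, c(-0.999, 0.999), tol = tol)$root
    }
  }
  ensure_psd(rho)
}
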
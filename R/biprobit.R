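# Bivariate probit with an endogenous binary regressor, the ML machinery
# behind the instrumented (IV) probit used for the complier average causal
# effect.  Written against vectorized primitives because the person-period
# likelihood is evaluated on 1e5+ rows per iteration.

#' Standard bivariate normal CDF, vectorized in the margins
#'
#' \eqn{P(X \le h, Y \le k)} for standard bivariate normal with correlation
#' \code{rho} (a scalar).  Uses the Drezner-Wesolowsky identity
#' \eqn{\Phi_2(h,k,\rho) = \Phi(h)\Phi(k) + \int_0^\rho \phi_2(h,k,r)\,dr}
#' with fixed-order Gauss-Legendre quadrature in \eqn{r}, which is smooth on
#' \eqn{[0,\rho]} for \eqn{|\rho| \le 0.99}.
#'
#' @param h,k Numeric vectors (recycled to common length).
#' @param rho Scalar correlation in (-1, 1).
#' @param nodes Quadrature order; by default chosen from \code{|rho|} (the
#'   integrand sharpens as \code{|rho|} approaches 1).
#' @return Numeric vector of probabilities.
#' @export
pbinorm <- function(h, k, rho, nodes = NULL) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n); k <- rep_len(k, n)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  if (abs(rho) >= 1) stop("rho must lie strictly inside (-1, 1)")
  if (is.null(nodes)) {
    nodes <- if (abs(rho) <= 0.85) 12 else if (abs(rho) <= 0.95) 32 else 64
  }
  gl <- gauss_legendre(nodes)
  r <- rho / 2 * (gl$x + 1)           # map [-1,1] -> [0, rho]
  w <- gl$w * rho / 2
  acc <- 0
  for (j in seq_along(r)) {
    acc <- acc + w[j] * dbinorm(h, k, r[j])
  }
  pmin(pmax(base + acc, 1e-300), 1)
}

clamp_rho <- function(r) max(min(r, 0.999), -0.999)

# standard bivariate normal density at correlation r (scalar r)
dbinorm <- function(h, k, r) {
  om <- 1 - r^2
  exp(-(h^2 - 2 * r * h * k + k^2) / (2 * om)) / (2 * pi * sqrt(om))
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method (symmetric tridiagonal Jacobi matrix).
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

# Negative log-likelihood and analytic score of the recursive bivariate
# probit system
#   y*  = X1 %*% beta1 + u      (outcome equation; X1 contains the
#                                endogenous treatment column)
#   a*  = X2 %*% beta2 + v      (treatment equation; X2 contains the
#                                excluded instrument)
#   (u, v) ~ BVN(0, 0, 1, 1, rho),   rho = tanh(theta).
# Using q1 = 2y-1, q2 = 2a-1 the cell probability is
# Phi2(q1 eta1, q2 eta2, q1 q2 rho).
biprobit_nll <- function(par, y, a, X1, X2, wt = NULL) {
  if (is.null(wt)) wt <- rep(1, length(y))
  k1 <- ncol(X1)
  eta1 <- drop(X1 %*% par[seq_len(k1)])
  eta2 <- drop(X2 %*% par[k1 + seq_len(ncol(X2))])
  rho <- clamp_rho(tanh(par[length(par)]))
  q1 <- 2 * y - 1; q2 <- 2 * a - 1
  # rho enters with sign q1*q2, which is +/-; split the rows by sign so the
  # scalar-rho quadrature applies
  s <- q1 * q2
  p <- numeric(length(y))
  for (sg in c(-1, 1)) {
    m <- s == sg
    if (any(m)) p[m] <- pbinorm(q1[m] * eta1[m], q2[m] * eta2[m], sg * rho)
  }
  -sum(wt * log(p))
}

biprobit_score <- function(par, y, a, X1, X2, wt = NULL, by_row = FALSE) {
  if (is.null(wt)) wt <- rep(1, length(y))
  k1 <- ncol(X1); k2 <- ncol(X2)
  eta1 <- drop(X1 %*% par[seq_len(k1)])
  eta2 <- drop(X2 %*% par[k1 + seq_len(k2)])
  theta <- par[length(par)]
  rho <- clamp_rho(tanh(theta))
  q1 <- 2 * y - 1; q2 <- 2 * a - 1
  w1 <- q1 * eta1; w2 <- q2 * eta2
  s <- q1 * q2
  p <- g1 <- g2 <- gr <- numeric(length(y))
  for (sg in c(-1, 1)) {
    m <- s == sg
    if (!any(m)) next
    r <- sg * rho
    om <- sqrt(1 - r^2)
    pm <- pbinorm(w1[m], w2[m], r)
    p[m] <- pm
    # d log Phi2 / d w1 = phi(w1) Phi((w2 - r w1)/om) / Phi2, etc.
    g1[m] <- stats::dnorm(w1[m]) * stats::pnorm((w2[m] - r * w1[m]) / om) / pm
    g2[m] <- stats::dnorm(w2[m]) * stats::pnorm((w1[m] - r * w2[m]) / om) / pm
    gr[m] <- sg * dbinorm(w1[m], w2[m], r) / pm
  }
  drho_dtheta <- 1 - rho^2
  if (by_row) {
    cbind(X1 * (wt * q1 * g1), X2 * (wt * q2 * g2), wt * gr * drho_dtheta)
  } else {
    -c(crossprod(X1, wt * q1 * g1), crossprod(X2, wt * q2 * g2),
       sum(wt * gr) * drho_dtheta)
  }
}

# Fit the system from single-equation probit starts: a short BFGS pass
# locates the basin, then damped BHHH (Gauss-Newton on the outer product
# of scores, which approximates the information matrix at the optimum)
# polishes to high precision with the analytic score.  Standard errors are
# BHHH.  Falls back to two-stage residual inclusion if the ML path fails.
fit_biprobit <- function(y, a, X1, X2, wt = NULL, maxit = 200) {
  k1 <- ncol(X1); k2 <- ncol(X2)
  if (is.null(wt)) wt <- rep(1, length(y))
  # scale columns to unit sd (binary/intercept columns untouched) so the
  # optimizer sees a well-conditioned surface; mapped back below
  col_scale <- function(X) {
    s <- apply(X, 2, stats::sd)
    s[s == 0 | s < 1e-12] <- 1
    binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
    s[binary] <- 1
    s
  }
  s1 <- col_scale(X1); s2 <- col_scale(X2)
  X1s <- sweep(X1, 2, s1, "/"); X2s <- sweep(X2, 2, s2, "/")
  sw <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  g1 <- sw(stats::glm.fit(X1s, y, family = stats::binomial("probit"),
                          weights = wt))
  g2 <- sw(stats::glm.fit(X2s, a, family = stats::binomial("probit"),
                          weights = wt))
  start <- c(g1$coefficients, g2$coefficients, atanh(0.01))
  start[!is.finite(start)] <- 0
  fit <- try(stats::optim(start, biprobit_nll, biprobit_score,
                          y = y, a = a, X1 = X1s, X2 = X2s, wt = wt,
                          method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-6)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(list(converged = FALSE))
  par <- fit$par
  nll <- fit$value
  # gradient thresholds scaled to the effective sample size (the score of
  # a summed log-likelihood grows like sqrt(n) away from the optimum)
  g_break <- 1e-6 * sqrt(sum(wt))
  g_accept <- 1e-3 * sqrt(sum(wt))
  # damped BHHH polish with backtracking line search
  for (it in seq_len(40)) {
    g <- biprobit_score(par, y, a, X1s, X2s, wt = wt)
    if (max(abs(g)) < g_break) break
    sc <- biprobit_score(par, y, a, X1s, X2s, wt = sqrt(wt), by_row = TRUE)
    step <- try(solve(crossprod(sc), -g), silent = TRUE)
    if (inherits(step, "try-error")) break
    lam <- 1
    improved <- FALSE
    while (lam >= 1e-4) {
      cand <- par + lam * step
      nll_c <- biprobit_nll(cand, y, a, X1s, X2s, wt = wt)
      if (is.finite(nll_c) && nll_c < nll) {
        improved <- nll - nll_c > 1e-10 * (1 + abs(nll))
        par <- cand
        nll <- nll_c
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  g <- biprobit_score(par, y, a, X1s, X2s, wt = wt)
  if (max(abs(g)) > g_accept) {
    return(list(converged = FALSE))
  }
  sc <- biprobit_score(par, y, a, X1s, X2s, wt = sqrt(wt), by_row = TRUE)
  vc <- try(solve(crossprod(sc)), silent = TRUE)
  if (inherits(vc, "try-error")) return(list(converged = FALSE))
  # undo the column scaling
  sc_all <- c(s1, s2, 1)
  par <- par / sc_all
  vc <- vc / tcrossprod(sc_all)
  nm <- c(paste0("y:", colnames(X1)), paste0("a:", colnames(X2)), "atanh_rho")
  names(par) <- nm
  dimnames(vc) <- list(nm, nm)
  list(converged = TRUE, par = par, vcov = vc, rho = tanh(par[length(par)]),
       logLik = -nll, k1 = k1, k2 = k2)
}

# Two-stage residual inclusion fallback: probit first stage for the
# treatment, then a probit outcome model including the first-stage
# generalized residual as a control function.
fit_2sri <- function(y, a, X1, X2) {
  sw <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  fs <- sw(stats::glm.fit(X2, a, family = stats::binomial("probit")))
  eta <- drop(X2 %*% fs$coefficients)
  gres <- ifelse(a == 1, stats::dnorm(eta) / pmax(stats::pnorm(eta), 1e-10),
                 -stats::dnorm(eta) / pmax(1 - stats::pnorm(eta), 1e-10))
  X1r <- cbind(X1, gres = gres)
  out <- sw(stats::glm.fit(X1r, y, family = stats::binomial("probit")))
  # model-based covariance from the weighted cross-product (naive: ignores
  # first-stage estimation error; this path is a fallback, and is tagged)
  w <- out$weights
  vc <- try(solve(crossprod(X1r * sqrt(w))), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- NULL
  list(converged = TRUE, coefficients = out$coefficients, vcov = vc)
}
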
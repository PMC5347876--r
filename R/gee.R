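# Generalized estimating equations for correlated binary person-months.
#
# Month-level in-care indicators from the same patient are correlated, so a
# marginal logistic model is fitted by GEE (Liang & Zeger moment approach)
# with an exchangeable working correlation and a robust sandwich variance.
# The moment estimators use Pearson residuals; the sandwich estimator is
# consistent even when the working correlation is wrong.

#' Fit a marginal logistic model by generalized estimating equations
#'
#' @param formula Model formula with a binary (0/1 or logical) response.
#' @param id Cluster identifier vector (one entry per row of `data`), or a
#'   bare column name in `data`.
#' @param data Data frame.
#' @param corstr Working correlation structure: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param maxit,tol Fisher-scoring iteration cap and convergence tolerance on
#'   the max absolute coefficient change.
#' @return Object of class `eic_gee` with elements `coefficients`, `vcov`
#'   (robust), `vcov_naive`, `alpha` (working correlation), `converged`,
#'   `n_obs`, `n_clusters`, `formula`.
#' @export
gee_logit <- function(formula, id, data, corstr = c("exchangeable",
                                                    "independence"),
                      maxit = 50, tol = 1e-8) {
  corstr <- match.arg(corstr)
  id_quo <- substitute(id)
  if (is.name(id_quo) && as.character(id_quo) %in% names(data)) {
    id <- data[[as.character(id_quo)]]
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  if (!is.null(dropped)) id <- id[-dropped]
  X <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) {
    stop("response must be binary (0/1)", call. = FALSE)
  }
  if (length(id) != nrow(X)) {
    stop("cluster id length does not match the model frame", call. = FALSE)
  }
  p <- ncol(X)
  cl <- split(seq_along(y), as.character(id))
  n_clusters <- length(cl)
  if (n_clusters < 2L) {
    stop("GEE needs at least two clusters", call. = FALSE)
  }

  beta <- tryCatch(
    suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, p))
  if (any(!is.finite(beta))) beta <- rep(0, p)

  alpha <- 0
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) {
      stop("fitted probabilities numerically 0 or 1: possible separation",
           call. = FALSE)
    }
    e <- (y - mu) / sqrt(w)                       # Pearson residuals

    if (corstr == "exchangeable") {
      phi <- sum(e^2) / (length(y) - p)
      num <- 0; npairs <- 0
      for (idx in cl) {
        ni <- length(idx)
        if (ni > 1L) {
          s <- sum(e[idx])
          num <- num + (s^2 - sum(e[idx]^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (npairs > p) num / (phi * (npairs - p)) else 0
      alpha <- max(min(alpha, 0.95), 0)
    }

    # scoring update: beta + (sum_i D'V^{-1}D)^{-1} sum_i D'V^{-1}(y - mu)
    H <- matrix(0, p, p)
    g <- numeric(p)
    for (idx in cl) {
      ni <- length(idx)
      Xi <- X[idx, , drop = FALSE]
      wi <- w[idx]
      ri <- y[idx] - mu[idx]
      # D_i = A_i X_i with A_i = diag(w);  V_i = A^{1/2} R A^{1/2}
      # so D'V^{-1} = X' A^{1/2} R^{-1} A^{-1/2} (= X' when R = I)
      DtVinv <- gee_dtvinv(Xi, wi, alpha, corstr)
      H <- H + DtVinv %*% (Xi * wi)
      g <- g + drop(DtVinv %*% ri)
    }
    Hinv <- tryCatch(solve(H), error = function(e)
      stop("singular estimating-equation information: model not identifiable",
           call. = FALSE))
    step <- drop(Hinv %*% g)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("GEE did not converge in ", maxit, " iterations", call. = FALSE)
  }

  # sandwich: bread %*% meat %*% bread with cluster-level score outer products
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  H <- matrix(0, p, p)
  meat <- matrix(0, p, p)
  for (idx in cl) {
    ni <- length(idx)
    Xi <- X[idx, , drop = FALSE]
    wi <- w[idx]
    ri <- y[idx] - mu[idx]
    DtVinv <- gee_dtvinv(Xi, wi, alpha, corstr)
    H <- H + DtVinv %*% (Xi * wi)
    si <- drop(DtVinv %*% ri)
    meat <- meat + si %o% si
  }
  bread <- solve(H)
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- list(colnames(X), colnames(X))

  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         vcov = vc, vcov_naive = bread, alpha = alpha,
         converged = converged, n_obs = length(y), n_clusters = n_clusters,
         corstr = corstr, formula = formula),
    class = "eic_gee")
}

# Internal: D_i' V_i^{-1} for one cluster under the exchangeable working
# correlation, using R^{-1} = (I - alpha/(1+(n-1)alpha) J) / (1 - alpha).
gee_dtvinv <- function(Xi, wi, alpha, corstr) {
  ni <- length(wi)
  if (corstr == "independence" || ni == 1L || alpha == 0) {
    return(t(Xi))
  }
  a2 <- alpha / (1 + (ni - 1) * alpha)
  sw <- sqrt(wi)
  B <- t(Xi * sw)                                 # p x ni, X' A^{1/2}
  Rinv_t <- (B - a2 * rowSums(B)) / (1 - alpha)   # X' A^{1/2} R^{-1}
  t(t(Rinv_t) / sw)
}

#' @export
coef.eic_gee <- function(object, ...) object$coefficients

#' @export
vcov.eic_gee <- function(object, ...) object$vcov

#' @export
print.eic_gee <- function(x, ...) {
  cat(sprintf(
    "<eic_gee> logistic GEE, %s working correlation (alpha = %.3f)\n",
    x$corstr, x$alpha))
  cat(sprintf("  %d observations in %d clusters\n", x$n_obs, x$n_clusters))
  se <- sqrt(diag(x$vcov))
  est <- x$coefficients
  z <- est / se
  tab <- data.frame(estimate = est, robust_se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, 4))
  invisible(x)
}

#' Tidy coefficient table for a GEE fit
#'
#' @param fit An `eic_gee` object.
#' @param conf_level Confidence level for Wald intervals. Default 0.95.
#' @return Tibble with term, log-odds estimate, robust SE, odds ratio,
#'   confidence bounds and p-value.
#' @export
gee_tidy <- function(fit, conf_level = 0.95) {
  se <- sqrt(diag(fit$vcov))
  est <- fit$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    robust_se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est - zq * se)),
    ci_high = exp(unname(est + zq * se)),
    p = 2 * stats::pnorm(-abs(unname(est) / unname(se))))
}
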
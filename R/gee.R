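# Generalized estimating equations for marginal (population-averaged)
# logistic and Poisson regression with an exchangeable working correlation
# within patients and robust (sandwich) covariance. Implemented directly:
# Fisher scoring on the estimating equations, the Liang-Zeger moment
# estimator for the common intra-cluster correlation, and the closed-form
# inverse of the exchangeable working correlation, so each iteration is a
# couple of cluster-wise matrix cross-products.

#' Fit a marginal regression model by GEE
#'
#' Solves the generalized estimating equations
#' \eqn{\sum_i D_i' V_i^{-1} (y_i - \mu_i) = 0} under an exchangeable
#' working correlation (a single correlation \eqn{\alpha} shared by all
#' within-cluster pairs, re-estimated by moments at each scoring step) for
#' the binomial-logit or Poisson-log family. Standard errors are robust
#' sandwich estimates; the scale \eqn{\phi} is estimated from Pearson
#' residuals, so the Poisson family is a quasi-likelihood contract valid
#' for non-integer outcomes such as fractional hospital days. With one
#' observation per cluster (or `corstr = "independence"`) the solution
#' coincides with ordinary maximum-likelihood GLM estimation.
#'
#' @param formula model formula.
#' @param data data.frame with the model variables.
#' @param id cluster identifier: a column name in `data` or a vector.
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param corstr `"exchangeable"` (default) or `"independence"`.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (default 1e-6).
#' @param max_iter scoring iteration cap (default 100).
#' @return object of class `qtcds_gee`: coefficients, `robust_se`,
#'   `naive_se`, `vcov_robust`, 95% CIs on the link scale, `exponentiated`
#'   estimates (OR or IRR) with CIs, `alpha`, `phi`, convergence flags,
#'   and the pieces needed for margins.
#' @export
gee_fit <- function(formula, data, id, family = c("binomial", "poisson"),
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-6, max_iter = 100L) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  data <- as.data.frame(data)
  if (is.character(id) && length(id) == 1) {
    stopifnot(id %in% names(data))
    idv <- data[[id]]
  } else {
    stopifnot(length(id) == nrow(data))
    idv <- id
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  omit <- attr(mf, "na.action")
  if (!is.null(omit)) idv <- idv[-omit]
  y <- stats::model.response(mf)
  if (is.logical(y) || is.factor(y)) y <- as.numeric(y) - is.factor(y) * 1
  y <- as.numeric(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    kept <- sort(qrX$pivot[seq_len(qrX$rank)])
    warning("dropping aliased column(s): ",
            paste(colnames(X)[-kept], collapse = ", "), call. = FALSE)
    X <- X[, kept, drop = FALSE]
  }
  n <- length(y); p <- ncol(X)
  if (family == "binomial" && any(y < 0 | y > 1))
    stop("binomial outcome must lie in [0, 1]", call. = FALSE)
  if (family == "poisson" && any(y < 0))
    stop("poisson outcome must be non-negative", call. = FALSE)

  cl <- factor(idv, levels = unique(idv))
  n_i <- tabulate(cl)
  nclus <- length(n_i)

  linkinv <- if (family == "binomial") stats::plogis else exp
  varfun <- if (family == "binomial") function(m) m * (1 - m) else identity

  # independence start values
  # quasi-families: identical scores, but no density evaluation, so
  # fractional Poisson outcomes (hospital days) start cleanly
  beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = if (family == "binomial")
      stats::quasibinomial() else stats::quasipoisson())$coefficients),
    error = function(e) rep(0, p))
  beta[is.na(beta)] <- 0

  alpha <- 0; phi <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    v <- pmax(varfun(mu), 1e-12)
    s <- sqrt(v)
    e <- (y - mu) / s                       # Pearson residuals
    phi <- sum(e^2) / max(n - p, 1)
    if (corstr == "exchangeable") {
      ge <- rowsum(e, cl)                   # per-cluster residual sums
      se2 <- rowsum(e^2, cl)
      pair_sum <- sum((ge^2 - se2) / 2)
      n_pairs <- sum(n_i * (n_i - 1) / 2)
      alpha <- if (n_pairs > p) pair_sum / (phi * (n_pairs - p)) else 0
      amin <- -1 / max(max(n_i) - 1, 1) + 1e-6
      alpha <- min(max(alpha, amin), 0.99)
    }
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / (1 - alpha + n_i * alpha)   # per cluster
    Z <- X * s
    S <- rowsum(Z, cl)                        # cluster colsums of Z
    g <- drop(rowsum(e, cl))
    M <- c1 * (crossprod(Z) - t(S) %*% (S * c2))
    U <- c1 * (drop(crossprod(Z, e)) - drop(t(S) %*% (c2 * g)))
    step <- tryCatch(solve(M, U), error = function(e2)
      drop(qr.solve(M, U, tol = 1e-12)))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GEE did not converge in ", max_iter, " iterations ",
            "(max step ", signif(max(abs(step)), 3), ")", call. = FALSE)
  if (max(abs(X %*% beta)) > 30)
    warning("extreme linear predictor: possible separation", call. = FALSE)

  # final quantities and sandwich covariance
  eta <- drop(X %*% beta)
  mu <- linkinv(eta)
  v <- pmax(varfun(mu), 1e-12)
  s <- sqrt(v)
  e <- (y - mu) / s
  c1 <- 1 / (1 - alpha)
  c2 <- alpha / (1 - alpha + n_i * alpha)
  Z <- X * s
  S <- rowsum(Z, cl)
  g <- drop(rowsum(e, cl))
  M <- c1 * (crossprod(Z) - t(S) %*% (S * c2))
  Zte <- rowsum(Z * e, cl)                  # cluster-wise Z'e rows
  Umat <- c1 * (Zte - (c2 * g) * S)
  Minv <- tryCatch(solve(M), error = function(e2) pseudo_inverse(M))
  vcov_robust <- Minv %*% crossprod(Umat) %*% Minv
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))
  robust_se <- sqrt(pmax(diag(vcov_robust), 0))
  naive_se <- sqrt(pmax(diag(phi * Minv), 0))

  est <- stats::setNames(drop(beta), colnames(X))
  ci_lo <- est - 1.96 * robust_se
  ci_hi <- est + 1.96 * robust_se
  fit <- list(
    coefficients = est, robust_se = robust_se, naive_se = naive_se,
    vcov_robust = vcov_robust,
    ci95 = cbind(lower = ci_lo, upper = ci_hi),
    exponentiated = cbind(estimate = exp(est), lower = exp(ci_lo),
                          upper = exp(ci_hi)),
    alpha = alpha, phi = phi, converged = converged, n_iter = iter,
    n_obs = n, n_clusters = nclus, family = family, corstr = corstr,
    formula = formula, terms = attr(mf, "terms"),
    model_frame = mf, cluster = cl)
  class(fit) <- "qtcds_gee"
  fit
}

pseudo_inverse <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' @export
print.qtcds_gee <- function(x, ...) {
  cat("Marginal ", x$family, " GEE (", x$corstr, "), ",
      x$n_obs, " obs in ", x$n_clusters, " clusters\n", sep = "")
  cat("alpha =", signif(x$alpha, 4), " phi =", signif(x$phi, 4),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    exp = exp(x$coefficients),
                    lower = x$exponentiated[, "lower"],
                    upper = x$exponentiated[, "upper"],
                    z = x$coefficients / x$robust_se)
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.qtcds_gee <- function(object, ...) object$coefficients

#' @export
vcov.qtcds_gee <- function(object, ...) object$vcov_robust

#' Joint Wald test on a group of coefficients
#'
#' Computes \eqn{\beta_g' V_g^{-1} \beta_g} with the robust covariance. A
#' singular covariance block is inverted by generalized inverse and the
#' rank is reported as the degrees of freedom.
#'
#' @param fit a [gee_fit()] result.
#' @param terms character vector of coefficient names, or a single regular
#'   expression (used when no exact match).
#' @return list with `statistic`, `df` (rank), `p_value`, `terms`.
#' @export
wald_joint_test <- function(fit, terms) {
  stopifnot(inherits(fit, "qtcds_gee"))
  nm <- names(fit$coefficients)
  sel <- if (all(terms %in% nm)) terms else grep(terms[1], nm, value = TRUE)
  if (!length(sel)) stop("no coefficients match", call. = FALSE)
  b <- fit$coefficients[sel]
  V <- fit$vcov_robust[sel, sel, drop = FALSE]
  rk <- qr(V)$rank
  Vi <- if (rk < length(sel)) pseudo_inverse(V) else solve(V)
  stat <- drop(t(b) %*% Vi %*% b)
  list(statistic = stat, df = rk,
       p_value = stats::pchisq(stat, rk, lower.tail = FALSE),
       terms = sel, rank_deficient = rk < length(sel))
}

#' Predictive margins by marginal standardization
#'
#' Imposes a covariate condition on every observation of the fitting data,
#' averages the predicted response over the observed covariate
#' distribution, and reports a delta-method standard error.
#'
#' @param fit a [gee_fit()] result.
#' @param condition named list of covariate values to impose (e.g.
#'   `list(alert_fired = TRUE)`); empty for the overall mean response.
#' @return list with `margin` (probability or rate) and `se`.
#' @export
predict_margins <- function(fit, condition = list()) {
  stopifnot(inherits(fit, "qtcds_gee"))
  mf <- fit$model_frame
  for (nm in names(condition)) {
    if (!nm %in% names(mf))
      stop("condition references unknown covariate: ", nm, call. = FALSE)
    val <- condition[[nm]]
    if (is.factor(mf[[nm]]))
      mf[[nm]] <- factor(rep(val, nrow(mf)), levels = levels(mf[[nm]]))
    else mf[[nm]] <- rep(val, nrow(mf))
  }
  X <- stats::model.matrix(fit$terms, mf)
  eta <- drop(X %*% fit$coefficients)
  if (fit$family == "binomial") {
    mu <- stats::plogis(eta); dmu <- mu * (1 - mu)
  } else {
    mu <- exp(eta); dmu <- mu
  }
  grad <- drop(crossprod(X, dmu)) / nrow(X)
  se <- sqrt(drop(t(grad) %*% fit$vcov_robust %*% grad))
  list(margin = mean(mu), se = se)
}
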
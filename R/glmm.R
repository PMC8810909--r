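#' Binomial random-intercept mixed model via the Laplace approximation
#'
#' Fits a logistic regression with a single Gaussian random intercept
#' per cluster (here, per city): for observation i in cluster j,
#' \deqn{y_i ~ Bernoulli(p_i), logit(p_i) = x_i' beta + u_j,
#'   u_j ~ N(0, sigma^2).}
#' The marginal likelihood is approximated by the Laplace method. For a
#' candidate sigma, the inner step maximizes the joint penalized
#' log-likelihood over (beta, u) by penalized IRLS, solving the blocked
#' normal equations exactly with a Schur complement on the cluster
#' block (the random-effect crossproduct is diagonal for a single
#' intercept). The outer step maximizes the profiled Laplace objective
#' over log(sigma) in one dimension. Standard errors for beta come from
#' the inverse of the Schur-complement information at the optimum,
#' conditional on the estimated sigma.
#'
#' @param formula model formula for the fixed effects, with a binary
#'   response (0/1)
#' @param data data.frame holding the response, predictors, and the
#'   cluster column
#' @param cluster name of the cluster column in `data` (character), or
#'   a factor of length `nrow(data)`
#' @param sigma if `NULL` (default) the random-intercept SD is
#'   estimated; a fixed numeric value (e.g. 0) fits with sigma held
#'   there, giving the plain GLM in the limit `sigma = 0`
#' @param tol relative tolerance on the objective for both loops
#' @param max_iter maximum outer iterations
#' @return an object of class `glmm_fit`; see Details
#'
#' @details The returned object carries `beta` (named), `se`, `vcov`,
#' `sigma` (random-intercept SD), `u` (per-cluster conditional modes),
#' `loglik` (Laplace marginal log-likelihood), `fitted` (conditional
#' probabilities), `converged`, `n_iter`, `sigma_collapsed` (TRUE when
#' the sigma estimate hit the lower boundary), the model frame pieces
#' needed by `predict`, and `scaling` (standardization statistics, when
#' fitted through [fit_melanism_model()]).
#' @seealso [wald_tests()], [predict_cline()], [binned_residuals()],
#'   [rac_refit()]
#' @export
fit_glmm <- function(formula, data, cluster, sigma = NULL,
                     tol = 1e-8, max_iter = 200L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- if (is.character(cluster) && length(cluster) == 1L) {
    factor(data[[cluster]])
  } else factor(cluster)
  if (length(g) != nrow(X)) stop("cluster length does not match data")
  if (nlevels(g) < 2L && is.null(sigma))
    stop("need >= 2 clusters to estimate the random-intercept SD")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  p <- ncol(X); J <- nlevels(g); n <- nrow(X)
  gi <- as.integer(g)

  # penalized IRLS for fixed sigma; returns mode, objective pieces
  inner <- function(sig, beta0 = NULL, u0 = NULL) {
    beta <- if (is.null(beta0)) c(stats::qlogis(pmin(pmax(mean(y), 1e-3),
                                                     1 - 1e-3)),
                                  rep(0, p - 1L)) else beta0
    u <- if (is.null(u0)) rep(0, J) else u0
    pen_loglik <- function(beta, u) {
      eta <- drop(X %*% beta) + u[gi]
      ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
      ll - if (sig > 0) sum(u^2) / (2 * sig^2) else 0
    }
    pen_ll <- pen_loglik(beta, u)
    M <- NULL
    for (it in 1:100) {
      eta <- drop(X %*% beta) + u[gi]
      pr <- stats::plogis(eta)
      w <- pmax(pr * (1 - pr), 1e-10)
      z <- eta + (y - pr) / w
      if (sig > 0) {
        A <- rowsum(w * X, gi)                      # J x p
        s <- rowsum(w, gi)[, 1L]                    # cluster weight sums
        b <- rowsum(w * z, gi)[, 1L]
        Dinv <- 1 / (s + 1 / sig^2)
        XtWX <- crossprod(X, w * X)
        XtWz <- crossprod(X, w * z)
        M <- XtWX - crossprod(A, Dinv * A)
        rhs <- XtWz - crossprod(A, Dinv * b)
        beta_new <- drop(solve(M, rhs))
        u_new <- Dinv * (b - drop(A %*% beta_new))
      } else {
        XtWX <- crossprod(X, w * X)
        beta_new <- drop(solve(XtWX, crossprod(X, w * z)))
        u_new <- rep(0, J)
        M <- XtWX
      }
      # step halving: the IRLS proposal must not decrease the
      # penalized log-likelihood (guards quasi-separated fits)
      prop_beta <- beta_new; prop_u <- u_new
      step <- 1
      pen_new <- pen_loglik(beta_new, u_new)
      while (!is.finite(pen_new) || pen_new < pen_ll - 1e-10) {
        step <- step / 2
        if (step < 1e-8) {
          beta_new <- beta; u_new <- u; pen_new <- pen_ll
          break
        }
        beta_new <- beta + step * (prop_beta - beta)
        u_new <- u + step * (prop_u - u)
        pen_new <- pen_loglik(beta_new, u_new)
      }
      beta <- beta_new; u <- u_new
      if (abs(pen_new - pen_ll) < tol * (abs(pen_new) + 1)) {
        pen_ll <- pen_new
        break
      }
      pen_ll <- pen_new
    }
    pr <- stats::plogis(drop(X %*% beta) + u[gi])
    w <- pmax(pr * (1 - pr), 1e-10)
    s <- rowsum(w, gi)[, 1L]
    lap <- pen_ll - if (sig > 0) 0.5 * sum(log1p(sig^2 * s)) else 0
    list(beta = beta, u = u, loglik = lap, M = M, fitted = pr,
         iters = it)
  }

  n_outer <- 0L
  if (is.null(sigma)) {
    state <- NULL
    obj <- function(logsig) {
      n_outer <<- n_outer + 1L
      st <- inner(exp(logsig),
                  beta0 = if (!is.null(state)) state$beta,
                  u0 = if (!is.null(state)) state$u)
      state <<- st
      -st$loglik
    }
    lower <- log(1e-4); upper <- log(10)
    opt <- stats::optimize(obj, c(lower, upper), tol = 1e-6)
    sig_hat <- exp(opt$minimum)
    collapsed <- opt$minimum < lower + 1e-3
    if (collapsed) sig_hat <- 0
    fit <- inner(sig_hat)
    converged <- TRUE
  } else {
    if (sigma < 0) stop("sigma must be >= 0")
    sig_hat <- sigma
    fit <- inner(sig_hat)
    collapsed <- FALSE
    converged <- fit$iters < 100L
  }

  V <- solve(fit$M)
  se <- sqrt(diag(V))
  beta <- stats::setNames(fit$beta, colnames(X))
  names(se) <- colnames(X)
  structure(list(
    beta = beta, se = se, vcov = V,
    sigma = sig_hat, sigma_collapsed = collapsed,
    u = stats::setNames(fit$u, levels(g)),
    loglik = fit$loglik,
    fitted = fit$fitted,
    y = y, X = X, cluster = g,
    formula = formula, terms = attr(mf, "terms"),
    converged = converged, n_iter = n_outer,
    scaling = NULL,
    call = match.call()),
    class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial random-intercept GLMM (Laplace approximation)\n")
  cat(sprintf("  %d observations, %d clusters; logLik %.2f\n",
              length(x$y), nlevels(x$cluster), x$loglik))
  cat(sprintf("  random-intercept SD: %.4f%s\n", x$sigma,
              if (x$sigma_collapsed) " (collapsed to boundary)" else ""))
  cat("Fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...) object$beta

#' @export
vcov.glmm_fit <- function(object, ...) object$vcov

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 1L,
            nobs = length(object$y), class = "logLik")
}

#' @export
summary.glmm_fit <- function(object, ...) {
  tab <- wald_tests(object)
  out <- list(coefficients = tab, sigma = object$sigma,
              loglik = object$loglik, n = length(object$y),
              n_clusters = nlevels(object$cluster),
              converged = object$converged,
              sigma_collapsed = object$sigma_collapsed)
  class(out) <- "summary.glmm_fit"
  out
}

#' @export
print.summary.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial GLMM (Laplace): %d obs, %d clusters, logLik %.2f\n",
    x$n, x$n_clusters, x$loglik))
  cat(sprintf("Random-intercept SD: %.4f\n\n", x$sigma))
  tab <- x$coefficients
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
residuals.glmm_fit <- function(object,
                               type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson")
    r <- r / sqrt(object$fitted * (1 - object$fitted))
  r
}

#' @export
fitted.glmm_fit <- function(object, ...) object$fitted

#' @export
predict.glmm_fit <- function(object, newdata = NULL,
                             type = c("link", "response"),
                             re = c("zero", "conditional"), ...) {
  type <- match.arg(type); re <- match.arg(re)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$beta)
    if (re == "conditional") eta <- eta + object$u[as.integer(object$cluster)]
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    eta <- drop(X %*% object$beta[colnames(X)])
    if (re == "conditional") {
      u <- object$u[as.character(newdata$city_id)]
      u[is.na(u)] <- 0
      eta <- eta + u
    }
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
simulate.glmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta_fixed <- drop(object$X %*% object$beta)
  J <- nlevels(object$cluster)
  out <- as.data.frame(lapply(seq_len(nsim), function(k) {
    u <- stats::rnorm(J, 0, object$sigma)
    stats::rbinom(length(eta_fixed), 1,
                  stats::plogis(eta_fixed + u[as.integer(object$cluster)]))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Wald tests for every fixed-effect term
#'
#' Two-sided Wald z-tests: `z = estimate / SE`,
#' `p = 2 * (1 - pnorm(|z|))`.
#'
#' @param fit a [fit_glmm()] object
#' @return data.frame with columns term, estimate, se, z, p
#' @export
wald_tests <- function(fit) {
  z <- fit$beta / fit$se
  data.frame(term = names(fit$beta),
             estimate = unname(fit$beta),
             se = unname(fit$se),
             z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Binned residual diagnostic for a binary-response fit
#'
#' Observations are stably sorted by fitted probability (ties broken
#' by row index) and cut into `n_bins` equal-count bins; each bin
#' reports the mean fitted probability, mean response residual, and a
#' 2 SE band `2 * sd(resid) / sqrt(bin size)`.
#'
#' @param fit a [fit_glmm()] object
#' @param n_bins number of bins; default `ceiling(sqrt(n))`
#' @return data.frame with bin, n, mean_fitted, mean_resid, se2
#' @export
binned_residuals <- function(fit, n_bins = NULL) {
  n <- length(fit$y)
  if (is.null(n_bins)) n_bins <- ceiling(sqrt(n))
  if (n_bins > n) stop("n_bins cannot exceed the number of observations")
  ord <- order(fit$fitted, seq_len(n))
  r <- (fit$y - fit$fitted)[ord]
  f <- fit$fitted[ord]
  bin <- ceiling(seq_len(n) * n_bins / n)
  size <- as.integer(table(bin))
  msd <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  data.frame(
    bin = seq_len(n_bins),
    n = size,
    mean_fitted = as.numeric(tapply(f, bin, mean)),
    mean_resid = as.numeric(tapply(r, bin, mean)),
    se2 = 2 * as.numeric(tapply(r, bin, msd)) / sqrt(size))
}
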
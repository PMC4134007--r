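#' Maximum-likelihood logistic regression via IRLS
#'
#' Fits a binomial GLM with the logit link by iteratively reweighted least
#' squares. Convergence is declared when the largest score component falls
#' below `score_tol` or the relative log-likelihood change falls below
#' `ll_tol`, within `max_iter` iterations. Standard errors come from the
#' inverse observed information at the final iterate; any standard error
#' above `se_cap` (on the log-odds scale) marks the fit as not converged,
#' which flags quasi-separated cells for downstream handling.
#'
#' @param y Binary 0/1 response with both classes present.
#' @param X Numeric design matrix of full column rank (include the intercept
#'   column yourself).
#' @param max_iter,score_tol,ll_tol,se_cap Convergence controls.
#' @return List with `beta`, `se` (named by the columns of `X`), `converged`,
#'   `loglik`, `iterations`.
#' @export
fit_logistic <- function(y, X, max_iter = 25L, score_tol = 1e-8,
                         ll_tol = 1e-10, se_cap = 10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)))
    stop_input("response must be binary 0/1", "phewascan_bad_arg")
  if (length(unique(y)) < 2)
    stop_input("response has a single class; logistic fit undefined",
               "phewascan_single_class")
  if (nrow(X) != length(y))
    stop_input("design matrix rows must match response length",
               "phewascan_bad_arg")
  if (qr(X)$rank < ncol(X))
    stop_input("design matrix is rank deficient", "phewascan_rank_deficient")

  p <- ncol(X)
  beta <- numeric(p)
  if (all(X[, 1] == 1)) beta[1] <- stats::qlogis(mean(y))
  eps <- 1e-10
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, eps), 1 - eps)
    score <- drop(crossprod(X, y - mu))
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (max(abs(score)) < score_tol ||
        (is.finite(ll_old) && abs(ll - ll_old) < ll_tol * (abs(ll_old) + 1e-30))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), eps), 1 - eps)
  info <- crossprod(X * (mu * (1 - mu)), X)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, p))
  if (anyNA(se) || any(se > se_cap)) converged <- FALSE
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se = se, converged = converged,
       loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)),
       iterations = iter)
}
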
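#' Firth penalized-likelihood logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood `l(b) + 0.5 * log det
#' I(b)` by modified-score Newton iterations with step-halving. The penalty
#' keeps estimates finite under complete separation; with `penalty = 0` the
#' fit reduces to the ordinary maximum-likelihood logistic regression.
#'
#' @param y binary 0/1 response (>= 1 of each class).
#' @param X design matrix including an intercept column; must be full rank.
#' @param penalty weight on the Jeffreys adjustment (1 = Firth, 0 = MLE).
#' @param tol convergence: max absolute modified-score component < `tol`.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   score trace.
#' @return list: `coef`, `se` (Wald, from the Fisher information at the
#'   solution), `p` (two-sided Wald), `iterations`, `loglik`.
#' @export
firth_logistic <- function(y, X, penalty = 1, tol = 1e-6, max_iter = 100L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one case and one control", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  k <- ncol(X)
  b <- numeric(k)
  trace <- numeric(0)
  penlik <- function(b) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    if (penalty > 0) {
      info <- crossprod(X * sqrt(mu * (1 - mu)))
      ll <- ll + penalty * 0.5 * determinant(info)$modulus
    }
    ll
  }
  ll_old <- penlik(b)
  for (iter in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% b))
    w <- mu * (1 - mu)
    Xw <- X * sqrt(w)
    info <- crossprod(Xw)
    info_inv <- tryCatch(solve(info), error = function(e)
      stop("Fisher information is singular", call. = FALSE))
    h <- rowSums((Xw %*% info_inv) * Xw)
    score <- drop(crossprod(X, y - mu + penalty * h * (0.5 - mu)))
    trace <- c(trace, max(abs(score)))
    if (max(abs(score)) < tol) {
      se <- sqrt(diag(info_inv))
      z <- b / se
      return(list(coef = setNames(b, colnames(X)),
                  se = setNames(se, colnames(X)),
                  p = setNames(2 * pnorm(-abs(z)), colnames(X)),
                  iterations = iter - 1L, loglik = ll_old))
    }
    step <- drop(info_inv %*% score)
    # step-halving against divergence of the penalized likelihood
    for (half in 0:10) {
      b_new <- b + step / 2^half
      ll_new <- penlik(b_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-10) break
    }
    b <- b_new
    ll_old <- ll_new
  }
  stop("Firth iterations did not converge; score trace: ",
       paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
       call. = FALSE)
}
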
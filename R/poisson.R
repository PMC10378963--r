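#' Counting-process Poisson representation of the Cox model
#'
#' With Breslow ties, the Cox partial likelihood is exactly the profile
#' likelihood of a Poisson model on the risk-set expansion: one pseudo
#' observation per (distinct event time, at-risk subject) with outcome 1
#' for the subject(s) dying at that time and a free intercept per event
#' time (the log baseline-hazard mass). Fitting that penalized Poisson
#' model and the penalized partial likelihood must therefore agree on the
#' regression coefficients; the package uses this identity as an internal
#' cross-check of the Cox engine.
#'
#' @name poisson_equivalence
NULL

#' Expand survival data over risk sets
#'
#' @param time,event Survival time and 0/1 event indicator.
#' @return Data frame with `row` (subject index), `interval` (event-time
#'   stratum) and `y` (Poisson outcome).
#' @export
expand_risk_sets <- function(time, event) {
  stopifnot(length(time) == length(event))
  tev <- sort(unique(time[event > 0]))
  if (!length(tev)) stop("no events to expand")
  out <- lapply(seq_along(tev), function(m) {
    at_risk <- which(time >= tev[m])
    data.frame(row = at_risk, interval = m,
               y = as.integer(time[at_risk] == tev[m] &
                                event[at_risk] > 0))
  })
  do.call(rbind, out)
}

#' Penalized Poisson fit on the risk-set expansion
#'
#' Maximizes the Poisson log-likelihood of the expanded data minus
#' `0.5 * beta' Spen beta` (the interval intercepts are unpenalized) by
#' Newton iteration with step halving -- an implementation independent of
#' the partial-likelihood code path.
#'
#' @param X Subject-level design matrix (n x p).
#' @param time,event Survival data.
#' @param Spen p x p penalty for the regression coefficients (may be 0).
#' @param maxit,tol Iteration cap and gradient tolerance.
#' @return List with `beta` (length p), `alpha` (interval intercepts),
#'   `loglik`, `converged`.
#' @export
fit_poisson_equivalent <- function(X, time, event, Spen = NULL,
                                   maxit = 200, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(Spen)) Spen <- matrix(0, p, p)
  ex <- expand_risk_sets(time, event)
  Xe <- X[ex$row, , drop = FALSE]
  A <- stats::model.matrix(~ 0 + factor(ex$interval))
  D <- cbind(Xe, A)
  y <- ex$y
  q <- ncol(D)
  Sfull <- matrix(0, q, q)
  Sfull[seq_len(p), seq_len(p)] <- Spen
  theta <- c(rep(0, p), rep(log(mean(y) + 1e-8), ncol(A)))
  pll <- function(th) {
    eta <- drop(D %*% th)
    sum(y * eta - exp(eta)) - 0.5 * sum(th * (Sfull %*% th))
  }
  obj <- pll(theta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% theta)
    mu <- exp(eta)
    g <- drop(crossprod(D, y - mu)) - drop(Sfull %*% theta)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    H <- crossprod(D * mu, D) + Sfull
    step <- solve(H, g)
    for (h in 0:30) {
      cand <- theta + step / 2^h
      oc <- pll(cand)
      if (is.finite(oc) && oc >= obj - 1e-12) break
    }
    theta <- cand
    obj <- oc
  }
  list(beta = theta[seq_len(p)], alpha = theta[-seq_len(p)],
       loglik = obj + 0.5 * sum(theta * (Sfull %*% theta)),
       converged = converged)
}
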
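#' Thin plate regression splines and constraint projectors
#'
#' One-dimensional thin plate regression splines (TPRS) provide the penalized
#' bases for both smooth terms of the model: the volume smooth and the
#' intensity weight function. The full thin plate spline represents a smooth
#' as a radial expansion `f(x) = sum_i delta_i eta(|x - x_i|) + a + b x` with
#' kernel `eta(r) = r^3 / 12`, penalized by the integrated squared second
#' derivative `delta' E delta` (zero exactly on affine functions -- the
#' penalty null space). The regression version reduces the radial part to a
#' low rank by eigen-decomposing the kernel matrix and keeping the leading
#' eigenvectors, after absorbing the side condition `T' delta = 0`.
#'
#' Bases are built on a bounded set of knots (quantile-spaced over the
#' supplied points when there are many) and can be evaluated anywhere.
#'
#' @name spline_engine
NULL

tps_eta <- function(r) abs(r)^3 / 12

#' Build a 1-d thin plate regression spline basis
#'
#' @param points Numeric vector the smooth is built over (e.g. observed
#'   volumes, or histogram bin representatives).
#' @param basis_dim Total basis dimension `q` including the two null-space
#'   columns (constant, linear).
#' @param max_knots Cap on the number of radial knots; quantile-spaced
#'   unique values of `points` are used beyond it.
#' @return Object of class `tprs_basis`: list with `knots`, scaling, the
#'   coefficient map `UZ` for the radial part, penalty `S` (q x q, PSD, zero
#'   on the last two columns), `nullspace_dim = 2` and `q`.
#' @examples
#' b <- build_tprs(seq(0, 1, length = 50), basis_dim = 8)
#' B <- eval_basis(b, seq(0, 1, length = 11))
#' dim(B)
#' @export
build_tprs <- function(points, basis_dim = 10, max_knots = 200) {
  x <- sort(unique(as.numeric(points)))
  if (basis_dim < 3) stop("basis_dim must be at least 3")
  if (length(x) < basis_dim)
    stop("need at least basis_dim distinct points (got ",
         length(x), " for basis_dim ", basis_dim, ")")
  if (length(x) > max_knots)
    x <- unique(stats::quantile(x, seq(0, 1, length.out = max_knots),
                                names = FALSE, type = 7))
  shift <- min(x)
  scale <- max(x) - shift
  xs <- (x - shift) / scale
  m <- length(xs)
  k_rad <- basis_dim - 2

  E <- tps_eta(outer(xs, xs, "-"))
  eg <- eigen(E, symmetric = TRUE)
  keep <- order(abs(eg$values), decreasing = TRUE)[seq_len(k_rad + 2)]
  U <- eg$vectors[, keep, drop = FALSE]
  d <- eg$values[keep]
  # absorb T' delta = 0, T = [1, x]: delta = U %*% Z %*% z
  Tm <- cbind(1, xs)
  A <- crossprod(Tm, U)                       # 2 x (k_rad + 2)
  Z <- qr.Q(qr(t(A)), complete = TRUE)[, -(1:2), drop = FALSE]
  UZ <- U %*% Z                               # m x k_rad
  S_rad <- crossprod(Z, Z * d)                # Z' diag(d) Z, PSD in theory
  S_rad <- (S_rad + t(S_rad)) / 2
  es <- eigen(S_rad, symmetric = TRUE)
  S_rad <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
  S <- matrix(0, basis_dim, basis_dim)
  S[seq_len(k_rad), seq_len(k_rad)] <- S_rad
  structure(list(knots = x, shift = shift, scale = scale, UZ = UZ,
                 S = (S + t(S)) / 2, q = basis_dim, nullspace_dim = 2,
                 penalty_rank = k_rad),
            class = "tprs_basis")
}

#' Evaluate a spline basis at new points
#'
#' @param basis A `tprs_basis` or `constrained_basis`.
#' @param x Numeric vector of evaluation points (original scale).
#' @return Matrix with one row per point and one column per coefficient.
#' @export
eval_basis <- function(basis, x) UseMethod("eval_basis")

#' @export
eval_basis.tprs_basis <- function(basis, x) {
  xs <- (as.numeric(x) - basis$shift) / basis$scale
  ks <- (basis$knots - basis$shift) / basis$scale
  R <- tps_eta(outer(xs, ks, "-")) %*% basis$UZ
  cbind(R, 1, xs, deparse.level = 0)
}

#' @export
print.tprs_basis <- function(x, ...) {
  cat("TPRS basis: q =", x$q, "(", x$penalty_rank, "penalized +",
      x$nullspace_dim, "null ) on", length(x$knots), "knots in [",
      x$shift, ",", x$shift + x$scale, "]\n")
  invisible(x)
}

penalty_matrix <- function(basis) basis$S

#' Remove a function span from a spline basis
#'
#' Constrains the functions representable by `basis` to be orthogonal
#' (uniform inner product over `at`) to the given span: `"constant"` gives
#' the usual sum-to-zero identifiability constraint, `c("constant",
#' "linear")` removes the whole affine family -- the constraint that makes
#' the intensity weight function carry no information about mean intensity.
#' The constraint is absorbed: the returned basis has `q - s` columns, its
#' penalty is transformed congruently, and every representable function is
#' exactly invariant to adding any element of the removed span.
#'
#' @param basis A `tprs_basis`.
#' @param span Character subset of `c("constant", "linear")`.
#' @param at Evaluation points defining the inner product (defaults to the
#'   basis knots).
#' @return Object of class `constrained_basis` wrapping the parent basis,
#'   the orthonormal coefficient map `Z` (columns span the retained
#'   coefficient space) and the transformed penalty.
#' @export
remove_span <- function(basis, span = c("constant", "linear"), at = NULL) {
  stopifnot(inherits(basis, "tprs_basis"))
  span <- match.arg(span, c("constant", "linear"), several.ok = TRUE)
  if (is.null(at)) at <- basis$knots
  at <- as.numeric(at)
  C <- cbind(constant = rep(1, length(at)),
             linear = (at - basis$shift) / basis$scale)[, span, drop = FALSE]
  if (qr(C)$rank < ncol(C))
    stop("removed span is rank-deficient at the evaluation points")
  Qc <- qr.Q(qr(C))
  B_at <- eval_basis(basis, at)
  M <- crossprod(Qc, B_at)                    # s x q constraint matrix
  Z <- svd(M, nu = 0, nv = basis$q)$v[, -(seq_len(ncol(C))), drop = FALSE]
  S <- crossprod(Z, basis$S %*% Z)
  S <- (S + t(S)) / 2
  structure(list(parent = basis, Z = Z, S = S, q = ncol(Z),
                 span = span, at = at,
                 penalty_rank = qr(S, tol = 1e-10)$rank),
            class = "constrained_basis")
}

#' @export
eval_basis.constrained_basis <- function(basis, x) {
  eval_basis(basis$parent, x) %*% basis$Z
}

#' @export
print.constrained_basis <- function(x, ...) {
  cat("Constrained basis: removed {", paste(x$span, collapse = ", "),
      "}; q =", x$q, "( penalty rank", x$penalty_rank, ")\n")
  invisible(x)
}

#' Idempotent projector onto the retained coefficient space
#'
#' Mostly of diagnostic interest: `P = Z Z'` with `Z` orthonormal, so
#' `P P = P` and basis columns projected by `P` regress to zero on the
#' removed span.
#' @param basis A `constrained_basis`.
#' @export
constraint_projector <- function(basis) {
  stopifnot(inherits(basis, "constrained_basis"))
  tcrossprod(basis$Z)
}

#' Design rows for the functional (histogram) predictor
#'
#' The functional term enters the hazard as a weighted average of relative
#' frequencies, `sum_k w(z_k) p_k`, with `w = B beta` evaluated at the bin
#' representatives. Its design row is therefore `sum_k p_k B(z_k, .)`, so
#' that `row %*% beta` reproduces the weighted average exactly.
#'
#' @param hist An `intensity_histogram`, or a matrix/data frame of relative
#'   frequencies with one row per participant (columns in bin order).
#' @param basis Basis for the weight function (normally a
#'   `constrained_basis` with the affine span removed), built over the bin
#'   representatives `z`.
#' @param z Bin representatives; must match the number of histogram bins.
#' @return A matrix of design rows (one per participant).
#' @export
functional_design_row <- function(hist, basis, z) {
  if (inherits(hist, "intensity_histogram")) {
    if (length(hist$p) != length(z))
      stop("histogram has ", length(hist$p), " bins but ", length(z),
           " representatives were supplied")
    p <- matrix(hist$p, nrow = 1)
  } else {
    p <- if (is.matrix(hist) || is.data.frame(hist)) as.matrix(hist)
         else matrix(as.numeric(hist), nrow = 1)
    if (ncol(p) != length(z))
      stop("histogram matrix has ", ncol(p), " columns but ", length(z),
           " representatives were supplied")
  }
  unname(p %*% eval_basis(basis, z))
}
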
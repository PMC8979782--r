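#' Cubic B-spline basis for a weight function over a finite lag window
#'
#' Builds the basis in which the lag-weight function `w(t)` of a weighted
#' cumulative exposure (WCE) model is expressed: cubic (order 4) B-splines on
#' the lag axis `t = 1, ..., window`, with interior knots equally spaced on
#' `(0, window)` and boundary knots of standard multiplicity at `0` and
#' `window`. The unconstrained basis has `n_knots + 4` columns and satisfies
#' the partition-of-unity identity at every interior lag. The right-constrained
#' variant drops the last two columns, which forces `w(window) = 0` with a
#' smooth (zero-derivative) approach, encoding the assumption that doses taken
#' at the far edge of the window carry no residual effect.
#'
#' @param window positive integer; maximum lag (days) beyond which past doses
#'   carry no weight.
#' @param n_knots number of interior knots (>= 0).
#' @param constrained logical; if `TRUE`, drop the trailing columns so that
#'   every retained basis function vanishes at `t = window`.
#' @param knots optional numeric vector of interior knot positions in
#'   `(0, window)`, overriding the equally-spaced default.
#'
#' @return An object of class `spline_basis`: a list with elements `window`,
#'   `n_knots`, `order`, `constrained`, `knots` (full knot vector including
#'   boundary multiplicities), and `B`, the `window x J` matrix of basis values
#'   tabulated at integer lags `1..window`.
#'
#' @examples
#' b <- spline_basis(75, n_knots = 1)
#' dim(b$B)                     # 75 x 5
#' rowSums(b$B[1:74, ])         # partition of unity at interior lags
#' @export
spline_basis <- function(window, n_knots = 1, constrained = FALSE, knots = NULL) {
  window <- as.integer(window)
  order <- 4L
  if (window < order)
    stop("window-too-small: lag window must be at least the spline order (4 days)",
         call. = FALSE)
  if (n_knots < 0) stop("n_knots must be >= 0", call. = FALSE)
  if (is.null(knots)) {
    interior <- if (n_knots > 0) seq(0, window, length.out = n_knots + 2)[-c(1, n_knots + 2)]
                else numeric(0)
  } else {
    interior <- sort(as.numeric(knots))
    if (length(interior) != n_knots)
      stop("length(knots) must equal n_knots", call. = FALSE)
    if (any(interior <= 0 | interior >= window))
      stop("interior knots must lie strictly inside (0, window)", call. = FALSE)
  }
  kv <- c(rep(0, order), interior, rep(window, order))
  B <- splines::splineDesign(kv, x = seq_len(window), ord = order)
  J_full <- n_knots + order
  stopifnot(ncol(B) == J_full)
  if (constrained) {
    if (J_full - 2L < 1L)
      stop("window-too-small: constrained basis needs at least 3 columns", call. = FALSE)
    B <- B[, seq_len(J_full - 2L), drop = FALSE]
  }
  colnames(B) <- paste0("wce", seq_len(ncol(B)))
  structure(
    list(window = window, n_knots = as.integer(n_knots), order = order,
         constrained = constrained, knots = kv, B = B),
    class = "spline_basis"
  )
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("Cubic B-spline lag basis: window %d days, %d interior knot(s), %d column(s)%s\n",
              x$window, x$n_knots, ncol(x$B),
              if (x$constrained) ", right-constrained (w(T) = 0)" else ""))
  invisible(x)
}

#' Evaluate a weight function from basis and coefficients
#'
#' Returns `w(t) = sum_j theta_j B_j(t)` at integer lags `1..window`; by
#' convention `w(t) = 0` beyond the window.
#'
#' @param basis a [spline_basis()].
#' @param theta coefficient vector, one per basis column; units are
#'   log-hazard-ratio per unit of dose held one day at that lag.
#' @return numeric vector of length `basis$window`.
#' @export
eval_weights <- function(basis, theta) {
  stopifnot(inherits(basis, "spline_basis"))
  theta <- as.numeric(theta)
  if (length(theta) != ncol(basis$B))
    stop("theta length must match the number of basis columns", call. = FALSE)
  drop(basis$B %*% theta)
}

#' WCE covariates for one exposure series at a given risk-set day
#'
#' Computes `D_j(u) = sum_{t=1}^{min(u, T)} B_j(t) * X(u - t)`, the spline-
#' projected weighted sum of past daily doses, where `X(d)` is the dose on day
#' `d` (0-indexed from the series origin) and `u` is the follow-up day. The
#' same-day dose is excluded (minimum lag one day): exposure counts only up to
#' the day before the evaluation day.
#'
#' @param doses numeric vector of daily doses, element `d + 1` holding day `d`.
#' @param basis a [spline_basis()].
#' @param day_u integer follow-up day (1-based) at which to evaluate.
#' @return numeric vector `D_j(u)`, one entry per basis column.
#' @export
wce_covariates <- function(doses, basis, day_u) {
  stopifnot(inherits(basis, "spline_basis"))
  day_u <- as.integer(day_u)
  if (day_u < 1L) stop("day_u must be >= 1", call. = FALSE)
  tmax <- min(day_u, basis$window)
  if (tmax < 1L)
    return(structure(numeric(ncol(basis$B)), names = colnames(basis$B)))
  lags <- seq_len(tmax)
  x <- doses[day_u - lags + 1L]          # X(u - t), day (u - t) stored at index u - t + 1
  x[is.na(x)] <- 0
  drop(crossprod(basis$B[lags, , drop = FALSE], x))
}

# Full D matrix for one series: rows u = 1..length(doses), one column per basis
# column. The lag-embedded dose matrix E[u, t] = X(u - t) turns the discrete
# convolution with the tabulated basis into a single matrix product E %*% B.
wce_covariate_matrix <- function(doses, basis) {
  L <- length(doses)
  J <- ncol(basis$B)
  if (L == 0L) return(matrix(0, 0L, J, dimnames = list(NULL, colnames(basis$B))))
  Tw <- basis$window
  xpad <- c(rep(0, Tw), doses)
  idx <- rep(Tw + seq_len(L), Tw) - rep(seq_len(Tw), each = L)  # (u, t) -> u - t
  E <- matrix(xpad[idx + 1L], L, Tw)
  D <- E %*% basis$B
  dimnames(D) <- list(NULL, colnames(basis$B))
  D
}
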
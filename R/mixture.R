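#' Construct validated mixture parameters
#'
#' The promoter-shape model is a three-component finite mixture on the bin
#' grid: two double-exponential (Laplace) components capturing unimodal or
#' bimodal peaks, plus a uniform component modelling the flat tails that
#' elongating Pol-II leaves over the gene body:
#' \deqn{f(t) = \pi_1 \frac{e^{-|t-\mu_1|/\beta_1}}{2\beta_1}
#'            + \pi_2 \frac{e^{-|t-\mu_2|/\beta_2}}{2\beta_2}
#'            + \pi_3 \frac{1[a \le t \le b]}{b-a}}
#'
#' @param pi Length-3 nonnegative mixing proportions summing to 1.
#' @param mu Length-2 Laplace locations, in bin units.
#' @param beta Length-2 Laplace scales, in bin units (>= 0.1).
#' @param a,b Uniform support endpoints, \code{a < b}.
#' @return An object of class \code{mixture_params}.
#' @export
mixture_params <- function(pi, mu, beta, a = -50, b = 50) {
  pi <- as.numeric(pi); mu <- as.numeric(mu); beta <- as.numeric(beta)
  stopifnot(length(pi) == 3, length(mu) == 2, length(beta) == 2)
  if (any(pi < -1e-9)) stop("mixing proportions must be nonnegative")
  if (abs(sum(pi) - 1) > 1e-6) stop("mixing proportions must sum to 1")
  if (any(beta < 0.1 - 1e-12)) stop("Laplace scales must be >= 0.1 bins")
  if (b <= a) stop("uniform support needs a < b")
  structure(list(pi = pmax(pi, 0) / sum(pmax(pi, 0)), mu = mu, beta = beta,
                 a = a, b = b), class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "<mixture_params> pi=(%.3f, %.3f, %.3f)  mu=(%.2f, %.2f)  beta=(%.2f, %.2f)  U[%.1f, %.1f]\n",
    x$pi[1], x$pi[2], x$pi[3], x$mu[1], x$mu[2], x$beta[1], x$beta[2],
    x$a, x$b))
  invisible(x)
}

#' Mixture density at bin coordinates
#'
#' @param t Numeric vector of bin coordinates.
#' @param params A \code{mixture_params} object.
#' @return \code{f(t)}, vectorized over \code{t}.
#' @export
mixture_density <- function(t, params) {
  p <- params
  if (p$b <= p$a) stop("uniform support needs a < b")
  p$pi[1] * exp(-abs(t - p$mu[1]) / p$beta[1]) / (2 * p$beta[1]) +
    p$pi[2] * exp(-abs(t - p$mu[2]) / p$beta[2]) / (2 * p$beta[2]) +
    p$pi[3] * as.numeric(t >= p$a & t <= p$b) / (p$b - p$a)
}

# Discrete model distribution on the grid: q(t) = f(t) / sum_T f.
mixture_grid_probs <- function(params, grid) {
  f <- mixture_density(grid, params)
  s <- sum(f)
  if (s <= 0) return(rep(NA_real_, length(grid)))
  f / s
}

#' Kullback-Leibler objective for a profile fit
#'
#' With \code{p = y / sum(y)} and \code{q} the model density normalized over
#' the grid, returns \code{sum(p * log(p / q))}. Bins with \code{p = 0}
#' contribute nothing; a bin with \code{p > 0} but \code{q = 0} yields
#' \code{Inf}. The value is always >= 0 and equals 0 exactly when p = q.
#' Minimizing this normalized divergence is equivalent to minimizing the raw
#' \code{sum(y * log(y / f))} form: rescaling \code{y} multiplies the
#' objective by a constant and normalizing \code{f} shifts it by one, so the
#' argmin is unchanged while "0 at a perfect fit" becomes testable.
#'
#' @param y Nonnegative counts on the grid, \code{sum(y) > 0}.
#' @param params A \code{mixture_params} object.
#' @param grid Bin coordinates (default \code{-50:50}).
#' @return The divergence (nonnegative, possibly \code{Inf}).
#' @export
kl_objective <- function(y, params, grid = -50:50) {
  if (length(y) != length(grid)) stop("y and grid lengths differ")
  if (any(y < 0)) stop("counts must be nonnegative")
  sy <- sum(y)
  if (sy <= 0) stop("all-zero count vector")
  p <- y / sy
  q <- mixture_grid_probs(params, grid)
  pos <- p > 0
  if (any(pos & q <= 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}
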
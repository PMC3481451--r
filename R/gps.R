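#' Generalized pattern search over a box
#'
#' Derivative-free minimization by coordinate polling on an adaptive mesh:
#' from the incumbent \code{x} the 2n points \code{x +/- delta * e_i} (clipped
#' to the bounds) are polled in order, the first improving point is accepted
#' and the mesh size doubles; if no poll point improves, the mesh halves. The
#' coordinate directions form a positive spanning set, so the method converges
#' to a stationary point as the mesh refines.
#'
#' Four stopping criteria are checked, in this order, and the first to fire is
#' reported: total function evaluations reaching \code{max_evals}; iterations
#' reaching \code{max_iters}; mesh size \code{delta} (the minimum distance
#' between points polled in consecutive iterations) falling below
#' \code{step_tol}; and, after a successful poll, the improvement over the
#' previous best falling below \code{ftol} while the mesh is already finer
#' than \code{ftol} — the convention of the classic pattern-search toolboxes,
#' where a function-value tolerance only applies on a fine mesh (a tiny gain
#' on a coarse mesh is routine and says nothing about convergence).
#'
#' @param fn Objective function of a numeric vector; must be finite at
#'   \code{x0}.
#' @param x0 Starting point, within the bounds.
#' @param lower,upper Box bounds (recycled to \code{length(x0)}).
#' @param delta0 Initial mesh size (default 1).
#' @param max_evals,max_iters,step_tol,ftol Stopping criteria (defaults
#'   20000, 2000, 1e-6, 1e-6).
#' @return List with \code{x_best}, \code{f_best}, \code{n_evals},
#'   \code{n_iters}, \code{stop_reason} (one of \code{"max_evals"},
#'   \code{"max_iters"}, \code{"step_tol"}, \code{"ftol"}) and \code{trace}
#'   (best objective value after each iteration, non-increasing).
#' @export
gps_minimize <- function(fn, x0, lower = -Inf, upper = Inf, delta0 = 1,
                         max_evals = 20000L, max_iters = 2000L,
                         step_tol = 1e-6, ftol = 1e-6) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (any(x0 < lower) || any(x0 > upper)) stop("x0 outside bounds")
  f0 <- fn(x0)
  if (!is.finite(f0)) stop("objective not finite at x0")
  x <- x0; fx <- f0
  n_evals <- 1L; n_iters <- 0L
  delta <- delta0
  trace <- numeric(0)
  stop_reason <- NULL
  repeat {
    if (n_evals >= max_evals) { stop_reason <- "max_evals"; break }
    if (n_iters >= max_iters) { stop_reason <- "max_iters"; break }
    if (delta < step_tol)     { stop_reason <- "step_tol";  break }
    n_iters <- n_iters + 1L
    improved <- FALSE
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        xc <- x
        xc[i] <- min(max(x[i] + s * delta, lower[i]), upper[i])
        if (xc[i] == x[i]) next                 # clipped onto the incumbent
        fc <- fn(xc)
        n_evals <- n_evals + 1L
        if (is.finite(fc) && fc < fx) {
          gain <- fx - fc
          x <- xc; fx <- fc
          improved <- TRUE
          # a tiny gain only terminates once the mesh is fine too; at a
          # coarse mesh a small improvement says nothing about convergence
          if (gain < ftol && delta < ftol) stop_reason <- "ftol"
          break
        }
        if (n_evals >= max_evals) break
      }
      if (improved || n_evals >= max_evals) break
    }
    trace <- c(trace, fx)
    if (!is.null(stop_reason)) break
    delta <- if (improved) delta * 2 else delta / 2
  }
  list(x_best = x, f_best = fx, n_evals = n_evals, n_iters = n_iters,
       stop_reason = stop_reason, trace = trace)
}
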
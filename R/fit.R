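# Map the unconstrained GPS vector to mixture parameters and back. The
# optimizer works in a box: logits (l1, l2) give the mixing proportions via a
# softmax with the third logit fixed at 0, scales are optimized on the log
# scale, locations are boxed to the grid span. This removes the simplex and
# positivity constraints from the optimizer entirely; mu1 <= mu2 is enforced
# only when the result is reported.
theta_to_params <- function(theta, a, b, estimate_support = FALSE,
                            grid_range = c(-50, 50)) {
  e <- exp(c(theta[1], theta[2], 0))
  pi <- e / sum(e)
  if (estimate_support) { a <- theta[7]; b <- theta[8] }
  mixture_params(pi = pi, mu = theta[3:4], beta = exp(theta[5:6]),
                 a = a, b = b)
}

#' Fit the promoter-shape mixture to one profile by KL minimization
#'
#' Minimizes the Kullback-Leibler divergence between the observed bin
#' distribution and the three-component mixture (two Laplace peaks plus a
#' uniform) with a generalized pattern search, restarted from
#' \code{n_starts} initial points: two data-informed starts placing the peak
#' locations at the two highest smoothed local maxima of the profile, and the
#' remainder seeded Latin-hypercube draws over the parameter box. The best
#' restart wins.
#'
#' By default the uniform support is pinned to the full window
#' (\code{[min(grid), max(grid)]}): a narrower uniform zeroes the model
#' density at observed bins and makes the divergence infinite, while the
#' full-window uniform plays its intended role of absorbing the profile's
#' flat tails. Setting \code{estimate_uniform_support = TRUE} frees a and b
#' within bounds that keep all observed bins covered.
#'
#' @param y Nonnegative counts on the bin grid.
#' @param grid Bin coordinates (default \code{-50:50}).
#' @param n_starts Number of restarts (default 16).
#' @param seed Integer seed for the Latin-hypercube starts.
#' @param estimate_uniform_support Free the uniform endpoints (default FALSE).
#' @param max_evals,max_iters,step_tol,ftol Stopping criteria passed to
#'   \code{\link{gps_minimize}}.
#' @return A \code{klmix} model object with \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot} and \code{simulate} methods.
#' @export
fit_mixture <- function(y, grid = -50:50, n_starts = 16L, seed = 1L,
                        estimate_uniform_support = FALSE,
                        max_evals = 20000L, max_iters = 2000L,
                        step_tol = 1e-6, ftol = 1e-6) {
  if (length(y) != length(grid)) stop("y and grid lengths differ")
  if (any(y < 0)) stop("counts must be nonnegative")
  sy <- sum(y)
  if (sy <= 0) stop("all-zero count vector")
  p <- y / sy
  pos <- p > 0
  lo_t <- min(grid); hi_t <- max(grid)
  a0 <- lo_t; b0 <- hi_t
  est <- estimate_uniform_support
  obs <- range(grid[pos])

  obj <- function(th) {
    e1 <- exp(th[1]); e2 <- exp(th[2]); s <- e1 + e2 + 1
    pi1 <- e1 / s; pi2 <- e2 / s; pi3 <- 1 / s
    b1 <- exp(th[5]); b2 <- exp(th[6])
    aa <- if (est) th[7] else a0
    bb <- if (est) th[8] else b0
    if (bb <= aa) return(Inf)
    f <- pi1 * exp(-abs(grid - th[3]) / b1) / (2 * b1) +
         pi2 * exp(-abs(grid - th[4]) / b2) / (2 * b2) +
         pi3 * as.numeric(grid >= aa & grid <= bb) / (bb - aa)
    q <- f / sum(f)
    if (any(pos & q <= 0)) return(Inf)
    sum(p[pos] * log(p[pos] / q[pos]))
  }

  lower <- c(-8, -8, lo_t, lo_t, log(0.1), log(0.1))
  upper <- c( 8,  8, hi_t, hi_t, log(hi_t - lo_t), log(hi_t - lo_t))
  if (est) {
    lower <- c(lower, lo_t, obs[2])
    upper <- c(upper, obs[1], hi_t)
  }
  d <- length(lower)

  # two data-informed starts: peaks at the two highest smoothed local maxima
  sm <- smooth_moving_average(y, 3)
  n <- length(sm)
  is_max <- sm >= c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf)
  peaks <- order(sm * is_max, decreasing = TRUE)
  top2 <- grid[peaks[1:2]]
  l_pi <- log(0.4 / 0.2)                     # pi = (0.4, 0.4, 0.2)
  start1 <- c(l_pi, l_pi, min(top2), max(top2), log(5), log(5))
  start2 <- c(l_pi, l_pi, grid[peaks[1]], grid[peaks[1]], log(5), log(15))
  if (est) {
    start1 <- c(start1, lo_t, hi_t)
    start2 <- c(start2, lo_t, hi_t)
  }
  starts <- list(start1, start2)
  n_lhs <- max(n_starts - 2L, 0L)
  if (n_lhs > 0) {
    u <- with_seed(seed, lhs::randomLHS(n_lhs, d))
    for (i in seq_len(n_lhs))
      starts[[2L + i]] <- lower + u[i, ] * (upper - lower)
  }
  starts <- starts[seq_len(n_starts)]

  best <- NULL; best_idx <- NA_integer_; total_evals <- 0L
  per_start <- numeric(length(starts))
  for (i in seq_along(starts)) {
    res <- gps_minimize(obj, starts[[i]], lower, upper, delta0 = 1,
                        max_evals = max_evals, max_iters = max_iters,
                        step_tol = step_tol, ftol = ftol)
    total_evals <- total_evals + res$n_evals
    per_start[i] <- res$f_best
    if (is.null(best) || res$f_best < best$f_best) { best <- res; best_idx <- i }
  }

  params <- theta_to_params(best$x_best, a0, b0, est)
  if (params$mu[1] > params$mu[2]) {          # canonical ordering mu1 <= mu2
    params$mu <- params$mu[2:1]
    params$beta <- params$beta[2:1]
    params$pi <- params$pi[c(2, 1, 3)]
  }
  structure(list(params = params, objective = best$f_best,
                 n_evals = best$n_evals, n_iters = best$n_iters,
                 stop_reason = best$stop_reason, start_index = best_idx,
                 start_objectives = per_start, total_evals = total_evals,
                 y = as.numeric(y), grid = grid, seed = seed,
                 call = match.call()),
            class = "klmix")
}

#' @export
print.klmix <- function(x, ...) {
  cat("Promoter-shape mixture fit (KL minimization by pattern search)\n")
  print(x$params)
  cat(sprintf("KL divergence: %.6g   (start %d, %s after %d evals)\n",
              x$objective, x$start_index, x$stop_reason, x$n_evals))
  invisible(x)
}

#' @export
summary.klmix <- function(object, ...) {
  structure(list(fit = object), class = "summary.klmix")
}

#' @export
print.summary.klmix <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("Restart objectives:\n")
  print(signif(f$start_objectives, 4))
  cat("Total function evaluations across restarts:", f$total_evals, "\n")
  invisible(x)
}

#' @export
coef.klmix <- function(object, ...) {
  p <- object$params
  c(pi1 = p$pi[1], pi2 = p$pi[2], pi3 = p$pi[3],
    mu1 = p$mu[1], mu2 = p$mu[2], beta1 = p$beta[1], beta2 = p$beta[2],
    a = p$a, b = p$b)
}

#' Predict the fitted density
#'
#' @param object A \code{klmix} fit.
#' @param newdata Bin coordinates (defaults to the fitting grid).
#' @param type \code{"density"} for the continuous mixture density,
#'   \code{"prob"} for probabilities normalized over the fitting grid.
#' @param ... Unused.
#' @export
predict.klmix <- function(object, newdata = object$grid,
                          type = c("density", "prob"), ...) {
  type <- match.arg(type)
  if (type == "density") return(mixture_density(newdata, object$params))
  q <- mixture_grid_probs(object$params, object$grid)
  stats::approx(object$grid, q, xout = newdata, rule = 2)$y
}

#' @export
fitted.klmix <- function(object, ...) {
  sum(object$y) * mixture_grid_probs(object$params, object$grid)
}

#' @export
residuals.klmix <- function(object, type = c("raw", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - fitted(object)
  if (type == "pearson") r <- r / sqrt(pmax(fitted(object), 1e-12))
  r
}

#' @export
plot.klmix <- function(x, ...) {
  p_obs <- x$y / sum(x$y)
  q <- mixture_grid_probs(x$params, x$grid)
  plot(x$grid, p_obs, type = "h", col = "grey60",
       xlab = "bin position relative to TSS", ylab = "probability",
       main = "Observed profile and fitted mixture", ...)
  lines(x$grid, q, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate profiles from a fitted mixture
#'
#' @param object A \code{klmix} fit.
#' @param nsim Number of simulated profiles.
#' @param seed Integer seed.
#' @param n_reads Reads per simulated profile (defaults to the observed
#'   total, rounded).
#' @param ... Unused.
#' @return Matrix (\code{nsim} rows) of multinomial counts on the grid.
#' @export
simulate.klmix <- function(object, nsim = 1, seed = NULL,
                           n_reads = round(sum(object$y)), ...) {
  with_seed(seed, {
    q <- mixture_grid_probs(object$params, object$grid)
    t(stats::rmultinom(nsim, size = n_reads, prob = q))
  })
}

#' Fit per-cluster signature models for both marks
#'
#' For every cluster, the member profiles' Pol-II and H3K4me2 windows are
#' averaged and each mean is fitted independently with
#' \code{\link{fit_mixture}}. The scan template is the fitted Pol-II density
#' followed by the fitted H3K4me2 density, each evaluated on the grid and
#' standardized (zero mean, unit norm per segment). A cluster whose mean
#' profile is flat in either mark is flagged degenerate and excluded from
#' scanning.
#'
#' @param assignment A \code{signature_clusters} object.
#' @param profiles The \code{tss_profiles} the clustering was run on.
#' @param seed Integer seed (fanned out per cluster and mark).
#' @param n_starts,... Passed to \code{\link{fit_mixture}}.
#' @return List of \code{signature_model} objects (one per cluster).
#' @export
fit_signature_models <- function(assignment, profiles, seed = 1L,
                                 n_starts = 16L, ...) {
  stopifnot(inherits(assignment, "signature_clusters"),
            inherits(profiles, "tss_profiles"))
  if (length(assignment$labels) != nrow(profiles$y1))
    stop("assignment does not cover the profiles")
  grid <- -profiles$half_bins:profiles$half_bins
  lapply(seq_len(assignment$k), function(cl) {
    members <- assignment$labels == cl
    if (!any(members)) stop("cluster ", cl, " has no members")
    m1 <- colMeans(profiles$y1[members, , drop = FALSE])
    m2 <- colMeans(profiles$y2[members, , drop = FALSE])
    fit1 <- fit_mixture(m1, grid = grid, n_starts = n_starts,
                        seed = seed + 2L * cl, ...)
    fit2 <- fit_mixture(m2, grid = grid, n_starts = n_starts,
                        seed = seed + 2L * cl + 1L, ...)
    s1 <- standardize_segment(mixture_grid_probs(fit1$params, grid))
    s2 <- standardize_segment(mixture_grid_probs(fit2$params, grid))
    degenerate <- isTRUE(attr(s1, "degenerate")) ||
      isTRUE(attr(s2, "degenerate"))
    if (degenerate)
      warning("cluster ", cl, " yields a flat template; flagged degenerate")
    structure(list(cluster_id = cl, fit_pol2 = fit1, fit_h3k4 = fit2,
                   template = c(as.numeric(s1), as.numeric(s2)),
                   n_members = sum(members), degenerate = degenerate,
                   grid = grid),
              class = "signature_model")
  })
}

#' @export
print.signature_model <- function(x, ...) {
  cat("<signature_model> cluster", x$cluster_id, "(", x$n_members,
      "members )", if (x$degenerate) "[degenerate]" else "", "\n")
  cat("  Pol-II:  "); print(x$fit_pol2$params)
  cat("  H3K4me2: "); print(x$fit_h3k4$params)
  invisible(x)
}
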
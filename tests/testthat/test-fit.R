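test_that("mixture fitting recovers bimodal generating parameters", {
  truth <- mixture_params(c(0.4, 0.4, 0.2), mu = c(-10, 10), beta = c(5, 5))
  y <- simulate_profile(truth, 10000, seed = 101)
  fit <- fit_mixture(y, seed = 1)
  co <- coef(fit)
  expect_lt(abs(co["mu1"] - (-10)), 2)
  expect_lt(abs(co["mu2"] - 10), 2)
  expect_lt(max(abs(co[c("pi1", "pi2", "pi3")] - c(0.4, 0.4, 0.2))), 0.05)
  expect_true(fit$stop_reason %in%
                c("max_evals", "max_iters", "step_tol", "ftol"))
})

test_that("unimodal and uniform profiles are fitted sensibly", {
  lap <- mixture_params(c(0.9, 0.05, 0.05), mu = c(0, 20), beta = c(5, 5))
  y <- simulate_profile(lap, 20000, seed = 7)
  fit <- fit_mixture(y, seed = 2)
  q_true <- promsig:::mixture_grid_probs(lap, -50:50)
  q_fit <- promsig:::mixture_grid_probs(fit$params, -50:50)
  expect_lt(abs(max(q_fit) - max(q_true)) / max(q_true), 0.1)

  u <- mixture_params(c(0, 0, 1), mu = c(0, 0), beta = c(1, 1))
  yu <- simulate_profile(u, 50000, seed = 8)
  fitu <- fit_mixture(yu, seed = 3)
  expect_gte(coef(fitu)["pi3"], 0.9)
})

test_that("fitting a reversed profile mirrors the location parameters", {
  truth <- mixture_params(c(0.45, 0.35, 0.2), mu = c(-15, 6), beta = c(4, 7))
  y <- simulate_profile(truth, 20000, seed = 31)
  f1 <- fit_mixture(y, seed = 4)
  f2 <- fit_mixture(rev(y), seed = 4)
  expect_equal(coef(f2)["mu1"], -coef(f1)["mu2"], tolerance = 0.5,
               ignore_attr = TRUE)
  expect_equal(coef(f2)["mu2"], -coef(f1)["mu1"], tolerance = 0.5,
               ignore_attr = TRUE)
  # canonical ordering holds on both
  expect_lte(coef(f1)["mu1"], coef(f1)["mu2"])
  expect_lte(coef(f2)["mu1"], coef(f2)["mu2"])
})

test_that("klmix model methods are coherent", {
  truth <- mixture_params(c(0.4, 0.4, 0.2), mu = c(-10, 10), beta = c(5, 5))
  y <- simulate_profile(truth, 5000, seed = 41)
  fit <- fit_mixture(y, seed = 5)
  expect_s3_class(fit, "klmix")
  expect_named(coef(fit), c("pi1", "pi2", "pi3", "mu1", "mu2", "beta1",
                            "beta2", "a", "b"))
  expect_equal(sum(coef(fit)[1:3]), 1, tolerance = 1e-9)
  expect_equal(sum(fitted(fit)), sum(y), tolerance = 1e-9)
  expect_equal(residuals(fit), y - fitted(fit))
  expect_equal(predict(fit, 0), mixture_density(0, fit$params))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(3, 101))
  expect_true(all(rowSums(sims) == round(sum(y))))
  expect_identical(simulate(fit, nsim = 3, seed = 9), sims)  # seeded
  expect_output(print(summary(fit)), "Restart objectives")
})

test_that("deterministic restarts: same seed, same fit", {
  y <- simulate_profile(random_seeded_params(77), 5000, seed = 77)
  f1 <- fit_mixture(y, seed = 10)
  f2 <- fit_mixture(y, seed = 10)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$objective, f2$objective)
})

test_that("signature models are fitted per cluster with sane templates", {
  shapes <- shape_library()[1:2]
  grid <- -50:50
  set.seed(55)
  n_per <- 12
  y1 <- rbind(t(replicate(n_per, c(rmultinom(1, 4000,
          promsig:::mixture_grid_probs(shapes[[1]]$pol2, grid))))),
        t(replicate(n_per, c(rmultinom(1, 4000,
          promsig:::mixture_grid_probs(shapes[[2]]$pol2, grid))))))
  y2 <- rbind(t(replicate(n_per, c(rmultinom(1, 4000,
          promsig:::mixture_grid_probs(shapes[[1]]$h3k4, grid))))),
        t(replicate(n_per, c(rmultinom(1, 4000,
          promsig:::mixture_grid_probs(shapes[[2]]$h3k4, grid))))))
  prof <- structure(list(
    tss = data.frame(chrom = "c", pos = seq_len(2 * n_per), strand = "+",
                     gene_id = paste0("g", seq_len(2 * n_per))),
    y1 = y1, y2 = y2, skipped = NULL, bin_width = 100L, half_bins = 50L),
    class = "tss_profiles")
  asg <- kmeans_correlation(profile_matrix(prof), 2, seed = 6)
  models <- fit_signature_models(asg, prof, seed = 6)
  expect_length(models, 2)
  for (m in models) {
    expect_length(m$template, 202)
    expect_false(m$degenerate)
    # template halves standardized: zero mean, unit norm
    expect_equal(mean(m$template[1:101]), 0, tolerance = 1e-9)
    expect_equal(sum(m$template[1:101]^2), 1, tolerance = 1e-9)
  }
  # each fitted Pol-II density correlates >= 0.99 with one generating density
  g1 <- promsig:::mixture_grid_probs(shapes[[1]]$pol2, grid)
  g2 <- promsig:::mixture_grid_probs(shapes[[2]]$pol2, grid)
  for (m in models) {
    qf <- promsig:::mixture_grid_probs(m$fit_pol2$params, grid)
    expect_gte(max(cor(qf, g1), cor(qf, g2)), 0.99)
  }
  bad <- asg; bad$labels <- rep(1L, length(asg$labels)); bad$k <- 2L
  expect_error(fit_signature_models(bad, prof, seed = 1), "no members")
})
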
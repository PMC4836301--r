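# Toy used throughout: 1 pathway, form b1, 10 probes (all members, mixed
# CGI), 5 pairs, pair effects off, variances known.
toy_setup <- function(seed = 7, m = 10, n = 5) {
  tf <- toy_features(m)
  spec <- model_spec("b1", include_pair_effect = FALSE)
  truth <- simulation_truth(spec, 1, gamma = 0.2, tau2_Y = 0.02,
                            tau2_N = 0.005, sigma2_eps = 0.01,
                            tau2_delta = 0)
  sim <- simulate_theta(tf$features, spec, truth, n_pairs = n, seed = seed)
  list(features = tf$features, spec = spec, theta = sim$theta,
       fixed = list(b_Y = 0, b_N = 0, tau2_Y = 0.02, tau2_N = 0.005,
                    sigma2_eps = 0.01))
}

test_that("preconditions reject degenerate designs", {
  tf <- toy_features(4)
  spec <- model_spec("b1", include_pair_effect = FALSE)
  th1 <- matrix(0.1, 1, 4)  # one pair only
  expect_error(run_gibbs(th1, spec, pm_priors(), tf$features,
                         quick_config()), "at least 2 pairs")
  # pathway with zero member probes
  pc <- pathway_collection(list(
    list(id = "P1", genes = "g01", edges = NULL),
    list(id = "PX", genes = "nosuchgene", edges = NULL)))
  ann <- data.frame(probe_id = c("a", "b"), gene_symbol = c("g01", "g01"),
                    cgi_status = c(TRUE, FALSE))
  ft <- assemble_features(ann, pc)
  expect_error(run_gibbs(matrix(0.1, 3, 2), spec, pm_priors(), ft,
                         quick_config()), "zero member probes")
})

test_that("same seed reproduces draws exactly; different seeds differ", {
  ts <- toy_setup()
  cfg <- quick_config(seed = 42, n_iter = 400, n_burnin = 100, thin = 1)
  f1 <- run_gibbs(ts$theta, ts$spec, pm_priors(), ts$features, cfg,
                  fixed = ts$fixed)
  f2 <- run_gibbs(ts$theta, ts$spec, pm_priors(), ts$features, cfg,
                  fixed = ts$fixed)
  expect_identical(extract_draws(f1, "gamma"), extract_draws(f2, "gamma"))
  cfg2 <- quick_config(seed = 43, n_iter = 400, n_burnin = 100, thin = 1)
  f3 <- run_gibbs(ts$theta, ts$spec, pm_priors(), ts$features, cfg2,
                  fixed = ts$fixed)
  expect_false(identical(extract_draws(f1, "gamma"),
                         extract_draws(f3, "gamma")))
})

test_that("Gibbs posterior of gamma matches the conjugate closed form", {
  ts <- toy_setup(seed = 31)
  fit <- run_gibbs(ts$theta, ts$spec, pm_priors(), ts$features,
                   mcmc_config(n_iter = 6000, n_burnin = 500, thin = 1,
                               n_chains = 1, seed = 9),
                   fixed = ts$fixed)
  g <- extract_draws(fit, "gamma")[, 1]
  orc <- conjugate_posterior_oracle(ts$theta, ts$features, sigma2 = 0.01,
                                    tau2_Y = 0.02, tau2_N = 0.005)
  mcse <- sd(g) / sqrt(length(g))  # block draw => essentially iid
  expect_lt(abs(mean(g) - orc$mean), 4 * mcse)
  expect_lt(abs(var(g) - orc$var), 4 * orc$var * sqrt(2 / length(g)))
})

test_that("conjugate oracle obeys its flat-prior and point-mass limits", {
  ts <- toy_setup(seed = 5)
  x <- as.numeric(ts$features$membership[, 1])
  w <- ifelse(ts$features$cgi, 0.02, 0.005) + 0.01 / 5
  ybar <- colMeans(ts$theta$theta)
  wls <- sum(x * ybar / w) / sum(x^2 / w)  # weighted least squares
  flat <- conjugate_posterior_oracle(ts$theta, ts$features, 0.01, 0.02,
                                     0.005,
                                     priors = pm_priors(gamma_var = 1e12))
  expect_equal(flat$mean, wls, tolerance = 1e-6)
  point <- conjugate_posterior_oracle(ts$theta, ts$features, 0.01, 0.02,
                                      0.005,
                                      priors = pm_priors(gamma_var = 1e-12))
  expect_lt(abs(point$mean), 1e-6)
})

test_that("oracle agrees with brute-force nested quadrature", {
  # independent route: integrate the likelihood over beta_j numerically for
  # each gamma on a grid, then take posterior moments by trapezoid weights
  tf <- toy_features(4)
  spec <- model_spec("b1", include_pair_effect = FALSE)
  truth <- simulation_truth(spec, 1, gamma = 0.1, b_Y = 0.01, b_N = -0.01,
                            tau2_Y = 0.02, tau2_N = 0.005,
                            sigma2_eps = 0.01, tau2_delta = 0)
  sim <- simulate_theta(tf$features, spec, truth, n_pairs = 3, seed = 17)
  th <- sim$theta$theta
  pr <- pm_priors(gamma_var = 0.25)
  cgi <- tf$features$cgi
  x <- as.numeric(tf$features$membership[, 1])

  gamma_grid <- seq(-0.8, 0.9, by = 0.001)
  beta_grid <- seq(-1.2, 1.2, by = 0.002)
  log_post <- vapply(gamma_grid, function(g) {
    ll <- 0
    for (j in 1:4) {
      f <- dnorm(beta_grid, if (cgi[j]) 0.01 else -0.01,
                 sqrt(if (cgi[j]) 0.02 else 0.005))
      for (i in 1:3)
        f <- f * dnorm(th[i, j], beta_grid + x[j] * g, sqrt(0.01))
      ll <- ll + log(sum(f) * 0.002)
    }
    ll + dnorm(g, 0, sqrt(0.25), log = TRUE)
  }, numeric(1))
  w <- exp(log_post - max(log_post))
  w <- w / sum(w)
  quad_mean <- sum(w * gamma_grid)
  quad_var <- sum(w * (gamma_grid - quad_mean)^2)

  orc <- conjugate_posterior_oracle(sim$theta, tf$features, 0.01, 0.02,
                                    0.005, b_Y = 0.01, b_N = -0.01,
                                    priors = pr)
  expect_equal(quad_mean, orc$mean, tolerance = 1e-4)
  expect_equal(quad_var, orc$var, tolerance = 1e-4)
})

test_that("split R-hat is 1 for identical chains and large for disjoint ones", {
  ts <- toy_setup()
  cfg <- quick_config(seed = 1, n_iter = 300, n_burnin = 100, thin = 1)
  fit <- run_gibbs(ts$theta, ts$spec, pm_priors(), ts$features, cfg,
                   fixed = ts$fixed)
  fake <- fit
  fake$chains <- list(fit$chains[[1]], fit$chains[[1]])  # exact copies
  # duplicate chains contribute no between-chain variance: R-hat ~ 1
  expect_true(all(abs(gelman_rubin(fake) - 1) < 0.05))
  const <- fake
  for (ch in 1:2) {
    const$chains[[ch]]$gamma[] <- c(0, 10)[ch]
    const$chains[[ch]]$b[] <- c(0, 10)[ch]
  }
  r_const <- gelman_rubin(const)
  expect_gt(r_const[["P1"]], 10)

  # long well-mixed chains on the conjugate toy stay near 1
  fit2 <- run_gibbs(ts$theta, ts$spec, pm_priors(), ts$features,
                    mcmc_config(n_iter = 3000, n_burnin = 500, thin = 1,
                                n_chains = 2, seed = 2),
                    fixed = ts$fixed)
  expect_lt(max(gelman_rubin(fit2)), 1.05)
})

test_that("gamma prior variance -> 0 reproduces the null model's beta posterior", {
  tf <- toy_features(8)
  spec_b1 <- model_spec("b1", include_pair_effect = FALSE)
  spec_a <- model_spec("a", include_pair_effect = FALSE)
  truth <- simulation_truth(spec_a, 1, b_Y = 0.05, b_N = -0.02,
                            tau2_Y = 0.02, tau2_N = 0.005,
                            sigma2_eps = 0.01, tau2_delta = 0)
  sim <- simulate_theta(tf$features, spec_a, truth, n_pairs = 20, seed = 23)
  cfg <- mcmc_config(n_iter = 4000, n_burnin = 1000, thin = 1,
                     n_chains = 1, seed = 3)
  fit_b1 <- run_gibbs(sim$theta, spec_b1, pm_priors(gamma_var = 1e-10),
                      tf$features, cfg)
  fit_a <- run_gibbs(sim$theta, spec_a, pm_priors(), tf$features, cfg)
  beta_b1 <- colMeans(extract_draws(fit_b1, "beta"))
  beta_a <- colMeans(extract_draws(fit_a, "beta"))
  mcse <- apply(extract_draws(fit_a, "beta"), 2, sd) / sqrt(3000)
  expect_true(all(abs(beta_b1 - beta_a) < 6 * mcse + 1e-4))
})

test_that("Geweke joint-distribution check: sweeps preserve the generative law", {
  # marginal-conditional draws (prior + data) vs successive-conditional
  # draws (sweep + data re-simulation) must share the parameter marginals;
  # the pathway holds only half the genes so gamma and b_Y mix freely
  genes <- sprintf("g%02d", 1:6)
  pw <- pathway_collection(list(list(id = "P1", genes = genes[1:3],
                                     edges = NULL)))
  ann <- data.frame(probe_id = sprintf("cg%03d", 1:6), gene_symbol = genes,
                    cgi_status = rep(c(TRUE, FALSE), 3))
  tf <- list(features = assemble_features(ann, pw))
  spec <- model_spec("b1", include_pair_effect = TRUE)
  # moderately informative priors keep the prior draws on a sane scale
  pr <- pm_priors(b_mean = 0, b_var = 0.04, gamma_mean = 0,
                  gamma_var = 0.04, tau2_shape = 6, tau2_rate = 0.1,
                  sigma2_shape = 6, sigma2_rate = 0.05,
                  delta_shape = 6, delta_rate = 0.02)
  n <- 4
  R <- 5000        # marginal-conditional (iid) sample size
  R_sc <- 15000    # successive-conditional sweeps, thinned by 3
  draw_prior_state <- function() {
    b <- rnorm(2, pr$b_mean, sqrt(pr$b_var))
    names(b) <- c("b_Y", "b_N")
    tau2 <- c(tau2_Y = 1 / rgamma(1, pr$tau2_shape, rate = pr$tau2_rate),
              tau2_N = 1 / rgamma(1, pr$tau2_shape, rate = pr$tau2_rate))
    sigma2 <- 1 / rgamma(1, pr$sigma2_shape, rate = pr$sigma2_rate)
    tau2_delta <- 1 / rgamma(1, pr$delta_shape, rate = pr$delta_rate)
    beta <- rnorm(6, ifelse(tf$features$cgi, b["b_Y"], b["b_N"]),
                  sqrt(ifelse(tf$features$cgi, tau2["tau2_Y"],
                              tau2["tau2_N"])))
    list(beta = beta, gamma = rnorm(1, pr$gamma_mean, sqrt(pr$gamma_var)),
         b = b, tau2 = tau2, sigma2 = sigma2,
         delta = rnorm(n, 0, sqrt(tau2_delta)), tau2_delta = tau2_delta)
  }
  ctx0 <- pathmeth:::gibbs_context(matrix(0, n, 6), spec, pr, tf$features)

  set.seed(101)
  mc <- matrix(NA_real_, R, 4)  # b_Y, gamma, log sigma2, log tau2_Y
  for (r in 1:R) {
    st <- draw_prior_state()
    mc[r, ] <- c(st$b[["b_Y"]], st$gamma, log(st$sigma2),
                 log(st$tau2[["tau2_Y"]]))
  }
  set.seed(202)
  sc <- matrix(NA_real_, R_sc, 4)
  st <- draw_prior_state()
  for (r in 1:R_sc) {
    th <- pathmeth:::simulate_theta_given_state(st, ctx0)
    ctx <- pathmeth:::gibbs_context(th, spec, pr, tf$features)
    st <- pathmeth:::gibbs_sweep(st, th, ctx)
    sc[r, ] <- c(st$b[["b_Y"]], st$gamma[1], log(st$sigma2[1]),
                 log(st$tau2[["tau2_Y"]]))
  }
  sc <- sc[seq(3, R_sc, by = 3), ]
  for (k in 1:4) {
    ks <- suppressWarnings(ks.test(mc[, k], sc[, k]))$statistic
    expect_lt(unname(ks), 0.07)
  }
})
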
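test_that("posterior sign probability counts strictly positive draws", {
  expect_equal(posterior_sign_probability(c(1, 2, 3, -1)), 0.75)
  expect_equal(posterior_sign_probability(c(-2, -0.1)), 0)
  expect_equal(posterior_sign_probability(c(0, 0, 1, -1)), 0.25)  # ties
  set.seed(6)
  p <- posterior_sign_probability(rnorm(10000))
  expect_lt(abs(p - 0.5), 0.02)
})

test_that("score of strength rescales the distance from indifference", {
  expect_equal(score_of_strength(0.5), 0)
  expect_equal(score_of_strength(0.96), 0.92)
  expect_equal(score_of_strength(0.01), 0.98)
  ps <- seq(0, 1, by = 0.05)
  expect_equal(score_of_strength(ps), score_of_strength(1 - ps))  # symmetry
  expect_error(score_of_strength(1.2), "p >= 0")
})

test_that("a degenerate posterior has pD = 0 and DIC equal to the plug-in deviance", {
  # all parameters fixed and beta pinned (tau2 = 0): every draw identical
  tf <- toy_features(4)
  spec <- model_spec("a", include_pair_effect = FALSE)
  truth <- simulation_truth(spec, 1, b_Y = 0.1, b_N = 0.1, tau2_Y = 0,
                            tau2_N = 0, sigma2_eps = 0.01, tau2_delta = 0)
  sim <- simulate_theta(tf$features, spec, truth, n_pairs = 4, seed = 2)
  fit <- run_gibbs(sim$theta, spec, pm_priors(), tf$features,
                   quick_config(n_iter = 200, n_burnin = 50, thin = 1),
                   fixed = list(b_Y = 0.1, b_N = 0.1, tau2_Y = 0,
                                tau2_N = 0, sigma2_eps = 0.01))
  d <- compute_dic(fit, sim$theta)
  expect_equal(d$p_d, 0, tolerance = 1e-10)
  expect_equal(d$dic, d$plugin_deviance, tolerance = 1e-10)
})

test_that("the conjugate toy has about one effective parameter", {
  tf <- toy_features(10)
  spec <- model_spec("b1", include_pair_effect = FALSE)
  truth <- simulation_truth(spec, 1, gamma = 0.2, tau2_Y = 0, tau2_N = 0,
                            sigma2_eps = 0.01, tau2_delta = 0)
  fx <- list(b_Y = 0, b_N = 0, tau2_Y = 0, tau2_N = 0, sigma2_eps = 0.01)
  pds <- vapply(1:5, function(s) {
    sim <- simulate_theta(tf$features, spec, truth, n_pairs = 5, seed = s)
    fit <- run_gibbs(sim$theta, spec, pm_priors(), tf$features,
                     mcmc_config(n_iter = 3000, n_burnin = 500, thin = 1,
                                 n_chains = 1, seed = s + 100), fixed = fx)
    compute_dic(fit, sim$theta)$p_d
  }, numeric(1))
  expect_lt(abs(mean(pds) - 1), 0.25)
})

test_that("model ranking follows DIC with a parsimony tie-break", {
  r <- rank_models(c(a = 100, b1 = 90), n_pathways = 3)
  expect_identical(r$selected, "b1")
  expect_identical(r$table$form, c("b1", "a"))
  # indistinguishable DICs: fewer parameters wins
  r2 <- rank_models(c(b1 = 90.5, b2 = 90.0), n_pathways = 3, margin = 2)
  expect_identical(r2$selected, "b1")
  # strict minimum at margin 0
  r3 <- rank_models(c(b1 = 90.5, b2 = 90.0), n_pathways = 3, margin = 0)
  expect_identical(r3$selected, "b2")
  # clearly separated DICs ignore parsimony
  r4 <- rank_models(c(b1 = 95, b2 = 90.0), n_pathways = 3, margin = 2)
  expect_identical(r4$selected, "b2")
})

test_that("DMP/DMG calling applies the BPP threshold and gene rules", {
  lam <- cbind(p1 = c(rep(1, 98), rep(-1, 2)),     # P(>0) = 0.98 -> hyper
               p2 = c(rep(-1, 99), 1),             # hypo
               p3 = rep(c(1, -1), 50),             # none
               p4 = c(rep(1, 60), rep(-1, 40)))    # none
  genes <- c("G1", "G1", "G2", "G2")
  calls <- call_dmps_dmgs(lam, threshold = 0.975,
                          probe_ids = colnames(lam), genes = genes)
  expect_identical(calls$probes$direction, c("hyper", "hypo", "none", "none"))
  g1 <- calls$genes[calls$genes$gene == "G1", ]
  expect_true(g1$dmg)
  expect_identical(g1$direction, "hyper+hypo")  # both directions reported
  expect_false(calls$genes$dmg[calls$genes$gene == "G2"])

  # all probabilities at 0.5: no DMG at any sensible threshold
  lam0 <- matrix(rep(c(1, -1), 50), 100, 2)
  colnames(lam0) <- c("q1", "q2")
  calls0 <- call_dmps_dmgs(lam0, probe_ids = colnames(lam0),
                           genes = c("H1", "H2"))
  expect_false(any(calls0$genes$dmg))

  # ALL-probe rule: G1 (both probes flagged, opposite directions) stays a
  # DMG, but no single direction reaches all of its probes
  calls_all <- call_dmps_dmgs(lam, gene_rule = "all",
                              probe_ids = colnames(lam), genes = genes)
  expect_true(calls_all$genes$dmg[calls_all$genes$gene == "G1"])
  expect_false(calls_all$genes$hyper[calls_all$genes$gene == "G1"])
  expect_false(calls_all$genes$dmg[calls_all$genes$gene == "G2"])
  expect_error(call_dmps_dmgs(lam, threshold = 0.4,
                              probe_ids = colnames(lam), genes = genes),
               "threshold")
})

test_that("the DMG set shrinks monotonically in the threshold", {
  set.seed(14)
  lam <- matrix(rnorm(200 * 30, mean = rep(runif(30, -0.1, 0.1), each = 200),
                      sd = 0.05), 200, 30)
  colnames(lam) <- sprintf("p%02d", 1:30)
  genes <- rep(sprintf("g%02d", 1:10), each = 3)
  prev <- Inf
  for (thr in c(0.6, 0.8, 0.95, 0.99)) {
    calls <- call_dmps_dmgs(lam, threshold = thr,
                            probe_ids = colnames(lam), genes = genes)
    n_dmg <- sum(calls$genes$dmg)
    expect_lte(n_dmg, prev)
    prev <- n_dmg
  }
})

test_that("pathway report carries sign probabilities, scores and intervals", {
  # membership must not cover every probe, or gamma is confounded with the
  # stratum means: P1 holds half of the 12 one-probe genes
  genes <- sprintf("g%02d", 1:12)
  pc <- pathway_collection(list(list(id = "P1", genes = genes[1:6],
                                     edges = NULL)))
  ann <- data.frame(probe_id = sprintf("cg%03d", 1:12), gene_symbol = genes,
                    cgi_status = rep(c(TRUE, FALSE), 6))
  ft <- assemble_features(ann, pc)
  tf <- list(features = ft)
  spec <- model_spec("b1", include_pair_effect = FALSE)
  truth <- simulation_truth(spec, 1, gamma = 0.3, tau2_Y = 0.01,
                            tau2_N = 0.01, sigma2_eps = 0.01,
                            tau2_delta = 0)
  sim <- simulate_theta(tf$features, spec, truth, n_pairs = 30, seed = 4)
  fit <- run_gibbs(sim$theta, spec, pm_priors(), tf$features,
                   quick_config(seed = 8))
  rep1 <- pathway_report(fit)
  expect_equal(nrow(rep1), 1L)
  expect_identical(rep1$stratum, "all")
  expect_equal(rep1$score_of_strength,
               2 * abs(rep1$p_positive - 0.5))
  expect_lte(rep1$gamma_lower, rep1$gamma_upper)
  expect_gt(rep1$p_positive, 0.9)  # strong positive truth

  # CGI-dependent form reports Y and N rows per pathway
  spec2 <- model_spec("b2", include_pair_effect = FALSE)
  fit2 <- run_gibbs(sim$theta, spec2, pm_priors(), tf$features,
                    quick_config(seed = 8))
  rep2 <- pathway_report(fit2)
  expect_equal(nrow(rep2), 2L)
  expect_setequal(rep2$stratum, c("Y", "N"))
})
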
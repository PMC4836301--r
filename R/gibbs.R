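#' MCMC configuration
#'
#' @param n_iter Total Gibbs iterations per chain.
#' @param n_burnin Burn-in iterations discarded from the front
#'   (`n_iter > n_burnin >= 0`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of independent chains.
#' @param seed RNG seed recorded with the run.
#' @param init Initialisation: `"prior"` draws location parameters from
#'   their priors (variances start at the prior mode); `"zeros"` starts all
#'   locations at 0 and variances at 0.01.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(n_iter = 12000, n_burnin = 2000, thin = 5,
                        n_chains = 2, seed = 1,
                        init = c("prior", "zeros")) {
  init <- match.arg(init)
  stopifnot(n_iter > n_burnin, n_burnin >= 0, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 init = init),
            class = "mcmc_config")
}

# Immutable per-run context shared by all sweeps: design, strata, priors,
# and which parameters are held fixed.
gibbs_context <- function(th, spec, priors, features, fixed = list()) {
  n <- nrow(th)
  m <- ncol(th)
  if (n < 2L || m < 2L)
    stop("need at least 2 pairs and 2 probes to fit the model")
  if (!is.null(features$probe_ids) &&
      !is.null(colnames(th)) &&
      !identical(colnames(th), features$probe_ids))
    stop("theta probe order does not match the feature block")
  X <- gamma_design(spec, features)
  if (ncol(X) > 0L) {
    empty <- colSums(features$membership) == 0L
    if (any(empty))
      stop("degenerate design: pathway(s) with zero member probes: ",
           paste(features$pathway_ids[empty], collapse = ", "))
  }
  allowed <- c("b_Y", "b_N", "tau2_Y", "tau2_N", "sigma2_eps", "tau2_delta")
  bad <- setdiff(names(fixed), allowed)
  if (length(bad) > 0L)
    stop("cannot fix unknown parameter(s): ", paste(bad, collapse = ", "))
  for (s in c("Y", "N")) {
    tname <- paste0("tau2_", s)
    if (!is.null(fixed[[tname]]) && fixed[[tname]] == 0 &&
        is.null(fixed[[paste0("b_", s)]]))
      stop(tname, " fixed at 0 pins beta to b_", s,
           "; fix b_", s, " as well")
  }
  cgi <- features$cgi
  # Z carries the stratum intercept columns ahead of the gamma design; the
  # (b_Y, b_N, gamma) block is drawn jointly with beta collapsed out.
  Z <- cbind(b_Y = as.numeric(cgi), b_N = as.numeric(!cgi), X)
  list(n = n, m = m, X = X, Z = Z, p = ncol(X), cgi = cgi,
       strat = ifelse(cgi, 1L, 2L),   # 1 = CGI stratum, 2 = non-CGI
       m_Y = sum(cgi), m_N = sum(!cgi),
       colsum = colSums(th), spec = spec, priors = priors, fixed = fixed,
       n_sigma = if (spec$stratum_noise) 2L else 1L)
}

.rinvgamma <- function(shape, rate) {
  g <- stats::rgamma(1L, shape = shape, rate = rate)
  # guard against under/overflow in vague-prior draws for empty strata
  min(max(1 / g, 1e-12), 1e12)
}

# Per-probe observation variance vector from the (1 or 2 component) sigma2
.sigma2_by_probe <- function(sigma2, ctx) {
  if (ctx$n_sigma == 1L) rep(sigma2[1L], ctx$m)
  else unname(sigma2[ctx$strat])
}

gibbs_init <- function(ctx, init = "prior") {
  pr <- ctx$priors
  ig_mode <- function(shape, rate) rate / (shape + 1)
  if (init == "prior") {
    b <- stats::rnorm(2L, pr$b_mean, sqrt(min(pr$b_var, 1)))
    gamma <- stats::rnorm(ctx$p, pr$gamma_mean, sqrt(min(pr$gamma_var, 1)))
    tau2 <- rep(ig_mode(pr$tau2_shape, pr$tau2_rate), 2L)
    sigma2 <- rep(ig_mode(pr$sigma2_shape, pr$sigma2_rate), ctx$n_sigma)
    tau2_delta <- ig_mode(pr$delta_shape, pr$delta_rate)
  } else {
    b <- c(0, 0)
    gamma <- numeric(ctx$p)
    tau2 <- c(0.01, 0.01)
    sigma2 <- rep(0.01, ctx$n_sigma)
    tau2_delta <- 0.01
  }
  names(b) <- c("b_Y", "b_N")
  names(tau2) <- c("tau2_Y", "tau2_N")
  fx <- ctx$fixed
  for (nm in c("b_Y", "b_N")) if (!is.null(fx[[nm]])) b[nm] <- fx[[nm]]
  for (nm in c("tau2_Y", "tau2_N")) if (!is.null(fx[[nm]])) tau2[nm] <- fx[[nm]]
  if (!is.null(fx$sigma2_eps)) sigma2 <- rep_len(fx$sigma2_eps, ctx$n_sigma)
  if (!is.null(fx$tau2_delta)) tau2_delta <- fx$tau2_delta
  b_probe <- ifelse(ctx$cgi, b["b_Y"], b["b_N"])
  tau2_probe <- ifelse(ctx$cgi, tau2["tau2_Y"], tau2["tau2_N"])
  beta <- ifelse(tau2_probe == 0, b_probe,
                 stats::rnorm(ctx$m, b_probe, sqrt(tau2_probe)))
  delta <- if (ctx$spec$include_pair_effect && tau2_delta > 0)
    stats::rnorm(ctx$n, 0, sqrt(tau2_delta)) else numeric(ctx$n)
  list(beta = beta, gamma = gamma, b = b, tau2 = tau2, sigma2 = sigma2,
       delta = delta, tau2_delta = tau2_delta)
}

# One systematic-scan sweep over all full conditionals (all conjugate).
gibbs_sweep <- function(state, th, ctx) {
  pr <- ctx$priors
  fx <- ctx$fixed
  n <- ctx$n
  sig2j <- .sigma2_by_probe(state$sigma2, ctx)
  tau2_probe <- unname(state$tau2[ctx$strat])
  sum_delta <- sum(state$delta)

  # (b_Y, b_N, gamma) | theta, delta, variances — a single block draw with
  # beta_j collapsed out: the probe means thetabar_j - deltabar are
  # independent N(b_s(j) + x_j' gamma, tau2_s(j) + sigma2_j / n), so the
  # block posterior is Gaussian.  Blocking breaks the beta/gamma/intercept
  # confounding that cripples single-site scans on this hierarchy.
  w <- tau2_probe + sig2j / n
  ybar <- ctx$colsum / n - sum_delta / n
  free_b <- c(is.null(fx$b_Y), is.null(fx$b_N))
  cols <- c(which(free_b), if (ctx$p > 0L) 2L + seq_len(ctx$p))
  if (length(cols) > 0L) {
    off <- numeric(ctx$m)
    if (!free_b[1L]) off <- off + ctx$Z[, 1L] * state$b[["b_Y"]]
    if (!free_b[2L]) off <- off + ctx$Z[, 2L] * state$b[["b_N"]]
    Zf <- ctx$Z[, cols, drop = FALSE]
    prior_prec <- c(rep(1 / pr$b_var, 2L),
                    rep(1 / pr$gamma_var, ctx$p))[cols]
    prior_mean <- c(rep(pr$b_mean, 2L),
                    rep(pr$gamma_mean, ctx$p))[cols]
    A <- crossprod(Zf / sqrt(w)) + diag(prior_prec, length(cols))
    bv <- drop(crossprod(Zf, (ybar - off) / w)) + prior_prec * prior_mean
    U <- chol(A)
    mu_blk <- backsolve(U, backsolve(U, bv, transpose = TRUE))
    draw <- drop(mu_blk + backsolve(U, stats::rnorm(length(cols))))
    for (i in seq_along(cols)) {
      cl <- cols[i]
      if (cl == 1L) state$b[["b_Y"]] <- draw[i]
      else if (cl == 2L) state$b[["b_N"]] <- draw[i]
      else state$gamma[cl - 2L] <- draw[i]
    }
  }
  b_probe <- unname(state$b[ctx$strat])

  # beta_j | rest: N; probes with tau2 = 0 are pinned to their stratum mean
  phi <- if (ctx$p > 0L) drop(ctx$X %*% state$gamma) else numeric(ctx$m)
  free <- tau2_probe > 0
  resid_sum <- ctx$colsum - n * phi - sum_delta
  itau <- numeric(ctx$m)
  itau[free] <- 1 / tau2_probe[free]
  prec <- n / sig2j + itau
  mean_b <- (resid_sum / sig2j + b_probe * itau) / prec
  beta <- stats::rnorm(ctx$m, mean_b, sqrt(1 / prec))
  beta[!free] <- b_probe[!free]
  state$beta <- beta
  lambda <- state$beta + phi

  # delta_i | rest: N, shared precision across pairs
  if (ctx$spec$include_pair_effect) {
    if (state$tau2_delta == 0) {
      state$delta <- numeric(ctx$n)
    } else {
      isig <- 1 / sig2j
      prec_d <- sum(isig) + 1 / state$tau2_delta
      mean_d <- (drop(th %*% isig) - sum(lambda * isig)) / prec_d
      state$delta <- stats::rnorm(ctx$n, mean_d, sqrt(1 / prec_d))
    }
  }

  # stratum variances tau2_Y, tau2_N | rest (the stratum means were drawn
  # in the collapsed block above)
  for (s in c("Y", "N")) {
    in_s <- if (s == "Y") ctx$cgi else !ctx$cgi
    ms <- sum(in_s)
    tname <- paste0("tau2_", s)
    if (is.null(fx[[tname]])) {
      ss <- if (ms > 0L)
        sum((state$beta[in_s] - state$b[[paste0("b_", s)]])^2) else 0
      state$tau2[tname] <- .rinvgamma(pr$tau2_shape + ms / 2,
                                      pr$tau2_rate + ss / 2)
    }
  }

  # pair-effect variance
  if (ctx$spec$include_pair_effect && is.null(fx$tau2_delta))
    state$tau2_delta <- .rinvgamma(pr$delta_shape + ctx$n / 2,
                                   pr$delta_rate + sum(state$delta^2) / 2)

  # observation noise (shared or per CGI stratum)
  if (is.null(fx$sigma2_eps)) {
    resid <- th - matrix(lambda, ctx$n, ctx$m, byrow = TRUE) - state$delta
    cs <- colSums(resid^2)
    if (ctx$n_sigma == 1L) {
      state$sigma2 <- .rinvgamma(pr$sigma2_shape + n * ctx$m / 2,
                                 pr$sigma2_rate + sum(cs) / 2)
    } else {
      state$sigma2 <- c(
        .rinvgamma(pr$sigma2_shape + n * ctx$m_Y / 2,
                   pr$sigma2_rate + sum(cs[ctx$cgi]) / 2),
        .rinvgamma(pr$sigma2_shape + n * ctx$m_N / 2,
                   pr$sigma2_rate + sum(cs[!ctx$cgi]) / 2))
    }
  }
  state$lambda <- lambda
  state
}

# Simulate a theta matrix from the current state (Geweke-style checks).
simulate_theta_given_state <- function(state, ctx) {
  lambda <- state$beta + if (ctx$p > 0L) drop(ctx$X %*% state$gamma) else 0
  mu <- matrix(lambda, ctx$n, ctx$m, byrow = TRUE)
  if (ctx$spec$include_pair_effect) mu <- mu + state$delta
  sig2j <- .sigma2_by_probe(state$sigma2, ctx)
  mu + matrix(stats::rnorm(ctx$n * ctx$m, 0, rep(sqrt(sig2j), each = ctx$n)),
              ctx$n, ctx$m)
}

.state_deviance <- function(state, th, ctx) {
  lambda <- state$lambda
  mu <- matrix(lambda, ctx$n, ctx$m, byrow = TRUE)
  if (ctx$spec$include_pair_effect) mu <- mu + state$delta
  deviance_theta(th, mu, .sigma2_by_probe(state$sigma2, ctx))
}

#' Fit the hierarchical methylation model by Gibbs sampling
#'
#' Systematic-scan Gibbs sampler: every full conditional is conjugate
#' (normal for beta, gamma, b, delta; inverse-gamma for the variance
#' components), so no Metropolis step is needed.  Draws of the probe-level
#' effect lambda are stored per iteration so that probe/gene probabilities
#' are computed from exactly the sampled states.
#'
#' @param theta A `paired_diff` (or plain n x m matrix with probes in
#'   feature order).
#' @param spec A `model_spec`.
#' @param priors A `pm_priors`.
#' @param features A `probe_features` matching the probe order of `theta`.
#' @param config An `mcmc_config`.
#' @param fixed Named list of parameters held fixed (not updated): any of
#'   `b_Y`, `b_N`, `tau2_Y`, `tau2_N`, `sigma2_eps`, `tau2_delta`.  Fixing
#'   `tau2_Y`/`tau2_N` at 0 pins the corresponding beta_j at the stratum
#'   mean (which must then also be fixed).
#' @return A `pm_fit` object holding per-chain, post-burn-in, thinned draws
#'   of every parameter block plus the per-draw deviance.
#' @export
run_gibbs <- function(theta, spec, priors = pm_priors(), features,
                      config = mcmc_config(), fixed = list()) {
  th <- if (inherits(theta, "paired_diff")) theta$theta else as.matrix(theta)
  stopifnot(inherits(spec, "model_spec"), inherits(priors, "pm_priors"),
            inherits(features, "probe_features"),
            inherits(config, "mcmc_config"))
  ctx <- gibbs_context(th, spec, priors, features, fixed)
  n_keep <- (config$n_iter - config$n_burnin) %/% config$thin
  if (n_keep < 1L) stop("no draws kept: check n_iter/n_burnin/thin")

  set.seed(config$seed)
  gnames <- colnames(ctx$X)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    state <- gibbs_init(ctx, config$init)
    draws <- list(
      gamma = matrix(NA_real_, n_keep, ctx$p,
                     dimnames = list(NULL, gnames)),
      beta = matrix(NA_real_, n_keep, ctx$m,
                    dimnames = list(NULL, features$probe_ids)),
      lambda = matrix(NA_real_, n_keep, ctx$m,
                      dimnames = list(NULL, features$probe_ids)),
      b = matrix(NA_real_, n_keep, 2L, dimnames = list(NULL, c("b_Y", "b_N"))),
      tau2 = matrix(NA_real_, n_keep, 2L,
                    dimnames = list(NULL, c("tau2_Y", "tau2_N"))),
      sigma2 = matrix(NA_real_, n_keep, ctx$n_sigma,
                      dimnames = list(NULL, if (ctx$n_sigma == 1L) "sigma2_eps"
                                      else c("sigma2_Y", "sigma2_N"))),
      delta = matrix(NA_real_, n_keep,
                     if (spec$include_pair_effect) ctx$n else 0L),
      tau2_delta = matrix(NA_real_, n_keep, 1L,
                          dimnames = list(NULL, "tau2_delta")),
      deviance = numeric(n_keep))
    kept <- 0L
    for (t in seq_len(config$n_iter)) {
      state <- gibbs_sweep(state, th, ctx)
      if (t > config$n_burnin &&
          (t - config$n_burnin) %% config$thin == 0L) {
        kept <- kept + 1L
        if (!all(is.finite(c(state$beta, state$gamma, state$b, state$tau2,
                             state$sigma2, state$tau2_delta))))
          stop("non-finite parameter state at iteration ", t)
        draws$gamma[kept, ] <- state$gamma
        draws$beta[kept, ] <- state$beta
        draws$lambda[kept, ] <- state$lambda
        draws$b[kept, ] <- state$b
        draws$tau2[kept, ] <- state$tau2
        draws$sigma2[kept, ] <- state$sigma2
        if (spec$include_pair_effect) draws$delta[kept, ] <- state$delta
        draws$tau2_delta[kept, ] <- state$tau2_delta
        draws$deviance[kept] <- .state_deviance(state, th, ctx)
      }
    }
    chains[[ch]] <- draws
  }
  structure(list(chains = chains, spec = spec, priors = priors,
                 config = config, fixed = fixed,
                 probe_ids = features$probe_ids,
                 genes = features$genes,
                 pathway_ids = features$pathway_ids,
                 cgi = features$cgi,
                 gamma_names = gnames,
                 n_pairs = ctx$n),
            class = "pm_fit")
}

#' @export
print.pm_fit <- function(x, ...) {
  cat(sprintf("pm_fit: form %s, %d chain(s) x %d draws, %d probes, %d pathway(s)\n",
              x$spec$form, length(x$chains), nrow(x$chains[[1L]]$beta),
              length(x$probe_ids), length(x$pathway_ids)))
  invisible(x)
}

#' Pool posterior draws of one parameter block across chains
#'
#' @param fit A `pm_fit`.
#' @param component One of `"gamma"`, `"beta"`, `"lambda"`, `"b"`, `"tau2"`,
#'   `"sigma2"`, `"delta"`, `"tau2_delta"`, `"deviance"`.
#' @return Matrix (draws x dimension) or vector for `"deviance"`.
#' @export
extract_draws <- function(fit, component) {
  stopifnot(inherits(fit, "pm_fit"))
  parts <- lapply(fit$chains, `[[`, component)
  if (component == "deviance") return(unlist(parts, use.names = FALSE))
  do.call(rbind, parts)
}

#' Closed-form posterior of gamma for the conjugate toy model
#'
#' Independent test oracle for the sampler: single pathway, form `b1`, no
#' pair effects, all variance components (and stratum means) known.  With
#' beta_j marginalised, the probe means thetabar_j are independent normals
#' with variance `tau2_(stratum) + sigma2/n`, giving an exact Gaussian
#' posterior for gamma by weighted-least-squares algebra.
#'
#' @param theta A `paired_diff` or n x m matrix.
#' @param features A `probe_features` with a single pathway.
#' @param sigma2 Known observation variance.
#' @param tau2_Y,tau2_N Known CGI-stratum variances of beta_j.
#' @param b_Y,b_N Known stratum means of beta_j (default 0).
#' @param priors A `pm_priors` (only the gamma prior is used).
#' @return List with `mean` and `var` of the Gaussian posterior of gamma.
#' @export
conjugate_posterior_oracle <- function(theta, features, sigma2, tau2_Y,
                                       tau2_N, b_Y = 0, b_N = 0,
                                       priors = pm_priors()) {
  th <- if (inherits(theta, "paired_diff")) theta$theta else as.matrix(theta)
  stopifnot(length(features$pathway_ids) == 1L)
  n <- nrow(th)
  x <- as.numeric(features$membership[, 1L])
  w <- ifelse(features$cgi, tau2_Y, tau2_N) + sigma2 / n
  ybar <- colMeans(th) - ifelse(features$cgi, b_Y, b_N)
  prec <- sum(x^2 / w) + 1 / priors$gamma_var
  mean <- (sum(x * ybar / w) + priors$gamma_mean / priors$gamma_var) / prec
  list(mean = mean, var = 1 / prec)
}

#' Split-R-hat convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction factor computed on split chains
#' for every scalar parameter (gamma components, stratum means and
#' variances, observation noise, pair-effect variance).
#'
#' @param fit A `pm_fit` with at least 2 chains (or 1 chain, which is then
#'   split in two).
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(fit) {
  stopifnot(inherits(fit, "pm_fit"))
  comp <- c("gamma", "b", "tau2", "sigma2", "tau2_delta")
  rhat1 <- function(mat) {
    # mat: draws x chains (split)
    L <- nrow(mat)
    W <- mean(apply(mat, 2L, stats::var))
    B <- L * stats::var(colMeans(mat))
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((L - 1) / L * W + B / L) / W)
  }
  out <- c()
  for (cm in comp) {
    first <- fit$chains[[1L]][[cm]]
    if (is.null(first) || ncol(first) == 0L) next
    for (j in seq_len(ncol(first))) {
      halves <- do.call(cbind, lapply(fit$chains, function(chn) {
        v <- chn[[cm]][, j]
        L <- floor(length(v) / 2) * 2
        matrix(v[seq_len(L)], ncol = 2L)
      }))
      nm <- colnames(first)[j]
      if (is.null(nm)) nm <- paste0(cm, j)
      out[nm] <- rhat1(halves)
    }
  }
  out
}
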
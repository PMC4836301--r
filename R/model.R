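#' Specify a pathway-effect model form
#'
#' The probe-level effect is lambda_j = beta_j + Phi_j, where beta_j is the
#' CGI-stratum probe effect and Phi_j the pathway effect, a sum of
#' per-pathway contributions f_k(P_j):
#'
#' * `a`   — null pathway effect, Phi = 0;
#' * `b1`  — CGI-independent constant effect, f_k = I_jk * gamma_k;
#' * `b2`  — CGI-dependent constant effect: gamma_k splits into a CGI
#'   (`Y`) and a non-CGI (`N`) coefficient;
#' * `c1`  — CGI-independent degree effect, f_k = E_jk * gamma_k, with E_jk
#'   the gene's neighbour count (degree) in pathway k;
#' * `c2`  — CGI-dependent degree effect;
#' * `c1_inv`, `c2_inv` — inverse-degree variants, replacing E_jk by 1/E_jk
#'   (0 for isolated genes), for the view that hub genes carry individually
#'   smaller effects.
#'
#' Per-pathway parameter counts: `a` has 0, `b1`/`c1`/`c1_inv` have K, and
#' `b2`/`c2`/`c2_inv` have 2K.
#'
#' @param form One of `"a"`, `"b1"`, `"b2"`, `"c1"`, `"c2"`, `"c1_inv"`,
#'   `"c2_inv"`.
#' @param include_pair_effect Include a per-pair random intercept delta_i
#'   (default TRUE).
#' @param stratum_noise Use separate observation variances for CGI and
#'   non-CGI probes (default FALSE: one shared sigma^2_eps).
#' @return A `model_spec` object.
#' @export
model_spec <- function(form = c("a", "b1", "b2", "c1", "c2", "c1_inv",
                                "c2_inv"),
                       include_pair_effect = TRUE, stratum_noise = FALSE) {
  form <- match.arg(form)
  structure(list(form = form,
                 include_pair_effect = isTRUE(include_pair_effect),
                 stratum_noise = isTRUE(stratum_noise)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: form %s, pair effect %s, %s noise\n", x$form,
              if (x$include_pair_effect) "on" else "off",
              if (x$stratum_noise) "CGI-stratified" else "shared"))
  invisible(x)
}

#' Number of pathway parameters for a form
#'
#' @param spec A `model_spec` (or form string).
#' @param n_pathways Number of pathways K.
#' @return Integer parameter count: 0, K or 2K.
#' @export
n_gamma <- function(spec, n_pathways) {
  form <- if (inherits(spec, "model_spec")) spec$form else spec
  switch(form,
         a = 0L,
         b1 = , c1 = , c1_inv = as.integer(n_pathways),
         b2 = , c2 = , c2_inv = 2L * as.integer(n_pathways),
         stop("unknown form: ", form))
}

#' Design matrix mapping gamma to the pathway effect
#'
#' Returns the m x p matrix X with Phi = X gamma for the given form.
#' CGI-dependent forms interleave the base matrix with the CGI indicator:
#' columns are `<pathway>.Y` (CGI probes) then `<pathway>.N`.
#'
#' @param spec A `model_spec`.
#' @param features A `probe_features`.
#' @return Numeric matrix (m x p, p possibly 0) with named columns.
#' @export
gamma_design <- function(spec, features) {
  stopifnot(inherits(spec, "model_spec"), inherits(features, "probe_features"))
  base <- switch(spec$form,
                 a = NULL,
                 b1 = , b2 = features$membership,
                 c1 = , c2 = features$degree,
                 c1_inv = , c2_inv = features$inv_degree)
  if (is.null(base)) {
    X <- matrix(0, length(features$probe_ids), 0L)
    rownames(X) <- features$probe_ids
    return(X)
  }
  base <- base * 1.0
  if (spec$form %in% c("b2", "c2", "c2_inv")) {
    cgi <- as.numeric(features$cgi)
    X <- cbind(base * cgi, base * (1 - cgi))
    colnames(X) <- c(paste0(features$pathway_ids, ".Y"),
                     paste0(features$pathway_ids, ".N"))
  } else {
    X <- base
    colnames(X) <- features$pathway_ids
  }
  rownames(X) <- features$probe_ids
  X
}

#' Pathway effect Phi for a parameter vector
#'
#' @param spec A `model_spec`.
#' @param features A `probe_features`.
#' @param gamma Numeric vector of pathway parameters, length
#'   `n_gamma(spec, K)`.
#' @return Length-m numeric vector Phi_j.
#' @export
pathway_effect <- function(spec, features, gamma) {
  X <- gamma_design(spec, features)
  if (length(gamma) != ncol(X))
    stop(sprintf("gamma has length %d; form '%s' with %d pathway(s) needs %d",
                 length(gamma), spec$form, length(features$pathway_ids),
                 ncol(X)))
  if (ncol(X) == 0L) return(stats::setNames(numeric(nrow(X)), rownames(X)))
  drop(X %*% gamma)
}

#' Probe-level total effect lambda = beta + Phi
#'
#' @param beta Length-m vector of probe CGI effects.
#' @param spec,features,gamma As in [pathway_effect()].
#' @return Length-m numeric vector lambda_j.
#' @export
lambda_vector <- function(beta, spec, features, gamma) {
  phi <- pathway_effect(spec, features, gamma)
  if (length(beta) != length(phi))
    stop("beta length does not match the number of probes")
  beta + phi
}

#' Mean surface mu_ij of the observation model
#'
#' mu_ij = lambda_j, plus the pair random intercept delta_i when pair
#' effects are enabled.
#'
#' @param lambda Length-m vector of probe effects.
#' @param n_pairs Number of matched pairs n.
#' @param delta Optional length-n vector of pair effects; required iff
#'   `spec$include_pair_effect`.
#' @param spec A `model_spec`.
#' @return n x m numeric matrix.
#' @export
mean_surface <- function(lambda, n_pairs, delta = NULL, spec = model_spec("a")) {
  m <- length(lambda)
  if (spec$include_pair_effect) {
    if (is.null(delta) || length(delta) != n_pairs)
      stop("pair effects enabled: delta must have length n_pairs")
  } else if (!is.null(delta) && any(delta != 0)) {
    stop("pair effects disabled but nonzero delta supplied")
  }
  mu <- matrix(lambda, n_pairs, m, byrow = TRUE)
  if (spec$include_pair_effect) mu <- mu + delta
  mu
}

#' Gaussian log-likelihood and deviance of a theta matrix
#'
#' Sum over pairs i and probes j of log N(theta_ij | mu_ij, sigma^2_j),
#' where sigma^2_j is the observation variance of probe j (shared, or per
#' CGI stratum).  The deviance -2 log L feeds the DIC.
#'
#' @param theta A `paired_diff` or a plain n x m matrix.
#' @param mu n x m mean surface.
#' @param sigma2 Either a single shared variance or a length-m vector of
#'   per-probe variances; all strictly positive.
#' @return `log_likelihood`: scalar log-likelihood.
#' @export
log_likelihood <- function(theta, mu, sigma2) {
  th <- if (inherits(theta, "paired_diff")) theta$theta else as.matrix(theta)
  stopifnot(all(dim(th) == dim(mu)), all(sigma2 > 0))
  n <- nrow(th)
  m <- ncol(th)
  sig2 <- rep_len(sigma2, m)
  ss <- colSums((th - mu)^2)
  -0.5 * (n * sum(log(2 * pi * sig2)) + sum(ss / sig2))
}

#' @rdname log_likelihood
#' @return `deviance_theta`: scalar deviance, -2 log L.
#' @export
deviance_theta <- function(theta, mu, sigma2) {
  -2 * log_likelihood(theta, mu, sigma2)
}

#' Prior settings for the hierarchical model
#'
#' Normal priors on the CGI-stratum base means b_Y, b_N and on every
#' pathway parameter gamma; inverse-gamma priors on the variance
#' components (CGI-stratum probe variances tau^2_Y, tau^2_N, observation
#' noise sigma^2_eps, pair-effect variance tau^2_delta).  Defaults are
#' conventional vague choices — N(0, 10^2) and IG(0.01, 0.01) — and can be
#' overridden.
#'
#' @param b_mean,b_var Mean and variance of the normal prior on b_Y and b_N.
#' @param gamma_mean,gamma_var Mean and variance of the normal prior on each
#'   gamma parameter.
#' @param tau2_shape,tau2_rate Inverse-gamma shape/rate for tau^2_Y, tau^2_N.
#' @param sigma2_shape,sigma2_rate Inverse-gamma shape/rate for sigma^2_eps.
#' @param delta_shape,delta_rate Inverse-gamma shape/rate for tau^2_delta.
#' @return A `pm_priors` object.
#' @export
pm_priors <- function(b_mean = 0, b_var = 100,
                      gamma_mean = 0, gamma_var = 100,
                      tau2_shape = 0.01, tau2_rate = 0.01,
                      sigma2_shape = 0.01, sigma2_rate = 0.01,
                      delta_shape = 0.01, delta_rate = 0.01) {
  p <- list(b_mean = b_mean, b_var = b_var,
            gamma_mean = gamma_mean, gamma_var = gamma_var,
            tau2_shape = tau2_shape, tau2_rate = tau2_rate,
            sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate,
            delta_shape = delta_shape, delta_rate = delta_rate)
  vars <- c(p$b_var, p$gamma_var, p$tau2_shape, p$tau2_rate, p$sigma2_shape,
            p$sigma2_rate, p$delta_shape, p$delta_rate)
  if (any(!is.finite(vars)) || any(vars <= 0))
    stop("all prior variances and inverse-gamma parameters must be strictly positive")
  structure(p, class = "pm_priors")
}

#' @export
print.pm_priors <- function(x, ...) {
  cat(sprintf(paste0("pm_priors: b ~ N(%g, %g), gamma ~ N(%g, %g), ",
                     "tau2 ~ IG(%g, %g), sigma2 ~ IG(%g, %g), ",
                     "tau2_delta ~ IG(%g, %g)\n"),
              x$b_mean, x$b_var, x$gamma_mean, x$gamma_var,
              x$tau2_shape, x$tau2_rate, x$sigma2_shape, x$sigma2_rate,
              x$delta_shape, x$delta_rate))
  invisible(x)
}

#' Serialize / read priors and model spec as key-value text
#'
#' @param priors A `pm_priors`.
#' @param spec A `model_spec`.
#' @param path Output (or input) file path.
#' @return `write_model_config`: `path` invisibly.  `read_model_config`:
#'   list with elements `priors` and `spec`.
#' @export
write_model_config <- function(priors, spec, path) {
  stopifnot(inherits(priors, "pm_priors"), inherits(spec, "model_spec"))
  kv <- c(unclass(priors),
          list(form = spec$form,
               include_pair_effect = spec$include_pair_effect,
               stratum_noise = spec$stratum_noise))
  writeLines(format_run_summary(kv), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  kv <- read_run_summary(path)
  spec <- model_spec(form = kv$form,
                     include_pair_effect = as.logical(kv$include_pair_effect),
                     stratum_noise = as.logical(kv$stratum_noise))
  nm <- setdiff(names(formals(pm_priors)), character(0))
  args <- lapply(kv[intersect(nm, names(kv))], as.numeric)
  list(priors = do.call(pm_priors, args), spec = spec)
}
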
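#' Posterior sign probability
#'
#' Fraction of posterior draws strictly greater than zero.  Draws exactly
#' equal to zero count as not-positive, so `P(x > 0)` and `P(x < 0)` never
#' double-count ties.
#'
#' @param draws Numeric vector of posterior draws (at least one).
#' @return Probability in \[0, 1\].
#' @export
posterior_sign_probability <- function(draws) {
  stopifnot(length(draws) >= 1L, is.numeric(draws))
  mean(draws > 0)
}

#' Score of strength
#'
#' Rescaled distance of a sign probability from the no-difference point 0.5:
#' `2 * |p - 0.5|`, ranging from 0 (indifference) to 1 (certain direction).
#'
#' @param p Probability (or vector of probabilities) in \[0, 1\].
#' @return Score(s) in \[0, 1\].
#' @export
score_of_strength <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  2 * abs(p - 0.5)
}

#' Pathway-level posterior report
#'
#' For each pathway, the posterior probability that its effect parameter is
#' positive (hypermethylation in cases), the score of strength, and the
#' posterior mean and equal-tailed credible interval of gamma.  For the
#' CGI-dependent forms both the CGI (`Y`) and non-CGI (`N`) coefficients
#' are reported.
#'
#' @param fit A `pm_fit`.
#' @param level Credible-interval level (default 0.95).
#' @return Data.frame with one row per gamma parameter: `pathway_id`,
#'   `stratum` (`Y`/`N` or `all`), `form`, `p_positive`,
#'   `score_of_strength`, `gamma_mean`, `gamma_lower`, `gamma_upper`.
#' @export
pathway_report <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "pm_fit"))
  g <- extract_draws(fit, "gamma")
  if (ncol(g) == 0L)
    return(data.frame(pathway_id = character(0), stratum = character(0),
                      form = character(0), p_positive = numeric(0),
                      score_of_strength = numeric(0),
                      gamma_mean = numeric(0), gamma_lower = numeric(0),
                      gamma_upper = numeric(0), stringsAsFactors = FALSE))
  K <- length(fit$pathway_ids)
  two <- ncol(g) == 2L * K
  pw <- if (two) rep(fit$pathway_ids, 2L) else fit$pathway_ids
  stratum <- if (two) rep(c("Y", "N"), each = K) else rep("all", K)
  p_pos <- apply(g, 2L, posterior_sign_probability)
  qs <- apply(g, 2L, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2))
  out <- data.frame(pathway_id = pw, stratum = stratum, form = fit$spec$form,
                    p_positive = unname(p_pos),
                    score_of_strength = score_of_strength(unname(p_pos)),
                    gamma_mean = unname(colMeans(g)),
                    gamma_lower = unname(qs[1L, ]),
                    gamma_upper = unname(qs[2L, ]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(match(out$pathway_id, fit$pathway_ids), out$stratum), ,
      drop = FALSE]
}

#' Deviance information criterion of a fit
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance and
#' `pD = Dbar - D(posterior means)` the effective number of parameters,
#' where the plug-in deviance evaluates the likelihood at the posterior
#' means of lambda, delta and the observation variance.  A negative `pD`
#' (a known DIC pathology under poor mixing or non-log-concave summaries)
#' is flagged with a warning but still returned.
#'
#' @param fit A `pm_fit`.
#' @param theta The `paired_diff` (or matrix) the model was fitted to.
#' @return List with `dic`, `p_d`, `mean_deviance`, `plugin_deviance`.
#' @export
compute_dic <- function(fit, theta) {
  stopifnot(inherits(fit, "pm_fit"))
  th <- if (inherits(theta, "paired_diff")) theta$theta else as.matrix(theta)
  dbar <- mean(extract_draws(fit, "deviance"))
  lambda_hat <- colMeans(extract_draws(fit, "lambda"))
  n <- nrow(th)
  mu <- matrix(lambda_hat, n, ncol(th), byrow = TRUE)
  if (fit$spec$include_pair_effect)
    mu <- mu + colMeans(extract_draws(fit, "delta"))
  sig_hat <- colMeans(extract_draws(fit, "sigma2"))
  sig2j <- if (length(sig_hat) == 1L) rep(sig_hat, ncol(th))
           else ifelse(fit$cgi, sig_hat[1L], sig_hat[2L])
  dhat <- deviance_theta(th, mu, sig2j)
  p_d <- dbar - dhat
  if (p_d < 0)
    warning(sprintf("negative effective parameter count pD = %.3f", p_d))
  list(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar,
       plugin_deviance = dhat)
}

#' Rank model forms by DIC with a parsimony tie-break
#'
#' Orders fitted forms by ascending DIC.  All forms whose DIC lies within
#' `margin` of the minimum are considered indistinguishable, and among them
#' the form with the fewest pathway parameters is selected (ties broken by
#' lower DIC, then form name).  `margin = 0` selects the strict minimum.
#'
#' @param dics Named numeric vector of DIC values (names are form labels),
#'   or a data.frame with columns `form` and `dic`.
#' @param n_pathways Number of pathways K, used to count parameters per
#'   form.
#' @param margin Indifference margin on the DIC scale (default 2).
#' @return List with `table` (data.frame `form`, `dic`, `n_params`, ascending
#'   DIC) and `selected` (form label).
#' @export
rank_models <- function(dics, n_pathways, margin = 2) {
  if (is.data.frame(dics)) {
    forms <- as.character(dics$form)
    vals <- as.numeric(dics$dic)
  } else {
    forms <- names(dics)
    vals <- as.numeric(dics)
  }
  stopifnot(length(forms) >= 2L, !is.null(forms), margin >= 0)
  np <- vapply(forms, n_gamma, integer(1), n_pathways = n_pathways)
  ord <- order(vals, np, forms)
  tab <- data.frame(form = forms[ord], dic = vals[ord],
                    n_params = unname(np[ord]), row.names = NULL,
                    stringsAsFactors = FALSE)
  cand <- tab[tab$dic < min(tab$dic) + margin | tab$dic == min(tab$dic), ,
              drop = FALSE]
  sel <- cand[order(cand$n_params, cand$dic, cand$form), , drop = FALSE]
  list(table = tab, selected = sel$form[1L])
}

#' Call methylation-variable probes and differentially methylated genes
#'
#' A probe is methylation-variable when its posterior probability of a
#' positive (hyper) or negative (hypo) lambda_j reaches the Bayesian
#' posterior probability threshold (default 0.975).  A gene is a
#' differentially methylated gene (DMG) when at least one of its probes is
#' flagged (`gene_rule = "any"`, the default) or when all are
#' (`gene_rule = "all"`); genes carrying both hyper- and hypo-flagged
#' probes are reported with both directions.
#'
#' @param fit A `pm_fit` (its stored lambda draws are used), or a matrix of
#'   lambda draws (draws x probes) if `probe_ids`/`genes` are given.
#' @param threshold BPP threshold in (0.5, 1\] (default 0.975).
#' @param gene_rule `"any"` (default) or `"all"`.
#' @param probe_ids,genes Optional overrides when `fit` is a plain matrix.
#' @return List with `probes` (data.frame `probe_id`, `gene`, `p_positive`,
#'   `p_negative`, `variable`, `direction`) and `genes` (data.frame `gene`,
#'   `dmg`, `hyper`, `hypo`, `direction`).
#' @export
call_dmps_dmgs <- function(fit, threshold = 0.975,
                           gene_rule = c("any", "all"),
                           probe_ids = NULL, genes = NULL) {
  gene_rule <- match.arg(gene_rule)
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must lie in (0.5, 1]")
  if (inherits(fit, "pm_fit")) {
    lam <- extract_draws(fit, "lambda")
    probe_ids <- fit$probe_ids
    genes <- fit$genes
  } else {
    lam <- as.matrix(fit)
    stopifnot(!is.null(probe_ids), !is.null(genes))
  }
  p_pos <- apply(lam, 2L, function(v) mean(v > 0))
  p_neg <- apply(lam, 2L, function(v) mean(v < 0))
  hyper <- p_pos >= threshold
  hypo <- p_neg >= threshold
  variable <- hyper | hypo
  direction <- ifelse(hyper, "hyper", ifelse(hypo, "hypo", "none"))
  probes <- data.frame(probe_id = probe_ids, gene = genes,
                       p_positive = unname(p_pos), p_negative = unname(p_neg),
                       variable = unname(variable),
                       direction = unname(direction),
                       row.names = NULL, stringsAsFactors = FALSE)
  agg <- function(flags) {
    if (gene_rule == "any") tapply(flags, genes, any)
    else tapply(flags, genes, all)
  }
  g_hyper <- agg(hyper)
  g_hypo <- agg(hypo)
  g_var <- if (gene_rule == "any") tapply(variable, genes, any)
           else tapply(variable, genes, all)
  gname <- names(g_var)
  gdir <- ifelse(g_hyper[gname] & g_hypo[gname], "hyper+hypo",
                 ifelse(g_hyper[gname], "hyper",
                        ifelse(g_hypo[gname], "hypo", "none")))
  genes_df <- data.frame(gene = gname, dmg = unname(g_var[gname]),
                         hyper = unname(g_hyper[gname]),
                         hypo = unname(g_hypo[gname]),
                         direction = unname(gdir),
                         row.names = NULL, stringsAsFactors = FALSE)
  genes_df <- genes_df[order(genes_df$gene), , drop = FALSE]
  rownames(genes_df) <- NULL
  list(probes = probes, genes = genes_df, threshold = threshold,
       gene_rule = gene_rule)
}
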
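#' Simulate overlapping pathways with Erdos-Renyi topology
#'
#' Generates K gene sets in which a fixed fraction of each pathway's genes
#' is shared with the previous pathway (so multi-membership occurs, as in
#' real gene-set collections), and wires each pathway internally with
#' independent undirected Erdos-Renyi edges.
#'
#' @param K Number of pathways.
#' @param genes_per_pathway Genes per pathway (scalar or length-K vector).
#' @param overlap_fraction Fraction of each pathway's genes shared with the
#'   preceding pathway, in \[0, 1).
#' @param edge_prob Probability of an edge between any two member genes,
#'   in \[0, 1\].
#' @param seed RNG seed.
#' @return A `pathway_collection`.
#' @export
simulate_pathways <- function(K = 3, genes_per_pathway = 20,
                              overlap_fraction = 0.2, edge_prob = 0.15,
                              seed = 1) {
  stopifnot(K >= 1, edge_prob >= 0, edge_prob <= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  sizes <- rep_len(genes_per_pathway, K)
  set.seed(seed)
  n_shared <- floor(overlap_fraction * sizes)
  n_new <- sizes - c(0L, n_shared[-1L])
  total <- sum(n_new)
  pool <- sprintf("G%04d", seq_len(total))
  pathways <- vector("list", K)
  used <- 0L
  prev <- character(0)
  for (k in seq_len(K)) {
    fresh <- pool[used + seq_len(n_new[k])]
    used <- used + n_new[k]
    shared <- if (k > 1L) prev[seq_len(n_shared[k])] else character(0)
    genes <- c(shared, fresh)
    # all unordered pairs, kept with probability edge_prob
    edges <- matrix(character(0), 0L, 2L)
    if (length(genes) >= 2L) {
      pairs <- t(utils::combn(genes, 2L))
      keep <- stats::runif(nrow(pairs)) < edge_prob
      edges <- pairs[keep, , drop = FALSE]
    }
    pathways[[k]] <- list(id = sprintf("PW%02d", k), genes = genes,
                          edges = edges)
    prev <- genes
  }
  pathway_collection(pathways)
}

#' Simulate a probe annotation for a pathway collection
#'
#' Each member gene receives a uniform number of probes in
#' `probes_per_gene`, and each probe a Bernoulli CGI label.  The default
#' CGI proportion of 0.76 mirrors the fraction observed among array probes
#' in ovarian-cancer methylation data.
#'
#' @param pathways A `pathway_collection`.
#' @param probes_per_gene Length-2 integer range (inclusive) of probes per
#'   gene; both bounds at least 1.  Defaults to `c(1, 4)` so that the
#'   default study (~60 genes) carries roughly 150 probes.
#' @param cgi_prob Probability that a probe lies in a CGI (default 0.76).
#' @param seed RNG seed.
#' @return A probe annotation data.frame (`probe_id`, `gene_symbol`,
#'   `cgi_status`).
#' @export
simulate_probes <- function(pathways, probes_per_gene = c(1, 4),
                            cgi_prob = 0.76, seed = 1) {
  stopifnot(inherits(pathways, "pathway_collection"),
            length(probes_per_gene) == 2L, all(probes_per_gene >= 1),
            probes_per_gene[1] <= probes_per_gene[2],
            cgi_prob >= 0, cgi_prob <= 1)
  genes <- unique(unlist(lapply(pathways$pathways, `[[`, "genes")))
  set.seed(seed)
  sizes <- probes_per_gene[1]:probes_per_gene[2]
  counts <- sizes[sample.int(length(sizes), length(genes), replace = TRUE)]
  gene_col <- rep(genes, counts)
  probe_ids <- sprintf("cg%06d", seq_along(gene_col))
  cgi <- stats::runif(length(gene_col)) < cgi_prob
  validate_probe_annotation(
    data.frame(probe_id = probe_ids, gene_symbol = gene_col,
               cgi_status = cgi, stringsAsFactors = FALSE))
}

#' Default ground-truth parameters for simulation
#'
#' The defaults state a world consistent with array methylation data:
#' near-zero stratum means, CGI probes with markedly larger between-probe
#' dispersion than non-CGI probes (`tau2_Y = 0.04` vs `tau2_N = 0.0025`),
#' observation noise `sigma2_eps = 0.01` (SD 0.1) and a small pair effect
#' (`tau2_delta = 0.0025`).
#'
#' @param spec A `model_spec`.
#' @param n_pathways Number of pathways K (to size gamma).
#' @param gamma True pathway parameters (default all 0).
#' @param b_Y,b_N True stratum means of beta_j.
#' @param tau2_Y,tau2_N True stratum variances of beta_j.
#' @param sigma2_eps True observation variance.
#' @param tau2_delta True pair-effect variance (ignored when the spec has
#'   pair effects off).
#' @return A named list of truth parameters.
#' @export
simulation_truth <- function(spec, n_pathways, gamma = NULL,
                             b_Y = 0, b_N = 0,
                             tau2_Y = 0.04, tau2_N = 0.0025,
                             sigma2_eps = 0.01, tau2_delta = 0.0025) {
  p <- n_gamma(spec, n_pathways)
  if (is.null(gamma)) gamma <- numeric(p)
  if (length(gamma) != p)
    stop(sprintf("gamma must have length %d for form '%s' with %d pathway(s)",
                 p, spec$form, n_pathways))
  stopifnot(tau2_Y >= 0, tau2_N >= 0, sigma2_eps >= 0, tau2_delta >= 0)
  list(gamma = gamma, b_Y = b_Y, b_N = b_N, tau2_Y = tau2_Y, tau2_N = tau2_N,
       sigma2_eps = sigma2_eps, tau2_delta = tau2_delta)
}

#' Simulate a paired-difference matrix from the generative model
#'
#' Draws probe effects beta_j from their CGI-stratum normal distribution,
#' pair effects delta_i (when enabled), then observations
#' `theta_ij ~ N(lambda_j + delta_i, sigma2_eps)`.  Values are clipped to
#' \[-1, 1\] (theta is a difference of ratios) and the clip count is
#' recorded in attribute `"n_clipped"`; under the default parameter scales
#' clipping is rare.
#'
#' @param features A `probe_features`.
#' @param spec A `model_spec`.
#' @param truth Truth parameters from [simulation_truth()].
#' @param n_pairs Number of matched pairs.
#' @param seed RNG seed.
#' @return List with `theta` (a `paired_diff`) and `truth` (the input truth
#'   augmented with the realised `beta`, `lambda`, `delta`, the generating
#'   form and the seed).
#' @export
simulate_theta <- function(features, spec, truth = NULL, n_pairs = 50,
                           seed = 1) {
  stopifnot(inherits(features, "probe_features"), inherits(spec, "model_spec"),
            n_pairs >= 1)
  if (is.null(truth))
    truth <- simulation_truth(spec, length(features$pathway_ids))
  set.seed(seed)
  m <- length(features$probe_ids)
  sd_beta <- sqrt(ifelse(features$cgi, truth$tau2_Y, truth$tau2_N))
  mean_beta <- ifelse(features$cgi, truth$b_Y, truth$b_N)
  beta <- stats::rnorm(m, mean_beta, sd_beta)
  lambda <- lambda_vector(beta, spec, features, truth$gamma)
  delta <- if (spec$include_pair_effect)
    stats::rnorm(n_pairs, 0, sqrt(truth$tau2_delta)) else numeric(n_pairs)
  mu <- mean_surface(lambda, n_pairs,
                     delta = if (spec$include_pair_effect) delta else NULL,
                     spec = spec)
  th <- mu + matrix(stats::rnorm(n_pairs * m, 0, sqrt(truth$sigma2_eps)),
                    n_pairs, m)
  n_clipped <- sum(abs(th) > 1)
  if (n_clipped > 0L) {
    message(sprintf("clipped %d theta value(s) to [-1, 1]", n_clipped))
    th <- pmin(pmax(th, -1), 1)
  }
  theta <- paired_diff(sprintf("pair%03d", seq_len(n_pairs)),
                       features$probe_ids, th)
  attr(theta, "n_clipped") <- n_clipped
  truth$beta <- beta
  truth$lambda <- lambda
  truth$delta <- delta
  truth$form <- spec$form
  truth$seed <- seed
  list(theta = theta, truth = truth)
}

#' Simulate age/covariate metadata for matching
#'
#' Cases and controls receive uniform ages in `age_range` and a categorical
#' covariate (e.g. ethnicity) drawn from `levels`.
#'
#' @param n_cases,n_controls Group sizes.
#' @param age_range Length-2 age range in years.
#' @param levels Covariate levels (default two ethnicity labels).
#' @param covariate Covariate column name (default `"ethnicity"`).
#' @param seed RNG seed.
#' @return A sample metadata data.frame.
#' @export
simulate_metadata <- function(n_cases, n_controls, age_range = c(40, 80),
                              levels = c("A", "B"), covariate = "ethnicity",
                              seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  df <- data.frame(
    sample_id = c(sprintf("case%03d", seq_len(n_cases)),
                  sprintf("ctrl%03d", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    age = round(stats::runif(n, age_range[1], age_range[2]), 1),
    stringsAsFactors = FALSE)
  df[[covariate]] <- sample(levels, n, replace = TRUE)
  validate_sample_metadata(df)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: pathways with topology, probe annotation, a theta
#' matrix drawn from the requested model form with ground truth, and
#' (optionally) the full on-disk file bundle — GMT membership, edge list,
#' annotation, theta TSV and a structured-text truth file.  With the same
#' seed the emitted files are byte-identical across runs.
#'
#' @param K Number of pathways (default 3).
#' @param genes_per_pathway Genes per pathway (default 20, i.e. ~60 genes).
#' @param n_pairs Matched pairs (default 50).
#' @param spec A `model_spec` (default form `b2` with pair effects).
#' @param truth Optional truth from [simulation_truth()].
#' @param overlap_fraction,edge_prob,probes_per_gene,cgi_prob Passed to the
#'   topology/probe generators.
#' @param seed Master seed; component seeds are derived from it.
#' @param out_dir Optional directory: when given, the file bundle is
#'   written there.
#' @return List with `pathways`, `annotation`, `features`, `theta`, `truth`
#'   and (if written) `paths`.
#' @export
simulate_study <- function(K = 3, genes_per_pathway = 20, n_pairs = 50,
                           spec = model_spec("b2"), truth = NULL,
                           overlap_fraction = 0.2, edge_prob = 0.15,
                           probes_per_gene = c(1, 4), cgi_prob = 0.76,
                           seed = 1, out_dir = NULL) {
  pathways <- simulate_pathways(K, genes_per_pathway, overlap_fraction,
                                edge_prob, seed = seed)
  annotation <- simulate_probes(pathways, probes_per_gene, cgi_prob,
                                seed = seed + 1L)
  features <- assemble_features(annotation, pathways)
  sim <- simulate_theta(features, spec, truth, n_pairs, seed = seed + 2L)
  out <- list(pathways = pathways, annotation = annotation,
              features = features, theta = sim$theta, truth = sim$truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(
      gmt = file.path(out_dir, "pathways.gmt"),
      edges = file.path(out_dir, "edges.tsv"),
      annotation = file.path(out_dir, "annotation.tsv"),
      theta = file.path(out_dir, "theta.tsv"),
      truth = file.path(out_dir, "truth.txt"))
    write_gmt(pathways, paths[["gmt"]])
    write_edge_list(pathways, paths[["edges"]])
    utils::write.table(annotation, paths[["annotation"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_theta_matrix(sim$theta, paths[["theta"]])
    tr <- sim$truth
    scalar <- tr[c("b_Y", "b_N", "tau2_Y", "tau2_N", "sigma2_eps",
                   "tau2_delta", "form", "seed")]
    scalar$gamma <- paste(format(tr$gamma, digits = 15), collapse = ",")
    writeLines(format_run_summary(scalar), paths[["truth"]])
    out$paths <- paths
  }
  out
}
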
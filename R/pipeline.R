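#' Read an end-to-end run configuration
#'
#' Key-value text (`key: value` per line).  Recognised keys: input paths
#' (`theta`, or `beta_cases`/`beta_controls`/`metadata` for matching mode,
#' plus `gmt`, `edges`, `annotation`), `forms` (comma-separated model
#' forms), matching settings (`caliper`, `exact_on`,
#' `max_cases_per_control`), MCMC settings (`n_iter`, `n_burnin`, `thin`,
#' `n_chains`, `seed`), decision thresholds (`dmg_threshold`,
#' `dic_margin`), `include_pair_effect`, and `out_dir`.
#'
#' @param path Config file path.
#' @return A named list (`run_config`).
#' @export
read_run_config <- function(path) {
  kv <- read_run_summary(path)
  cfg <- list(
    theta = kv$theta, beta_cases = kv$beta_cases,
    beta_controls = kv$beta_controls, metadata = kv$metadata,
    gmt = kv$gmt, edges = kv$edges, annotation = kv$annotation,
    forms = strsplit(kv$forms %||% "a,b1,b2,c1,c2", ",")[[1L]],
    caliper = as.numeric(kv$caliper %||% 3),
    exact_on = if (is.null(kv$exact_on) || !nzchar(kv$exact_on)) character(0)
               else strsplit(kv$exact_on, ",")[[1L]],
    max_cases_per_control = as.integer(kv$max_cases_per_control %||% 1),
    n_iter = as.integer(kv$n_iter %||% 12000),
    n_burnin = as.integer(kv$n_burnin %||% 2000),
    thin = as.integer(kv$thin %||% 5),
    n_chains = as.integer(kv$n_chains %||% 2),
    seed = as.integer(kv$seed %||% 1),
    include_pair_effect = as.logical(kv$include_pair_effect %||% TRUE),
    dmg_threshold = as.numeric(kv$dmg_threshold %||% 0.975),
    dic_margin = as.numeric(kv$dic_margin %||% 2),
    out_dir = kv$out_dir %||% "pathmeth_out")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pathway-methylation analysis
#'
#' End-to-end orchestration: (optionally) match cases to controls and form
#' paired differences, assemble pathway features, fit every requested model
#' form by Gibbs sampling, rank the forms by DIC with the parsimony
#' tie-break, and write the pathway and probe/gene reports for the selected
#' form together with a run manifest that lists every output and suffices
#' to rerun the job.  Any stage failure aborts with the stage name.
#'
#' @param config A named list as from [read_run_config()], or a path to a
#'   config file.
#' @return Invisibly, a list with `dic_table`, `selected_form`,
#'   `pathway_report`, `probe_report`, `fits` and `paths`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  for (key in c("theta", "beta_cases", "beta_controls", "metadata", "gmt",
                "edges", "annotation")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input file for '%s' not found: %s", key, p))
  }

  annotation <- stage("annotation", read_probe_annotation(config$annotation))
  membership <- stage("gene-sets", read_gmt(config$gmt))
  pathways <- stage("topology", read_edge_list(config$edges, membership))
  features <- stage("features", assemble_features(annotation, pathways))

  if (!is.null(config$theta)) {
    theta <- stage("theta", read_theta_matrix(config$theta))
  } else {
    theta <- stage("matching", {
      meta <- read_sample_metadata(config$metadata)
      cases <- read_beta_matrix(config$beta_cases)
      controls <- read_beta_matrix(config$beta_controls)
      pairing <- match_pairs(meta, caliper = config$caliper,
                             exact_on = config$exact_on,
                             max_cases_per_control = config$max_cases_per_control)
      compute_theta(cases, controls, pairing)
    })
  }
  if (!identical(theta$probe_ids, features$probe_ids)) {
    idx <- match(features$probe_ids, theta$probe_ids)
    if (anyNA(idx))
      stop("stage 'align' failed: theta lacks probes present in the annotation")
    theta <- paired_diff(theta$pair_ids, features$probe_ids,
                         theta$theta[, idx, drop = FALSE])
  }

  mc <- mcmc_config(n_iter = config$n_iter, n_burnin = config$n_burnin,
                    thin = config$thin, n_chains = config$n_chains,
                    seed = config$seed)
  priors <- config$priors %||% pm_priors()
  fits <- list()
  dics <- numeric(0)
  for (form in config$forms) {
    fit <- stage(paste0("fit-", form), {
      spec <- model_spec(form,
                         include_pair_effect = config$include_pair_effect)
      run_gibbs(theta, spec, priors, features, mc)
    })
    fits[[form]] <- fit
    dics[form] <- compute_dic(fit, theta)$dic
  }

  if (length(dics) >= 2L) {
    ranking <- rank_models(dics, n_pathways = length(features$pathway_ids),
                           margin = config$dic_margin)
    selected <- ranking$selected
    dic_table <- ranking$table
  } else {
    selected <- names(dics)[1L]
    dic_table <- data.frame(form = selected, dic = unname(dics),
                            n_params = n_gamma(selected,
                                               length(features$pathway_ids)),
                            stringsAsFactors = FALSE)
  }

  fit_sel <- fits[[selected]]
  pw_report <- pathway_report(fit_sel)
  calls <- call_dmps_dmgs(fit_sel, threshold = config$dmg_threshold)
  probe_rep <- calls$probes

  out_dir <- config$out_dir %||% "pathmeth_out"
  summary_fields <- list(
    selected_form = selected, forms = paste(config$forms, collapse = ","),
    seed = mc$seed, n_iter = mc$n_iter, n_burnin = mc$n_burnin,
    thin = mc$thin, n_chains = mc$n_chains,
    dmg_threshold = config$dmg_threshold, dic_margin = config$dic_margin,
    n_probes = length(features$probe_ids), n_pairs = length(theta$pair_ids))
  for (i in seq_len(nrow(dic_table)))
    summary_fields[[paste0("dic_", dic_table$form[i])]] <- dic_table$dic[i]
  paths <- stage("reports",
                 write_reports(pw_report, probe_rep, summary_fields, out_dir))
  dic_path <- file.path(out_dir, "dic_table.tsv")
  utils::write.table(dic_table, dic_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gene_path <- file.path(out_dir, "gene_report.tsv")
  utils::write.table(calls$genes, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, dic_table = dic_path, gene_report = gene_path)

  manifest <- file.path(out_dir, "run_manifest.txt")
  man_fields <- c(summary_fields,
                  list(outputs = paste(basename(paths), collapse = ","),
                       config_echo = paste(
                         vapply(names(config), function(k)
                           paste0(k, "=", paste(format(config[[k]]),
                                                collapse = ";")),
                           character(1)),
                         collapse = " | ")))
  writeLines(format_run_summary(man_fields), manifest)
  paths <- c(paths, manifest = manifest)

  invisible(list(dic_table = dic_table, selected_form = selected,
                 pathway_report = pw_report, probe_report = probe_rep,
                 gene_report = calls$genes, fits = fits, theta = theta,
                 features = features, paths = paths))
}
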
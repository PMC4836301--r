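#' Greedy age-caliper case-control matching
#'
#' Builds matched case-control pairs from a sample metadata table.  A pair is
#' eligible when the case-control age difference is strictly less than the
#' caliper and the samples agree exactly on every covariate named in
#' `exact_on` (e.g. ethnicity).  Matching is greedy and deterministic: cases
#' are taken in increasing age order (ties by sample id), and each is
#' assigned the eligible control with the smallest age gap, ties broken by
#' control id in lexicographic order.  A control may be reused for up to
#' `max_cases_per_control` cases, supporting the one-control-to-many-cases
#' design used when controls are scarce.
#'
#' @param metadata Sample metadata data.frame (see
#'   [validate_sample_metadata()]).
#' @param caliper Maximum allowed age difference in years (strict `<`).
#' @param exact_on Character vector of covariate column names requiring
#'   exact equality (default none).
#' @param max_cases_per_control Maximum number of cases matched to one
#'   control (default 1, i.e. one-to-one matching).
#' @return A `pairing` object: list with `pairs` (data.frame `case`,
#'   `control`, `age_case`, `age_control`), `unmatched_cases`, and the
#'   matching settings.
#' @export
match_pairs <- function(metadata, caliper, exact_on = character(0),
                        max_cases_per_control = 1L) {
  metadata <- validate_sample_metadata(metadata)
  if (!is.numeric(caliper) || length(caliper) != 1L || caliper <= 0)
    stop("caliper must be a single positive number of years")
  max_cases_per_control <- as.integer(max_cases_per_control)
  stopifnot(max_cases_per_control >= 1L)
  miss <- setdiff(exact_on, colnames(metadata))
  if (length(miss) > 0L)
    stop("exact_on covariate(s) not in metadata: ", paste(miss, collapse = ", "))

  cases <- metadata[metadata$group == "case", , drop = FALSE]
  controls <- metadata[metadata$group == "control", , drop = FALSE]
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("metadata must contain at least one case and one control")

  cases <- cases[order(cases$age, cases$sample_id), , drop = FALSE]
  used <- stats::setNames(integer(nrow(controls)), controls$sample_id)

  pair_rows <- vector("list", nrow(cases))
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, , drop = FALSE]
    gap <- abs(controls$age - cs$age)
    ok <- gap < caliper & used[controls$sample_id] < max_cases_per_control
    for (cov in exact_on)
      ok <- ok & (controls[[cov]] == cs[[cov]])
    if (!any(ok)) {
      unmatched <- c(unmatched, cs$sample_id)
      next
    }
    cand <- controls[ok, , drop = FALSE]
    cand <- cand[order(gap[ok], cand$sample_id), , drop = FALSE]
    ctrl <- cand[1L, , drop = FALSE]
    used[ctrl$sample_id] <- used[ctrl$sample_id] + 1L
    pair_rows[[i]] <- data.frame(case = cs$sample_id,
                                 control = ctrl$sample_id,
                                 age_case = cs$age,
                                 age_control = ctrl$age,
                                 stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_rows)
  if (is.null(pairs))
    pairs <- data.frame(case = character(0), control = character(0),
                        age_case = numeric(0), age_control = numeric(0),
                        stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L)
    warning("no matchable case-control pair under the given caliper/covariates")

  # matching contract asserted on every run
  stopifnot(all(abs(pairs$age_case - pairs$age_control) < caliper),
            !anyDuplicated(pairs$case),
            all(table(pairs$control) <= max_cases_per_control))

  structure(list(pairs = pairs, unmatched_cases = unmatched,
                 caliper = caliper, exact_on = exact_on,
                 max_cases_per_control = max_cases_per_control),
            class = "pairing")
}

#' @export
print.pairing <- function(x, ...) {
  cat(sprintf("pairing: %d pair(s), %d unmatched case(s), caliper < %g year(s)\n",
              nrow(x$pairs), length(x$unmatched_cases), x$caliper))
  invisible(x)
}

#' Compute paired methylation differences (theta)
#'
#' For each matched pair i and probe j, theta\[i, j\] = beta_case\[j, i\] -
#' beta_control\[j, i\]: the observed case-control difference in methylation
#' level, the model's observation.
#'
#' @param cases,controls `beta_matrix` objects with identical probe order.
#' @param pairing A `pairing` from [match_pairs()], or a data.frame with
#'   columns `case` and `control`.
#' @return A `paired_diff` with pair ids `"<case>|<control>"`.
#' @export
compute_theta <- function(cases, controls, pairing) {
  stopifnot(inherits(cases, "beta_matrix"), inherits(controls, "beta_matrix"))
  pairs <- if (inherits(pairing, "pairing")) pairing$pairs else pairing
  stopifnot(is.data.frame(pairs), all(c("case", "control") %in% colnames(pairs)))
  if (!identical(cases$probe_ids, controls$probe_ids))
    stop("case and control beta matrices must share identical probe order")
  miss_c <- setdiff(pairs$case, cases$sample_ids)
  miss_k <- setdiff(pairs$control, controls$sample_ids)
  if (length(miss_c) > 0L || length(miss_k) > 0L)
    stop("pairing references samples absent from the beta matrices: ",
         paste(c(miss_c, miss_k), collapse = ", "))
  theta <- t(cases$values[, pairs$case, drop = FALSE] -
               controls$values[, pairs$control, drop = FALSE])
  paired_diff(paste(pairs$case, pairs$control, sep = "|"),
              cases$probe_ids, theta)
}

#' CGI-stratified dispersion summary of paired differences
#'
#' Descriptive check of CGI heterogeneity: pooled mean and variance of all
#' theta entries within the CGI and non-CGI probe strata, plus a Welch
#' two-sample t statistic comparing per-probe mean theta between strata.
#' With a single stratum present the test is flagged undefined rather than
#' raising.
#'
#' @param theta A `paired_diff`.
#' @param annotation Probe annotation covering all probes of `theta`.
#' @return List with per-stratum `n_probes`, `mean`, `variance`, and
#'   `welch` (`statistic`, `p_value`, `df`, `defined`).
#' @export
cgi_dispersion_summary <- function(theta, annotation) {
  stopifnot(inherits(theta, "paired_diff"))
  annotation <- validate_probe_annotation(annotation)
  idx <- match(theta$probe_ids, annotation$probe_id)
  if (anyNA(idx))
    stop("annotation does not cover all probes: ",
         paste(theta$probe_ids[is.na(idx)], collapse = ", "))
  cgi <- annotation$cgi_status[idx]

  stratum_stats <- function(cols) {
    v <- as.vector(theta$theta[, cols, drop = FALSE])
    list(n_probes = sum(cols), mean = if (length(v)) mean(v) else NA_real_,
         variance = if (length(v) > 1L) stats::var(v) else NA_real_)
  }
  cgi_s <- stratum_stats(cgi)
  non_s <- stratum_stats(!cgi)

  probe_means <- colMeans(theta$theta)
  welch <- list(statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                defined = FALSE)
  if (sum(cgi) >= 2L && sum(!cgi) >= 2L &&
      (stats::var(probe_means[cgi]) + stats::var(probe_means[!cgi])) > 0) {
    tt <- stats::t.test(probe_means[cgi], probe_means[!cgi])
    welch <- list(statistic = unname(tt$statistic),
                  p_value = tt$p.value, df = unname(tt$parameter),
                  defined = TRUE)
  }
  list(cgi = cgi_s, non_cgi = non_s, welch = welch)
}

#' Single-marker paired t-test baseline with Bonferroni correction
#'
#' The classical two-stage baseline: a one-sample t-test of each probe's
#' theta column against zero, with an optional Bonferroni-adjusted
#' significance threshold `alpha / m_probes`.  A probe is significant iff
#' its p-value is strictly below the threshold.  Zero-variance columns are
#' flagged degenerate and reported with p = 1.
#'
#' @param theta A `paired_diff` with at least 2 pairs.
#' @param alpha Familywise significance level (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Data.frame with columns `probe_id`, `mean_theta`, `t_statistic`,
#'   `p_value`, `degenerate`, `significant`; the per-test threshold is
#'   attached as attribute `"threshold"`.
#' @export
paired_t_baseline <- function(theta, alpha = 0.05,
                              correction = c("bonferroni", "none")) {
  stopifnot(inherits(theta, "paired_diff"))
  correction <- match.arg(correction)
  n <- length(theta$pair_ids)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  m <- length(theta$probe_ids)

  mu <- colMeans(theta$theta)
  s2 <- apply(theta$theta, 2L, stats::var)
  degenerate <- s2 == 0
  tstat <- rep(NA_real_, m)
  p <- rep(1, m)
  ok <- !degenerate
  tstat[ok] <- mu[ok] / sqrt(s2[ok] / n)
  p[ok] <- 2 * stats::pt(abs(tstat[ok]), df = n - 1L, lower.tail = FALSE)

  threshold <- if (correction == "bonferroni") alpha / m else alpha
  out <- data.frame(probe_id = theta$probe_ids, mean_theta = mu,
                    t_statistic = tstat, p_value = p,
                    degenerate = degenerate,
                    significant = !degenerate & p < threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  out
}
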
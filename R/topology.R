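#' Probe-by-pathway membership indicators
#'
#' Entry \[j, k\] is 1 iff the gene carrying probe j belongs to pathway k.
#' Because genes can sit in several pathways, a row may contain more than
#' one 1.  Probes whose gene is in no pathway get an all-zero row; their ids
#' are attached as attribute `"orphan_probes"`.
#'
#' @param annotation Probe annotation (see [validate_probe_annotation()]).
#' @param pathways A `pathway_collection`.
#' @return Integer m x K matrix with probe ids as rownames and pathway ids
#'   as colnames.
#' @export
build_membership <- function(annotation, pathways) {
  annotation <- validate_probe_annotation(annotation)
  stopifnot(inherits(pathways, "pathway_collection"))
  ids <- names(pathways$pathways)
  M <- matrix(0L, nrow(annotation), length(ids),
              dimnames = list(annotation$probe_id, ids))
  for (k in seq_along(ids))
    M[, k] <- as.integer(annotation$gene_symbol %in%
                           pathways$pathways[[k]]$genes)
  orphans <- annotation$probe_id[rowSums(M) == 0L]
  attr(M, "orphan_probes") <- orphans
  M
}

#' Per-pathway gene degrees
#'
#' The degree (connectivity) of gene g in pathway k is its number of
#' distinct neighbour genes over the pathway's undirected edges.  Member
#' genes with no incident edge have degree 0.
#'
#' @param pathways A `pathway_collection`.
#' @return Named list (by pathway id) of named integer vectors gene -> degree,
#'   covering every member gene.
#' @export
compute_degree <- function(pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  out <- lapply(pathways$pathways, function(p) {
    deg <- stats::setNames(integer(length(p$genes)), p$genes)
    if (nrow(p$edges) > 0L) {
      tab <- table(c(p$edges[, 1L], p$edges[, 2L]))
      deg[names(tab)] <- as.integer(tab)
    }
    # handshake lemma: total degree is twice the edge count
    stopifnot(sum(deg) == 2L * nrow(p$edges))
    deg
  })
  names(out) <- names(pathways$pathways)
  out
}

#' Assemble the per-probe model features
#'
#' Combines membership indicators, gene degrees and CGI status into the
#' feature block the pathway-effect functions consume.  All probes of the
#' same gene inherit identical membership and degree rows.  Isolated member
#' genes keep membership 1 with degree 0, so they contribute under constant
#' pathway-effect forms but not under degree-weighted ones; their
#' inverse-degree weight is 0 by convention (never 1/0).
#'
#' @inheritParams build_membership
#' @param degree_scale Optional positive scaling applied to raw degrees
#'   (default 1: raw neighbour counts).
#' @return A `probe_features` object: list with `membership`, `degree`,
#'   `inv_degree` (m x K matrices), `cgi` (logical m-vector), `probe_ids`,
#'   `genes`, `pathway_ids`.
#' @export
assemble_features <- function(annotation, pathways, degree_scale = 1) {
  annotation <- validate_probe_annotation(annotation)
  stopifnot(degree_scale > 0)
  M <- build_membership(annotation, pathways)
  deg_by_pw <- compute_degree(pathways)
  ids <- names(pathways$pathways)
  D <- matrix(0, nrow(annotation), length(ids),
              dimnames = dimnames(M))
  for (k in seq_along(ids)) {
    dk <- deg_by_pw[[k]]
    hit <- M[, k] == 1L
    D[hit, k] <- dk[annotation$gene_symbol[hit]] * degree_scale
  }
  inv <- ifelse(D > 0, 1 / D, 0)
  stopifnot(all((D > 0) <= (M == 1L)),      # degree > 0 implies membership
            all(D[M == 0L] == 0))
  structure(list(membership = M, degree = D, inv_degree = inv,
                 cgi = annotation$cgi_status,
                 probe_ids = annotation$probe_id,
                 genes = annotation$gene_symbol,
                 pathway_ids = ids,
                 orphan_probes = attr(M, "orphan_probes")),
            class = "probe_features")
}

#' @export
print.probe_features <- function(x, ...) {
  cat(sprintf("probe_features: %d probes, %d pathways, %d CGI probe(s), %d orphan probe(s)\n",
              length(x$probe_ids), length(x$pathway_ids), sum(x$cgi),
              length(x$orphan_probes)))
  invisible(x)
}
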
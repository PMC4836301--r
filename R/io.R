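#' Read a beta-value methylation matrix
#'
#' Reads a delimited text file of methylation beta values (probes in rows,
#' samples in columns; first column holds probe ids, first row the sample
#' header).  Beta values are methylated/total fluorescent-signal ratios and
#' must lie in \[0, 1\].
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter (default tab).
#' @param clip_tol Non-negative tolerance: values outside \[0, 1\] by at most
#'   `clip_tol` are clipped to the boundary instead of raising an error.
#'   Defaults to 0 (strict).
#' @param na_string String encoding missing values (default `"NA"`).
#' @return A `beta_matrix` object: a list with `probe_ids`, `sample_ids` and
#'   the numeric `values` matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, delimiter = "\t", clip_tol = 0,
                             na_string = "NA") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = na_string, comment.char = "",
                          quote = "")
  if (ncol(df) < 2L) stop("beta matrix file needs a probe-id column and at least one sample column")
  probe_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  values <- matrix(NA_real_, nrow(raw), ncol(raw))
  suppressWarnings(values[] <- as.numeric(raw))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell at probe row %d, sample column %d ('%s')",
                 bad[1L, 1L], bad[1L, 2L], raw[bad[1L, , drop = FALSE]]))
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  beta_matrix(probe_ids, sample_ids, values, clip_tol = clip_tol)
}

#' Construct and validate a beta matrix
#'
#' @param probe_ids Character vector of unique probe ids (rows).
#' @param sample_ids Character vector of unique sample ids (columns).
#' @param values Numeric matrix of beta values in \[0, 1\] (NA allowed).
#' @inheritParams read_beta_matrix
#' @return A validated `beta_matrix` object.
#' @export
beta_matrix <- function(probe_ids, sample_ids, values, clip_tol = 0) {
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids))
    stop("beta matrix dimensions inconsistent with probe/sample ids")
  .check_unique(probe_ids, "probe id")
  .check_unique(sample_ids, "sample id")
  out_of_range <- !is.na(values) & (values < 0 | values > 1)
  if (any(out_of_range)) {
    off <- abs(pmax(values - 1, 0) + pmin(values, 0))
    if (clip_tol > 0 && max(off[out_of_range]) <= clip_tol) {
      values <- pmin(pmax(values, 0), 1)
    } else {
      idx <- which(out_of_range, arr.ind = TRUE)[1L, ]
      stop(sprintf("beta value %g outside [0, 1] at probe '%s', sample '%s'",
                   values[idx[1L], idx[2L]], probe_ids[idx[1L]],
                   sample_ids[idx[2L]]))
    }
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(probe_ids = probe_ids, sample_ids = sample_ids,
                 values = values),
            class = "beta_matrix")
}

.check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0L)
    stop(sprintf("duplicate %ss: %s", what, paste(d, collapse = ", ")))
  invisible(TRUE)
}

#' Write a beta matrix to delimited text
#'
#' @param x A `beta_matrix`.
#' @param path Output file path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(probe_id = x$probe_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", x$sample_ids)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a delimited file with at least the columns `sample_id`, `group`
#' (`case`/`control`) and `age`; any further columns are kept as covariates
#' (e.g. ethnicity) available for exact matching.
#'
#' @inheritParams read_beta_matrix
#' @return A data.frame with validated `sample_id`, `group`, `age` and any
#'   covariate columns.
#' @export
read_sample_metadata <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  validate_sample_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param df Data.frame with columns `sample_id`, `group`, `age` plus
#'   optional covariates.
#' @return The validated data.frame (group normalised to lower case).
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample_id", "group", "age")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  .check_unique(df$sample_id, "sample id")
  df$group <- tolower(as.character(df$group))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad) > 0L)
    stop("group must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  df$age <- as.numeric(df$age)
  if (anyNA(df$age) || any(df$age < 0))
    stop("age must be numeric and non-negative for every sample")
  df
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, `gene_symbol`, `cgi_status`.  CGI status may be
#' encoded as logical (`TRUE`/`FALSE`), 0/1 or `Y`/`N`; it is returned as a
#' logical where `TRUE` means the probe lies in a CpG island.  Probes mapping
#' to multiple genes are not supported: each probe carries exactly one gene
#' symbol.
#'
#' @inheritParams read_beta_matrix
#' @return A data.frame `probe_id`, `gene_symbol`, `cgi_status` (logical).
#' @export
read_probe_annotation <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  validate_probe_annotation(df)
}

#' Validate a probe annotation table
#'
#' @param df Data.frame with `probe_id`, `gene_symbol`, `cgi_status`.
#' @return The validated data.frame, `cgi_status` coerced to logical.
#' @export
validate_probe_annotation <- function(df) {
  need <- c("probe_id", "gene_symbol", "cgi_status")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  df$probe_id <- as.character(df$probe_id)
  .check_unique(df$probe_id, "probe id")
  df$gene_symbol <- as.character(df$gene_symbol)
  if (anyNA(df$gene_symbol) || any(!nzchar(df$gene_symbol)))
    stop("every probe must have a non-empty gene symbol")
  df$cgi_status <- .as_cgi_logical(df$cgi_status)
  if (anyNA(df$cgi_status))
    stop("cgi_status must be defined (TRUE/FALSE, 1/0 or Y/N) for every probe")
  df
}

.as_cgi_logical <- function(x) {
  if (is.logical(x)) return(x)
  s <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("TRUE", "T", "1", "Y", "YES")] <- TRUE
  out[s %in% c("FALSE", "F", "0", "N", "NO")] <- FALSE
  out
}

#' Read gene sets in GMT format
#'
#' Each tab-separated line is `pathway_id<TAB>description<TAB>gene1<TAB>...`.
#' Gene lists are deduplicated preserving first occurrence.
#'
#' @param path Path to a GMT file.
#' @return A named list; each element has `id`, `description` and `genes`
#'   (character vector).  Names are the pathway ids, in file order.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need id, description and at least one gene",
                   i, length(f)))
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop(sprintf("GMT line %d has an empty gene list", i))
    ids[i] <- f[1L]
    out[[i]] <- list(id = f[1L], description = f[2L], genes = genes)
  }
  .check_unique(ids, "pathway id")
  names(out) <- ids
  out
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Named list as returned by [read_gmt()], or a
#'   `pathway_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  if (inherits(gene_sets, "pathway_collection")) {
    gene_sets <- lapply(gene_sets$pathways, function(p)
      list(id = p$id, description = p$id, genes = p$genes))
  }
  lines <- vapply(gene_sets, function(p)
    paste(c(p$id, p$description, p$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a pathway collection with intra-set topology
#'
#' A pathway collection holds K gene sets together with the undirected
#' gene-gene edges inside each set.  Edges are unordered pairs, deduplicated;
#' self-edges and edges touching non-member genes are rejected.  A gene may
#' belong to several pathways.
#'
#' @param pathways List of elements each with `id` (string), `genes`
#'   (character vector) and `edges` (2-column character matrix, possibly with
#'   zero rows).
#' @return A `pathway_collection` object.
#' @export
pathway_collection <- function(pathways) {
  ids <- vapply(pathways, `[[`, character(1), "id")
  .check_unique(ids, "pathway id")
  pathways <- lapply(pathways, function(p) {
    p$genes <- unique(as.character(p$genes))
    if (length(p$genes) == 0L) stop("pathway '", p$id, "' has no genes")
    e <- p$edges
    if (is.null(e) || NROW(e) == 0L) {
      p$edges <- matrix(character(0), 0L, 2L)
      return(p)
    }
    e <- matrix(as.character(e), ncol = 2L)
    if (any(e[, 1L] == e[, 2L]))
      stop("self-edge in pathway '", p$id, "'")
    outside <- setdiff(unique(c(e)), p$genes)
    if (length(outside) > 0L)
      stop(sprintf("edge in pathway '%s' references non-member gene(s): %s",
                   p$id, paste(outside, collapse = ", ")))
    # canonical orientation, then dedup: (a,b) == (b,a)
    swap <- e[, 1L] > e[, 2L]
    e[swap, ] <- e[swap, 2:1]
    p$edges <- unique(e)
    p
  })
  names(pathways) <- ids
  structure(list(pathways = pathways), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathway(s)\n", length(x$pathways)))
  for (p in x$pathways)
    cat(sprintf("  %s: %d genes, %d edges\n", p$id, length(p$genes),
                nrow(p$edges)))
  invisible(x)
}

#' Read an undirected edge list and attach it to gene-set membership
#'
#' The edge file holds rows `pathway_id<TAB>gene_a<TAB>gene_b`.  Pathways in
#' `membership` absent from the edge file get an empty edge set (all member
#' genes isolated, degree 0).
#'
#' @param path Path to a 3-column delimited file (no header by default).
#' @param membership Gene sets as returned by [read_gmt()] (named list with
#'   `genes`), or a plain named list of character vectors.
#' @param delimiter Field delimiter (default tab).
#' @param header Whether the file has a header row (default FALSE).
#' @return A `pathway_collection`.
#' @export
read_edge_list <- function(path, membership, delimiter = "\t",
                           header = FALSE) {
  stopifnot(file.exists(path))
  sets <- .membership_sets(membership)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0L) {
    df <- data.frame(pathway_id = character(0), gene_a = character(0),
                     gene_b = character(0))
  } else {
    df <- utils::read.table(path, sep = delimiter, header = header,
                            stringsAsFactors = FALSE, comment.char = "",
                            quote = "")
    if (ncol(df) != 3L)
      stop("edge list must have exactly 3 columns: pathway_id, gene_a, gene_b")
    colnames(df) <- c("pathway_id", "gene_a", "gene_b")
  }
  unknown <- setdiff(unique(df$pathway_id), names(sets))
  if (length(unknown) > 0L)
    stop("edge list references unknown pathway id(s): ",
         paste(unknown, collapse = ", "))
  pathways <- lapply(names(sets), function(id) {
    rows <- df[df$pathway_id == id, , drop = FALSE]
    list(id = id, genes = sets[[id]],
         edges = cbind(rows$gene_a, rows$gene_b))
  })
  pathway_collection(pathways)
}

.membership_sets <- function(membership) {
  if (inherits(membership, "pathway_collection"))
    return(lapply(membership$pathways, `[[`, "genes"))
  if (is.list(membership) && length(membership) > 0L &&
      is.list(membership[[1L]]) && !is.null(membership[[1L]]$genes))
    return(lapply(membership, `[[`, "genes"))
  if (is.list(membership) && !is.null(names(membership)))
    return(lapply(membership, as.character))
  stop("membership must be a named list of gene sets or a read_gmt() result")
}

#' Write a pathway edge list
#'
#' @param pathways A `pathway_collection`.
#' @param path Output path (3-column TSV, no header).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  rows <- do.call(rbind, lapply(pathways$pathways, function(p) {
    if (nrow(p$edges) == 0L) return(NULL)
    data.frame(pathway_id = p$id, gene_a = p$edges[, 1L],
               gene_b = p$edges[, 2L], stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(pathway_id = character(0), gene_a = character(0),
                       gene_b = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a paired-difference (theta) matrix
#'
#' On disk the theta matrix has probes in rows and matched pairs in columns
#' (first column = probe id, header = pair ids).  In memory it is stored
#' pairs x probes, matching the model's observation layout.  Probes with any
#' missing value across pairs are dropped with a message.
#'
#' @inheritParams read_beta_matrix
#' @return A `paired_diff` object (see [paired_diff()]).
#' @export
read_theta_matrix <- function(path, delimiter = "\t", na_string = "NA") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, na.strings = na_string,
                          comment.char = "", quote = "")
  probe_ids <- as.character(df[[1L]])
  pair_ids <- colnames(df)[-1L]
  values <- t(as.matrix(df[, -1L, drop = FALSE]))  # pairs x probes
  storage.mode(values) <- "double"
  keep <- !apply(values, 2L, anyNA)
  if (any(!keep)) {
    message(sprintf("dropping %d probe(s) with missing theta values", sum(!keep)))
    values <- values[, keep, drop = FALSE]
    probe_ids <- probe_ids[keep]
  }
  paired_diff(pair_ids, probe_ids, values)
}

#' Construct a paired-difference matrix
#'
#' Holds theta values: the per-pair difference in methylation beta values
#' (case minus control) at each probe, hence bounded by \[-1, 1\].
#'
#' @param pair_ids Character vector of matched-pair ids (rows).
#' @param probe_ids Character vector of probe ids (columns).
#' @param theta Numeric matrix, `n_pairs` x `m_probes`, values in \[-1, 1\].
#' @return A `paired_diff` object.
#' @export
paired_diff <- function(pair_ids, probe_ids, theta) {
  pair_ids <- as.character(pair_ids)
  probe_ids <- as.character(probe_ids)
  theta <- as.matrix(theta)
  storage.mode(theta) <- "double"
  if (nrow(theta) != length(pair_ids) || ncol(theta) != length(probe_ids))
    stop("theta dimensions inconsistent with pair/probe ids")
  .check_unique(pair_ids, "pair id")
  .check_unique(probe_ids, "probe id")
  if (any(!is.na(theta) & abs(theta) > 1))
    stop("theta values must lie in [-1, 1] (difference of beta ratios)")
  dimnames(theta) <- list(pair_ids, probe_ids)
  structure(list(pair_ids = pair_ids, probe_ids = probe_ids, theta = theta),
            class = "paired_diff")
}

#' @export
print.paired_diff <- function(x, ...) {
  cat(sprintf("paired_diff: %d pair(s) x %d probe(s)\n",
              length(x$pair_ids), length(x$probe_ids)))
  invisible(x)
}

#' Write a paired-difference matrix (probes x pairs on disk)
#'
#' @param x A `paired_diff`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_theta_matrix <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "paired_diff"))
  df <- data.frame(probe_id = x$probe_ids, t(x$theta), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", x$pair_ids)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write analysis reports and a run summary
#'
#' Writes the pathway report and probe/gene report as TSV with a fixed
#' column order, plus a key-value run summary (model form, seed, iterations,
#' DIC, ...) as structured text.
#'
#' @param pathway_report Data.frame from [pathway_report()].
#' @param probe_report Data.frame from [call_dmps_dmgs()].
#' @param run_summary Named list of scalar fields.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written file paths.
#' @export
write_reports <- function(pathway_report, probe_report, run_summary,
                          out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir)
  }
  paths <- c(pathway_report = file.path(out_dir, "pathway_report.tsv"),
             probe_report = file.path(out_dir, "probe_report.tsv"),
             run_summary = file.path(out_dir, "run_summary.txt"))
  utils::write.table(pathway_report, paths[["pathway_report"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(probe_report, paths[["probe_report"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(format_run_summary(run_summary), paths[["run_summary"]])
  paths
}

#' Format / parse the key-value run summary
#'
#' @param x Named list of scalar fields.
#' @return `format_run_summary`: character vector of `key: value` lines.
#' @export
format_run_summary <- function(x) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  vapply(names(x), function(k)
    paste0(k, ": ", paste(format(x[[k]], digits = 15), collapse = ",")),
    character(1))
}

#' @rdname format_run_summary
#' @param path Path to a run-summary file.
#' @return `read_run_summary`: named list of character values.
#' @export
read_run_summary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, `[[`, 2L)
  names(out) <- vapply(kv, `[[`, character(1), 1L)
  out
}
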
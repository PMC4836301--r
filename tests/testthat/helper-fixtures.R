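# Shared fixture builders (all generated in code; nothing on disk).

# Single-pathway toy: 10 one-probe genes, all members, alternating CGI.
toy_features <- function(m = 10L) {
  genes <- sprintf("g%02d", seq_len(m))
  pw <- pathway_collection(list(list(id = "P1", genes = genes, edges = NULL)))
  ann <- data.frame(probe_id = sprintf("cg%03d", seq_len(m)),
                    gene_symbol = genes,
                    cgi_status = rep(c(TRUE, FALSE), length.out = m),
                    stringsAsFactors = FALSE)
  list(features = assemble_features(ann, pw), annotation = ann,
       pathways = pw)
}

# Three pathways over 9 genes with hand-laid topology and overlaps.
small_collection <- function() {
  pathway_collection(list(
    list(id = "P1", genes = c("A", "B", "C"),
         edges = rbind(c("A", "B"), c("B", "C"), c("A", "C"))),  # triangle
    list(id = "P2", genes = c("C", "D", "E", "F", "H"),
         edges = rbind(c("H", "C"), c("H", "D"), c("H", "E"),
                       c("H", "F"))),                            # star, hub H
    list(id = "P3", genes = c("A", "G", "I"), edges = NULL)))    # isolated
}

small_annotation <- function() {
  data.frame(
    probe_id = sprintf("cg%02d", 1:12),
    gene_symbol = c("A", "A", "B", "C", "D", "E", "F", "G", "H", "I",
                    "Z", "C"),
    cgi_status = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                   TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# Fast MCMC settings for unit-scale checks.
quick_config <- function(seed = 1, n_iter = 1200, n_burnin = 200, thin = 2,
                         n_chains = 1) {
  mcmc_config(n_iter = n_iter, n_burnin = n_burnin, thin = thin,
              n_chains = n_chains, seed = seed)
}
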
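# Fixtures built in code: tiny abundance matrices, contrasts and graphs.

# abundance matrix from a list of per-group value matrices (proteins x reps)
make_abundance <- function(by_group, control = names(by_group)[1L],
                           protein_ids = NULL) {
  groups <- names(by_group)
  mats <- lapply(by_group, as.matrix)
  n <- nrow(mats[[1L]])
  if (is.null(protein_ids)) protein_ids <- sprintf("P%02d", seq_len(n))
  vals <- do.call(cbind, mats)
  sample_ids <- unlist(lapply(groups, function(g) {
    paste0(g, "_", seq_len(ncol(mats[[g]])))
  }))
  colnames(vals) <- sample_ids
  rownames(vals) <- protein_ids
  sg <- stats::setNames(rep(groups, vapply(mats, ncol, 1L)), sample_ids)
  abundance_matrix(vals, sg, control)
}

# contrast vector directly from a named logfc vector (NA = invalid)
fake_contrast <- function(logfc, case = "CASE", control = "CTRL") {
  structure(
    list(logfc = logfc, case_group = case, control_group = control,
         n_case = rep(3L, length(logfc)), n_control = rep(3L, length(logfc)),
         summary = "linear-mean"),
    class = "contrast_vector"
  )
}

# named undirected graph from an edge matrix / vector of pairs
named_graph <- function(edges, isolated = character(0)) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

# two-sided empirical p by direct counting, mirroring the add-one /
# exhaustive conventions, used as an independent check on tiny nulls
naive_two_sided_p <- function(obs, null, exhaustive = FALSE) {
  ctr <- mean(null)
  cnt <- sum(abs(null - ctr) >= abs(obs - ctr) - 1e-9)
  if (exhaustive) cnt / length(null) else (cnt + 1) / (length(null) + 1)
}
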
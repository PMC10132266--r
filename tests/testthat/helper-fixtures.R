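# Small in-code fixtures shared across test files.

# A feature_table built directly from a matrix, defaulting every feature to
# the clinical modality.
mk_table <- function(values, modality = NULL, scale_state = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (is.null(modality))
    modality <- stats::setNames(rep("clinical", ncol(values)),
                                colnames(values))
  feature_table(values, modality, scale_state = scale_state)
}

# Standardized two-node table whose single positive edge has co-expression
# score exactly `score` for every subject.
mk_edge_table <- function(scores_a, scores_b) {
  v <- cbind(A = scores_a, B = scores_b)
  rownames(v) <- paste0("s", seq_along(scores_a))
  feature_table(v, c(A = "protein", B = "protein"),
                scale_state = "standardized")
}

# Write a TSV matrix file (subjects in rows) plus its modality map; returns
# the two paths.
write_matrix_fixture <- function(values, modality,
                                 dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE)
  mat <- file.path(dir, "matrix.tsv")
  map <- file.path(dir, "map.tsv")
  df <- data.frame(subject_id = rownames(values), values,
                   check.names = FALSE)
  utils::write.table(df, mat, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(feature_id = names(modality),
                                modality = unname(modality)),
                     map, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mat, map = map)
}

# Minimal hand-built signature model with a single positive edge (A, B),
# shrunken centroids +1 / -1, unit scale (pooled_sd + s0 = 1), flat priors.
mk_one_edge_model <- function(classes = c("c1", "c2"),
                              centroids = c(1, -1), priors = c(0.5, 0.5)) {
  edges <- data.frame(node_a = "A", node_b = "B", sign = 1L,
                      edge_id = "A|B", stringsAsFactors = FALSE)
  cent <- matrix(centroids, 1L, 2L, dimnames = list("A|B", classes))
  structure(list(
    classes = classes,
    priors = stats::setNames(priors, classes),
    m_k = stats::setNames(c(0.5, 0.5), classes),
    edges = edges,
    overall_centroid = stats::setNames(0, "A|B"),
    class_centroids = cent,
    shrunken_centroids = cent,
    pooled_sd = stats::setNames(0.5, "A|B"),
    s0 = 0.5,
    d_scores = cent,
    shrunken_d = cent,
    delta_star = 0,
    cv_error_curve = data.frame(delta = 0, error = 0, se = 0),
    gate_passed = TRUE, n_folds = 2L, seed = 1L,
    selection = "gated_min", priors_mode = "empirical"),
    class = "signature_model")
}

# Brute-force AUC over all positive/negative pairs with ties counted 1/2.
auc_bruteforce <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# A small seeded synthetic dataset with signal, reused by the heavier tests.
mk_signal_dataset <- function(seed = 7, effect = 1, n_signal = 20) {
  cfg <- synthetic_config(structure = "random_sparse", density = 500 / 4950,
                          strength = 0.3, n_signal_edges = n_signal,
                          effect = effect, missing_rate = 0, seed = seed)
  generate_dataset(cfg)
}
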
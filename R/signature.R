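#' Per-subject edge co-expression scores
#'
#' For every network edge, combines the two standardized node values per
#' subject into a single score that carries the direction of the partial
#' correlation: `(z_a + z_b)/sqrt(2)` for a positive edge and
#' `(z_a - z_b)/sqrt(2)` for a negative edge (nodes in canonical table
#' order). The `1/sqrt(2)` factor keeps scores of independent unit-variance
#' nodes at unit variance. A score is missing iff either node value is
#' missing. Edges whose nodes are absent from the table are dropped with a
#' warning.
#'
#' @param table A standardized `feature_table`.
#' @param network A `precision_network`, or any data frame with columns
#'   `node_a`, `node_b`, `sign`.
#' @return An object of class `edge_score_matrix`: `edges` (data frame
#'   `node_a`, `node_b`, `sign`, `edge_id`), `scores` (subjects x edges
#'   matrix), `subject_ids`.
#' @export
coexpression_scores <- function(table, network) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale_state != "standardized")
    stop("co-expression scores require a standardized table")
  edges <- if (inherits(network, "precision_network")) network$edges
           else as.data.frame(network)
  stopifnot(all(c("node_a", "node_b", "sign") %in% colnames(edges)))
  feats <- feature_ids(table)
  present <- edges$node_a %in% feats & edges$node_b %in% feats
  if (!all(present)) {
    warning(sum(!present), " edge(s) dropped: node(s) absent from the table")
    edges <- edges[present, , drop = FALSE]
  }
  if (!nrow(edges)) stop("no network edge has both nodes in the table")
  # canonical orientation: node_a precedes node_b in the table's order
  ia <- match(edges$node_a, feats)
  ib <- match(edges$node_b, feats)
  flip <- ia > ib
  if (any(flip)) {
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
    t2 <- ia[flip]; ia[flip] <- ib[flip]; ib[flip] <- t2
  }
  edges <- edges[, c("node_a", "node_b", "sign")]
  edges$edge_id <- paste(edges$node_a, edges$node_b, sep = "|")
  dup <- duplicated(edges$edge_id)
  if (any(dup)) edges <- edges[!dup, , drop = FALSE]

  za <- table$values[, match(edges$node_a, feats), drop = FALSE]
  zb <- table$values[, match(edges$node_b, feats), drop = FALSE]
  sgn <- matrix(edges$sign, nrow(za), nrow(edges), byrow = TRUE)
  scores <- (za + sgn * zb) / sqrt(2)
  colnames(scores) <- edges$edge_id
  rownames(scores) <- subject_ids(table)
  structure(list(edges = edges, scores = scores,
                 subject_ids = subject_ids(table)),
            class = "edge_score_matrix")
}

#' @export
print.edge_score_matrix <- function(x, ...) {
  cat(sprintf("edge_score_matrix: %d subjects x %d edges (%d missing scores)\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  invisible(x)
}

#' Shrunken-centroid class statistics on edge scores
#'
#' Computes, per edge i and class k: class centroids `xbar_ik`, overall
#' centroid `xbar_i`, pooled within-class standard deviation `s_i`, the
#' offset `s0` (median of `s_i` over edges), the contrast scale
#' `m_k = sqrt(1/n_k - 1/n)`, empirical priors `pi_k = n_k/n`, and the
#' d-scores `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))`. All moments use
#' observed scores only; an edge unobserved in a class contributes a zero
#' d-score for that class.
#'
#' @param E An `edge_score_matrix`.
#' @param labels Class label per subject (character/factor), in `E`'s subject
#'   order or named by subject id.
#' @param classes Optional explicit class order (default: order of first
#'   appearance).
#' @param priors `"empirical"` (class frequencies) or `"equal"`.
#' @return List with `classes`, `n_k`, `pi_k`, `m_k`, `overall_centroid`,
#'   `class_centroids`, `pooled_sd`, `s0`, `d_scores`.
#' @export
class_statistics <- function(E, labels, classes = NULL,
                             priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  labels <- align_labels(labels, E$subject_ids)
  if (is.null(classes)) classes <- unique(labels)
  stopifnot(all(labels %in% classes), length(classes) >= 2L)
  n_k <- vapply(classes, function(k) sum(labels == k), 0L)
  if (any(n_k < 2L))
    stop("every class needs at least 2 subjects; counts: ",
         paste(sprintf("%s=%d", classes, n_k), collapse = ", "))
  n <- length(labels)
  X <- E$scores
  K <- length(classes)
  E_n <- ncol(X)

  overall <- colMeans(X, na.rm = TRUE)
  cls_cent <- matrix(NA_real_, E_n, K, dimnames = list(colnames(X), classes))
  ss_within <- rep(0, E_n)
  n_obs <- rep(0L, E_n)
  for (k in seq_len(K)) {
    Xk <- X[labels == classes[k], , drop = FALSE]
    mk <- colMeans(Xk, na.rm = TRUE)
    cls_cent[, k] <- mk
    dev <- sweep(Xk, 2L, mk)
    ss_within <- ss_within + colSums(dev^2, na.rm = TRUE)
    n_obs <- n_obs + colSums(!is.na(Xk))
  }
  # edge unobserved in a class: centroid falls back to the overall centroid
  unobserved <- is.na(cls_cent)
  if (any(unobserved))
    cls_cent[unobserved] <- matrix(overall, E_n, K)[unobserved]
  pooled_sd <- sqrt(ss_within / pmax(n_obs - K, 1L))
  s0 <- stats::median(pooled_sd)
  m_k <- sqrt(1 / n_k - 1 / n)
  d <- (cls_cent - overall) / outer(pooled_sd + s0, m_k)
  pi_k <- if (priors == "empirical") n_k / n else rep(1 / K, K)
  names(pi_k) <- classes
  list(classes = classes, n_k = n_k, pi_k = pi_k, m_k = m_k,
       overall_centroid = overall, class_centroids = cls_cent,
       pooled_sd = pooled_sd, s0 = s0, d_scores = d)
}

align_labels <- function(labels, subject_ids) {
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    miss <- setdiff(subject_ids, names(labels))
    if (length(miss))
      stop("labels missing for subject(s): ", paste(miss, collapse = ", "))
    labels <- unname(labels[subject_ids])
  } else if (length(labels) != length(subject_ids)) {
    stop("labels must match the number of subjects")
  }
  labels
}

#' Soft-threshold d-scores
#'
#' `d' = sign(d) * max(|d| - delta, 0)`: the sparsity-inducing shrinkage of
#' the nearest-shrunken-centroid construction.
#'
#' @param d Numeric vector/matrix of d-scores.
#' @param delta Non-negative shrinkage amount.
#' @return Shrunken d-scores, same shape as `d`.
#' @export
soft_threshold <- function(d, delta) {
  stopifnot(delta >= 0)
  sign(d) * pmax(abs(d) - delta, 0)
}

# Shrunken class centroids from statistics and a shrinkage level.
shrunken_centroids <- function(stats, delta) {
  d_shr <- soft_threshold(stats$d_scores, delta)
  cent <- stats$overall_centroid +
    (stats$pooled_sd + stats$s0) * d_shr %*% diag(stats$m_k,
                                                  length(stats$m_k))
  dimnames(cent) <- dimnames(stats$class_centroids)
  list(centroids = cent, d_shrunken = d_shr)
}

# Discriminant scores for a score matrix X (subjects x edges, NA allowed):
# delta_k = sum over observed edges of (x_i - centroid_ik)^2 / scale_i^2
#           - 2 log pi_k.
# Subjects with no observed edge fall back to the priors.
discriminant_scores <- function(X, centroids, scale, pi_k) {
  K <- ncol(centroids)
  n <- nrow(X)
  delta <- matrix(NA_real_, n, K,
                  dimnames = list(rownames(X), colnames(centroids)))
  for (k in seq_len(K)) {
    dev <- sweep(X, 2L, centroids[, k]) / rep(scale, each = n)
    delta[, k] <- rowSums(dev^2, na.rm = TRUE) - 2 * log(pi_k[k])
  }
  edges_used <- rowSums(!is.na(X))
  no_info <- edges_used == 0L
  # softmax of -delta/2 with max-subtraction
  z <- -delta / 2
  z <- z - apply(z, 1L, max)
  prob <- exp(z) / rowSums(exp(z))
  if (any(no_info)) prob[no_info, ] <- rep(pi_k, each = sum(no_info))
  predicted <- colnames(centroids)[max.col(prob, ties.method = "first")]
  list(delta = delta, probabilities = prob, predicted = predicted,
       edges_used = edges_used)
}

#' Default shrinkage grid
#'
#' Equally spaced values from 0 to the largest |d-score|.
#'
#' @param d_scores Matrix of d-scores.
#' @param n_delta Grid size (default 30).
#' @return Increasing numeric vector of shrinkage levels.
#' @export
default_delta_grid <- function(d_scores, n_delta = 30L) {
  dmax <- max(abs(d_scores))
  if (!is.finite(dmax) || dmax == 0) dmax <- 1
  seq(0, dmax, length.out = n_delta)
}

#' Cross-validated selection of the shrinkage level
#'
#' Stratified k-fold cross-validation of the shrunken-centroid classifier on
#' edge scores: folds are assigned by a seeded shuffle within class, class
#' statistics are refit on each training split, and held-out subjects are
#' classified by the discriminant rule at every shrinkage level.
#'
#' Three selection rules are available. `"gated_min"` (the default) first
#' asks whether any shrinkage level improves significantly on the empty,
#' prior-only classifier -- a paired one-sided t-test of fold errors at
#' Bonferroni-corrected level 0.05 over the grid; if none does, the largest
#' (fully shrunken) level is selected, so label-free data yield an empty
#' signature rather than a noise-driven one. When the gate passes, and under
#' `"min"`, the level minimizing the mean misclassification error is taken,
#' ties broken toward the largest level (sparsest classifier). `"1se"` takes
#' the largest level within one standard error (over folds) of the minimum.
#'
#' @param E An `edge_score_matrix`.
#' @param labels Class label per subject.
#' @param grid Shrinkage grid; defaults to [default_delta_grid()] on the
#'   full-data d-scores.
#' @param n_folds Number of folds (default 10; reduced with a warning when a
#'   class is smaller than the fold count).
#' @param seed Seed for the fold shuffle (default 1).
#' @param classes,priors Passed to [class_statistics()].
#' @param selection `"gated_min"`, `"min"` or `"1se"`.
#' @return List with `cv_error_curve` (data frame: `delta`, `error`, `se`),
#'   `delta_star`, `n_folds`, `folds` (assignment per subject),
#'   `gate_passed` (significance gate verdict, `NA` unless `"gated_min"`).
#' @export
cross_validate <- function(E, labels, grid = NULL, n_folds = 10L, seed = 1L,
                           classes = NULL, priors = c("empirical", "equal"),
                           selection = c("gated_min", "min", "1se")) {
  priors <- match.arg(priors)
  selection <- match.arg(selection)
  labels <- align_labels(labels, E$subject_ids)
  if (is.null(classes)) classes <- unique(labels)
  if (length(classes) < 2L) stop("cross-validation needs at least 2 classes")
  n_k <- vapply(classes, function(k) sum(labels == k), 0L)
  if (min(n_k) < n_folds) {
    n_folds <- max(2L, min(n_k))
    warning("smallest class has ", min(n_k),
            " subjects; n_folds reduced to ", n_folds)
  }
  if (is.null(grid)) {
    full <- class_statistics(E, labels, classes = classes, priors = priors)
    grid <- default_delta_grid(full$d_scores)
  }
  grid <- sort(grid)
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    for (k in classes) {
      idx <- which(labels == k)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  err <- matrix(NA_real_, n_folds, length(grid))
  err_ref <- numeric(n_folds)   # empty (prior-only) classifier per fold
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    Etr <- subset_edge_scores(E, tr)
    st <- class_statistics(Etr, labels[tr], classes = classes,
                           priors = priors)
    Xte <- E$scores[!tr, , drop = FALSE]
    yte <- labels[!tr]
    for (g in seq_along(grid)) {
      sc <- shrunken_centroids(st, grid[g])
      pred <- discriminant_scores(Xte, sc$centroids,
                                  st$pooled_sd + st$s0, st$pi_k)$predicted
      err[f, g] <- mean(pred != yte)
    }
    prior_class <- classes[which.max(st$pi_k)]
    err_ref[f] <- mean(yte != prior_class)
  }
  curve <- data.frame(delta = grid,
                      error = colMeans(err),
                      se = apply(err, 2L, stats::sd) / sqrt(n_folds))
  sel <- select_delta(curve, selection, err, err_ref)
  list(cv_error_curve = curve, delta_star = sel$delta_star,
       n_folds = n_folds, folds = fold, selection = selection,
       gate_passed = sel$gate_passed)
}

select_delta <- function(curve, selection, err = NULL, err_ref = NULL,
                         alpha = 0.05) {
  i_min <- which(curve$error <= min(curve$error))
  gate_passed <- NA
  if (selection == "1se") {
    best <- max(i_min)
    cutoff <- curve$error[best] + curve$se[best]
    return(list(delta_star = max(curve$delta[curve$error <= cutoff]),
                gate_passed = gate_passed))
  }
  if (selection == "gated_min") {
    # one-sided paired t-test per grid point: does this classifier beat the
    # prior-only classifier across folds? Bonferroni over the grid.
    p <- vapply(seq_len(ncol(err)), function(g) {
      d <- err[, g] - err_ref
      s <- stats::sd(d)
      if (is.na(s) || s == 0) return(if (mean(d) < 0) 0 else 1)
      stats::pt(mean(d) / (s / sqrt(length(d))), df = length(d) - 1)
    }, 0)
    gate_passed <- any(p < alpha / length(p))
    if (!gate_passed)
      return(list(delta_star = max(curve$delta), gate_passed = FALSE))
  }
  list(delta_star = max(curve$delta[i_min]), gate_passed = gate_passed)
}

subset_edge_scores <- function(E, keep) {
  E$scores <- E$scores[keep, , drop = FALSE]
  E$subject_ids <- E$subject_ids[keep]
  E
}

#' Fit a predictive subnetwork signature
#'
#' The supervised stage: edge co-expression scores are computed against the
#' background network, shrunken-centroid d-scores are derived per outcome
#' class, the shrinkage level is chosen by stratified cross-validation, and
#' the edges with a nonzero shrunken d-score form the signature. Edges
#' observed in fewer than `min_obs_fraction` of subjects are excluded from
#' the search.
#'
#' @param table A standardized `feature_table` of the training cohort.
#' @param network A `precision_network` (background network).
#' @param labels Class label per subject (vector, or named by subject id).
#' @param classes Optional explicit class order.
#' @param priors `"empirical"` or `"equal"`.
#' @param n_folds,seed,grid,selection Passed to [cross_validate()].
#' @param n_delta Grid size when `grid` is `NULL`.
#' @param min_obs_fraction Minimum observed-score fraction per edge
#'   (default 0.5).
#' @return An object of class `signature_model`.
#' @export
fit_signature <- function(table, network, labels, classes = NULL,
                          priors = c("empirical", "equal"), n_folds = 10L,
                          seed = 1L, grid = NULL, n_delta = 30L,
                          selection = c("gated_min", "min", "1se"),
                          min_obs_fraction = 0.5) {
  priors <- match.arg(priors)
  selection <- match.arg(selection)
  E <- coexpression_scores(table, network)
  obs_frac <- colMeans(!is.na(E$scores))
  keep <- obs_frac >= min_obs_fraction
  if (!all(keep)) {
    warning(sum(!keep), " edge(s) observed in < ",
            round(100 * min_obs_fraction), "% of subjects excluded")
    E$edges <- E$edges[keep, , drop = FALSE]
    E$scores <- E$scores[, keep, drop = FALSE]
  }
  labels <- align_labels(labels, E$subject_ids)
  if (is.null(classes)) classes <- unique(labels)
  st <- class_statistics(E, labels, classes = classes, priors = priors)
  if (is.null(grid)) grid <- default_delta_grid(st$d_scores, n_delta)
  cv <- cross_validate(E, labels, grid = grid, n_folds = n_folds,
                       seed = seed, classes = classes, priors = priors,
                       selection = selection)
  sc <- shrunken_centroids(st, cv$delta_star)
  active <- rowSums(sc$d_shrunken != 0) > 0
  if (!any(active))
    warning("empty signature: every d-score shrunk to zero at delta* = ",
            signif(cv$delta_star, 4))
  model <- structure(list(
    classes = st$classes, priors = st$pi_k, m_k = st$m_k,
    edges = E$edges[active, , drop = FALSE],
    overall_centroid = st$overall_centroid[active],
    class_centroids = st$class_centroids[active, , drop = FALSE],
    shrunken_centroids = sc$centroids[active, , drop = FALSE],
    pooled_sd = st$pooled_sd[active], s0 = st$s0,
    d_scores = st$d_scores[active, , drop = FALSE],
    shrunken_d = sc$d_shrunken[active, , drop = FALSE],
    delta_star = cv$delta_star, cv_error_curve = cv$cv_error_curve,
    gate_passed = cv$gate_passed,
    n_folds = cv$n_folds, seed = seed, selection = selection,
    priors_mode = priors),
    class = "signature_model")
  model
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("signature_model: %d edges, classes {%s}\n", nrow(x$edges),
              paste(x$classes, collapse = ", ")))
  i <- which(x$cv_error_curve$delta == x$delta_star)[1L]
  cat(sprintf("  delta* = %.4g (CV error %.3f, %d folds, seed %d)\n",
              x$delta_star, x$cv_error_curve$error[i], x$n_folds, x$seed))
  invisible(x)
}

#' Export a signature model
#'
#' Writes (i) `signature.tsv` with the selected edges, signs, d-scores,
#' shrunken d-scores and centroids per class; (ii)
#' `signature_cytoscape.tsv` with per-edge display attributes (color key
#' from the sign of the outcome-class d-score, width key from its
#' magnitude); (iii) `model.json`, a full serialization sufficient to
#' reconstruct the model for prediction via [read_signature()].
#'
#' @param model A `signature_model`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_signature <- function(model, dir) {
  stopifnot(inherits(model, "signature_model"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  sig_path <- file.path(dir, "signature.tsv")
  cyt_path <- file.path(dir, "signature_cytoscape.tsv")
  json_path <- file.path(dir, "model.json")

  tab <- model$edges[, c("node_a", "node_b", "sign")]
  for (k in model$classes) {
    tab[[paste0("d_", k)]] <- model$d_scores[, k]
    tab[[paste0("d_shrunken_", k)]] <- model$shrunken_d[, k]
    tab[[paste0("centroid_", k)]] <- model$shrunken_centroids[, k]
  }
  utils::write.table(tab, sig_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  outcome <- model$classes[length(model$classes)]
  d_out <- if (nrow(model$edges)) model$d_scores[, outcome] else numeric()
  cyt <- data.frame(
    edge = paste(model$edges$node_a,
                 ifelse(model$edges$sign > 0, "(pp)", "(pn)"),
                 model$edges$node_b),
    color_key = ifelse(d_out >= 0, "up_in_outcome", "down_in_outcome"),
    width_key = abs(d_out))
  utils::write.table(cyt, cyt_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(unclass(model), json_path, auto_unbox = TRUE,
                       digits = I(17), matrix = "rowmajor",
                       dataframe = "columns")
  invisible(c(signature = sig_path, cytoscape = cyt_path,
              model = json_path))
}

#' Read a serialized signature model
#'
#' @param path Path to a `model.json` written by [export_signature()].
#' @return A `signature_model` giving identical predictions to the original.
#' @export
read_signature <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- length(m$classes)
  as_mat <- function(x) {
    x <- matrix(unlist(x), ncol = K,
                dimnames = list(m$edges$node_a, m$classes))
    rownames(x) <- paste(m$edges$node_a, m$edges$node_b, sep = "|")
    x
  }
  m$edges <- as.data.frame(m$edges, stringsAsFactors = FALSE)
  if (nrow(m$edges)) {
    m$class_centroids <- as_mat(m$class_centroids)
    m$shrunken_centroids <- as_mat(m$shrunken_centroids)
    m$d_scores <- as_mat(m$d_scores)
    m$shrunken_d <- as_mat(m$shrunken_d)
    nm <- rownames(m$d_scores)
    m$overall_centroid <- stats::setNames(m$overall_centroid, nm)
    m$pooled_sd <- stats::setNames(m$pooled_sd, nm)
  } else {
    empty <- matrix(numeric(), 0L, K, dimnames = list(NULL, m$classes))
    m$class_centroids <- m$shrunken_centroids <- empty
    m$d_scores <- m$shrunken_d <- empty
  }
  m$priors <- stats::setNames(unlist(m$priors), m$classes)
  m$m_k <- stats::setNames(unlist(m$m_k), m$classes)
  m$cv_error_curve <- as.data.frame(m$cv_error_curve)
  structure(m, class = "signature_model")
}

# Evaluate code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
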
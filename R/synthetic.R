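#' Build a sparse positive-definite precision matrix
#'
#' `"banded"` gives a tridiagonal matrix with unit diagonal and constant
#' `strength` off-diagonal (eigenvalues `1 + 2 * strength * cos(k*pi/(p+1))`,
#' positive for `|strength| < 0.5`). `"random_sparse"` draws a symmetric
#' support of `round(density * p*(p-1)/2)` edges with entries of magnitude
#' `strength` and random sign, then shifts the diagonal so the smallest
#' eigenvalue is at least 0.1.
#'
#' @param p Number of features (>= 2).
#' @param structure `"banded"` or `"random_sparse"`.
#' @param density Edge density in `(0, 1]` for `"random_sparse"`; 0 is
#'   allowed and yields a diagonal matrix.
#' @param strength Off-diagonal magnitude.
#' @param seed Seed for the random support/signs.
#' @return A symmetric positive-definite matrix.
#' @export
make_precision <- function(p, structure = c("banded", "random_sparse"),
                           density = 0.05, strength = 0.4, seed = 1L) {
  structure <- match.arg(structure)
  stopifnot(p >= 2L)
  omega <- diag(p)
  if (structure == "banded") {
    for (i in seq_len(p - 1L)) {
      omega[i, i + 1L] <- strength
      omega[i + 1L, i] <- strength
    }
  } else {
    stopifnot(density >= 0, density <= 1)
    pairs <- which(upper.tri(omega), arr.ind = TRUE)
    m <- round(density * nrow(pairs))
    if (m > 0L) {
      with_seed(seed, {
        sel <- sample(nrow(pairs), m)
        sgn <- sample(c(-1, 1), m, replace = TRUE)
        for (e in seq_len(m)) {
          i <- pairs[sel[e], 1L]; j <- pairs[sel[e], 2L]
          omega[i, j] <- omega[j, i] <- sgn[e] * strength
        }
      })
    }
  }
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 0.1) {
    shift <- 0.1 - ev_min
    if (shift > 50)
      stop("cannot reach positive definiteness with a reasonable diagonal")
    diag(omega) <- diag(omega) + shift
  }
  omega
}

#' Sample from a zero-mean Gaussian with a given precision matrix
#'
#' @param precision Symmetric positive-definite precision matrix.
#' @param n Number of draws.
#' @param seed Seed.
#' @return An `n x p` matrix.
#' @export
sample_mvn <- function(precision, n, seed = 1L) {
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix is not positive definite")
  sigma <- solve(precision)
  sigma <- (sigma + t(sigma)) / 2
  x <- with_seed(seed, MASS::mvrnorm(n, mu = rep(0, ncol(precision)),
                                     Sigma = sigma))
  if (n == 1L) x <- matrix(x, nrow = 1L)
  x
}

#' Inject a group-specific co-expression shift along edges
#'
#' For class-1 (outcome) subjects, adds `effect/sqrt(2)` to both node columns
#' of each positive edge, and `+effect/sqrt(2)` / `-effect/sqrt(2)` to the two
#' nodes of a negative edge, so that the edge's co-expression centroid shifts
#' by approximately `effect` while class-0 marginals are untouched.
#'
#' @param data Numeric matrix (subjects x features).
#' @param edges Data frame with integer/feature-name columns `node_a`,
#'   `node_b` and `sign` in `{-1, 1}`.
#' @param effect Shift on the co-expression score scale.
#' @param labels Binary vector; the second level (by first appearance)
#'   receives the shift. Unbalanced labels yield a warning only.
#' @return The shifted matrix.
#' @export
inject_signal <- function(data, edges, effect, labels) {
  if (effect == 0 || nrow(edges) == 0L) return(data)
  labels <- as.character(labels)
  lv <- unique(labels)
  stopifnot(length(lv) == 2L, length(labels) == nrow(data))
  if (sum(labels == lv[1L]) != sum(labels == lv[2L]))
    warning("labels are unbalanced; signal injected into class ", lv[2L])
  shifted <- labels == lv[2L]
  col_idx <- function(x) if (is.numeric(x)) x else match(x, colnames(data))
  ia <- col_idx(edges$node_a); ib <- col_idx(edges$node_b)
  stopifnot(!anyNA(ia), !anyNA(ib))
  h <- effect / sqrt(2)
  for (e in seq_len(nrow(edges))) {
    data[shifted, ia[e]] <- data[shifted, ia[e]] + h
    data[shifted, ib[e]] <- data[shifted, ib[e]] + edges$sign[e] * h
  }
  data
}

#' Mask entries completely at random
#'
#' @param data Numeric matrix.
#' @param rate Missingness rate in `[0, 1)`.
#' @param seed Seed for the mask.
#' @return The matrix with masked entries set to `NA`.
#' @export
inject_missing <- function(data, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(data)
  mask <- with_seed(seed,
                    matrix(stats::runif(length(data)) < rate, nrow(data)))
  data[mask] <- NA_real_
  data
}

#' Default configuration for the synthetic generator
#'
#' A desk-scale stand-in for a multi-modal post-MI cohort: 100 features split
#' across five modalities, two balanced outcome classes of 150 subjects, a
#' banded precision structure of strength 0.4 (partial correlations around
#' 0.4, comparable to the strongest edges seen in clinical multi-omics
#' networks), 20 signal edges with a unit co-expression shift, and 5%
#' missingness.
#'
#' @param ... Overrides for any field.
#' @return A named list of generator settings.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    p_per_modality = c(protein = 60L, lipid = 15L, acylcarnitine = 10L,
                       imaging = 10L, clinical = 5L),
    n_per_class = 150L,
    classes = c("event_free", "outcome"),
    structure = "banded",
    density = 0.05,
    strength = 0.4,
    n_signal_edges = 20L,
    effect = 1,
    missing_rate = 0.05,
    seed = 1L)
  upd <- list(...)
  stopifnot(all(names(upd) %in% names(cfg)))
  cfg[names(upd)] <- upd
  cfg
}

#' Generate a ground-truthed multi-modal dataset
#'
#' End-to-end generator: draws Gaussian data under a known sparse precision
#' matrix, injects a class-specific mean shift along randomly chosen signal
#' edges (on the co-expression scale), exponentiates the molecular modality
#' blocks to a positive raw scale (so the log2 path is exercised), and masks
#' entries completely at random. All ground truth is returned alongside the
#' raw `feature_table`.
#'
#' @param config A list from [synthetic_config()].
#' @return An object of class `synthetic_dataset` with fields `table`
#'   (raw-scale `feature_table`), `true_precision`, `true_edges` (data frame
#'   `node_a`, `node_b`, `sign`, `partial_correlation`), `signal_edges`,
#'   `labels` (named by subject), `effect`, `missing_rate`, `seed`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- config
  p <- sum(cfg$p_per_modality)
  mods <- rep(names(cfg$p_per_modality), cfg$p_per_modality)
  feats <- paste0(substr(mods, 1, 4), "_",
                  unlist(lapply(cfg$p_per_modality, seq_len)))
  n <- 2L * cfg$n_per_class
  labels <- rep(cfg$classes, each = cfg$n_per_class)
  subjects <- sprintf("S%03d", seq_len(n))

  omega <- make_precision(p, cfg$structure, cfg$density, cfg$strength,
                          seed = cfg$seed)
  d <- sqrt(diag(omega))
  idx <- which(omega != 0 & upper.tri(omega), arr.ind = TRUE)
  true_edges <- data.frame(
    node_a = feats[idx[, 1L]], node_b = feats[idx[, 2L]],
    partial_correlation = -omega[idx] / (d[idx[, 1L]] * d[idx[, 2L]]),
    stringsAsFactors = FALSE)
  true_edges$sign <- ifelse(true_edges$partial_correlation >= 0, 1L, -1L)

  x <- sample_mvn(omega, n, seed = cfg$seed + 1L)
  n_sig <- min(cfg$n_signal_edges, nrow(true_edges))
  signal_edges <- if (n_sig > 0L) {
    sel <- with_seed(cfg$seed + 2L, sample(nrow(true_edges), n_sig))
    true_edges[sel, , drop = FALSE]
  } else true_edges[0L, , drop = FALSE]
  if (cfg$effect != 0 && n_sig > 0L) {
    se <- signal_edges
    se$node_a <- match(se$node_a, feats)
    se$node_b <- match(se$node_b, feats)
    x <- inject_signal(x, se, cfg$effect, labels)
  }
  # molecular modalities live on a positive raw scale; log2 recovers the
  # Gaussian values
  molecular <- mods %in% c("protein", "lipid", "acylcarnitine")
  x[, molecular] <- 2^x[, molecular]
  x <- inject_missing(x, cfg$missing_rate, seed = cfg$seed + 3L)
  dimnames(x) <- list(subjects, feats)
  table <- feature_table(x, stats::setNames(mods, feats),
                         scale_state = "raw",
                         provenance = sprintf("synthetic (seed %d)",
                                              cfg$seed))
  structure(list(table = table, true_precision = omega,
                 true_edges = true_edges, signal_edges = signal_edges,
                 labels = stats::setNames(labels, subjects),
                 effect = cfg$effect, missing_rate = cfg$missing_rate,
                 seed = cfg$seed, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d subjects x %d features, %d true edges, %d signal edges (effect %g, missing %g, seed %d)\n",
    nrow(x$table$values), ncol(x$table$values), nrow(x$true_edges),
    nrow(x$signal_edges), x$effect, x$missing_rate, x$seed))
  invisible(x)
}

#' Ground-truth network of a synthetic dataset
#'
#' Wraps the true precision matrix as a `precision_network` so it can serve
#' as the background network of the supervised stage.
#'
#' @param dataset A `synthetic_dataset`.
#' @return A `precision_network`.
#' @export
true_network <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  omega <- dataset$true_precision
  dimnames(omega) <- list(feature_ids(dataset$table),
                          feature_ids(dataset$table))
  to_partial_correlations(omega, feature_ids(dataset$table),
                          dataset$table$modality,
                          n = nrow(dataset$table$values))
}

#' Edge-recovery precision/recall/F1 against a truth set
#'
#' Edges are compared as unordered node pairs.
#'
#' @param estimated,truth Data frames with columns `node_a`, `node_b`.
#' @return List with `precision`, `recall`, `f1`, `n_estimated`, `n_true`.
#' @export
edge_f1 <- function(estimated, truth) {
  key <- function(e) {
    if (!nrow(e)) return(character())
    paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b), sep = "|")
  }
  est <- unique(key(estimated)); tru <- unique(key(truth))
  tp <- length(intersect(est, tru))
  prec <- if (length(est)) tp / length(est) else 0
  rec <- if (length(tru)) tp / length(tru) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       n_estimated = length(est), n_true = length(tru))
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the raw matrix TSV, the modality map, the labels file, and a truth
#' JSON (precision support, signal edges), matching the formats consumed by
#' [read_feature_table()].
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  mat_path <- file.path(dir, "matrix.tsv")
  map_path <- file.path(dir, "modality_map.tsv")
  lab_path <- file.path(dir, "labels.tsv")
  truth_path <- file.path(dir, "truth.json")
  v <- dataset$table$values
  df <- data.frame(subject_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, mat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = names(dataset$table$modality),
               modality = unname(dataset$table$modality)),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(subject_id = names(dataset$labels),
               class = unname(dataset$labels)),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(true_edges = dataset$true_edges,
         signal_edges = dataset$signal_edges,
         effect = dataset$effect, missing_rate = dataset$missing_rate,
         seed = dataset$seed),
    truth_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(c(matrix = mat_path, modality_map = map_path,
              labels = lab_path, truth = truth_path))
}
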
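#' Standardize a new cohort with its own moments
#'
#' External cohorts are pareto-scaled using their own per-feature means and
#' standard deviations, never the training cohort's; this keeps the score
#' scale comparable when the two cohorts were assayed on different platforms.
#' A feature that is constant in the new cohort cannot be scaled and becomes
#' all-missing with a warning instead of aborting the prediction.
#'
#' @param table A `feature_table` on the raw or log scale.
#' @return The standardized table.
#' @export
standardize_new <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 2L) stop("standardization needs >= 2 subjects")
  if (table$scale_state == "standardized") return(table)
  v <- table$values
  dropped <- character()
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    obs <- !is.na(x)
    s <- if (sum(obs) >= 2L) stats::sd(x[obs]) else 0
    if (is.na(s) || s == 0) {
      v[, j] <- NA_real_
      dropped <- c(dropped, colnames(v)[j])
    } else {
      v[, j] <- (x - mean(x[obs])) / sqrt(s)
    }
  }
  if (length(dropped))
    warning("constant/undersampled feature(s) set to missing: ",
            paste(dropped, collapse = ", "))
  table$values <- v
  table$scale_state <- "standardized"
  table
}

#' Predict class membership from a subnetwork signature
#'
#' Applies a fitted `signature_model` to a standardized cohort. For each
#' subject, co-expression scores are computed for the signature edges whose
#' two nodes are both observed; the discriminant score per class is
#' `delta_k = sum_i (x_i - centroid_ik)^2 / (s_i + s0)^2 - 2 log pi_k`, summed
#' over that same available edge set for every class, and converted to class
#' probabilities by `exp(-delta/2)` normalization (max-subtracted). Subjects
#' with no computable signature edge fall back to the prior probabilities and
#' are flagged; subjects with fewer than half the signature edges available
#' are flagged as `partial`.
#'
#' @param object A `signature_model`.
#' @param table A `feature_table` standardized via [standardize_new()] (or
#'   the training-side [pareto_scale()]).
#' @param ... Unused.
#' @return A `prediction_result` data frame: `subject_id`, one `delta_<k>`
#'   and `prob_<k>` column per class, `predicted_class`, `edges_used`,
#'   `flag`.
#' @export
predict.signature_model <- function(object, table, ...) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale_state != "standardized")
    stop("standardize the cohort first (standardize_new)")
  X <- signature_scores(object, table)
  res <- discriminant_scores(X, object$shrunken_centroids,
                             object$pooled_sd + object$s0, object$priors)
  n_sig <- nrow(object$edges)
  if (n_sig > 0L && all(res$edges_used == 0L))
    stop("no signature edge is computable for any subject")
  flag <- ifelse(res$edges_used == 0L, "no_edges",
                 ifelse(res$edges_used < n_sig / 2, "partial", "ok"))
  out <- data.frame(subject_id = subject_ids(table),
                    stringsAsFactors = FALSE)
  for (k in object$classes) out[[paste0("delta_", k)]] <- res$delta[, k]
  for (k in object$classes) out[[paste0("prob_", k)]] <-
    res$probabilities[, k]
  out$predicted_class <- res$predicted
  out$edges_used <- res$edges_used
  out$flag <- flag
  class(out) <- c("prediction_result", "data.frame")
  out
}

# Score matrix (subjects x signature edges) for the model's edges; NA where a
# node is missing or absent from the table entirely.
signature_scores <- function(model, table) {
  feats <- feature_ids(table)
  n <- nrow(table$values)
  m <- nrow(model$edges)
  X <- matrix(NA_real_, n, m,
              dimnames = list(subject_ids(table),
                              paste(model$edges$node_a, model$edges$node_b,
                                    sep = "|")))
  if (!m) return(X)
  for (i in seq_len(m)) {
    a <- model$edges$node_a[i]; b <- model$edges$node_b[i]
    if (!(a %in% feats) || !(b %in% feats)) next
    X[, i] <- (table$values[, a] +
               model$edges$sign[i] * table$values[, b]) / sqrt(2)
  }
  X
}

#' Quantile-based risk stratification
#'
#' Cuts per-subject outcome probabilities into `n_groups` ordered strata
#' (tertiles by default); ties on a boundary go to the lower stratum. If the
#' scores admit fewer distinct quantile boundaries than requested, strata are
#' collapsed with a warning (all-equal scores end up in stratum 1).
#'
#' @param scores Numeric vector (e.g. predicted outcome-class probability).
#' @param n_groups Number of strata (default 3).
#' @return Integer vector of stratum assignments in `1..n_groups`, with the
#'   boundaries in attribute `"boundaries"`.
#' @export
stratify <- function(scores, n_groups = 3L) {
  stopifnot(n_groups >= 1L)
  if (length(scores) < n_groups)
    stop("fewer subjects (", length(scores), ") than groups (", n_groups, ")")
  if (n_groups == 1L)
    return(structure(rep(1L, length(scores)), boundaries = numeric()))
  br <- stats::quantile(scores, probs = seq(0, 1, length.out = n_groups + 1),
                        na.rm = TRUE, names = FALSE)
  inner <- br[-c(1L, length(br))]
  if (anyDuplicated(inner) || length(unique(br)) < 2L) {
    warning("degenerate quantile boundaries; strata collapsed")
    inner <- unique(inner[!duplicated(inner)])
    if (length(unique(scores)) == 1L)
      return(structure(rep(1L, length(scores)), boundaries = numeric()))
  }
  g <- 1L + rowSums(outer(scores, inner, `>`))
  structure(as.integer(g), boundaries = inner)
}

#' ROC AUC with a bootstrap confidence interval
#'
#' The AUC is computed by the rank (Mann-Whitney) formulation with ties
#' counted 1/2; the confidence interval by seeded stratified bootstrap
#' (percentile method).
#'
#' @param scores Numeric score per subject (higher = more outcome-like).
#' @param labels Binary labels; `positive` names the outcome level.
#' @param positive Positive class (default: last level by first appearance).
#' @param n_boot Bootstrap replicates (default 2000; 0 skips the interval).
#' @param conf Confidence level (default 0.95).
#' @param seed Bootstrap seed (default 1).
#' @return List with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
auc <- function(scores, labels, positive = NULL, n_boot = 2000L,
                conf = 0.95, seed = 1L) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("AUC needs exactly 2 classes present; got ", length(lv))
  if (is.null(positive)) positive <- lv[2L]
  stopifnot(positive %in% lv)
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  point <- auc_rank(scores, pos)
  if (n_boot <= 0)
    return(list(auc = point, ci_low = NA_real_, ci_high = NA_real_,
                n_pos = sum(pos), n_neg = sum(!pos)))
  ip <- which(pos); inn <- which(!pos)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bp <- sample(ip, replace = TRUE)
      bn <- sample(inn, replace = TRUE)
      auc_rank(c(scores[bp], scores[bn]),
               c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
    }, 0)
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  list(auc = point, ci_low = ci[1L], ci_high = ci[2L],
       n_pos = sum(pos), n_neg = sum(!pos))
}

auc_rank <- function(scores, pos) {
  r <- rank(scores)  # midranks handle ties as 1/2
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-edge AUC table for a signature
#'
#' Evaluates each signature edge's co-expression score as a standalone
#' marker: AUC with bootstrap CI against binary labels, alongside the edge's
#' d-scores. Rows are sorted by AUC, descending; edges with no observed
#' score get a missing AUC and a warning.
#'
#' @param model A `signature_model` with two classes.
#' @param E An `edge_score_matrix` holding scores for (at least) the
#'   signature edges.
#' @param labels Binary class label per subject of `E`.
#' @param positive Outcome class (default: the model's last class).
#' @param n_boot,seed Passed to [auc()].
#' @return Data frame: `node_a`, `node_b`, `sign`, `auc`, `ci_low`,
#'   `ci_high`, one `d_<class>` column per class.
#' @export
edge_auc_table <- function(model, E, labels, positive = NULL,
                           n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(model, "signature_model"),
            inherits(E, "edge_score_matrix"))
  labels <- align_labels(labels, E$subject_ids)
  if (length(unique(labels)) != 2L) stop("labels must be binary")
  if (is.null(positive)) positive <- model$classes[length(model$classes)]
  ids <- paste(model$edges$node_a, model$edges$node_b, sep = "|")
  out <- model$edges[, c("node_a", "node_b", "sign")]
  out$auc <- out$ci_low <- out$ci_high <- NA_real_
  for (i in seq_along(ids)) {
    j <- match(ids[i], colnames(E$scores))
    if (is.na(j)) next
    s <- E$scores[, j]
    obs <- !is.na(s)
    if (!any(obs) || length(unique(labels[obs])) < 2L) {
      warning("edge ", ids[i], " has no scorable subjects in both classes")
      next
    }
    a <- auc(s[obs], labels[obs], positive = positive, n_boot = n_boot,
             seed = seed + i)
    out$auc[i] <- a$auc; out$ci_low[i] <- a$ci_low
    out$ci_high[i] <- a$ci_high
  }
  for (k in model$classes) out[[paste0("d_", k)]] <- model$d_scores[, k]
  out[order(-out$auc, na.last = TRUE), , drop = FALSE]
}
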
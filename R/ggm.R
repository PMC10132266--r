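#' Pairwise-complete covariance estimate
#'
#' Computes the sample covariance between every pair of features over the
#' subjects where both are observed, with means recomputed on each
#' pairwise-complete subset and an n-1 denominator. This is the input to the
#' graphical lasso when the concatenated multi-modal matrix carries missing
#' entries. Pairs with fewer than 2 joint observations (no estimable
#' covariance) get 0 and a warning.
#'
#' @param table A standardized `feature_table`.
#' @return An object of class `covariance_estimate` with elements
#'   `feature_ids`, `S`, `n_effective` (per-pair complete counts),
#'   `n_nominal` (total subjects) and `psd_repaired`.
#' @export
pairwise_covariance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale_state != "standardized")
    stop("covariance is computed on standardized tables; run pareto_scale()")
  v <- table$values
  p <- ncol(v)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 3L))
    stop("feature(s) with fewer than 3 observations: ",
         paste(colnames(v)[n_obs < 3L], collapse = ", "))
  obs <- !is.na(v)
  n_eff <- crossprod(obs)              # joint complete counts
  v0 <- v; v0[!obs] <- 0
  # pairwise sums of x, y and xy over the joint subset
  sx  <- crossprod(obs, v0)            # sx[a,b] = sum of x_b over subjects where a and b observed... careful
  # crossprod(obs, v0)[a, b] = sum_s obs[s,a] * v0[s,b] = sum of b over joint(a,b)
  sxy <- crossprod(v0)                 # sum of a*b over joint subset
  m_b <- sx / n_eff                    # mean of b on joint(a,b)
  m_a <- t(m_b)                        # mean of a on joint(a,b)
  S <- (sxy - n_eff * m_a * m_b) / (n_eff - 1)
  too_few <- n_eff < 2L
  if (any(too_few)) {
    warning(sum(too_few[upper.tri(too_few)]),
            " feature pair(s) with < 2 joint observations; covariance set to 0")
    S[too_few] <- 0
  }
  S <- (S + t(S)) / 2
  dimnames(S) <- list(colnames(v), colnames(v))
  dimnames(n_eff) <- dimnames(S)
  structure(list(feature_ids = colnames(v), S = S, n_effective = n_eff,
                 n_nominal = nrow(v), psd_repaired = FALSE,
                 modality = table$modality),
            class = "covariance_estimate")
}

#' Repair a covariance estimate to positive semi-definiteness
#'
#' Pairwise-complete covariance matrices need not be PSD. Eigenvalues below
#' `eps` are clipped up to `eps` and the matrix reconstructed; the
#' `psd_repaired` flag records whether any clipping happened.
#'
#' @param est A `covariance_estimate` (or plain symmetric matrix).
#' @param eps Lower eigenvalue bound (default 1e-6).
#' @return The repaired estimate, same class as the input.
#' @export
nearest_psd <- function(est, eps = 1e-6) {
  stopifnot(eps > 0)
  S <- if (inherits(est, "covariance_estimate")) est$S else est
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= eps) {
    if (inherits(est, "covariance_estimate")) est$psd_repaired <- FALSE
    return(est)
  }
  vals <- pmax(e$values, eps)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  S2 <- (S2 + t(S2)) / 2
  dimnames(S2) <- dimnames(S)
  if (inherits(est, "covariance_estimate")) {
    est$S <- S2
    est$psd_repaired <- TRUE
    est
  } else S2
}

#' Sparse precision estimation by graphical lasso
#'
#' Maximizes `log det(Omega) - tr(S Omega) - lambda * sum_{a != b} |Omega_ab|`
#' (diagonal unpenalized) by block coordinate descent with a coordinate-wise
#' lasso inner solver. At `lambda = 0` with well-conditioned S this reduces to
#' the direct inverse; at `lambda >= max |S_ab|` the solution is diagonal.
#'
#' @param S A `covariance_estimate` or symmetric PSD matrix.
#' @param lambda Non-negative L1 penalty on off-diagonal precision entries.
#' @param tol Convergence tolerance on the mean absolute off-diagonal change
#'   of the working covariance per sweep.
#' @param max_iter Maximum number of outer sweeps.
#' @param warm Optional warm start: the value of a previous call (used along
#'   a lambda path).
#' @return List with `omega` (sparse symmetric PD precision matrix), `W`
#'   (estimated covariance), `iterations`, `gap`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-5, max_iter = 200L,
                            warm = NULL) {
  stopifnot(lambda >= 0, tol > 0, max_iter >= 1L)
  Sm <- if (inherits(S, "covariance_estimate")) S$S else S
  if (max(abs(Sm - t(Sm))) > 1e-10) stop("S must be symmetric")
  W0 <- if (!is.null(warm)) warm$W else NULL
  B0 <- if (!is.null(warm)) warm$B else NULL
  fit <- .glasso_cpp(unname(Sm), lambda, tol, as.integer(max_iter), W0, B0)
  if (!fit$converged)
    stop(sprintf(
      "graphical lasso did not converge in %d sweeps (gap %.3g > tol %.3g)",
      max_iter, fit$gap, tol))
  dimnames(fit$omega) <- dimnames(Sm)
  fit
}

#' Extended BIC of a precision estimate
#'
#' `n * (tr(S Omega) - log det Omega) + E * log n + 4 * E * gamma * log p`,
#' where `E` counts nonzero off-diagonal pairs (upper triangle) and `p` the
#' features. `gamma = 0` recovers ordinary BIC; additive constants are
#' dropped consistently across the lambda path.
#'
#' @param omega Symmetric positive-definite precision matrix.
#' @param S A `covariance_estimate` or covariance matrix.
#' @param n Sample size.
#' @param gamma eBIC parameter in `[0, 1]` (default 0.5).
#' @return The eBIC value (scalar).
#' @export
ebic <- function(omega, S, n, gamma = 0.5) {
  stopifnot(gamma >= 0, gamma <= 1, n > 1)
  Sm <- if (inherits(S, "covariance_estimate")) S$S else S
  ld <- determinant(omega, logarithm = TRUE)
  if (ld$sign <= 0) stop("omega is not positive definite")
  p <- ncol(omega)
  E <- sum(omega[upper.tri(omega)] != 0)
  n * (sum(Sm * omega) - as.numeric(ld$modulus)) +
    E * log(n) + 4 * E * gamma * log(p)
}

#' Default penalty grid for the graphical lasso
#'
#' Log-spaced values from `lambda_max` (the largest off-diagonal |S|, at
#' which the estimated network is empty) down to `ratio * lambda_max`.
#'
#' @param S A `covariance_estimate` or covariance matrix.
#' @param n_lambdas Grid size (default 30).
#' @param ratio Smallest/largest penalty ratio (default 0.01).
#' @return Decreasing numeric vector of penalties.
#' @export
default_lambda_grid <- function(S, n_lambdas = 30L, ratio = 0.01) {
  Sm <- if (inherits(S, "covariance_estimate")) S$S else S
  lmax <- max(abs(Sm[upper.tri(Sm)]))
  if (lmax <= 0) return(rep(0, n_lambdas))
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambdas))
}

#' Fit the graphical lasso along a penalty path and select by eBIC
#'
#' Sweeps the grid from the largest penalty down, warm-starting each fit from
#' the previous solution, and records `(lambda, eBIC, n_edges)` per point.
#' The selected penalty minimizes the eBIC; ties go to the larger penalty
#' (sparser model).
#'
#' @param S A `covariance_estimate` or symmetric PSD matrix.
#' @param n Sample size used in the eBIC.
#' @param gamma eBIC parameter (default 0.5).
#' @param grid Penalty grid; defaults to [default_lambda_grid()].
#' @param tol,max_iter Passed to [graphical_lasso()].
#' @return List with `ebic_path` (data frame: lambda, ebic, n_edges),
#'   `lambda_star`, and `fits` (omega per grid point, in grid order).
#' @export
lambda_path <- function(S, n, gamma = 0.5, grid = NULL, tol = 1e-5,
                        max_iter = 200L) {
  if (is.null(grid)) grid <- default_lambda_grid(S)
  stopifnot(length(grid) >= 1L, all(grid >= 0))
  grid <- sort(grid, decreasing = TRUE)
  fits <- vector("list", length(grid))
  path <- data.frame(lambda = grid, ebic = NA_real_, n_edges = NA_integer_)
  warm <- NULL
  for (i in seq_along(grid)) {
    fit <- graphical_lasso(S, grid[i], tol = tol, max_iter = max_iter,
                           warm = warm)
    warm <- fit
    fits[[i]] <- fit$omega
    path$ebic[i] <- ebic(fit$omega, S, n, gamma)
    path$n_edges[i] <- as.integer(sum(fit$omega[upper.tri(fit$omega)] != 0))
  }
  best <- which(path$ebic <= min(path$ebic))
  lambda_star <- max(grid[best])   # ties -> larger penalty, sparser model
  list(ebic_path = path, lambda_star = lambda_star,
       omega_star = fits[[which(grid == lambda_star)[1L]]], fits = fits)
}

#' Convert a precision matrix to a partial-correlation network
#'
#' Every nonzero off-diagonal precision entry becomes an edge with partial
#' correlation `r_ab = -omega_ab / sqrt(omega_aa * omega_bb)`; a positive
#' precision entry therefore maps to a negative partial correlation.
#'
#' @param omega Symmetric PD precision matrix with dimnames.
#' @param feature_ids Feature identifiers (defaults to `colnames(omega)`).
#' @param modality Named modality vector covering the features.
#' @param lambda_star,gamma,ebic_path,n Provenance of the selection, stored
#'   on the network.
#' @return An object of class `precision_network`: `feature_ids`, `omega`,
#'   `edges` (data frame `node_a`, `node_b`, `partial_correlation`, `sign`,
#'   `modality_a`, `modality_b`), plus the selection metadata.
#' @export
to_partial_correlations <- function(omega, feature_ids = colnames(omega),
                                    modality = NULL, lambda_star = NA_real_,
                                    gamma = NA_real_, ebic_path = NULL,
                                    n = NA_integer_) {
  p <- ncol(omega)
  if (is.null(feature_ids)) feature_ids <- paste0("V", seq_len(p))
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) stop("omega is not positive definite")
  d <- sqrt(diag(omega))
  R <- -omega / tcrossprod(d)
  idx <- which(omega != 0 & upper.tri(omega), arr.ind = TRUE)
  edges <- data.frame(
    node_a = feature_ids[idx[, 1L]],
    node_b = feature_ids[idx[, 2L]],
    partial_correlation = R[idx],
    stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$partial_correlation >= 0, 1L, -1L)
  if (!is.null(modality)) {
    edges$modality_a <- unname(modality[edges$node_a])
    edges$modality_b <- unname(modality[edges$node_b])
  } else {
    edges$modality_a <- rep(NA_character_, nrow(edges))
    edges$modality_b <- rep(NA_character_, nrow(edges))
  }
  structure(list(feature_ids = feature_ids, omega = omega, edges = edges,
                 lambda_star = lambda_star, gamma = gamma,
                 ebic_path = ebic_path, n = n),
            class = "precision_network")
}

#' @export
print.precision_network <- function(x, ...) {
  p <- length(x$feature_ids)
  e <- nrow(x$edges)
  cat(sprintf(
    "precision_network: %d nodes, %d edges (density %.2f%%)\n",
    p, e, network_density(e, p)))
  if (!is.na(x$lambda_star))
    cat(sprintf("  lambda* = %.4g (gamma = %.2g, n = %d)\n",
                x$lambda_star, x$gamma, x$n))
  if (e) {
    r <- x$edges$partial_correlation
    cat(sprintf("  partial correlations in [%.3f, %.3f]\n", min(r), max(r)))
  }
  invisible(x)
}

#' Percent density of an undirected graph
#'
#' `100 * E / (p * (p - 1) / 2)`. For example, 27334 edges over 1690 nodes
#' give a density of 1.9%.
#'
#' @param n_edges Number of edges.
#' @param n_nodes Number of nodes.
#' @return Density in percent.
#' @export
network_density <- function(n_edges, n_nodes) {
  100 * n_edges / (n_nodes * (n_nodes - 1) / 2)
}

#' End-to-end network inference from a standardized table
#'
#' Convenience orchestrator: pairwise-complete covariance, PSD repair,
#' eBIC-selected graphical lasso path, partial-correlation conversion.
#'
#' @param table A standardized `feature_table`.
#' @param gamma eBIC parameter (default 0.5).
#' @param grid Optional penalty grid.
#' @param lambda Fix the penalty and bypass eBIC selection.
#' @param tol,max_iter Passed to [graphical_lasso()].
#' @param eps PSD-repair eigenvalue floor.
#' @return A `precision_network`.
#' @export
infer_network <- function(table, gamma = 0.5, grid = NULL, lambda = NULL,
                          tol = 1e-5, max_iter = 200L, eps = 1e-6) {
  est <- pairwise_covariance(table)
  est <- nearest_psd(est, eps = eps)
  n <- est$n_nominal
  if (!is.null(lambda)) {
    fit <- graphical_lasso(est, lambda, tol = tol, max_iter = max_iter)
    path <- data.frame(lambda = lambda,
                       ebic = ebic(fit$omega, est, n, gamma),
                       n_edges = sum(fit$omega[upper.tri(fit$omega)] != 0))
    return(to_partial_correlations(fit$omega, est$feature_ids,
                                   table$modality, lambda_star = lambda,
                                   gamma = gamma, ebic_path = path, n = n))
  }
  sel <- lambda_path(est, n, gamma = gamma, grid = grid, tol = tol,
                     max_iter = max_iter)
  to_partial_correlations(sel$omega_star, est$feature_ids, table$modality,
                          lambda_star = sel$lambda_star, gamma = gamma,
                          ebic_path = sel$ebic_path, n = n)
}

#' Export a network for Cytoscape and downstream tools
#'
#' Writes an edge TSV (`node_a`, `node_b`, `partial_correlation`, `sign`,
#' `modality_a`, `modality_b`), a SIF file (interaction type `pp` for
#' positive, `pn` for negative partial correlation), and a JSON metadata
#' file with the selected penalty, gamma, sample size and the eBIC path.
#'
#' @param network A `precision_network`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, dir) {
  stopifnot(inherits(network, "precision_network"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  edge_path <- file.path(dir, "edges.tsv")
  sif_path <- file.path(dir, "network.sif")
  meta_path <- file.path(dir, "network_meta.json")
  e <- network$edges
  utils::write.table(
    e[, c("node_a", "node_b", "partial_correlation", "sign",
          "modality_a", "modality_b")],
    edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sif <- if (nrow(e)) {
    paste(e$node_a, ifelse(e$sign > 0, "pp", "pn"), e$node_b)
  } else character()
  writeLines(sif, sif_path)
  meta <- list(lambda_star = network$lambda_star, gamma = network$gamma,
               n = network$n, n_nodes = length(network$feature_ids),
               n_edges = nrow(e), ebic_path = network$ebic_path)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(edges = edge_path, sif = sif_path, meta = meta_path))
}

#' Read an exported edge table back into an edge list
#'
#' @param path Path to an `edges.tsv` written by [export_network()].
#' @return The edge data frame.
#' @export
read_network_edges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
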
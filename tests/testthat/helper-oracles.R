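# Independent brute-force shrunken-centroid machinery used as the oracle:
# everything computed with explicit loops, no code shared with the package.
pam_oracle <- function(X, labels, delta = 0, priors = NULL) {
  classes <- unique(labels)
  K <- length(classes)
  n <- nrow(X); E <- ncol(X)
  nk <- sapply(classes, function(k) sum(labels == k))
  if (is.null(priors)) priors <- nk / n
  xbar <- colMeans(X)
  cent <- sapply(classes, function(k) colMeans(X[labels == k, , drop = FALSE]))
  cent <- matrix(cent, E, K)
  s2 <- numeric(E)
  for (i in seq_len(E)) {
    tot <- 0
    for (k in seq_len(K)) {
      xs <- X[labels == classes[k], i]
      tot <- tot + sum((xs - cent[i, k])^2)
    }
    s2[i] <- tot / (n - K)
  }
  s <- sqrt(s2)
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- matrix(0, E, K)
  for (i in seq_len(E)) for (k in seq_len(K))
    d[i, k] <- (cent[i, k] - xbar[i]) / (mk[k] * (s[i] + s0))
  dsh <- sign(d) * pmax(abs(d) - delta, 0)
  csh <- matrix(0, E, K)
  for (i in seq_len(E)) for (k in seq_len(K))
    csh[i, k] <- xbar[i] + mk[k] * (s[i] + s0) * dsh[i, k]
  pred <- character(n)
  for (j in seq_len(n)) {
    dk <- sapply(seq_len(K), function(k)
      sum((X[j, ] - csh[, k])^2 / (s + s0)^2) - 2 * log(priors[k]))
    pred[j] <- classes[which.min(dk)]
  }
  list(classes = classes, xbar = xbar, cent = cent, s = s, s0 = s0,
       mk = mk, d = d, csh = csh, pred = pred)
}

mk_score_matrix <- function(X, labels = NULL) {
  # wraps a plain matrix as an edge_score_matrix with positive dummy edges
  E <- ncol(X)
  edges <- data.frame(node_a = paste0("a", seq_len(E)),
                      node_b = paste0("b", seq_len(E)),
                      sign = 1L, stringsAsFactors = FALSE)
  edges$edge_id <- paste(edges$node_a, edges$node_b, sep = "|")
  colnames(X) <- edges$edge_id
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  structure(list(edges = edges, scores = X, subject_ids = rownames(X)),
            class = "edge_score_matrix")
}
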
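# Brute-force pairwise-complete covariance: explicit double loop over
# feature pairs with means recomputed on each joint subset.
cov_bruteforce <- function(v) {
  p <- ncol(v)
  S <- matrix(0, p, p, dimnames = list(colnames(v), colnames(v)))
  for (a in seq_len(p)) for (b in seq_len(p)) {
    ok <- !is.na(v[, a]) & !is.na(v[, b])
    x <- v[ok, a]; y <- v[ok, b]
    S[a, b] <- sum((x - mean(x)) * (y - mean(y))) / (sum(ok) - 1)
  }
  S
}

test_that("pairwise-complete covariance recomputes means on each joint subset", {
  x <- c(1, 2, 3, NA); y <- c(2, 4, NA, 8)
  # joint subset is subjects 1,2: means 1.5 and 3, covariance 1.0
  v <- cbind(x = x, y = y, z = rnorm(4))
  rownames(v) <- paste0("s", 1:4)
  tab <- mk_table(v, scale_state = "raw")
  tab$scale_state <- "standardized"  # bypass scaling: test the estimator only
  est <- pairwise_covariance(tab)
  expect_equal(est$S["x", "y"], 1.0)
  expect_equal(est$S, cov_bruteforce(v))
  expect_equal(est$n_effective["x", "y"], 2)
  expect_equal(diag(est$n_effective), c(x = 3, y = 3, z = 4))
  expect_equal(est$n_nominal, 4L)
  expect_lt(max(abs(est$S - t(est$S))), 1e-12)

  # complete data equals the ordinary sample covariance
  set.seed(5)
  w <- matrix(rnorm(60), 20, 3)
  tabw <- mk_table(w); tabw$scale_state <- "standardized"
  expect_equal(unname(pairwise_covariance(tabw)$S), unname(stats::cov(w)))

  # pareto-scaled complete feature has post-scaling variance = its raw sd
  raw <- matrix(rnorm(50, 3, 2), 25, 2)
  tabr <- pareto_scale(mk_table(raw))
  expect_equal(diag(pairwise_covariance(tabr)$S),
               apply(raw, 2, stats::sd), ignore_attr = TRUE)

  # a feature with < 3 observations errors
  few <- v; few[1:2, 1] <- NA
  tabf <- mk_table(few); tabf$scale_state <- "standardized"
  expect_error(pairwise_covariance(tabf), "fewer than 3")
})

test_that("PSD repair clips eigenvalues at eps and flags the repair", {
  S <- matrix(c(1, 1.2, 1.2, 1), 2)   # eigenvalues 2.2 and -0.2
  S2 <- nearest_psd(S, eps = 1e-6)
  ev <- eigen(S2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 1e-6, tolerance = 1e-9)

  est <- structure(list(S = S, feature_ids = c("a", "b"), n_nominal = 10L,
                        psd_repaired = FALSE),
                   class = "covariance_estimate")
  est2 <- nearest_psd(est)
  expect_true(est2$psd_repaired)

  # a PSD matrix passes through unchanged
  I3 <- diag(3)
  estI <- structure(list(S = I3, psd_repaired = TRUE),
                    class = "covariance_estimate")
  out <- nearest_psd(estI)
  expect_identical(out$S, I3)
  expect_false(out$psd_repaired)
})

test_that("graphical lasso matches analytic 2x2 solutions and the identity", {
  # independent features: diagonal unpenalized, Omega = I at any lambda
  for (lam in c(0, 0.3, 2))
    expect_equal(graphical_lasso(diag(3), lam)$omega, diag(3))

  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  f <- graphical_lasso(S, 0)
  expect_equal(f$omega, 1 / (1 - 0.25) * matrix(c(1, -0.5, -0.5, 1), 2),
               tolerance = 1e-6)
  # lambda at/above |S_12| forces the off-diagonal to zero
  f2 <- graphical_lasso(S, 0.6)
  expect_equal(f2$omega, diag(2))
})

test_that("graphical lasso equals the direct inverse at lambda = 0", {
  for (seed in 1:3) {
    set.seed(seed)
    p <- sample(5:20, 1)
    A <- matrix(rnorm(5 * p * p), 5 * p, p)
    S <- crossprod(A) / (5 * p)
    f <- graphical_lasso(S, 0)
    expect_lt(max(abs(f$omega - solve(S))), 1e-4)
  }
})

test_that("KKT conditions certify every solution and path point", {
  set.seed(11)
  p <- 12
  A <- matrix(rnorm(40 * p), 40, p)
  S <- stats::cov(A)
  for (lam in c(0.02, 0.1, 0.3)) {
    f <- graphical_lasso(S, lam, tol = 1e-7)
    R <- solve(f$omega) - S
    off <- upper.tri(R)
    expect_lte(max(abs(R[off])), lam + 1e-3)
    nz <- off & f$omega != 0
    if (any(nz))
      expect_equal(abs(R[nz]), rep(lam, sum(nz)), tolerance = 1e-3)
    ev <- eigen(f$omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("eBIC follows its closed form and reduces to BIC at gamma 0", {
  expect_equal(ebic(diag(3), diag(3), n = 100, gamma = 0.5), 300)

  set.seed(2)
  A <- matrix(rnorm(200), 50, 4)
  S <- stats::cov(A)
  om <- graphical_lasso(S, 0.1)$omega
  E <- sum(om[upper.tri(om)] != 0)
  p <- 4; n <- 50
  manual <- n * (sum(S * om) - determinant(om)$modulus[1])
  expect_equal(ebic(om, S, n, 0), manual + E * log(n))
  expect_equal(ebic(om, S, n, 0.5) - ebic(om, S, n, 0), 4 * E * 0.5 * log(p))
  # one extra edge at unchanged fit costs log n + 4 gamma log p
  expect_error(ebic(diag(c(1, -1)), diag(2), 10, 0.5), "positive definite")
})

test_that("the eBIC path is monotone in sparsity and breaks ties to sparser fits", {
  set.seed(4)
  om0 <- make_precision(15, "banded", strength = 0.4)
  x <- sample_mvn(om0, 200, seed = 4)
  S <- stats::cov(x)
  res <- lambda_path(S, n = 200, gamma = 0.5)
  expect_equal(nrow(res$ebic_path), 30L)
  # edges non-increasing in lambda (path stored with decreasing lambda);
  # exact solutions may wobble by an edge near zero penalty where an entry
  # re-crosses zero, so allow a couple of edges of slack overall
  viol <- -pmin(diff(res$ebic_path$n_edges), 0)
  expect_lte(sum(viol), 2)
  expect_gt(res$ebic_path$n_edges[30], res$ebic_path$n_edges[1])
  expect_true(res$lambda_star %in% res$ebic_path$lambda)
  # a grid point at/above max |S_ab| gives the empty network
  lmax <- max(abs(S[upper.tri(S)]))
  res2 <- lambda_path(S, 200, grid = c(lmax * 1.01, lmax * 0.5))
  expect_equal(res2$ebic_path$n_edges[1L], 0L)
  # single-element grid selects that element
  res3 <- lambda_path(S, 200, grid = 0.2)
  expect_equal(res3$lambda_star, 0.2)
})

test_that("partial correlations carry the sign flip and magnitude bound", {
  om <- matrix(c(4 / 3, -2 / 3, -2 / 3, 4 / 3), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  net <- to_partial_correlations(om, modality = c(a = "protein",
                                                  b = "lipid"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$partial_correlation, 0.5)
  expect_equal(net$edges$modality_a, "protein")
  # positive precision entry -> negative partial correlation
  om2 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = dimnames(om))
  net2 <- to_partial_correlations(om2)
  expect_lt(net2$edges$partial_correlation, 0)
  # diagonal precision -> empty edge list
  expect_equal(nrow(to_partial_correlations(diag(3))$edges), 0L)
  # all |r| < 1 on a random PD precision
  set.seed(9)
  om3 <- make_precision(20, "random_sparse", density = 0.2, strength = 0.4,
                        seed = 9)
  net3 <- to_partial_correlations(om3)
  expect_true(all(abs(net3$edges$partial_correlation) < 1))
})

test_that("bivariate partial correlation is recovered near the true rho", {
  rho <- 0.5
  Sigma <- matrix(c(1, rho, rho, 1), 2)
  set.seed(123)
  x <- MASS::mvrnorm(5000, c(0, 0), Sigma)
  colnames(x) <- c("u", "v"); rownames(x) <- paste0("s", 1:5000)
  tab <- pareto_scale(mk_table(x))
  est <- nearest_psd(pairwise_covariance(tab))
  f <- graphical_lasso(est, 1e-4)
  net <- to_partial_correlations(f$omega)
  expect_equal(net$edges$partial_correlation, rho, tolerance = 0.05)
})

test_that("network export round-trips edges and writes SIF plus metadata", {
  om <- make_precision(6, "banded", strength = 0.3)
  dimnames(om) <- list(paste0("f", 1:6), paste0("f", 1:6))
  net <- to_partial_correlations(om, lambda_star = 0.1, gamma = 0.5,
                                 n = 100L,
                                 ebic_path = data.frame(lambda = 0.1,
                                                        ebic = 1,
                                                        n_edges = 5L))
  dir <- tempfile("net")
  paths <- export_network(net, dir)
  back <- read_network_edges(paths["edges"])
  expect_equal(back$node_a, net$edges$node_a)
  expect_equal(back$partial_correlation, net$edges$partial_correlation)
  expect_equal(length(readLines(paths["sif"])), nrow(net$edges))
  meta <- jsonlite::read_json(paths["meta"], simplifyVector = TRUE)
  expect_equal(meta$lambda_star, 0.1)
  expect_equal(meta$n_edges, nrow(net$edges))

  # empty network still writes valid header-only files
  net0 <- to_partial_correlations(diag(3))
  dir0 <- tempfile("net0")
  p0 <- export_network(net0, dir0)
  expect_equal(nrow(read_network_edges(p0["edges"])), 0L)
})
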
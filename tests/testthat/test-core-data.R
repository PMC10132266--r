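test_that("delimited matrices parse with sentinels, orientation and errors", {
  v <- matrix(c(1, 2, 3, 4, NA, 6), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("fA", "fB")))
  mod <- c(fA = "protein", fB = "clinical")
  fx <- write_matrix_fixture(v, mod)
  tab <- read_feature_table(fx$matrix, modality_map = fx$map)
  expect_s3_class(tab, "feature_table")
  expect_equal(sum(is.na(tab$values)), 1L)
  expect_equal(tab$values[c("s1", "s2", "s3"), "fA"], c(s1 = 1, s2 = 2, s3 = 3))
  expect_equal(tab$scale_state, "raw")

  # features-in-rows orientation transposes to the same table
  fx2 <- write_matrix_fixture(t(v), mod)
  tab2 <- read_feature_table(fx2$matrix, orientation = "features_in_rows",
                             modality_map = fx2$map)
  expect_identical(tab2$values, tab$values)

  # duplicate header is named in the error
  d <- tempfile("dup"); dir.create(d)
  writeLines(c("id\tfA\tfA", "s1\t1\t2"), file.path(d, "m.tsv"))
  expect_error(read_feature_table(file.path(d, "m.tsv"),
                                  modality_map = fx$map),
               "fA")
  # unparseable cell is an error, not silent missing
  writeLines(c("id\tfA\tfB", "s1\t1\toops"), file.path(d, "m2.tsv"))
  expect_error(read_feature_table(file.path(d, "m2.tsv"),
                                  modality_map = fx$map),
               "unparseable")
  # modality map must cover every feature
  writeLines(c("feature_id\tmodality", "fA\tprotein"), file.path(d, "map.tsv"))
  fx3 <- write_matrix_fixture(v, mod)
  expect_error(read_feature_table(fx3$matrix,
                                  modality_map = file.path(d, "map.tsv")),
               "fB")
})

test_that("merging modalities takes the subject union and keeps features disjoint", {
  t1 <- mk_table(matrix(1:4, 2, dimnames = list(c("A", "B"), c("p1", "p2"))),
                 c(p1 = "protein", p2 = "protein"))
  t2 <- mk_table(matrix(5:8, 2, dimnames = list(c("B", "C"), c("l1", "l2"))),
                 c(l1 = "lipid", l2 = "lipid"))
  m <- merge_modalities(list(t1, t2))
  expect_setequal(subject_ids(m), c("A", "B", "C"))
  expect_equal(feature_ids(m), c("p1", "p2", "l1", "l2"))
  expect_true(all(is.na(m$values["C", c("p1", "p2")])))
  expect_true(all(is.na(m$values["A", c("l1", "l2")])))
  expect_equal(m$values["B", "p1"], 2)

  # single table is the identity
  expect_equal(merge_modalities(list(t1))$values, t1$values,
               ignore_attr = FALSE, tolerance = 0)

  # shared feature id errors
  t3 <- mk_table(matrix(1:2, 2, dimnames = list(c("X", "Y"), "p1")),
                 c(p1 = "protein"))
  expect_error(merge_modalities(list(t1, t3)), "p1")
  # incompatible scale states error
  t4 <- pareto_scale(t2)
  expect_error(merge_modalities(list(t1, t4)), "scale_state")
})

test_that("unit harmonization applies the natriuretic-peptide factors and inverts", {
  v <- matrix(1, 2, 4, dimnames = list(c("s1", "s2"),
                                       c("ANP", "BNP", "NTproBNP",
                                         "NTproANP")))
  tab <- mk_table(v)
  map <- unit_conversion_map(
    feature_id = c("ANP", "BNP", "NTproBNP", "NTproANP"),
    factor = c(3.081, 3.47, 8.475, 12.7),
    from_unit = c("pmol/L", "pmol/L", "pmol/L", "nmol/L"),
    to_unit = c("pg/ml", "pg/ml", "pg/ml", "ng/ml"))
  out <- harmonize_units(tab, map)
  expect_equal(unname(out$values["s1", ]), c(3.081, 3.47, 8.475, 12.7))

  # empty map is the identity
  expect_identical(harmonize_units(tab, map[0, ])$values, tab$values)
  # inverse map recovers the input to high relative accuracy
  back <- harmonize_units(out, invert_unit_map(map))
  expect_equal(back$values, tab$values, tolerance = 1e-10)
  # unknown feature errors
  expect_error(harmonize_units(tab, unit_conversion_map("nope", 2)), "nope")
  # missing entries stay missing
  v2 <- v; v2[1, 1] <- NA
  out2 <- harmonize_units(mk_table(v2), map)
  expect_true(is.na(out2$values[1, 1]))
})

test_that("completeness filter keeps the inclusive boundary and reports drops", {
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:4)))
  v[1:4, 1] <- NA   # 6/10 observed -> dropped at 0.7
  v[1:3, 2] <- NA   # 7/10 observed -> kept (boundary inclusive)
  tab <- mk_table(v)
  out <- filter_completeness(tab, 0.7)
  expect_false("f1" %in% feature_ids(out))
  expect_true("f2" %in% feature_ids(out))
  expect_equal(attr(out, "dropped"), "f1")

  # fully observed table unchanged
  full <- mk_table(matrix(rnorm(20), 5))
  expect_identical(filter_completeness(full, 1)$values, full$values)
  # keeping nothing errors
  allna <- mk_table(matrix(c(NA, 1, NA, NA), 4, 1))
  expect_error(filter_completeness(allna, 0.9), "every feature")
  # property: min_fraction at the smallest observed fraction keeps all
  fracs <- colMeans(!is.na(v))
  expect_equal(ncol(filter_completeness(tab, min(fracs))$values), 4L)
})

test_that("log transform is base 2 on molecular modalities with offset guard", {
  v <- matrix(c(4, 1, 0, 2), 2, 2,
              dimnames = list(c("s1", "s2"), c("prot", "echo")))
  tab <- mk_table(v, c(prot = "protein", echo = "imaging"))
  out <- log_transform(tab, offset = 1)
  expect_equal(unname(out$values[, "prot"]), c(log2(5), 1))
  # imaging column untouched by default
  expect_equal(unname(out$values[, "echo"]), c(0, 2))
  expect_equal(out$scale_state, "log")

  # value 4, offset 0 -> 2 on a clinical feature when requested explicitly
  out0 <- log_transform(mk_table(matrix(4, 1, 1)), 0,
                        modalities = "clinical")
  expect_equal(unname(out0$values[1, 1]), 2)
  # nonpositive value with offset 0 names feature and subject
  bad <- mk_table(matrix(c(-1), 1, 1,
                         dimnames = list("subj9", "protX")),
                  c(protX = "protein"))
  expect_error(log_transform(bad, 0), "protX.*subj9")
})

test_that("pareto scaling divides centered values by sqrt(sd)", {
  tab <- mk_table(matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(pareto_scale(tab)$values[, 1]), c(-1, 0, 1))

  tab2 <- mk_table(matrix(c(4, 8), 2, 1))
  s <- stats::sd(c(4, 8))
  expect_equal(unname(pareto_scale(tab2)$values[, 1]),
               c(-2, 2) / sqrt(s))
  expect_equal(unname(pareto_scale(tab2)$values[, 1]),
               c(-1.189207, 1.189207), tolerance = 1e-6)

  expect_error(pareto_scale(mk_table(matrix(5, 3, 1))), "constant")

  # missing entries preserved; observed mean is 0 after scaling
  v <- matrix(rnorm(30), 10, 3); v[c(1, 12)] <- NA
  out <- pareto_scale(mk_table(v))
  expect_equal(sum(is.na(out$values)), 2L)
  expect_lt(max(abs(colMeans(out$values, na.rm = TRUE))), 1e-8)
  expect_equal(out$scale_state, "standardized")
})

test_that("outlier flagging uses median +/- k*MAD and skips zero-MAD features", {
  x <- c(1, 2, 1, 2, 100)
  tab <- mk_table(matrix(x, 5, 1))
  out <- flag_outliers(tab, k = 5)
  # median 2, mad = 1.4826 * 1; |100 - 2| >> 5 * mad
  expect_true(is.na(out$values[5, 1]))
  expect_equal(attr(out, "n_flagged"), 1L)
  expect_equal(out$values[1:4, 1], x[1:4], ignore_attr = TRUE)

  # zero-MAD feature is skipped with a warning
  z <- mk_table(matrix(c(1, 1, 1, 1, 100), 5, 1))
  expect_warning(out2 <- flag_outliers(z, k = 5), "zero MAD")
  expect_equal(sum(is.na(out2$values)), 0L)

  # huge k leaves the table unchanged
  expect_identical(flag_outliers(tab, k = 1e9)$values, tab$values)
  # all-missing feature passes through untouched
  two <- cbind(tab$values, f2 = NA_real_)
  tab2 <- mk_table(two)
  expect_true(all(is.na(flag_outliers(tab2, 5)$values[, 2])))
})

test_that("simple imputation fills by median or knn and errors on empty features", {
  tab <- mk_table(matrix(c(1, NA, 3), 3, 1))
  expect_equal(unname(impute_simple(tab, "median")$values[, 1]), c(1, 2, 3))

  # complete table is the identity
  full <- mk_table(matrix(rnorm(12), 4, 3))
  expect_identical(impute_simple(full, "median")$values, full$values)

  # knn uses the nearest subjects on shared features
  v <- rbind(s1 = c(1, 2, 5), s2 = c(1.1, 2.1, NA), s3 = c(10, 20, 50))
  colnames(v) <- paste0("f", 1:3)
  out <- impute_simple(mk_table(v), "knn", k = 1)
  expect_equal(out$values["s2", "f3"], 5)  # s1 is the nearest neighbour

  expect_error(impute_simple(mk_table(matrix(NA_real_, 3, 1)), "median"),
               "entirely missing")
})

test_that("missing-entry counts respect the preprocessing contracts", {
  set.seed(3)
  v <- matrix(rnorm(200, 10, 2), 20, 10)
  v[sample(length(v), 15)] <- NA
  tab <- mk_table(v)
  n0 <- sum(is.na(v))
  expect_equal(sum(is.na(pareto_scale(tab)$values)), n0)
  map <- unit_conversion_map("f1", 2.5)
  expect_equal(sum(is.na(harmonize_units(tab, map)$values)), n0)
  expect_gte(sum(is.na(suppressWarnings(flag_outliers(tab, 2)$values))), n0)
  expect_lte(sum(is.na(impute_simple(tab, "median")$values)), n0)
})
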
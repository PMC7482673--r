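test_that("contrast index is antisymmetric, bounded and scale-free", {
  expect_equal(contrast_index(2, 2), 0)
  expect_equal(contrast_index(3, 1), 0.5)
  expect_warning(res <- contrast_index(0, 0), "NA")
  expect_true(is.na(res))
  set.seed(1)
  x <- runif(1000, 0, 10); y <- runif(1000, 0, 10)
  ci <- contrast_index(x, y)
  expect_true(all(ci >= -1 & ci <= 1))
  expect_equal(ci, -contrast_index(y, x))
  expect_equal(ci, contrast_index(3.7 * x, 3.7 * y)) # common scaling cancels
})

test_that("feature specs validate their protein sets", {
  expect_error(feature_spec("bad", "index", "A", "A"), "disjoint")
  expect_error(feature_spec("bad", "sum", "A", "B"), "no denominator")
  expect_error(feature_spec("bad", "index", "A"), "denominator")
  tab <- make_table(matrix(1, 2, 2, dimnames = list(NULL, c("A", "B"))))
  sp <- feature_spec("ghost", "sum", "Z")
  expect_error(evaluate_features(tab, list(sp)), "Z")
})

test_that("sum and index features evaluate to their defining arithmetic", {
  m <- matrix(1, 3, 4, dimnames = list(NULL, c("GluN1", "GluN2A", "GluN2B", "GluA2")))
  tab <- make_table(m)
  f <- evaluate_features(tab, list(
    feature_spec("glut", "sum", colnames(m)),
    feature_spec("bal", "index", c("GluN1", "GluN2A", "GluN2B"), "GluA2")))
  expect_equal(unname(feature_matrix(f)[, "glut"]), rep(4, 3))
  expect_equal(unname(feature_matrix(f)[, "bal"]), rep((3 - 1) / (3 + 1), 3))
})

test_that("the nine cat features on a 4-sample fixture match hand computation", {
  proteins <- c("Syn", "GluN1", "GluN2A", "GluN2B", "GluA2", "GABAAa1", "GABAAa3")
  m <- rbind(c(1.0, 1.2, 0.8, 1.1, 0.9, 0.7, 0.6),
             c(2.0, 1.0, 1.5, 0.5, 1.2, 1.1, 0.4),
             c(0.5, 0.8, 0.2, 1.4, 0.6, 0.3, 0.9),
             c(1.5, 1.5, 1.0, 1.0, 1.0, 1.0, 1.0))
  colnames(m) <- proteins
  f <- feature_matrix(evaluate_features(make_table(m), cat_feature_specs()))

  glut <- m[, "GluN1"] + m[, "GluN2A"] + m[, "GluN2B"] + m[, "GluA2"]
  gaba <- m[, "GABAAa1"] + m[, "GABAAa3"]
  expect_equal(unname(f[, "Protein Sum"]), unname(rowSums(m)))
  expect_equal(unname(f[, "GlutR Sum"]), unname(glut))
  expect_equal(unname(f[, "GABAAR Sum"]), unname(gaba))
  expect_equal(unname(f[, "GlutR:GABAAR"]), unname((glut - gaba) / (glut + gaba)))
  expect_equal(unname(f[, "GluN2A:GluN2B"]),
               unname((m[, "GluN2A"] - m[, "GluN2B"]) / (m[, "GluN2A"] + m[, "GluN2B"])))
  expect_equal(unname(f[, "GABAAa1:GluN2A"]),
               unname((m[, "GABAAa1"] - m[, "GluN2A"]) / (m[, "GABAAa1"] + m[, "GluN2A"])))
  expect_equal(dim(f), c(4, 9))
})

test_that("missing referenced proteins make only that sample's feature missing", {
  m <- rbind(c(1, 2), c(NA, 2))
  colnames(m) <- c("A", "B")
  f <- feature_matrix(evaluate_features(make_table(m), list(
    feature_spec("s", "sum", c("A", "B")),
    feature_spec("bOnly", "sum", "B"))))
  expect_true(is.na(f[2, "s"]))
  expect_equal(f[2, "bOnly"], 2)
})

test_that("common rescaling leaves indices unchanged and scales sums", {
  set.seed(2)
  m <- matrix(runif(20, 0.5, 2), 5, 4, dimnames = list(NULL, LETTERS[1:4]))
  specs <- list(feature_spec("s", "sum", c("A", "B")),
                feature_spec("i", "index", c("A", "B"), c("C", "D")))
  f1 <- feature_matrix(evaluate_features(make_table(m), specs))
  f2 <- feature_matrix(evaluate_features(make_table(2.5 * m), specs))
  expect_equal(f2[, "i"], f1[, "i"])
  expect_equal(f2[, "s"], 2.5 * f1[, "s"])
})

test_that("sample permutation permutes feature rows identically", {
  set.seed(3)
  m <- matrix(runif(12, 1, 2), 4, 3, dimnames = list(NULL, LETTERS[1:3]))
  specs <- list(feature_spec("i", "index", "A", c("B", "C")))
  perm <- c(3, 1, 4, 2)
  f1 <- feature_matrix(evaluate_features(make_table(m), specs))
  f2 <- feature_matrix(evaluate_features(make_table(m[perm, ]), specs))
  expect_equal(unname(f2), unname(f1[perm, , drop = FALSE]))
})

# hand-built model with designed var_coords for the proposal heuristics
fake_model <- function(vc) {
  structure(list(var_coords = vc, protein_names = rownames(vc)),
            class = "pca_model")
}

test_that("all-positive loadings propose class sums but no novel pairs", {
  vc <- matrix(c(0.9, 0.8, 0.7, 0.2), ncol = 1,
               dimnames = list(c("A", "B", "C", "D"), "Dim1"))
  specs <- propose_features(fake_model(vc), 1,
                            protein_classes = list(Top = c("A", "B")))
  kinds <- vapply(specs, `[[`, character(1), "kind")
  expect_true(all(kinds == "sum"))
  expect_setequal(vapply(specs, `[[`, character(1), "name"),
                  c("Protein Sum", "Top Sum"))
})

test_that("large opposite-sign amplitudes force a novel-pair index", {
  vc <- cbind(Dim1 = c(0.1, 0.15, 0.12, 0.05),
              Dim2 = c(0.9, -0.9, 0.1, 0.05))
  rownames(vc) <- c("A", "B", "C", "D")
  specs <- propose_features(fake_model(vc), 2, amplitude_quantile = 0.5)
  novel <- Filter(function(s) s$provenance == "novel_pair", specs)
  expect_length(novel, 1)
  expect_equal(novel[[1]]$numerator, "A")  # positive side is the numerator
  expect_equal(novel[[1]]$denominator, "B")
})

test_that("a cat-like sign structure yields the expected oppositions", {
  # Dim1 all positive (glutamatergic dominant); Dim2 GluN2A vs GABAAa1 and
  # GluA2 opposed; Dim3 GABAAa1 vs GABAAa3 opposed
  proteins <- c("Syn", "GluN1", "GluN2A", "GluN2B", "GluA2", "GABAAa1", "GABAAa3")
  vc <- cbind(Dim1 = c(0.2, 0.7, 0.8, 0.6, 0.7, 0.3, 0.4),
              Dim2 = c(0.05, 0.1, 0.6, -0.3, -0.5, -0.7, 0.1),
              Dim3 = c(0.05, 0.1, 0.2, 0.1, -0.3, 0.5, -0.6))
  rownames(vc) <- proteins
  specs <- propose_features(fake_model(vc), 3, amplitude_quantile = 0.6)
  sets <- lapply(specs, function(s) sort(c(s$numerator, s$denominator)))
  expect_true(list(sort(c("GluN2A", "GABAAa1"))) %in% sets ||
                any(vapply(sets, identical, logical(1), sort(c("GABAAa1", "GluN2A")))))
  expect_true(any(vapply(sets, identical, logical(1), sort(c("GluN2A", "GluA2")))))
  # exhaustive rule check: every novel pair satisfies the opposition rule
  thr <- apply(abs(vc), 2, quantile, 0.6)
  for (sp in Filter(function(s) s$provenance == "novel_pair", specs)) {
    pr <- c(sp$numerator, sp$denominator)
    hit <- FALSE
    for (d in 1:3) {
      if (abs(vc[pr[1], d]) >= thr[d] && abs(vc[pr[2], d]) >= thr[d] &&
          vc[pr[1], d] * vc[pr[2], d] < 0) hit <- TRUE
    }
    expect_true(hit)
  }
})

test_that("validation flags a feature identical to a score column", {
  set.seed(4)
  x <- matrix(rexp(60, 0.5), 20, 3, dimnames = list(NULL, LETTERS[1:3]))
  model <- fit_pca(center(make_table(x)))
  ft <- make_feature_table(cbind(copy = model$scores[, 1]))
  v <- validate_features(ft, model$scores, 2)
  expect_equal(v$r["Dim1", "copy"], 1, tolerance = 1e-10)
  expect_true(v$significant["Dim1", "copy"])
  expect_true(v$validated["copy"])
})

test_that("Bonferroni adjustment multiplies raw p by the test count", {
  set.seed(5)
  x <- matrix(rnorm(100 * 5, mean = 10), 100, 5, dimnames = list(NULL, LETTERS[1:5]))
  model <- fit_pca(center(make_table(x)))
  fm <- matrix(rnorm(100 * 9), 100, 9,
               dimnames = list(NULL, paste0("f", 1:9)))
  ft <- make_feature_table(fm)
  v <- validate_features(ft, model$scores, 3)
  raw <- sapply(1:9, function(j) cor.test(fm[, j], model$scores[, 1])$p.value)
  expect_equal(unname(v$p_adjusted[1, ]), pmin(1, 27 * raw), tolerance = 1e-12)
})

test_that("constant features warn and are reported not significant", {
  set.seed(6)
  x <- matrix(rnorm(30, mean = 10), 10, 3, dimnames = list(NULL, LETTERS[1:3]))
  model <- fit_pca(center(make_table(x)))
  ft <- make_feature_table(cbind(flat = rep(2, 10)))
  expect_warning(v <- validate_features(ft, model$scores, 2), "constant")
  expect_false(any(v$significant))
})
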
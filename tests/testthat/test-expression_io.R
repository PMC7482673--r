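test_that("CSV parsing maps blanks and NA tokens to missing, never zero", {
  path <- write_csv_fixture(c(
    "case,region,run,P1,P2",
    "c1,C,1,1.5,",
    "c1,C,2,na,2.0",
    "c2,C,1,0.5,NaN"))
  tab <- read_expression_table(path, c("P1", "P2"),
                               c(case_id = "case", region = "region", run = "run"))
  m <- protein_matrix(tab)
  expect_equal(nrow(tab), 3)
  expect_equal(sum(is.na(m)), 3)
  expect_equal(m[1, "P1"], 1.5)
  expect_true(is.na(m[2, "P1"]))
  expect_true(is.na(m[3, "P2"]))
  expect_identical(metadata(tab)$case_id, c("c1", "c1", "c2"))
})

test_that("reader rejects missing files, absent columns and duplicate keys", {
  expect_error(read_expression_table(tempfile(), "P1"), "not found")
  path <- write_csv_fixture(c("case,P1", "c1,1", "c2,2"))
  expect_error(read_expression_table(path, c("P1", "P9"), c(case_id = "case")),
               "P9")
  dup <- write_csv_fixture(c("case,run,P1", "c1,1,1", "c1,1,2"))
  expect_error(read_expression_table(dup, "P1", c(case_id = "case", run = "run")),
               "unique")
  neg <- write_csv_fixture(c("case,P1", "c1,-1"))
  expect_error(read_expression_table(neg, "P1", c(case_id = "case")), "negative")
})

test_that("a human-style 30 cases x 3 runs x 7 proteins file reads as 90 rows", {
  proteins <- paste0("P", 1:7)
  grid <- expand.grid(case = sprintf("c%02d", 1:30), run = 1:3,
                      stringsAsFactors = FALSE)
  vals <- matrix(round(runif(nrow(grid) * 7, 0.5, 2), 3), ncol = 7)
  lines <- c(paste(c("case", "run", proteins), collapse = ","),
             apply(cbind(grid, vals), 1, paste, collapse = ","))
  tab <- read_expression_table(write_csv_fixture(lines), proteins,
                               c(case_id = "case", run = "run"))
  expect_equal(nrow(tab), 90)
  expect_equal(length(protein_names(tab)), 7)
  av <- average_runs(tab)
  expect_equal(accounting(av)$cells, 210)
})

test_that("run averaging means over observed runs and keeps all-missing cells", {
  tab <- make_table(
    rbind(c(4, 1), c(6, NA), c(NA, NA), c(NA, NA)),
    meta = data.frame(case = c("c1", "c1", "c2", "c2"), run = c("1", "2", "1", "2")))
  av <- average_runs(tab)
  m <- protein_matrix(av)
  expect_equal(nrow(av), 2)
  expect_equal(m[1, 1], 5)   # mean of 4, 6
  expect_equal(m[1, 2], 1)   # mean over the single observed run
  expect_true(all(is.na(m[2, ]))) # missing in every run stays missing
  expect_false("run" %in% metadata_fields(av))
})

test_that("tables without a run field pass through run averaging unchanged", {
  tab <- make_table(matrix(1:4, 2), meta = data.frame(case = c("a", "b")))
  expect_identical(protein_matrix(average_runs(tab)), protein_matrix(tab))
})

test_that("averaging a full 2-run fixture halves the observed measurement count", {
  # 279 case-region combinations x 2 runs x 7 proteins = 3,906 observations
  grid <- expand.grid(case = sprintf("c%02d", 1:31), region = sprintf("r%d", 1:9),
                      run = c("1", "2"), stringsAsFactors = FALSE)
  set.seed(42)
  vals <- matrix(runif(nrow(grid) * 7, 0.5, 2), ncol = 7)
  tab <- make_table(vals, meta = grid)
  expect_equal(accounting(tab)$observed, 3906)
  av <- average_runs(tab)
  expect_equal(accounting(av)$cells, 1953)
  expect_equal(accounting(av)$missing, 0)
})

test_that("imputation is the identity on complete tables and forced by a duplicate neighbour", {
  tab <- make_table(matrix(runif(12, 1, 2), 4))
  expect_identical(protein_matrix(impute_missing(tab)), protein_matrix(tab))

  m <- rbind(c(1, 2, 3), c(1, 2, NA), c(9, 9, 7))
  tab2 <- make_table(m)
  out <- impute_missing(tab2, k = 1)
  expect_equal(protein_matrix(out)[2, 3], 3) # exact-duplicate row 1 wins
})

test_that("k-NN imputation matches exhaustive distance enumeration on a 5-row toy", {
  m <- rbind(c(1.0, 2.0, 3.0),
             c(1.1, 2.1, NA),
             c(5.0, 5.0, 5.0),
             c(1.3, 1.8, 2.0),
             c(4.0, 4.5, 6.0))
  # oracle: standardize columns on observed cells, enumerate all donor
  # distances for row 2 over its observed columns, take the 2 closest
  mu <- colMeans(m, na.rm = TRUE)
  sd_ <- apply(m, 2, sd, na.rm = TRUE)
  z <- sweep(sweep(m, 2, mu), 2, sd_, "/")
  donors <- c(1, 3, 4, 5)
  d <- sapply(donors, function(r) {
    shared <- intersect(which(!is.na(z[2, ])), which(!is.na(z[r, ])))
    sqrt(sum((z[2, shared] - z[r, shared])^2) * 3 / length(shared))
  })
  expected <- mean(m[donors[order(d)][1:2], 3])

  out <- impute_missing(make_table(m), k = 2)
  expect_equal(protein_matrix(out)[2, 3], expected)
  # observed values preserved bit-for-bit
  obs <- !is.na(m)
  expect_identical(protein_matrix(out)[obs], m[obs])
})

test_that("imputation refuses rows with every protein missing", {
  m <- rbind(c(1, 2), c(NA, NA), c(3, 4))
  tab <- make_table(m, meta = data.frame(case = c("a", "b", "c")))
  expect_error(impute_missing(tab), "b")
})

test_that("centering removes column means without scaling and is idempotent", {
  tab <- make_table(cbind(c(1, 2, 3), c(10, 30, 50)))
  cm <- center(tab)
  expect_equal(unname(cm$values[, 1]), c(-1, 0, 1))
  expect_equal(cm$column_means, c(P1 = 2, P2 = 30))
  expect_equal(apply(cm$values, 2, var), apply(protein_matrix(tab), 2, var))
  expect_equal(max(abs(colSums(cm$values))), 0, tolerance = 1e-9 * nrow(tab))
  cm2 <- center(make_table(cm$values + 100)) # re-centering shifted data
  expect_equal(unname(cm2$values), unname(cm$values))
})

test_that("centering demands a complete matrix", {
  tab <- make_table(rbind(c(1, NA), c(2, 3)))
  expect_error(center(tab), "average_runs|impute")
})

test_that("run averaging commutes with centering on pre-averaged data", {
  grid <- expand.grid(case = letters[1:6], run = c("1", "2"),
                      stringsAsFactors = FALSE)
  set.seed(7)
  tab <- make_table(matrix(runif(nrow(grid) * 3, 1, 2), ncol = 3), meta = grid)
  av <- average_runs(tab)
  direct <- center(av)$values
  re <- center(make_table(protein_matrix(av),
                          meta = metadata(av)))$values
  expect_equal(direct, re, tolerance = 1e-9)
})
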
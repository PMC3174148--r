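test_that("fitted offsets equal the soft-thresholded standardized differences", {
  sim <- small_sim(seed = 3, P = 25, q = 5)
  classes <- c("positive", "negative")
  for (delta in c(0, 0.4, 1, 2.5)) {
    fit <- fit_nsc(sim$matrix, delta = delta)
    orc <- oracle_nsc(unclass(sim$matrix), labels_of(sim$matrix), classes, delta)
    expect_equal(unname(fit$shrunken_offsets), orc$dprime, tolerance = 1e-12)
    expect_equal(unname(fit$shrunken_centroids), orc$shrunk, tolerance = 1e-12)
    expect_equal(fit$sd_floor, orc$s0)
    expect_setequal(fit$retained_genes,
                    rownames(sim$matrix)[rowSums(orc$dprime != 0) > 0])
  }
  # soft-threshold arithmetic on raw numbers: 2.5 -> 1.5, -0.5 -> 0 at delta 1
  orc <- oracle_nsc(unclass(sim$matrix), labels_of(sim$matrix), classes, 0)
  d <- orc$d
  expect_equal(sign(d) * pmax(abs(d) - 1, 0),
               oracle_nsc(unclass(sim$matrix), labels_of(sim$matrix),
                          classes, 1)$dprime)
})

test_that("at delta = 0 a well-separated toy is classified without error", {
  m <- rbind(g1 = c(rep(5, 6), rep(0, 6)), g2 = c(rep(0, 6), rep(5, 6))) +
    matrix(rnorm(24, sd = 0.3), 2)
  colnames(m) <- paste0("s", 1:12)
  x <- ppea_matrix(m, rep(c("positive", "negative"), each = 6))
  fit <- fit_nsc(x, delta = 0)
  expect_equal(test_error(fit, x), 0)
})

test_that("retained-gene count is monotone in delta and matches per-gene checks", {
  set.seed(8)
  m <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  x <- ppea_matrix(m, rep(c("positive", "negative"), each = 10))
  orc <- oracle_nsc(m, labels_of(x), c("positive", "negative"), 0)
  grid <- seq(0, max(abs(orc$d)) * 1.05, length.out = 15)
  counts <- vapply(grid, function(dl) {
    length(fit_nsc(x, delta = dl)$retained_genes)
  }, integer(1))
  brute <- vapply(grid, function(dl) {
    sum(apply(abs(orc$d), 1, function(row) any(row > dl)))
  }, integer(1))
  expect_equal(counts, brute)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0L)
})

test_that("prediction agrees with an independently coded discriminant", {
  sim <- small_sim(seed = 11, P = 30, q = 5)
  fit <- fit_nsc(sim$matrix, delta = 0.8)
  set.seed(12)
  newx <- matrix(rnorm(30 * 20, mean = 8), 30,
                 dimnames = list(rownames(sim$matrix), paste0("n", 1:20)))
  got <- predict_nsc(fit, newx)
  orc <- oracle_nsc(unclass(sim$matrix), labels_of(sim$matrix),
                    fit$class_names, 0.8)
  want <- oracle_nsc_predict(orc, fit$priors, fit$class_names, newx)
  expect_identical(got$pred, want)
})

test_that("delta = 0 with equal priors reduces to standardized nearest centroid", {
  sim <- small_sim(seed = 21, P = 20, q = 4)
  fit <- fit_nsc(sim$matrix, delta = 0, priors = "uniform")
  set.seed(22)
  newx <- matrix(rnorm(20 * 15, mean = 8), 20,
                 dimnames = list(rownames(sim$matrix), paste0("n", 1:15)))
  denom <- fit$pooled_sd + fit$sd_floor
  d1 <- colSums(((newx - fit$class_centroids[, 1]) / denom)^2)
  d2 <- colSums(((newx - fit$class_centroids[, 2]) / denom)^2)
  want <- ifelse(d1 <= d2, fit$class_names[1], fit$class_names[2])
  expect_identical(predict_nsc(fit, newx)$pred, unname(want))
})

test_that("a fully shrunken model with equal priors ties to the first class", {
  sim <- small_sim(seed = 31, P = 15, q = 0)
  orc <- oracle_nsc(unclass(sim$matrix), labels_of(sim$matrix),
                    c("positive", "negative"), 0)
  fit <- fit_nsc(sim$matrix, delta = max(abs(orc$d)) + 1, priors = "uniform")
  expect_length(fit$retained_genes, 0)
  pred <- predict_nsc(fit, sim$matrix)
  expect_true(all(pred$pred == fit$class_names[1]))
})

test_that("cross-validated threshold search honors its selection rule", {
  sim <- small_sim(seed = 41, P = 30, q = 5)
  cv <- withr::with_seed(41, select_threshold_cv(sim$matrix))
  expect_equal(cv$chosen_error, min(cv$cv_error))
  tied <- which(cv$cv_error == cv$chosen_error)
  expect_equal(cv$genes_retained[match(cv$chosen_delta, cv$grid)],
               min(cv$genes_retained[tied]))
  # among equal-error, equal-gene-count candidates the largest delta wins
  final <- tied[cv$genes_retained[tied] == min(cv$genes_retained[tied])]
  expect_equal(cv$chosen_delta, max(cv$grid[final]))
  # grid spans 0 .. max |d|
  orc <- oracle_nsc(unclass(sim$matrix), labels_of(sim$matrix),
                    c("positive", "negative"), 0)
  expect_equal(range(cv$grid), c(0, max(abs(orc$d))))
})

test_that("a single-candidate grid trivially selects delta = 0", {
  sim <- small_sim(seed = 43, P = 20, q = 3)
  cv <- withr::with_seed(1, select_threshold_cv(sim$matrix, n_thresholds = 1))
  expect_equal(cv$chosen_delta, 0)
  expect_length(cv$grid, 1)
})

test_that("shrinkage discards noise genes before planted markers", {
  sim <- simulate_two_class(P = 30, n_pos = 20, n_neg = 20, q = 5,
                            effect = 3, seed = 47)
  cv <- withr::with_seed(47, select_threshold_cv(sim$matrix))
  expect_lte(cv$chosen_error, 0.1)
  # the minimal surviving set is made of planted markers only
  fit <- fit_nsc(sim$matrix, delta = cv$chosen_delta)
  expect_gte(length(fit$retained_genes), 1)
  expect_true(all(fit$retained_genes %in% sim$planted))
  # at the threshold keeping five genes, those five are the planted set
  td <- tidy(cv)
  d5 <- max(td$delta[td$genes_retained == 5])
  expect_setequal(fit_nsc(sim$matrix, delta = d5)$retained_genes, sim$planted)
})

test_that("fold counts shrink to the smaller class with a message", {
  sim <- simulate_two_class(P = 20, n_pos = 4, n_neg = 8, q = 3,
                            effect = 3, seed = 53)
  expect_message(withr::with_seed(1, select_threshold_cv(sim$matrix, folds = 10)),
                 "reducing folds")
})

test_that("test_error is the plain misclassified fraction", {
  m <- rbind(g1 = c(9, 9, 1, 1), g2 = c(1, 1, 9, 9)) +
    matrix(rnorm(8, sd = 0.1), 2)
  colnames(m) <- paste0("s", 1:4)
  x <- ppea_matrix(m, c("positive", "positive", "negative", "negative"))
  fit <- fit_nsc(x, delta = 0)
  expect_equal(test_error(fit, x), 0)
  # a test set where one of four samples sits on the wrong side -> 0.25
  z <- rbind(g1 = c(9, 9, 9, 1), g2 = c(1, 1, 1, 9))
  colnames(z) <- paste0("t", 1:4)
  y <- ppea_matrix(z, c("positive", "positive", "negative", "negative"))
  expect_equal(test_error(fit, y), 0.25)
})

test_that("degenerate training inputs raise errors", {
  m <- matrix(3, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  x <- ppea_matrix(m, rep(c("positive", "negative"), each = 3))
  expect_error(fit_nsc(x), "zero within-class variance")
})
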
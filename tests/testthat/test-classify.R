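test_that("a single perfectly separating feature gives consensus accuracy 1", {
  set.seed(50)
  n <- 60
  y <- rep(c("mutant", "wildtype"), each = n / 2)
  X <- data.frame(sep = ifelse(y == "mutant", runif(n, 0, 1), runif(n, 2, 3)),
                  noise = rnorm(n))
  cv <- repeated_stratified_cv(X, y, rf_settings("idh", n_repeats = 10,
                                                 master_seed = 1))
  cs <- consensus_confusion(cv)
  expect_equal(cs$accuracy, 1)
  expect_equal(cs$sensitivity, 1)
  expect_equal(cs$specificity, 1)
})

test_that("every subject is predicted exactly once per repeat", {
  set.seed(51)
  X <- data.frame(a = rnorm(24), b = rnorm(24))
  y <- rep(c("mutant", "wildtype"), each = 12)
  st <- rf_settings("idh", n_repeats = 25, master_seed = 2)
  cv <- repeated_stratified_cv(X, y, st)
  expect_equal(dim(cv$pred), c(25, 24))
  expect_false(any(is.na(cv$pred)))
  expect_true(all(cv$errors %in% c(-1, 0, 1)))
})

test_that("stratified folds preserve class proportions within one subject", {
  set.seed(52)
  y <- factor(rep(c("a", "b", "c"), times = c(11, 17, 24)))
  for (rep in 1:20) {
    fold <- dscradiomics:::stratified_folds(y, 2)
    for (cl in levels(y)) {
      n1 <- sum(y == cl & fold == 1); n2 <- sum(y == cl & fold == 2)
      expect_lte(abs(n1 - n2), 1)
    }
  }
})

test_that("a fixed master seed reproduces the whole CV result", {
  set.seed(53)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- rep(c("mutant", "wildtype"), 15)
  st <- rf_settings("idh", n_repeats = 5, master_seed = 9)
  cv1 <- repeated_stratified_cv(X, y, st)
  cv2 <- repeated_stratified_cv(X, y, st)
  expect_identical(cv1$votes, cv2$votes)
  expect_identical(cv1$pred, cv2$pred)
})

test_that("task defaults carry the published hyperparameters", {
  si <- rf_settings("idh")
  expect_equal(c(si$n_trees, si$max_depth, si$min_samples_leaf), c(200, 10, 4))
  sg <- rf_settings("grade")
  expect_equal(c(sg$n_trees, sg$max_depth, sg$min_samples_leaf), c(800, 50, 4))
  expect_equal(c(si$n_repeats, si$n_folds), c(250, 2))
  expect_error(repeated_stratified_cv(data.frame(a = rnorm(5)),
                                      c("m", "m", "m", "w", "w"),
                                      rf_settings("idh", n_repeats = 2)),
               "at least")
})

test_that("consensus rates satisfy their defining identities on a known matrix", {
  # constructed result: 60 wildtype, 90 mutant; confusion [[50,10],[20,70]]
  truth <- c(rep("wildtype", 60), rep("mutant", 90))
  votes <- matrix(0, 150, 2, dimnames = list(NULL, c("mutant", "wildtype")))
  votes[1:50, "wildtype"] <- 0.8; votes[1:50, "mutant"] <- 0.2
  votes[51:60, "mutant"] <- 0.8; votes[51:60, "wildtype"] <- 0.2
  votes[61:80, "wildtype"] <- 0.6; votes[61:80, "mutant"] <- 0.4
  votes[81:150, "mutant"] <- 0.9; votes[81:150, "wildtype"] <- 0.1
  res <- structure(list(votes = votes, classes = c("mutant", "wildtype"),
                        class_code = c(1, 0),
                        labels = factor(truth,
                                        levels = c("mutant", "wildtype")),
                        true_code = ifelse(truth == "mutant", 1, 0),
                        settings = rf_settings("idh")),
                   class = "cv_result")
  cs <- consensus_confusion(res)
  expect_equal(cs$accuracy, (50 + 70) / 150)
  expect_equal(cs$sensitivity, 70 / 90)
  expect_equal(cs$specificity, 50 / 60)
  expect_equal(sum(cs$confusion), 150)
  expect_equal(unname(rowSums(cs$confusion)[c("wildtype", "mutant")]),
               c(60, 90))
})

test_that("grade distance 2 errors are excluded from the within-1 fraction", {
  truth <- c("2", "2", "3", "3", "4", "4", "4", "4")
  votes <- matrix(0, 8, 3, dimnames = list(NULL, c("2", "3", "4")))
  votes[1, "4"] <- 1                      # II predicted IV: distance 2
  votes[2, "2"] <- 1
  votes[cbind(3:8, match(c("3", "3", "4", "4", "4", "4"), colnames(votes)))] <- 1
  res <- structure(list(votes = votes, classes = c("2", "3", "4"),
                        class_code = c(2, 3, 4),
                        labels = factor(truth),
                        true_code = as.numeric(truth),
                        settings = rf_settings("grade")),
                   class = "cv_result")
  cs <- consensus_confusion(res)
  expect_equal(cs$within_distance_1, 7 / 8)
  expect_equal(cs$accuracy, 7 / 8)
})

test_that("vote ties resolve to the lower ordinal class", {
  votes <- matrix(0.5, 2, 2, dimnames = list(NULL, c("mutant", "wildtype")))
  res <- structure(list(votes = votes, classes = c("mutant", "wildtype"),
                        class_code = c(1, 0),
                        labels = factor(c("mutant", "wildtype"),
                                        levels = c("mutant", "wildtype")),
                        true_code = c(1, 0),
                        settings = rf_settings("idh")),
                   class = "cv_result")
  cs <- consensus_confusion(res)
  expect_equal(cs$consensus, c("wildtype", "wildtype"))  # code 0 < 1
})

test_that("pure-noise features classify at chance level", {
  set.seed(54)
  X <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
  names(X) <- paste0("f", 1:10)
  y <- rep(c("mutant", "wildtype"), each = 100)
  accs <- vapply(1:5, function(s) {
    cv <- repeated_stratified_cv(X, y, rf_settings("idh", n_repeats = 20,
                                                   master_seed = s))
    consensus_confusion(cv)$accuracy
  }, 0)
  expect_true(all(accs >= 0.4 & accs <= 0.6))
})

test_that("error-by-parameter flags a planted noisy centre and respects identity cases", {
  set.seed(55)
  n <- 200
  man <- data.frame(manufacturer = rep(c("Siemens", "Philips"), each = n / 2),
                    field_T = rep(c(1.5, 3), each = n / 2),
                    TR_ms = 1500, TE_ms = 40, FA_deg = 90, slice_mm = 5,
                    matrix_size = 128, inplane_mm = 1,
                    centre = rep(1:2, each = n / 2))
  y <- rep(rep(c("mutant", "wildtype"), each = n / 4), 2)
  # centre 2 subjects get pure-noise features; centre 1 separable
  X <- data.frame(sep = ifelse(y == "mutant", 0, 3) +
                    rnorm(n, 0, ifelse(man$centre == 2, 6, 0.1)))
  cv <- repeated_stratified_cv(X, y, rf_settings("idh", n_repeats = 20,
                                                 master_seed = 3))
  suppressWarnings(tab <- error_by_parameter(cv, man))
  row <- tab[tab$parameter == "field", ]
  expect_equal(nrow(row), 1)
  expect_gt(row$mean_abs_error_b, row$mean_abs_error_a)  # 3T = noisy centre
  expect_lt(row$p_abs_error, 0.05)

  # identical error vectors in both bins -> p = 1
  cv0 <- cv
  cv0$errors <- matrix(0, nrow(cv$errors), ncol(cv$errors))
  suppressWarnings(tab0 <- error_by_parameter(cv0, man))
  expect_true(all(tab0$p_abs_error == 1))
})

test_that("null prediction errors give calibrated p-values across an unrelated covariate", {
  set.seed(56)
  n <- 60
  man <- data.frame(manufacturer = "GE",
                    field_T = rep(c(1.5, 3), each = n / 2),
                    TR_ms = 1500, TE_ms = 40, FA_deg = 90, slice_mm = 5,
                    matrix_size = 128, inplane_mm = 1)
  ps <- replicate(100, {
    res <- structure(list(errors = matrix(rnorm(5 * n), 5, n)),
                     class = "cv_result")
    suppressWarnings(error_by_parameter(res, man))$p_error
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
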
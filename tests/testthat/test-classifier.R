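sep_toy <- function(n = 40, seed = 71) {
  set.seed(seed)
  tibble::tibble(
    id = paste0("r", seq_len(2 * n)),
    label = rep(c("disease", "neutral"), each = n),
    f1 = c(rnorm(n, 3, 0.3), rnorm(n, -3, 0.3)),
    f2 = rnorm(2 * n))
}

test_that("standardize centers and scales on train only, dropping constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 5))
  expect_warning(sc <- standardize(x), "constant feature")
  expect_equal(sc$kept, c("a", "c"))
  expect_equal(unname(colMeans(sc$x)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc$x, 2, sd)), c(1, 1), tolerance = 1e-12)
  # test rows use training parameters, not their own
  te <- nfsindel:::apply_scaling(cbind(a = 10, c = 10), sc$center, sc$scale)
  expect_equal(unname(te[1, "a"]), (10 - 2) / 1, tolerance = 1e-12)
  expect_error(standardize(cbind(k = c(1, 1))), "constant")
})

test_that("training separates a separable toy set and is reproducible", {
  d <- sep_toy()
  m <- train_svm(d, c("f1", "f2"), C = 10, gamma = 0.5, seed = 1)
  expect_equal(mean(predict(m, d) == d$label), 1)
  m2 <- train_svm(d, c("f1", "f2"), C = 10, gamma = 0.5, seed = 1)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_model(m, f1); save_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(train_svm(dplyr::mutate(d, label = "disease"),
                         c("f1", "f2")), "Both classes")
})

test_that("model round-trips through plain text with identical predictions", {
  d <- sep_toy(seed = 72)
  m <- train_svm(d, c("f1", "f2"), C = 2, gamma = 0.3, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  new <- sep_toy(n = 15, seed = 73)
  expect_identical(predict(m, new, type = "decision"),
                   predict(m2, new, type = "decision"))
  expect_identical(predict(m, new, type = "prob"),
                   predict(m2, new, type = "prob"))
  # corrupted file and version mismatch are explicit errors
  bad <- withr::local_tempfile(lines = "{not json")
  expect_error(load_model(bad), "parse")
  j <- jsonlite::read_json(path)
  j$version <- 99
  v <- withr::local_tempfile()
  jsonlite::write_json(j, v, auto_unbox = TRUE)
  expect_error(load_model(v), "version")
})

test_that("serialized decision function matches the LIBSVM fit it came from", {
  d <- sep_toy(n = 30, seed = 74)
  feats <- c("f1", "f2")
  m <- train_svm(d, feats, C = 1, gamma = 0.7, seed = 1, calibrate = FALSE)
  # reference: e1071 on the identically scaled matrix
  sc <- standardize(nfsindel:::feature_matrix(d, feats))
  ref <- nfsindel:::fit_rbf(sc$x, factor(d$label,
                                         levels = c("neutral", "disease")),
                            C = 1, gamma = 0.7)
  want <- nfsindel:::rbf_decision(ref, sc$x)$decision
  expect_equal(predict(m, d, type = "decision"), want, tolerance = 1e-10)
})

test_that("k-fold partitions cover every record exactly once with even
           fold sizes", {
  d <- sep_toy(n = 50, seed = 75)   # n = 100
  cv <- kfold_cv(d, c("f1", "f2"), C = 1, gamma = 0.5, k = 10, seed = 3)
  expect_equal(as.integer(table(cv$predictions$fold)), rep(10L, 10))
  expect_setequal(cv$predictions$id, d$id)
  expect_false(anyNA(cv$predictions$decision))
  expect_false(anyNA(cv$predictions$prob))
  expect_equal(sum(unlist(cv$counts)), 100)
  expect_gt(cv$metrics$mcc, 0.8)   # separable signal survives CV
  g <- glance(cv)
  expect_equal(g$n, 100L)
  expect_s3_class(tidy(cv), "tbl_df")
})

test_that("the parameter grid enumerates 880 points and the search returns
           its argmax", {
  g <- svm_grid()
  expect_equal(nrow(g), 880L)
  expect_equal(length(unique(g$log2C)), 11L)
  expect_equal(length(unique(g$log2gamma)), 10L)
  expect_equal(length(unique(g$n_window)), 8L)
  expect_setequal(unique(g$log2C), seq(-5, 15, 2))
  expect_setequal(unique(g$log2gamma), seq(-15, 3, 2))

  d <- sep_toy(n = 25, seed = 76)
  small <- svm_grid(log2C = c(-1, 3), log2gamma = c(-3, 1), n_window = 0)
  gs <- grid_search(d, c("f1", "f2"), grid = small, k = 5, seed = 2)
  expect_equal(nrow(gs$table), 4L)
  expect_equal(gs$best$mcc, max(gs$table$mcc))
  gs2 <- grid_search(d, c("f1", "f2"), grid = small, k = 5, seed = 2)
  expect_identical(gs$table, gs2$table)  # fixed seed -> identical table
})

test_that("greedy selection increases MCC strictly and stops on copies", {
  d <- sep_toy(n = 40, seed = 77)
  d$f1_copy <- d$f1
  d$f1_copy2 <- d$f1
  tr <- greedy_select(d, c("f1", "f1_copy", "f1_copy2"), C = 5,
                      gamma = 0.5, k = 5, seed = 4)
  expect_equal(length(tr$selected), 1L)       # no copy can improve
  expect_equal(tr$selected[1], "f1")          # ties break to canonical order
  expect_equal(tr$stop_reason, "no improvement")

  d2 <- sep_toy(n = 40, seed = 78)
  set.seed(8); d2$noise <- rnorm(nrow(d2))
  tr2 <- greedy_select(d2, c("noise", "f1", "f2"), C = 5, gamma = 0.5,
                       k = 5, seed = 4)
  expect_equal(tr2$selected[1], "f1")         # informative feature first
  expect_true(all(diff(tr2$trace$mcc) > 0))   # strictly increasing
  expect_gte(max(tr2$trace$mcc),
             tr2$trace$mcc[1])                # final >= best single
})

test_that("label noise at rate zero reproduces fold-wise CV behavior and
           degrades gracefully", {
  d <- simulate_feature_cohort(150, 150, mu1 = 2.5, seed = 79)
  r0 <- label_noise_experiment(d, "f_info", rate = 0, C = 1, gamma = 1,
                               k = 5, repeats = 2, seed = 11)
  expect_equal(nrow(r0$per_fold), 10L)        # repeats x folds
  expect_gt(r0$mean_mcc, 0.5)
  r10 <- label_noise_experiment(d, "f_info", rate = 0.10, C = 1, gamma = 1,
                                k = 5, repeats = 2, seed = 11)
  # heavy noise cannot systematically beat the clean run by a wide margin
  expect_lt(r10$mean_mcc, r0$mean_mcc + r0$sd_mcc)
  expect_error(label_noise_experiment(d, "f_info", rate = 0.6),
               "rate")
})

test_that("maf filtering removes only low-frequency neutral records", {
  d <- tibble::tibble(
    id = paste0("r", 1:5),
    label = c("neutral", "neutral", "neutral", "disease", "disease"),
    maf = c(0.01, 0.02, 0.3, NA, 0.001))
  kept <- maf_filter(d)
  expect_setequal(kept$id, c("r2", "r3", "r4", "r5"))  # 0.02 retained (strict <)
  d_bad <- dplyr::mutate(d, maf = ifelse(id == "r1", NA, maf))
  expect_error(maf_filter(d_bad), "r1")
})

test_that("independent-test runner refuses overlapping ids", {
  tr <- sep_toy(n = 30, seed = 80)
  te <- sep_toy(n = 10, seed = 81)
  te$id <- paste0("t", seq_len(nrow(te)))
  res <- run_independent_test(tr, te, c("f1", "f2"), C = 5, gamma = 0.5)
  expect_gt(res$metrics$mcc, 0.8)
  expect_equal(nrow(res$predictions), nrow(te))
  te_bad <- te
  te_bad$id[1] <- tr$id[1]
  expect_error(run_independent_test(tr, te_bad, c("f1", "f2")), "share")
  # symmetric swap runs
  res2 <- run_independent_test(te, tr, c("f1", "f2"), C = 5, gamma = 0.5)
  expect_gt(res2$metrics$auc, 0.9)
})
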
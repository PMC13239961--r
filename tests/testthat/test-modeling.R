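test_that("grouped splits separate plans cleanly", {
  ids <- rep(sprintf("p%02d", 1:10), each = 4)
  sp <- grouped_split(ids, 0.70, seed = 3)
  expect_length(sp$train_plan_ids, 7)
  expect_length(sp$test_plan_ids, 3)
  expect_length(intersect(sp$train_plan_ids, sp$test_plan_ids), 0)
  expect_setequal(c(sp$train_plan_ids, sp$test_plan_ids), unique(ids))
  expect_identical(grouped_split(ids, 0.70, seed = 3), sp)
  expect_error(grouped_split(rep("a", 5)), class = "rotqa_invalid_input")
  expect_error(grouped_split(c("a", "b"), fraction = 0.99),
               class = "rotqa_invalid_input")
})

test_that("min-max scaling maps the training range to [0, 1] and inverts exactly", {
  tr <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  te <- cbind(a = c(1, 7), b = c(5, 9))
  sc <- min_max_scale(tr, te)
  expect_equal(unname(sc$train[, "a"]), c(0, 0.5, 1))
  expect_true(all(sc$train[, "b"] == 0))     # constant column rule
  expect_equal(unname(sc$test[, "a"]), c(-0.25, 1.25))  # may exceed [0,1]
  back <- min_max_unscale(sc$train, sc$ranges)
  expect_equal(unname(back[, "a"]), c(2, 4, 6), tolerance = 1e-12)
  expect_equal(unname(back[, "b"]), c(5, 5, 5), tolerance = 1e-12)
})

test_that("attribution ranking finds a planted signal", {
  hits <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    dat <- with_seed(s, {
      X <- matrix(runif(60 * 6), 60, 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
      list(X = X, y = 2 * X[, "f1"] + rnorm(60, sd = 0.1))
    })
    rk <- rank_features(dat$X, dat$y, seed = s)
    hits <- hits + (rk$feature[1] == "f1")
  }
  expect_gte(hits, round(0.95 * n_seeds) - 1)
})

test_that("tree-path attributions are additive to the model prediction", {
  dat <- with_seed(2, {
    X <- matrix(runif(80 * 5), 80, 5, dimnames = list(NULL, paste0("f", 1:5)))
    list(X = X, y = X[, 1] - 0.5 * X[, 2] + rnorm(80, sd = 0.05))
  })
  rk <- rank_features(dat$X, dat$y, seed = 2)
  contrib <- attr(rk, "contributions")
  bst <- attr(rk, "model")
  pred <- predict(bst, xgboost::xgb.DMatrix(dat$X, nthread = 1))
  expect_equal(unname(rowSums(contrib)), unname(pred), tolerance = 1e-6)
})

test_that("duplicated feature columns share the importance mass", {
  dat <- with_seed(5, {
    X <- matrix(runif(120 * 4), 120, 4,
                dimnames = list(NULL, c("a", "n1", "n2", "n3")))
    list(X = X, y = 3 * X[, "a"] + rnorm(120, sd = 0.1))
  })
  single <- rank_features(dat$X, dat$y, seed = 5)
  Xdup <- cbind(dat$X, a_copy = dat$X[, "a"])
  dup <- rank_features(Xdup, dat$y, seed = 5)
  mass_single <- single$importance[single$feature == "a"]
  mass_dup <- sum(dup$importance[dup$feature %in% c("a", "a_copy")])
  expect_lt(abs(mass_dup - mass_single) / mass_single, 0.2)
})

test_that("constant targets are rejected by the ranker", {
  X <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(rank_features(X, rep(1, 20)), class = "rotqa_invalid_input")
})

test_that("two-stage selection respects k and recovers planted dosiomic signal", {
  recovered <- 0
  n_seeds <- 15
  for (s in seq_len(n_seeds)) {
    dat <- with_seed(s, {
      rad <- matrix(runif(60 * 20), 60, 20,
                    dimnames = list(NULL, paste0("rad", 1:20)))
      dos <- matrix(runif(60 * 40), 60, 40,
                    dimnames = list(NULL, paste0("dos", 1:40)))
      list(rad = rad, dos = dos,
           y = 2 * dos[, "dos7"] + rnorm(60, sd = 0.1))
    })
    sel <- two_stage_select(dat$rad, dat$dos, dat$y, k = 17, seed = s)
    expect_lte(sum(startsWith(sel$stage1$radiomics$retained, "rad")), 17)
    expect_lte(length(sel$stage1$dosiomics$retained), 17)
    recovered <- recovered + ("dos7" %in% sel$retained)
  }
  expect_gte(recovered, round(0.95 * n_seeds) - 1)
})

test_that("k = 0 selects nothing so modeling degenerates to angles only", {
  sel <- two_stage_select(matrix(runif(40), 20, 2),
                          matrix(runif(40), 20, 2), runif(20), k = 0)
  expect_length(sel$retained, 0)
})

test_that("k larger than a group is clipped with a warning", {
  rad <- matrix(runif(60), 20, 3, dimnames = list(NULL, paste0("r", 1:3)))
  dos <- matrix(runif(400), 20, 20, dimnames = list(NULL, paste0("d", 1:20)))
  y <- rad[, 1] + runif(20, 0, 0.1)
  expect_warning(two_stage_select(rad, dos, y, k = 17, seed = 1),
                 "clipped")
})

test_that("a noise-free linear target is fit perfectly on held-out plans", {
  dat <- with_seed(7, {
    ids <- rep(sprintf("p%02d", 1:12), each = 6)
    X <- cbind(x1 = runif(72), x2 = runif(72))
    list(ids = ids, X = X, y = 3 + 2 * X[, "x1"])
  })
  sp <- grouped_split(dat$ids, 0.7, seed = 1)
  rep <- fit_evaluate(dat$X, dat$y, dat$ids, sp, cv_folds = 5, seed = 1)
  expect_equal(rep$r2, 1, tolerance = 1e-6)
  expect_lt(rep$mae, 1e-8)
  expect_gte(rep$rmse, rep$mae)
})

test_that("a pure-noise target yields near-zero held-out performance", {
  low <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    dat <- with_seed(100 + s, {
      ids <- rep(sprintf("p%02d", 1:20), each = 5)
      X <- matrix(runif(100 * 4), 100, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
      list(ids = ids, X = X, y = rnorm(100))
    })
    sp <- grouped_split(dat$ids, 0.7, seed = s)
    rep <- fit_evaluate(dat$X, dat$y, dat$ids, sp, cv_folds = 5, seed = s)
    expect_gte(rep$rmse, rep$mae)
    low <- low + (rep$r2 <= 0.1)
  }
  expect_gte(low, n_seeds - 1)
})

test_that("the three scenarios run on one shared split with the stated inputs", {
  coh <- simulate_cohort(cohort_protocol(
    n_plans = 8, plan = plan_spec(grid_n = 16, spacing_mm = 5.5), seed = 4))
  m <- cohort_metrics(coh, include_gamma = FALSE, include_dd = FALSE)
  ft <- cohort_features(coh)
  cmp <- suppressWarnings(scenario_compare(m, ft, k = 4, cv_folds = 3,
                                           seed = 4))
  expect_s3_class(cmp$full, "model_report")
  expect_equal(cmp$rotation_only$n_features, 3)  # pitch, roll, yaw
  expect_identical(cmp$full$n_train, cmp$rotation_only$n_train)
  for (srep in list(cmp$full, cmp$rotation_only, cmp$features_only)) {
    expect_gte(srep$rmse, srep$mae)
    expect_lte(srep$r2, 1)
  }
  # reproducible under the same seed
  cmp2 <- suppressWarnings(scenario_compare(m, ft, k = 4, cv_folds = 3,
                                            seed = 4))
  expect_equal(cmp2$full$r2, cmp$full$r2)
  expect_equal(cmp2$features_only$r2, cmp$features_only$r2)
})

test_that("no plan appears on both sides of any scenario split", {
  coh <- simulate_cohort(cohort_protocol(
    n_plans = 6, plan = plan_spec(grid_n = 16, spacing_mm = 5.5), seed = 9),
    keep_volumes = FALSE)
  m <- cohort_metrics(coh, include_gamma = FALSE, include_dd = FALSE)
  sp <- grouped_split(m$plan_id, 0.7, seed = 2)
  expect_length(intersect(sp$train_plan_ids, sp$test_plan_ids), 0)
  expect_setequal(union(sp$train_plan_ids, sp$test_plan_ids),
                  unique(m$plan_id))
})
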
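#' Grouped train/test split at the plan level
#'
#' All records of a plan fall on the same side of the split, so no plan
#' geometry leaks from training into testing. The training side gets
#' `round(fraction * n_plans)` plans.
#'
#' @param plan_ids character vector of plan ids (one per record, or the
#'   unique plans).
#' @param fraction training fraction (default 0.70).
#' @param seed integer seed.
#' @return list of class `split_plan` with `train_plan_ids` and
#'   `test_plan_ids`.
#' @export
grouped_split <- function(plan_ids, fraction = 0.70, seed = 1) {
  plans <- sort(unique(plan_ids))
  if (length(plans) < 2) stop_rotqa("need at least 2 plans to split",
                                    "rotqa_invalid_input")
  n_train <- round(fraction * length(plans))
  if (n_train < 1 || n_train >= length(plans)) {
    stop_rotqa("fraction leaves an empty split side", "rotqa_invalid_input")
  }
  train <- with_seed(seed, sample(plans, n_train))
  structure(list(train_plan_ids = sort(train),
                 test_plan_ids = sort(setdiff(plans, train)),
                 fraction = fraction, seed = seed),
            class = "split_plan")
}

#' Min-max scale feature columns to the training range
#'
#' Columns are mapped to `[0, 1]` using the training minimum/maximum;
#' test rows use the same ranges (and may exceed `[0, 1]`). Constant
#' training columns map to 0.
#'
#' @param train,test numeric matrices with identical columns (`test` may
#'   be `NULL`).
#' @return list with `train`, `test` and the fitted `ranges` (2 x p).
#' @export
min_max_scale <- function(train, test = NULL) {
  train <- as.matrix(train)
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  scale_one <- function(m) {
    m <- as.matrix(m)
    out <- sweep(m, 2, lo, "-")
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out[, rng == 0] <- 0
    out
  }
  list(train = scale_one(train),
       test = if (!is.null(test)) scale_one(test) else NULL,
       ranges = rbind(min = lo, max = hi))
}

#' Invert a min-max scaling
#'
#' @param scaled scaled matrix.
#' @param ranges the `ranges` element from [min_max_scale()].
#' @return matrix on the original scale (constant columns return their
#'   training value).
#' @export
min_max_unscale <- function(scaled, ranges) {
  rng <- ranges["max", ] - ranges["min", ]
  out <- sweep(as.matrix(scaled), 2, ifelse(rng > 0, rng, 0), "*")
  sweep(out, 2, ranges["min", ], "+")
}

xgb_train_quiet <- function(X, y, seed, nrounds = 150, max_depth = 4,
                            eta = 0.1, subsample = 0.8) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = eta,
                  max_depth = max_depth, subsample = subsample,
                  colsample_bytree = 0.8, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1),
    nrounds = nrounds, verbose = 0)
}

#' Rank features by tree-path additive attribution
#'
#' Fits a gradient-boosted regression ensemble on (features -> target) and
#' ranks features by the mean absolute per-sample additive attribution
#' (SHAP-style tree path contributions), i.e. each feature's average
#' marginal contribution to the model output.
#'
#' @param X numeric feature matrix (named columns).
#' @param y numeric target (nonconstant).
#' @param seed integer seed.
#' @param nrounds boosting rounds.
#' @param n_bags number of independently seeded ensembles whose
#'   attributions are averaged (stabilizes the ranking at small sample
#'   sizes; 1 reproduces a single-model ranking).
#' @return data.frame with `feature` and `importance`, ranked decreasing;
#'   the per-sample contribution matrix of the first ensemble is attached
#'   as attribute `"contributions"`.
#' @export
rank_features <- function(X, y, seed = 1, nrounds = 150, n_bags = 3) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || sd(y) == 0) {
    stop_rotqa("target must be nonconstant with >= 2 rows",
               "rotqa_invalid_input")
  }
  imp <- 0
  contrib1 <- NULL
  bst1 <- NULL
  for (b in seq_len(max(1, n_bags))) {
    bst <- xgb_train_quiet(X, y, derive_seed(seed, paste0("bag", b)),
                           nrounds)
    contrib <- as.matrix(predict(bst, xgboost::xgb.DMatrix(X, nthread = 1),
                                 predcontrib = TRUE))
    feat_cols <- setdiff(colnames(contrib), c("BIAS", "(Intercept)"))
    imp <- imp + colMeans(abs(contrib[, feat_cols, drop = FALSE]))
    if (b == 1) {
      contrib1 <- contrib
      bst1 <- bst
    }
  }
  imp <- imp / max(1, n_bags)
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  attr(out, "contributions") <- contrib1
  attr(out, "model") <- bst1
  out
}

#' Two-stage attribution-based feature selection
#'
#' Stage 1 ranks the radiomic and dosiomic groups independently and keeps
#' the top `k` of each (prefiltering balances the two groups' very
#' different sizes). Stage 2 retrains on the merged set, recomputes
#' attributions, and retains the features whose mean absolute attribution
#' is at least `floor_frac` of the stage-2 total.
#'
#' @param radiomics,dosiomics row-aligned numeric feature matrices.
#' @param target numeric target (e.g. SSIM).
#' @param k per-group stage-1 retention (default 17; clipped with a
#'   warning when a group is smaller).
#' @param floor_frac stage-2 importance floor as a fraction of the total
#'   importance mass (default 0.01).
#' @param seed integer seed.
#' @return list of class `selection_result` with per-group rankings,
#'   per-group retained names, the stage-2 ranking, and `retained`.
#' @export
two_stage_select <- function(radiomics, dosiomics, target, k = 17,
                             floor_frac = 0.01, seed = 1) {
  radiomics <- as.matrix(radiomics)
  dosiomics <- as.matrix(dosiomics)
  if (nrow(radiomics) != nrow(dosiomics)) {
    stop_rotqa("feature tables are not row-aligned", "rotqa_invalid_input")
  }
  if (k == 0) {
    return(structure(list(stage1 = list(), stage2 = NULL,
                          retained = character(0), k = 0),
                     class = "selection_result"))
  }
  keep_top <- function(X, tag) {
    kk <- min(k, ncol(X))
    if (kk < k) warning(sprintf("k clipped to %d for %s", kk, tag))
    rk <- rank_features(X, target, seed = derive_seed(seed, tag))
    list(ranking = rk, retained = head(rk$feature, kk))
  }
  s_rad <- keep_top(radiomics, "radiomics")
  s_dos <- keep_top(dosiomics, "dosiomics")
  merged <- cbind(radiomics[, s_rad$retained, drop = FALSE],
                  dosiomics[, s_dos$retained, drop = FALSE])
  rk2 <- rank_features(merged, target, seed = derive_seed(seed, "stage2"))
  total <- sum(rk2$importance)
  retained <- if (total > 0) {
    rk2$feature[rk2$importance >= floor_frac * total]
  } else {
    rk2$feature
  }
  structure(list(stage1 = list(radiomics = s_rad, dosiomics = s_dos),
                 stage2 = rk2, retained = retained, k = k,
                 floor_frac = floor_frac),
            class = "selection_result")
}

# Fixed candidate family. Linear candidates carry explicit regularization
# strengths so that tuning happens in the grouped outer CV - records of one
# plan are near-duplicates, so any record-level internal CV would leak.
model_candidates <- function(seed) {
  c(list(ols = list(kind = "ols")),
    lapply(setNames(c(0.03, 0.1, 0.3, 1), paste0("ridge_", c(0.03, 0.1, 0.3, 1))),
           function(l) list(kind = "glmnet", alpha = 0, lambda = l)),
    lapply(setNames(c(0.003, 0.01), paste0("lasso_", c(0.003, 0.01))),
           function(l) list(kind = "glmnet", alpha = 1, lambda = l)),
    list(
      xgb_shallow = list(kind = "xgb", max_depth = 2, eta = 0.05,
                         nrounds = 300),
      xgb_deep = list(kind = "xgb", max_depth = 4, eta = 0.1, nrounds = 150),
      rf = list(kind = "ranger", num.trees = 300)))
}

fit_candidate <- function(cand, X, y, seed) {
  switch(cand$kind,
    ols = {
      # least squares via QR; aliased coefficients are dropped rather than
      # warning on rank deficiency
      A <- cbind(1, as.matrix(X))
      beta <- qr.coef(qr(A), y)
      beta[is.na(beta)] <- 0
      list(predict = function(newX) {
        as.vector(cbind(1, as.matrix(newX)) %*% beta)
      })
    },
    glmnet = {
      keep <- apply(X, 2, sd) > 0
      if (!any(keep)) keep[1] <- TRUE
      fit <- glmnet::glmnet(X[, keep, drop = FALSE], y, alpha = cand$alpha,
                            lambda = cand$lambda, standardize = TRUE)
      list(predict = function(newX) {
        as.vector(predict(fit, as.matrix(newX)[, keep, drop = FALSE]))
      })
    },
    xgb = {
      bst <- xgb_train_quiet(X, y, seed, cand$nrounds, cand$max_depth,
                             cand$eta)
      list(predict = function(newX) {
        predict(bst, xgboost::xgb.DMatrix(as.matrix(newX), nthread = 1))
      })
    },
    ranger = {
      df <- data.frame(.y = y, X, check.names = TRUE)
      fit <- ranger::ranger(.y ~ ., data = df, num.trees = cand$num.trees,
                            seed = seed, num.threads = 1)
      list(predict = function(newX) {
        nd <- data.frame(newX, check.names = TRUE)
        predict(fit, data = nd, num.threads = 1)$predictions
      })
    })
}

r2_score <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Fit and evaluate an SSIM-prediction model
#'
#' Searches a small fixed candidate family (ridge/lasso regression,
#' gradient-boosted trees at two depths, random forest) by grouped
#' 10-fold cross-validated R-squared on the training plans, refits the
#' winner on all training rows, and reports held-out test metrics.
#'
#' @param X numeric feature matrix (all records).
#' @param y numeric target.
#' @param plan_ids plan id per row (grouping for folds and split).
#' @param split a [grouped_split()].
#' @param cv_folds folds for the candidate search (default 10).
#' @param seed integer seed.
#' @param scenario label stored in the report.
#' @return list of class `model_report`: `r2`, `mae`, `rmse`, `medae`,
#'   `scenario`, `model` (winner name), `cv_scores` (per-fold R-squared of
#'   the winner), `cv_r2` per candidate, `n_train`, `n_test`.
#' @export
fit_evaluate <- function(X, y, plan_ids, split, cv_folds = 10, seed = 1,
                         scenario = "full") {
  X <- as.matrix(X)
  tr <- plan_ids %in% split$train_plan_ids
  te <- plan_ids %in% split$test_plan_ids
  if (!any(te) || !any(tr)) stop_rotqa("degenerate split",
                                       "rotqa_invalid_input")
  sc <- min_max_scale(X[tr, , drop = FALSE], X[te, , drop = FALSE])
  ytr <- y[tr]
  yte <- y[te]
  if (sd(ytr) == 0) stop_rotqa("constant training target",
                               "rotqa_invalid_input")

  # grouped CV folds over training plans
  tr_plans <- sort(unique(plan_ids[tr]))
  nf <- min(cv_folds, length(tr_plans))
  fold_of_plan <- with_seed(derive_seed(seed, "folds"), {
    setNames(sample(rep(seq_len(nf), length.out = length(tr_plans))),
             tr_plans)
  })
  fold <- fold_of_plan[plan_ids[tr]]

  cands <- model_candidates(seed)
  cv_r2 <- setNames(numeric(length(cands)), names(cands))
  cv_fold_scores <- list()
  for (nm in names(cands)) {
    pred <- rep(NA_real_, sum(tr))
    fold_scores <- numeric(0)
    for (f in seq_len(nf)) {
      hold <- fold == f
      if (!any(hold) || sum(!hold) < 3) next
      fit <- fit_candidate(cands[[nm]], sc$train[!hold, , drop = FALSE],
                           ytr[!hold], derive_seed(seed, paste0(nm, f)))
      pred[hold] <- fit$predict(sc$train[hold, , drop = FALSE])
      if (sd(ytr[hold]) > 0) {
        fold_scores <- c(fold_scores, r2_score(ytr[hold], pred[hold]))
      }
    }
    ok <- !is.na(pred)
    cv_r2[nm] <- r2_score(ytr[ok], pred[ok])
    cv_fold_scores[[nm]] <- fold_scores
  }
  winner <- names(which.max(cv_r2))
  fit <- fit_candidate(cands[[winner]], sc$train, ytr,
                       derive_seed(seed, "final"))
  pred_te <- fit$predict(sc$test)
  err <- yte - pred_te
  structure(list(r2 = r2_score(yte, pred_te),
                 mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 medae = median(abs(err)),
                 scenario = scenario, model = winner,
                 cv_scores = cv_fold_scores[[winner]], cv_r2 = cv_r2,
                 n_train = sum(tr), n_test = sum(te),
                 n_features = ncol(X)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> %s (%s): R2 %.3f, MAE %.4f, RMSE %.4f, MedAE %.4f\n",
    x$scenario, x$model, x$r2, x$mae, x$rmse, x$medae))
  invisible(x)
}

#' Compare the three modeling scenarios
#'
#' On one identical grouped split: (a) full model = selected
#' radiomic/dosiomic features + rotation angles, (b) rotation angles only
#' (pitch/roll/yaw magnitudes, 3 inputs), (c) selected features only.
#' Selection (two-stage, attribution-based) runs on training rows only.
#'
#' @param metrics data.frame from [cohort_metrics()] (needs `plan_id`,
#'   `ssim` and the angle columns).
#' @param features data.frame from [cohort_features()].
#' @param k stage-1 per-group retention (default 17).
#' @param cv_folds CV folds (default 10).
#' @param seed integer seed.
#' @param split optional [grouped_split()]; built from the plans when
#'   `NULL`.
#' @return list of class `scenario_comparison` with `full`,
#'   `rotation_only`, `features_only` model reports plus `selection` and
#'   `split`.
#' @export
scenario_compare <- function(metrics, features, k = 17, cv_folds = 10,
                             seed = 1, split = NULL) {
  df <- merge(metrics, features, by = "plan_id", sort = FALSE)
  if (is.null(split)) split <- grouped_split(df$plan_id, 0.70,
                                             derive_seed(seed, "split"))
  angles <- cbind(pitch = abs(df$pitch_deg), roll = abs(df$roll_deg),
                  yaw = abs(df$yaw_deg))
  rad_cols <- grep("^radiomics_", names(features), value = TRUE)
  dos_cols <- grep("^dosiomics_", names(features), value = TRUE)
  tr <- df$plan_id %in% split$train_plan_ids
  sel <- two_stage_select(df[tr, rad_cols, drop = FALSE],
                          df[tr, dos_cols, drop = FALSE],
                          df$ssim[tr], k = k,
                          seed = derive_seed(seed, "select"))
  feat_mat <- as.matrix(df[, sel$retained, drop = FALSE])
  run <- function(X, scen) {
    fit_evaluate(X, df$ssim, df$plan_id, split, cv_folds,
                 derive_seed(seed, scen), scenario = scen)
  }
  # with an empty selection the full model degenerates to rotation-only
  structure(list(
    full = run(cbind(feat_mat, angles), "full"),
    rotation_only = run(angles, "rotation_only"),
    features_only = if (length(sel$retained) > 0) {
      run(feat_mat, "features_only")
    } else {
      NULL
    },
    selection = sel, split = split),
    class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  for (s in c("full", "rotation_only", "features_only")) print(x[[s]])
  invisible(x)
}
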
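#' Training scheme for NH classifiers
#'
#' Bundles the choices of the model-building stage: population
#' (leave-one-patient-out) versus personalized (within-patient 80/20)
#' training, the metric maximized by the hyperparameter grid search, the
#' RBF-SVM grids over cost `C` and kernel width `gamma`, and the fold
#' structure of the nested stratified cross-validation.
#'
#' @param mode `"population"` or `"personalized"`.
#' @param optimize_metric Metric maximized in the inner grid search:
#'   `"gmean"`, `"mcc"` or `"f1"`.
#' @param include_pa Use the physical-activity features (17 features) or
#'   not (15)?
#' @param c_grid,gamma_grid Positive hyperparameter grids.
#' @param outer_folds,inner_folds Fold counts of the nested CV (>= 2).
#' @param n_repeats Repetitions of the personalized 80/20 split.
#' @param rng_seed Integer seed for all resampling.
#' @return An object of class `nh_scheme`.
#' @export
nh_scheme <- function(mode = c("population", "personalized"),
                      optimize_metric = c("gmean", "mcc", "f1"),
                      include_pa = TRUE,
                      c_grid = 2^seq(-5, 15, by = 2),
                      gamma_grid = 2^seq(-15, 3, by = 2),
                      outer_folds = 5L, inner_folds = 5L,
                      n_repeats = 5L, rng_seed = 1L) {
  mode <- match.arg(mode)
  optimize_metric <- match.arg(optimize_metric)
  stopifnot(length(c_grid) >= 1, all(c_grid > 0),
            length(gamma_grid) >= 1, all(gamma_grid > 0),
            outer_folds >= 2, inner_folds >= 2)
  structure(
    list(mode = mode, optimize_metric = optimize_metric,
         include_pa = include_pa,
         c_grid = sort(c_grid), gamma_grid = sort(gamma_grid),
         outer_folds = as.integer(outer_folds),
         inner_folds = as.integer(inner_folds),
         n_repeats = as.integer(n_repeats),
         rng_seed = as.integer(rng_seed)),
    class = "nh_scheme")
}

#' Stratified fold assignment
#'
#' Assigns instances to `k` folds so that every fold's class ratio is
#' within one instance of the global ratio: indices of each class are
#' shuffled and dealt round-robin.
#'
#' @param labels 0/1 label vector.
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

#' Leave-one-patient-out split
#'
#' @param instances Instance data frame with a `patient_id` column.
#' @param held_out_patient Patient id used as test set.
#' @return List with elements `train` and `test` (data frames).
#' @export
split_population <- function(instances, held_out_patient) {
  if (!held_out_patient %in% instances$patient_id) {
    stop("unknown patient id: ", held_out_patient, call. = FALSE)
  }
  test <- instances[instances$patient_id == held_out_patient, , drop = FALSE]
  train <- instances[instances$patient_id != held_out_patient, , drop = FALSE]
  if (!nrow(test)) stop("held-out patient has no instances", call. = FALSE)
  list(train = train, test = test)
}

#' Stratified within-patient train/test split
#'
#' Splits one patient's instances into training (default 80%) and testing
#' (20%) sets, preserving the class ratio to within one instance.
#'
#' @param instances Instances of a single patient.
#' @param train_frac Training fraction.
#' @return List with elements `train` and `test`.
#' @export
split_personalized <- function(instances, train_frac = 0.8) {
  y <- instances$label
  if (length(unique(y)) < 2L) {
    stop("patient has a single class; personalized model not evaluable",
         call. = FALSE)
  }
  if (nrow(instances) < 10L) {
    stop("too few instances for a personalized split", call. = FALSE)
  }
  test_idx <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- round(length(idx) * (1 - train_frac))
    n_test <- max(1L, n_test)
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = instances[-test_idx, , drop = FALSE],
       test = instances[test_idx, , drop = FALSE])
}

feature_columns <- function(instances, include_pa = TRUE) {
  want <- nh_feature_names(include_pa)
  missing <- setdiff(want, names(instances))
  if (length(missing)) {
    stop("instance table lacks feature columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  want
}

# per-column standardization fit on training data only
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
apply_scaler <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)
}

# RBF-SVM with inverse-frequency class weights; returns fit + scaler
fit_svm <- function(x, y, cost, gamma) {
  sc <- fit_scaler(x)
  yf <- factor(y, levels = c(0, 1))
  tab <- table(yf)
  w <- sum(tab) / (2 * pmax(tab, 1))
  fit <- e1071::svm(apply_scaler(x, sc), yf, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = w, scale = FALSE)
  list(fit = fit, scaler = sc)
}

# decision-function margin oriented so larger = more positive
svm_scores <- function(model, x) {
  pr <- stats::predict(model$fit, apply_scaler(x, model$scaler),
                       decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1]
  if (colnames(dv)[1] == "0/1") s <- -s
  list(class = as.integer(as.character(pr)), score = as.numeric(s))
}

metric_of <- function(cm, which) {
  switch(which, gmean = gmean(cm), mcc = mcc(cm), f1 = f1_score(cm),
         stop("unknown metric ", which, call. = FALSE))
}

# stratified k-fold grid search; returns best (cost, gamma).
# Ties broken toward the smallest cost, then the smallest gamma (grids are
# sorted), preferring smoother models.
grid_search <- function(x, y, scheme) {
  k <- min(scheme$inner_folds, min(table(y)))
  if (k < 2L) stop("too few instances of a class for inner CV", call. = FALSE)
  folds <- stratified_folds(y, k)
  best <- c(cost = scheme$c_grid[1], gamma = scheme$gamma_grid[1])
  best_val <- -Inf
  for (cost in scheme$c_grid) {
    for (gamma in scheme$gamma_grid) {
      pred <- integer(length(y))
      for (f in seq_len(k)) {
        m <- fit_svm(x[folds != f, , drop = FALSE], y[folds != f],
                     cost, gamma)
        pred[folds == f] <- svm_scores(m, x[folds == f, , drop = FALSE])$class
      }
      val <- metric_of(confusion_matrix(y, pred), scheme$optimize_metric)
      if (!is.na(val) && val > best_val + 1e-12) {
        best_val <- val
        best <- c(cost = cost, gamma = gamma)
      }
    }
  }
  list(cost = unname(best["cost"]), gamma = unname(best["gamma"]),
       value = best_val)
}

#' Fit an NH classifier with nested cross-validation
#'
#' The main fitting function. On the training instances it runs an outer
#' stratified `outer_folds`-fold loop; within each outer-training portion
#' an inner stratified `inner_folds`-fold grid search selects the SVM
#' hyperparameters `(C, gamma)` maximizing `optimize_metric`, a model is
#' fitted on the outer-training portion, and evaluated on the held-out
#' outer fold. Fold-wise metrics and their medians estimate
#' generalization. A final model is fitted on all instances with
#' hyperparameters chosen by a grid search over the full training set;
#' feature standardization is always fitted on the respective training
#' portion only.
#'
#' @param instances Instance data frame (features + `label`; a
#'   `patient_id` column is carried along but not used as a feature).
#' @param scheme An [nh_scheme()].
#' @return An object of class `nh_model` with components `outer_models`
#'   (one per outer fold, each with its scaler and chosen
#'   hyperparameters), `cv_metrics` (per-fold metric rows),
#'   `cv_median` (median metric set across folds), `final` (model fitted
#'   on all data), `final_params`, `n`, `class_balance` and `scheme`.
#' @export
nh_fit <- function(instances, scheme = nh_scheme()) {
  feats <- feature_columns(instances, scheme$include_pa)
  x <- as.matrix(instances[, feats])
  y <- as.integer(instances$label)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  set.seed(scheme$rng_seed)
  k <- scheme$outer_folds
  folds <- stratified_folds(y, k)
  outer_models <- vector("list", k)
  rows <- NULL
  for (f in seq_len(k)) {
    xtr <- x[folds != f, , drop = FALSE]; ytr <- y[folds != f]
    gs <- grid_search(xtr, ytr, scheme)
    m <- fit_svm(xtr, ytr, gs$cost, gs$gamma)
    m$cost <- gs$cost; m$gamma <- gs$gamma
    outer_models[[f]] <- m
    pr <- svm_scores(m, x[folds == f, , drop = FALSE])
    ms <- metric_set(confusion_matrix(y[folds == f], pr$class),
                     pr$score, y[folds == f])
    if (is.na(ms[scheme$optimize_metric])) {
      warning("optimize metric undefined on outer fold ", f, "; fold skipped",
              call. = FALSE)
      next
    }
    rows <- rbind(rows, data.frame(fold = f, cost = gs$cost,
                                   gamma = gs$gamma, t(ms)))
  }
  if (is.null(rows)) stop("metric undefined on every outer fold", call. = FALSE)
  gs_all <- grid_search(x, y, scheme)
  final <- fit_svm(x, y, gs_all$cost, gs_all$gamma)
  structure(
    list(outer_models = outer_models, cv_metrics = rows,
         cv_median = apply(rows[, c("se", "sp", "mcc", "f1", "gmean", "auc")],
                           2, stats::median, na.rm = TRUE),
         final = final,
         final_params = c(cost = gs_all$cost, gamma = gs_all$gamma),
         folds = folds, features = feats, n = length(y),
         class_balance = mean(y), scheme = scheme),
    class = "nh_model")
}

#' @export
print.nh_model <- function(x, ...) {
  cat(sprintf(
    paste0("<nh_model> RBF-SVM, %s scheme, optimized for %s\n",
           "  n = %d instances (%.1f%% positive), %d features\n",
           "  final (C, gamma) = (%g, %g)\n",
           "  nested-CV median: SE %.2f, SP %.2f, Gmean %.2f, AUC %.2f\n"),
    x$scheme$mode, x$scheme$optimize_metric, x$n, 100 * x$class_balance,
    length(x$features), x$final_params["cost"], x$final_params["gamma"],
    x$cv_median["se"], x$cv_median["sp"], x$cv_median["gmean"],
    x$cv_median["auc"]))
  invisible(x)
}

#' @export
summary.nh_model <- function(object, ...) {
  out <- list(cv_metrics = object$cv_metrics,
              cv_median = object$cv_median,
              final_params = object$final_params,
              n = object$n, class_balance = object$class_balance,
              scheme = object$scheme)
  class(out) <- "summary.nh_model"
  out
}

#' @export
print.summary.nh_model <- function(x, ...) {
  cat("Nested cross-validation (outer folds):\n")
  print(x$cv_metrics, row.names = FALSE, digits = 3)
  cat("\nMedian across folds:\n")
  print(round(x$cv_median, 3))
  cat(sprintf("\nFinal model: C = %g, gamma = %g on %d instances\n",
              x$final_params["cost"], x$final_params["gamma"], x$n))
  invisible(x)
}

#' Predict nocturnal hypoglycemia for new instances
#'
#' @param object An `nh_model`.
#' @param newdata Instance data frame containing the model's feature
#'   columns.
#' @param type `"class"` for 0/1 predictions, `"score"` for the oriented
#'   RBF decision-function margin (larger = more NH-like).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.nh_model <- function(object, newdata, type = c("class", "score"),
                             ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[, object$features])
  pr <- svm_scores(object$final, x)
  if (type == "class") pr$class else pr$score
}

# evaluate each outer-fold model on an external test set; median metrics
eval_models_on <- function(models, test, feats) {
  xte <- as.matrix(test[, feats])
  yte <- as.integer(test$label)
  ms <- t(vapply(models, function(m) {
    pr <- svm_scores(m, xte)
    metric_set(confusion_matrix(yte, pr$class), pr$score, yte)
  }, numeric(6)))
  apply(ms, 2, stats::median, na.rm = TRUE)
}

#' Leave-one-patient-out population evaluation
#'
#' For every patient: train on all other patients with [nh_fit()] (nested
#' stratified CV and grid search), then evaluate each of the five
#' outer-fold models on the held-out patient and report the median of the
#' five evaluations, so the reported numbers are medians of five
#' model replicates.
#'
#' @param instances Cohort instance table.
#' @param scheme An [nh_scheme()] with `mode = "population"`.
#' @param patients Patient ids to hold out (default: all).
#' @return Data frame with one row per patient (`se`, `sp`, `mcc`, `f1`,
#'   `gmean`, `auc`, `evaluable`).
#' @export
evaluate_population <- function(instances, scheme = nh_scheme("population"),
                                patients = unique(instances$patient_id)) {
  feats <- feature_columns(instances, scheme$include_pa)
  rows <- lapply(patients, function(p) {
    sp <- split_population(instances, p)
    res <- tryCatch({
      fit <- nh_fit(sp$train, scheme)
      med <- eval_models_on(fit$outer_models, sp$test, feats)
      data.frame(patient_id = p, t(med), evaluable = TRUE)
    }, error = function(e) {
      data.frame(patient_id = p, se = NA_real_, sp = NA_real_,
                 mcc = NA_real_, f1 = NA_real_, gmean = NA_real_,
                 auc = NA_real_, evaluable = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Personalized per-patient evaluation
#'
#' For every patient with both classes and at least 10 instances: repeat a
#' stratified 80/20 split `n_repeats` times; on each training portion a
#' stratified grid search picks `(C, gamma)`, the model is fitted and
#' evaluated on the 20% test portion; the median across repetitions is
#' reported. Patients that cannot be evaluated (single-class data) appear
#' with `evaluable = FALSE` rather than being dropped.
#'
#' @param instances Cohort instance table.
#' @param scheme An [nh_scheme()] with `mode = "personalized"`.
#' @return Data frame as in [evaluate_population()].
#' @export
evaluate_personalized <- function(instances,
                                  scheme = nh_scheme("personalized")) {
  feats <- feature_columns(instances, scheme$include_pa)
  patients <- unique(instances$patient_id)
  rows <- lapply(patients, function(p) {
    inst <- instances[instances$patient_id == p, , drop = FALSE]
    res <- tryCatch({
      set.seed(scheme$rng_seed)
      ms <- t(vapply(seq_len(scheme$n_repeats), function(r) {
        spl <- split_personalized(inst)
        xtr <- as.matrix(spl$train[, feats])
        ytr <- as.integer(spl$train$label)
        gs <- grid_search(xtr, ytr, scheme)
        m <- fit_svm(xtr, ytr, gs$cost, gs$gamma)
        pr <- svm_scores(m, as.matrix(spl$test[, feats]))
        yte <- as.integer(spl$test$label)
        metric_set(confusion_matrix(yte, pr$class), pr$score, yte)
      }, numeric(6)))
      med <- apply(ms, 2, stats::median, na.rm = TRUE)
      data.frame(patient_id = p, t(med), evaluable = TRUE)
    }, error = function(e) {
      data.frame(patient_id = p, se = NA_real_, sp = NA_real_,
                 mcc = NA_real_, f1 = NA_real_, gmean = NA_real_,
                 auc = NA_real_, evaluable = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate all scheme combinations
#'
#' Runs the population and/or personalized evaluations for each requested
#' optimization metric and feature set, returning one long per-patient,
#' per-scheme table; cohort medians follow via [stats::median] over the
#' evaluable rows.
#'
#' @param instances Cohort instance table.
#' @param modes Schemes to run.
#' @param metrics Optimization metrics to run.
#' @param include_pa Logical vector of feature-set variants.
#' @param ... Passed to [nh_scheme()] (grids, folds, seed).
#' @return Data frame with columns `mode`, `optimize_metric`,
#'   `include_pa`, `patient_id`, the metric columns and `evaluable`.
#' @export
evaluate_all <- function(instances,
                         modes = c("population", "personalized"),
                         metrics = c("gmean", "mcc", "f1"),
                         include_pa = c(TRUE, FALSE), ...) {
  out <- NULL
  for (mode in modes) {
    for (met in metrics) {
      for (pa in include_pa) {
        scheme <- nh_scheme(mode, met, include_pa = pa, ...)
        tab <- if (mode == "population") {
          evaluate_population(instances, scheme)
        } else {
          evaluate_personalized(instances, scheme)
        }
        out <- rbind(out, cbind(data.frame(mode = mode,
                                           optimize_metric = met,
                                           include_pa = pa), tab))
      }
    }
  }
  rownames(out) <- NULL
  out
}
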
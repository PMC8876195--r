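# toy separable instance table: feature "cgm_t" separates the classes
toy_instances <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  feats <- nh_feature_names(TRUE)
  x <- as.data.frame(matrix(rnorm(n * length(feats), sd = 0.1), n,
                            dimnames = list(NULL, feats)))
  x$cgm_t <- ifelse(y == 1, 60, 140) + rnorm(n, sd = 2)
  cbind(data.frame(patient_id = rep(c("A", "B", "C"), length.out = n)),
        x, data.frame(label = y))
}

small_scheme <- function(mode = "population", ...) {
  nh_scheme(mode, "gmean", c_grid = c(1, 16), gamma_grid = c(0.01, 0.06),
            rng_seed = 11, ...)
}

test_that("stratified folds keep every fold's class ratio within one", {
  set.seed(3)
  for (rep in 1:10) {
    y <- rbinom(57, 1, 0.3)
    if (sum(y) < 5) next
    f <- stratified_folds(y, 5)
    expect_setequal(unique(f), 1:5)
    for (k in 1:5) {
      expect_lte(abs(sum(y[f == k]) - sum(y) / 5), 1)
      expect_lte(abs(sum(y[f == k] == 0) - sum(y == 0) / 5), 1)
    }
  }
})

test_that("population split is a partition with no patient overlap", {
  inst <- toy_instances()
  sp <- split_population(inst, "B")
  expect_setequal(sp$test$patient_id, "B")
  expect_false("B" %in% sp$train$patient_id)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(inst))
  expect_error(split_population(inst, "Z"), "unknown")
})

test_that("personalized split is stratified 80/20 and guarded", {
  inst <- toy_instances(67)
  inst$label <- c(rep(1, 22), rep(0, 45))
  set.seed(10)
  sp <- split_personalized(inst)
  expect_true(nrow(sp$test) %in% 13:14)
  expect_true(sum(sp$test$label) %in% 4:5)
  expect_equal(nrow(sp$train) + nrow(sp$test), 67)
  set.seed(77); a <- split_personalized(inst)
  set.seed(77); b <- split_personalized(inst)
  expect_identical(a$test$night_id, b$test$night_id)
  single <- inst; single$label <- 0
  expect_error(split_personalized(single), "single class")
  expect_error(split_personalized(inst[18:26, ]), "few instances")
})

test_that("a degenerate one-point grid is returned unconditionally", {
  inst <- toy_instances()
  sch <- nh_scheme("population", "gmean", c_grid = 7, gamma_grid = 0.02)
  set.seed(1)
  gs <- noctiguard:::grid_search(as.matrix(inst[, nh_feature_names(TRUE)]),
                                 inst$label, sch)
  expect_equal(gs$cost, 7)
  expect_equal(gs$gamma, 0.02)
})

test_that("nested CV separates a linearly separable toy problem", {
  fit <- nh_fit(toy_instances(), small_scheme())
  expect_s3_class(fit, "nh_model")
  expect_equal(unname(fit$cv_median["se"]), 1)
  expect_equal(unname(fit$cv_median["sp"]), 1)
  pred <- predict(fit, toy_instances(seed = 2))
  expect_equal(pred, toy_instances(seed = 2)$label)
  sc <- predict(fit, toy_instances(seed = 2), type = "score")
  expect_gt(min(sc[toy_instances(seed = 2)$label == 1]),
            max(sc[toy_instances(seed = 2)$label == 0]))
})

test_that("single-class training data is refused", {
  inst <- toy_instances()
  inst$label <- 0
  expect_error(nh_fit(inst, small_scheme()), "both classes")
})

test_that("fits are deterministic under a fixed scheme seed", {
  inst <- test_instances()[1:120, ]
  f1 <- nh_fit(inst, small_scheme())
  f2 <- nh_fit(inst, small_scheme())
  expect_identical(f1$folds, f2$folds)
  expect_identical(f1$cv_metrics, f2$cv_metrics)
})

test_that("no leakage: held-out patient absent from all training folds", {
  inst <- test_instances()
  p <- unique(inst$patient_id)[2]
  sp <- split_population(inst, p)
  fit <- nh_fit(sp$train, small_scheme())
  # audit by id: every instance used in any outer fold comes from train
  expect_false(p %in% sp$train$patient_id)
  expect_equal(sort(unique(c(sp$train$patient_id, sp$test$patient_id))),
               sort(unique(inst$patient_id)))
  expect_equal(length(fit$folds), nrow(sp$train))
})

test_that("shuffling training labels destroys skill (permutation control)", {
  inst <- test_instances()
  p <- unique(inst$patient_id)[1]
  sp <- split_population(inst, p)
  real <- nh_fit(sp$train, small_scheme())
  shuf <- sp$train
  set.seed(123)
  shuf$label <- sample(shuf$label)
  perm <- nh_fit(shuf, small_scheme())
  expect_lte(unname(perm$cv_median["gmean"]), 0.6)
  expect_gt(unname(real$cv_median["gmean"]),
            unname(perm$cv_median["gmean"]))
})

test_that("evaluation tables have the cohort layout with X rows", {
  inst <- test_instances()
  # make one patient single-class to force a non-evaluable row
  pids <- unique(inst$patient_id)
  inst2 <- inst[!(inst$patient_id == pids[4] & inst$label == 1), ]
  tab <- evaluate_personalized(inst2, small_scheme("personalized"))
  expect_equal(nrow(tab), length(pids))
  expect_false(tab$evaluable[tab$patient_id == pids[4]])
  expect_true(any(tab$evaluable))
  ev <- tab[tab$evaluable, ]
  expect_true(all(ev$se >= 0 & ev$se <= 1))
  expect_true(all(ev$sp >= 0 & ev$sp <= 1))
})
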
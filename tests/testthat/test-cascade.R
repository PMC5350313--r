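test_that("axis defaults carry the reference hyperparameters", {
  hp_ilv <- cascade_hyperparams("iLV")
  expect_equal(c(hp_ilv$gamma, hp_ilv$cost_C), c(0.15, 65))
  hp_lvrv <- cascade_hyperparams("LVRV")
  expect_equal(c(hp_lvrv$gamma, hp_lvrv$cost_C), c(0.05, 10))
  expect_error(cascade_hyperparams(cost_C = -1, gamma = 1), "positive")
  expect_error(cascade_hyperparams("iLV", split_fraction = 1.2), "in \\(0, 1\\)")
})

test_that("train/test split honors fraction, stratification and determinism", {
  co <- generate_cohort(cohort_spec(master_seed = 3))
  for (axis_col in c("lvrv_true", "ilv_true")) {
    truth <- class3(co$table[[axis_col]])
    sp <- split_train_test(truth, 0.7, seed = 5)
    expect_length(sp$train, 51)
    expect_length(sp$test, 24)
    expect_setequal(c(sp$train, sp$test), seq_len(75))
    # every class lands in the test set
    expect_setequal(as.character(unique(truth[sp$test])), c("A", "M", "MdS"))
  }
  # reference test-set composition per axis
  t_lvrv <- table(class3(co$table$lvrv_true)[
    split_train_test(class3(co$table$lvrv_true), 0.7, seed = 5)$test])
  expect_equal(unname(c(t_lvrv)), c(10L, 4L, 10L))
  t_ilv <- table(class3(co$table$ilv_true)[
    split_train_test(class3(co$table$ilv_true), 0.7, seed = 5)$test])
  expect_equal(unname(c(t_ilv)), c(11L, 2L, 11L))

  sp1 <- split_train_test(class3(co$table$lvrv_true), 0.7, seed = 9)
  sp2 <- split_train_test(class3(co$table$lvrv_true), 0.7, seed = 9)
  expect_identical(sp1, sp2)

  expect_equal(lengths(split_train_test(rep("x", 10), 0.5, seed = 1,
                                        stratify = FALSE)),
               c(train = 5L, test = 5L))
  expect_error(split_train_test(c("A", "A", "M"), 0.7, 1), "stratify")
})

test_that("separable blobs are fit perfectly and ties go to the less severe class", {
  toy <- toy_cohort()
  m <- train_cascade(toy$X, toy$y, "iLV")
  pred <- predict(m, toy$X)
  expect_equal(as.character(pred), as.character(toy$y))

  # a point exactly on the stage-1 boundary routes to absent
  w1 <- m$stage1$weights
  x_raw <- m$normalizer$center + m$normalizer$scale *
    (-m$stage1$bias * w1 / sum(w1^2))
  expect_equal(as.character(predict(m, x_raw)), "A")

  expect_error(predict(m, rep(0, 3)), "dimension")
  expect_error(train_cascade(toy$X[toy$y != "M", ], toy$y[toy$y != "M"],
                             "iLV"), "all three classes")
})

test_that("unit class weights reduce the weighted stage to the unweighted one", {
  toy <- toy_cohort(n_per_class = c(A = 10, M = 15, MdS = 15), sep = 3)
  hp_w1 <- cascade_hyperparams("iLV", class_weights = c(mild = 1, nonmild = 1))
  m1 <- train_cascade(toy$X, toy$y, "iLV", hp_w1)
  m2 <- train_cascade(toy$X, toy$y, "iLV",
                      cascade_hyperparams("iLV",
                                          class_weights = c(mild = 1.0,
                                                            nonmild = 1.0)))
  pres <- toy$y != "A"
  fit <- e1071::svm(apply_normalizer(m1$normalizer, toy$X)[pres, ],
                    factor(ifelse(toy$y[pres] == "M", "mild", "nonmild")),
                    kernel = "linear", cost = hp_w1$cost_C, scale = FALSE)
  w_ref <- drop(t(fit$coefs) %*% fit$SV)
  expect_equal(abs(sum(m1$stage2$weights * w_ref)) /
                 sqrt(sum(m1$stage2$weights^2) * sum(w_ref^2)), 1,
               tolerance = 1e-6)
  expect_equal(m1$stage2$weights, m2$stage2$weights)
})

test_that("subjects routed absent at stage 1 never reach stage 2", {
  toy <- toy_cohort()
  m <- train_cascade(toy$X, toy$y, "iLV")
  pred <- predict(m, toy$X)
  # corrupting stage 2 must not touch any absent-routed prediction
  m_bad <- m
  m_bad$stage2$weights <- -10 * m$stage2$weights
  m_bad$stage2$bias <- 99
  pred_bad <- predict(m_bad, toy$X)
  expect_identical(pred == "A", pred_bad == "A")
  expect_identical(as.character(pred[pred == "A"]),
                   as.character(pred_bad[pred_bad == "A"]))
})

test_that("cross-validation is seeded, reduces folds with warning, errors when impossible", {
  toy <- toy_cohort(n_per_class = c(A = 12, M = 6, MdS = 12))
  hp <- cascade_hyperparams("iLV", folds = 5, seed = 4)
  cv1 <- suppressWarnings(cross_validate(toy$X, toy$y, "iLV", hp))
  cv2 <- suppressWarnings(cross_validate(toy$X, toy$y, "iLV", hp))
  expect_identical(cv1, cv2)
  expect_equal(cv1$stage1$mean, 100)
  expect_equal(cv1$stage1$sd, 0)

  # folds > smallest stage-2 class (6 mild) -> reduced with a warning
  hp10 <- cascade_hyperparams("iLV", folds = 10, seed = 4)
  expect_warning(cross_validate(toy$X, toy$y, "iLV", hp10), "reducing folds")

  tiny <- toy_cohort(n_per_class = c(A = 3, M = 2, MdS = 3))
  expect_error(suppressWarnings(
    cross_validate(tiny$X, tiny$y, "iLV",
                   cascade_hyperparams("iLV", folds = 10))),
    "fewer subjects")
})

test_that("shuffled labels on a balanced set give chance-level stage-1 accuracy", {
  set.seed(6)
  n <- 60
  X <- matrix(rnorm(n * 6), n)
  y <- factor(rep(c("A", "M", "MdS"), each = n / 3), levels = c("A", "M", "MdS"))
  y <- y[sample(n)]  # labels carry no information about X
  cv <- suppressWarnings(cross_validate(X, y, "iLV",
                                        cascade_hyperparams("iLV", folds = 5,
                                                            seed = 8)))
  # absent:present is 1:2 here; null accuracy ~ max(p, 1-p) band
  expect_gt(cv$stage1$mean, 30)
  expect_lt(cv$stage1$mean, 90)
})

test_that("models serialize to JSON and back without changing predictions", {
  toy <- toy_cohort()
  m <- train_cascade(toy$X, toy$y, "LVRV")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(as.character(predict(m2, toy$X)),
               as.character(predict(m, toy$X)))
  expect_equal(m2$hyperparams$cost_C, m$hyperparams$cost_C)
  expect_equal(m2$axis, "LVRV")
})
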
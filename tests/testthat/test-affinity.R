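# The regressor tests run with the scaled-down desk configuration
# (32/64/32 hidden units, 150 epochs) so the whole file stays fast.

test_that("the regressor fits constant and noiseless linear labels", {
  set.seed(1)
  x <- matrix(rnorm(64 * 6), 64)
  fit_const <- affinity_net(x, rep(-9, 64),
                            desk_predictor_config(epochs = 60, seed = 2))
  expect_true(all(abs(predict(fit_const, x) + 9) < 0.05))

  x2 <- matrix(rnorm(300 * 8), 300)
  w <- rnorm(8)
  y2 <- as.numeric(x2 %*% w) - 10
  fit_lin <- affinity_net(x2, y2, desk_predictor_config(seed = 3))
  expect_lte(rmse(y2, predict(fit_lin, x2)), 0.1)
})

test_that("training is deterministic given the seed", {
  set.seed(7)
  x <- matrix(rnorm(80 * 4), 80)
  y <- rnorm(80) - 9
  cfg <- desk_predictor_config(epochs = 30, seed = 11)
  f1 <- affinity_net(x, y, cfg)
  f2 <- affinity_net(x, y, cfg)
  expect_identical(predict(f1, x), predict(f2, x))
  f3 <- affinity_net(x, y, desk_predictor_config(epochs = 30, seed = 12))
  expect_false(identical(predict(f1, x), predict(f3, x)))
})

test_that("training rejects mismatched or non-finite data", {
  x <- matrix(rnorm(40), 20)
  expect_error(affinity_net(x, rnorm(19), desk_predictor_config()),
               class = "sgnc_data_error")
  expect_error(affinity_net(x, c(rnorm(19), NA), desk_predictor_config()),
               class = "sgnc_data_error")
  expect_error(affinity_net(x[1:8, ], rnorm(8),
                            desk_predictor_config(batch_size = 16)),
               class = "sgnc_data_error")
})

test_that("metrics match textbook formulas to 1e-10", {
  set.seed(9)
  obs <- rnorm(200); pred <- obs + rnorm(200, sd = 0.3)
  r_manual <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(pearson_r(obs, pred), r_manual, tolerance = 1e-10)
  expect_equal(rmse(obs, pred), sqrt(sum((obs - pred)^2) / 200),
               tolerance = 1e-10)
})

test_that("cross-validation folds partition the sample near-evenly", {
  set.seed(2)
  x <- matrix(rnorm(103 * 3), 103)
  y <- as.numeric(x %*% c(1, 2, 3))
  cv <- kfold_cv(x, y, desk_predictor_config(epochs = 5, seed = 4), k = 10)
  expect_equal(sum(cv$per_fold$n), 103L)
  expect_lte(diff(range(cv$per_fold$n)), 1L)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_false(anyNA(cv$predictions))
  # fold assignment reproducible from the seed
  cv2 <- kfold_cv(x, y, desk_predictor_config(epochs = 5, seed = 4), k = 10)
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$pooled_r, cv2$pooled_r)
})

test_that("cross-validation recovers a planted linear signal", {
  set.seed(21)
  x <- matrix(rnorm(250 * 8), 250)
  w <- rnorm(8); w <- w / sqrt(sum(w^2)) * 2.5
  y <- as.numeric(x %*% w) - 10
  cv <- kfold_cv(x, y, desk_predictor_config(seed = 5), k = 5)
  expect_gte(cv$pooled_r, 0.95)
  expect_true(all(abs(cv$per_fold$r) <= 1))
})

test_that("pure-noise labels give near-zero cross-validated correlation", {
  set.seed(22)
  x <- matrix(rnorm(200 * 8), 200)
  y <- rnorm(200) - 9
  cv <- kfold_cv(x, y, desk_predictor_config(epochs = 60, seed = 6), k = 5)
  expect_lte(abs(cv$pooled_r), 0.25)
})

test_that("the panel equals per-target single predictions", {
  set.seed(30)
  x <- matrix(rnorm(120 * 5), 120)
  preds <- list(
    DAT = affinity_net(x, as.numeric(x %*% rnorm(5)) - 11,
                       desk_predictor_config(epochs = 20, seed = 1), "DAT"),
    hERG = affinity_net(x, as.numeric(x %*% rnorm(5)) - 6,
                        desk_predictor_config(epochs = 20, seed = 2), "hERG"))
  z <- matrix(rnorm(20 * 5), 20)
  cand <- data.frame(id = sprintf("C%02d", 1:20))
  cand <- cbind(cand, as.data.frame(`colnames<-`(z, paste0("z", 0:4))))
  panel <- predict_panel(cand, preds, targets = c("DAT", "hERG"))
  for (i in 1:20) {
    expect_equal(panel$DAT[i], predict(preds$DAT, z[i, ]))
    expect_equal(panel$hERG[i], predict(preds$hERG, z[i, ]))
  }
  # empty input gives an empty, well-formed table
  empty <- predict_panel(cand[0, ], preds, targets = c("DAT", "hERG"))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("id", "DAT", "hERG"))
  expect_error(predict_panel(cand, preds), class = "sgnc_config_error")
})
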
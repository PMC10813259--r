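# Stepwise regression and the capsule-parameter surrogate.

test_that("training-set registry reproduces the nine laxity subsets", {
  n_expected <- c(32L, 16L, 16L, 24L, 12L, 12L, 16L, 8L, 8L)
  for (id in 1:9) {
    sp <- training_set_spec(id)
    expect_identical(sp$n_laxity, n_expected[id])
    expect_identical(length(capsulereg:::.spec_predictors(sp)),
                     n_expected[id])
  }
  expect_identical(training_set_spec(1)$flexions, c(0, 30, 60, 90))
  expect_identical(training_set_spec(4)$flexions, c(0, 45, 90))
  expect_identical(training_set_spec(8)$directions,
                   c("internal", "external"))
  expect_error(training_set_spec(10), "1..9")
})

test_that("stepwise regression recovers a noise-free sparse linear model exactly", {
  set.seed(51)
  X <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  y <- 2.5 * X[, 3] - 1.75 * X[, 7] + 4
  f <- stepwise_fit(X, y)
  expect_setequal(f$terms, c("x3", "x7"))
  expect_equal(unname(f$coefficients["x3"]), 2.5, tolerance = 1e-9)
  expect_equal(unname(f$coefficients["x7"]), -1.75, tolerance = 1e-9)
  expect_equal(unname(f$coefficients["(Intercept)"]), 4, tolerance = 1e-9)
  expect_lt(f$rmse, 1e-9)
})

test_that("stepwise false-entry rate under a pure-noise response matches the entry threshold", {
  set.seed(52)
  nsel <- replicate(400, {
    X <- matrix(rnorm(60 * 10), 60, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    length(stepwise_fit(X, rnorm(60))$terms)
  })
  # under the null each of 10 candidates enters at roughly the 0.05
  # level; the best-of-10 first-entry chance is ~0.4, later entries are
  # rarer, so the mean count sits well below 1 but clearly above 0
  expect_gt(mean(nsel), 0.15)
  expect_lt(mean(nsel), 1.2)
})

test_that("degenerate stepwise inputs are rejected or reduced to the intercept", {
  set.seed(53)
  X <- matrix(rnorm(50 * 5), 50, 5, dimnames = list(NULL, paste0("x", 1:5)))
  f <- stepwise_fit(X, rep(2.2, 50))
  expect_identical(f$terms, character(0))
  expect_equal(unname(f$coefficients["(Intercept)"]), 2.2)
  Xc <- cbind(X, const = 1)
  expect_error(stepwise_fit(Xc, rnorm(50)), "constant")
  expect_error(stepwise_fit(X[1:5, ], rnorm(5)), "at least 10")
})

test_that("surrogate trains 12 outputs on the declared candidate sets, deterministically", {
  ds <- fixture_small_trials()
  m <- capsule_surrogate(ds, training_set_spec(1))
  expect_identical(length(m$fits), 12L)
  expect_identical(length(m$predictor_names), 36L)   # 32 laxity + 4 PC
  expect_true(all(unlist(lapply(m$fits, `[[`, "terms")) %in%
                    m$predictor_names))
  m2 <- capsule_surrogate(ds, training_set_spec(1))
  expect_identical(coef(m), coef(m2))
  expect_error(capsule_surrogate(ds[1:30, ], training_set_spec(1)),
               "at least 50")
})

test_that("predictions equal the explicit regression equation", {
  ds <- fixture_small_trials()
  m <- capsule_surrogate(ds, training_set_spec(2))
  row <- ds[17, , drop = FALSE]
  pred <- predict(m, row)
  vals <- attr(pred, "values")
  for (out in names(m$fits)) {
    co <- m$fits[[out]]$coefficients
    manual <- co[["(Intercept)"]] +
      sum(co[m$fits[[out]]$terms] *
            as.numeric(row[, m$fits[[out]]$terms]))
    expect_equal(unname(vals[out]), manual, tolerance = 1e-12)
  }
  expect_s3_class(pred, "capsule_parameters")

  # at the training means the prediction equals the training output means
  mu <- as.data.frame(as.list(m$training_means))
  pm <- attr(predict(m, mu), "values")
  d_ok <- ds[ds$ok, ]
  for (out in names(m$fits))
    expect_equal(unname(pm[out]), mean(d_ok[[out]]), tolerance = 1e-9)

  # residual consistency: stored residuals match refitting by hand
  fitted_all <- fitted(m)
  for (out in c("sector1_stiffness", "sector3_prestrain"))
    expect_equal(unname(d_ok[[out]] - fitted_all[, out]),
                 unname(m$fits[[out]]$residuals), tolerance = 1e-12)

  expect_error(predict(m, data.frame(pc1 = 1)), "missing predictors")
})

test_that("wider candidate sets do not worsen training fit at study scale", {
  ds <- fixture_full_trials()
  m1 <- capsule_surrogate(ds, training_set_spec(1))
  m8 <- capsule_surrogate(ds, training_set_spec(8))
  r1 <- vapply(m1$fits, `[[`, numeric(1), "rmse")
  r8 <- vapply(m8$fits, `[[`, numeric(1), "rmse")
  expect_true(all(r1 <= r8 + 1e-9))
})

test_that("surrogate recovers true parameters in a near-linear taut regime", {
  # with every sector taut and tight input spread, laxity is close to
  # linear in the parameters and all twelve outputs are identifiable
  d <- default_distributions()
  d$mean[7:12] <- c(1.00, 0.97, 0.94, 0.96, 0.93, 0.95)
  d$sd[1:6] <- 8
  d$sd[7:12] <- 0.015
  sm <- fixture_shape_model()
  cfgm <- default_mesh_config(n_lines = 12)
  ds <- generate_trial_dataset(500, sm, dists = d, mesh_config = cfgm,
                               seed = 94)
  train <- capsulereg:::.subset_trials(ds, 1:450)
  hold <- ds[451:500, ]
  m <- capsule_surrogate(train, training_set_spec(1))
  P <- predict(m, hold)
  for (out in capsulereg:::.mech_param_names) {
    r2 <- cor(P[, out], hold[[out]])^2
    expect_gt(r2, 0.8)
  }
})

test_that("surrogate JSON serialization round-trips predictions", {
  ds <- fixture_small_trials()
  m <- capsule_surrogate(ds, training_set_spec(8))
  path <- tempfile(fileext = ".json")
  write_surrogate_json(m, path)
  m2 <- read_surrogate_json(path)
  p1 <- attr(predict(m, ds[5, , drop = FALSE]), "values")
  p2 <- attr(predict(m2, ds[5, , drop = FALSE]), "values")
  expect_equal(p1, p2, tolerance = 1e-12)
})
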
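# Train/test splitting, standardization, and the linear discriminant model.

test_that("the 80/20 split has the documented sizes and is a partition", {
  sp <- split_train_test(1452, 0.8, seed = 1)
  expect_length(sp$train, 1162)
  expect_length(sp$test, 290)
  expect_identical(sort(c(sp$train, sp$test)), 1:1452)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- split_train_test(1452, 0.8, seed = 1)
  expect_identical(sp, sp2)
  expect_error(split_train_test(100, 1.2), "fraction")
  expect_error(split_train_test(100, 0), "fraction")
})

test_that("standardization centres/scales training data and reuses its moments", {
  set.seed(6)
  tr <- matrix(rnorm(300, 10, 4), ncol = 3,
               dimnames = list(NULL, c("a", "b", "c")))
  st <- standardize_features(tr, tr)
  expect_true(all(abs(colMeans(st$train)) < 1e-12))
  expect_equal(apply(st$train, 2, sd), c(a = 1, b = 1, c = 1),
               tolerance = 1e-12)
  expect_identical(st$train, st$test)
  expect_equal(standardize_features(matrix(c(1, 2, 3)))$train[, 1],
               c(-1, 0, 1))
  trz <- cbind(tr, d = 5)
  expect_error(standardize_features(trz), "d")
})

test_that("two symmetric 1-D classes put the boundary at zero", {
  set.seed(10)
  x <- matrix(c(rnorm(400, -1, 1), rnorm(400, 1, 1)))
  g <- factor(rep(c("a", "b"), each = 400))
  m <- lda_fit(x, g)
  # force the exactly symmetric population model
  m$means <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), NULL))
  m$prior <- c(a = 0.5, b = 0.5)
  m$W <- matrix(1)
  p0 <- predict(m, matrix(0))
  expect_equal(as.numeric(p0$posterior), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("posteriors are normalised and match the closed-form 1-D logistic", {
  set.seed(20)
  x <- matrix(c(rnorm(60, 0, 1), rnorm(90, 2, 1)))
  g <- factor(rep(c("lo", "hi"), times = c(60, 90)), levels = c("lo", "hi"))
  m <- lda_fit(x, g)
  xs <- matrix(seq(-2, 4, length.out = 25))
  pr <- predict(m, xs)
  expect_equal(rowSums(pr$posterior), rep(1, 25), tolerance = 1e-12)
  # closed form: with shared variance s2, log odds are linear in x
  mu <- m$means[, 1]; s2 <- m$W[1, 1]
  eta <- (mu["hi"] - mu["lo"]) / s2 * xs[, 1] +
    (mu["lo"]^2 - mu["hi"]^2) / (2 * s2) +
    log(m$prior["hi"] / m$prior["lo"])
  expect_equal(unname(pr$posterior[, "hi"]), unname(1 / (1 + exp(-eta))),
               tolerance = 1e-9)
})

test_that("rows at a class mean are assigned that class under equal priors", {
  set.seed(30)
  x <- rbind(matrix(rnorm(200, 0, 0.5), ncol = 2),
             matrix(rnorm(200, 4, 0.5), ncol = 2))
  g <- factor(rep(c("a", "b"), each = 100))
  m <- lda_fit(x, g)
  pr <- predict(m, m$means)
  expect_identical(as.character(pr$class), c("a", "b"))
})

test_that("the model agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(44)
  n <- 150
  mus <- rbind(c(0, 0, 0), c(2, 0, 1), c(0, 2, -1), c(1.5, 1.5, 0.5))
  x <- do.call(rbind, lapply(1:4, function(c1)
    sweep(matrix(rnorm(n * 3), ncol = 3), 2, mus[c1, ], "+")))
  g <- factor(rep(paste0("g", 1:4), each = n))
  m <- lda_fit(x, g)
  ref <- MASS::lda(x, g)
  pm <- predict(m, x)
  pref <- stats::predict(ref, x)
  expect_equal(as.character(pm$class), as.character(pref$class))
  expect_equal(unname(pm$posterior), unname(pref$posterior),
               tolerance = 1e-6)
  expect_equal(m$trace_proportion, unname(ref$svd^2 / sum(ref$svd^2)),
               tolerance = 1e-6)
})

test_that("trace proportions sum to one, decrease, and axes are W-orthonormal", {
  set.seed(50)
  x <- matrix(rnorm(1200), ncol = 4)
  x[1:100, 1] <- x[1:100, 1] + 2
  x[101:200, 2] <- x[101:200, 2] + 1.5
  g <- factor(rep(c("a", "b", "c"), each = 100))
  m <- lda_fit(x, g)
  expect_equal(sum(m$trace_proportion), 1, tolerance = 1e-12)
  expect_true(all(diff(m$trace_proportion) <= 1e-12))
  expect_identical(ncol(m$scaling), 2L)          # min(C-1, p)
  ortho <- t(m$scaling) %*% m$W %*% m$scaling
  expect_equal(ortho, diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: dominant coefficient of each axis is positive
  for (j in 1:2) expect_gt(m$scaling[which.max(abs(m$scaling[, j])), j], 0)
})

test_that("pre-standardization column scaling leaves predictions unchanged", {
  set.seed(60)
  x <- matrix(rnorm(900), ncol = 3)
  x[1:150, ] <- x[1:150, ] + 1
  g <- factor(rep(c("a", "b"), each = 150))
  fit_pred <- function(xm) {
    sp <- split_train_test(nrow(xm), 0.8, seed = 2)
    st <- standardize_features(xm[sp$train, ], xm[sp$test, ])
    m <- lda_fit(st$train, g[sp$train])
    as.character(predict(m, st$test)$class)
  }
  x2 <- sweep(x, 2, c(100, 0.01, 7), "*")
  expect_identical(fit_pred(x), fit_pred(x2))
})

test_that("degenerate inputs are rejected and near-singular covariance is ridged", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(lda_fit(x, factor(rep("a", 10))), "2 classes")
  expect_error(lda_fit(x, factor(c("a", rep("b", 9)))), "fewer than 2")
  expect_error(predict(lda_fit(x, factor(rep(c("a", "b"), 5))),
                       matrix(rnorm(9), ncol = 3)),
               "columns")
  # duplicated column makes W singular; ridge keeps the fit alive
  xd <- cbind(x, x[, 1])
  expect_message(md <- lda_fit(xd, factor(rep(c("a", "b"), 5))), "ridge")
  expect_true(md$ridge_applied)
})

test_that("preliminary two-group models collapse labels and separate when separable", {
  set.seed(70)
  n <- 400
  g4 <- sample(c("mc_low", "mc_high", "vs_low", "vs_high"), n, replace = TRUE)
  x <- matrix(rnorm(n * 3), ncol = 3)
  # task label perfectly encoded in predictor 1; level weakly in predictor 2
  x[, 1] <- ifelse(grepl("^mc", g4), 3, -3) + rnorm(n, 0, 0.3)
  x[, 2] <- ifelse(grepl("low$", g4), 0.3, -0.3) + rnorm(n)
  sp <- split_train_test(n, 0.8, seed = 3)
  st <- standardize_features(x[sp$train, ], x[sp$test, ])
  pre <- fit_preliminary_models(st$train, st$test,
                                g4[sp$train], g4[sp$test])
  expect_gt(pre$type$accuracy, 0.98)
  expect_gt(pre$level$accuracy, 0.5)
  expect_identical(ncol(pre$type$model$scaling), 1L)
  expect_equal(pre$type$model$trace_proportion, 1)
})

test_that("feature_matrix drops incomplete rows and keeps the fixed column order", {
  set.seed(80)
  ft <- synthetic_feature_table(4, participant_effect_sd = 1)
  ft$hrv_s[3] <- NA
  expect_message(fm <- feature_matrix(ft), "dropped 1")
  expect_identical(nrow(fm$x), nrow(ft) - 1L)
  expect_identical(colnames(fm$x),
                   c("fix_dur_ms", "sacc_amp_px", "k_coef", "hrv_s",
                     "gsr_ohm", "lhipa", "pupil_dilation_pct",
                     "dspan_backward"))
  expect_error(feature_matrix(ft[, setdiff(names(ft), "lhipa")]), "lhipa")
})
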
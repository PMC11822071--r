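# Linear discriminant model on standardized predictors: train/test split,
# z-standardization with training moments, eigen-solution of the
# between/within scatter problem, Gaussian posteriors, and the two
# preliminary two-group models (load type, load level).

.predictor_cols <- c("fix_dur_ms", "sacc_amp_px", "k_coef", "hrv_s",
                     "gsr_ohm", "lhipa", "pupil_dilation_pct",
                     "dspan_backward")

#' Predictor matrix for the discriminant model
#'
#' Extracts the eight predictors in fixed column order (fixation duration,
#' saccade amplitude, K coefficient, HRV, GSR, LHIPA, pupil dilation,
#' backward digit span), dropping rows with any missing predictor.
#'
#' @param features Feature table from [build_feature_table()].
#' @return List with `x` (numeric matrix), `group` (factor), `ids`
#'   (participant/trial), `task`, `load`, and `n_dropped`.
#' @export
feature_matrix <- function(features) {
  missing_cols <- setdiff(.predictor_cols, names(features))
  if (length(missing_cols) > 0)
    stop("feature table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(features[, .predictor_cols])
  storage.mode(x) <- "double"
  keep <- stats::complete.cases(x) & apply(is.finite(x), 1, all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("feature_matrix: dropped ", n_dropped,
            " row(s) with missing predictors")
  list(x = x[keep, , drop = FALSE],
       group = factor(features$group[keep]),
       ids = paste(features$participant_id, features$trial_id,
                   sep = "/")[keep],
       task = features$task[keep],
       load = features$load[keep],
       n_dropped = n_dropped)
}

#' Random train/test split of trial rows
#'
#' @param n Number of rows, or a data.frame/matrix whose rows are split.
#' @param fraction Training fraction in (0, 1); the training set receives
#'   `round(fraction * n)` rows.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   covering all rows).
#' @export
split_train_test <- function(n, fraction = 0.8, seed = 1L) {
  if (!is.numeric(n)) n <- nrow(n)
  if (is.null(n) || n < 2) stop("need at least 2 rows to split")
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  set.seed(seed)
  n_train <- round(fraction * n)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Standardize predictors with training moments
#'
#' Training columns are centred and scaled to mean 0 / SD 1; test columns
#' are transformed with the training statistics.
#'
#' @param train Training predictor matrix.
#' @param test Optional test matrix with identical columns.
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
standardize_features <- function(train, test = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance training column(s): ",
         paste(colnames(train)[zero], collapse = ", "))
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  te <- if (!is.null(test)) {
    test <- as.matrix(test)
    stopifnot(ncol(test) == ncol(train))
    sweep(sweep(test, 2, ctr), 2, scl, "/")
  } else NULL
  list(train = tr, test = te, center = ctr, scale = scl)
}

#' Fit a linear discriminant model
#'
#' Estimates class means, priors (class frequencies) and the pooled
#' within-class covariance `W`, then solves the generalized eigenproblem
#' `B a = lambda W a` (B = between-class scatter) through the
#' Cholesky-whitened symmetric form for numerical stability. Axes are
#' scaled so the pooled within-class variance of each discriminant score is
#' 1 (the convention of classical discriminant software) and signed so the
#' largest-magnitude coefficient is positive. Eigenvalues give the
#' proportions of discriminative variance ("proportion of trace").
#'
#' When `W` is near-singular a ridge `1e-8 * tr(W)/p` is added to its
#' diagonal (with a message).
#'
#' @param x Predictor matrix (rows = trials).
#' @param grouping Factor of class labels (>= 2 classes, each with >= 2
#'   rows).
#' @return Object of class `cogload_lda`: `classes`, `prior`, `means`,
#'   `grand_mean`, `W`, `scaling` (p x r coefficient matrix, columns LD1..),
#'   `svd_values`, `trace_proportion`, `ridge_applied`.
#' @export
lda_fit <- function(x, grouping) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  g <- droplevels(factor(grouping))
  stopifnot(nrow(x) == length(g))
  classes <- levels(g)
  C <- length(classes)
  if (C < 2) stop("need at least 2 classes")
  counts <- table(g)
  if (any(counts < 2))
    stop("class(es) with fewer than 2 rows: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  N <- nrow(x)
  p <- ncol(x)
  prior <- as.numeric(counts) / N
  names(prior) <- classes
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[g == cl, , drop = FALSE])))
  rownames(means) <- classes
  grand <- colMeans(x)

  Wsc <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[g == cl, , drop = FALSE], 2, means[cl, ])
    Wsc <- Wsc + crossprod(xc)
  }
  W <- Wsc / (N - C)
  ridge_applied <- FALSE
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R) || rcond(W) < 1e-12) {
    W <- W + diag(1e-8 * sum(diag(W)) / p, p)
    ridge_applied <- TRUE
    message("lda_fit: near-singular pooled covariance; ridge applied")
    R <- chol(W)
  }
  Md <- sweep(means, 2, grand)
  B <- crossprod(Md * sqrt(as.numeric(counts))) / (N - C)
  Rinv <- backsolve(R, diag(p))
  A <- crossprod(Rinv, B %*% Rinv)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  r <- min(C - 1, p)
  vals <- pmax(e$values[seq_len(r)], 0)
  axes <- Rinv %*% e$vectors[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    k <- which.max(abs(axes[, j]))
    if (axes[k, j] < 0) axes[, j] <- -axes[, j]
  }
  dimnames(axes) <- list(colnames(x), paste0("LD", seq_len(r)))
  structure(
    list(classes = classes, prior = prior, means = means,
         grand_mean = grand, W = W, scaling = axes, svd_values = vals,
         trace_proportion = if (sum(vals) > 0) vals / sum(vals)
                            else rep(NA_real_, r),
         ridge_applied = ridge_applied, n = N),
    class = "cogload_lda"
  )
}

#' @export
print.cogload_lda <- function(x, ...) {
  cat("<cogload_lda> ", length(x$classes), " classes, ",
      ncol(x$scaling), " discriminant axis(es)\n", sep = "")
  cat("Priors:\n")
  print(round(x$prior, 4))
  cat("Coefficients of linear discriminants:\n")
  print(round(x$scaling, 3))
  cat("Proportion of trace:\n")
  print(round(x$trace_proportion, 4))
  invisible(x)
}

#' Predict classes and posteriors from a discriminant model
#'
#' Posteriors are the shared-covariance Gaussian class posteriors
#' `p(c | x) ∝ prior_c exp(-0.5 (x - m_c)' W^{-1} (x - m_c))`,
#' normalised per row; scores are the projections of the centred rows on
#' the discriminant axes; the predicted class maximises the posterior.
#'
#' @param object A [lda_fit()] model.
#' @param newdata Matrix of rows standardized with the training moments.
#' @param ... Unused.
#' @return List with `class` (factor), `posterior` (rows sum to 1) and
#'   `scores`.
#' @export
predict.cogload_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != nrow(object$scaling))
    stop("newdata has ", ncol(x), " columns; model expects ",
         nrow(object$scaling))
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), rownames(object$scaling)))
    stop("newdata columns do not match the model's predictors")
  Winv <- chol2inv(chol(object$W))
  C <- length(object$classes)
  loglik <- matrix(0, nrow(x), C)
  for (ci in seq_len(C)) {
    d <- sweep(x, 2, object$means[ci, ])
    loglik[, ci] <- -0.5 * rowSums((d %*% Winv) * d) +
      log(object$prior[ci])
  }
  mx <- apply(loglik, 1, max)
  post <- exp(loglik - mx)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  scores <- sweep(x, 2, object$grand_mean) %*% object$scaling
  cls <- factor(object$classes[max.col(post, ties.method = "first")],
                levels = object$classes)
  list(class = cls, posterior = post, scores = scores)
}

#' Fit the two preliminary two-group models
#'
#' Collapses the four-group factor into (a) cognitive-load type
#' (mental calculation vs. visual search, i.e. intrinsic vs. extraneous)
#' and (b) load level (low vs. high), fits a two-class discriminant model
#' for each on the standardized training rows, and reports test accuracy.
#'
#' @param train,test Standardized predictor matrices.
#' @param train_group,test_group Four-group labels of the rows.
#' @return List with elements `type` and `level`, each containing `model`,
#'   `accuracy` and `predicted`.
#' @export
fit_preliminary_models <- function(train, test, train_group, test_group) {
  collapse <- list(
    type = function(g) factor(ifelse(grepl("^mc", g), "icl", "ecl"),
                              levels = c("icl", "ecl")),
    level = function(g) factor(ifelse(grepl("low$", g), "low", "high"),
                               levels = c("low", "high"))
  )
  lapply(collapse, function(f) {
    m <- lda_fit(train, f(train_group))
    pr <- predict(m, test)
    acc <- mean(pr$class == f(test_group))
    list(model = m, accuracy = acc, predicted = pr$class)
  })
}
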
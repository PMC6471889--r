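## Supervised regression of environmental parameters on community
## composition, with the entire-community vs active-community comparison.
## Features are per-sample relative abundances (samples in rows); the
## regressor is the package's bagged regression-tree ensemble (100 trees,
## mtry = p/3, minimum leaf size 1 - the standard random-forest regression
## defaults in the R ecosystem).

#' Train/test split of sample ids
#'
#' `floor(n * train_fraction)` samples train; the remainder test.
#' Reproducible for a given seed.
#'
#' @param samples character vector of sample ids.
#' @param train_fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_samples <- function(samples, train_fraction = 0.8, seed = 1L) {
  assert_scalar_number(train_fraction, "train_fraction",
                       lower = 1e-9, upper = 1 - 1e-9)
  n <- length(samples)
  n_train <- floor(n * train_fraction)
  if (n_train < 2L || n - n_train < 2L)
    stop("too few samples for a ", train_fraction, " split of ", n,
         call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = samples[sort(idx)], test = samples[sort(setdiff(seq_len(n), idx))])
}

#' Fit the ensemble regressor
#'
#' Returns a lightweight model handle storing the training data, the
#' hyperparameters and the seed; prediction regrows the (deterministic)
#' forest, so the handle is small and fully reproducible.
#'
#' @param features numeric matrix, samples x features (relative
#'   abundances).
#' @param target numeric response, one value per training sample, no
#'   missing values (drop those samples upstream).
#' @param seed RNG seed for bootstrap and feature sampling.
#' @param ntree,mtry,min_node ensemble hyperparameters; `mtry` defaults to
#'   `max(1, floor(p/3))`.
#' @return object of class `growthseq_rf`.
#' @export
fit_regressor <- function(features, target, seed = 1L, ntree = 100L,
                          mtry = NULL, min_node = 1L) {
  features <- as.matrix(features)
  if (length(target) != nrow(features))
    stop("target length must equal nrow(features)", call. = FALSE)
  if (anyNA(target))
    stop("missing target values; drop those samples before fitting",
         call. = FALSE)
  if (var(target) == 0)
    warning("constant target; the model will predict that constant",
            call. = FALSE)
  mtry <- mtry %||% max(1L, floor(ncol(features) / 3))
  structure(list(X = features, y = as.numeric(target),
                 ntree = as.integer(ntree), mtry = as.integer(mtry),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "growthseq_rf")
}

#' @export
predict.growthseq_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X))
    stop("feature-space mismatch: model has ", ncol(object$X),
         " features, newdata has ", ncol(newdata), call. = FALSE)
  as.numeric(.rf_fit_predict(object$X, object$y, newdata, object$ntree,
                             object$mtry, object$min_node, object$seed))
}

#' Prediction-accuracy metrics
#'
#' MSE plus the slope, squared Pearson correlation and p-value of the
#' ordinary least-squares fit of predicted (y) on observed (x) - the
#' accuracy summary used to compare feature sets.
#'
#' @param observed,predicted paired numeric vectors, length >= 3.
#' @return list: `mse`, `r_squared`, `slope`, `p_value`, `n`.
#' @export
evaluate <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3L)
    stop("need >= 3 paired values", call. = FALSE)
  mse <- mean((observed - predicted)^2)
  if (var(observed) == 0)
    return(list(mse = mse, r_squared = NA_real_, slope = NA_real_,
                p_value = NA_real_, n = length(observed)))
  fit <- lm(predicted ~ observed)
  sm <- suppressWarnings(summary(fit))  # silence perfect-fit notes
  slope <- unname(coef(fit)[2L])
  r2 <- if (var(predicted) == 0) 0 else unname(cor(observed, predicted)^2)
  p <- if (var(predicted) == 0) NA_real_ else
    unname(sm$coefficients[2L, 4L])
  list(mse = mse, r_squared = r2, slope = slope, p_value = p,
       n = length(observed))
}

## Feature matrix (samples x OTUs) for a feature set. "active" subsets to
## OTUs with mu_mean > 0 and renormalises each sample to sum 1.
feature_matrix <- function(table, samples, feature_set = c("entire", "active"),
                           growth = NULL) {
  feature_set <- match.arg(feature_set)
  rel <- to_relative_abundance(unclass(table)[, samples, drop = FALSE])
  if (feature_set == "active") {
    if (is.null(growth)) stop("'active' feature set needs a growth result",
                              call. = FALSE)
    keep <- growth$otu_id[growth$active]
    rel <- rel[rownames(rel) %in% keep, , drop = FALSE]
    tot <- colSums(rel)
    tot[tot == 0] <- 1
    rel <- sweep(rel, 2L, tot, "/")
  }
  t(rel)
}

#' Regress one environmental parameter on community composition
#'
#' Samples with a missing value of the parameter are dropped (and
#' counted); the remainder is split 80/20 (configurable), the ensemble is
#' trained on the training portion and evaluated on the held-out portion.
#'
#' @param table an [otu_table()].
#' @param metadata sample metadata.
#' @param parameter metadata column name (e.g. "temperature").
#' @param feature_set `"entire"` or `"active"`.
#' @param growth a `growth_result` (required for `"active"`).
#' @param samples sample ids to use; default the activated-sludge subset.
#' @param train_fraction,seed,ntree see [split_samples()], [fit_regressor()].
#' @return object of class `regression_report`: list with the metrics of
#'   [evaluate()], `parameter`, `feature_set`, `n_train`, `n_test`,
#'   `n_usable`, `n_dropped_missing`, and per-test-sample `observed` /
#'   `predicted`.
#' @export
regress_parameter <- function(table, metadata, parameter,
                              feature_set = c("entire", "active"),
                              growth = NULL, samples = NULL,
                              train_fraction = 0.8, seed = 1L,
                              ntree = 100L) {
  feature_set <- match.arg(feature_set)
  if (!parameter %in% names(metadata))
    stop("unknown parameter: ", parameter, call. = FALSE)
  samples <- samples %||% as_sample_ids(metadata)
  samples <- intersect(samples, colnames(table))
  target <- metadata[[parameter]][match(samples, metadata$sample_id)]
  usable <- samples[!is.na(target)]
  n_dropped <- length(samples) - length(usable)
  split <- split_samples(usable, train_fraction,
                         derive_seed(seed, paste0("split.", parameter)))
  X <- feature_matrix(table, usable, feature_set, growth)
  y <- metadata[[parameter]][match(usable, metadata$sample_id)]
  names(y) <- usable
  model <- fit_regressor(X[split$train, , drop = FALSE], y[split$train],
                         seed = derive_seed(seed, paste0("rf.", parameter)),
                         ntree = ntree)
  pred <- predict(model, X[split$test, , drop = FALSE])
  ev <- evaluate(y[split$test], pred)
  structure(c(ev, list(parameter = parameter, feature_set = feature_set,
                       n_train = length(split$train),
                       n_test = length(split$test),
                       n_usable = length(usable),
                       n_dropped_missing = n_dropped,
                       observed = unname(y[split$test]), predicted = pred,
                       test_samples = split$test, model = model,
                       split = split, X = X, y = y)),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> %s (%s community): MSE %.4g, R2 %.3f, slope %.3f (n=%d/%d)\n",
    x$parameter, x$feature_set, x$mse, x$r_squared, x$slope,
    x$n_train, x$n_test))
  invisible(x)
}

#' Entire-vs-active comparison table
#'
#' One row per parameter with the accuracy metrics of both feature sets
#' and the active/entire ratios (defined only where the denominator is
#' positive).
#'
#' @param entire,active named lists of `regression_report`s over the same
#'   parameters (and the same test samples per parameter).
#' @return data.frame with columns parameter, mse_entire, r2_entire,
#'   p_entire, slope_entire, mse_active, r2_active, p_active,
#'   slope_active, mse_ratio, r2_ratio, slope_ratio.
#' @export
compare_feature_sets <- function(entire, active) {
  stopifnot(identical(names(entire), names(active)))
  rows <- lapply(names(entire), function(p) {
    e <- entire[[p]]; a <- active[[p]]
    ratio <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_
    data.frame(parameter = p,
               mse_entire = e$mse, r2_entire = e$r_squared,
               p_entire = e$p_value, slope_entire = e$slope,
               mse_active = a$mse, r2_active = a$r_squared,
               p_active = a$p_value, slope_active = a$slope,
               mse_ratio = ratio(a$mse, e$mse),
               r2_ratio = ratio(a$r_squared, e$r_squared),
               slope_ratio = ratio(a$slope, e$slope),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-sample prediction intervals by repeated estimation
#'
#' Refits the ensemble `n_repeats` times, each time on a bootstrap
#' resample of the training samples with a fresh forest seed, and reports
#' the 2.5/97.5 percentile band of the test predictions ("95% confidence
#' interval with repeated estimation").
#'
#' @param report a `regression_report` from [regress_parameter()].
#' @param n_repeats number of refits (>= 2).
#' @param seed RNG seed.
#' @return data.frame: sample, observed, predicted, ci_low, ci_high.
#' @export
prediction_intervals <- function(report, n_repeats = 100L, seed = 1L) {
  if (n_repeats < 2L)
    stop("n_repeats must be >= 2 to form an interval", call. = FALSE)
  tr <- report$split$train
  te <- report$split$test
  X <- report$X; y <- report$y
  preds <- matrix(NA_real_, length(te), n_repeats)
  idx_draws <- with_seed(derive_seed(seed, "pi.boot"), {
    replicate(n_repeats, sample(length(tr), replace = TRUE))
  })
  for (r in seq_len(n_repeats)) {
    take <- tr[idx_draws[, r]]
    m <- fit_regressor(X[take, , drop = FALSE], y[take],
                       seed = derive_seed(seed, paste0("pi.rf.", r)),
                       ntree = report$model$ntree,
                       mtry = report$model$mtry,
                       min_node = report$model$min_node)
    preds[, r] <- predict(m, X[te, , drop = FALSE])
  }
  data.frame(sample = te,
             observed = unname(y[te]),
             predicted = report$predicted,
             ci_low = apply(preds, 1L, quantile, probs = 0.025),
             ci_high = apply(preds, 1L, quantile, probs = 0.975),
             stringsAsFactors = FALSE)
}

#' Tank-holdout regression protocol
#'
#' Trains on all samples from all tanks but one and tests on the held-out
#' tank (the "two tanks train, third tank tests" design). Returns one
#' report per held-out tank plus the pooled metrics.
#'
#' @inheritParams regress_parameter
#' @return list of per-tank `evaluate()` metrics plus `pooled` metrics
#'   over all held-out predictions.
#' @export
regress_tank_holdout <- function(table, metadata, parameter,
                                 feature_set = c("entire", "active"),
                                 growth = NULL, seed = 1L, ntree = 100L) {
  feature_set <- match.arg(feature_set)
  samples <- intersect(as_sample_ids(metadata), colnames(table))
  target <- metadata[[parameter]][match(samples, metadata$sample_id)]
  usable <- samples[!is.na(target)]
  md <- metadata[match(usable, metadata$sample_id), ]
  X <- feature_matrix(table, usable, feature_set, growth)
  y <- metadata[[parameter]][match(usable, metadata$sample_id)]
  names(y) <- usable
  tanks <- sort(unique(md$tank[md$tank != "none"]))
  obs_all <- numeric(); pred_all <- numeric()
  per_tank <- list()
  for (tk in tanks) {
    te <- usable[md$tank == tk]
    tr <- setdiff(usable, te)
    if (length(te) < 3L || length(tr) < 3L) next
    m <- fit_regressor(X[tr, , drop = FALSE], y[tr],
                       seed = derive_seed(seed, paste0("holdout.", tk)),
                       ntree = ntree)
    p <- predict(m, X[te, , drop = FALSE])
    per_tank[[tk]] <- evaluate(y[te], p)
    obs_all <- c(obs_all, y[te]); pred_all <- c(pred_all, p)
  }
  c(per_tank, list(pooled = evaluate(obs_all, pred_all)))
}
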
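## Redundancy analysis: PCA of the fitted values of the multivariate
## least-squares regression of the (centred, optionally Hellinger-
## transformed) community matrix on the standardised environmental
## matrix. Variance convention follows vegan: eigenvalues are sums of
## squares divided by (n - 1), so constrained + unconstrained eigenvalues
## sum to the total variance of the centred community matrix.

#' Hellinger transformation
#'
#' Square root of per-sample proportions; after the transform every
#' sample's sum of squares is 1. Standard pre-treatment before RDA on
#' abundance data.
#'
#' @param rel matrix of relative abundances, samples x features (rows sum
#'   to 1) or features x samples (columns sum to 1; auto-detected and
#'   returned in samples x features orientation).
#' @return numeric matrix, samples x features.
#' @export
hellinger_transform <- function(rel) {
  rel <- as.matrix(rel)
  if (any(rel < 0)) stop("negative proportions", call. = FALSE)
  cs <- colSums(rel); rs <- rowSums(rel)
  if (all(abs(cs - 1) < 1e-6) && !all(abs(rs - 1) < 1e-6))
    rel <- t(rel)  # features x samples input
  sqrt(rel)
}

#' Redundancy analysis
#'
#' @param Y community matrix, samples x features (already transformed,
#'   e.g. by [hellinger_transform()]). Centred internally.
#' @param X environmental matrix or data.frame, samples x variables;
#'   standardised internally. Rows with missing values are dropped from
#'   both matrices with a message.
#' @return object of class `rda_result`: eigenvalues (constrained and
#'   unconstrained), proportion of total variance per constrained axis,
#'   site scores (sample positions on constrained axes), species scores,
#'   biplot scores (correlations of variables with the constrained axes;
#'   scaling-2 style), rank, and totals.
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(data.frame(X, check.names = FALSE))
  if (nrow(Y) != nrow(X)) stop("Y and X need matching rows", call. = FALSE)
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    message("dropping ", sum(!ok), " sample(s) with missing constraints")
    Y <- Y[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]
  }
  n <- nrow(Y)
  if (n <= ncol(X) + 1L)
    stop("need n_samples > n_constraints + 1", call. = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X)
  if (any(!is.finite(Xs))) {
    const <- apply(X, 2L, function(v) var(v) == 0)
    stop("constant constraint column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs))
    warning("collinear constraints: rank ", qrX$rank, " < ", ncol(Xs),
            call. = FALSE)
  Yhat <- qr.fitted(qrX, Yc)
  sv <- svd(Yhat)
  pos <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[pos]
  eig <- d^2 / (n - 1)
  total <- sum(Yc^2) / (n - 1)
  resid <- Yc - Yhat
  sv_r <- svd(resid)
  eig_un <- (sv_r$d[sv_r$d > max(sv_r$d, 1e-300) * 1e-10])^2 / (n - 1)
  axes <- paste0("RDA", seq_along(eig))
  sites <- sv$u[, pos, drop = FALSE] %*% diag(d, length(d))
  dimnames(sites) <- list(rownames(Y), axes)
  species <- sv$v[, pos, drop = FALSE]
  dimnames(species) <- list(colnames(Y), axes)
  biplot <- cor(Xs, sites)
  colnames(biplot) <- axes
  structure(list(eig = setNames(eig, axes),
                 eig_unconstrained = eig_un,
                 proportion = setNames(eig / total, axes),
                 total_variance = total,
                 sites = sites, species = species, biplot = biplot,
                 rank = qrX$rank, n = n, X = Xs, Y = Yc),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "<rda_result> %d samples, %d constrained axes; constrained %.1f%% of total variance\n",
    x$n, length(x$eig), 100 * sum(x$proportion)))
  invisible(x)
}

#' Marginal permutation test for one constraint
#'
#' Tests a single environmental variable while keeping all others in the
#' model (marginal test). The variable's values are permuted across
#' samples; the pseudo-F compares the variance it explains on top of the
#' other constraints with the residual variance of the full model;
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param Y community matrix (samples x features, transformed).
#' @param X environmental matrix/data.frame.
#' @param variable column name of the variable to test.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return list: `pseudo_F`, `p_value`, `n_perm`, `n` (samples used).
#' @export
permutation_test <- function(Y, X, variable, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  X <- as.matrix(data.frame(X, check.names = FALSE))
  if (!variable %in% colnames(X))
    stop("unknown variable: ", variable, call. = FALSE)
  Y <- as.matrix(Y)
  ok <- stats::complete.cases(X)
  Y <- Y[ok, , drop = FALSE]; X <- X[ok, , drop = FALSE]
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X)
  j <- match(variable, colnames(X))
  others <- Xs[, -j, drop = FALSE]
  q_oth <- if (ncol(others)) qr(others) else NULL
  fit_ss <- function(v) {
    M <- cbind(others, v)
    qM <- qr(M)
    ss_full <- sum(qr.fitted(qM, Yc)^2)
    df2 <- n - qM$rank - 1L
    list(ss = ss_full, rank = qM$rank, df2 = df2)
  }
  ss_others <- if (is.null(q_oth)) 0 else sum(qr.fitted(q_oth, Yc)^2)
  rank_others <- if (is.null(q_oth)) 0L else q_oth$rank
  total <- sum(Yc^2)
  f_stat <- function(v) {
    f <- fit_ss(v)
    df1 <- max(1L, f$rank - rank_others)
    ((f$ss - ss_others) / df1) / ((total - f$ss) / f$df2)
  }
  F_obs <- f_stat(Xs[, j])
  F_perm <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) f_stat(Xs[sample.int(n), j]),
           numeric(1L))
  })
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  list(pseudo_F = F_obs, p_value = p, n_perm = as.integer(n_perm), n = n)
}

#' Marginal permutation tests for every constraint
#'
#' Convenience wrapper running [permutation_test()] per variable. Samples
#' missing the tested variable are dropped for that variable's test only.
#'
#' @inheritParams permutation_test
#' @param variables column names to test; default all columns of `X`.
#' @return data.frame: variable, pseudo_F, p_value, n, n_perm.
#' @export
rda_significance <- function(Y, X, variables = NULL, n_perm = 999L,
                             seed = 1L) {
  Xdf <- as.data.frame(X, check.names = FALSE)
  variables <- variables %||% names(Xdf)
  rows <- lapply(variables, function(v) {
    keep <- !is.na(Xdf[[v]])
    res <- permutation_test(as.matrix(Y)[keep, , drop = FALSE],
                            Xdf[keep, , drop = FALSE], v, n_perm,
                            derive_seed(seed, paste0("perm.", v)))
    data.frame(variable = v, pseudo_F = res$pseudo_F,
               p_value = res$p_value, n = res$n, n_perm = res$n_perm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
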
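## Sloan neutral community model. For a metacommunity taxon at mean
## relative abundance p, the local relative abundance in a community of
## N_T individuals with immigration probability m is Beta-distributed:
##
##   q ~ Beta(N_T*m*p, N_T*m*(1 - p))
##
## and the expected occurrence frequency above a detection limit d is
## P(q > d) = 1 - I_d(N_T*m*p, N_T*m*(1 - p)), with I the regularised
## incomplete beta function. Fitting m by least squares of observed
## occurrence frequencies on this curve yields the community-level
## immigration probability; 1 - m is the local-reproduction probability.

#' Observed occurrence frequency and mean relative abundance
#'
#' Occurrence frequency is the fraction of samples in the subset where the
#' OTU is detected (count >= 1); mean relative abundance is averaged over
#' the same samples.
#'
#' @param table an [otu_table()].
#' @param samples character vector of sample ids (non-empty subset of
#'   `colnames(table)`).
#' @return data.frame: `otu_id`, `freq_obs`, `p_mean`.
#' @export
observed_frequency <- function(table, samples = colnames(table)) {
  if (!length(samples)) stop("empty sample subset", call. = FALSE)
  bad <- setdiff(samples, colnames(table))
  if (length(bad))
    stop("unknown sample id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  sub <- unclass(table)[, samples, drop = FALSE]
  rel <- to_relative_abundance(sub)
  data.frame(otu_id = rownames(table),
             freq_obs = rowMeans(sub >= 1L),
             p_mean = rowMeans(rel),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Neutral-model predicted occurrence frequency
#'
#' @param p_mean mean relative abundance(s) in `[0, 1]`.
#' @param N_T reads (individuals) per local community, >= 1.
#' @param m immigration probability in `(0, 1]`.
#' @param d detection limit as relative abundance in `(0, 1)`; default one
#'   read, `1/N_T`.
#' @return predicted occurrence frequency in `[0, 1]`.
#' @export
predicted_frequency <- function(p_mean, N_T, m, d = 1 / N_T) {
  assert_scalar_number(N_T, "N_T", lower = 1)
  assert_scalar_number(m, "m", lower = .Machine$double.xmin, upper = 1)
  assert_scalar_number(d, "d", lower = .Machine$double.xmin, upper = 1 - 1e-12)
  if (any(p_mean < 0 | p_mean > 1))
    stop("p_mean must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(p_mean))
  interior <- p_mean > 0 & p_mean < 1
  out[interior] <- pbeta(d, N_T * m * p_mean[interior],
                         N_T * m * (1 - p_mean[interior]),
                         lower.tail = FALSE)
  out[p_mean == 0] <- 0  # degenerate Beta(0, a): all mass at 0
  out[p_mean == 1] <- 1  # degenerate Beta(a, 0): all mass at 1
  out
}

#' Fit the neutral-model immigration probability m
#'
#' Minimises the sum of squared differences between observed and predicted
#' occurrence frequencies over m in (1e-6, 1]. The objective has a single
#' bounded parameter, so Brent's method is used; the minimiser is the same
#' least-squares estimate a Levenberg-Marquardt fit of the same curve
#' returns, and the fit is deterministic.
#'
#' @param freq_obs,p_mean numeric vectors as from [observed_frequency()].
#' @param N_T reads per local community.
#' @param d detection limit (default `1/N_T`).
#' @return object of class `neutral_fit`: list with `m`, `r_squared`,
#'   `N_T`, `d`, `n_otus`, and a per-OTU data.frame `fit`
#'   (`p_mean`, `freq_obs`, `freq_pred`).
#' @export
fit_neutral_m <- function(freq_obs, p_mean, N_T, d = 1 / N_T) {
  stopifnot(length(freq_obs) == length(p_mean))
  keep <- is.finite(freq_obs) & is.finite(p_mean) & p_mean > 0
  fo <- freq_obs[keep]; pm <- p_mean[keep]
  n_inform <- sum(fo > 0 & fo < 1)
  if (n_inform < 10L)
    warning("only ", n_inform,
            " OTUs with 0 < freq_obs < 1; the fit may be poorly constrained",
            call. = FALSE)
  sse <- function(m) sum((fo - predicted_frequency(pm, N_T, m, d))^2)
  opt <- optimize(sse, interval = c(1e-6, 1), tol = 1e-10)
  m_hat <- opt$minimum
  pred <- predicted_frequency(pm, N_T, m_hat, d)
  sst <- sum((fo - mean(fo))^2)
  r2 <- if (sst > 0) 1 - opt$objective / sst else NA_real_
  structure(list(m = m_hat, r_squared = r2, N_T = N_T, d = d,
                 n_otus = length(fo),
                 fit = data.frame(p_mean = pm, freq_obs = fo,
                                  freq_pred = pred)),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf(
    "<neutral_fit> m = %.4f (local reproduction %.4f), R2 = %.3f, %d OTUs, N_T = %d\n",
    x$m, 1 - x$m, x$r_squared, x$n_otus, as.integer(x$N_T)))
  invisible(x)
}

#' Shared-taxon (Venn) summary between two communities
#'
#' Presence is >= 1 read in the community's pooled samples; the sequence
#' fraction is computed over the downstream community's pooled reads.
#'
#' @param upstream,downstream count matrices (or [otu_table()] column
#'   subsets); feature spaces are merged by row name (absent = 0).
#' @return list: `n_shared`, `n_unique_upstream`, `n_unique_downstream`,
#'   `shared_seq_fraction_downstream`.
#' @export
shared_taxa <- function(upstream, downstream) {
  up <- rowSums(as.matrix(unclass(upstream)))
  dn <- rowSums(as.matrix(unclass(downstream)))
  feats <- union(names(up), names(dn))
  u <- setNames(numeric(length(feats)), feats); u[names(up)] <- up
  v <- setNames(numeric(length(feats)), feats); v[names(dn)] <- dn
  pres_u <- u >= 1; pres_d <- v >= 1
  shared <- pres_u & pres_d
  frac <- if (sum(v) > 0) sum(v[shared]) / sum(v) else 0
  list(n_shared = sum(shared),
       n_unique_upstream = sum(pres_u & !pres_d),
       n_unique_downstream = sum(pres_d & !pres_u),
       shared_seq_fraction_downstream = frac)
}
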
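## Steady-state mass balance on one aeration tank + clarifier control
## volume. For population x with relative abundance p in each biomass
## stream, cell numbers are proxied by VSS mass times p (the unknown
## mass-per-cell factor cancels):
##
##   dN_x/dt = Q_in*X_in*p_in,x - Q_waste*X_waste*p_waste,x
##             - Q_eff*X_eff*p_eff,x + mu_x * V_AS*X_AS*p_AS,x
##
## At steady state (dN/dt = 0) with negligible clarifier-effluent biomass
## (Q_eff*X_eff ~ 0):
##
##   mu_x = (Q_waste*X_waste*p_waste,x - Q_in*X_in*p_in,x)
##          / (V_AS*X_AS*p_AS,x)        [d^-1]

.reactor_cols <- c("tank", "date", "V_AS_m3", "Q_in_m3d", "Q_waste_m3d",
                   "Q_eff_m3d", "X_AS_gL", "X_in_gL", "X_waste_gL",
                   "X_eff_gL")

#' Read a reactor specification table
#'
#' TSV with one row per tank-date and columns tank, date, V_AS_m3,
#' Q_in_m3d, Q_waste_m3d, Q_eff_m3d, X_AS_gL, X_in_gL, X_waste_gL,
#' X_eff_gL. Flow closure `Q_in = Q_waste + Q_eff` is validated to 1% and
#' violations are reported as warnings, not errors.
#'
#' @param path file path.
#' @return data.frame, one row per tank-date.
#' @export
read_reactor_spec <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_reactor_spec(df)
}

validate_reactor_spec <- function(df) {
  miss <- setdiff(.reactor_cols, names(df))
  if (length(miss))
    stop("reactor spec missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- setdiff(.reactor_cols, c("tank", "date"))
  for (p in num) {
    if (!is.numeric(df[[p]])) df[[p]] <- as.numeric(df[[p]])
    if (anyNA(df[[p]]) || any(df[[p]] < 0))
      stop("reactor spec column ", p, " must be non-negative", call. = FALSE)
  }
  closure <- abs(df$Q_in_m3d - (df$Q_waste_m3d + df$Q_eff_m3d)) /
    pmax(df$Q_in_m3d, .Machine$double.eps)
  if (any(closure > 0.01))
    warning(sum(closure > 0.01),
            " tank-date(s) violate flow closure Q_in = Q_waste + Q_eff by >1%",
            call. = FALSE)
  df
}

#' @rdname read_reactor_spec
#' @param spec reactor-spec data.frame.
#' @export
write_reactor_spec <- function(spec, path) {
  write.table(spec[, .reactor_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Per-OTU net growth rate for one tank-date
#'
#' Applies the steady-state mass balance (see package vignette) to one
#' tank-date. OTUs absent from the aeration tank (`p_AS = 0`) have an
#' undefined growth rate: `mu` is `NA` there and `washed_out` flags the
#' subset that nonetheless enters with the influent (`p_in > 0`).
#'
#' @param spec one-row reactor-spec data.frame for the tank-date.
#' @param p_in,p_AS,p_waste relative-abundance vectors over a shared
#'   feature index for the UASB effluent, aeration tank (replicate mean)
#'   and wasted sludge (clarifier underflow) streams.
#' @return list with `mu` (d^-1, NA where undefined), `washed_out`
#'   (logical), and the scalar fluxes used.
#' @export
net_growth_rate <- function(spec, p_in, p_AS, p_waste) {
  stopifnot(length(p_in) == length(p_AS), length(p_AS) == length(p_waste))
  V <- spec$V_AS_m3; X_AS <- spec$X_AS_gL
  if (V * X_AS == 0)
    stop("V_AS * X_AS is zero: control volume holds no biomass",
         call. = FALSE)
  influx <- spec$Q_in_m3d * spec$X_in_gL        # g/L * m3/d (common factor)
  outflux <- spec$Q_waste_m3d * spec$X_waste_gL
  inventory <- V * X_AS
  mu <- (outflux * p_waste - influx * p_in) / (inventory * p_AS)
  undef <- p_AS == 0
  mu[undef] <- NA_real_
  list(mu = mu,
       washed_out = undef & p_in > 0,
       influx = influx, outflux = outflux, inventory = inventory)
}

#' Steady-state screening for one tank-date
#'
#' Three checks mirroring the mass-balance assumptions: (1) stable TOC in
#' the aeration tank over the sampling window (population-SD coefficient of
#' variation below `cv_max`); (2) negligible clarifier biological activity
#' (relative TOC difference between aeration tank and clarifier below
#' `d_max`); (3) negligible clarifier-effluent biomass
#' (`X_eff / X_waste < r_max`).
#'
#' @param toc_series numeric, >= 3 TOC observations in the window (mg/L).
#' @param X_eff,X_waste effluent and wasted-sludge VSS (g/L).
#' @param toc_AS,toc_clarifier representative TOC in the aeration tank and
#'   clarifier (mg/L).
#' @param cv_max,r_max,d_max thresholds (defaults 0.15, 0.05, 0.15).
#' @return list with the three statistics and `passed`.
#' @export
steady_state_check <- function(toc_series, X_eff, X_waste, toc_AS,
                               toc_clarifier, cv_max = 0.15, r_max = 0.05,
                               d_max = 0.15) {
  if (length(toc_series) < 3L)
    stop("need >= 3 TOC observations for the steady-state window",
         call. = FALSE)
  toc_cv <- cv_pop(toc_series)
  tss_eff_ratio <- if (X_waste > 0) X_eff / X_waste else NA_real_
  clarifier_toc_delta <- abs(toc_AS - toc_clarifier) / abs(toc_AS)
  passed <- isTRUE(toc_cv < cv_max) && isTRUE(tss_eff_ratio < r_max) &&
    isTRUE(clarifier_toc_delta < d_max)
  list(toc_cv = toc_cv, tss_eff_ratio = tss_eff_ratio,
       clarifier_toc_delta = clarifier_toc_delta, passed = passed)
}

#' Classify a population as active or inactive
#'
#' Active means strictly positive mean net growth rate; `mu <= 0` is
#' inactive, and populations that enter with the influent but are never
#' detected in activated sludge (washed out, undefined `mu`) are inactive.
#'
#' @param mu_mean mean net growth rate (d^-1), `NA` if undefined.
#' @param washed_out logical, same length.
#' @return logical: `TRUE` for active.
#' @export
classify_activity <- function(mu_mean, washed_out = rep(FALSE, length(mu_mean))) {
  !is.na(mu_mean) & mu_mean > 0 & !washed_out
}

## Build the three stream-abundance vectors for one tank-event from the
## relative-abundance matrix and the metadata. p_AS is the arithmetic mean
## of the two replicate aeration-tank locations; p_waste is the clarifier
## underflow of the same tank and event.
stream_abundances <- function(rel, metadata, tank, event) {
  pick <- function(loc, tk) {
    ids <- metadata$sample_id[metadata$event == event &
                                metadata$location == loc &
                                (is.na(tk) | metadata$tank == tk)]
    ids[ids %in% colnames(rel)]
  }
  in_id <- pick("UASB_effluent", NA)
  as_id <- pick("aeration_tank", tank)
  wa_id <- pick("clarifier_underflow", tank)
  if (!length(in_id) || !length(as_id) || !length(wa_id))
    return(NULL)
  list(p_in = rowMeans(rel[, in_id, drop = FALSE]),
       p_AS = rowMeans(rel[, as_id, drop = FALSE]),
       p_waste = rowMeans(rel[, wa_id, drop = FALSE]))
}

#' Per-OTU growth rates across all tank-dates
#'
#' Runs the steady-state screen and the mass balance on every tank-event,
#' then averages per-OTU growth rates over the tank-dates where they are
#' defined ("calculated ... separately and averaged"). Screened-out
#' tank-dates are excluded and reported.
#'
#' @param table an [otu_table()] covering all locations (unrarefied counts;
#'   the mass balance uses proportions, so rarefaction only discards
#'   information here).
#' @param metadata sample metadata (see [read_sample_metadata()]).
#' @param reactor reactor-spec data.frame; rows are matched to tank-events
#'   by `tank` and `date` == event index.
#' @param cv_max,r_max,d_max steady-state thresholds, see
#'   [steady_state_check()].
#' @param enforce_steady_state drop tank-dates failing the screen
#'   (default). If `FALSE`, failures are kept with a warning.
#' @return object of class `growth_result`: data.frame with columns
#'   `otu_id`, `mu_mean` (d^-1), `n_tank_dates`, `active`,
#'   `mean_abundance_AS`, `washed_out`; attributes `mu_by_tank_date`
#'   (matrix), `screen` (per tank-date steady-state report) and
#'   `excluded` (character).
#' @export
growth_rates <- function(table, metadata, reactor, cv_max = 0.15,
                         r_max = 0.05, d_max = 0.15,
                         enforce_steady_state = TRUE) {
  rel <- to_relative_abundance(table)
  events <- sort(unique(metadata$event))
  tanks <- sort(unique(metadata$tank[metadata$location == "aeration_tank"]))
  mu_mat <- NULL; wo_mat <- NULL
  screen <- list(); excluded <- character()
  for (ev in events) for (tk in tanks) {
    sp <- reactor[reactor$tank == tk & reactor$date == ev, , drop = FALSE]
    if (!nrow(sp)) next
    ab <- stream_abundances(rel, metadata, tk, ev)
    if (is.null(ab)) next
    key <- paste0(tk, ".", ev)
    md_as <- metadata[metadata$event == ev & metadata$tank == tk, ]
    toc_as <- md_as$TOC[md_as$location == "aeration_tank"]
    toc_cl <- md_as$TOC[md_as$location == "clarifier_underflow"]
    chk <- steady_state_check(
      c(toc_as, toc_cl), sp$X_eff_gL[1L], sp$X_waste_gL[1L],
      mean(toc_as, na.rm = TRUE), mean(toc_cl, na.rm = TRUE),
      cv_max, r_max, d_max)
    screen[[key]] <- chk
    if (!chk$passed) {
      if (enforce_steady_state) {
        excluded <- c(excluded, key)
        next
      }
      warning("tank-date ", key, " failed steady-state screen; kept on request",
              call. = FALSE)
    }
    res <- net_growth_rate(sp[1L, ], ab$p_in, ab$p_AS, ab$p_waste)
    mu_mat <- cbind(mu_mat, res$mu)
    wo_mat <- cbind(wo_mat, res$washed_out)
    colnames(mu_mat)[ncol(mu_mat)] <- key
    colnames(wo_mat)[ncol(wo_mat)] <- key
  }
  if (is.null(mu_mat))
    stop("no tank-date passed the steady-state screen", call. = FALSE)
  rownames(mu_mat) <- rownames(rel)
  average_growth_rates(mu_mat, wo_mat, rel, metadata, screen, excluded)
}

#' Average per-tank-date growth rates into one result per OTU
#'
#' The mean is taken over the tank-dates where mu is defined; OTUs with no
#' defined value keep `mu_mean = NA`. `washed_out` marks OTUs that enter
#' with the influent on some tank-date but are never detected in activated
#' sludge there.
#'
#' @param mu_mat OTU x tank-date matrix of growth rates (NA = undefined).
#' @param wo_mat logical matrix of the same shape (washed-out flags).
#' @param rel relative-abundance matrix (for `mean_abundance_AS`).
#' @param metadata sample metadata.
#' @param screen,excluded bookkeeping from [growth_rates()].
#' @return see [growth_rates()].
#' @export
average_growth_rates <- function(mu_mat, wo_mat, rel, metadata,
                                 screen = list(), excluded = character()) {
  n_def <- rowSums(!is.na(mu_mat))
  mu_mean <- ifelse(n_def > 0, rowMeans(mu_mat, na.rm = TRUE), NA_real_)
  washed <- rowSums(wo_mat) > 0 & n_def == 0
  as_ids <- intersect(as_sample_ids(metadata), colnames(rel))
  mean_ab <- rowMeans(rel[, as_ids, drop = FALSE])
  out <- data.frame(
    otu_id = rownames(mu_mat),
    mu_mean = mu_mean,
    n_tank_dates = n_def,
    active = classify_activity(mu_mean, washed),
    mean_abundance_AS = mean_ab,
    washed_out = washed,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("growth_result", "data.frame"),
            mu_by_tank_date = mu_mat, screen = screen, excluded = excluded)
}

#' Summarise the active/inactive partition
#'
#' @param result a `growth_result` from [growth_rates()].
#' @param rel relative-abundance matrix of the activated-sludge samples
#'   used for the sequence fractions.
#' @return list: `n_active`, `n_inactive`, `n_washed_out`,
#'   `active_seq_fraction` (fraction of AS reads carried by active OTUs).
#' @export
active_community_summary <- function(result, rel) {
  stopifnot(inherits(result, "growth_result"))
  idx <- match(result$otu_id, rownames(rel))
  w <- rowMeans(rel)[idx]
  w[is.na(w)] <- 0
  frac <- if (sum(w) > 0) sum(w[result$active]) / sum(w) else 0
  list(n_active = sum(result$active),
       n_inactive = sum(!result$active),
       n_washed_out = sum(result$washed_out),
       active_seq_fraction = frac)
}

#' Write/read the growth-rate result table
#'
#' TSV with columns otu_id, mu_mean_per_day, n_tank_dates, active,
#' mean_abundance_AS, washed_out.
#'
#' @param result a `growth_result`.
#' @param path file path.
#' @return `path` (writer) or a data.frame (reader).
#' @export
write_growth_result <- function(result, path) {
  df <- as.data.frame(result)
  names(df)[names(df) == "mu_mean"] <- "mu_mean_per_day"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_result
#' @export
read_growth_result <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[names(df) == "mu_mean_per_day"] <- "mu_mean"
  df
}
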
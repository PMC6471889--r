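## Synthetic UASB -> activated-sludge system with known ground truth.
##
## World construction (one "world" per seed):
##   1. A log-normal source community seeds the UASB: obligate anaerobes
##      carry most of the effluent biomass, aerobes are carried through at
##      a small mass fraction.
##   2. Each anaerobe gets an intrinsic net growth rate mu < 0 (decay under
##      aeration); its steady-state aeration-tank proportion follows from
##      the mass balance: p_AS = b*p_in / (a - mu), with a = Q_w*X_w/(V*X_AS)
##      (= 1/SRT) and b = Q_in*X_in/(V*X_AS).
##   3. Aerobes share the remaining proportion via a floored Gaussian
##      temperature niche exp(-(T - T_opt)^2 / (2*sigma_T^2)), with
##      tank-specific batch factors; their realized mu is read back from
##      the same closed form and is strictly positive by construction.
##   4. Because every stream's proportions sum to one, the conservation
##      identity sum_x mu_x*V*X_AS*p_AS,x = Q_w*X_w - Q_in*X_in holds
##      exactly on the noiseless proportions of every tank-date.
##   5. Reads are sampled multinomially at the configured depth; washed-out
##      populations (p_AS = 0 in counts) arise through sampling, as in real
##      amplicon tables.

#' Simulation configuration
#'
#' Defaults state the emulated system: ~1200 taxa, 30% obligate
#' anaerobes, log-normal(0, 2) source abundances, reactor geometry
#' V = 5000 m3, Q_in = 1000 m3/d, Q_waste = 50 m3/d (SRT = 50 d),
#' X_AS = 4 g/L, X_in = 0.1 g/L, X_waste = 8 g/L, 18,578 reads/sample,
#' 6 sampling events x 3 parallel tanks x 2 aeration-tank replicates
#' (11 samples per event), temperature rising 10 -> 30 degC over events.
#'
#' @param ... overrides of the defaults listed above (see argument list).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_otus = 1200L, frac_obligate_anaerobe = 0.3,
                       source_meanlog = 0, source_sdlog = 2,
                       V_AS = 5000, Q_in = 1000, Q_waste = 50, Q_eff = 950,
                       X_AS = 4, X_in = 0.1, X_waste = 8, X_eff = 0.001,
                       depth = 18578L, n_events = 6L, n_tanks = 3L,
                       n_reps = 2L, temp_min = 10, temp_max = 30,
                       sigma_T = 6, niche_floor = 0.05,
                       mu_inactive_range = c(-0.3, -0.05),
                       active_read_fraction = NULL,
                       aerobe_source_frac = 0.05, tank_effect_sd = 0.15,
                       source_drift_sd = 0, replicate_noise_sd = 0.1,
                       inactive_patchiness_sd = 0.3,
                       inactive_load_sd = 2.5, active_event_noise_sd = 0.2,
                       m_neutral = 0.028,
                       toc_base = 80, toc_slope = -1.5, toc_event_sd = 8,
                       toc_sample_sd = 1.5,
                       do_mean = 2, do_sd = 0.5,
                       nh4_base = 0.3, nh4_slope = 0.02, nh4_event_sd = 0.08,
                       nh4_sample_sd = 0.03,
                       po4_base = 1, po4_slope = 0.03, po4_event_sd = 0.06,
                       po4_sample_sd = 0.03,
                       ta_mean = 0.05, ta_sd = 0.02,
                       temp_noise_sd = 0.2, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown sim_config field(s): ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  cfg <- as.list(environment())
  cfg$extra <- NULL
  stopifnot(cfg$n_otus >= 10, cfg$frac_obligate_anaerobe > 0,
            cfg$frac_obligate_anaerobe < 1, cfg$depth >= 100,
            cfg$n_events >= 1, cfg$n_tanks >= 1, cfg$n_reps >= 1,
            all(cfg$mu_inactive_range < 0),
            cfg$aerobe_source_frac > 0, cfg$aerobe_source_frac < 1)
  structure(cfg, class = "sim_config")
}

#' Simulate the full reactor system
#'
#' @param config a [sim_config()].
#' @param seed master seed; fixes the world (taxa, niches, growth rates)
#'   and the read sampling.
#' @param read_seed optional separate seed for the multinomial read
#'   sampling only, so replicate sequencing runs of the same world can be
#'   drawn.
#' @return list (class `sim_bundle`) with `otu` ([otu_table()]),
#'   `metadata`, `reactor`, and `truth`. `truth` holds the noiseless
#'   per-tank-date stream proportions (`p_in`, `p_AS`, `p_waste`), the
#'   true per-tank-date growth rates `mu` and their mean, the `active`
#'   labels, per-taxon `T_opt`, the source community, the mass-balance
#'   coefficients `a` and `b`, the realized active read fraction and the
#'   neutral `m` the config states.
#' @export
simulate_reactor_system <- function(config = sim_config(), seed = 1L,
                                    read_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  world <- with_seed(derive_seed(seed, "world"), build_world(cfg))
  reads <- with_seed(derive_seed(read_seed %||% seed, "reads"),
                     sample_reads(cfg, world))
  meta <- with_seed(derive_seed(seed, "env"), build_metadata(cfg, world))
  reactor <- build_reactor(cfg)
  structure(list(otu = reads, metadata = meta, reactor = reactor,
                 truth = world$truth, config = cfg),
            class = "sim_bundle")
}

build_world <- function(cfg) {
  n <- cfg$n_otus
  n_an <- round(n * cfg$frac_obligate_anaerobe)
  n_ae <- n - n_an
  ids <- sprintf("OTU_%04d", seq_len(n))
  anaerobe <- c(rep(TRUE, n_an), rep(FALSE, n_ae))

  s_an <- rlnorm(n_an, cfg$source_meanlog, cfg$source_sdlog)
  s_ae <- rlnorm(n_ae, cfg$source_meanlog, cfg$source_sdlog)
  temps <- if (cfg$n_events == 1L) mean(c(cfg$temp_min, cfg$temp_max)) else
    seq(cfg$temp_min, cfg$temp_max, length.out = cfg$n_events)
  tanks <- LETTERS[seq_len(cfg$n_tanks)]
  keys <- as.vector(outer(tanks, seq_len(cfg$n_events), paste, sep = "."))

  # upstream community drifts between sampling events (month-scale
  # variation of the full-scale UASB community)
  p_in <- matrix(0, n, cfg$n_events, dimnames = list(ids, NULL))
  for (e in seq_len(cfg$n_events)) {
    wa <- s_an * rlnorm(n_an, 0, cfg$source_drift_sd)
    we <- s_ae * rlnorm(n_ae, 0, cfg$source_drift_sd)
    p_in[anaerobe, e] <- (1 - cfg$aerobe_source_frac) * wa / sum(wa)
    p_in[!anaerobe, e] <- cfg$aerobe_source_frac * we / sum(we)
  }

  a <- cfg$Q_waste * cfg$X_waste / (cfg$V_AS * cfg$X_AS)  # 1/SRT, d^-1
  b <- cfg$Q_in * cfg$X_in / (cfg$V_AS * cfg$X_AS)
  mu_inact <- runif(n_an, min(cfg$mu_inactive_range),
                    max(cfg$mu_inactive_range))

  T_opt <- runif(n_ae, cfg$temp_min - 5, cfg$temp_max + 5)
  eps <- matrix(rlnorm(cfg$n_tanks * n_ae, 0, cfg$tank_effect_sd),
                cfg$n_tanks, n_ae)

  p_AS <- matrix(0, n, length(keys), dimnames = list(ids, keys))
  for (e in seq_len(cfg$n_events)) {
    # quasi-steady state on each sampling date: inactive proportions
    # follow the balance for that date's influent composition
    p_as_inact <- b * p_in[anaerobe, e] / (a - mu_inact)
    if (!is.null(cfg$active_read_fraction))
      p_as_inact <- p_as_inact * (1 - cfg$active_read_fraction) /
        sum(p_as_inact)
    f_act <- 1 - sum(p_as_inact)
    if (f_act <= 0 || any(p_as_inact < 0))
      stop("simulation config yields non-positive active proportion ",
           "(sum of inactive AS proportions = ", format(sum(p_as_inact)),
           " at event ", e, "); loosen mu_inactive_range or flows",
           call. = FALSE)
    niche <- cfg$niche_floor + (1 - cfg$niche_floor) *
      exp(-(temps[e] - T_opt)^2 / (2 * cfg$sigma_T^2))
    for (tk in seq_len(cfg$n_tanks)) {
      # unmeasured drivers (loading, micronutrients) perturb the active
      # community beyond its temperature response
      w <- s_ae * niche * eps[tk, ] *
        rlnorm(n_ae, 0, cfg$active_event_noise_sd)
      col <- paste0(tanks[tk], ".", e)
      p_AS[anaerobe, col] <- p_as_inact
      p_AS[!anaerobe, col] <- f_act * w / sum(w)
    }
  }
  # closed form on noiseless proportions, per tank-date
  mu <- matrix(NA_real_, n, length(keys), dimnames = list(ids, keys))
  for (e in seq_len(cfg$n_events)) for (tk in tanks) {
    col <- paste0(tk, ".", e)
    mu[, col] <- a - b * p_in[, e] / p_AS[, col]
  }
  inact_share <- colSums(p_AS[anaerobe, , drop = FALSE])
  truth <- list(
    otu_ids = ids,
    anaerobe = anaerobe,
    source_p = setNames(rowMeans(p_in), ids),
    p_in = p_in,
    p_AS = p_AS,
    p_waste = p_AS,  # clarifier underflow mirrors tank composition
    mu = mu,
    mu_mean = rowMeans(mu),
    active = unname(rowMeans(mu) > 0),
    T_opt = setNames(c(rep(NA_real_, sum(anaerobe)), T_opt), ids),
    a = a, b = b,
    active_read_fraction = 1 - mean(inact_share),
    m_neutral = cfg$m_neutral,
    temperatures = temps,
    tanks = tanks)
  list(truth = truth, temps = temps, tanks = tanks)
}

sample_ids_for <- function(cfg) {
  tanks <- LETTERS[seq_len(cfg$n_tanks)]
  out <- character(0)
  for (e in seq_len(cfg$n_events)) {
    out <- c(out, sprintf("E%d.UASB.bed", e), sprintf("E%d.UASB.eff", e))
    for (tk in tanks)
      out <- c(out,
               sprintf("E%d.%s.AS%d", e, tk, seq_len(cfg$n_reps)),
               sprintf("E%d.%s.CU", e, tk))
  }
  out
}

sample_reads <- function(cfg, world) {
  truth <- world$truth
  ids <- sample_ids_for(cfg)
  counts <- matrix(0L, length(truth$otu_ids), length(ids),
                   dimnames = list(truth$otu_ids, ids))
  # per-sample within-reactor heterogeneity (grab-sample composition
  # jitter) on top of multinomial read sampling
  # grab-sample heterogeneity: active flocs are well mixed, immigrant
  # particulate biomass is patchy, so inactive taxa get a wider
  # per-sample jitter
  jitter_sd <- ifelse(truth$anaerobe, cfg$inactive_patchiness_sd,
                      cfg$replicate_noise_sd)
  draw <- function(p, granular = FALSE) {
    if (any(jitter_sd > 0)) {
      p <- p * rlnorm(length(p), 0, jitter_sd)
      # immigrant biomass travels as granule debris; an instantaneous grab
      # from the turbulent aeration basin catches a heavy-tailed clump
      # load (mean-one), while the settled underflow and the effluent
      # stream integrate over hours and are not affected
      if (granular && cfg$inactive_load_sd > 0)
        p[truth$anaerobe] <- p[truth$anaerobe] *
          rlnorm(1L, -cfg$inactive_load_sd^2 / 2, cfg$inactive_load_sd)
      p <- p / sum(p)
    }
    as.integer(rmultinom(1L, cfg$depth, p))
  }
  for (e in seq_len(cfg$n_events)) {
    counts[, sprintf("E%d.UASB.bed", e)] <- draw(truth$p_in[, e])
    counts[, sprintf("E%d.UASB.eff", e)] <- draw(truth$p_in[, e])
    for (tk in world$tanks) {
      key <- paste0(tk, ".", e)
      for (r in seq_len(cfg$n_reps))
        counts[, sprintf("E%d.%s.AS%d", e, tk, r)] <- draw(truth$p_AS[, key], granular = TRUE)
      counts[, sprintf("E%d.%s.CU", e, tk)] <- draw(truth$p_waste[, key])
    }
  }
  otu_table(counts)
}

build_metadata <- function(cfg, world) {
  ids <- sample_ids_for(cfg)
  temps <- world$temps
  rows <- lapply(ids, function(id) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
    e <- as.integer(sub("^E", "", parts[1L]))
    te <- temps[e]
    if (parts[2L] == "UASB") {
      loc <- if (parts[3L] == "bed") "UASB_bed" else "UASB_effluent"
      tank <- "none"
    } else {
      tank <- parts[2L]
      loc <- if (parts[3L] == "CU") "clarifier_underflow" else "aeration_tank"
    }
    data.frame(sample_id = id, event = e, location = loc, tank = tank,
               temperature = te + rnorm(1L, 0, cfg$temp_noise_sd),
               stringsAsFactors = FALSE)
  })
  md <- do.call(rbind, rows)
  te <- md$temperature
  uasb <- md$location %in% c("UASB_bed", "UASB_effluent")
  cu <- md$location == "clarifier_underflow"
  # loading varies between sampling dates (event-level), tanks are well
  # mixed within a date (small sample-level spread)
  ev_noise <- function(sd) rnorm(cfg$n_events, 0, sd)[md$event]
  toc_proc <- cfg$toc_base + cfg$toc_slope * (te - 20) +
    ev_noise(cfg$toc_event_sd) + rnorm(nrow(md), 0, cfg$toc_sample_sd)
  md$TOC <- ifelse(uasb, 300 + rnorm(nrow(md), 0, 20), toc_proc)
  # clarifier TOC tracks its tank's aeration TOC (negligible activity)
  for (i in which(cu)) {
    mates <- md$event == md$event[i] & md$tank == md$tank[i] &
      md$location == "aeration_tank"
    md$TOC[i] <- mean(md$TOC[mates]) + rnorm(1L, 0, 0.5)
  }
  md$DO <- pmax(0.05, ifelse(uasb, 0.05,
                             ifelse(cu, rnorm(nrow(md), 0.5, 0.1),
                                    rnorm(nrow(md), cfg$do_mean, cfg$do_sd))))
  md$NH4 <- pmax(0.01, cfg$nh4_base + cfg$nh4_slope * (te - 10) +
                   ev_noise(cfg$nh4_event_sd) +
                   rnorm(nrow(md), 0, cfg$nh4_sample_sd))
  md$PO4 <- pmax(0.01, cfg$po4_base + cfg$po4_slope * (te - 10) +
                   ev_noise(cfg$po4_event_sd) +
                   rnorm(nrow(md), 0, cfg$po4_sample_sd))
  md$PO4[cu] <- NA_real_  # unavailable at one third of locations
  md$TA <- pmax(0.001, rnorm(nrow(md), cfg$ta_mean, cfg$ta_sd))
  md
}

build_reactor <- function(cfg) {
  grid <- expand.grid(tank = LETTERS[seq_len(cfg$n_tanks)],
                      date = seq_len(cfg$n_events),
                      stringsAsFactors = FALSE)
  data.frame(grid,
             V_AS_m3 = cfg$V_AS, Q_in_m3d = cfg$Q_in,
             Q_waste_m3d = cfg$Q_waste, Q_eff_m3d = cfg$Q_eff,
             X_AS_gL = cfg$X_AS, X_in_gL = cfg$X_in,
             X_waste_gL = cfg$X_waste, X_eff_gL = cfg$X_eff,
             stringsAsFactors = FALSE)
}

#' Simulate local communities under the Sloan neutral model
#'
#' Each local community draws every taxon's relative abundance from
#' `Beta(N_T*m*p, N_T*m*(1-p))`, renormalises, and samples `N_T` reads
#' multinomially (beta-binomial marginal per taxon).
#'
#' @param p source (metacommunity) relative abundances, summing to 1.
#' @param N_T reads per local community.
#' @param m immigration probability in (0, 1].
#' @param n_samples number of local communities.
#' @param seed RNG seed.
#' @return an [otu_table()] (`n_samples` columns).
#' @export
simulate_neutral_metacommunity <- function(p, N_T, m, n_samples,
                                           seed = 1L) {
  stopifnot(abs(sum(p) - 1) < 1e-6, m > 0, m <= 1, N_T >= 1)
  ids <- names(p) %||% sprintf("OTU_%04d", seq_along(p))
  counts <- with_seed(seed, {
    out <- matrix(0L, length(p), n_samples)
    for (j in seq_len(n_samples)) {
      q <- numeric(length(p))
      pos <- p > 0 & p < 1
      q[pos] <- rbeta(sum(pos), N_T * m * p[pos], N_T * m * (1 - p[pos]))
      q[p >= 1] <- 1
      if (sum(q) == 0) q[which.max(p)] <- 1
      out[, j] <- as.integer(rmultinom(1L, N_T, q / sum(q)))
    }
    out
  })
  otu_table(counts, ids, sprintf("S%03d", seq_len(n_samples)))
}

#' Write a simulation bundle to disk
#'
#' Emits `otu_table.tsv`, `metadata.tsv`, `reactor.tsv`,
#' `ground_truth.tsv` (otu_id, anaerobe, active, mu_mean, T_opt,
#' source_p) and `config.json`. Output is byte-identical across runs with
#' the same seed.
#'
#' @param bundle a `sim_bundle` from [simulate_reactor_system()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(bundle$otu, file.path(dir, "otu_table.tsv"))
  write_sample_metadata(format_metadata(bundle$metadata),
                        file.path(dir, "metadata.tsv"))
  write_reactor_spec(bundle$reactor, file.path(dir, "reactor.tsv"))
  tr <- bundle$truth
  gt <- data.frame(otu_id = tr$otu_ids, anaerobe = tr$anaerobe,
                   active = tr$active,
                   mu_mean = sprintf("%.10g", tr$mu_mean),
                   T_opt = sprintf("%.6g", tr$T_opt),
                   source_p = sprintf("%.10g", tr$source_p),
                   stringsAsFactors = FALSE)
  write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

## Round environmental values for stable text output (measurement-scale
## precision; keeps fixture files byte-identical across platforms).
format_metadata <- function(md) {
  for (p in intersect(.env_params, names(md)))
    md[[p]] <- round(md[[p]], 6)
  md
}
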
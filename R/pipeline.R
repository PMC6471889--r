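## End-to-end orchestration: simulate? -> growth -> neutral -> overlap ->
## regression -> RDA -> machine-readable report. Each stage writes into
## its own subdirectory of `out_dir`; the report records a digest of every
## file so identical config + seed gives identical digests (no timestamps
## are written anywhere).

#' Default pipeline configuration
#'
#' @param simulate `TRUE` to generate inputs with the bundled generator
#'   (using `sim` overrides), or `FALSE` to read `otu_table`, `metadata`
#'   and `reactor` file paths.
#' @param sim named list of [sim_config()] overrides.
#' @param otu_table,metadata,reactor input paths (when `simulate = FALSE`).
#' @param depth rarefaction depth for occurrence-based analyses (neutral
#'   model, overlap); `NULL` uses the smallest sample total.
#' @param params environmental parameters to regress.
#' @param train_fraction,repeats regression settings ([regress_parameter()],
#'   [prediction_intervals()]).
#' @param permutations RDA permutation count.
#' @param rda_vars variables entering the RDA (missing-heavy variables are
#'   dropped per-test, not listed here).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(),
                            otu_table = NULL, metadata = NULL,
                            reactor = NULL, depth = NULL,
                            params = c("temperature", "TOC", "DO", "NH4",
                                       "PO4", "TA"),
                            train_fraction = 0.8, repeats = 100L,
                            permutations = 999L,
                            rda_vars = c("temperature", "TOC", "DO", "NH4",
                                         "TA"),
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!isTRUE(cfg$simulate)) {
    miss <- c("otu_table", "metadata", "reactor")[vapply(
      list(otu_table, metadata, reactor), is.null, logical(1L))]
    if (length(miss))
      stop("pipeline config error: simulate = FALSE but missing input(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields mirror [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages run in order simulate -> growth -> neutral -> overlap ->
#' regression -> rda -> report; a stage failure halts the run with a
#' diagnostic naming the stage. Identical config + seed reproduces every
#' stage output byte-for-byte.
#'
#' @param config a `pipeline_config` (or path to its JSON file).
#' @param out_dir output directory.
#' @return the pipeline report (list), invisibly written to
#'   `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  report <- list(tool = "growthseq",
                 version = as.character(utils::packageVersion("growthseq")),
                 seed = seed, stages = list())
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    report$stages[[name]] <<- c(list(status = "ok"), res$summary)
    res$value
  }

  inputs <- stage("inputs", {
    if (isTRUE(config$simulate)) {
      sc <- do.call(sim_config, as.list(config$sim))
      bundle <- simulate_reactor_system(sc, seed = derive_seed(seed, "sim"))
      d <- file.path(out_dir, "simulate")
      write_fixture(bundle, d)
      list(value = bundle,
           summary = list(n_otus = nrow(bundle$otu),
                          n_samples = ncol(bundle$otu), dir = "simulate"))
    } else {
      bundle <- list(otu = read_otu_table(config$otu_table),
                     metadata = read_sample_metadata(config$metadata),
                     reactor = read_reactor_spec(config$reactor),
                     truth = NULL)
      list(value = bundle,
           summary = list(n_otus = nrow(bundle$otu),
                          n_samples = ncol(bundle$otu)))
    }
  })
  otu <- inputs$otu; md <- inputs$metadata; reactor <- inputs$reactor

  growth <- stage("growth", {
    g <- growth_rates(otu, md, reactor)
    dir.create(file.path(out_dir, "growth"), showWarnings = FALSE)
    write_growth_result(g, file.path(out_dir, "growth", "growth_rates.tsv"))
    rel_as <- to_relative_abundance(
      unclass(otu)[, intersect(as_sample_ids(md), colnames(otu)),
                   drop = FALSE])
    s <- active_community_summary(g, rel_as)
    list(value = g, summary = s)
  })

  as_ids <- intersect(as_sample_ids(md), colnames(otu))
  depth <- config$depth %||% min(colSums(unclass(otu)[, as_ids, drop = FALSE]))
  rare <- stage("rarefy", {
    r <- rarefy(otu, depth, seed = derive_seed(seed, "rarefy"))
    list(value = r, summary = list(depth = depth,
                                   n_samples = ncol(r)))
  })

  neutral <- stage("neutral", {
    ids <- intersect(as_ids, colnames(rare))
    obs <- observed_frequency(rare, ids)
    fit <- fit_neutral_m(obs$freq_obs, obs$p_mean, N_T = depth)
    dir.create(file.path(out_dir, "neutral"), showWarnings = FALSE)
    write.table(cbind(otu_id = obs$otu_id[obs$p_mean > 0], fit$fit),
                file.path(out_dir, "neutral", "neutral_fit.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(m = fit$m, r_squared = fit$r_squared, N_T = fit$N_T,
           d = fit$d, n_otus = fit$n_otus),
      file.path(out_dir, "neutral", "neutral_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(value = fit,
         summary = list(m = fit$m, r_squared = fit$r_squared))
  })

  overlap <- stage("overlap", {
    up_ids <- intersect(
      md$sample_id[md$location %in% c("UASB_bed", "UASB_effluent")],
      colnames(rare))
    ov <- shared_taxa(unclass(rare)[, up_ids, drop = FALSE],
                      unclass(rare)[, intersect(as_ids, colnames(rare)),
                                    drop = FALSE])
    list(value = ov, summary = ov)
  })

  regression <- stage("regression", {
    dir.create(file.path(out_dir, "regression"), showWarnings = FALSE)
    entire <- list(); active <- list()
    for (p in config$params) {
      entire[[p]] <- regress_parameter(otu, md, p, "entire",
                                       train_fraction = config$train_fraction,
                                       seed = derive_seed(seed, "regress"))
      active[[p]] <- regress_parameter(otu, md, p, "active", growth = growth,
                                       train_fraction = config$train_fraction,
                                       seed = derive_seed(seed, "regress"))
      ci <- prediction_intervals(active[[p]],
                                 n_repeats = config$repeats,
                                 seed = derive_seed(seed, paste0("ci.", p)))
      ci$observed <- round(ci$observed, 8)
      ci$predicted <- round(ci$predicted, 8)
      ci$ci_low <- round(ci$ci_low, 8); ci$ci_high <- round(ci$ci_high, 8)
      write.table(ci, file.path(out_dir, "regression",
                                paste0(p, "_predictions.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    comp <- compare_feature_sets(entire, active)
    num <- vapply(comp, is.numeric, logical(1L))
    comp[num] <- lapply(comp[num], round, 8)
    write.table(comp, file.path(out_dir, "regression", "comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(entire = entire, active = active, comparison = comp),
         summary = list(parameters = config$params,
                        mse_ratio = setNames(comp$mse_ratio,
                                             comp$parameter)))
  })

  rda <- stage("rda", {
    ids <- intersect(as_ids, colnames(otu))
    rel <- to_relative_abundance(unclass(otu)[, ids, drop = FALSE])
    act <- growth$otu_id[growth$active]
    rel <- rel[rownames(rel) %in% act, , drop = FALSE]
    tot <- colSums(rel); tot[tot == 0] <- 1
    rel <- sweep(rel, 2L, tot, "/")
    Y <- hellinger_transform(t(rel))
    Xdf <- md[match(ids, md$sample_id), config$rda_vars, drop = FALSE]
    rownames(Xdf) <- ids
    fit <- rda_fit(Y, Xdf)
    sig <- rda_significance(Y, Xdf, n_perm = config$permutations,
                            seed = derive_seed(seed, "rda"))
    dir.create(file.path(out_dir, "rda"), showWarnings = FALSE)
    for (nm in c("sites", "species", "biplot")) {
      m <- round(fit[[nm]], 8)
      write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                  file.path(out_dir, "rda", paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      list(eigenvalues = unname(fit$eig),
           proportion = unname(fit$proportion),
           tests = sig),
      file.path(out_dir, "rda", "significance.json"),
      auto_unbox = TRUE, digits = 8, dataframe = "rows")
    list(value = list(fit = fit, significance = sig),
         summary = list(p_values = setNames(sig$p_value, sig$variable),
                        constrained_proportion = sum(fit$proportion)))
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "report.json"]
  report$files <- as.list(setNames(unname(tools::md5sum(files)),
                                   sub(paste0("^", out_dir, "/?"), "", files)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
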
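#' Load a pipeline run configuration
#'
#' Reads a YAML run configuration and fills defaults. The configuration is
#' round-trippable: loading the result of [save_run_config()] reproduces the
#' same list.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return A validated config list of class `fc_run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    input = list(mode = "synthetic"),
    parcellation = "default",
    parcellation_nodes = 90,
    preprocess = list(drop_volumes = 10, detrend = TRUE, bandpass = TRUE,
                      low_hz = 0.01, high_hz = 0.08),
    transforms = list(integrity = "exp_shift", network = "fisher_z"),
    stats = list(covariates = c("age", "sex", "education"),
                 B = 1000, q = 0.05, scheme = "freedman_lane"),
    levels = c("integrity", "network", "edge"),
    clinical = list(enabled = TRUE,
                    scales = c("updrs3", "mmse", "moca", "hama", "hamd")),
    seed = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$input$mode %in% c("synthetic", "roi_tables", "nifti")) {
    abort("input$mode must be one of synthetic, roi_tables, nifti.")
  }
  needs_seed <- cfg$input$mode == "synthetic" || cfg$stats$B > 0
  if (needs_seed && is.null(cfg$seed)) {
    abort("A seed is mandatory whenever simulation or permutation is requested.")
  }
  class(cfg) <- c("fc_run_config", class(cfg))
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg Config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

load_cohort_from_config <- function(cfg, parc) {
  mode <- cfg$input$mode
  if (mode == "synthetic") {
    sp <- cfg$input$spec %||% list()
    spec <- do.call(cohort_spec, sp)
    return(simulate_cohort(spec, parc, seed = cfg$seed))
  }
  ph <- readr::read_tsv(cfg$input$phenotypes, show_col_types = FALSE,
                        progress = FALSE)
  pp <- cfg$preprocess
  ts_list <- purrr::map(seq_len(nrow(ph)), function(i) {
    sid <- ph$subject_id[i]
    raw <- if (mode == "roi_tables") {
      read_roi_table(cfg$input$roi_tables[[i]], subject_id = sid,
                     tr = cfg$input$tr)
    } else {
      extract_roi_timeseries(cfg$input$volumes[[i]], cfg$input$labels,
                             parc, subject_id = sid, tr = cfg$input$tr)
    }
    clean_timeseries(raw, drop_volumes = pp$drop_volumes,
                     detrend = pp$detrend, bandpass = pp$bandpass,
                     low_hz = pp$low_hz, high_hz = pp$high_hz)
  })
  fc_cohort(ts_list, ph)
}

#' Run the full three-level connectivity analysis
#'
#' Orchestrates atlas loading, input acquisition (synthetic simulation, ROI
#' tables, or NIfTI extraction plus preprocessing), feature-table
#' construction, per-level covariate-adjusted contrasts with Freedman-Lane
#' permutation and BH-FDR, and exploratory clinical regressions on the
#' features flagged significant at the network level. Rerunning with the
#' same configuration and seed reproduces every output bit-identically.
#'
#' @param config An `fc_run_config`, a config list, or a YAML path (see
#'   [load_run_config()]).
#' @param out_dir Optional output directory; when given, per-level result
#'   TSVs, the regression TSV, the cohort summary and a JSON run manifest
#'   are written there.
#' @return An object of class `fc_analysis`: list with `contrasts` (named
#'   list of `fc_contrast` per level), `clinical` (`fc_clinreg` or `NULL`),
#'   `cohort_summary`, `features`, `phenotypes`, `config`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_run_config(config)
  t0 <- Sys.time()
  parc <- if (identical(cfg$parcellation, "default")) aal90_parcellation()
          else load_parcellation(cfg$parcellation,
                                 n_nodes = cfg$parcellation_nodes)
  cohort <- load_cohort_from_config(cfg, parc)
  timing <- list(setup = as.numeric(Sys.time() - t0, units = "secs"))

  t1 <- Sys.time()
  feats <- build_feature_tables(cohort, parc,
                                integrity_conversion = cfg$transforms$integrity,
                                network_transform = cfg$transforms$network)
  timing$features <- as.numeric(Sys.time() - t1, units = "secs")

  contrasts <- list()
  for (lv in cfg$levels) {
    t2 <- Sys.time()
    contrasts[[lv]] <- fc_level_analysis(
      feats[[lv]], cohort$phenotypes, level = lv,
      covariates = cfg$stats$covariates, B = cfg$stats$B,
      seed = cfg$seed, q = cfg$stats$q, scheme = cfg$stats$scheme)
    timing[[paste0("stats_", lv)]] <- as.numeric(Sys.time() - t2, units = "secs")
  }

  clinical <- NULL
  if (isTRUE(cfg$clinical$enabled) && "network" %in% names(contrasts)) {
    sig <- contrasts$network$feature[contrasts$network$significant]
    if (length(sig) > 0) {
      clinical <- clinical_regression(
        feats$network, cohort$phenotypes, scales = cfg$clinical$scales,
        features = sig, covariates = cfg$stats$covariates)
    }
  }
  summary_vars <- intersect(c("age", "education", "duration_months", "hy_stage",
                              "updrs3", "mmse", "moca", "hama", "hamd"),
                            names(cohort$phenotypes))
  cohort_summary <- describe_cohort(cohort$phenotypes, variables = summary_vars)

  manifest <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    n_subjects = as.list(table(cohort$phenotypes$group)),
    feature_counts = as.list(attr(feats, "meta")$feature_counts[cfg$levels]),
    B = cfg$stats$B, q = cfg$stats$q, scheme = cfg$stats$scheme,
    timing_s = lapply(timing, function(x) round(x, 3)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("rsfcnet")))

  res <- structure(list(contrasts = contrasts, clinical = clinical,
                        cohort_summary = cohort_summary, features = feats,
                        phenotypes = cohort$phenotypes, config = cfg,
                        manifest = manifest),
                   class = "fc_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

format_result_tsv <- function(tbl) {
  dplyr::mutate(tbl, dplyr::across(dplyr::where(is.numeric),
                                   ~ formatC(.x, digits = 10, format = "g")))
}

#' Write an analysis result bundle to disk
#'
#' Writes per-level contrast TSVs, the clinical-regression TSV, the cohort
#' summary TSV, and `manifest.json`. Numeric columns are formatted with a
#' fixed rule so identical analyses produce byte-identical files.
#'
#' @param res An `fc_analysis`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (lv in names(res$contrasts)) {
    readr::write_tsv(format_result_tsv(as_tibble(res$contrasts[[lv]])),
                     file.path(out_dir, paste0(lv, "_contrast.tsv")),
                     progress = FALSE)
  }
  if (!is.null(res$clinical)) {
    readr::write_tsv(format_result_tsv(as_tibble(res$clinical)),
                     file.path(out_dir, "clinical_regression.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(format_result_tsv(res$cohort_summary),
                   file.path(out_dir, "cohort_summary.tsv"), progress = FALSE)
  # timings vary between runs; manifest determinism covers everything else
  manifest <- res$manifest
  manifest$timing_s <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.fc_analysis <- function(x, ...) {
  cat("<fc_analysis>\n")
  grp <- x$manifest$n_subjects
  cat("  subjects:", paste(names(grp), unlist(grp), sep = " = ", collapse = ", "), "\n")
  for (lv in names(x$contrasts)) {
    ct <- x$contrasts[[lv]]
    cat(sprintf("  %s level: %d features, %d significant (q <= %g, B = %d)\n",
                lv, nrow(ct), sum(ct$significant, na.rm = TRUE),
                attr(ct, "q"), attr(ct, "B")))
  }
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical regressions: %d (feature, scale) pairs, %d at p < 0.05 (uncorrected)\n",
                nrow(x$clinical), sum(x$clinical$p < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}
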
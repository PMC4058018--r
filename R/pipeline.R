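#' Read and validate a run configuration
#'
#' The configuration is a YAML file with the sections `paths` (`slides`:
#' named list of sample id -> slide directory; `manifest`: sample manifest
#' CSV; `output`: output directory), `count` (any [count_config()]
#' argument), `enumeration` (`cells_per_slide`, `blood_volume_ml`
#' fallbacks), `cohort` (`patients`, `healthy` CSV paths, `dichotomy`
#' cut-off for the log-rank split) and the top-level keys `seed` and
#' `log_level`. Unknown keys at any validated level are rejected.
#'
#' @param path YAML config file, or a list with the same structure.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    yaml::read_yaml(path)
  } else path
  known <- c("paths", "count", "enumeration", "cohort", "seed", "log_level")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  count_args <- cfg$count %||% list()
  unknown <- setdiff(names(count_args), names(formals(count_config)))
  if (length(unknown))
    stopf("unknown count config keys: %s", paste(unknown, collapse = ", "))
  cfg$count <- do.call(count_config, count_args)
  cfg$enumeration <- modifyList(list(cells_per_slide = 5e4,
                                     blood_volume_ml = 10),
                                cfg$enumeration %||% list())
  cfg$cohort <- modifyList(list(patients = NULL, healthy = NULL,
                                dichotomy = 100),
                           cfg$cohort %||% list())
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$log_level <- cfg$log_level %||% "info"
  structure(cfg, class = "run_config")
}

.log_msg <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  message(sprintf(fmt, ...))
}

# provenance block: config hash (md5 of its canonical YAML), seed, version
.provenance <- function(cfg, out_dir) {
  cfg_file <- file.path(out_dir, "config_used.yml")
  plain <- unclass(cfg)
  plain$count <- unclass(plain$count)
  yaml::write_yaml(plain, cfg_file)
  list(config_md5 = unname(tools::md5sum(cfg_file)),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("cmcount")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the counting pipeline over the slides of a manifest
#'
#' For every manifest sample with a `slide_dir`, reads the slide, counts it
#' ([count_slide()]), extrapolates to CMCs per mL ([per_ml()]) and writes
#' per-object and per-sample CSVs, per-FOV overlay PNGs and a provenance
#' JSON (config hash, seed, package version). Thresholds actually used are
#' logged per slide.
#'
#' @param config a `run_config` (or path to one; see [read_run_config()]).
#' @return data.frame of per-sample results, invisibly; files are written
#'   under `config$paths$output`.
#' @export
run_count <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$paths$manifest))
    stopf("config$paths$manifest is required for run_count")
  man <- read_manifest(cfg$paths$manifest)
  if (!"slide_dir" %in% names(man))
    stopf("manifest must carry a slide_dir column for run_count")
  out_dir <- cfg$paths$output %||% "cmcount_output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- vector("list", nrow(man))
  all_cells <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sid <- man$sample_id[i]
    slide <- read_slide(man$slide_dir[i])
    sc <- count_slide(slide, cfg$count,
                      overlay_dir = file.path(out_dir, "overlays", sid))
    .log_msg(cfg, "[%s] thresholds: t_red=%.1f t_green=%.1f (%s); CMC=%d",
             sid, sc$thresholds$t_red, sc$thresholds$t_green,
             sc$thresholds$mode, sc$tally[["n_cmc"]])
    cells <- sc$cells; cells$sample_id <- sid
    all_cells[[i]] <- cells
    rows[[i]] <- data.frame(
      sample_id = sid, fraction = man$fraction[i],
      n_cmc_slide = sc$tally[["n_cmc"]], n_leuko = sc$tally[["n_leuko"]],
      n_dual = sc$tally[["n_dual"]], n_null = sc$tally[["n_null"]],
      n_debris = sc$tally[["n_debris"]], n_border = sc$tally[["n_border"]],
      cv_percent = sc$cv_percent,
      t_red = sc$thresholds$t_red, t_green = sc$thresholds$t_green,
      n_cmc_ml = per_ml(sc$tally[["n_cmc"]], man$total_cells[i],
                        man$cells_per_slide[i], man$blood_volume_ml[i]))
  }
  results <- do.call(rbind, rows)
  write.csv(do.call(rbind, all_cells), file.path(out_dir, "objects.csv"),
            row.names = FALSE)
  write.csv(results[, c("sample_id", "fraction", "n_cmc_slide", "n_leuko",
                        "n_dual", "n_null", "n_debris", "n_border",
                        "cv_percent")],
            file.path(out_dir, "tally.csv"), row.names = FALSE)
  write.csv(results[, c("sample_id", "n_cmc_slide", "cv_percent", "n_cmc_ml")],
            file.path(out_dir, "ncmc_per_ml.csv"), row.names = FALSE)
  jsonlite::write_json(.provenance(cfg, out_dir),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(results)
}

#' Run the cohort statistics report
#'
#' Computes the cohort summary, the exact Mann-Whitney comparison of
#' patients against healthy controls, Cox proportional-hazards fits of
#' survival on both log conventions of the per-mL count (natural log and
#' log10), and the log-rank test on the cohort dichotomized at
#' `config$cohort$dichotomy` CMC/mL, then writes them as JSON and as a
#' human-readable text report.
#'
#' @param config a `run_config` (or path / list; see [read_run_config()]).
#'   When `config$cohort$patients` is `NULL` the packaged patient table is
#'   used, and likewise the packaged synthetic healthy controls.
#' @return The report list, invisibly; `cohort_report.json` and
#'   `cohort_report.txt` are written under `config$paths$output`.
#' @export
run_cohort <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  patients <- if (is.null(cfg$cohort$patients)) melanoma_cohort() else {
    p <- cfg$cohort$patients
    if (!file.exists(p)) stopf("patient table not found: %s", p)
    tab <- read.csv(p, stringsAsFactors = FALSE)
    need <- c("survival_months", "alive_at_analysis", "n_cmc_ml")
    missing <- setdiff(need, names(tab))
    if (length(missing) || nrow(tab) == 0)
      stopf("patient table %s malformed: %s", p,
            if (nrow(tab) == 0) "no rows"
            else paste("missing columns", paste(missing, collapse = ", ")))
    bad <- which(!is.finite(tab$survival_months) | tab$survival_months < 0 |
                   !is.finite(tab$n_cmc_ml) | tab$n_cmc_ml < 0)
    if (length(bad))
      stopf("patient table %s has invalid rows: %s", p,
            paste(bad, collapse = ", "))
    tab$alive_at_analysis <- as.logical(tab$alive_at_analysis)
    tab
  }
  healthy <- if (is.null(cfg$cohort$healthy)) healthy_controls()
             else read.csv(cfg$cohort$healthy, stringsAsFactors = FALSE)

  events <- !patients$alive_at_analysis
  mw <- mann_whitney_exact(patients$n_cmc_ml, healthy$n_cmc_ml)
  cox_ln <- cox_ph_single(patients$survival_months, events,
                          log(patients$n_cmc_ml))
  cox_l10 <- cox_ph_single(patients$survival_months, events,
                           log10(patients$n_cmc_ml))
  grp <- patients$n_cmc_ml <= cfg$cohort$dichotomy
  lr <- if (length(unique(grp)) == 2)
    logrank_test(patients$survival_months, events, grp) else NULL

  report <- list(
    summary = summarize_cohort(patients),
    mann_whitney = mw,
    cox_ln = unclass(cox_ln), cox_log10 = unclass(cox_l10),
    logrank = c(lr, list(dichotomy = cfg$cohort$dichotomy)))

  out_dir <- cfg$paths$output %||% "cmcount_output"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report_json <- report
  report_json$summary[grep("^by_", names(report_json$summary))] <-
    lapply(report$summary[grep("^by_", names(report$summary))], as.list)
  jsonlite::write_json(report_json, file.path(out_dir, "cohort_report.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- c(
    sprintf("Cohort: n = %d, median %g CMC/mL (range %g - %g)",
            report$summary$n, report$summary$median, report$summary$min,
            report$summary$max),
    sprintf("Mann-Whitney patients vs healthy: U = %g, p = %.3g (%s)",
            mw$U, mw$p, mw$method),
    sprintf("Cox (ln count):    HR %.2f, 95%% CI (%.2f, %.2f), p = %.2f",
            cox_ln$hr, cox_ln$hr_ci[1], cox_ln$hr_ci[2], cox_ln$p),
    sprintf("Cox (log10 count): HR %.2f, 95%% CI (%.2f, %.2f), p = %.2f",
            cox_l10$hr, cox_l10$hr_ci[1], cox_l10$hr_ci[2], cox_l10$p),
    if (!is.null(lr))
      sprintf("Log-rank at <= %g/mL: chisq = %.2f, p = %.3f",
              cfg$cohort$dichotomy, lr$chisq, lr$p))
  writeLines(txt, file.path(out_dir, "cohort_report.txt"))
  .log_msg(cfg, "%s", paste(txt, collapse = "\n"))
  invisible(report)
}
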
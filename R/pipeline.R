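## End-to-end orchestration: cohort summary, the full analysis battery
## (I/O -> gating -> scoring -> spatial -> correlations -> survival),
## a run manifest for reproducibility, and presentational plots.

#' Summarize a clinical cohort table
#'
#' Categorical fields as counts and percentages of N (one decimal,
#' half-up); numeric fields as mean and SD.
#'
#' @param clinical data.frame, one row per patient.
#' @param categorical,continuous column names to summarize; defaults pick
#'   the recognised clinical fields present.
#' @return list with `n`, `categorical` (data.frame: field, level, n,
#'   percent) and `continuous` (field, mean, sd).
#' @export
summarize_cohort <- function(clinical,
                             categorical = intersect(c("sex", "treatment_group",
                                                       "histology", "death_event",
                                                       "metastasis_event"),
                                                     names(clinical)),
                             continuous = intersect(c("age", "tumor_size_cm"),
                                                    names(clinical))) {
  n <- nrow(clinical)
  cat_rows <- list()
  for (f in categorical) {
    tab <- table(clinical[[f]], useNA = "no")
    cat_rows[[f]] <- data.frame(field = f, level = names(tab),
                                n = as.integer(tab),
                                percent = round_half_up(100 * as.integer(tab) / n, 1),
                                stringsAsFactors = FALSE)
  }
  cont_rows <- lapply(continuous, function(f)
    data.frame(field = f, mean = mean(clinical[[f]], na.rm = TRUE),
               sd = stats::sd(clinical[[f]], na.rm = TRUE)))
  list(n = n,
       categorical = if (length(cat_rows)) do.call(rbind, c(cat_rows, make.row.names = FALSE)) else NULL,
       continuous = if (length(cont_rows)) do.call(rbind, cont_rows) else NULL)
}

#' Battery run configuration
#'
#' @param cohort a [cohort_config()] (synthetic input) or `NULL` when
#'   reading files.
#' @param spatial a [point_process_config()] for synthetic cores.
#' @param cell_table_path,clinical_path delimited inputs for real runs
#'   (used when `cohort` is `NULL`).
#' @param dialect a [cell_dialect()] for real cell tables.
#' @param gating a [gating_config()].
#' @param radius neighborhood radius, micrometres.
#' @param phenotypes effector flag columns analysed spatially.
#' @param survival_markers one or two flag columns whose per-patient
#'   densities drive median-stratified survival (two give the four-group
#'   analysis).
#' @param endpoint `"OS"` or `"MFS"`.
#' @param by_treatment compute per-treatment-group clustering matrices.
#' @param seed integer seed for synthetic stages.
#' @param outdir optional directory for delimited outputs + manifest.
#' @return a `battery_config` list.
#' @export
battery_config <- function(cohort = cohort_config(),
                           spatial = point_process_config(),
                           cell_table_path = NULL, clinical_path = NULL,
                           dialect = cell_dialect(), gating = gating_config(),
                           radius = 30,
                           phenotypes = c("CD3", "CD8", "NKp46"),
                           survival_markers = c("NKp46", "CD8"),
                           endpoint = "OS", by_treatment = TRUE,
                           seed = 1L, outdir = NULL) {
  if (radius <= 0) stopf("radius must be > 0")
  if (!length(survival_markers) %in% 1:2)
    stopf("survival_markers must name 1 or 2 flags")
  structure(list(cohort = cohort, spatial = spatial,
                 cell_table_path = cell_table_path,
                 clinical_path = clinical_path, dialect = dialect,
                 gating = gating, radius = radius, phenotypes = phenotypes,
                 survival_markers = survival_markers, endpoint = endpoint,
                 by_treatment = by_treatment, seed = seed, outdir = outdir),
            class = "battery_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("battery stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis battery
#'
#' Executes, in order: input (synthetic simulation or file reading) ->
#' phenotype gating -> per-patient marker scoring -> spatial clustering
#' (overall, per treatment group, MHC-I partition, paired NK-vs-T
#' in-range) -> density/expression correlations -> median-stratified
#' survival (single marker and, when two markers are configured, the
#' four-group analysis). Deterministic for a fixed config and seed.
#'
#' @param config a [battery_config()].
#' @return a `run_report` list; see its printed structure. The `manifest`
#'   element echoes the config, seed and package version.
#' @export
run_paper_battery <- function(config = battery_config()) {
  stopifnot(inherits(config, "battery_config"))
  warnings_log <- character()

  inp <- stage("input", {
    if (!is.null(config$cohort)) {
      cc <- config$cohort; cc$seed <- config$seed
      sim <- simulate_cohort(cc, config$spatial)
      list(cores = sim$cores, clinical = sim$clinical, truth = sim$truth)
    } else {
      cores <- read_cell_table(config$cell_table_path, config$dialect)
      list(cores = classify_cells(cores, config$gating),
           clinical = read_clinical_table(config$clinical_path),
           truth = NULL)
    }
  })
  cores <- inp$cores

  cohort_summary <- stage("cohort_summary", summarize_cohort(inp$clinical))

  scores <- stage("scoring", {
    out <- lapply(unique(c(config$phenotypes, config$survival_markers)),
                  function(m) marker_scores(cores, m, "density_per_mm2"))
    names(out) <- vapply(out, function(d) d$marker[1], "")
    out
  })
  mhc1_expr <- stage("scoring", {
    df <- do.call(rbind, lapply(cores, function(tb) {
      tumor <- tb
      tumor$cells <- tb$cells[!is.na(tb$cells$MHC1), , drop = FALSE]
      data.frame(patient_id = tb$patient_id,
                 value = if (nrow(tumor$cells))
                   mean(tumor$cells$MHC1) else NA_real_)
    }))
    stats::aggregate(value ~ patient_id, df, mean, na.action = stats::na.omit)
  })

  spatial_res <- stage("spatial", {
    overall <- clustering_matrix(cores, config$phenotypes, config$radius)
    by_trt <- NULL
    if (config$by_treatment && "treatment_group" %in% names(inp$clinical)) {
      trt <- stats::setNames(inp$clinical$treatment_group,
                             inp$clinical$patient_id)
      grp <- split(cores, trt[vapply(cores, function(tb) tb$patient_id, "")])
      by_trt <- lapply(grp, clustering_matrix,
                       phenotypes = config$phenotypes, radius = config$radius)
    }
    part <- partition_centers_by_flag(cores, "MHC1", config$phenotypes,
                                      config$radius)
    paired <- paired_in_range(cores, "NKp46", "NKp46", "CD3", config$radius)
    paired_test <- if (!is.null(paired) && nrow(paired) >= 2)
      t_test2(paired$count_a, paired$count_b, paired = TRUE) else NULL
    list(overall = overall, by_treatment = by_trt, mhc1_partition = part,
         paired_nk_vs_cd3 = paired, paired_test = paired_test)
  })

  correlations <- stage("correlations", {
    out <- lapply(config$phenotypes, function(ph) {
      res <- tryCatch(density_expression_correlation(cores, ph, mhc1_expr),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warnings_log <<- c(warnings_log,
                           sprintf("correlation %s: %s", ph,
                                   conditionMessage(res)))
        NULL
      } else res
    })
    names(out) <- config$phenotypes
    out
  })

  surv_res <- stage("survival", {
    rec <- build_endpoints(inp$clinical, config$endpoint)
    labels <- lapply(config$survival_markers, function(m)
      stratify_by_median(scores[[m]]))
    single <- stratified_km(labels[[1]], rec)
    four <- if (length(labels) == 2) stratified_km(labels, rec) else NULL
    list(records = rec, labels = labels, single_marker = single,
         four_group = four)
  })

  report <- structure(list(
    cohort_summary = cohort_summary, scores = scores, mhc1_expr = mhc1_expr,
    spatial = spatial_res, correlations = correlations,
    survival = surv_res, truth = inp$truth, warnings = warnings_log,
    manifest = list(config = config, seed = config$seed,
                    package_version = as.character(utils::packageVersion("sarcspat")),
                    timestamp = NA)), class = "run_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d patients, %d cores, radius %g um\n",
              x$cohort_summary$n, sum(x$scores[[1]]$n_replicates),
              x$manifest$config$radius))
  cat("pooled clustering matrix:\n")
  print(round(x$spatial$overall$pooled, 2))
  part <- x$spatial$mhc1_partition
  cat(sprintf("MHC-I partition: %d positive / %d negative centers\n",
              part$pos$n_centers, part$neg$n_centers))
  if (!is.null(x$survival$single_marker$logrank)) {
    lr <- x$survival$single_marker$logrank
    cat(sprintf("single-marker log-rank: chi2 = %.3f, p = %.4f\n",
                lr$statistic, lr$p_value))
  }
  if (length(x$warnings)) cat("warnings:", length(x$warnings), "\n")
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  if (!is.null(report$cohort_summary$categorical))
    w(report$cohort_summary$categorical, "cohort_summary")
  w(do.call(rbind, report$scores), "marker_scores")
  pooled <- report$spatial$overall$pooled
  w(data.frame(center = rownames(pooled), pooled, check.names = FALSE),
    "clustering_pooled")
  if (!is.null(report$spatial$overall$per_center))
    w(report$spatial$overall$per_center, "per_center_counts")
  part <- report$spatial$mhc1_partition
  w(rbind(cbind(partition = "MHC1_pos", part$pos$summary),
          cbind(partition = "MHC1_neg", part$neg$summary)),
    "mhc1_partition")
  manifest <- report$manifest
  manifest$config$cohort <- unclass(manifest$config$cohort)
  jsonlite::write_json(
    list(seed = manifest$seed, package_version = manifest$package_version,
         radius = report$manifest$config$radius,
         phenotypes = report$manifest$config$phenotypes),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Render presentational figures for a battery report
#'
#' Kaplan-Meier curves per stratum and a heat-map of the pooled
#' clustering matrix, written as a vector PDF. Purely presentational;
#' failures degrade to warnings.
#'
#' @param report a [run_paper_battery()] result.
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
plot_outputs <- function(report, path = "sarcspat-report.pdf") {
  tryCatch({
    grDevices::pdf(path, width = 7, height = 5)
    on.exit(grDevices::dev.off())
    km <- report$survival$single_marker
    graphics::plot(NA, xlim = c(0, max(vapply(km$curves, function(cv)
      max(cv$time, 1), 0))), ylim = c(0, 1), xlab = "months",
      ylab = "survival probability", main = "Median-stratified survival")
    cols <- seq_along(km$curves)
    for (i in seq_along(km$curves)) {
      cv <- km$curves[[i]]
      graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), col = cols[i],
                      do.points = FALSE)
    }
    graphics::legend("bottomleft", legend = names(km$curves), col = cols,
                     lty = 1, bty = "n")
    pooled <- report$spatial$overall$pooled
    graphics::image(seq_len(ncol(pooled)), seq_len(nrow(pooled)),
                    t(pooled[rev(seq_len(nrow(pooled))), , drop = FALSE]),
                    axes = FALSE, xlab = "target", ylab = "center",
                    main = sprintf("Mean in-range counts (r = %g um)",
                                   report$manifest$config$radius))
    graphics::axis(1, seq_len(ncol(pooled)), colnames(pooled))
    graphics::axis(2, seq_len(nrow(pooled)), rev(rownames(pooled)))
    graphics::box()
  }, error = function(e) warnf("plotting failed: %s", conditionMessage(e)))
  invisible(path)
}
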
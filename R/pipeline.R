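# Pipeline orchestration: CSV ingestion with schema validation, per-stage
# runners and the end-to-end simulate -> derive -> analyze -> correlate ->
# report workflow. Stages communicate only through documented CSVs so any
# stage's input can be replaced by real scanner / testing-machine exports.

DXA_SCHEMA <- c("specimen_id", "projection", "bone_width_cm", "bone_area_cm2",
                "bmc_g", "bmd_g_cm2", "roi_height_cm")
CURVE_SCHEMA <- c("specimen_id", "displacement_mm", "load_N")
SPECIMEN_SCHEMA <- c("specimen_id", "exposed_length_lo_mm")

#' Read a DXA measurement table
#'
#' Expects columns `specimen_id`, `projection` (AP|LAT), `bone_width_cm`,
#' `bone_area_cm2`, `bmc_g`, `bmd_g_cm2`, `roi_height_cm` (UTF-8, header row,
#' '.' decimal separator). Column names are normalised to the package's
#' internal cm/g names.
#'
#' @param path CSV file path.
#' @return Tibble with columns `specimen_id`, `projection`, `bone_width`,
#'   `bone_area`, `bmc`, `bmd`, `roi_height`.
#' @export
read_dxa_measurements <- function(path) {
  df <- read_checked(path, DXA_SCHEMA)
  out <- tibble::tibble(
    specimen_id = as.character(df$specimen_id),
    projection = toupper(df$projection),
    bone_width = df$bone_width_cm, bone_area = df$bone_area_cm2,
    bmc = df$bmc_g, bmd = df$bmd_g_cm2, roi_height = df$roi_height_cm
  )
  bad <- which(!out$projection %in% c("AP", "LAT"))
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid projection at row(s) %s (need AP or LAT)",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read compression-test curves and specimen lengths
#'
#' @param curves_path Long-format CSV with `specimen_id`, `displacement_mm`,
#'   `load_N`.
#' @param specimens_path CSV with `specimen_id`, `exposed_length_lo_mm`.
#' @return List of tibbles `curves` (column `load_n`) and `specimens`.
#' @export
read_mechanical_curves <- function(curves_path, specimens_path) {
  curves <- read_checked(curves_path, CURVE_SCHEMA)
  specimens <- read_checked(specimens_path, SPECIMEN_SCHEMA)
  list(
    curves = tibble::tibble(
      specimen_id = as.character(curves$specimen_id),
      displacement_mm = curves$displacement_mm,
      load_n = curves$load_N
    ),
    specimens = tibble::tibble(
      specimen_id = as.character(specimens$specimen_id),
      exposed_length_lo_mm = specimens$exposed_length_lo_mm
    )
  )
}

read_checked <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("cannot read %s: %s", path,
                                                  conditionMessage(e)),
                                          call. = FALSE))
  missing <- setdiff(schema, names(df))
  if (nrow(df) == 0L) {
    stop(sprintf("schema error in %s: file has no data rows", path),
         call. = FALSE)
  }
  if (length(missing) > 0L) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Validate pipeline input files
#'
#' Row-level checks per file: schema presence, strictly positive widths,
#' areas, masses and ROI heights; non-negative and per-specimen non-decreasing
#' displacements; positive exposed lengths; and cross-file orphan specimen
#' ids. Nothing is modified; a report is returned.
#'
#' @param dxa_path,curves_path,specimens_path CSV paths (any may be `NULL` to
#'   skip that file's checks).
#' @return Tibble with columns `file`, `check`, `pass`, `detail`.
#' @export
validate_inputs <- function(dxa_path = NULL, curves_path = NULL,
                            specimens_path = NULL) {
  rows <- list()
  add <- function(file, check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      file = file, check = check, pass = pass, detail = detail)
  }
  dxa <- curves <- specimens <- NULL
  if (!is.null(dxa_path)) {
    dxa <- tryCatch(read_dxa_measurements(dxa_path), error = function(e) e)
    if (inherits(dxa, "error")) {
      add(dxa_path, "schema", FALSE, conditionMessage(dxa)); dxa <- NULL
    } else {
      add(dxa_path, "schema", TRUE)
      for (col in c("bone_width", "bone_area", "bmc", "bmd", "roi_height")) {
        bad <- which(!is.finite(dxa[[col]]) | dxa[[col]] <= 0)
        add(dxa_path, paste0("positive_", col), length(bad) == 0L,
            if (length(bad)) paste("row(s)", paste(bad, collapse = ", "))
            else "")
      }
    }
  }
  if (!is.null(curves_path) && !is.null(specimens_path)) {
    mech <- tryCatch(read_mechanical_curves(curves_path, specimens_path),
                     error = function(e) e)
    if (inherits(mech, "error")) {
      add(curves_path, "schema", FALSE, conditionMessage(mech))
    } else {
      curves <- mech$curves; specimens <- mech$specimens
      add(curves_path, "schema", TRUE)
      add(specimens_path, "schema", TRUE)
      bad_mono <- names(Filter(isTRUE, lapply(
        split(curves$displacement_mm, curves$specimen_id), is.unsorted)))
      add(curves_path, "displacement_non_decreasing", length(bad_mono) == 0L,
          if (length(bad_mono)) paste("specimen(s)",
                                      paste(bad_mono, collapse = ", "))
          else "")
      bad_neg <- which(curves$displacement_mm < 0)
      add(curves_path, "displacement_non_negative", length(bad_neg) == 0L,
          if (length(bad_neg)) paste("row(s)", paste(bad_neg, collapse = ", "))
          else "")
      bad_lo <- which(!is.finite(specimens$exposed_length_lo_mm) |
                        specimens$exposed_length_lo_mm <= 0)
      add(specimens_path, "positive_exposed_length", length(bad_lo) == 0L,
          if (length(bad_lo)) paste("row(s)", paste(bad_lo, collapse = ", "))
          else "")
      orphans <- setdiff(unique(curves$specimen_id), specimens$specimen_id)
      add(curves_path, "no_orphan_specimens", length(orphans) == 0L,
          if (length(orphans)) paste(orphans, collapse = ", ") else "")
    }
  }
  if (!is.null(dxa) && !is.null(curves)) {
    orphans <- setdiff(unique(curves$specimen_id), unique(dxa$specimen_id))
    add(curves_path, "specimens_have_dxa", length(orphans) == 0L,
        if (length(orphans)) paste(orphans, collapse = ", ") else "")
  }
  do.call(rbind, rows)
}

#' Analyze all compression curves of a cohort
#'
#' Joins each specimen's curve with its exposed length and DXA-derived
#' cross-sectional area and runs [summarize_mechanics()].
#'
#' @param curves Long tibble (`specimen_id`, `displacement_mm`, `load_n`).
#' @param specimens Tibble (`specimen_id`, `exposed_length_lo_mm`).
#' @param dxa_derived Tibble from [derive_dxa()] providing
#'   `cross_section_area`.
#' @param ... Passed to [summarize_mechanics()].
#' @return Tibble of per-specimen mechanical summaries.
#' @export
analyze_mechanics <- function(curves, specimens, dxa_derived, ...) {
  lo <- stats::setNames(specimens$exposed_length_lo_mm,
                        specimens$specimen_id)
  area <- stats::setNames(dxa_derived$cross_section_area,
                          dxa_derived$specimen_id)
  out <- lapply(split(curves, curves$specimen_id), function(cv) {
    id <- cv$specimen_id[1]
    if (is.na(lo[id])) stop(sprintf("no exposed length for specimen '%s'", id),
                            call. = FALSE)
    if (is.na(area[id])) stop(sprintf("no DXA area for specimen '%s'", id),
                              call. = FALSE)
    summarize_mechanics(cv, lo[[id]], area[[id]], specimen_id = id, ...)
  })
  res <- do.call(rbind, out)
  res[order(match(res$specimen_id, unique(curves$specimen_id))), ]
}

#' Run the full analysis pipeline
#'
#' Either consumes an existing fixture/export directory (`input_dir`
#' containing `dxa_measurements.csv`, `mechanical_curves.csv`,
#' `specimens.csv`) or, when `input_dir` is `NULL`, simulates a cohort with
#' `config` into `<output_dir>/inputs` first. Writes `dxa_derived.csv`,
#' `mechanical_summary.csv`, `correlation_table.csv`, `cohort_summary.csv`
#' and `run_log.txt` into `output_dir`.
#'
#' @param output_dir Output directory (created if absent).
#' @param input_dir Optional directory of input CSVs.
#' @param config [cohort_config()] used when simulating.
#' @param yield_offset Offset strain for yield detection (default 0.002).
#' @param window_fraction Modulus window fraction (default 0.2).
#' @param failure_rule `"ultimate"` or `"drop10"`.
#' @param confidence,alpha CI level and power significance level.
#' @param adjust Multiplicity adjustment for the correlation table.
#' @return Invisibly, a list with the four result tibbles.
#' @export
run_full_pipeline <- function(output_dir, input_dir = NULL,
                              config = cohort_config(),
                              yield_offset = 0.002, window_fraction = 0.2,
                              failure_rule = "ultimate",
                              confidence = 0.95, alpha = 0.05,
                              adjust = "none") {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  simulated <- is.null(input_dir)
  if (simulated) {
    input_dir <- file.path(output_dir, "inputs")
    write_fixture_set(generate_cohort(config), input_dir)
  }
  dxa_path <- file.path(input_dir, "dxa_measurements.csv")
  curves_path <- file.path(input_dir, "mechanical_curves.csv")
  specimens_path <- file.path(input_dir, "specimens.csv")

  dxa <- read_dxa_measurements(dxa_path)
  mech_in <- read_mechanical_curves(curves_path, specimens_path)

  derived <- derive_dxa(dxa)
  mech <- analyze_mechanics(mech_in$curves, mech_in$specimens, derived,
                            offset = yield_offset,
                            window_fraction = window_fraction,
                            failure_rule = failure_rule)
  corr <- build_correlation_table(derived, mech, confidence = confidence,
                                  alpha = alpha, adjust = adjust)
  summary_tbl <- cohort_table(mech, derived)

  out_derived <- tibble::tibble(
    specimen_id = derived$specimen_id,
    cross_section_area_cm2 = derived$cross_section_area,
    volume_cm3 = derived$volume,
    bmc_mean_g = derived$bmc_mean,
    bmd_mean_g_cm2 = derived$bmd_mean,
    vbmd_mean_g_cm3 = derived$vbmd_mean
  )
  utils::write.csv(out_derived, file.path(output_dir, "dxa_derived.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(mech),
                   file.path(output_dir, "mechanical_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(corr),
                   file.path(output_dir, "correlation_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summary_tbl),
                   file.path(output_dir, "cohort_summary.csv"),
                   row.names = FALSE)

  log_lines <- c(
    sprintf("regenDXA %s", as.character(utils::packageVersion("regenDXA"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("inputs: %s%s", normalizePath(input_dir),
            if (simulated) sprintf(" (simulated, seed %d, n %d, rho %.3f)",
                                   config$seed, config$n_specimens,
                                   config$rho_vbmd_mech) else ""),
    sprintf("yield_offset: %g", yield_offset),
    sprintf("modulus_window_fraction: %g", window_fraction),
    sprintf("failure_rule: %s", failure_rule),
    sprintf("confidence: %g  alpha: %g  adjust: %s", confidence, alpha,
            adjust),
    sprintf("rows: dxa_measurements=%d specimens=%d curve_samples=%d", nrow(dxa),
            nrow(mech_in$specimens), nrow(mech_in$curves)),
    sprintf("rows: dxa_derived=%d mechanical_summary=%d correlation_table=%d",
            nrow(out_derived), nrow(mech), nrow(corr))
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))

  invisible(list(dxa_derived = derived, mechanical_summary = mech,
                 correlation_table = corr, cohort_summary = summary_tbl))
}
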
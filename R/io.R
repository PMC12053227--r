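# Observed-data file format, result export, and the seeded generator of
# synthetic multi-study concentration-time fixtures.

.observed_cols <- c("study", "species", "analyte", "matrix", "dose_mgkg",
                    "time_day", "conc", "unit")

#' Read an observed concentration-time dataset
#'
#' One canonical tabular dialect: comma-separated, header row, dot decimal,
#' UTF-8, columns `study, species, analyte, matrix, dose_mgkg, time_day,
#' conc, unit`. Schema violations are descriptive errors citing the
#' offending column or row.
#'
#' @param path path to a CSV file.
#' @return validated data frame of observed records.
#' @export
read_observed <- function(path) {
  if (!file.exists(path)) .stop("observed-data file not found: %s", path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_observed(df)
}

#' Validate an observed-records data frame
#'
#' @param df data frame to check against the observed-data schema.
#' @return the data frame, invisibly valid (errors otherwise).
#' @export
validate_observed <- function(df) {
  for (col in .observed_cols) {
    if (!col %in% names(df)) .stop("observed-data schema error: missing column '%s'", col)
  }
  bad <- which(!df$analyte %in% .analytes)
  if (length(bad)) {
    .stop("row %d: unknown analyte '%s' (supported: %s)", bad[1],
          df$analyte[bad[1]], paste(.analytes, collapse = ", "))
  }
  bad <- which(!df$unit %in% .units)
  if (length(bad)) {
    .stop("row %d: unknown unit '%s' (supported: %s)", bad[1],
          df$unit[bad[1]], paste(.units, collapse = ", "))
  }
  for (col in c("dose_mgkg", "time_day", "conc")) {
    if (!is.numeric(df[[col]])) .stop("observed-data schema error: column '%s' is not numeric", col)
  }
  bad <- which(df$conc < 0)
  if (length(bad)) .stop("row %d: negative concentration", bad[1])
  df
}

#' Write an observed concentration-time dataset
#'
#' Numeric columns are written with full double precision so that a
#' write/read round trip is lossless.
#'
#' @param records validated observed data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observed <- function(records, path) {
  validate_observed(records)
  out <- records[, .observed_cols]
  for (col in c("dose_mgkg", "time_day", "conc")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a simulation result to a plain tabular file
#'
#' Long-format time series (time, tissue, sub-compartment, analyte,
#' concentration, unit) for plasma and all tissues, preceded by commented
#' metadata lines recording species, regimen, solver settings and a hash of
#' the parameter set.
#'
#' @param res an `adc_sim` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(res, path) {
  stopifnot(inherits(res, "adc_sim"))
  tmp <- tempfile()
  saveRDS(res$params, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  pl <- res$plasma
  plasma_long <- rbind(
    data.frame(time_days = pl$time_days, tissue = "plasma",
               subcompartment = "plasma", analyte = "total_mab",
               conc = pl$total_mab_ugml, unit = "ug/mL"),
    data.frame(time_days = pl$time_days, tissue = "plasma",
               subcompartment = "plasma", analyte = "conjugated_mmae",
               conc = pl$conjugated_mmae_ngml, unit = "ng/mL"),
    data.frame(time_days = pl$time_days, tissue = "plasma",
               subcompartment = "plasma", analyte = "unconjugated_mmae",
               conc = pl$unconjugated_mmae_ngml, unit = "ng/mL"),
    data.frame(time_days = pl$time_days, tissue = "plasma",
               subcompartment = "plasma", analyte = "dar",
               conc = pl$dar, unit = "ratio"))
  long <- rbind(plasma_long, tissue_concentrations(res))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# adcpbpk simulation result"),
    sprintf("# species: %s", res$species),
    sprintf("# regimen: %s %g mg/kg at days %s", res$regimen$label,
            res$regimen$dose_per_admin,
            paste(res$regimen$times_days, collapse = " ")),
    sprintf("# solver: %s rtol %g atol %g", res$meta$method, res$meta$rtol,
            res$meta$atol),
    sprintf("# params_md5: %s", hash)
  ), con)
  writeLines(paste(names(long), collapse = ","), con)
  writeLines(do.call(paste, c(unname(long), list(sep = ","))), con)
  invisible(path)
}

#' Specify a synthetic multi-study observed-data fixture
#'
#' Describes a sparse, noisy multi-study concentration-time dataset
#' emulating pooled literature data: each study samples the model-predicted
#' truth at its times and dose, with multiplicative lognormal noise
#' (mean 1, coefficient of variation `cv`).
#'
#' @param species simulated species.
#' @param dose_levels doses (mg/kg), recycled across studies.
#' @param n_studies number of studies.
#' @param times_days sampling times shared by all studies.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param seed integer seed fixing the dataset.
#' @param analytes subset of reportable analytes.
#' @param params optional parameter override for the truth simulation.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(species = "rat", dose_levels = 10, n_studies = 6,
                         times_days = c(0.25, 1, 3, 7, 14, 21, 28, 42),
                         cv = 0.3, seed = 1,
                         analytes = c("total_mAb", "conjugated_MMAE",
                                      "unconjugated_MMAE"),
                         params = NULL) {
  stopifnot(cv >= 0, n_studies >= 1, all(dose_levels > 0),
            all(times_days > 0))
  analytes <- match.arg(analytes, .analytes, several.ok = TRUE)
  structure(list(species = species, dose_levels = dose_levels,
                 n_studies = n_studies, times_days = sort(times_days),
                 cv = cv, seed = as.integer(seed), analytes = analytes,
                 params = params), class = "fixture_spec")
}

#' Generate a synthetic observed-data fixture
#'
#' Simulates the true single-dose trajectories at a 1 mg/kg reference dose,
#' scales them to each study's dose (the system is dose-linear at the
#' doses of interest), samples them at the study times, and applies seeded
#' mean-one lognormal noise. Deterministic given the seed; the caller's
#' random-number state is left untouched.
#'
#' @param spec a [fixture_spec()].
#' @param truth optional precomputed `adc_sim` at 1 mg/kg (single dose, at
#'   least `max(times_days)` long); supplied when generating many noise
#'   replicates of the same truth.
#' @return list with `records` (observed-data frame, see
#'   [read_observed()]) and `truth` (the reference simulation).
#' @export
generate_fixture <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(truth)) {
    args <- list(species = spec$species,
                 regimen = build_regimen("single", 1),
                 t_end = max(spec$times_days))
    if (!is.null(spec$params)) args$params <- spec$params
    truth <- do.call(simulate_adc, args)
  }
  cols <- c(total_mAb = "total_mab_ugml",
            conjugated_MMAE = "conjugated_mmae_ngml",
            unconjugated_MMAE = "unconjugated_mmae_ngml",
            conjugated_mAb = "total_mab_ugml")
  units <- c(total_mAb = "ug/mL", conjugated_MMAE = "ng/mL",
             unconjugated_MMAE = "ng/mL", conjugated_mAb = "ug/mL")
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- list()
  for (s in seq_len(spec$n_studies)) {
    dose <- spec$dose_levels[((s - 1L) %% length(spec$dose_levels)) + 1L]
    for (an in spec$analytes) {
      base <- approx(truth$times, truth$plasma[[cols[[an]]]],
                     xout = spec$times_days)$y * dose
      noise <- exp(rnorm(length(base), -sdlog^2 / 2, sdlog))
      rows[[length(rows) + 1L]] <- data.frame(
        study = sprintf("study_%02d", s), species = spec$species,
        analyte = an, matrix = "plasma", dose_mgkg = dose,
        time_day = spec$times_days, conc = base * noise,
        unit = units[[an]], row.names = NULL)
    }
  }
  list(records = validate_observed(do.call(rbind, rows)), truth = truth)
}
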
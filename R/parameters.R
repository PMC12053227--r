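#' Default ADC parameter set for a species
#'
#' Assembles the full parameter set driving a simulation: antibody
#' disposition (`mab`), payload disposition (`payload`, including the
#' species-independent tissue Kp/PS table), the empirical DAR-dependent
#' deconjugation rate (`deconjugation`) and the antibody-payload coupling
#' constants (`coupling`). Species-varying values (FcRn kon/koff, fup,
#' blood-cell partition, intrinsic clearance, degradation fold-change,
#' deconjugation scaling factor) follow the translational model's reported
#' per-species table; remaining constants are platform-style defaults
#' documented in the packaged files.
#'
#' @param species one of `"mouse"`, `"rat"`, `"monkey"`, `"human"`.
#' @return a named list of class `adc_parameters` with elements `species`,
#'   `mab`, `payload`, `deconjugation`, `coupling`.
#' @export
#' @examples
#' p <- default_adc_parameters("human")
#' p$deconjugation$SF
default_adc_parameters <- function(species) {
  species <- match.arg(species, adc_species)
  path <- system.file("extdata", paste0("adc_params_", species, ".yaml"),
                      package = "adcpbpk", mustWork = TRUE)
  read_adc_params(path)
}

.kp_table_default <- function() {
  path <- system.file("extdata", "mmae_kp_ps.csv", package = "adcpbpk",
                      mustWork = TRUE)
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read an ADC parameter file
#'
#' Parameter files are YAML with sections `mab`, `payload`, `deconjugation`
#' and `coupling` (see the packaged `adc_params_*.yaml` for the layout).
#' A missing field is a schema error naming the field. The per-tissue
#' Kp/PS table is attached from `kp_table` in the file (inline table) or,
#' when absent, from the packaged default.
#'
#' @param path path to a YAML parameter file.
#' @return an `adc_parameters` list.
#' @export
read_adc_params <- function(path) {
  if (!file.exists(path)) .stop("parameter file not found: %s", path)
  raw <- yaml::read_yaml(path)
  need <- list(
    mab = c("kon_FcRn", "koff_FcRn", "CL_up", "FR", "kdeg_base"),
    payload = c("fup", "Kp_BC", "CLint"),
    deconjugation = c("alpha", "beta", "F", "tau", "SF"),
    coupling = c("DAR0", "f_Kdeg", "MW_mAb", "MW_MMAE")
  )
  for (sec in names(need)) {
    if (is.null(raw[[sec]])) .stop("parameter schema error: missing section '%s'", sec)
    for (f in need[[sec]]) {
      v <- raw[[sec]][[f]]
      if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
        .stop("parameter schema error: missing or non-numeric field '%s$%s'",
              sec, f)
      }
    }
  }
  p <- raw[names(need)]
  p$species <- sub("^adc_params_([a-z]+)\\.yaml$", "\\1", basename(path))
  if (!p$species %in% adc_species) p$species <- raw$species %||% NA_character_
  p$payload$ps_scaling <- raw$payload$ps_scaling %||% "none"
  if (is.null(raw$kp_table)) {
    p$payload$kp_table <- .kp_table_default()
  } else {
    p$payload$kp_table <- as.data.frame(
      lapply(raw$kp_table, unlist), stringsAsFactors = FALSE)
  }
  class(p) <- "adc_parameters"
  validate_adc_params(p)
  p
}

#' Write an ADC parameter set to a YAML file
#'
#' @param params an `adc_parameters` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adc_params <- function(params, path) {
  stopifnot(inherits(params, "adc_parameters"))
  x <- unclass(params)
  x$kp_table <- as.list(x$payload$kp_table)
  x$payload$kp_table <- NULL
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

validate_adc_params <- function(p) {
  m <- p$mab
  if (any(unlist(m[c("kon_FcRn", "koff_FcRn", "CL_up", "kdeg_base")]) < 0)) {
    .stop("mab rate constants must be >= 0")
  }
  if (m$FR < 0 || m$FR > 1) .stop("mab$FR must lie in [0, 1]")
  q <- p$payload
  if (q$fup <= 0 || q$fup > 1) .stop("payload$fup must lie in (0, 1]")
  if (q$Kp_BC < 0 || q$CLint < 0) .stop("payload Kp_BC and CLint must be >= 0")
  kp <- q$kp_table
  for (col in c("tissue", "Kp", "PS_cell", "PS_BC")) {
    if (!col %in% names(kp)) .stop("kp_table schema error: missing column '%s'", col)
  }
  if (!all(adc_tissues %in% kp$tissue)) {
    .stop("kp_table must cover every perfused tissue")
  }
  idx <- kp$tissue %in% adc_tissues
  if (any(!is.finite(kp$Kp[idx]) | kp$Kp[idx] <= 0)) {
    .stop("kp_table Kp must be positive for every tissue")
  }
  d <- p$deconjugation
  if (!(d$alpha >= d$beta && d$beta >= 0)) .stop("deconjugation requires alpha >= beta >= 0")
  if (d$F <= 0 || d$tau <= 0) .stop("deconjugation F and tau must be > 0")
  if (d$SF <= 0 || d$SF > 1) .stop("deconjugation SF must lie in (0, 1]")
  cp <- p$coupling
  if (cp$DAR0 <= 0) .stop("coupling$DAR0 must be > 0")
  if (cp$f_Kdeg < 1) .stop("coupling$f_Kdeg must be >= 1")
  if (cp$MW_mAb <= 0 || cp$MW_MMAE <= 0) .stop("molecular weights must be > 0")
  invisible(p)
}

#' @export
print.adc_parameters <- function(x, ...) {
  cat(sprintf(paste0("<adc_parameters> %s: DAR0 %.3g, f_Kdeg %g, SF %g, ",
                     "fup %.3g, CLint %.3g mL/min/kg\n"),
              x$species, x$coupling$DAR0, x$coupling$f_Kdeg,
              x$deconjugation$SF, x$payload$fup, x$payload$CLint))
  invisible(x)
}
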
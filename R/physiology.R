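#' Supported species and compartment layout
#'
#' The whole-body models cover fifteen perfused tissues plus a central blood
#' pool and a single well-mixed lymph-node pool. Splanchnic tissues drain
#' into the liver inflow; all other tissues return venous plasma to blood.
#'
#' @name adc_compartments
#' @aliases adc_species adc_tissues adc_splanchnic
#' @export adc_species adc_tissues adc_splanchnic adc_compartments
NULL

#' @rdname adc_compartments
adc_species <- c("mouse", "rat", "monkey", "human")

#' @rdname adc_compartments
adc_tissues <- c("lung", "heart", "kidney", "muscle", "skin", "liver",
                 "brain", "fat", "thymus", "bone", "small_intestine",
                 "large_intestine", "spleen", "pancreas", "other")

#' @rdname adc_compartments
adc_splanchnic <- c("spleen", "small_intestine", "large_intestine", "pancreas")

#' @rdname adc_compartments
adc_compartments <- c(adc_tissues, "blood", "lymph_node")

.expected_bw <- c(mouse = 0.028, rat = 0.28, monkey = 6.2, human = 70)

.tissue_cols <- c("V_plasma", "V_bloodcell", "V_endosomal", "V_interstitial",
                  "V_cellular", "Q_plasma", "L_lymph", "sigma_v", "sigma_i")

#' Load the physiology table for a species
#'
#' Reads a packaged (or user-supplied) species physiology file: per-tissue
#' sub-compartment volumes (plasma, blood cell, endosomal, interstitial,
#' cellular; L), plasma flows and lymph flows (L/h), vascular and lymphatic
#' reflection coefficients, plus whole-body constants (body weight,
#' hematocrit, endosomal FcRn concentration). The returned object has been
#' validated; a file that violates any physiological invariant is rejected.
#'
#' The packaged tables are synthetic parameterizations assembled from
#' standard physiology compilations (see file headers), not transcriptions
#' of any single published table.
#'
#' @param species one of `"mouse"`, `"rat"`, `"monkey"`, `"human"`.
#' @param source optional path to a physiology file; defaults to the
#'   packaged table for `species`.
#' @return an object of class `species_physiology`: a list with elements
#'   `species`, `body_weight` (kg), `hematocrit`, `FcRn_total` (nM),
#'   `lymph_fraction` and `tissues` (a 17-row data frame covering the
#'   perfused tissues plus `blood` and `lymph_node`).
#' @seealso [validate_physiology()], [write_physiology()]
#' @export
#' @examples
#' phys <- load_species_physiology("rat")
#' phys$body_weight
load_species_physiology <- function(species, source = NULL) {
  if (!is.character(species) || length(species) != 1L ||
      !(species %in% adc_species)) {
    .stop("unsupported species '%s' (supported: %s)",
          paste(as.character(species), collapse = ","),
          paste(adc_species, collapse = ", "))
  }
  if (is.null(source)) {
    source <- system.file("extdata", paste0("physiology_", species, ".csv"),
                          package = "adcpbpk", mustWork = TRUE)
  }
  phys <- read_physiology(source)
  if (!identical(phys$species, species)) {
    .stop("physiology file declares species '%s', requested '%s'",
          phys$species, species)
  }
  bad <- validate_physiology(phys)
  if (length(bad)) {
    .stop("invalid physiology for '%s':\n  - %s", species,
          paste(bad, collapse = "\n  - "))
  }
  phys
}

#' Read a physiology file without validating invariants
#'
#' Parses the `# key: value` header and the tissue table. Schema problems
#' (missing header keys or table columns) are errors naming the field;
#' value-level invariants are left to [validate_physiology()].
#'
#' @param path path to a physiology CSV.
#' @return a `species_physiology` object (possibly invalid).
#' @export
read_physiology <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    .stop("physiology file not found: %s", paste(path, collapse = ","))
  }
  lines <- readLines(path)
  hlines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hlines, regexec("^#\\s*([A-Za-z_]+):\\s*(\\S+)\\s*$", hlines))
  kv <- kv[lengths(kv) == 3L]
  hdr <- setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
  for (key in c("species", "body_weight_kg", "hematocrit", "fcrn_nM",
                "lymph_fraction")) {
    if (!key %in% names(hdr)) .stop("physiology schema error: missing header field '%s'", key)
  }
  tab <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                  stringsAsFactors = FALSE)
  if (!"name" %in% names(tab)) .stop("physiology schema error: missing column 'name'")
  for (col in .tissue_cols) {
    if (!col %in% names(tab)) .stop("physiology schema error: missing column '%s'", col)
    if (!is.numeric(tab[[col]])) .stop("physiology schema error: column '%s' is not numeric", col)
  }
  structure(list(
    species = unname(hdr[["species"]]),
    body_weight = as.numeric(hdr[["body_weight_kg"]]),
    hematocrit = as.numeric(hdr[["hematocrit"]]),
    FcRn_total = as.numeric(hdr[["fcrn_nM"]]),
    lymph_fraction = as.numeric(hdr[["lymph_fraction"]]),
    tissues = tab[, c("name", .tissue_cols)]
  ), class = "species_physiology")
}

#' Write a physiology object to a file
#'
#' Numeric fields are written with full double precision so that a
#' write/read round trip reproduces the object bit-exactly.
#'
#' @param phys a `species_physiology` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "species_physiology"))
  f <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# Species physiology for the whole-body ADC PBPK model: ",
           phys$species),
    paste0("# species: ", phys$species),
    paste0("# body_weight_kg: ", f(phys$body_weight)),
    paste0("# hematocrit: ", f(phys$hematocrit)),
    paste0("# fcrn_nM: ", f(phys$FcRn_total)),
    paste0("# lymph_fraction: ", f(phys$lymph_fraction))
  ), con)
  tab <- phys$tissues
  writeLines(paste(names(tab), collapse = ","), con)
  for (i in seq_len(nrow(tab))) {
    writeLines(paste(c(tab$name[i], f(as.numeric(tab[i, .tissue_cols]))),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Check physiological invariants
#'
#' Returns a character vector of violated invariants (empty when valid):
#' non-negative volumes and flows, lymph flow below plasma flow, reflection
#' coefficients in \[0, 1\], the exact compartment set, hematocrit in (0, 1),
#' the species body weight, and the flow balance between summed organ plasma
#' flows and the lung (total) flow (within 1%).
#'
#' @param phys a `species_physiology` object.
#' @return character vector of violation messages; `character(0)` when valid.
#' @export
validate_physiology <- function(phys) {
  out <- character(0)
  add <- function(...) out <<- c(out, sprintf(...))
  tab <- phys$tissues
  if (!setequal(tab$name, adc_compartments) ||
      nrow(tab) != length(adc_compartments)) {
    add("tissue set must contain exactly: %s",
        paste(adc_compartments, collapse = ", "))
  }
  for (col in c("V_plasma", "V_bloodcell", "V_endosomal", "V_interstitial",
                "V_cellular", "Q_plasma", "L_lymph")) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] < 0)
    for (i in bad) add("%s: %s must be >= 0 and finite", tab$name[i], col)
  }
  for (col in c("sigma_v", "sigma_i")) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] < 0 | tab[[col]] > 1)
    for (i in bad) add("%s: %s must lie in [0, 1]", tab$name[i], col)
  }
  per <- tab[tab$name %in% adc_tissues & tab$Q_plasma > 0, ]
  bad <- which(per$L_lymph >= per$Q_plasma)
  for (i in bad) add("%s: L_lymph must be < Q_plasma", per$name[i])
  if (!is.finite(phys$hematocrit) || phys$hematocrit <= 0 ||
      phys$hematocrit >= 1) {
    add("hematocrit must lie in (0, 1)")
  }
  if (!is.finite(phys$FcRn_total) || phys$FcRn_total < 0) {
    add("FcRn_total must be >= 0")
  }
  if (phys$species %in% names(.expected_bw) &&
      abs(phys$body_weight - .expected_bw[[phys$species]]) >
        1e-6 * .expected_bw[[phys$species]]) {
    add("body_weight %g kg does not match the %s reference weight %g kg",
        phys$body_weight, phys$species, .expected_bw[[phys$species]])
  }
  if (all(c("lung", adc_tissues) %in% tab$name)) {
    qlung <- tab$Q_plasma[tab$name == "lung"]
    qsum <- sum(tab$Q_plasma[tab$name %in% setdiff(adc_tissues, "lung")])
    if (qlung > 0 && abs(qsum - qlung) / qlung > 0.01) {
      add("flow balance: organ plasma flows sum to %.4g but lung flow is %.4g",
          qsum, qlung)
    }
  }
  out
}

#' @export
print.species_physiology <- function(x, ...) {
  cat(sprintf("<species_physiology> %s: %g kg, hct %.2f, FcRn %g nM, %d compartments\n",
              x$species, x$body_weight, x$hematocrit, x$FcRn_total,
              nrow(x$tissues)))
  invisible(x)
}
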
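# shared helpers: cheap parameter variants and small reference simulations

params_with <- function(species, ...) {
  p <- default_adc_parameters(species)
  mods <- list(...)
  for (nm in names(mods)) {
    path <- strsplit(nm, "\\.")[[1]]
    if (length(path) == 1L) p[[path]] <- mods[[nm]]
    else p[[path[1]]][[path[2]]] <- mods[[nm]]
  }
  p
}

# physiology copy with modified tissue columns (applied to perfused tissues)
phys_with <- function(species, ...) {
  phys <- load_species_physiology(species)
  mods <- list(...)
  per <- phys$tissues$name %in% adcpbpk::adc_tissues
  for (nm in names(mods)) phys$tissues[[nm]][per] <- mods[[nm]]
  phys
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
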
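## Sample compositions: empirical formula parsing, built-in materials,
## stoichiometric averages and attenuation quantities.

#' Parse an empirical formula
#'
#' Parses strings such as `"H50C30N9O10S1"` into a named vector of
#' stoichiometric counts. A missing count means 1; fractional counts are
#' allowed (useful for solvent-averaged compositions).
#'
#' @param text Empirical-formula string: alternating element symbols and
#'   optional positive counts.
#' @return Named numeric vector of counts, one entry per element, in order of
#'   first appearance (repeated symbols are summed).
#' @examples
#' parse_formula("H50C30N9O10S1")
#' parse_formula("CON2H4")  # urea
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) stop("empty formula", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- paste(tokens, collapse = "")
    stop("could not parse formula '", text, "' near '",
         substr(text, nchar(covered) + 1, nchar(text)), "'", call. = FALSE)
  }
  syms <- sub("[0-9.]*$", "", tokens)
  nums <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(nums), as.numeric(nums), 1)
  known <- element_data()$symbol
  if (!all(syms %in% known)) {
    stop("unknown element symbol(s) in formula: ",
         paste(unique(syms[!syms %in% known]), collapse = ", "), call. = FALSE)
  }
  if (any(counts <= 0) || anyNA(counts)) {
    stop("stoichiometric counts must be positive", call. = FALSE)
  }
  out <- tapply(counts, factor(syms, levels = unique(syms)), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Define a sample composition
#'
#' A composition is an empirical formula plus (optionally) a mass density; it
#' is the material argument of all dosimetry functions.
#'
#' @param formula Empirical-formula string (see [parse_formula()]) or a named
#'   numeric vector of counts.
#' @param density Mass density in g/cm3, or `NULL` if not needed.
#' @param name Optional label.
#' @return An object of class `fx_composition`: a list with elements `counts`
#'   (named numeric), `density` and `name`.
#' @examples
#' composition("H2O", density = 1.0, name = "water")
#' @export
composition <- function(formula, density = NULL, name = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts > 0))
  if (!is.null(density)) stopifnot(is.numeric(density), density > 0)
  structure(list(counts = counts, density = density,
                 name = name %||% paste0(names(counts),
                                         ifelse(counts == 1, "", counts),
                                         collapse = "")),
            class = "fx_composition")
}

#' @export
print.fx_composition <- function(x, ...) {
  cat("<composition> ", x$name, "\n", sep = "")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = ":", collapse = " "), "\n")
  cat("  density:", if (is.null(x$density)) "unset" else paste(x$density, "g/cm3"), "\n")
  cat("  mean atomic mass:", signif(mean_atomic_mass(x), 5), "g/mol\n")
  invisible(x)
}

#' Built-in materials
#'
#' Four reference compositions: `"avg_protein"` (H50C30N9O10S1 at
#' 1.35 g/cm3, the canonical average protein), `"water"`, `"carbon"`
#' (graphite density) and `"psi_crystal"` (a photosystem-I crystal including
#' 78% solvent, H141400 O57300 C16900 N3310 S89 Fe12 Mg96 P3 Ca1 at
#' 1.077 g/cm3).
#'
#' @param name One of `"avg_protein"`, `"water"`, `"carbon"`, `"psi_crystal"`.
#' @return An [composition()] object.
#' @examples
#' material("avg_protein")
#' @export
material <- function(name = c("avg_protein", "water", "carbon", "psi_crystal")) {
  name <- match.arg(name)
  switch(name,
    avg_protein = composition("H50C30N9O10S1", 1.35, "avg_protein"),
    water = composition("H2O", 1.0, "water"),
    carbon = composition("C", 2.26, "carbon"),
    psi_crystal = composition("H141400O57300C16900N3310S89Fe12Mg96P3Ca1",
                              1.077, "psi_crystal")
  )
}

.fx_as_composition <- function(comp) {
  if (is.character(comp)) material(comp) else comp
}

#' Stoichiometric mean atomic mass
#'
#' @param comp An [composition()] object or built-in material name.
#' @return Mean atomic mass in g/mol per atom,
#'   `sum(count_i * m_i) / sum(count_i)`.
#' @examples
#' mean_atomic_mass(material("water"))  # 18.015 / 3
#' @export
mean_atomic_mass <- function(comp) {
  comp <- .fx_as_composition(comp)
  m <- .fx_element_row(names(comp$counts))$mass_g_mol
  sum(comp$counts * m) / sum(comp$counts)
}

#' Mean number of electrons per atom
#'
#' Stoichiometric average of atomic numbers; the cap on the average
#' ionization an atom of the material can reach.
#'
#' @inheritParams mean_atomic_mass
#' @return Electrons per atom.
#' @export
mean_electrons_per_atom <- function(comp) {
  comp <- .fx_as_composition(comp)
  z <- .fx_element_row(names(comp$counts))$z
  sum(comp$counts * z) / sum(comp$counts)
}

#' Mass attenuation coefficient mu/rho
#'
#' Stoichiometry-weighted photoabsorption per unit mass,
#' `N_A * sum(c_i sigma_i) / sum(c_i m_i)`. Intensive: independent of density.
#'
#' @inheritParams mean_atomic_mass
#' @param energy_ev Photon energy (eV); vectorized.
#' @return mu/rho in cm2/g.
#' @export
mass_attenuation <- function(comp, energy_ev) {
  comp <- .fx_as_composition(comp)
  sig <- vapply(energy_ev, function(e) {
    sum(comp$counts * vapply(names(comp$counts), cross_section, 0, energy_ev = e))
  }, 0)
  mass <- sum(comp$counts * .fx_element_row(names(comp$counts))$mass_g_mol)
  .fx$n_avogadro * sig * .fx$barn_cm2 / mass
}

#' Linear attenuation coefficient mu
#'
#' The transmission through thickness t is `exp(-mu * t)`. Requires a density.
#'
#' @inheritParams mass_attenuation
#' @return mu in 1/cm.
#' @examples
#' attenuation_coefficient(material("avg_protein"), 6000)  # 32.5 1/cm
#' @export
attenuation_coefficient <- function(comp, energy_ev) {
  comp <- .fx_as_composition(comp)
  if (is.null(comp$density)) {
    stop("composition has no density; set `density` in composition()",
         call. = FALSE)
  }
  comp$density * mass_attenuation(comp, energy_ev)
}

#' Absorption length 1/mu
#'
#' @inheritParams attenuation_coefficient
#' @return Absorption length in micrometres.
#' @examples
#' absorption_length(material("avg_protein"), 6000)  # about 308 um
#' @export
absorption_length <- function(comp, energy_ev) {
  1e4 / attenuation_coefficient(comp, energy_ev)
}
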
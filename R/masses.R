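#' Monoisotopic atomic masses
#'
#' Single authoritative table of monoisotopic atomic masses used throughout
#' the package. Values are the CODATA/AME2020 monoisotopic masses of the
#' principal isotope, as used by the proteomics community (Unimod/IUPAC),
#' in daltons.
#'
#' @return Named numeric vector of monoisotopic masses (Da), one entry per
#'   element symbol.
#' @examples
#' atomic_masses()[["C"]]
#' @export
atomic_masses <- function() {
  c(
    H = 1.0078250319,
    C = 12.0,
    N = 14.0030740052,
    O = 15.9949146221,
    S = 31.97207069,
    P = 30.97376151,
    Se = 79.9165218
  )
}

# physical constants (CODATA); the proton is H minus one electron
.proton_mass <- 1.00727646688
.electron_mass <- 0.00054857990946

#' Mass of a proton / electron
#'
#' @return Monoisotopic mass in Da.
#' @keywords internal
proton_mass <- function() .proton_mass

#' Parse a molecular formula into an elemental composition
#'
#' Accepts Hill-style formulas such as `"C24H34N2O4"`. A composition is a
#' named integer vector (element symbol -> count); counts must be
#' non-negative.
#'
#' @param formula Character scalar, e.g. `"C2H3NO"`.
#' @return Named integer vector (elemental composition).
#' @examples
#' parse_formula("C2H3NO")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  sym <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(sub("^[A-Za-z]+", "", parts))
  cnt[is.na(cnt)] <- 1L
  comp <- tapply(cnt, sym, sum)
  out <- as.integer(comp)
  names(out) <- names(comp)
  out
}

#' Combine two elemental compositions
#'
#' Element-wise addition (or subtraction with `sign = -1`). Subtracting more
#' atoms than present is an error: compositions never go negative.
#'
#' @param a,b Named integer vectors as returned by [parse_formula()].
#' @param sign `+1` to add, `-1` to subtract `b` from `a`.
#' @return Named integer composition.
#' @export
combine_compositions <- function(a, b, sign = 1L) {
  stopifnot(sign %in% c(-1L, 1L))
  elems <- union(names(a), names(b))
  av <- stats::setNames(rep(0L, length(elems)), elems)
  av[names(a)] <- av[names(a)] + a
  av[names(b)] <- av[names(b)] + sign * b
  if (any(av < 0L)) {
    stop(
      "composition would be negative for element(s): ",
      paste(elems[av < 0L], collapse = ", ")
    )
  }
  av[av > 0L]
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named integer vector (element -> count) or a formula
#'   string, which is parsed with [parse_formula()].
#' @return Monoisotopic mass in Da. The empty composition has mass 0.
#' @examples
#' monoisotopic_mass("C2H3NO") # carbamidomethyl delta, 57.021
#' monoisotopic_mass("O")      # methionine oxidation delta, 15.995
#' @export
monoisotopic_mass <- function(composition) {
  if (is.character(composition)) composition <- parse_formula(composition)
  if (length(composition) == 0L) {
    return(0)
  }
  tab <- atomic_masses()
  unknown <- setdiff(names(composition), names(tab))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(tab[names(composition)] * as.numeric(composition))
}

#' m/z of an ion from its elemental composition
#'
#' Computes the mass-to-charge ratio for a species of total charge
#' `charge`, formed by adding `protons_added` protons to the composition.
#' The convention is fixed and documented here: the composition is summed
#' from neutral-atom masses; each added proton contributes the bare proton
#' mass (1.00727646688 Da, i.e. electron already removed); any remaining
#' charge (`charge - protons_added`, for intrinsic cations whose formula is
#' written as the cation) is balanced by subtracting electron masses.
#'
#' @param composition Composition vector or formula string for the species
#'   *excluding* added protons (for an intrinsic cation, the cation formula).
#' @param charge Total positive charge, >= 1.
#' @param protons_added Number of protons added (default `charge`, the
#'   usual protonated-molecule case).
#' @return m/z in Th.
#' @examples
#' ion_mz("C24H36N2O4", charge = 1)                    # [M+H]+ = 417.27
#' ion_mz("C77H88N31O16S", charge = 1, protons_added = 0) # intrinsic cation
#' @export
ion_mz <- function(composition, charge = 1L, protons_added = charge) {
  if (charge < 1L) stop("charge must be >= 1")
  if (protons_added < 0L || protons_added > charge) {
    stop("protons_added must lie in [0, charge]")
  }
  m <- monoisotopic_mass(composition)
  (m + protons_added * .proton_mass -
    (charge - protons_added) * .electron_mass) / charge
}

#' Convert a neutral mass to the m/z of its protonated ion
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive charge state.
#' @return m/z in Th.
#' @export
mass_to_mz <- function(neutral_mass, charge) {
  (neutral_mass + charge * .proton_mass) / charge
}

#' Convert an observed precursor m/z back to a neutral mass
#'
#' @param mz Observed m/z.
#' @param charge Charge state.
#' @return Neutral monoisotopic mass (Da).
#' @export
mz_to_mass <- function(mz, charge) {
  mz * charge - charge * .proton_mass
}

# residue elemental compositions of the 20 standard amino acids
# (residue = amino acid minus water)
.residue_formulas <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

# cached residue monoisotopic masses, derived from the atomic table at load
.residue_masses_env <- new.env(parent = emptyenv())

#' Monoisotopic residue masses of the 20 standard amino acids
#'
#' Residue masses (amino acid minus water), computed once from the package's
#' atomic mass table and the standard residue elemental compositions.
#'
#' @return Named numeric vector, one-letter residue code -> mass (Da).
#' @export
residue_masses <- function() {
  if (is.null(.residue_masses_env$masses)) {
    .residue_masses_env$masses <- vapply(
      .residue_formulas, monoisotopic_mass, numeric(1)
    )
  }
  .residue_masses_env$masses
}

water_mass <- function() monoisotopic_mass("H2O")

#' Define a modification
#'
#' A modification has a name, a target residue (one-letter code, or `"any"`),
#' a monoisotopic mass shift, and a mode (`"static"` modifications apply to
#' every target residue; `"dynamic"` ones optionally). If an elemental
#' composition is supplied the delta mass is derived from it and checked
#' against `delta_mass` (3 decimal places) when both are given.
#'
#' @param name Modification name (used in output tables).
#' @param target_residue One-letter amino-acid code or `"any"`.
#' @param delta_mass Monoisotopic mass shift in Da (optional if
#'   `composition` given).
#' @param composition Formula string or composition vector (optional).
#' @param mode `"static"` or `"dynamic"`.
#' @return An object of class `mod_spec`.
#' @examples
#' mod_spec("Ad", "Y", composition = "C24H34N2O4", mode = "dynamic")
#' @export
mod_spec <- function(name, target_residue, delta_mass = NULL,
                     composition = NULL, mode = c("dynamic", "static")) {
  mode <- match.arg(mode)
  if (is.null(delta_mass) && is.null(composition)) {
    stop("one of delta_mass or composition is required")
  }
  if (!is.null(composition)) {
    if (is.character(composition)) composition <- parse_formula(composition)
    comp_mass <- monoisotopic_mass(composition)
    if (!is.null(delta_mass) &&
      round(comp_mass, 3) != round(delta_mass, 3)) {
      stop(
        "composition mass ", round(comp_mass, 3),
        " does not match delta_mass ", round(delta_mass, 3)
      )
    }
    delta_mass <- comp_mass
  }
  structure(
    list(
      name = name, target_residue = target_residue,
      delta_mass = delta_mass, composition = composition, mode = mode
    ),
    class = "mod_spec"
  )
}

#' @export
print.mod_spec <- function(x, ...) {
  cat(sprintf(
    "<mod_spec> %s: %+0.3f Da on %s (%s)\n",
    x$name, x$delta_mass, x$target_residue, x$mode
  ))
  invisible(x)
}

#' Default modification set
#'
#' The modifications of the dual-labeling workflow: carbamidomethylation of
#' cysteine (+57.021 Da, static), methionine oxidation (+15.995 Da,
#' dynamic), the adamantane-phenol tag Ad on tyrosine (+414.252 Da,
#' dynamic; the neutral Ad phenol C24H36N2O4 couples minus two hydrogens)
#' and biotin Bt on lysine (+226.078 Da, dynamic). All deltas are derived
#' from elemental compositions.
#'
#' @return Named list of [mod_spec()] objects.
#' @export
default_modifications <- function() {
  list(
    Carbamidomethyl = mod_spec("Carbamidomethyl", "C",
      composition = "C2H3NO", mode = "static"
    ),
    Oxidation = mod_spec("Oxidation", "M",
      composition = "O", mode = "dynamic"
    ),
    Ad = mod_spec("Ad", "Y",
      composition = "C24H34N2O4", mode = "dynamic"
    ),
    Bt = mod_spec("Bt", "K",
      composition = "C10H14N2O2S", mode = "dynamic"
    )
  )
}

#' Neutral monoisotopic mass of a (possibly modified) peptide
#'
#' Sum of residue masses plus one water plus all modification deltas.
#'
#' @param sequence Peptide sequence using the 20 standard one-letter codes.
#' @param mod_deltas Numeric vector of modification mass shifts (Da),
#'   one per modification carried by the peptide (positions are irrelevant
#'   for the precursor mass).
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' peptide_neutral_mass("G") # glycine, 75.032
#' @export
peptide_neutral_mass <- function(sequence, mod_deltas = numeric(0)) {
  rm <- residue_masses()
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(rm))
  if (length(bad)) {
    stop("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
  }
  sum(rm[aa]) + water_mass() + sum(mod_deltas)
}

# vectorised residue-sum over many sequences; internal hot path
.sequence_residue_mass <- function(sequences) {
  rm <- residue_masses()
  vapply(
    strsplit(sequences, ""),
    function(aa) sum(rm[aa]),
    numeric(1)
  )
}
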
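# Physical constants for peptide mass and isotope-envelope computation.
# Monoisotopic masses and natural abundances: IUPAC/CODATA values.

PROTON_MASS <- 1.007276

# monoisotopic mass of the lightest isotope per element
ELEMENT_MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

WATER_MASS <- 2 * ELEMENT_MONO_MASS[["H"]] + ELEMENT_MONO_MASS[["O"]]

# per-element isotope tables: exact masses and natural abundances.
# Nitrogen abundance is overridden at arbitrary 15N enrichment.
ISOTOPE_TABLE <- list(
  C = list(mass = c(12.0, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.0141017778),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740048, 15.0001088982),
           abundance = c(0.996358, 0.003642)),
  O = list(mass = c(15.9949146196, 16.9991317, 17.9991610),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

N15_NATURAL_ABUNDANCE <- 0.003642

# residue elemental compositions (residue = amino acid minus water)
RESIDUE_COMPOSITION <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

ELEMENT_NAMES <- c("C", "H", "N", "O", "S")

composition_mass <- function(comp) {
  sum(ELEMENT_MONO_MASS[ELEMENT_NAMES] * comp[ELEMENT_NAMES])
}

RESIDUE_MONO_MASS <- vapply(RESIDUE_COMPOSITION, composition_mass, numeric(1))

#' Shipped modification table
#'
#' Named monoisotopic mass shifts for the modifications used throughout the
#' pipeline, with elemental composition where known so that modified peptides
#' contribute correctly to isotope envelopes. `diGly` is the Gly-Gly remnant
#' left on a ubiquitylated lysine after tryptic digestion.
#'
#' @return A data frame with columns `name`, `delta_mass` (Da, monoisotopic)
#'   and a `composition` list-column (named C/H/N/O/S counts, or `NULL` for
#'   mass-only modifications).
#' @examples
#' modification_table()
#' @export
modification_table <- function() {
  out <- data.frame(
    name = c("carbamidomethyl", "oxidation", "diGly"),
    delta_mass = c(
      composition_mass(c(C = 2, H = 3, N = 1, O = 1, S = 0)),
      ELEMENT_MONO_MASS[["O"]],
      composition_mass(c(C = 4, H = 6, N = 2, O = 2, S = 0))
    ),
    stringsAsFactors = FALSE
  )
  out$composition <- list(
    c(C = 2, H = 3, N = 1, O = 1, S = 0),
    c(C = 0, H = 0, N = 0, O = 1, S = 0),
    c(C = 4, H = 6, N = 2, O = 2, S = 0)
  )
  out
}

mod_delta <- function(name) {
  tab <- modification_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown modification name: ", name)
  tab$delta_mass[i]
}

mod_composition <- function(name) {
  tab <- modification_table()
  i <- match(name, tab$name)
  if (is.na(i)) return(NULL)
  tab$composition[[i]]
}
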
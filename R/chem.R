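#' Construct a peptide
#'
#' A peptide is a one-letter amino-acid sequence with optional modifications
#' (each a 1-based residue position, a name and a monoisotopic mass shift) and
#' an optional charge state. It is the unit for all mass, m/z and fragment
#' computations.
#'
#' Modifications whose `name` matches the shipped [modification_table()] may
#' omit `delta_mass`; unknown names must supply it and then contribute to
#' masses but not to elemental compositions.
#'
#' @param sequence one-letter residue string (20 standard codes; I and L are
#'   distinct characters of identical mass).
#' @param modifications list of modifications, each a list/vector with fields
#'   `position`, `name`, and optionally `delta_mass` (Da).
#' @param charge positive integer, optional until an m/z is requested.
#' @return An object of class `peptide`.
#' @examples
#' peptide("VTIAQGGVLPNIQAVLLPKK",
#'         modifications = list(list(position = 19, name = "diGly")),
#'         charge = 3)
#' @export
peptide <- function(sequence, modifications = list(), charge = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(RESIDUE_COMPOSITION))
  if (length(bad) > 0) {
    stop("unknown residue code(s) in sequence: ", paste(unique(bad), collapse = ", "))
  }
  mods <- lapply(modifications, function(m) {
    m <- as.list(m)
    if (is.null(m$position) || is.null(m$name)) {
      stop("each modification needs 'position' and 'name'")
    }
    pos <- as.integer(m$position)
    if (pos < 1L || pos > length(aa)) {
      stop("modification position ", pos, " outside [1, ", length(aa), "]")
    }
    delta <- if (!is.null(m$delta_mass)) as.numeric(m$delta_mass) else mod_delta(m$name)
    if (!is.finite(delta)) stop("modification delta_mass must be finite")
    list(position = pos, name = as.character(m$name), delta_mass = delta)
  })
  if (!is.null(charge)) {
    charge <- as.integer(charge)
    if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  }
  structure(
    list(sequence = sequence, residues = aa, modifications = mods, charge = charge),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  modtxt <- if (length(x$modifications) == 0) "none" else {
    paste(vapply(x$modifications, function(m) {
      sprintf("%s@%d(%+.5f)", m$name, m$position, m$delta_mass)
    }, character(1)), collapse = "; ")
  }
  cat("Peptide:", x$sequence, "\n")
  cat("  length:", length(x$residues),
      " charge:", if (is.null(x$charge)) "unset" else x$charge, "\n")
  cat("  modifications:", modtxt, "\n")
  invisible(x)
}

#' Elemental composition of a peptide
#'
#' Sums residue compositions plus one water; modifications with a registered
#' elemental formula (see [modification_table()]) are included, while
#' mass-shift-only modifications are excluded (they still count toward
#' [monoisotopic_mass()]).
#'
#' @param pep a [peptide()].
#' @return Named integer vector of C, H, N, O, S counts.
#' @examples
#' peptide_composition(peptide("G"))  # glycine: C2 H5 N1 O2
#' @export
peptide_composition <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  comp <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # start from water
  for (aa in pep$residues) comp <- comp + RESIDUE_COMPOSITION[[aa]]
  for (m in pep$modifications) {
    mc <- mod_composition(m$name)
    if (!is.null(mc)) comp <- comp + mc[ELEMENT_NAMES]
  }
  comp
}

#' Monoisotopic mass of a peptide
#'
#' Residue-mass sum plus water (18.010565 Da) plus all modification mass
#' shifts; additive in modifications.
#'
#' @param pep a [peptide()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(peptide("G"))  # 75.03203
#' @export
monoisotopic_mass <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  m <- sum(RESIDUE_MONO_MASS[pep$residues]) + WATER_MASS
  for (mod in pep$modifications) m <- m + mod$delta_mass
  unname(m)
}

#' Precursor m/z of a charged peptide
#'
#' @param pep a [peptide()].
#' @param charge charge state z; defaults to the peptide's own charge.
#' @return (M + z * 1.007276) / z, in Th.
#' @examples
#' p <- peptide("LLSGVTIAQGGVLPNIQAVLLPKK",
#'              modifications = list(list(position = 23, name = "diGly")))
#' round(precursor_mz(p, 3), 4)  # 848.5143
#' @export
precursor_mz <- function(pep, charge = pep$charge) {
  stopifnot(inherits(pep, "peptide"))
  if (is.null(charge)) stop("charge required: set it on the peptide or pass it explicitly")
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  (monoisotopic_mass(pep) + charge * PROTON_MASS) / charge
}

#' Fragment ion m/z (b and y series)
#'
#' y_n contains the n C-terminal residues plus water; b_n the n N-terminal
#' residues without water. Modifications on residues inside the fragment span
#' are included.
#'
#' @param pep a [peptide()].
#' @param ion_series `"b"` or `"y"`.
#' @param n ion length, 1 <= n < peptide length.
#' @param charge fragment charge (default 1).
#' @return m/z in Th.
#' @examples
#' fragment_mz(peptide("AK"), "y", 1)  # y1 of K: 147.1128
#' @export
fragment_mz <- function(pep, ion_series = c("y", "b"), n, charge = 1L) {
  stopifnot(inherits(pep, "peptide"))
  ion_series <- match.arg(ion_series)
  L <- length(pep$residues)
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n >= L) {
    stop("ion length n must satisfy 1 <= n < ", L, " (got ", n, ")")
  }
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  span <- if (ion_series == "y") seq.int(L - n + 1L, L) else seq.int(1L, n)
  m <- sum(RESIDUE_MONO_MASS[pep$residues[span]])
  if (ion_series == "y") m <- m + WATER_MASS
  for (mod in pep$modifications) {
    if (mod$position %in% span) m <- m + mod$delta_mass
  }
  (m + charge * PROTON_MASS) / charge
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P, emitting every
#' peptide with 0..`missed_cleavages` internal missed cleavage sites along
#' with its 1-based inclusive span in protein coordinates.
#'
#' @param protein_sequence one-letter amino-acid string.
#' @param missed_cleavages maximum internal missed cleavages (>= 0).
#' @param min_length drop peptides shorter than this (default 1, keep all).
#' @return Data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' tryptic_digest("AKPR", 0)   # K-P suppressed: one peptide AKPR
#' tryptic_digest("AKRG", 1)
#' @export
tryptic_digest <- function(protein_sequence, missed_cleavages = 0L, min_length = 1L) {
  stopifnot(is.character(protein_sequence), length(protein_sequence) == 1L)
  missed_cleavages <- as.integer(missed_cleavages)
  if (is.na(missed_cleavages) || missed_cleavages < 0L) {
    stop("missed_cleavages must be >= 0")
  }
  empty <- data.frame(sequence = character(0), start = integer(0),
                      end = integer(0), missed_cleavages = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(protein_sequence)) return(empty)
  aa <- strsplit(protein_sequence, "")[[1]]
  L <- length(aa)
  # cleavage sites: after position i if aa[i] in {K,R} and aa[i+1] != P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == L | aa[pmin(cut_after + 1L, L)] != "P"]
  bounds <- c(0L, cut_after[cut_after < L], L)  # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nfrag <- length(starts)
  rows <- list()
  for (i in seq_len(nfrag)) {
    for (k in 0:missed_cleavages) {
      j <- i + k
      if (j > nfrag) break
      s <- starts[i]; e <- ends[j]
      if (e - s + 1L < min_length) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste(aa[s:e], collapse = ""),
        start = s, end = e, missed_cleavages = k,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read protein sequences from a FASTA file
#'
#' Standard FASTA dialect; the description line is truncated at the first
#' whitespace token, which becomes the protein id.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs
}
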
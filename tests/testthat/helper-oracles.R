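# Independent oracles used across the suite. These deliberately take the
# brute-force / closed-form route, never the package's own code path.

# --- isotope envelope oracle: direct polynomial expansion ------------------
# Enumerates, per element, every way of distributing n atoms over the
# element's isotopes (multinomial), then crosses all elements and aggregates
# isotopologues by their integer nominal-mass shift.

.oracle_compositions <- function(n, k) {
  # all k-part compositions of n (order matters): small n only
  if (k == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (first in 0:n) {
    rest <- .oracle_compositions(n - first, k - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

.oracle_element_species <- function(element, n, n15 = NULL) {
  iso <- pulseN15:::ISOTOPE_TABLE[[element]]
  ab <- iso$abundance
  if (element == "N" && !is.null(n15)) ab <- c(1 - n15, n15)
  k <- length(ab)
  comp <- .oracle_compositions(n, k)
  prob <- apply(comp, 1, function(cc) {
    exp(lgamma(n + 1) - sum(lgamma(cc + 1))) * prod(ab^cc)
  })
  mass <- comp %*% iso$mass
  shift <- comp %*% as.integer(round(iso$mass - iso$mass[1]))
  data.frame(prob = prob, mass = as.numeric(mass), shift = as.integer(shift))
}

oracle_envelope <- function(composition, n15 = pulseN15:::N15_NATURAL_ABUNDANCE) {
  species <- data.frame(prob = 1, mass = 0, shift = 0L)
  for (el in names(composition)) {
    n <- composition[[el]]
    if (is.na(n) || n == 0) next
    es <- .oracle_element_species(el, n, n15)
    species <- do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
      data.frame(prob = species$prob[i] * es$prob,
                 mass = species$mass[i] + es$mass,
                 shift = species$shift[i] + es$shift)
    }))
  }
  agg_p <- tapply(species$prob, species$shift, sum)
  agg_m <- tapply(species$prob * species$mass, species$shift, sum) / agg_p
  ord <- order(as.integer(names(agg_p)))
  data.frame(mass = as.numeric(agg_m[ord]), abundance = as.numeric(agg_p[ord]))
}

# --- misc helpers ----------------------------------------------------------

# residue monoisotopic masses summed by hand from a published-style table,
# independent of the package's composition arithmetic
HAND_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

hand_peptide_mass <- function(seq, mods = 0) {
  sum(HAND_RESIDUE_MASS[strsplit(seq, "")[[1]]]) + 18.010565 + sum(mods)
}

# same-partition check up to label permutation
same_partition <- function(a, b) {
  ta <- table(a, b)
  sum(apply(ta, 1, function(r) sum(r > 0)) == 1) == nrow(ta) &&
    sum(apply(ta, 2, function(r) sum(r > 0)) == 1) == ncol(ta)
}

make_turnover_df <- function(ids, mat, tissue = "head") {
  ages <- as.numeric(colnames(mat))
  do.call(rbind, lapply(seq_along(ages), function(j) {
    data.frame(protein_id = ids, tissue = tissue, age_days = ages[j],
               n15_pct = mat[, j], n_peptides = 2L, stringsAsFactors = FALSE)
  }))
}
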
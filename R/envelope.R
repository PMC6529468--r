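# Theoretical isotope envelopes at arbitrary 15N enrichment.
#
# Peaks are aggregated by nominal mass shift (integer Da offset from the
# all-light species); within a nominal peak the reported mass is the
# abundance-weighted mean of the contributing isotopologues. Aggregation by
# summed integer shifts is associative, so convolving pre-aggregated element
# distributions is exact — no isotope fine structure is resolved.

# distribution as a list(shift = integer vector, abundance, mass_moment)
# where mass_moment[k] = sum over species in bin k of abundance * mass.

.dist_single_atom <- function(element, n15 = NULL) {
  iso <- ISOTOPE_TABLE[[element]]
  ab <- iso$abundance
  if (element == "N" && !is.null(n15)) ab <- c(1 - n15, n15)
  shift <- as.integer(round(iso$mass - iso$mass[1]))
  list(shift = shift, abundance = ab, mass_moment = ab * iso$mass)
}

.dist_convolve <- function(a, b, prune = 1e-15) {
  max_shift <- max(a$shift) + max(b$shift)
  ab <- numeric(max_shift + 1L)
  mm <- numeric(max_shift + 1L)
  for (i in seq_along(a$shift)) {
    k <- a$shift[i] + b$shift + 1L
    ab[k] <- ab[k] + a$abundance[i] * b$abundance
    # mass of combined species = mass_a + mass_b; moment adds accordingly
    mm[k] <- mm[k] + a$abundance[i] * b$mass_moment +
      a$mass_moment[i] * b$abundance
  }
  keep <- ab > prune
  list(shift = which(keep) - 1L, abundance = ab[keep], mass_moment = mm[keep])
}

.dist_power <- function(d, n, prune = 1e-15) {
  # exponentiation by squaring over the convolution product
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- if (is.null(result)) base else .dist_convolve(result, base, prune)
    }
    n <- n %/% 2
    if (n > 0) base <- .dist_convolve(base, base, prune)
  }
  result
}

#' Theoretical isotope envelope of an elemental composition
#'
#' Convolves per-element isotope distributions across all atoms, with the
#' nitrogen channel at an arbitrary 15N abundance, so the same routine yields
#' the light (natural-abundance) and heavy (metabolically enriched) envelopes
#' of a pulse-15N experiment. Peaks are aggregated per nominal mass; the
#' envelope is truncated once cumulative abundance reaches `coverage` and
#' renormalized to sum to 1.
#'
#' @param composition named vector of non-negative C/H/N/O/S counts, e.g. from
#'   [peptide_composition()].
#' @param n15_enrichment fraction of nitrogen atoms that are 15N; the default
#'   is the natural abundance 0.003642, reproducing the unlabeled envelope.
#' @param coverage cumulative-abundance truncation point (default 0.999).
#' @return An object of class `isotope_envelope`: a data frame with `mass`
#'   (Da, strictly increasing) and `abundance` (fractions summing to 1).
#' @examples
#' env <- isotope_envelope(peptide_composition(peptide("GG")))
#' env
#' @export
isotope_envelope <- function(composition, n15_enrichment = N15_NATURAL_ABUNDANCE,
                             coverage = 0.999) {
  if (any(composition < 0)) stop("element counts must be non-negative")
  if (n15_enrichment < 0 || n15_enrichment > 1) {
    stop("n15_enrichment must be in [0, 1]")
  }
  known <- names(composition) %in% ELEMENT_NAMES
  if (!all(known)) {
    stop("unknown element(s): ", paste(names(composition)[!known], collapse = ", "))
  }
  comp <- stats::setNames(rep(0, length(ELEMENT_NAMES)), ELEMENT_NAMES)
  comp[names(composition)] <- composition
  if (sum(comp) == 0) stop("empty composition")
  total <- NULL
  for (el in ELEMENT_NAMES) {
    n <- as.integer(comp[[el]])
    if (n == 0) next
    d <- .dist_power(.dist_single_atom(el, n15_enrichment), n)
    total <- if (is.null(total)) d else .dist_convolve(total, d)
  }
  mass <- total$mass_moment / total$abundance
  ab <- total$abundance / sum(total$abundance)
  # keep the smallest set of most-abundant peaks reaching cumulative coverage
  ord <- order(ab, decreasing = TRUE)
  ncut <- which(cumsum(ab[ord]) >= coverage)[1]
  if (is.na(ncut)) ncut <- length(ab)
  keep <- sort(ord[seq_len(ncut)])
  mass <- mass[keep]
  ab <- ab[keep] / sum(ab[keep])
  structure(
    data.frame(mass = mass, abundance = ab),
    class = c("isotope_envelope", "data.frame")
  )
}

#' @export
print.isotope_envelope <- function(x, ...) {
  cat("Isotope envelope:", nrow(x), "peaks\n")
  df <- data.frame(mass = sprintf("%.5f", x$mass),
                   abundance = sprintf("%.6f", x$abundance))
  print(df, row.names = FALSE)
  invisible(x)
}
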
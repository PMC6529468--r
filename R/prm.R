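# Parallel reaction monitoring (PRM) targets and quantification for the
# ubiquitylated H2A C-terminal peptides.

#' Build a PRM target for a diGly peptide
#'
#' Computes the precursor m/z and the singly charged y3-y7 fragment m/z for a
#' peptide carrying an explicitly placed diGly modification. The diGly site
#' must be supplied on the peptide: the precursor m/z is site-invariant, but
#' fragment identities shift by the remnant mass when the modified lysine
#' lies within the fragment, so the site is never guessed.
#'
#' @param pep a [peptide()] with a diGly modification; at least 8 residues
#'   (y7 must exist).
#' @param charge precursor charge, default 3.
#' @return Object of class `prm_target`: list with `peptide`, `precursor_mz`,
#'   and `fragments` (data frame `ion`, `n`, `mz`, `charge`).
#' @examples
#' p <- peptide("VTIAQGGVLPNIQAVLLPKK",
#'              modifications = list(list(position = 19, name = "diGly")))
#' round(build_prm_target(p)$precursor_mz, 4)  # 725.1071
#' @export
build_prm_target <- function(pep, charge = 3L) {
  stopifnot(inherits(pep, "peptide"))
  if (!any(vapply(pep$modifications, function(m) m$name == "diGly", logical(1)))) {
    stop("peptide carries no diGly modification; the site must be explicit")
  }
  if (length(pep$residues) < 8) {
    stop("peptide must have at least 8 residues (y7 undefined otherwise)")
  }
  ns <- 3:7
  frag <- data.frame(
    ion = paste0("y", ns),
    n = ns,
    mz = vapply(ns, function(n) fragment_mz(pep, "y", n, charge = 1L), numeric(1)),
    charge = 1L,
    stringsAsFactors = FALSE
  )
  structure(list(peptide = pep,
                 precursor_mz = precursor_mz(pep, charge),
                 precursor_charge = as.integer(charge),
                 fragments = frag),
            class = "prm_target")
}

#' @export
print.prm_target <- function(x, ...) {
  cat("PRM target:", x$peptide$sequence, "\n")
  cat(sprintf("  precursor m/z %.4f (z = %d)\n", x$precursor_mz, x$precursor_charge))
  df <- x$fragments
  df$mz <- sprintf("%.5f", df$mz)
  print(df[, c("ion", "mz", "charge")], row.names = FALSE)
  invisible(x)
}

#' Write PRM targets as a TSV table
#'
#' Columns: peptide, modifications (`pos:name:delta`), charge, precursor_mz,
#' y3..y7 m/z.
#'
#' @param targets list of [build_prm_target()] objects.
#' @param path output TSV path.
#' @export
write_prm_table <- function(targets, path) {
  rows <- lapply(targets, function(t) {
    mods <- paste(vapply(t$peptide$modifications, function(m) {
      sprintf("%d:%s:%.5f", m$position, m$name, m$delta_mass)
    }, character(1)), collapse = ";")
    row <- data.frame(peptide = t$peptide$sequence, modifications = mods,
                      charge = t$precursor_charge,
                      precursor_mz = sprintf("%.4f", t$precursor_mz),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(t$fragments))) {
      row[[t$fragments$ion[i]]] <- sprintf("%.4f", t$fragments$mz[i])
    }
    row
  })
  write_tsv_atomic(do.call(rbind, rows), path)
  invisible(path)
}

#' Summed y3-y7 PRM quantification
#'
#' The quantity is the plain sum of the five fragment intensities, without
#' normalization (equal total protein input across samples is a pipeline
#' precondition). Missing ions are treated as zero with a warning.
#'
#' @param fragment_intensities named numeric vector, names among y3..y7.
#' @param sample_id,group optional labels carried into the result.
#' @return Object of class `prm_quant`: list with `sample_id`, `group`,
#'   `summed_intensity`.
#' @export
quantify_prm <- function(fragment_intensities, sample_id = NA_character_,
                         group = NA_character_) {
  ions <- paste0("y", 3:7)
  if (any(fragment_intensities < 0)) stop("fragment intensities must be >= 0")
  extra <- setdiff(names(fragment_intensities), ions)
  if (length(extra) > 0) stop("unknown ion label(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(ions, names(fragment_intensities))
  if (length(missing) > 0) {
    warning("missing ion(s) treated as 0: ", paste(missing, collapse = ", "))
  }
  v <- stats::setNames(rep(0, length(ions)), ions)
  v[names(fragment_intensities)] <- fragment_intensities
  structure(list(sample_id = sample_id, group = group,
                 summed_intensity = sum(v)),
            class = "prm_quant")
}

#' Compare PRM quantifications between age groups
#'
#' Fold change is the ratio of group means (old/young); the p-value is a
#' two-sided two-sample Student's t test, equal-variance by default (Welch
#' by flag).
#'
#' @param young,old numeric vectors of summed intensities (or lists of
#'   `prm_quant` objects), >= 2 samples each.
#' @param var_equal equal-variance t test (default TRUE).
#' @return List with `fold_change` (old/young; `NA` with a flag when the
#'   young mean is zero), `p_value`, `n_young`, `n_old`, `flag`.
#' @export
prm_group_compare <- function(young, old, var_equal = TRUE) {
  pull <- function(v) {
    if (is.list(v)) vapply(v, function(q) q$summed_intensity, numeric(1)) else v
  }
  young <- pull(young); old <- pull(old)
  if (length(young) < 2 || length(old) < 2) stop("need >= 2 samples per group")
  my <- mean(young)
  flag <- ""
  fc <- if (my == 0) { flag <- "zero_young_mean"; NA_real_ } else mean(old) / my
  list(fold_change = fc,
       p_value = stats::t.test(old, young, var.equal = var_equal)$p.value,
       n_young = length(young), n_old = length(old), flag = flag)
}
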
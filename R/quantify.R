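#' Paired light/heavy extracted ion chromatogram
#'
#' @param times scan times in seconds, strictly increasing, length >= 3.
#' @param light,heavy non-negative intensity vectors aligned to `times`.
#' @return An object of class `xic_pair`.
#' @export
xic_pair <- function(times, light, heavy) {
  stopifnot(length(times) >= 3,
            length(light) == length(times),
            length(heavy) == length(times))
  if (any(diff(times) <= 0)) stop("scan times must be strictly increasing")
  if (any(light < 0) || any(heavy < 0)) stop("intensities must be non-negative")
  structure(list(times = times, light = light, heavy = heavy),
            class = "xic_pair")
}

#' 15N proportion from channel areas
#'
#' The turnover readout: heavy signal over total signal.
#'
#' @param light_area,heavy_area non-negative channel areas, not both zero.
#' @return heavy / (light + heavy).
#' @examples
#' n15_proportion(25, 75)  # 0.75
#' @export
n15_proportion <- function(light_area, heavy_area) {
  stopifnot(all(light_area >= 0), all(heavy_area >= 0))
  tot <- light_area + heavy_area
  if (any(tot == 0)) stop("light and heavy areas are both zero")
  heavy_area / tot
}

#' Estimate the heavy/light ratio of one XIC pair
#'
#' The ratio is the least-squares slope through the origin of heavy on light
#' intensities across scans (the co-elution of the isotopologue pair makes
#' the paired scans proportional when the signal is clean); fit quality is
#' the squared Pearson correlation of the two traces. Pairs below the r2
#' threshold are flagged rejected; an area-ratio fallback is available.
#' A zero light trace maps to proportion 1.0 (all-heavy), keeping downstream
#' math in [0, 1] rather than propagating infinite ratios.
#'
#' @param xic an [xic_pair()].
#' @param r2_threshold minimum fit r-squared to accept a regression estimate.
#' @param method `"regression"` (default) or `"area"` (simple area ratio).
#' @return An object of class `peptide_quant`: list with `ratio_heavy_over_light`,
#'   `n15_proportion`, `fit_r2`, `method`, `rejected`, `flag`.
#' @examples
#' x <- xic_pair(1:5, light = c(1, 3, 5, 3, 1), heavy = 2 * c(1, 3, 5, 3, 1))
#' estimate_pair_ratio(x)$n15_proportion  # 2/3
#' @export
estimate_pair_ratio <- function(xic, r2_threshold = 0.5,
                                method = c("regression", "area")) {
  stopifnot(inherits(xic, "xic_pair"))
  method <- match.arg(method)
  l <- xic$light; h <- xic$heavy
  if (all(l == 0) && all(h == 0)) {
    return(structure(list(ratio_heavy_over_light = NA_real_,
                          n15_proportion = NA_real_, fit_r2 = NA_real_,
                          method = method, rejected = TRUE,
                          flag = "zero_signal"),
                     class = "peptide_quant"))
  }
  if (all(l == 0)) {
    return(structure(list(ratio_heavy_over_light = Inf, n15_proportion = 1.0,
                          fit_r2 = 1.0, method = method, rejected = FALSE,
                          flag = "zero_light"),
                     class = "peptide_quant"))
  }
  r2 <- if (stats::sd(l) == 0 || stats::sd(h) == 0) 1.0 else {
    r <- stats::cor(l, h)
    if (r < 0) 0 else r^2  # anti-correlated traces are not a co-eluting pair
  }
  ratio <- if (method == "regression") sum(h * l) / sum(l * l) else sum(h) / sum(l)
  structure(list(ratio_heavy_over_light = ratio,
                 n15_proportion = ratio / (1 + ratio),
                 fit_r2 = r2,
                 method = method,
                 rejected = method == "regression" && r2 < r2_threshold,
                 flag = ""),
            class = "peptide_quant")
}

#' @export
print.peptide_quant <- function(x, ...) {
  cat(sprintf("Peptide quant [%s]%s: ratio H/L = %.4f, 15N%% = %.4f, r2 = %.3f\n",
              x$method, if (x$rejected) " (rejected)" else "",
              x$ratio_heavy_over_light, x$n15_proportion, x$fit_r2))
  invisible(x)
}

#' Roll peptide quantifications up to protein 15N proportions
#'
#' Protein 15N% is the median of accepted peptide proportions per protein per
#' age. Evidence rules: at least two quantified peptides in `"total"`
#' (whole-proteome) mode, at least one in `"ubiquitylome"` mode.
#' Under-evidenced protein/age combinations are omitted (their count is
#' attached as the `n_dropped` attribute).
#'
#' @param quants data frame with columns `protein_id`, `tissue`, `age_days`,
#'   `peptide_id`, `n15_proportion` (accepted quants only).
#' @param mode `"total"` or `"ubiquitylome"`.
#' @return Data frame `protein_id`, `tissue`, `age_days`, `n15_pct`
#'   (fraction), `n_peptides`.
#' @export
rollup_protein <- function(quants, mode = c("total", "ubiquitylome")) {
  mode <- match.arg(mode)
  min_pep <- if (mode == "total") 2L else 1L
  need <- c("protein_id", "tissue", "age_days", "peptide_id", "n15_proportion")
  stopifnot(all(need %in% names(quants)))
  if (nrow(quants) == 0) {
    out <- data.frame(protein_id = character(0), tissue = character(0),
                      age_days = numeric(0), n15_pct = numeric(0),
                      n_peptides = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  key <- interaction(quants$protein_id, quants$tissue, quants$age_days, drop = TRUE)
  groups <- split(quants, key)
  rows <- lapply(groups, function(g) {
    n <- length(unique(g$peptide_id))
    data.frame(protein_id = g$protein_id[1], tissue = g$tissue[1],
               age_days = g$age_days[1],
               n15_pct = stats::median(g$n15_proportion),
               n_peptides = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dropped <- sum(out$n_peptides < min_pep)
  out <- out[out$n_peptides >= min_pep, , drop = FALSE]
  out <- out[order(out$protein_id, out$tissue, out$age_days), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Quantify a PSM + XIC table set to protein turnover
#'
#' Runs [estimate_pair_ratio()] on every referenced XIC pair and rolls up to
#' per-protein 15N proportions. PSMs with a diGly modification form the
#' ubiquitylome subset (one-peptide rule); the remainder form the total
#' proteome (two-peptide rule).
#'
#' @param psms PSM records (schema of `psms.tsv`, see [read_psm_table()]).
#' @param xics long XIC table (`xic_id`, `scan_time`, `light_intensity`,
#'   `heavy_intensity`).
#' @param r2_threshold passed to [estimate_pair_ratio()].
#' @return List with `total` and `ubiquitylome` protein-turnover data frames
#'   and `peptide_quants` (per-XIC estimates).
#' @export
quantify_psms <- function(psms, xics, r2_threshold = 0.5) {
  is_ub <- grepl("diGly", psms$mod_positions)
  # one quant per unique (xic, peptide, protein, age, tissue)
  u <- unique(psms[, c("protein_id", "peptide_id", "tissue", "age_days", "xic_id")])
  xsplit <- split(xics[, c("scan_time", "light_intensity", "heavy_intensity")],
                  xics$xic_id)
  quants <- lapply(seq_len(nrow(u)), function(i) {
    xd <- xsplit[[u$xic_id[i]]]
    if (is.null(xd)) return(NULL)
    q <- estimate_pair_ratio(
      xic_pair(xd$scan_time, xd$light_intensity, xd$heavy_intensity),
      r2_threshold = r2_threshold
    )
    data.frame(u[i, , drop = FALSE],
               ratio = q$ratio_heavy_over_light,
               n15_proportion = q$n15_proportion,
               fit_r2 = q$fit_r2, rejected = q$rejected,
               stringsAsFactors = FALSE)
  })
  pq <- do.call(rbind, quants)
  rownames(pq) <- NULL
  ub_peptides <- unique(psms$peptide_id[is_ub])
  pq$is_ub <- pq$peptide_id %in% ub_peptides
  acc <- pq[!pq$rejected, , drop = FALSE]
  list(
    total = rollup_protein(acc[!acc$is_ub, , drop = FALSE], mode = "total"),
    ubiquitylome = rollup_protein(acc[acc$is_ub, , drop = FALSE],
                                  mode = "ubiquitylome"),
    peptide_quants = pq
  )
}
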
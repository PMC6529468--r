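# Ubiquitylome statistics: how diGly-marked (ubiquitylated) PSMs and
# proteins distribute over the old (15N) versus new (14N) proteome.

#' Channel proportions of a PSM subset
#'
#' Pure counting: the share of 15N PSMs among all PSMs of a subset (total
#' proteome or diGly-enriched ubiquitylome), the comparison behind
#' "old forms account for X% of the proteome but Y% of the ubiquitylome".
#'
#' @param psms PSM records with a `channel` column (`14N`/`15N`) and a
#'   `mod_positions` column.
#' @param subset `"total_proteome"` (PSMs without diGly), `"ubiquitylome"`
#'   (PSMs with diGly), or `"all"`.
#' @return Object of class `proportion_report`: list with `label`,
#'   `n_psm_total`, `n_psm_15N`, `percent_15N` (exact), and
#'   `percent_15N_rounded` (half-up whole percent).
#' @export
psm_channel_proportions <- function(psms,
                                    subset = c("total_proteome",
                                               "ubiquitylome", "all")) {
  subset <- match.arg(subset)
  is_ub <- grepl("diGly", psms$mod_positions)
  keep <- switch(subset,
                 total_proteome = !is_ub,
                 ubiquitylome = is_ub,
                 all = rep(TRUE, nrow(psms)))
  sub <- psms[keep, , drop = FALSE]
  if (nrow(sub) == 0) stop("no PSMs left after filter '", subset, "'")
  n15 <- sum(sub$channel == "15N")
  structure(list(label = subset,
                 n_psm_total = nrow(sub),
                 n_psm_15N = n15,
                 percent_15N = 100 * n15 / nrow(sub),
                 percent_15N_rounded = .round_half_up(100 * n15 / nrow(sub), 0)),
            class = "proportion_report")
}

#' @export
print.proportion_report <- function(x, ...) {
  cat(sprintf("%s: %d / %d PSMs 15N (%.0f%%)\n",
              x$label, x$n_psm_15N, x$n_psm_total, x$percent_15N_rounded))
  invisible(x)
}

#' Compare per-protein 15N proportions: ubiquitylome versus total proteome
#'
#' Matches proteins by id, reports the fraction whose ubiquitylome 15N% is
#' strictly higher than their total-proteome 15N%, and a two-sided
#' Mann-Whitney-Wilcoxon rank-sum p-value (tie-corrected). Both the unpaired
#' rank-sum p (primary) and the paired signed-rank p are emitted, since the
#' pairing convention is an analysis choice.
#'
#' @param total,ub protein-turnover data frames (`protein_id`, `n15_pct`),
#'   typically one age.
#' @param alternative passed to [stats::wilcox.test()], default two-sided.
#' @return List with `n_matched`, `fraction_higher_in_ub`, `p_value`
#'   (unpaired rank-sum) and `p_value_paired` (signed-rank).
#' @export
compare_protein_n15 <- function(total, ub, alternative = "two.sided") {
  stopifnot(all(c("protein_id", "n15_pct") %in% names(total)),
            all(c("protein_id", "n15_pct") %in% names(ub)))
  common <- intersect(total$protein_id, ub$protein_id)
  if (length(common) < 2) stop("fewer than 2 proteins matched between sets")
  tv <- total$n15_pct[match(common, total$protein_id)]
  uv <- ub$n15_pct[match(common, ub$protein_id)]
  list(
    n_matched = length(common),
    fraction_higher_in_ub = mean(uv > tv),
    p_value = stats::wilcox.test(uv, tv, alternative = alternative,
                                 exact = FALSE, correct = TRUE)$p.value,
    p_value_paired = stats::wilcox.test(uv, tv, paired = TRUE,
                                        alternative = alternative,
                                        exact = FALSE, correct = TRUE)$p.value
  )
}

#' Per-protein ubiquitylation-site count distribution
#'
#' Deduplicates site records on (protein, position) and bins proteins as
#' having exactly one site, more than one, and (as a sub-bin of the latter)
#' more than ten.
#'
#' @param sites data frame with `protein_id` and `site` (1-based protein
#'   coordinate) columns.
#' @param quantified_ids optional character vector restricting the histogram
#'   to quantified proteins (those passing the one-ub-peptide rule).
#' @return List with `per_protein` (named site counts), `exactly_1`,
#'   `more_than_1`, `more_than_10`, `n_proteins`.
#' @export
site_count_distribution <- function(sites, quantified_ids = NULL) {
  stopifnot(all(c("protein_id", "site") %in% names(sites)))
  u <- unique(sites[, c("protein_id", "site")])
  if (!is.null(quantified_ids)) {
    u <- u[u$protein_id %in% quantified_ids, , drop = FALSE]
  }
  counts <- table(u$protein_id)
  list(per_protein = counts,
       exactly_1 = sum(counts == 1),
       more_than_1 = sum(counts > 1),
       more_than_10 = sum(counts > 10),
       n_proteins = length(counts))
}

#' Map a peptide-level modification position to a protein coordinate
#'
#' @param peptide_start 1-based start of the peptide within the protein.
#' @param mod_position 1-based modified-residue position within the peptide.
#' @param protein_length optional; when given, out-of-range sites error.
#' @return Protein site coordinate `peptide_start + mod_position - 1`.
#' @examples
#' map_peptide_site_to_protein(112, 7)  # 118, e.g. H2A K118
#' @export
map_peptide_site_to_protein <- function(peptide_start, mod_position,
                                        protein_length = NULL) {
  stopifnot(all(peptide_start >= 1), all(mod_position >= 1))
  site <- peptide_start + mod_position - 1L
  if (!is.null(protein_length) && any(site > protein_length)) {
    stop("mapped site ", paste(site[site > protein_length], collapse = ","),
         " exceeds protein length ", protein_length)
  }
  site
}

#' Extract deduplicated ubiquitylation-site records from a PSM table
#'
#' Parses diGly entries out of `mod_positions`, maps each to protein
#' coordinates, and tallies PSM counts per channel. A diGly on the peptide's
#' C-terminal residue is chemically implausible (trypsin does not cleave
#' after a modified lysine); such records are kept but flagged.
#'
#' @param psms PSM records (diGly rows are selected automatically).
#' @return Data frame: `protein_id`, `site`, `tissue`, `age_days`, `n_14N`,
#'   `n_15N`, `c_terminal_flag`.
#' @export
ub_site_records <- function(psms) {
  ub <- psms[grepl("diGly", psms$mod_positions), , drop = FALSE]
  if (nrow(ub) == 0) {
    return(data.frame(protein_id = character(0), site = integer(0),
                      tissue = character(0), age_days = numeric(0),
                      n_14N = integer(0), n_15N = integer(0),
                      c_terminal_flag = logical(0), stringsAsFactors = FALSE))
  }
  mod_pos <- as.integer(sub(":.*$", "", ub$mod_positions))
  site <- map_peptide_site_to_protein(as.integer(ub$peptide_start), mod_pos)
  cterm <- mod_pos == nchar(ub$peptide_sequence)
  key <- interaction(ub$protein_id, site, ub$tissue, ub$age_days, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(ub)), key), function(idx) {
    data.frame(protein_id = ub$protein_id[idx[1]], site = site[idx[1]],
               tissue = ub$tissue[idx[1]], age_days = ub$age_days[idx[1]],
               n_14N = sum(ub$channel[idx] == "14N"),
               n_15N = sum(ub$channel[idx] == "15N"),
               c_terminal_flag = any(cterm[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$protein_id, out$site, out$age_days), , drop = FALSE]
  rownames(out) <- NULL
  out
}
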
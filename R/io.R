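# TSV schemas, validated reading, atomic writing, and the pipeline driver.
# All coordinates are 1-based inclusive; tables are tab-delimited UTF-8 with
# '.' as the decimal separator and a mandatory header row. Lines starting
# with '#' are provenance comments and are skipped on read.

PSM_COLUMNS <- c("psm_id", "protein_id", "peptide_id", "peptide_sequence",
                 "charge", "channel", "tissue", "age_days", "mod_positions",
                 "peptide_start", "xic_id")
XIC_COLUMNS <- c("xic_id", "scan_time", "light_intensity", "heavy_intensity")

# small deterministic 32-bit FNV-1a hash for provenance headers
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; multiply mod 2^32 in 16-bit limbs to
    # stay exact in doubles
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * 16777619) %% 4294967296 +
            ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Atomically write a TSV table
#'
#' Writes to a temporary file in the target directory and renames, so no
#' output is ever partially written. Optional provenance lines are prepended
#' as `#`-comments.
#'
#' @param df data frame.
#' @param path destination path.
#' @param provenance character vector of comment lines (without `#`).
#' @export
write_tsv_atomic <- function(df, path, provenance = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "w", encoding = "UTF-8")
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  close(con)
  if (!file.rename(tmp, path)) stop("failed to write ", path)
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = NULL)
}

#' Read and validate a PSM table
#'
#' Schema-validates `psms.tsv`: all required columns present, channel
#' normalized case-insensitively to `14N`/`15N` (accepting `n14`/`n15`
#' spellings), numeric fields parseable. Malformed rows are collected into an
#' error report with their line numbers; the read aborts if any exist unless
#' `skip_bad = TRUE`, in which case they are dropped and attached as the
#' `bad_rows` attribute.
#'
#' @param path path to the TSV.
#' @param skip_bad drop malformed rows instead of aborting.
#' @return Data frame of validated PSM records.
#' @export
read_psm_table <- function(path, skip_bad = FALSE) {
  raw <- .read_tsv(path)
  missing_cols <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    out <- raw
    out$charge <- integer(0); out$age_days <- numeric(0)
    out$peptide_start <- integer(0)
    return(out)
  }
  norm <- toupper(trimws(raw$channel))
  norm[norm == "N14"] <- "14N"
  norm[norm == "N15"] <- "15N"
  chan_ok <- norm %in% c("14N", "15N")
  age <- suppressWarnings(as.numeric(raw$age_days))
  charge <- suppressWarnings(as.integer(raw$charge))
  pstart <- suppressWarnings(as.integer(raw$peptide_start))
  pstart_ok <- raw$peptide_start %in% c("", "NA") | !is.na(pstart)
  bad <- !chan_ok | is.na(age) | is.na(charge) | !pstart_ok
  if (any(bad)) {
    # +1 header line; comment lines before data would shift numbering and are
    # not counted, which the schema docs note
    report <- data.frame(line = which(bad) + 1L,
                         psm_id = raw$psm_id[bad],
                         reason = ifelse(!chan_ok[bad], "bad channel",
                                         ifelse(is.na(age[bad]), "bad age_days",
                                                "bad numeric field")),
                         stringsAsFactors = FALSE)
    if (!skip_bad) {
      stop("malformed row(s) at line(s) ",
           paste(utils::head(report$line, 10), collapse = ", "),
           if (nrow(report) > 10) " ..." else "",
           "; use skip_bad = TRUE to drop them")
    }
  }
  out <- raw[!bad, , drop = FALSE]
  out$channel <- norm[!bad]
  out$age_days <- age[!bad]
  out$charge <- charge[!bad]
  out$peptide_start <- pstart[!bad]
  rownames(out) <- NULL
  if (any(bad)) attr(out, "bad_rows") <- report
  out
}

#' Read an XIC table
#'
#' @param path path to `xics.tsv` (columns xic_id, scan_time,
#'   light_intensity, heavy_intensity).
#' @return Data frame with numeric columns parsed.
#' @export
read_xic_table <- function(path) {
  raw <- .read_tsv(path)
  missing_cols <- setdiff(XIC_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("scan_time", "light_intensity", "heavy_intensity")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v) && nrow(raw) > 0) stop("non-numeric values in column ", col)
    raw[[col]] <- v
  }
  raw
}

#' Pipeline run configuration
#'
#' @param input_dir directory containing `psms.tsv` and `xics.tsv`.
#' @param output_dir directory for result tables.
#' @param llp_threshold 60 d retention threshold for LLPs (default 0.10).
#' @param ellp_floor individual 60 d retention floor for ELLPs (default 0.70).
#' @param r2_threshold XIC regression acceptance threshold (default 0.5).
#' @param fcm_c,fcm_m,fcm_tol,fcm_max_iter fuzzy c-means settings.
#' @param seed integer seed for the clustering stage (mandatory).
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       llp_threshold = 0.10, ellp_floor = 0.70,
                       r2_threshold = 0.5,
                       fcm_c = 4, fcm_m = 2, fcm_tol = 1e-6,
                       fcm_max_iter = 200, seed = NULL) {
  for (nm in c("llp_threshold", "ellp_floor", "r2_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) stop(nm, " must be in [0, 1]")
  }
  if (is.null(seed)) stop("seed is required")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 llp_threshold = llp_threshold, ellp_floor = ellp_floor,
                 r2_threshold = r2_threshold, fcm_c = fcm_c, fcm_m = fcm_m,
                 fcm_tol = fcm_tol, fcm_max_iter = fcm_max_iter,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Quantification (XIC ratios, protein rollup), turnover classification
#' (LLP threshold + fuzzy c-means ELLPs), then ubiquitylome statistics, each
#' stage writing its TSVs with a provenance header (package version, config
#' hash, seed). Identical config and seed give byte-identical outputs. A
#' stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @return Invisibly, named vector of output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  # hash covers the analysis parameters, not the I/O paths, so reruns into a
  # different directory remain byte-identical
  params <- unclass(config)
  params$input_dir <- params$output_dir <- NULL
  prov <- c(
    paste0("pulseN15 ", as.character(utils::packageVersion("pulseN15"))),
    paste0("config_hash=", .fnv1a(paste(deparse(params), collapse = ""))),
    paste0("seed=", config$seed)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- c(
    turnover = file.path(config$output_dir, "protein_turnover.tsv"),
    classification = file.path(config$output_dir, "classification.tsv"),
    ub_proportions = file.path(config$output_dir, "ub_proportions.tsv"),
    ub_sites = file.path(config$output_dir, "ub_sites.tsv"),
    ub_histogram = file.path(config$output_dir, "ub_site_histogram.tsv")
  )

  psms <- stage("read", read_psm_table(file.path(config$input_dir, "psms.tsv")))
  xics <- stage("read", read_xic_table(file.path(config$input_dir, "xics.tsv")))

  q <- stage("quantify", quantify_psms(psms, xics, config$r2_threshold))
  tt <- q$total
  tt$n15_pct <- sprintf("%.6f", tt$n15_pct)
  write_tsv_atomic(tt, out[["turnover"]], prov)

  cls <- stage("turnover", {
    traj <- trajectory_matrix(q$total)
    llp <- classify_llp(traj, config$llp_threshold)
    fit <- fcm_cluster(traj, c = config$fcm_c, m = config$fcm_m,
                       tol = config$fcm_tol, max_iter = config$fcm_max_iter,
                       seed = config$seed)
    ellp <- identify_ellp(fit, traj, config$ellp_floor)
    data.frame(protein_id = rownames(traj),
               tissue = attr(traj, "tissue"),
               is_llp = unname(llp),
               is_ellp = rownames(traj) %in% ellp,
               cluster = unname(fit$cluster),
               membership = sprintf("%.6f", fit$membership[
                 cbind(seq_len(nrow(traj)), fit$cluster)]),
               stringsAsFactors = FALSE)
  })
  write_tsv_atomic(cls, out[["classification"]], prov)

  ub <- stage("ubiquitylome", {
    props <- rbind(
      as.data.frame(unclass(psm_channel_proportions(psms, "total_proteome"))),
      as.data.frame(unclass(psm_channel_proportions(psms, "ubiquitylome")))
    )
    props$percent_15N <- sprintf("%.4f", props$percent_15N)
    sites <- ub_site_records(psms)
    quantified <- unique(q$ubiquitylome$protein_id)
    hist <- site_count_distribution(sites, quantified_ids = quantified)
    list(props = props,
         sites = sites,
         hist = data.frame(bin = c("exactly_1", "more_than_1", "more_than_10"),
                           n_proteins = c(hist$exactly_1, hist$more_than_1,
                                          hist$more_than_10),
                           stringsAsFactors = FALSE))
  })
  write_tsv_atomic(ub$props, out[["ub_proportions"]], prov)
  write_tsv_atomic(ub$sites, out[["ub_sites"]], prov)
  write_tsv_atomic(ub$hist, out[["ub_histogram"]], prov)
  invisible(out)
}
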
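# Seeded synthetic pulse-15N experiments with known ground truth.
#
# The generator emulates the study design: flies fully labeled with 15N,
# switched to 14N food at day 5, tissues sampled at 5/30/60 d. Each protein's
# old (15N) pool decays as a single exponential f_old(t) = exp(-k (t - t0));
# peptide XIC pairs split total intensity between heavy and light channels
# according to the purity-adjusted old fraction, with multiplicative
# log-normal noise; diGly PSMs can be biased toward the old pool via an odds
# multiplier beta.

TISSUE_PRESETS <- list(
  head   = c(extreme = 0.10, slow = 0.45, fast = 0.45),
  muscle = c(extreme = 0.25, slow = 0.54, fast = 0.21),
  testis = c(extreme = 0.08, slow = 0.23, fast = 0.69)
)

# log-normal parameters for per-day rate constants k of the three turnover
# classes; chosen so that over a 55-day chase the extreme class retains
# > 0.7 of its heavy pool, the slow class 0.15-0.5 (long-lived but not
# extreme), and the fast class < 0.05
TURNOVER_CLASSES <- data.frame(
  class = c("extreme", "slow", "fast"),
  meanlog = log(c(0.0025, 0.02, 0.10)),
  sdlog = c(0.35, 0.25, 0.30),
  stringsAsFactors = FALSE
)

#' Configuration of a synthetic pulse-15N experiment
#'
#' All knobs of the simulated experiment, with ground truth retained so that
#' recovery can be tested. Defaults mirror the emulated study design: three
#' ages (5, 30, 60 d) with the diet switch at day 5, heavy-channel label
#' purity 0.995, and a turnover-class mixture per tissue chosen to match the
#' observed long-lived-protein shares (head 55%, muscle 79%, testis 31%).
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein mean quantifiable peptides per protein
#'   (Poisson above a minimum of 1).
#' @param ages_days sampling ages in days.
#' @param chase_start_day day of the 15N-to-14N diet switch.
#' @param tissue one of `"head"`, `"muscle"`, `"testis"` (sets the default
#'   class mixture), or any label if `class_weights` is supplied.
#' @param class_weights named weights over `c("extreme","slow","fast")`
#'   summing to 1; defaults to the tissue preset.
#' @param turnover_classes data frame of per-class log-normal rate parameters
#'   (`class`, `meanlog`, `sdlog`).
#' @param label_purity probability that a heavy-pool molecule is observed in
#'   the 15N channel (misassignment probability 1 - purity).
#' @param noise_sigma log-scale s.d. of multiplicative intensity noise per
#'   scan per channel.
#' @param psm_depth expected PSMs per peptide per age for a protein of mean
#'   abundance (depth scales with relative abundance, so aggregate channel
#'   shares converge to abundance-weighted old fractions).
#' @param ub_site_density expected diGly sites per protein.
#' @param ub_old_bias_beta odds multiplier (>= 0) biasing diGly PSMs toward
#'   the old (15N) pool; 1 = unbiased. Default 3.72 turns a 0.28 old fraction
#'   into a 0.59 heavy share, the magnitude of bias the pipeline is designed
#'   to detect.
#' @param rng_seed integer seed; mandatory, the run is deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 500,
                             peptides_per_protein = 4,
                             ages_days = c(5, 30, 60),
                             chase_start_day = 5,
                             tissue = "head",
                             class_weights = NULL,
                             turnover_classes = TURNOVER_CLASSES,
                             label_purity = 0.995,
                             noise_sigma = 0.1,
                             psm_depth = 10,
                             ub_site_density = 1,
                             ub_old_bias_beta = 3.72,
                             rng_seed = NULL) {
  if (is.null(rng_seed)) stop("rng_seed is mandatory")
  if (is.null(class_weights)) {
    if (!tissue %in% names(TISSUE_PRESETS)) {
      stop("no preset for tissue '", tissue, "'; supply class_weights")
    }
    class_weights <- TISSUE_PRESETS[[tissue]]
  }
  if (abs(sum(class_weights) - 1) > 1e-9) stop("class_weights must sum to 1")
  if (label_purity <= 0 || label_purity > 1) stop("label_purity must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (ub_old_bias_beta < 0) stop("ub_old_bias_beta must be >= 0")
  if (any(ages_days < chase_start_day)) {
    stop("all ages must be >= chase_start_day")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = peptides_per_protein,
    ages_days = ages_days,
    chase_start_day = chase_start_day,
    tissue = tissue,
    class_weights = class_weights,
    turnover_classes = turnover_classes,
    label_purity = label_purity,
    noise_sigma = noise_sigma,
    psm_depth = psm_depth,
    ub_site_density = ub_site_density,
    ub_old_bias_beta = ub_old_bias_beta,
    rng_seed = as.integer(rng_seed)
  ), class = "generator_config")
}

#' Old-pool fraction under first-order decay
#'
#' @param k per-day rate constant (>= 0).
#' @param age_days sampling age.
#' @param chase_start_day day of the diet switch (old fraction is 1 there).
#' @return exp(-k * (age - chase_start)).
#' @export
f_old <- function(k, age_days, chase_start_day = 5) {
  stopifnot(all(k >= 0), all(age_days >= chase_start_day))
  exp(-k * (age_days - chase_start_day))
}

#' Probability that a diGly PSM falls in the 15N channel
#'
#' Odds-multiplier bias model: with old fraction `f` and bias `beta`,
#' P(15N) = beta f / (beta f + (1 - f)); beta = 1 recovers unbiased sampling.
#' The degenerate case f = 1, beta = 0 is defined as 0.
#'
#' @param f old-pool fraction in [0, 1].
#' @param beta odds multiplier >= 0.
#' @export
ub_channel_probability <- function(f, beta) {
  stopifnot(all(f >= 0 & f <= 1), beta >= 0)
  num <- beta * f
  den <- beta * f + (1 - f)
  ifelse(den == 0, 0, num / den)
}

.random_tryptic_sequence <- function(len, k_at = NULL) {
  # tryptic-looking surrogate: no internal K/R, terminal K or R; optionally
  # force a K at position k_at (diGly carrier)
  inner <- c("A", "G", "S", "P", "V", "T", "L", "I", "N", "D", "Q", "E", "F", "Y")
  aa <- sample(inner, len - 1L, replace = TRUE)
  aa <- c(aa, sample(c("K", "R"), 1L))
  if (!is.null(k_at) && k_at < len) aa[k_at] <- "K"
  paste(aa, collapse = "")
}

#' Simulate a proteome with known turnover ground truth
#'
#' Draws per-protein abundances, turnover classes and rate constants, builds
#' surrogate tryptic peptides (with monoisotopic masses from the chemistry
#' layer), and places diGly sites. Deterministic given `config$rng_seed`.
#'
#' @param config a [generator_config()].
#' @return An object of class `simulated_proteome`: a list with `proteins`
#'   (id, abundance, class, k, length), `f_old` (protein x age matrix of true
#'   old fractions), `peptides`, `ub_sites`, and the `config`.
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$rng_seed)
  n <- config$n_proteins
  ages <- config$ages_days
  empty <- function() {
    structure(list(
      proteins = data.frame(protein_id = character(0), abundance = numeric(0),
                            class = character(0), k = numeric(0),
                            length = integer(0), stringsAsFactors = FALSE),
      f_old = matrix(numeric(0), 0, length(ages),
                     dimnames = list(NULL, as.character(ages))),
      peptides = data.frame(protein_id = character(0), peptide_id = character(0),
                            sequence = character(0), mass = numeric(0),
                            stringsAsFactors = FALSE),
      ub_sites = data.frame(protein_id = character(0), site = integer(0),
                            peptide_id = character(0), sequence = character(0),
                            peptide_start = integer(0), mod_pos = integer(0),
                            stringsAsFactors = FALSE),
      config = config), class = "simulated_proteome")
  }
  if (n == 0) return(empty())

  cls_tab <- config$turnover_classes
  cls <- sample(names(config$class_weights), n, replace = TRUE,
                prob = config$class_weights)
  ci <- match(cls, cls_tab$class)
  k <- stats::rlnorm(n, meanlog = cls_tab$meanlog[ci], sdlog = cls_tab$sdlog[ci])
  proteins <- data.frame(
    protein_id = sprintf("P%05d", seq_len(n)),
    abundance = stats::rlnorm(n, meanlog = log(1e6), sdlog = 0.8),
    class = cls,
    k = k,
    length = sample(200:800, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  fmat <- outer(k, ages, function(kk, t) f_old(kk, t, config$chase_start_day))
  dimnames(fmat) <- list(proteins$protein_id, as.character(ages))

  mean_pep <- max(config$peptides_per_protein, 1)
  n_pep <- 1L + stats::rpois(n, mean_pep - 1)
  pep_rows <- vector("list", n)
  ub_rows <- vector("list", n)
  for (i in seq_len(n)) {
    lens <- sample(8:20, n_pep[i], replace = TRUE)
    seqs <- vapply(lens, .random_tryptic_sequence, character(1))
    pep_rows[[i]] <- data.frame(
      protein_id = proteins$protein_id[i],
      peptide_id = sprintf("%s_pep%02d", proteins$protein_id[i], seq_len(n_pep[i])),
      sequence = seqs,
      mass = vapply(seqs, function(s) monoisotopic_mass(peptide(s)), numeric(1)),
      stringsAsFactors = FALSE
    )
    n_ub <- stats::rpois(1, config$ub_site_density)
    if (n_ub > 0) {
      plen <- proteins$length[i]
      sites <- sort(sample.int(plen - 1L, min(n_ub, plen - 1L)))
      ulen <- sample(8:20, length(sites), replace = TRUE)
      # diGly K sits strictly inside the peptide (trypsin does not cleave
      # after a modified K), so mod_pos < peptide length
      mod_pos <- vapply(ulen, function(l) sample.int(l - 1L, 1L), integer(1))
      useq <- mapply(.random_tryptic_sequence, ulen, mod_pos)
      start <- pmax(1L, sites - mod_pos + 1L)
      ub_rows[[i]] <- data.frame(
        protein_id = proteins$protein_id[i],
        site = start + mod_pos - 1L,
        peptide_id = sprintf("%s_ub%02d", proteins$protein_id[i], seq_along(sites)),
        sequence = useq,
        peptide_start = start,
        mod_pos = mod_pos,
        stringsAsFactors = FALSE
      )
    }
  }
  peptides <- do.call(rbind, pep_rows)
  ub_sites <- do.call(rbind, ub_rows[!vapply(ub_rows, is.null, logical(1))])
  if (is.null(ub_sites)) ub_sites <- empty()$ub_sites
  rownames(peptides) <- rownames(ub_sites) <- NULL
  structure(list(proteins = proteins, f_old = fmat, peptides = peptides,
                 ub_sites = ub_sites, config = config),
            class = "simulated_proteome")
}

#' @export
print.simulated_proteome <- function(x, ...) {
  cat("Simulated pulse-15N proteome (tissue:", x$config$tissue, ")\n")
  cat("  proteins:", nrow(x$proteins),
      " peptides:", nrow(x$peptides),
      " diGly sites:", nrow(x$ub_sites), "\n")
  cat("  ages (d):", paste(x$config$ages_days, collapse = ", "),
      " seed:", x$config$rng_seed, "\n")
  if (nrow(x$proteins) > 0) {
    cat("  class mix:", paste(names(table(x$proteins$class)),
                              as.integer(table(x$proteins$class)),
                              sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Simulate a paired light/heavy extracted ion chromatogram
#'
#' A shared Gaussian elution profile is split between the heavy (15N) and
#' light (14N) channels: the heavy trace carries the purity-adjusted old
#' fraction `f_old * purity`, the light trace the complement. Each scan of
#' each channel receives independent multiplicative log-normal noise. Uses
#' the current RNG stream (seed it upstream for reproducibility).
#'
#' @param fold true old-pool fraction in [0, 1].
#' @param intensity total elution-peak area scale.
#' @param noise_sigma log-scale s.d. of the per-scan noise.
#' @param purity heavy-channel label purity.
#' @param n_scans number of scan points (>= 7).
#' @return An [xic_pair()].
#' @export
simulate_xic_pair <- function(fold, intensity = 1e6, noise_sigma = 0.1,
                              purity = 1, n_scans = 11) {
  stopifnot(fold >= 0, fold <= 1, n_scans >= 7)
  times <- seq(0, 20, length.out = n_scans)
  profile <- exp(-((times - 10)^2) / (2 * 3^2))
  profile <- profile / sum(profile) * intensity
  f_adj <- fold * purity
  noise <- function() exp(stats::rnorm(n_scans, 0, noise_sigma))
  xic_pair(times,
           light = profile * (1 - f_adj) * noise(),
           heavy = profile * f_adj * noise())
}

.sample_channels <- function(n, p) {
  ifelse(stats::runif(n) < p, "15N", "14N")
}

#' Simulate diGly (ubiquitylome) PSM records
#'
#' For each diGly site and age, draws PSMs whose channel is 15N with the
#' odds-biased probability [ub_channel_probability()] applied to the
#' purity-adjusted old fraction. Uses the current RNG stream.
#'
#' @param proteome a [simulate_proteome()] result.
#' @param config the generator configuration (defaults to the proteome's).
#' @return Data frame of PSM records (schema of `psms.tsv`).
#' @export
simulate_ub_psms <- function(proteome, config = proteome$config) {
  stopifnot(inherits(proteome, "simulated_proteome"))
  sites <- proteome$ub_sites
  out <- list()
  rel_ab <- with(proteome$proteins,
                 stats::setNames(abundance / mean(abundance), protein_id))
  for (age in config$ages_days) {
    f <- proteome$f_old[sites$protein_id, as.character(age)] * config$label_purity
    p15 <- ub_channel_probability(f, config$ub_old_bias_beta)
    depth <- stats::rpois(nrow(sites),
                          config$psm_depth * rel_ab[sites$protein_id])
    for (i in seq_len(nrow(sites))) {
      if (depth[i] == 0) next
      ch <- .sample_channels(depth[i], p15[i])
      out[[length(out) + 1L]] <- data.frame(
        protein_id = sites$protein_id[i],
        peptide_id = sites$peptide_id[i],
        peptide_sequence = sites$sequence[i],
        charge = 2L,
        channel = ch,
        tissue = config$tissue,
        age_days = age,
        mod_positions = sprintf("%d:diGly:%.5f", sites$mod_pos[i], mod_delta("diGly")),
        peptide_start = sites$peptide_start[i],
        xic_id = sprintf("xic_%s_a%d", sites$peptide_id[i], age),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(psm_id = character(0), protein_id = character(0),
                      peptide_id = character(0), peptide_sequence = character(0),
                      charge = integer(0), channel = character(0),
                      tissue = character(0), age_days = numeric(0),
                      mod_positions = character(0), peptide_start = integer(0),
                      xic_id = character(0), stringsAsFactors = FALSE))
  }
  psms <- do.call(rbind, out)
  psms <- cbind(psm_id = sprintf("psm_ub_%06d", seq_len(nrow(psms))), psms,
                stringsAsFactors = FALSE)
  rownames(psms) <- NULL
  psms
}

#' Simulate a full pulse-15N experiment
#'
#' Orchestrates [simulate_proteome()], per-peptide-per-age XIC pairs and PSM
#' channel draws for the total proteome, and the diGly subset via
#' [simulate_ub_psms()] (whose XIC pairs carry the bias-shifted heavy share).
#' Fully deterministic given `config$rng_seed`.
#'
#' @param config a [generator_config()].
#' @return An object of class `simulated_experiment`: list with `proteome`,
#'   `psms` (total + diGly records), and `xics` (long table: xic_id,
#'   scan_time, light_intensity, heavy_intensity).
#' @export
simulate_experiment <- function(config) {
  proteome <- simulate_proteome(config)  # seeds the stream
  pep <- proteome$peptides
  prot <- proteome$proteins
  ab <- stats::setNames(prot$abundance, prot$protein_id)
  psm_rows <- list()
  xic_rows <- list()
  rel_ab <- ab / mean(ab)
  for (age in config$ages_days) {
    fvec <- proteome$f_old[pep$protein_id, as.character(age)]
    f_adj <- fvec * config$label_purity
    # sampling depth scales with protein abundance, so the aggregate channel
    # share converges to the abundance-weighted mean old fraction
    depth <- stats::rpois(nrow(pep), config$psm_depth * rel_ab[pep$protein_id])
    for (i in seq_len(nrow(pep))) {
      xid <- sprintf("xic_%s_a%d", pep$peptide_id[i], age)
      xp <- simulate_xic_pair(fvec[i], intensity = ab[[pep$protein_id[i]]],
                              noise_sigma = config$noise_sigma,
                              purity = config$label_purity)
      xic_rows[[length(xic_rows) + 1L]] <- data.frame(
        xic_id = xid, scan_time = xp$times,
        light_intensity = xp$light, heavy_intensity = xp$heavy,
        stringsAsFactors = FALSE
      )
      if (depth[i] > 0) {
        psm_rows[[length(psm_rows) + 1L]] <- data.frame(
          protein_id = pep$protein_id[i],
          peptide_id = pep$peptide_id[i],
          peptide_sequence = pep$sequence[i],
          charge = 2L,
          channel = .sample_channels(depth[i], f_adj[i]),
          tissue = config$tissue,
          age_days = age,
          mod_positions = "",
          peptide_start = NA_integer_,
          xic_id = xid,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  psms <- do.call(rbind, psm_rows)
  psms <- cbind(psm_id = sprintf("psm_%06d", seq_len(nrow(psms))), psms,
                stringsAsFactors = FALSE)
  ub_psms <- simulate_ub_psms(proteome, config)
  # one biased XIC pair per diGly peptide per age
  sites <- proteome$ub_sites
  for (age in config$ages_days) {
    if (nrow(sites) == 0) break
    f <- proteome$f_old[sites$protein_id, as.character(age)] * config$label_purity
    p15 <- ub_channel_probability(f, config$ub_old_bias_beta)
    for (i in seq_len(nrow(sites))) {
      xid <- sprintf("xic_%s_a%d", sites$peptide_id[i], age)
      xp <- simulate_xic_pair(p15[i], intensity = ab[[sites$protein_id[i]]] / 10,
                              noise_sigma = config$noise_sigma, purity = 1)
      xic_rows[[length(xic_rows) + 1L]] <- data.frame(
        xic_id = xid, scan_time = xp$times,
        light_intensity = xp$light, heavy_intensity = xp$heavy,
        stringsAsFactors = FALSE
      )
    }
  }
  xics <- do.call(rbind, xic_rows)
  rownames(psms) <- rownames(xics) <- NULL
  structure(list(proteome = proteome,
                 psms = rbind(psms, ub_psms),
                 xics = xics),
            class = "simulated_experiment")
}

#' Write a simulated experiment as a plain-text fixture
#'
#' Emits `psms.tsv`, `xics.tsv`, `truth.tsv` (protein_id, class, k, per-age
#' true old fraction, ub site count), `proteins.fasta` (surrogate peptide
#' sequences concatenated per protein) and `config.dcf`. Byte-identical
#' across runs with the same seed.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(experiment, dir) {
  stopifnot(inherits(experiment, "simulated_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pr <- experiment$proteome
  ages <- pr$config$ages_days
  truth <- data.frame(protein_id = pr$proteins$protein_id,
                      class = pr$proteins$class,
                      k = sprintf("%.8f", pr$proteins$k),
                      stringsAsFactors = FALSE)
  for (a in ages) {
    truth[[sprintf("f_old_%dd", a)]] <- sprintf("%.8f", pr$f_old[, as.character(a)])
  }
  truth$n_ub_sites <- as.integer(table(factor(pr$ub_sites$protein_id,
                                              levels = pr$proteins$protein_id)))
  paths <- c(
    psms = file.path(dir, "psms.tsv"),
    xics = file.path(dir, "xics.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.dcf")
  )
  xics <- experiment$xics
  xics$scan_time <- sprintf("%.4f", xics$scan_time)
  xics$light_intensity <- sprintf("%.6f", xics$light_intensity)
  xics$heavy_intensity <- sprintf("%.6f", xics$heavy_intensity)
  write_tsv_atomic(experiment$psms, paths[["psms"]])
  write_tsv_atomic(xics, paths[["xics"]])
  write_tsv_atomic(truth, paths[["truth"]])
  cfg <- pr$config
  scal <- vapply(cfg, function(x) paste(format(unlist(x), digits = 12), collapse = ","),
                 character(1))
  write.dcf(as.data.frame(t(scal), stringsAsFactors = FALSE), paths[["config"]])
  if (nrow(pr$peptides) > 0) {
    fa <- file.path(dir, "proteins.fasta")
    seqs <- vapply(split(pr$peptides$sequence, pr$peptides$protein_id),
                   paste, character(1), collapse = "")
    writeLines(paste0(">", names(seqs), "\n", seqs), fa)
    paths <- c(paths, fasta = fa)
  }
  invisible(paths)
}
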
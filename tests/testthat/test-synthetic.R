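test_that("first-order decay closed forms hold in the simulated truth", {
  expect_equal(f_old(0, 60), 1)
  expect_equal(f_old(log(10) / 55, 60), 0.1, tolerance = 1e-12)
  cfg <- generator_config(n_proteins = 40, rng_seed = 11)
  pr <- simulate_proteome(cfg)
  for (a in c(5, 30, 60)) {
    expect_equal(pr$f_old[, as.character(a)],
                 setNames(exp(-pr$proteins$k * (a - 5)), pr$proteins$protein_id))
  }
  expect_equal(unname(pr$f_old[, "5"]), rep(1, 40))
})

test_that("turnover classes land in their designed retention ranges", {
  cfg <- generator_config(n_proteins = 600, rng_seed = 5)
  pr <- simulate_proteome(cfg)
  f60 <- pr$f_old[, "60"]
  expect_gt(mean(f60[pr$proteins$class == "extreme"]), 0.7)
  expect_lt(mean(f60[pr$proteins$class == "fast"]), 0.1)
})

test_that("same seed gives identical proteomes and experiments", {
  cfg <- generator_config(n_proteins = 25, rng_seed = 123)
  expect_identical(simulate_proteome(cfg), simulate_proteome(cfg))
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$psms, e2$psms)
  expect_identical(e1$xics, e2$xics)
})

test_that("zero-protein config yields an empty proteome, not an error", {
  pr <- simulate_proteome(generator_config(n_proteins = 0, rng_seed = 1))
  expect_equal(nrow(pr$proteins), 0)
  expect_equal(nrow(pr$peptides), 0)
})

test_that("noiseless XIC pairs split area exactly by the old fraction", {
  set.seed(1)
  x <- simulate_xic_pair(0.5, noise_sigma = 0)
  expect_equal(sum(x$heavy), sum(x$light), tolerance = 1e-12)
  x2 <- simulate_xic_pair(2 / 3, noise_sigma = 0)
  expect_equal(sum(x2$heavy) / sum(x2$light), 2, tolerance = 1e-12)
  expect_gte(length(x$times), 7)
})

test_that("noisy XIC heavy share is unbiased around the generating value", {
  set.seed(42)
  shares <- replicate(1000, {
    x <- simulate_xic_pair(0.6, noise_sigma = 0.1)
    sum(x$heavy) / (sum(x$heavy) + sum(x$light))
  })
  expect_equal(mean(shares), 0.6, tolerance = 0.01)
})

test_that("ub channel probability follows the odds-bias formula", {
  expect_equal(ub_channel_probability(0.28, 3.72), 0.591, tolerance = 1e-3)
  expect_equal(ub_channel_probability(0.4, 1), 0.4)          # beta = 1 unbiased
  expect_equal(ub_channel_probability(0.5, 1e9), 1, tolerance = 1e-8)
  expect_equal(ub_channel_probability(1, 0), 0)              # degenerate case
})

test_that("beta = 1 ub-PSM heavy share matches the unbiased expectation", {
  cfg <- generator_config(n_proteins = 150, rng_seed = 9, ub_old_bias_beta = 1,
                          label_purity = 1, ub_site_density = 2)
  pr <- simulate_proteome(cfg)
  set.seed(77)
  psms <- simulate_ub_psms(pr, cfg)
  sub <- psms[psms$age_days == 60, ]
  share <- mean(sub$channel == "15N")
  # expectation: depth-weighted mean f_old over sites (depth ~ abundance)
  rel <- setNames(pr$proteins$abundance, pr$proteins$protein_id)
  f <- pr$f_old[pr$ub_sites$protein_id, "60"]
  w <- rel[pr$ub_sites$protein_id]
  expect_equal(share, sum(w * f) / sum(w), tolerance = 0.05)
})

test_that("with beta > 1 the ub heavy share exceeds the total-proteome share", {
  for (seed in 1:5) {
    cfg <- generator_config(n_proteins = 120, rng_seed = seed,
                            ub_old_bias_beta = 3.72)
    ex <- simulate_experiment(cfg)
    sub <- ex$psms[ex$psms$age_days == 60, ]
    tot <- psm_channel_proportions(sub, "total_proteome")
    ub <- psm_channel_proportions(sub, "ubiquitylome")
    expect_gt(ub$percent_15N, tot$percent_15N)
  }
})

test_that("fixtures round-trip and are byte-identical across runs", {
  cfg <- generator_config(n_proteins = 15, rng_seed = 321)
  ex <- simulate_experiment(cfg)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  p1 <- write_fixture(ex, d1)
  p2 <- write_fixture(simulate_experiment(cfg), d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]), label = nm)
  }
  psms <- read_psm_table(p1[["psms"]])
  expect_equal(nrow(psms), nrow(ex$psms))
  xics <- read_xic_table(p1[["xics"]])
  expect_equal(nrow(xics), nrow(ex$xics))
  # ground truth permits exact recomputation of f_old from k
  truth <- read.delim(p1[["truth"]])
  expect_equal(exp(-truth$k * 55), truth$f_old_60d, tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})
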
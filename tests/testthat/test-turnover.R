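test_that("LLP threshold is inclusive at the 10% boundary", {
  traj <- matrix(c(1, 1, 1, 0.5, 0.4, 0.3, 0.10, 0.099, 0.8),
                 ncol = 3, byrow = FALSE,
                 dimnames = list(c("A", "B", "C"), c("5", "30", "60")))
  flags <- classify_llp(traj)
  expect_equal(unname(flags), c(TRUE, FALSE, TRUE))
  expect_error(classify_llp(traj[, c("5", "30")]), "60d")
})

test_that("classify_llp is monotone in the threshold", {
  set.seed(4)
  traj <- matrix(runif(300), ncol = 3,
                 dimnames = list(NULL, c("5", "30", "60")))
  prev <- classify_llp(traj, 0)
  for (th in c(0.1, 0.3, 0.7, 1)) {
    cur <- classify_llp(traj, th)
    expect_true(all(prev | !cur))  # raising threshold never adds LLPs
    prev <- cur
  }
})

test_that("LLP flags agree with brute-force truth comparison on synthetic data", {
  cfg <- generator_config(n_proteins = 200, rng_seed = 31, noise_sigma = 0,
                          label_purity = 1)
  pr <- simulate_proteome(cfg)
  traj <- pr$f_old
  flags <- classify_llp(traj)
  brute <- vapply(rownames(traj), function(id) traj[id, "60"] >= 0.10, logical(1))
  expect_identical(flags, brute)
})

test_that("llp_summary reproduces printed percentages with half-up rounding", {
  mk <- function(n_llp, n_total) c(rep(TRUE, n_llp), rep(FALSE, n_total - n_llp))
  expect_equal(llp_summary(mk(1715, 3074))$percentage, 55.8)
  expect_equal(llp_summary(mk(1502, 1903))$percentage, 78.9)
  expect_equal(llp_summary(mk(928, 3034))$percentage, 30.6)
  expect_equal(llp_summary(mk(1, 400))$percentage, 0.3)  # 0.25 rounds half-up
  expect_error(llp_summary(logical(0)), "no LLP flags")
})

test_that("FCM memberships are simplex rows and the objective never increases", {
  set.seed(12)
  x <- matrix(runif(240), ncol = 3, dimnames = list(NULL, c("5", "30", "60")))
  fit <- fcm_cluster(x, c = 4, seed = 2)
  expect_equal(rowSums(fit$membership), rep(1, nrow(x)), tolerance = 1e-9)
  expect_true(all(diff(fit$objective) <= 1e-10))
  expect_true(all(fit$centers >= apply(x, 2, min) - 1e-9 &
                  fit$centers <= apply(x, 2, max) + 1e-9))
  expect_identical(fit, fcm_cluster(x, c = 4, seed = 2))  # bit-identical rerun
})

test_that("FCM recovers well-separated groups and matches a k-means oracle", {
  set.seed(21)
  centers <- rbind(c(0.95, 0.9, 0.85), c(0.95, 0.5, 0.3), c(0.95, 0.1, 0.01))
  g <- rep(1:3, each = 40)
  x <- centers[g, ] + matrix(rnorm(360, 0, 0.01), ncol = 3)
  x <- pmin(pmax(x, 0), 1)
  colnames(x) <- c("5", "30", "60")
  fit <- fcm_cluster(x, c = 3, seed = 5)
  expect_true(same_partition(fit$cluster, g))
  for (j in 1:3) {
    grp <- which(fit$cluster == j)
    truth_grp <- unique(g[grp])
    expect_equal(unname(fit$centers[j, ]), unname(colMeans(x[g == truth_grp, ])),
                 tolerance = 1e-3)
  }
  km <- kmeans(x, centers = 3, nstart = 20)
  expect_true(same_partition(fit$cluster, km$cluster))
})

test_that("FCM agrees with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(33)
  x <- matrix(runif(150), ncol = 3)
  fit <- fcm_cluster(x, c = 3, seed = 14, n_restarts = 8)
  ref <- e1071::cmeans(x, centers = 3, m = 2, iter.max = 300)
  # same optimum up to label permutation: compare sorted centers and objective
  expect_equal(sort(as.numeric(fit$centers)), sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
  # e1071 reports the objective scaled by n
  expect_equal(utils::tail(fit$objective, 1), ref$withinerror * nrow(x),
               tolerance = 1e-4)
})

test_that("a point coincident with a center gets full membership there", {
  x <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1), c(0.5, 0.5, 0.5))
  colnames(x) <- c("5", "30", "60")
  fit <- fcm_cluster(x, c = 2, seed = 3)
  # duplicated extreme points coincide with their converged centers
  i <- which.max(fit$membership[1, ])
  expect_gt(fit$membership[1, i], 0.99)
  expect_error(fcm_cluster(rbind(x[1, ], x[1, ], x[1, ]), c = 2, seed = 1),
               "distinct")
})

test_that("ELLP selection takes the slowest cluster with a strict 0.70 floor", {
  traj <- rbind(
    E1 = c(1, 0.9, 0.85), E2 = c(1, 0.88, 0.80), E3 = c(1, 0.87, 0.71),
    E4 = c(1, 0.86, 0.70),   # exactly at floor: excluded
    M1 = c(1, 0.5, 0.3), M2 = c(1, 0.45, 0.28), M3 = c(1, 0.5, 0.33),
    F1 = c(1, 0.1, 0.01), F2 = c(1, 0.12, 0.02), F3 = c(1, 0.09, 0.015)
  )
  colnames(traj) <- c("5", "30", "60")
  fit <- fcm_cluster(traj, c = 3, seed = 7)
  ellp <- identify_ellp(fit, traj)
  expect_setequal(as.character(ellp), c("E1", "E2", "E3"))
  expect_false("E4" %in% ellp)
  # the selected cluster is the one with maximal 60d center
  expect_equal(attr(ellp, "slow_cluster"), unname(which.max(fit$centers[, "60"])))
})

test_that("ELLP recovery against generator truth is exact without noise", {
  cfg <- generator_config(n_proteins = 300, rng_seed = 17, noise_sigma = 0,
                          label_purity = 1)
  pr <- simulate_proteome(cfg)
  traj <- pr$f_old
  fit <- fcm_cluster(traj, c = 3, seed = 17)
  ellp <- identify_ellp(fit, traj)
  truth <- pr$proteins$protein_id[pr$proteins$class == "extreme"]
  expect_setequal(as.character(ellp), truth)
})

test_that("cross-tissue overlap enumerates every Venn region", {
  sets <- list(head = c("A", "B", "C"), muscle = c("B", "C", "D"),
               testis = "C")
  ov <- cross_tissue_overlap(sets)
  get <- function(region, col) ov[ov$region == region, col]
  expect_equal(get("head&muscle&testis", "intersection_count"), 1)
  expect_equal(get("head&muscle&testis", "exclusive_count"), 1)
  expect_equal(get("head&muscle", "intersection_count"), 2)
  expect_equal(get("head&muscle", "exclusive_count"), 1)  # B only
  expect_equal(get("head", "exclusive_count"), 1)         # A only
  # disjoint and identical set sanity
  dis <- cross_tissue_overlap(list(a = c("x", "y"), b = c("z")))
  expect_equal(dis[dis$region == "a&b", "intersection_count"], 0)
  same <- cross_tissue_overlap(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(same[same$region == "a&b", "intersection_count"], 2)
})
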
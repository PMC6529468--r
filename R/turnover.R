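# LLP/ELLP classification from 15N% trajectories.
#
# A long-lived protein (LLP) retains at least 10% of its heavy-labeled form
# at day 60 of the chase; extremely long-lived proteins (ELLPs) are the
# slowest-turnover trajectory cluster (fuzzy c-means) restricted to proteins
# individually retaining more than 70% at day 60.

#' Build a complete trajectory matrix from protein-turnover records
#'
#' Keeps only proteins quantified at every requested age (trajectory
#' clustering needs complete rows).
#'
#' @param turnover data frame from [rollup_protein()]/[quantify_psms()].
#' @param ages ages (days) forming the columns, default c(5, 30, 60).
#' @return Numeric matrix, rows = protein ids, columns = ages as characters;
#'   `tissue` attribute carries the (single) tissue tag.
#' @export
trajectory_matrix <- function(turnover, ages = c(5, 30, 60)) {
  stopifnot(all(c("protein_id", "age_days", "n15_pct") %in% names(turnover)))
  tis <- unique(turnover$tissue)
  if (length(tis) > 1) stop("trajectory_matrix expects a single tissue; got: ",
                            paste(tis, collapse = ", "))
  sub <- turnover[turnover$age_days %in% ages, , drop = FALSE]
  wide <- stats::reshape(sub[, c("protein_id", "age_days", "n15_pct")],
                         idvar = "protein_id", timevar = "age_days",
                         direction = "wide")
  cols <- paste0("n15_pct.", ages)
  missing_cols <- setdiff(cols, names(wide))
  if (length(missing_cols) > 0) {
    stop("no quantifications at age(s): ",
         paste(sub("n15_pct\\.", "", missing_cols), collapse = ", "))
  }
  wide <- wide[stats::complete.cases(wide[, cols]), , drop = FALSE]
  m <- as.matrix(wide[, cols])
  dimnames(m) <- list(wide$protein_id, as.character(ages))
  if (any(m < 0 | m > 1)) stop("15N proportions must lie in [0, 1]")
  attr(m, "tissue") <- if (length(tis)) tis else NA_character_
  m
}

#' Classify long-lived proteins by 60-day 15N retention
#'
#' LLP if and only if the 60 d 15N proportion is at least `threshold`
#' (inclusive).
#'
#' @param traj trajectory matrix (see [trajectory_matrix()]) or any numeric
#'   matrix with a `"60"` column of fractions.
#' @param threshold retention threshold, default 0.10.
#' @return Named logical vector of LLP flags.
#' @export
classify_llp <- function(traj, threshold = 0.10) {
  if (!"60" %in% colnames(traj)) stop("60d column required for LLP classification")
  stopifnot(threshold >= 0, threshold <= 1)
  stats::setNames(traj[, "60"] >= threshold, rownames(traj))
}

.round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize LLP flags as a count and percentage
#'
#' @param flags logical vector of LLP flags (non-empty).
#' @return List with `n_llp`, `n_total`, and `percentage` (half-up rounded to
#'   one decimal, e.g. 1715/3074 -> 55.8).
#' @export
llp_summary <- function(flags) {
  if (length(flags) == 0) stop("no LLP flags supplied")
  stopifnot(is.logical(flags), !anyNA(flags))
  n <- sum(flags)
  list(n_llp = n, n_total = length(flags),
       percentage = .round_half_up(100 * n / length(flags), 1))
}

#' Fuzzy c-means clustering of turnover trajectories
#'
#' Standard alternating-optimization FCM: memberships
#' u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)), centers as the u^m-weighted
#' means. The objective sum_ij u_ij^m d_ij^2 is non-increasing across
#' iterations; a point coincident with a center gets full membership there
#' (split equally over all coincident centers). Random membership
#' initialization from the seeded RNG; the best of `n_restarts` restarts (by
#' final objective) is returned, so the result is deterministic given `seed`.
#'
#' @param x numeric matrix (rows = proteins, columns = ages).
#' @param c number of clusters (>= 2; fewer than the number of distinct rows).
#' @param m fuzzifier (> 1), default 2.
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter iteration cap per restart.
#' @param seed integer RNG seed (mandatory).
#' @param n_restarts random restarts, default 5.
#' @return Object of class `fcm`: list with `membership` (rows sum to 1),
#'   `centers`, `cluster` (hard argmax assignment, ties to the lowest
#'   index), `objective` (per-iteration trace of the kept restart),
#'   `n_iterations`, `converged`, `m`, `seed`.
#' @export
fcm_cluster <- function(x, c = 4, m = 2, tol = 1e-6, max_iter = 200,
                        seed, n_restarts = 5) {
  x <- as.matrix(x)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (c < 2) stop("need at least 2 clusters")
  if (m <= 1) stop("fuzzifier m must be > 1")
  n_distinct <- nrow(unique(x))
  if (n_distinct < c) {
    stop("fewer distinct points (", n_distinct, ") than clusters (", c, ")")
  }
  n <- nrow(x)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    U <- matrix(stats::runif(n * c), n, c)
    U <- U / rowSums(U)
    obj_trace <- numeric(0)
    centers_prev <- NULL
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      Um <- U^m
      centers <- sweep(crossprod(Um, x), 1, colSums(Um), "/")
      D <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
        outer(rep(1, n), rowSums(centers^2))
      D[D < 0] <- 0  # numerical floor on squared distances
      zero <- D < 1e-300
      inv <- (1 / pmax(D, 1e-300))^(1 / (m - 1))
      U <- inv / rowSums(inv)
      hit <- rowSums(zero) > 0
      if (any(hit)) {
        U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
      }
      obj_trace <- c(obj_trace, sum(U^m * D))
      if (!is.null(centers_prev) &&
          max(abs(centers - centers_prev)) < tol) {
        converged <- TRUE
        break
      }
      centers_prev <- centers
    }
    fit <- list(membership = U, centers = centers, objective = obj_trace,
                n_iterations = iter, converged = converged)
    if (is.null(best) || utils::tail(obj_trace, 1) < utils::tail(best$objective, 1)) {
      best <- fit
    }
  }
  hard <- apply(best$membership, 1, which.max)  # ties -> lowest index
  colnames(best$centers) <- colnames(x)
  rownames(best$membership) <- rownames(x)
  structure(c(best, list(cluster = stats::setNames(hard, rownames(x)),
                         m = m, c = c, seed = as.integer(seed))),
            class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat("Fuzzy c-means fit:", x$c, "clusters, fuzzifier m =", x$m, "\n")
  cat("  n =", nrow(x$membership), " iterations =", x$n_iterations,
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  cat("  final objective:", format(utils::tail(x$objective, 1), digits = 6), "\n")
  cat("  centers:\n")
  print(round(x$centers, 4))
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$c), collapse = ", "), "\n")
  invisible(x)
}

#' Identify extremely long-lived proteins from an FCM fit
#'
#' Selects the cluster whose center has the highest 60 d 15N proportion (the
#' slowest-turnover cluster) and returns the proteins hard-assigned to it
#' whose own 60 d retention strictly exceeds `retention_floor`.
#'
#' @param fcm an [fcm_cluster()] result fitted on `traj`.
#' @param traj the trajectory matrix the fit was computed on.
#' @param retention_floor individual 60 d retention floor (strict), default 0.70.
#' @return Character vector of ELLP protein ids; the selected cluster index
#'   is attached as attribute `slow_cluster`.
#' @export
identify_ellp <- function(fcm, traj, retention_floor = 0.70) {
  stopifnot(inherits(fcm, "fcm"), "60" %in% colnames(traj))
  slow <- which.max(fcm$centers[, "60"])
  ids <- rownames(traj)[fcm$cluster == slow & traj[, "60"] > retention_floor]
  structure(ids, slow_cluster = unname(slow))
}

#' Cross-tissue overlap of protein sets
#'
#' Counts every region of the Venn partition over the named sets (exact
#' string comparison of identifiers), plus the plain intersection count of
#' each combination.
#'
#' @param sets named list (>= 2) of character vectors of protein ids.
#' @return Data frame with `region` (set names joined by `&`),
#'   `exclusive_count` (ids in exactly those sets) and `intersection_count`
#'   (ids in at least those sets).
#' @export
cross_tissue_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nm))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(nm)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- as.logical(combos[i, ])
    region <- paste(nm[inc], collapse = "&")
    excl <- sum(apply(member, 1, function(r) all(r == inc)))
    inter <- sum(apply(member[, inc, drop = FALSE], 1, all))
    data.frame(region = region, exclusive_count = excl,
               intersection_count = inter, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(nchar(out$region), out$region), , drop = FALSE]
}
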
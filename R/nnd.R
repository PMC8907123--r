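#' Nearest-neighbour distance statistics
#'
#' For each particle, the Euclidean distance to its nearest other particle
#' in the same pattern; the mean NND is the field's standard index of local
#' density (smaller than the CSR expectation indicates clustering). No edge
#' correction is applied: the Monte-Carlo null ([csr_null()]) is generated in
#' the same window with the same particle count, so boundary bias cancels in
#' the paired comparison.
#'
#' The reported `sd` is the sample standard deviation (n - 1 denominator)
#' over per-particle NNDs — the convention used by the mean-NND + 2SD
#' epsilon rule ([resolve_epsilon()]).
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @return an object of class `nnd_stats`: `per_point_nnd` (nm), `mean`,
#'   `sd`, `n`.
#' @examples
#' w <- rect_window(1000)
#' mean_nnd(point_pattern(c(0, 100, 300), c(0, 0, 0), w))$mean  # 133.33 nm
#' @export
mean_nnd <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- npoints(pattern)
  if (n < 2)
    stop("mean_nnd needs at least 2 points", call. = FALSE)
  d <- nnd_vector(coords(pattern))
  structure(list(per_point_nnd = d, mean = mean(d), sd = stats::sd(d),
                 n = n), class = "nnd_stats")
}

#' @export
print.nnd_stats <- function(x, ...) {
  cat(sprintf("nnd_stats: n = %d, mean = %.2f nm, sd = %.2f nm\n",
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Monte-Carlo CSR null for one pattern
#'
#' Simulates `n_sims` CSR patterns with the observed point count in the
#' observed window and records each simulation's mean NND and (optionally)
#' its scalar g(r) summary ([g_summary()]). The observed pattern's statistics
#' are recorded alongside for convenience.
#'
#' @param pattern a [point_pattern()] with >= 2 points.
#' @param n_sims number of simulations (default 200).
#' @param seed integer seed.
#' @param statistics which statistics to record: any of `"nnd"`, `"g"`.
#'   Dropping `"g"` makes large calibration runs much cheaper.
#' @param r_min,r_max,bandwidth g(r) summary parameters (nm), see
#'   [g_summary()].
#' @return an object of class `mc_null`: `n_sims`, `per_sim_mean_nnd`,
#'   `per_sim_mean_g` (or `NULL`), `observed_mean_nnd`, `observed_mean_g`,
#'   `seed`.
#' @export
csr_null <- function(pattern, n_sims = 200L, seed = NULL,
                     statistics = c("nnd", "g"),
                     r_min = 10, r_max = 50, bandwidth = 5) {
  stopifnot(inherits(pattern, "point_pattern"), n_sims >= 1)
  statistics <- match.arg(statistics, several.ok = TRUE)
  n <- npoints(pattern)
  if (n < 2)
    stop("csr_null needs at least 2 points", call. = FALSE)
  want_g <- "g" %in% statistics
  obs_nnd <- mean_nnd(pattern)$mean
  obs_g <- if (want_g) g_summary(pattern, r_min, r_max, bandwidth) else NULL
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(i) {
      xy <- runif_in_window(n, pattern$window)
      g <- if (want_g) {
        sim <- point_pattern(xy[, 1], xy[, 2], pattern$window, check = FALSE)
        g_summary(sim, r_min, r_max, bandwidth)
      } else NA_real_
      c(mean(nnd_vector(xy)), g)
    }, numeric(2))
  })
  structure(list(n_sims = as.integer(n_sims),
                 per_sim_mean_nnd = sims[1, ],
                 per_sim_mean_g = if (want_g) sims[2, ] else NULL,
                 observed_mean_nnd = obs_nnd,
                 observed_mean_g = obs_g,
                 seed = seed),
            class = "mc_null")
}

#' @export
print.mc_null <- function(x, ...) {
  cat(sprintf("mc_null: %d sims; observed mean NND %.2f nm vs null %.2f nm\n",
              x$n_sims, x$observed_mean_nnd, mean(x$per_sim_mean_nnd)))
  invisible(x)
}

#' Paired Monte-Carlo test for clustering across active zones
#'
#' For every AZ pattern with at least `min_points` particles, pairs the real
#' statistic (mean NND, and optionally the scalar g(r) summary) with the
#' mean of that AZ's own `n_sims`-simulation CSR null, then applies a
#' two-sided paired t-test across AZs. Clustered channels show a
#' significantly smaller real mean NND and a larger real mean g than the
#' null. Each AZ draws its null from a substream keyed on (seed, region_id),
#' so results do not depend on dataset ordering.
#'
#' @param dataset a [replica_dataset()] (only `region_class == "AZ"`
#'   patterns are used) or a list of [point_pattern()]s.
#' @param n_sims simulations per AZ (default 200).
#' @param seed master integer seed.
#' @param statistics any of `"nnd"`, `"g"`.
#' @param r_min,r_max,bandwidth g(r) summary parameters (nm).
#' @param min_points AZs with fewer particles are excluded (>= 2 required
#'   for NND).
#' @return a list of `paired_test_result` objects (one per statistic), each
#'   with `statistic`, `n_az`, `real`, `null`, `mean_real`, `mean_null`,
#'   `t`, `p`.
#' @export
paired_nnd_test <- function(dataset, n_sims = 200L, seed = NULL,
                            statistics = c("nnd", "g"),
                            r_min = 10, r_max = 50, bandwidth = 5,
                            min_points = 2L) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  pats <- if (inherits(dataset, "replica_dataset"))
    patterns_by_class(dataset, "AZ") else dataset
  stopifnot(all(vapply(pats, inherits, TRUE, "point_pattern")))
  pats <- Filter(function(p) npoints(p) >= max(2L, min_points), pats)
  if (length(pats) < 2)
    stop("paired test needs at least 2 AZs with enough particles",
         call. = FALSE)
  nulls <- lapply(pats, function(p)
    csr_null(p, n_sims = n_sims,
             seed = if (is.null(seed)) NULL
                    else substream_seed(seed, p$window$region_id),
             statistics = statistics,
             r_min = r_min, r_max = r_max, bandwidth = bandwidth))
  out <- list()
  for (s in statistics) {
    real <- vapply(nulls, function(z)
      if (s == "nnd") z$observed_mean_nnd else z$observed_mean_g, 0)
    null <- vapply(nulls, function(z)
      mean(if (s == "nnd") z$per_sim_mean_nnd else z$per_sim_mean_g), 0)
    tt <- stats::t.test(real, null, paired = TRUE)
    out[[s]] <- structure(
      list(statistic = s, n_az = length(pats), real = real, null = null,
           mean_real = mean(real), mean_null = mean(null),
           t = unname(tt$statistic), p = tt$p.value),
      class = "paired_test_result")
  }
  out
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "paired %s test: n = %d AZs, real %.3f vs null %.3f, t = %.2f, p = %.3g\n",
    x$statistic, x$n_az, x$mean_real, x$mean_null, x$t, x$p))
  invisible(x)
}
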
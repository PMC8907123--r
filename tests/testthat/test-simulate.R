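test_that("generators are seed-deterministic and leave the RNG untouched", {
  w <- unit_um_window()
  set.seed(999)
  before <- .Random.seed
  a <- simulate_csr(w, 50, seed = 7)
  expect_identical(.Random.seed, before)  # caller's stream untouched
  b <- simulate_csr(w, 50, seed = 7)
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(simulate_csr(w, 50, seed = 8))))
  c1 <- simulate_clustered(w, 4, 10, 15, seed = 3)
  c2 <- simulate_clustered(w, 4, 10, 15, seed = 3)
  expect_identical(coords(c1), coords(c2))
  s1 <- simulate_topography(w, "perimeter_release", seed = 5)
  s2 <- simulate_topography(w, "perimeter_release", seed = 5)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$vesicles, s2$vesicles)
})

test_that("CSR is uniform: empty case, quadrant counts, chi-square sweep", {
  w <- unit_um_window()
  expect_equal(npoints(simulate_csr(w, 0, seed = 1)), 0L)

  p <- simulate_csr(w, 10000, seed = 42)
  q <- table(cut(p$x, c(0, 500, 1000), include.lowest = TRUE),
             cut(p$y, c(0, 500, 1000), include.lowest = TRUE))
  expect_true(all(abs(q - 2500) / 2500 < 0.05))

  # 4x4-grid chi-square uniformity at alpha = 0.01 across seeds
  pass <- vapply(1:50, function(s) {
    pp <- simulate_csr(w, 320, seed = s)
    cnt <- table(cut(pp$x, seq(0, 1000, 250), include.lowest = TRUE),
                 cut(pp$y, seq(0, 1000, 250), include.lowest = TRUE))
    stats::chisq.test(as.vector(cnt))$p.value >= 0.01
  }, TRUE)
  expect_gte(mean(pass), 0.95)
})

test_that("CSR respects non-rectangular windows", {
  w <- disc_window(500, n_vertices = 64)
  p <- simulate_csr(w, 2000, seed = 9)
  expect_true(all(p$x^2 + p$y^2 <= 500^2 * 1.001))
  # mean radius of uniform points in a disc is 2R/3
  expect_equal(mean(sqrt(p$x^2 + p$y^2)), 2 * 500 / 3, tolerance = 0.03)
})

test_that("clustered patterns are tight in the single-parent limit", {
  w <- rect_window(500, centre = c(250, 250))
  p <- simulate_clustered(w, 1, 20, 10, seed = 31)
  expect_gte(npoints(p), 10)
  s <- mean_nnd(p)
  # CSR expectation for the same n in this window: 1/(2 sqrt(lambda))
  csr_expect <- 1 / (2 * sqrt(npoints(p) / polygon_area(w)))
  expect_lt(s$mean, csr_expect / 2)
  expect_equal(length(attr(p, "parent")), npoints(p))
  expect_true(all(attr(p, "parent") == 1L))
})

test_that("increasing cluster spread monotonically increases mean NND", {
  w <- unit_um_window()
  spreads <- c(5, 10, 20, 40, 80, 160)
  mean_for_spread <- function(sd_nm) {
    mean(vapply(1:20, function(s) {
      p <- simulate_clustered(w, 4, 10, sd_nm, seed = 700 + s)
      if (npoints(p) < 2) return(NA_real_)
      mean_nnd(p)$mean
    }, 0), na.rm = TRUE)
  }
  m <- vapply(spreads, mean_for_spread, 0)
  expect_gt(stats::cor(spreads, m, method = "spearman"), 0.9)
})

test_that("very diffuse clusters are indistinguishable from CSR", {
  w <- unit_um_window()
  # spread on the order of the window: the mean-NND MC test should not
  # reject more often than its nominal level (checked loosely over seeds)
  rej <- vapply(1:20, function(s) {
    p <- simulate_clustered(w, 4, 10, 1500, seed = 50 + s)
    if (npoints(p) < 5) return(NA)
    null <- csr_null(p, n_sims = 99, seed = 1000 + s, statistics = "nnd")
    mean(null$per_sim_mean_nnd <= null$observed_mean_nnd) < 0.025
  }, TRUE)
  expect_lte(mean(rej, na.rm = TRUE), 0.2)
})

test_that("topography scenes satisfy their geometric constraints", {
  w <- unit_um_window()
  # exclusion zone: every channel >= 50 nm from every vesicle centre
  sc <- simulate_topography(w, "exclusion_zone",
                            params = list(n_channels = 60, n_vesicles = 8),
                            seed = 2)
  dmin <- min(sqrt(outer(sc$channels[, 1], sc$vesicles[, 1], "-")^2 +
                     outer(sc$channels[, 2], sc$vesicles[, 2], "-")^2))
  expect_gte(dmin, 50)

  # one-to-one: bijection between vesicles and distinct clusters
  sc2 <- simulate_topography(w, "one_to_one",
                             params = list(n_clusters = 3, n_vesicles = 3),
                             seed = 3)
  expect_equal(sort(sc2$vesicle_cluster), 1:3)
  expect_error(simulate_topography(w, "one_to_one",
                                   params = list(n_clusters = 2,
                                                 n_vesicles = 3), seed = 1),
               "n_vesicles <= n_clusters")

  # perimeter release: vesicles sit at the dilated hull of their cluster
  sc3 <- simulate_topography(w, "perimeter_release",
                             params = list(n_clusters = 3, n_vesicles = 6,
                                           offset_nm = 10), seed = 4)
  for (v in seq_len(nrow(sc3$vesicles))) {
    ch <- sc3$channels[sc3$channel_cluster == sc3$vesicle_cluster[v], ,
                       drop = FALSE]
    gap <- min(sqrt((ch[, 1] - sc3$vesicles[v, 1])^2 +
                      (ch[, 2] - sc3$vesicles[v, 2])^2))
    expect_gte(gap, 5)     # outside the cluster by roughly the offset
    expect_lte(gap, 150)   # but tethered to it
  }

  # infeasible exclusion constraint errors out
  small <- rect_window(80, centre = c(40, 40))
  expect_error(simulate_topography(small, "exclusion_zone",
                                   params = list(n_channels = 5,
                                                 n_vesicles = 40,
                                                 exclusion_radius_nm = 60,
                                                 max_retries = 50), seed = 1),
               "saturated")
})

test_that("random-model vesicle distances match an independent CSR oracle", {
  w <- unit_um_window()
  sc <- simulate_topography(w, "random",
                            params = list(n_channels = 10000, n_vesicles = 5),
                            seed = 12)
  nearest_v <- function(ch, ves) {
    apply(sqrt(outer(ch[, 1], ves[, 1], "-")^2 +
                 outer(ch[, 2], ves[, 2], "-")^2), 1, min)
  }
  d_pkg <- nearest_v(sc$channels, sc$vesicles)
  # oracle: direct uniform draws in the same window with the same vesicles
  withr::with_seed(999, {
    ch0 <- cbind(runif(10000, 0, 1000), runif(10000, 0, 1000))
  })
  d_orc <- nearest_v(ch0, sc$vesicles)
  ks <- suppressWarnings(stats::ks.test(d_pkg, d_orc))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("virtual labeling thins, jitters and adds background correctly", {
  w <- unit_um_window()
  truth <- simulate_csr(w, 500, seed = 21)
  # identity case
  out <- virtual_labeling(truth, labeling_config(), seed = 1)
  expect_identical(coords(out), coords(truth))
  expect_true(all(!attr(out, "is_background")))

  # binomial thinning at the calibrated efficiency
  big <- simulate_csr(w, 10000, seed = 22)
  fracs <- vapply(1:200, function(s)
    npoints(virtual_labeling(big, labeling_config(efficiency = 0.64),
                             seed = s)) / 10000, 0)
  expect_equal(mean(fracs), 0.64, tolerance = 0.01 / 0.64)

  # Poisson background alone: 0.84 /um^2 over 75.5 um^2 -> mean 63.4
  wide <- rect_window(sqrt(75.5) * 1000, centre = c(0, 0),
                      region_id = "extra", region_class = "extra_AZ")
  empty <- point_pattern(numeric(0), numeric(0), wide)
  counts <- vapply(1:100, function(s)
    npoints(virtual_labeling(empty,
                             labeling_config(background_rate = 0.84),
                             seed = s)), 0L)
  expect_equal(mean(counts), 0.84 * 75.5, tolerance = 0.05)

  # aggregation clumps replace background singles
  agg <- labeling_config(background_rate = 2,
                         aggregation = list(clump_count = 4, clump_size = 5,
                                            clump_spread = 15))
  bg <- virtual_labeling(empty, agg, seed = 5)
  expect_gte(npoints(bg), 20)
  cl <- detect_clusters(bg, cluster_config(epsilon_rule = "fixed",
                                           epsilon_nm = 100))
  expect_gte(cl$n_clusters, 2)
})
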
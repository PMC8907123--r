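test_that("epsilon resolution follows the mean NND + 2 SD rule", {
  w <- unit_um_window()
  # equilateral triangle, side 10: all NNDs are 10, sd 0
  tri <- point_pattern(c(500, 510, 505), c(500, 500, 500 + 10 * sqrt(3) / 2), w)
  expect_equal(resolve_epsilon(tri), 10, tolerance = 1e-12)

  # collinear 0, 100, 300: NNDs (100, 100, 200), sample sd (n-1)
  col3 <- point_pattern(c(100, 200, 400), c(500, 500, 500), w)
  eps <- resolve_epsilon(col3)
  expect_equal(eps, 400 / 3 + 2 * sd(c(100, 100, 200)))
  expect_equal(eps, 248.8034, tolerance = 1e-6)

  cfg_fixed <- cluster_config(epsilon_rule = "fixed", epsilon_nm = 100)
  expect_equal(resolve_epsilon(col3, cfg_fixed), 100)
  expect_error(resolve_epsilon(point_pattern(1, 1, w)), "at least 2")
  expect_error(cluster_config(epsilon_rule = "fixed", epsilon_nm = -1),
               "positive")

  # pooled epsilon uses all per-particle NNDs of the dataset
  ds <- csr_dataset(n_az = 4, n = 20, seed = 60)
  all_nnd <- unlist(lapply(ds$patterns, function(p)
    mean_nnd(p)$per_point_nnd))
  expect_equal(pooled_epsilon(ds), mean(all_nnd) + 2 * sd(all_nnd))
})

test_that("DBSCAN handles the textbook small cases", {
  w <- unit_um_window()
  cfg <- cluster_config(min_points = 3, epsilon_rule = "fixed",
                        epsilon_nm = 50)
  # 3 points pairwise within eps -> one cluster, no noise
  p3 <- point_pattern(c(500, 530, 515), c(500, 500, 520), w)
  r3 <- dbscan_cluster(p3, cfg)
  expect_equal(r3$n_clusters, 1L)
  expect_equal(r3$labels, c(1L, 1L, 1L))
  expect_equal(r3$particles_per_cluster, 3L)

  # two isolated points -> all noise
  p2 <- point_pattern(c(100, 900), c(100, 900), w)
  r2 <- dbscan_cluster(p2, cfg)
  expect_equal(r2$labels, c(-1L, -1L))
  expect_equal(r2$n_clusters, 0L)

  # n < min_points -> all noise even if close together
  p2b <- point_pattern(c(500, 510), c(500, 500), w)
  expect_equal(dbscan_cluster(p2b, cfg)$labels, c(-1L, -1L))

  # the point itself counts towards min_points: a chain of 3 at eps spacing
  chain <- point_pattern(c(500, 540, 580), c(500, 500, 500), w)
  rc <- dbscan_cluster(chain, cfg)
  expect_equal(rc$n_clusters, 1L)
  expect_equal(sum(rc$labels == 1L), 3L)
})

test_that("DBSCAN agrees with a brute-force reachability oracle", {
  w <- unit_um_window()
  withr::with_seed(71, {
    for (rep in 1:50) {
      n <- sample(4:30, 1)
      xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
      # mix of diffuse and locally condensed configurations
      if (rep %% 2 == 0) {
        k <- sample(2:4, 1)
        ctr <- xy[seq_len(k), , drop = FALSE]
        xy <- ctr[sample(k, n, replace = TRUE), ] + matrix(rnorm(2 * n, 0, 40), ncol = 2)
        xy <- pmin(pmax(xy, 0), 1000)
      }
      eps <- runif(1, 30, 150)
      min_pts <- sample(2:4, 1)
      p <- point_pattern(xy[, 1], xy[, 2], w)
      got <- dbscan_cluster(p, cluster_config(min_points = min_pts,
                                              epsilon_rule = "fixed",
                                              epsilon_nm = eps))
      expect_same_partition(got$labels, oracle_dbscan(xy, eps, min_pts))
      # conservation: noise + cluster sizes = n
      expect_equal(sum(got$labels == -1L) + sum(got$particles_per_cluster),
                   n)
    }
  })
})

test_that("DBSCAN labels are permutation-invariant up to renumbering", {
  p <- simulate_clustered(unit_um_window(), 4, 10, 15, seed = 81)
  cfg <- cluster_config(epsilon_rule = "fixed", epsilon_nm = 60)
  base <- dbscan_cluster(p, cfg)
  withr::with_seed(82, {
    for (rep in 1:5) {
      perm <- sample(npoints(p))
      pp <- point_pattern(p$x[perm], p$y[perm], p$window, check = FALSE)
      shuffled <- dbscan_cluster(pp, cfg)
      # map shuffled labels back to original order and compare partitions
      back <- integer(npoints(p))
      back[perm] <- shuffled$labels
      expect_same_partition(base$labels, back)
    }
  })
})

test_that("fixed-radius clustering equals epsilon-graph components", {
  w <- unit_um_window()
  withr::with_seed(91, {
    for (rep in 1:10) {
      n <- sample(5:25, 1)
      xy <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
      eps <- runif(1, 50, 200)
      p <- point_pattern(xy[, 1], xy[, 2], w)
      got <- fixed_radius_cluster(p, cluster_config(method = "fixed_radius",
                                                    min_points = 1,
                                                    epsilon_rule = "fixed",
                                                    epsilon_nm = eps))
      expect_same_partition(got$labels, oracle_components(xy, eps))
    }
  })
})

test_that("clusters of well-separated parents are recovered", {
  p <- simulate_clustered(unit_um_window(), 4, 10, 10, seed = 95,
                          min_separation = 250)
  res <- detect_clusters(p)  # default: dbscan, minPts 3, mean NND + 2 SD
  expect_equal(res$n_clusters, 4L)
  expect_lte(sum(res$labels == -1L), 2L)
})

test_that("cluster summaries scale particles to channels by the efficiency", {
  w <- unit_um_window()
  p <- simulate_clustered(w, 3, 10, 10, seed = 97, min_separation = 300)
  res <- detect_clusters(p)
  s <- cluster_summary(res, efficiency = 0.64)
  expect_equal(s$per_cluster$est_channels,
               s$per_cluster$n_particles / 0.64)
  expect_equal(s$summary$channels_per_cluster_mean,
               s$summary$particles_per_cluster_mean / 0.64)
  expect_equal(s$summary$channels_per_cluster_sem,
               s$summary$particles_per_cluster_sem / 0.64)
  # identity at efficiency 1
  s1 <- cluster_summary(res, efficiency = 1)
  expect_equal(s1$summary$channels_per_cluster_mean,
               s1$summary$particles_per_cluster_mean)
  expect_error(cluster_summary(res, efficiency = 0), "efficiency")
  expect_error(cluster_summary(res, efficiency = 1.2), "efficiency")

  # hull areas: triangle of known area, degenerate pair -> 0
  tri <- point_pattern(c(100, 200, 100, 820, 850), c(100, 100, 200, 800, 830), w)
  rt <- dbscan_cluster(tri, cluster_config(min_points = 2,
                                           epsilon_rule = "fixed",
                                           epsilon_nm = 150))
  expect_equal(rt$n_clusters, 2L)
  expect_equal(sort(rt$cluster_hull_area), c(0, 5000))
})
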
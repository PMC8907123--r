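test_that("NND statistics match hand enumeration and brute force", {
  w <- rect_window(2000, centre = c(1000, 1000))
  p2 <- point_pattern(c(100, 140), c(50, 50), w)
  s2 <- mean_nnd(p2)
  expect_equal(s2$mean, 40)
  expect_equal(s2$sd, 0)
  expect_equal(s2$n, 2L)

  p3 <- point_pattern(c(0, 100, 300), c(0, 0, 0), w)
  s3 <- mean_nnd(p3)
  expect_equal(s3$per_point_nnd, c(100, 100, 200))
  expect_equal(s3$mean, 400 / 3)

  pcsr <- simulate_csr(w, 1000, seed = 14)
  expect_equal(mean_nnd(pcsr)$per_point_nnd, oracle_nnd(coords(pcsr)))

  expect_error(mean_nnd(point_pattern(1, 1, w)), "at least 2")
})

test_that("mean NND under CSR approaches the closed form 1/(2 sqrt(lambda))", {
  w <- unit_um_window()
  means <- vapply(1:100, function(s)
    mean_nnd(simulate_csr(w, 100, seed = s))$mean, 0)
  # lambda = 100 / 1e6 nm^-2 -> expectation 50 nm; border effects inflate
  expect_equal(mean(means), 50, tolerance = 0.10)
  expect_gt(mean(means), 50)  # edge effect has a known positive sign
})

test_that("the Monte-Carlo null flags clustered patterns and keeps CSR", {
  p <- simulate_clustered(az_window_typical(), 4, 8, 10, seed = 77)
  null <- csr_null(p, n_sims = 200, seed = 5, statistics = "nnd")
  expect_equal(null$n_sims, 200L)
  expect_lt(null$observed_mean_nnd,
            stats::quantile(null$per_sim_mean_nnd, 0.025))

  # CSR draws land in the central 95% of their own null about 95% of the
  # time; over 20 seeds at most a few excursions are expected
  inside <- vapply(1:20, function(s) {
    pc <- simulate_csr(az_window_typical(), 30, seed = 78 + s)
    nc <- csr_null(pc, n_sims = 100, seed = 5 + s, statistics = "nnd")
    q <- stats::quantile(nc$per_sim_mean_nnd, c(0.025, 0.975))
    nc$observed_mean_nnd > q[1] && nc$observed_mean_nnd < q[2]
  }, TRUE)
  expect_gte(sum(inside), 16)

  # degenerate but valid single-simulation null; determinism under seed
  pc <- simulate_csr(az_window_typical(), 30, seed = 78)
  n1 <- csr_null(pc, n_sims = 1, seed = 9)
  expect_length(n1$per_sim_mean_nnd, 1L)
  n1b <- csr_null(pc, n_sims = 1, seed = 9)
  expect_identical(n1$per_sim_mean_nnd, n1b$per_sim_mean_nnd)
})

test_that("paired test detects clustering and is order-invariant", {
  ds <- clustered_dataset(n_az = 8, seed = 300)
  res <- paired_nnd_test(ds, n_sims = 60, seed = 2, statistics = "nnd")
  expect_lt(res$nnd$p, 0.05)
  expect_lt(res$nnd$mean_real, res$nnd$mean_null)
  expect_equal(res$nnd$n_az, 8L)

  # reversing dataset order changes nothing: per-AZ substreams are keyed
  # on (seed, region_id), not position
  ds_rev <- replica_dataset(rev(ds$patterns))
  res_rev <- paired_nnd_test(ds_rev, n_sims = 60, seed = 2,
                             statistics = "nnd")
  expect_equal(sort(res_rev$nnd$real), sort(res$nnd$real))
  expect_equal(res_rev$nnd$p, res$nnd$p)
  expect_equal(res_rev$nnd$t, res$nnd$t)
})

test_that("paired test on its own null statistic is calibrated", {
  # real patterns drawn from the same CSR generator as the null: the paired
  # differences are centred at zero, so rejections stay near the nominal rate
  ps <- vapply(1:10, function(r) {
    ds <- csr_dataset(n_az = 15, n = 25, seed = 900 + 37 * r)
    paired_nnd_test(ds, n_sims = 100, seed = 31 + r,
                    statistics = "nnd")$nnd$p
  }, 0)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_lte(sum(ps < 0.05), 2)
  expect_gt(stats::median(ps), 0.1)

  expect_error(paired_nnd_test(replica_dataset(list(
    simulate_csr(az_window_typical("only"), 10, seed = 1))),
    n_sims = 10, seed = 1), "at least 2 AZs")
})
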
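# shared fixture builders (all generated in code; nothing stored on disk)

# unit-square AZ window, 1000 x 1000 nm, anchored at the origin
unit_um_window <- function(region_id = "az1", region_class = "AZ") {
  rect_window(1000, centre = c(500, 500), region_id = region_id,
              region_class = region_class)
}

# a typical complete AZ (~0.1 um^2)
az_window_typical <- function(region_id = "az1") {
  rect_window(316, centre = c(158, 158), region_id = region_id)
}

# two tight clumps of 20 points (sd 5 nm) 500 nm apart
two_clump_pattern <- function(seed = 11) {
  w <- rect_window(1000, centre = c(500, 500))
  withr::with_seed(seed, {
    xy <- rbind(cbind(rnorm(20, 250, 5), rnorm(20, 500, 5)),
                cbind(rnorm(20, 750, 5), rnorm(20, 500, 5)))
    point_pattern(xy[, 1], xy[, 2], w)
  })
}

# dataset of clustered AZs (the clustered-truth fixture)
clustered_dataset <- function(n_az = 20, seed = 100, n_parents = 3,
                              offspring_mean = 8, spread_sd = 12) {
  replica_dataset(lapply(seq_len(n_az), function(i)
    simulate_clustered(az_window_typical(paste0("az", i)),
                       n_parents, offspring_mean, spread_sd,
                       seed = seed + i)))
}

# dataset of CSR AZs with the same marginal counts
csr_dataset <- function(n_az = 20, n = 25, seed = 100) {
  replica_dataset(lapply(seq_len(n_az), function(i)
    simulate_csr(az_window_typical(paste0("az", i)), n, seed = seed + i)))
}

expect_same_partition <- function(labels_a, labels_b) {
  expect_identical(partition_signature(labels_a), partition_signature(labels_b))
}
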
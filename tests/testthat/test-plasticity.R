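test_that("LTP and LTD increments match their closed forms", {
  cfg <- stdp_config()
  expect_equal(ltp_delta(-1, cfg), 0.0667)
  expect_equal(ltp_delta(0, cfg), 0.0667 * exp(-2.5))
  expect_equal(round(ltp_delta(0, cfg), 4), 0.0055)
  expect_equal(ltp_delta(1, cfg), 0.0667 * exp(-5))
  expect_lt(abs(ltp_delta(1, cfg) - 4.494e-4), 5e-8)

  # strictly positive and strictly decreasing in w
  w <- seq(-1, 1, by = 0.05)
  expect_true(all(ltp_delta(w, cfg) > 0))
  expect_true(all(diff(ltp_delta(w, cfg)) < 0))

  expect_equal(ltd_delta(cfg), -0.0167)
  expect_equal(ltd_delta(stdp_config(c_ltd = 0)), 0)
})

test_that("synapses classify by a strict 10-ms coincidence window", {
  cfg <- stdp_config()
  event <- list(time_ms = 50, neuron = 1L)
  last <- c(49, 40, -Inf)  # 1 ms ago, exactly 10 ms ago, never spiked
  bd <- classify_synapses(event, last, cfg)
  expect_equal(bd$ltp_index, 1L)   # delta = 1 is inside
  expect_equal(bd$ltd_index, c(2L, 3L))  # delta = 10 is outside (strict)
  expect_equal(c(bd$p, bd$d), c(1L, 2L))

  # inputs spiking at the event time itself: delta = 0 is LTP
  bd0 <- classify_synapses(event, c(50, 50), cfg)
  expect_equal(bd0$p, 2L)
  # fully pruned neuron: both sets empty
  bdp <- classify_synapses(event, last, cfg, prune_mask_row = rep(TRUE, 3))
  expect_equal(c(bdp$p, bdp$d), c(0L, 0L))

  expect_error(classify_synapses(list(time_ms = 10, neuron = 1L), c(15), cfg),
               "precedes")
})

test_that("the scaled update reproduces hand-computed values", {
  cfg <- stdp_config()
  st <- manual_network(matrix(c(-1, 0.5, 0.2, -0.3), nrow = 1))
  ev <- list(time_ms = 45, neuron = 1L)
  bd <- list(ltp_index = 1L, ltd_index = 2:4, p = 1L, d = 3L)
  st2 <- apply_scaled_update(st, ev, bd, cfg)
  expect_equal(round(st2$W[1, 1], 4), -0.9500)   # -1 + (3/4) * 0.0667
  expect_equal(round(st2$W[1, 2], 4), 0.4958)    # 0.5 + (1/4) * (-0.0167)
  expect_equal(st2$update_count, 4)

  # LTD at the lower bound clips and stays exactly -1
  stc <- manual_network(matrix(c(-1, -1, 0.9, 0.9), nrow = 1))
  bd2 <- list(ltp_index = 3:4, ltd_index = 1:2, p = 2L, d = 2L)
  stc2 <- apply_scaled_update(stc, ev, bd2, cfg)
  expect_identical(stc2$W[1, 1:2], c(-1, -1))
})

test_that("vectorized update equals the scalar-loop oracle exactly", {
  cfg <- stdp_config()
  set.seed(11)
  for (rep in 1:200) {
    W <- matrix(runif(54, -1, 1), 6, 9)
    k <- sample.int(6, 1)
    is_ltp <- rbinom(9, 1, runif(1)) == 1
    bd <- list(ltp_index = which(is_ltp), ltd_index = which(!is_ltp),
               p = sum(is_ltp), d = sum(!is_ltp))
    st <- manual_network(W)
    got <- apply_scaled_update(st, list(time_ms = 0, neuron = k), bd, cfg)
    expect_identical(got$W[k, ], scalar_update_oracle(W[k, ], bd$ltp_index,
                                                      bd$ltd_index, cfg))
    expect_equal(got$update_count, 9)
  }
})

test_that("constant-LTP configuration balances LTP against LTD exactly", {
  cfg <- stdp_config(ltp_form = "constant")
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(3:20, 1)
    W <- matrix(runif(n, -0.5, 0.5), 1, n)  # away from bounds: no clipping
    is_ltp <- rbinom(n, 1, 0.5) == 1
    bd <- list(ltp_index = which(is_ltp), ltd_index = which(!is_ltp),
               p = sum(is_ltp), d = sum(!is_ltp))
    st2 <- apply_scaled_update(manual_network(W), list(time_ms = 0, neuron = 1L),
                               bd, cfg)
    # p * (d/n) * c - d * (p/n) * c = 0
    expect_lt(abs(sum(st2$W - W)), 1e-12)
  }
})

test_that("repeated LTP drives a weight to the bound with shrinking steps", {
  cfg <- stdp_config()
  st <- manual_network(matrix(-1, 1, 1))
  ev <- list(time_ms = 0, neuron = 1L)
  bd <- list(ltp_index = 1L, ltd_index = integer(0), p = 1L, d = 0L)
  # d = 0 means the scaled LTP step is zero: weight frozen by the scaling
  st0 <- apply_scaled_update(st, ev, bd, cfg)
  expect_equal(st0$W[1, 1], -1)

  # with a nonzero LTD partner the trajectory is monotone with shrinking steps
  st <- manual_network(matrix(c(-1, 0), 1, 2))
  bd <- list(ltp_index = 1L, ltd_index = 2L, p = 1L, d = 1L)
  traj <- numeric(2000)
  for (i in seq_along(traj)) {
    st <- apply_scaled_update(st, ev, bd, cfg)
    traj[i] <- st$W[1, 1]
  }
  unclipped <- traj[traj < 1]
  steps <- diff(c(-1, unclipped))
  expect_true(all(steps > 0))
  expect_true(all(diff(steps) < 0))
  expect_true(all(traj <= 1))
  expect_gt(traj[2000], 0.9)
})

test_that("frozen synapses take no updates through the hook", {
  cfg <- stdp_config()
  st <- manual_network(matrix(c(0.5, -0.5, 0.1), 1, 3))
  st$prune_mask[1, 2] <- TRUE
  st$last_input_spike_ms <- c(49, 49, 30)
  hook <- stdp_hook(cfg)
  st2 <- hook(st, list(time_ms = 50, neuron = 1L))
  expect_identical(st2$W[1, 2], -0.5)
  expect_false(identical(st2$W[1, 1], 0.5))
  # scaling denominator is the unpruned count: d=1, p=1, n=2
  expect_equal(st2$W[1, 1], 0.5 + (1 / 2) * ltp_delta(0.5, cfg))
  expect_equal(st2$update_count, 2)

  # the alternative convention keeps n at the total synapse count
  cfg_t <- stdp_config(scale_n = "total")
  st3 <- stdp_hook(cfg_t)(st, list(time_ms = 50, neuron = 1L))
  expect_equal(st3$W[1, 1], 0.5 + (1 / 3) * ltp_delta(0.5, cfg_t))
  expect_identical(st3$W[1, 2], -0.5)
})
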
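test_that("the preset ground truth honors its structural contract", {
  gt <- scenario_poa_inhibition(strength = 0.4)
  m <- gt$model
  mask <- build_connectivity_mask(m$nodes)
  expect_equal(m$B$poa["L-PT", "R-lateral-AC"], -0.4)
  expect_equal(sum(m$B$poa != 0), 1L)
  off <- m$A; diag(off) <- 0
  expect_true(all(off[!mask] == 0))       # A respects the rule mask
  expect_true(all(diag(m$A) < 0))
  expect_true(all(m$C[m$nodes != "L-PT", 1] > 0))
  expect_equal(m$C["L-PT", 1], 0)
  expect_error(ground_truth(m, snr = -1))
  expect_error(ground_truth(m, ar1 = 1))
})

test_that("noise-free generation equals the forward prediction exactly", {
  gt <- scenario_poa_inhibition(0.4, snr = Inf, drift_amplitude = 0,
                              subject_sd = 0, baseline = 0)
  d <- small_design(31)
  ts <- generate_subject(gt, d, seed = 1)
  pred <- forward_predict(gt$model, build_input_functions(d), hrf = gt$hrf)
  expect_equal(ts$data, pred$data, tolerance = 0)
})

test_that("default configuration matches the acquisition dimensions", {
  gt <- scenario_poa_inhibition(0.4)
  d <- generate_design(1)                  # defaults: 5 runs x 220 volumes
  ts <- generate_subject(gt, d, seed = 2)
  expect_equal(nrow(ts$data), 1100L)
  expect_equal(ncol(ts$data), 5L)
  expect_identical(ts$run_lengths, rep(220L, 5))
  expect_equal(ts$tr_s, 2)
})

test_that("realized SNR tracks the requested SNR", {
  gt <- scenario_poa_inhibition(0.4, snr = 2, drift_amplitude = 0)
  d <- generate_design(4)
  ts <- generate_subject(gt, d, seed = 3)
  sig <- attr(ts, "signal")
  noise <- ts$data - sig - matrix(gt$baseline, nrow(sig), ncol(sig),
                                  byrow = TRUE)
  realized <- mean(apply(sig, 2, sd) / apply(noise, 2, sd))
  expect_lt(abs(realized - 2) / 2, 0.10)

  # doubling the noise (snr 1 vs 2) halves the realized ratio
  gt1 <- scenario_poa_inhibition(0.4, snr = 1, drift_amplitude = 0)
  ts1 <- generate_subject(gt1, d, seed = 3)
  noise1 <- ts1$data - attr(ts1, "signal") -
    matrix(gt1$baseline, nrow(sig), ncol(sig), byrow = TRUE)
  realized1 <- mean(apply(attr(ts1, "signal"), 2, sd) /
                      apply(noise1, 2, sd))
  expect_lt(abs(realized1 - realized / 2) / (realized / 2), 0.10)
})

test_that("group generation is reproducible and subject-wise independent", {
  gt <- scenario_poa_inhibition(0.4)
  ds1 <- generate_group(gt, n_subjects = 3, master_seed = 5, n_runs = 1,
                        design_overrides = list(blocks_per_cell = 1L,
                                                volumes_per_run = 80L))
  ds2 <- generate_group(gt, n_subjects = 3, master_seed = 5, n_runs = 1,
                        design_overrides = list(blocks_per_cell = 1L,
                                                volumes_per_run = 80L))
  expect_identical(ds1$subjects[[1]]$ts$data, ds2$subjects[[1]]$ts$data)
  expect_identical(ds1$subjects[[3]]$design$trials,
                   ds2$subjects[[3]]$design$trials)
  # distinct subjects get distinct noise and designs
  expect_false(identical(ds1$subjects[[1]]$ts$data,
                         ds1$subjects[[2]]$ts$data))
  expect_false(identical(ds1$subjects[[1]]$design$trials,
                         ds1$subjects[[2]]$design$trials))
})

test_that("dataset writer/reader round trip is lossless", {
  gt <- scenario_poa_inhibition(0.4)
  ds <- generate_group(gt, n_subjects = 2, master_seed = 6, n_runs = 1,
                       design_overrides = list(blocks_per_cell = 1L,
                                               volumes_per_run = 80L))
  dir <- file.path(tempdir(), "audcm-ds-roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  for (s in 1:2) {
    expect_equal(back$subjects[[s]]$ts$data, ds$subjects[[s]]$ts$data,
                 tolerance = 0, ignore_attr = TRUE)
    expect_equal(back$subjects[[s]]$design$trials$onset,
                 ds$subjects[[s]]$design$trials$onset, tolerance = 0)
  }
  expect_equal(back$ground_truth$model$A, gt$model$A, tolerance = 0)
  expect_equal(back$ground_truth$snr, gt$snr)
  unlink(dir, recursive = TRUE)
})

test_that("the preset produces the disinhibition pattern in the evoked
           responses", {
  # Frozen from a noiseless single-run simulation: alveolar blocks evoke
  # larger responses than bilabial blocks in all four AC nodes (PT feedback
  # is disinhibited), while in L-PT the lost direct drive nearly cancels
  # the extra AC input.
  gt <- scenario_poa_inhibition(0.4, snr = Inf, drift_amplitude = 0,
                              subject_sd = 0, baseline = 0)
  d <- generate_design(3, n_runs = 1)
  ts <- generate_subject(gt, d, seed = 5)
  tab <- d$trials[!d$trials$is_target, ]
  blocks <- unique(data.frame(b = floor(tab$onset / 36), poa = tab$poa))
  block_mean <- function(node) {
    vapply(seq_len(nrow(blocks)), function(i) {
      t0 <- blocks$b[i] * 36 + 4
      v <- (floor(t0 / ts$tr_s) + 1):(floor((t0 + 20) / ts$tr_s))
      mean(ts$data[v, node])
    }, numeric(1))
  }
  for (node in setdiff(auditory_nodes(), "L-PT")) {
    amp <- block_mean(node)
    expect_gt(mean(amp[blocks$poa == "alveolar"]),
              mean(amp[blocks$poa == "bilabial"]))
  }
  amp_pt <- block_mean("L-PT")
  diff_pt <- mean(amp_pt[blocks$poa == "alveolar"]) -
    mean(amp_pt[blocks$poa == "bilabial"])
  expect_lt(abs(diff_pt) / mean(amp_pt), 0.05)
})
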
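test_that("default design reproduces the blocked trial accounting", {
  d <- generate_design(seed = 7)
  tr <- d$trials
  expect_equal(nrow(tr), 600L)
  expect_equal(sum(!tr$is_target), 540L)
  expect_equal(sum(tr$is_target), 60L)
  expect_equal(sum(tr$is_target) / nrow(tr), 0.10)

  # brute-force counting property: n_runs x 12 blocks x 10 trials
  expect_equal(nrow(tr), d$params$n_runs * 12L * 10L)
  expect_equal(sum(tr$is_target), d$params$n_runs * 12L)

  for (r in unique(tr$run)) {
    rt <- tr[tr$run == r, ]
    block_id <- floor(rt$onset / (d$params$block_s + d$params$off_s))
    expect_equal(length(unique(block_id)), 12L)
    counts <- table(block_id)
    expect_true(all(counts == 10L))
    # exactly one target per block, one PoA x VOT cell per block
    for (b in unique(block_id)) {
      bt <- rt[block_id == b, ]
      expect_equal(sum(bt$is_target), 1L)
      expect_equal(nrow(unique(bt[, c("poa", "vot")])), 1L)
      # trials span exactly the 20-s block and do not overlap
      b_start <- b * (d$params$block_s + d$params$off_s)
      expect_true(all(bt$onset >= b_start - 1e-9))
      expect_true(all(bt$onset + bt$duration <= b_start + 20 + 1e-9))
      o <- sort(bt$onset)
      expect_true(all(diff(o) >= bt$duration[1] - 1e-9))
    }
    # 3 blocks per cell, 12 ON blocks of 20 s + 12 OFF of 16 s fit the run
    cells <- table(paste(rt$poa, rt$vot))
    expect_true(all(cells == 30L))
    expect_lte(12 * (20 + 16), d$run_length_volumes * d$tr_s)
    expect_true(all(rt$onset + rt$duration <=
                      d$run_length_volumes * d$tr_s))
  }
  expect_true(all(tr$duration == 0.7))
})

test_that("design generation is seed-deterministic", {
  expect_identical(generate_design(7), generate_design(7))
  expect_false(identical(generate_design(7)$trials,
                         generate_design(8)$trials))
})

test_that("inconsistent overrides raise configuration errors", {
  expect_error(generate_design(1, overrides = list(block_s = 5)),
               "shorter than")
  expect_error(generate_design(1, overrides = list(volumes_per_run = 100L)),
               "exceeds run length")
  expect_error(generate_design(1, overrides = list(nonsense = 1)),
               "unknown design parameter")
})

test_that("a single trial becomes the expected boxcar samples", {
  d <- small_design(2)
  d$trials <- d$trials[1, ]
  d$trials$onset <- 10
  d$trials$is_target <- FALSE
  inp <- build_input_functions(d, dt_s = 0.125)
  nz <- which(inp$u_phonetic != 0)
  # ceil(0.7 / 0.125) = 6 samples starting at 0-based sample 80
  expect_equal(length(nz), 6L)
  expect_equal(nz[1] - 1L, 80L)
  expect_equal(nz, 81:86)
})

test_that("modulators are mean-centered on the phonetic support", {
  inp <- build_input_functions(generate_design(3, n_runs = 1))
  support <- inp$u_phonetic != 0
  expect_equal(mean(inp$u_poa[support]), 0, tolerance = 1e-12)
  expect_equal(mean(inp$u_vot[support]), 0, tolerance = 1e-12)
  expect_equal(mean(inp$u_inter[support]), 0, tolerance = 1e-12)
  # modulators are zero off-support; targets live in their own signal
  expect_true(all(inp$u_poa[!support] == 0))
  expect_true(all(inp$u_vot[!support] == 0))
  expect_true(all(inp$u_inter[!support] == 0))
  # target and phonetic boxcars may share at most the single boundary
  # micro-sample that the ceil(duration/dt) discretization overshoots
  expect_lte(sum(inp$u_phonetic != 0 & inp$u_target != 0),
             sum(inp$u_target != 0) / 6)
  # interaction = centered product of the uncentered codes
  raw_inter <- sign(inp$u_poa[support]) * sign(inp$u_vot[support])
  expect_equal(inp$u_inter[support],
               raw_inter - mean(raw_inter), tolerance = 1e-12)
})

test_that("dt must divide the TR and empty designs give zero signals", {
  d <- small_design(4)
  expect_error(build_input_functions(d, dt_s = 0.3), "divide")
  d0 <- d
  d0$trials <- d0$trials[0, ]
  inp <- build_input_functions(d0)
  expect_true(all(inp$u_phonetic == 0) && all(inp$u_poa == 0) &&
                all(inp$u_target == 0))
})

test_that("input building is linear under design concatenation", {
  d <- generate_design(11, n_runs = 2)
  inp <- build_input_functions(d)
  per_run <- lapply(1:2, function(r) {
    dr <- d
    dr$trials <- dr$trials[dr$trials$run == r, ]
    dr$trials$run <- 1
    dr$params$n_runs <- 1L
    build_input_functions(dr)
  })
  # concatenating single-run signals reproduces the two-run signal
  # (up to the centering, which is global; compare uncentered parts)
  expect_equal(inp$u_phonetic,
               c(per_run[[1]]$u_phonetic, per_run[[2]]$u_phonetic))
  expect_equal(inp$u_target,
               c(per_run[[1]]$u_target, per_run[[2]]$u_target))
})

test_that("events TSV round trip is lossless", {
  d <- small_design(9)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_events_tsv(d, path)
  back <- read_events_tsv(path)
  expect_equal(back$onset, d$trials$onset, tolerance = 0)
  expect_identical(back$poa, d$trials$poa)
  expect_identical(back$is_target, d$trials$is_target)
  expect_identical(back$run, d$trials$run)
})
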
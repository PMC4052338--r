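test_that("the connectivity rule yields the 16-connection mask", {
  mask <- build_connectivity_mask()
  expect_equal(sum(mask), 16L)
  expect_true(all(diag(mask) == FALSE))
  # symmetric as a relation
  expect_identical(mask, t(mask))
  # homolog yes, non-homolog no
  expect_true(mask["R-medial-AC", "L-medial-AC"])
  expect_false(mask["R-lateral-AC", "L-medial-AC"])
  expect_false(mask["L-lateral-AC", "R-medial-AC"])
  # every AC node is reciprocally connected to the left PT
  for (ac in setdiff(auditory_nodes(), "L-PT")) {
    expect_true(mask["L-PT", ac])
    expect_true(mask[ac, "L-PT"])
  }
  expect_error(build_connectivity_mask(c("L-medial-AC", "X-foo")),
               "unknown node role")
})

test_that("the modulation space has one member per permitted connection", {
  mask <- build_connectivity_mask()
  sp <- enumerate_poa_models(mask)
  expect_equal(length(sp$members), 16L)
  expect_setequal(sp$input_nodes, setdiff(auditory_nodes(), "L-PT"))
  bmasks <- lapply(sp$members, function(m) m$mask_B$poa)
  # each member modulates exactly one connection, all pairwise distinct
  expect_true(all(vapply(bmasks, sum, integer(1)) == 1L))
  for (i in 1:15) for (j in (i + 1):16)
    expect_equal(sum(bmasks[[i]] & bmasks[[j]]), 0L)
  # union of the B-masks is exactly the A-mask
  expect_identical(Reduce(`|`, bmasks), mask)
  # all members share A- and C-masks
  expect_true(all(vapply(sp$members, function(m)
    identical(m$mask_A, mask), logical(1))))
})

test_that("fixed-effects BMS matches a direct softmax oracle", {
  set.seed(42)
  L <- matrix(rnorm(4 * 5, sd = 2), 4, 5)
  r <- bms(L, mode = "ffx")
  s <- colSums(L)
  oracle <- exp(s - max(s)) / sum(exp(s - max(s)))
  expect_equal(unname(r$pP), unname(oracle), tolerance = 1e-12)
  expect_equal(sum(r$pP), 1, tolerance = 1e-10)
  expect_equal(r$winner, which.max(s))
})

test_that("equal evidences give uniform probabilities and a 280-nat lead is
           decisive", {
  L <- matrix(0, 3, 16)
  r <- bms(L, mode = "ffx")
  expect_equal(unname(r$pP), rep(1 / 16, 16))
  expect_equal(r$winner, 1L)   # tie broken to the lowest index

  L2 <- matrix(0, 1, 16)
  L2[1, 3] <- 280
  r2 <- bms(L2, mode = "ffx")
  expect_identical(max(r2$pP), 1)      # exact at double precision
  expect_equal(r2$winner, 3L)
  expect_true(all(r2$pP[-3] < 0.001))
})

test_that("BMS probabilities are invariant to constant evidence shifts", {
  set.seed(1)
  L <- matrix(rnorm(6 * 4), 6, 4)
  base <- bms(L, mode = "ffx")$pP
  for (shift in c(-50, 3.3, 1000)) {
    expect_equal(bms(L + shift, mode = "ffx")$pP, base, tolerance = 1e-9)
  }
  expect_error(bms(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
  expect_error(bms(matrix(1, 2, 1)), "2 models")
})

test_that("random-effects BMS returns coherent frequencies and finds a
           dominant model", {
  set.seed(3)
  L <- matrix(rnorm(8 * 4), 8, 4)
  L[, 2] <- L[, 2] + 6   # model 2 dominates in every subject
  r <- bms(L, mode = "rfx")
  expect_equal(sum(r$expected_freq), 1, tolerance = 1e-10)
  expect_equal(sum(r$pP), 1, tolerance = 1e-10)
  expect_equal(r$winner, 2L)
  expect_gt(r$xp[2], 0.95)
  expect_equal(sum(r$xp), 1, tolerance = 1e-10)
  # deterministic across calls
  expect_identical(r$xp, bms(L, mode = "rfx")$xp)
})

test_that("family comparison normalizes evidence mass per family", {
  # 3 families, arbitrary evidences: brute-force oracle
  set.seed(11)
  L <- matrix(rnorm(5 * 6), 5, 6)
  fams <- list(f1 = 1:2, f2 = 3:4, f3 = 5:6)
  p <- family_compare(L, fams, mode = "ffx")
  s <- colSums(L)
  mass <- vapply(fams, function(ix) sum(exp(s[ix] - max(s))), numeric(1))
  expect_equal(unname(p), unname(mass / sum(mass)), tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # identical evidences, two equal families -> (0.5, 0.5)
  L0 <- matrix(1.7, 3, 4)
  expect_equal(unname(family_compare(L0, list(a = 1:2, b = 3:4))),
               c(0.5, 0.5))
  # single family -> probability 1
  expect_equal(unname(family_compare(L0, list(all = 1:4))), 1)
  # merging two families sums their probabilities
  p3 <- family_compare(L, list(f12 = 1:4, f3 = 5:6), mode = "ffx")
  expect_equal(unname(p3[1]), unname(p[1] + p[2]), tolerance = 1e-10)
  expect_error(family_compare(L, list(1:2, 2:6)), "partition")
})

# Minimal hand-built inversion results for BMA arithmetic.
fake_fit <- function(a21, b21, cw) {
  nodes <- c("n1", "n2")
  A <- matrix(c(-0.5, a21, 0, -0.5), 2, 2, dimnames = list(nodes, nodes))
  B <- list(poa = matrix(c(0, b21, 0, 0), 2, 2,
                         dimnames = list(nodes, nodes)))
  C <- matrix(c(cw, 0), 2, 1, dimnames = list(nodes, "phonetic"))
  structure(list(A = A, B = B, C = C), class = "inversion_result")
}

test_that("BMA reduces to the expected weighted means", {
  f1 <- fake_fit(0.2, -0.1, 0.5)
  f2 <- fake_fit(0.6, 0.3, 0.1)
  f3 <- fake_fit(-0.4, 0.0, 1.0)
  # single model with pP = 1 reproduces it exactly
  r1 <- bma(list(list(f1)), weights = 1)
  expect_identical(r1$A, f1$A)
  expect_identical(r1$B$poa, f1$B$poa)
  # equal weights average the two means
  r2 <- bma(list(list(f1, f2)), weights = c(0.5, 0.5))
  expect_equal(r2$A[2, 1], 0.4)
  expect_equal(r2$B$poa[2, 1], 0.1)
  # arbitrary weights match the brute-force weighted sum
  w <- c(0.2, 0.3, 0.5)
  r3 <- bma(list(list(f1, f2, f3)), weights = w)
  expect_equal(r3$A[2, 1], sum(w * c(0.2, 0.6, -0.4)), tolerance = 1e-12)
  expect_equal(r3$C[1, 1], sum(w * c(0.5, 0.1, 1.0)), tolerance = 1e-12)
  # a connection absent from every model stays exactly zero
  expect_identical(r3$A[1, 2], 0)
  # identical models reproduce the common posterior mean exactly
  r4 <- bma(list(list(f1, f1)), weights = c(0.3, 0.7))
  expect_equal(r4$A, f1$A)
  expect_error(bma(list(list(f1, f2)), weights = c(1, 1, 1)),
               "misaligned")
})
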
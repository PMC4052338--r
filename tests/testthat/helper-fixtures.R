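# Shared fixtures, all generated in code.

# Reduced design for cheap unit tests: one run of 4 ON blocks (one per
# PoA x VOT cell), 80 volumes. Not the study-scale default.
small_design <- function(seed = 1) {
  generate_design(seed, n_runs = 1L,
                  overrides = list(blocks_per_cell = 1L,
                                   volumes_per_run = 80L))
}

# Two-node chain: input drives node 1, node 1 drives node 2.
two_node_model <- function(a21 = 0.3, c1 = 0.5) {
  nodes <- c("L-medial-AC", "L-lateral-AC")
  A <- matrix(c(-0.5, a21, 0, -0.5), 2, 2, dimnames = list(nodes, nodes))
  C <- matrix(c(c1, 0), 2, 1, dimnames = list(nodes, "phonetic"))
  dcm_model(nodes, A, C = C,
            mask_A = matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2),
            mask_C = matrix(c(TRUE, FALSE), 2, 1))
}

# One-node model with a single free input weight.
one_node_model <- function(a = -0.5, c1 = 1) {
  nodes <- "L-medial-AC"
  dcm_model(nodes, matrix(a, 1, 1), C = matrix(c1, 1, 1),
            mask_C = matrix(TRUE, 1, 1))
}

# Raw input list: single unit-area impulse at t = 0 on a dt grid.
impulse_inputs <- function(dt = 0.125, nt = 400L, m = 1L) {
  U <- matrix(0, nt, m)
  U[1, 1] <- 1 / dt
  list(dt_s = dt, U = U)
}
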
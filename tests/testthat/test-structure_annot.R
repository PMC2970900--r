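# ASA ---------------------------------------------------------------------

test_that("an isolated atom is fully exposed and symmetric pairs match", {
  t2 <- make_toy_structure("two_atoms", separation = 50)
  asa <- compute_asa(t2, step = 0)
  expect_equal(asa$asa_fraction, c(1, 1))       # no occluders at all
  t3 <- make_toy_structure("two_atoms", separation = 4)
  asa3 <- compute_asa(t3, step = 0)
  expect_lt(asa3$asa_fraction[1], 1)
  # symmetry holds to quadrature resolution: the spiral point set is not
  # mirror-symmetric, so counts may differ by a few of the 960 points
  expect_equal(asa3$asa_fraction[1], asa3$asa_fraction[2],
               tolerance = 5 / 960)
})

test_that("a fully buried atom has zero accessible surface", {
  bs <- make_toy_structure("buried_shell")
  asa <- compute_asa(bs, step = 0)
  expect_equal(asa$asa_fraction[1], 0)
})

test_that("ASA is invariant under rigid motion within quadrature tolerance", {
  m <- make_toy_structure("ideal_helix", n_residues = 8)
  base <- compute_asa(m, step = 0)$asa_fraction
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% R
  m2$atoms$x <- xyz[, 1] + 13.7
  m2$atoms$y <- xyz[, 2] - 4.2
  m2$atoms$z <- xyz[, 3] + 101
  moved <- compute_asa(m2, step = 0)$asa_fraction
  # quadrature tolerance: point-count error ~ sqrt(f(1-f)/n) ~ 0.013 at
  # n = 960; rigid motion must not change fractions beyond that scale
  expect_lt(max(abs(base - moved)), 0.015)
})

test_that("discretization snaps to multiples of the step with bounded error", {
  m <- make_toy_structure("ideal_helix", n_residues = 8)
  step <- sr_config()$asa_step
  raw <- compute_asa(m, step = 0)$asa_fraction
  disc <- compute_asa(m, step = step)$asa_fraction
  mult <- disc / step
  expect_equal(mult, round(mult), tolerance = 1e-9)
  expect_true(all(abs(disc - raw) <= step / 2 + 1e-12))
  expect_lte(sum(abs(disc - raw)), length(raw) * step / 2)
})

# Secondary structure ------------------------------------------------------

test_that("an ideal alpha helix assigns alpha_helix to interior residues", {
  h <- make_toy_structure("ideal_helix", n_residues = 12)
  ss <- assign_secondary_structure(h)
  expect_identical(nrow(ss), 12L)                 # every residue exactly once
  expect_true(all(ss$ss_state[3:10] == "alpha_helix"))
  expect_true(all(ss$ss_state %in% c("alpha_helix", "helix_310", "helix_pi",
                                     "beta_strand", "turn", "coil")))
})

test_that("a fully extended chain with no hydrogen bonds is all coil", {
  e <- make_toy_structure("extended", n_residues = 10)
  ss <- assign_secondary_structure(e)
  expect_true(all(ss$ss_state == "coil"))
})

test_that("chains shorter than three residues are coil", {
  t2 <- make_toy_structure("two_atoms")
  ss <- assign_secondary_structure(t2)
  expect_true(all(ss$ss_state == "coil"))
})

test_that("the precomputed backend maps the state letters one-to-one", {
  h <- make_toy_structure("ideal_helix", n_residues = 7)
  f <- tempfile()
  writeLines(sprintf("A %d %s", 1:7, c("H", "G", "I", "E", "T", "C", "B")), f)
  ss <- assign_secondary_structure(h, backend = "precomputed",
                                   precomputed_file = f)
  expect_identical(ss$ss_state,
                   c("alpha_helix", "helix_310", "helix_pi", "beta_strand",
                     "turn", "coil", "beta_strand"))
  writeLines("A 1 X", f)
  expect_error(assign_secondary_structure(h, backend = "precomputed",
                                          precomputed_file = f),
               "unknown state letter")
})

# Sequence mapping ---------------------------------------------------------

test_that("identical sequences map completely with identity 1", {
  s <- list(seq = strsplit("ARNDCQEG", "")[[1]], positions = 1:8)
  t <- list(seq = strsplit("ARNDCQEG", "")[[1]], positions = 11:18)
  m <- map_sequences(s, t)
  expect_identical(nrow(m$pairs), 8L)
  expect_equal(m$aligned_identity, 1)
  expect_identical(m$pairs$structure_seq_pos, 11:18)
})

test_that("an internal deletion shifts downstream pairs correctly", {
  s <- list(seq = strsplit("ARNDCQEGHI", "")[[1]], positions = 1:10)
  t <- list(seq = strsplit("ARNDQEGHI", "")[[1]], positions = 1:9)  # C removed
  m <- map_sequences(s, t)
  expect_identical(nrow(m$pairs), 9L)
  expect_false(5 %in% m$pairs$shift_seq_pos)       # deleted position unpaired
  expect_identical(m$pairs$structure_seq_pos[m$pairs$shift_seq_pos == 6], 5L)
  expect_identical(m$pairs$structure_seq_pos[m$pairs$shift_seq_pos == 10], 9L)
})

test_that("aligned mismatches are excluded from the mapping", {
  s <- list(seq = strsplit("ARNDCQEG", "")[[1]], positions = 1:8)
  t <- list(seq = strsplit("ARNGCQEG", "")[[1]], positions = 1:8)  # D->G
  m <- map_sequences(s, t)
  expect_identical(nrow(m$pairs), 7L)
  expect_false(4 %in% m$pairs$shift_seq_pos)
  # mapping one-to-one and strictly increasing in both coordinates
  expect_true(all(diff(m$pairs$shift_seq_pos) > 0))
  expect_true(all(diff(m$pairs$structure_seq_pos) > 0))
})

test_that("mappings below the identity floor are rejected", {
  s <- list(seq = strsplit("AAAAAAAA", "")[[1]], positions = 1:8)
  t <- list(seq = strsplit("GGGGGGGG", "")[[1]], positions = 1:8)
  expect_error(map_sequences(s, t), "do not correspond")
})

test_that("DP score matches the emitted alignment and the exhaustive optimum", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    s1 <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE)
    s2 <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], m, replace = TRUE)
    al <- shiftref:::nw_align(s1, s2)
    # self-consistency: traceback rescored equals the DP matrix score
    expect_equal(shiftref:::nw_score_alignment(s1, s2, al$i1, al$i2), al$score)
    # independent oracle: exhaustive enumeration over all alignments
    expect_equal(al$score, exhaustive_nw_score(s1, s2))
  }
})

test_that("NW scores agree with Biostrings global alignment", {
  # cross-library oracle at the same scoring scheme
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (rep in 1:10) {
    s1 <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE),
                collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE),
                collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      s1, s2, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    al <- shiftref:::nw_align(strsplit(s1, "")[[1]], strsplit(s2, "")[[1]])
    expect_equal(al$score, ref)
  }
})
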
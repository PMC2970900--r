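# Synthetic fixtures: reference databases with chosen class statistics,
# entries simulated forward from the shift model (class mean + group offset
# + Gaussian noise), and toy coordinate sets for the structure annotators.
# All generators are deterministic under a fixed seed.

#' Default synthetic class layout
#'
#' A small atom-mode class table emulating typical backbone/side-chain
#' statistics: amide and alpha protons, amide nitrogen, CA/CB aliphatic
#' carbons, an aromatic ring carbon and the carbonyl carbon, each across
#' three secondary-structure states and two ASA bins (buried [0, 0.5),
#' exposed [0.5, 1]). Means/sds are round numbers in the range seen for
#' folded proteins; exposed bins are slightly narrower than buried ones.
#'
#' @param count observations per class (default 200).
#' @return data.frame usable as the `layout` of [make_refdb()].
#' @export
default_refdb_layout <- function(count = 200L) {
  base <- data.frame(
    atom_name = c("H", "HA", "N", "CA", "CB", "CD1", "C"),
    residue_type = c("ALA", "ALA", "ALA", "ALA", "ALA", "PHE", "ALA"),
    mean_ppm = c(8.3, 4.4, 119, 56, 19, 131.5, 177.5),
    sd_buried = c(0.65, 0.45, 4.0, 2.2, 1.8, 1.4, 1.3),
    stringsAsFactors = FALSE)
  ss <- data.frame(ss_state = c("alpha_helix", "beta_strand", "coil"),
                   d_mean = c(0.6, -0.5, 0))
  out <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    do.call(rbind, lapply(seq_len(nrow(ss)), function(j) {
      data.frame(atom_name = base$atom_name[i],
                 residue_type = base$residue_type[i],
                 ss_state = ss$ss_state[j],
                 bin_index = 0:1, bin_low = c(0, 0.5), bin_high = c(0.5, Inf),
                 mean_ppm = base$mean_ppm[i] + ss$d_mean[j] * c(1, 1),
                 sd_ppm = base$sd_buried[i] * c(1, 0.8),
                 count = count)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic reference database
#'
#' In `direct` mode the class statistics are written into the database
#' exactly as given. In `fit` mode `count` values per class are drawn from
#' N(mean, sd^2) with ASA sampled inside the class bin, and the database is
#' fit from the draws through the ordinary build path (so undersized or
#' degenerate classes drop out per the usual rules).
#'
#' @param layout data.frame like [default_refdb_layout()]: atom_name,
#'   residue_type, ss_state, bin_index, bin_low, bin_high, mean_ppm, sd_ppm
#'   (or precision), count.
#' @param seed RNG seed (fit mode).
#' @param mode `"direct"` or `"fit"`.
#' @param class_mode atom-type granularity, `"atom"` (default, synthetic
#'   scale) or `"residue_atom"`.
#' @return a `reference_db`.
#' @export
make_refdb <- function(layout = default_refdb_layout(), seed = 1L,
                       mode = c("direct", "fit"),
                       class_mode = c("atom", "residue_atom")) {
  mode <- match.arg(mode)
  class_mode <- match.arg(class_mode)
  if (is.null(layout$sd_ppm)) layout$sd_ppm <- 1 / sqrt(layout$precision)
  tbc <- min(layout$count)
  if (mode == "fit") {
    set.seed(seed)
    obs <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
      L <- layout[i, ]
      hi <- min(L$bin_high, 1)
      asa <- if (L$bin_low == 0 && L$bin_high == 0) rep(0, L$count) else
        stats::runif(L$count, L$bin_low, hi)
      data.frame(residue_type = L$residue_type, atom_name = L$atom_name,
                 ss_state = L$ss_state, asa_fraction = asa,
                 value_ppm = stats::rnorm(L$count, L$mean_ppm, L$sd_ppm))
    }))
    return(build_reference_db(obs, target_bin_count = tbc, mode = class_mode))
  }
  atom_type <- atom_type_key(layout$residue_type, layout$atom_name,
                             class_mode)
  stats <- data.frame(atom_type = atom_type, ss_state = layout$ss_state,
                      bin_index = as.integer(layout$bin_index),
                      bin_low = layout$bin_low, bin_high = layout$bin_high,
                      count = as.integer(layout$count),
                      mean_ppm = layout$mean_ppm,
                      variance_ppm2 = layout$sd_ppm^2,
                      precision = 1 / layout$sd_ppm^2,
                      stringsAsFactors = FALSE)
  ord <- order(stats$atom_type, stats$ss_state, stats$bin_index)
  stats <- stats[ord, ]; rownames(stats) <- NULL
  scheme <- structure(
    list(bins = stats[, c("atom_type", "ss_state", "bin_index", "bin_low",
                          "bin_high", "count")],
         target_bin_count = as.integer(tbc), mode = class_mode),
    class = "binning_scheme")
  names(scheme$bins)[6] <- "build_count"
  new_reference_db(scheme, stats, list(n_entries = 0L, n_iterations = 0L,
                                       synthetic = TRUE))
}

# residue that legitimately carries each synthetic atom name
synth_residue_for <- function(atom_name) {
  at <- atom_table()
  vapply(atom_name, function(nm) {
    cand <- at$residue[at$atom == nm]
    if (!length(cand)) stop("no residue carries atom ", nm, call. = FALSE)
    # prefer PHE for aromatic ring names so groups come out aromatic
    if ("PHE" %in% cand && nm %in% c("CD1", "CD2", "CE1", "CE2", "CZ", "CG"))
      "PHE" else cand[1]
  }, character(1))
}

#' Simulate a synthetic entry from a reference database
#'
#' Draws `n_shifts` classes uniformly (with replacement) from the database
#' and simulates each shift as class mean + group offset +
#' N(0, (noise_scale / sqrt(class precision))^2), the forward direction of
#' the correction model (noise_scale = 1 is the model-matched case). Each
#' shift occupies its own residue position; annotations (heavy-atom ASA
#' inside the class bin, residue SS state) and an identity residue mapping
#' are returned alongside the known offsets.
#'
#' @param refdb a `reference_db`.
#' @param n_shifts number of shifts to simulate.
#' @param offsets named numeric: injected per-group offsets in ppm
#'   (missing groups get 0).
#' @param noise_scale multiplier on each class sd (0 = noiseless).
#' @param seed RNG seed.
#' @param entry_id identifier for the shift table.
#' @return list: `table` (shift_table), `annotations`, `mapping`,
#'   `classified` (precomputed classification), `offsets` (ground truth,
#'   all five groups).
#' @export
make_entry <- function(refdb, n_shifts = 200L, offsets = c(),
                       noise_scale = 1, seed = 1L, entry_id = "synthetic") {
  stopifnot(n_shifts >= 1, nrow(refdb$stats) > 0)
  set.seed(seed)
  off <- stats::setNames(numeric(5), NUCLEUS_GROUPS)
  off[names(offsets)] <- offsets
  st <- refdb$stats
  ci <- sample.int(nrow(st), n_shifts, replace = TRUE)
  atom_name <- if (refdb$scheme$mode == "atom") st$atom_type[ci] else
    sub("^[A-Z]{3} ", "", st$atom_type[ci])
  residue_type <- if (refdb$scheme$mode == "atom")
    synth_residue_for(atom_name) else sub(" .*$", "", st$atom_type[ci])
  group <- assign_group(residue_type, atom_name)
  value <- st$mean_ppm[ci] + off[group] +
    stats::rnorm(n_shifts, 0, noise_scale / sqrt(st$precision[ci]))
  records <- data.frame(chain_id = "A", seq_pos = seq_len(n_shifts),
                        residue_type = residue_type, atom_name = atom_name,
                        value_ppm = value, stringsAsFactors = FALSE)
  table <- new_shift_table(entry_id, records)
  # ASA sampled inside the class bin; zero bin stays at 0
  hi <- pmin(st$bin_high[ci], 1)
  asa <- ifelse(st$bin_low[ci] == 0 & st$bin_high[ci] == 0, 0,
                stats::runif(n_shifts, st$bin_low[ci], hi))
  anno <- data.frame(chain_id = "A", seq_pos = seq_len(n_shifts),
                     atom_name = heavy_parent(residue_type, atom_name),
                     asa_fraction = asa, ss_state = st$ss_state[ci],
                     stringsAsFactors = FALSE)
  mapping <- structure(list(pairs = data.frame(
    shift_seq_pos = seq_len(n_shifts),
    structure_seq_pos = seq_len(n_shifts)),
    aligned_identity = 1, score = n_shifts),
    class = "residue_mapping")
  classified <- classify_shifts(table, anno, mapping, refdb)
  list(table = table, annotations = anno, mapping = mapping,
       classified = classified, offsets = off)
}

#' Observations for a reference build, simulated forward
#'
#' Convenience for population experiments: draws one entry's worth of
#' observations (columns ready for [iterative_build()]), with per-group
#' offsets injected.
#'
#' @inheritParams make_entry
#' @return data.frame of annotated observations.
#' @export
make_observations <- function(refdb, n_shifts = 200L, offsets = c(),
                              noise_scale = 1, seed = 1L,
                              entry_id = "synthetic") {
  e <- make_entry(refdb, n_shifts, offsets, noise_scale, seed, entry_id)
  data.frame(entry_id = entry_id, residue_type = e$table$records$residue_type,
             atom_name = e$table$records$atom_name,
             ss_state = e$annotations$ss_state,
             asa_fraction = e$annotations$asa_fraction,
             value_ppm = e$table$records$value_ppm,
             stringsAsFactors = FALSE)
}

# -- toy coordinate sets -----------------------------------------------------

# place atom D at distance `bond` from C with angle A-C-D = `angle` and
# torsion B-A-C-D = `torsion` (NeRF construction, degrees)
place_atom <- function(B, A, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - A; bc <- bc / sqrt(sum(bc^2))
  ab <- A - B
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ideal backbone geometry (lengths in Angstrom, angles in degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

build_backbone <- function(n_res, phi, psi, omega = 180) {
  g <- BB_GEOM
  coords <- list()
  N <- c(0, 0, 0); CA <- c(g$n_ca, 0, 0)
  C <- place_atom(c(0, -1, 0), N, CA, g$ca_c, g$ang_n_ca_c, phi)
  for (i in seq_len(n_res)) {
    coords[[i]] <- list(N = N, CA = CA, C = C)
    if (i < n_res) {
      N2 <- place_atom(N, CA, C, g$c_n, g$ang_ca_c_n, psi)
      CA2 <- place_atom(CA, C, N2, g$n_ca, g$ang_c_n_ca, omega)
      C2 <- place_atom(C, N2, CA2, g$ca_c, g$ang_n_ca_c, phi)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  # carbonyl O in the peptide plane, trans to the next N
  for (i in seq_len(n_res)) {
    nxtN <- if (i < n_res) coords[[i + 1]]$N else NULL
    psi_o <- if (is.null(nxtN)) psi + 180 else NULL
    coords[[i]]$O <- if (is.null(nxtN)) {
      place_atom(coords[[i]]$N, coords[[i]]$CA, coords[[i]]$C, g$c_o,
                 g$ang_ca_c_o, psi + 180)
    } else {
      # O opposite N across the C: reflect along the CA-C-N bisector
      CC <- coords[[i]]$C
      v1 <- coords[[i]]$CA - CC; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- nxtN - CC; v2 <- v2 / sqrt(sum(v2^2))
      d <- -(v1 + v2); d <- d / sqrt(sum(d^2))
      CC + g$c_o * d
    }
  }
  coords
}

#' Toy coordinate sets for annotation tests
#'
#' Kinds: `ideal_helix` (poly-ALA backbone at phi = -57, psi = -47),
#' `extended` (phi = psi = 180, no hydrogen bonds), `two_atoms` (two glycine
#' CA atoms at a given separation), `buried_shell` (one CA enclosed in a
#' dense occluding shell of CA atoms).
#'
#' @param kind one of the four kinds.
#' @param n_residues chain length (helix/extended).
#' @param separation distance in Angstrom (two_atoms).
#' @param shell_radius,shell_points shell geometry (buried_shell).
#' @return a `structure_model`.
#' @export
make_toy_structure <- function(kind = c("ideal_helix", "extended",
                                        "two_atoms", "buried_shell"),
                               n_residues = 12L, separation = 20,
                               shell_radius = 4, shell_points = 192L) {
  kind <- match.arg(kind)
  if (kind %in% c("ideal_helix", "extended")) {
    stopifnot(n_residues >= 2)
    ang <- if (kind == "ideal_helix") c(-57, -47) else c(180, 180)
    bb <- build_backbone(n_residues, ang[1], ang[2])
    atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
      data.frame(chain_id = "A", seq_pos = i, residue_type = "ALA",
                 atom_name = c("N", "CA", "C", "O"),
                 x = c(bb[[i]]$N[1], bb[[i]]$CA[1], bb[[i]]$C[1], bb[[i]]$O[1]),
                 y = c(bb[[i]]$N[2], bb[[i]]$CA[2], bb[[i]]$C[2], bb[[i]]$O[2]),
                 z = c(bb[[i]]$N[3], bb[[i]]$CA[3], bb[[i]]$C[3], bb[[i]]$O[3]),
                 element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
    }))
    return(new_structure_model(kind, atoms))
  }
  if (kind == "two_atoms") {
    atoms <- data.frame(chain_id = "A", seq_pos = 1:2,
                        residue_type = "GLY", atom_name = "CA",
                        x = c(0, separation), y = 0, z = 0, element = "C",
                        stringsAsFactors = FALSE)
    return(new_structure_model(kind, atoms))
  }
  sp <- sphere_points(shell_points) * shell_radius
  atoms <- data.frame(chain_id = "A", seq_pos = seq_len(shell_points + 1L),
                      residue_type = "GLY", atom_name = "CA",
                      x = c(0, sp[, 1]), y = c(0, sp[, 2]), z = c(0, sp[, 3]),
                      element = "C", stringsAsFactors = FALSE)
  new_structure_model(kind, atoms)
}
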
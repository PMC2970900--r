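# Shrake-Rupley solvent-accessible surface area, reported as the fraction
# of each atom's probe-inflated sphere that is unoccluded, then discretized
# to multiples of a small step (default 0.43% of the in-vacuum surface).

# Chothia-style van der Waals radii by element (Angstrom)
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.00,
               P = 1.90, SE = 1.85)
DEFAULT_RADIUS <- 1.80

# Deterministic quasi-uniform sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface fractions
#'
#' Numerical (Shrake-Rupley) ASA on the heavy atoms of a structure:
#' each atom's sphere of radius r_vdw + probe is sampled at
#' `n_sphere_points` quasi-uniform points; a point is accessible when it
#' lies outside every neighbor's inflated sphere. The reported
#' `asa_fraction` is accessible points / total points, i.e. the exposed
#' fraction of the in-vacuum sphere surface, discretized to the nearest
#' multiple of `step` (0 disables discretization). Hydrogens are excluded
#' from the calculation; proton shifts inherit their bonded heavy atom's
#' value downstream.
#'
#' @param structure a `structure_model`.
#' @param probe_radius probe radius in Angstrom.
#' @param n_sphere_points quadrature points per atom.
#' @param step discretization step for the fraction (default 0.0043).
#' @return data.frame: chain_id, seq_pos, atom_name, asa_fraction.
#' @export
compute_asa <- function(structure,
                        probe_radius = sr_config()$probe_radius,
                        n_sphere_points = sr_config()$n_sphere_points,
                        step = sr_config()$asa_step) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms[structure$atoms$element != "H", , drop = FALSE]
  if (nrow(a) == 0L) stop("structure has no heavy atoms", call. = FALSE)
  r <- VDW_RADII[a$element]
  unknown <- is.na(r)
  if (any(unknown)) {
    message(sum(unknown), " atom(s) with unknown element given default radius ",
            DEFAULT_RADIUS)
    r[unknown] <- DEFAULT_RADIUS
  }
  r <- unname(r) + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sp <- sphere_points(n_sphere_points)
  n <- nrow(a)
  frac <- numeric(n)
  maxr <- max(r)
  for (i in seq_len(n)) {
    # candidate occluders: spheres that can reach atom i's surface
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    if (!length(nb)) { frac[i] <- 1; next }
    pts <- sp * r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      d2j <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- d2j >= r[j]^2
    }
    frac[i] <- sum(acc) / n_sphere_points
  }
  if (step > 0) frac <- round(frac / step) * step
  data.frame(chain_id = a$chain_id, seq_pos = a$seq_pos,
             atom_name = a$atom_name, asa_fraction = frac,
             stringsAsFactors = FALSE)
}
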
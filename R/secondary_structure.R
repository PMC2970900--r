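# Per-residue secondary structure from backbone coordinates using a
# hydrogen-bond electrostatic criterion (Kabsch-Sander style), mapped to six
# states: alpha_helix, helix_310, helix_pi, beta_strand, turn, coil.
# A documented approximation of STRIDE/DSSP, not a bit-exact reproduction;
# a precomputed backend ingests external assignments for full fidelity.

SS_LETTER_MAP <- c(H = "alpha_helix", G = "helix_310", I = "helix_pi",
                   E = "beta_strand", B = "beta_strand", T = "turn",
                   C = "coil")

# N-H..O=C hydrogen bond energy (kcal/mol); bonded if E < -0.5.
# Amide H is placed on N along the direction of the preceding C=O bond.
hbond_energy_matrix <- function(bb) {
  n <- nrow(bb$N)
  H <- bb$N
  for (i in 2:n) {
    co <- bb$C[i - 1, ] - bb$O[i - 1, ]
    H[i, ] <- bb$N[i, ] + co / sqrt(sum(co^2))
  }
  dist <- function(P, Q) {
    sqrt(outer(rowSums(P^2), rep(1, n)) + outer(rep(1, n), rowSums(Q^2)) -
           2 * P %*% t(Q))
  }
  rON <- dist(bb$O, bb$N); rCH <- dist(bb$C, H)
  rOH <- dist(bb$O, H);   rCN <- dist(bb$C, bb$N)
  E <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  # E[i, j]: CO of residue i accepting from NH of residue j; self and
  # sequence-adjacent pairs cannot hydrogen-bond
  E[, 1] <- Inf                       # first residue has no amide H placed
  E[abs(row(E) - col(E)) < 2] <- Inf
  E[is.na(E)] <- Inf
  E
}

#' Assign secondary structure states
#'
#' The builtin backend computes backbone N-H..O=C hydrogen bonds with the
#' classic electrostatic energy criterion (bond when E < -0.5 kcal/mol) and
#' applies pattern rules: two consecutive i -> i+4 turns give alpha_helix,
#' i -> i+3 gives helix_310, i -> i+5 gives helix_pi; ladder (bridge)
#' patterns give beta_strand; residues in an isolated hydrogen-bonded turn
#' give turn; everything else is coil. Residues with incomplete backbone are
#' coil. The precomputed backend reads whitespace-separated
#' (chain, seq_pos, letter) rows with letters H/G/I/E/B/T/C.
#'
#' @param structure a `structure_model`.
#' @param backend `"builtin"` or `"precomputed"`.
#' @param precomputed_file path of the state file for the precomputed backend.
#' @return data.frame: chain_id, seq_pos, ss_state.
#' @export
assign_secondary_structure <- function(structure,
                                       backend = c("builtin", "precomputed"),
                                       precomputed_file = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(structure, "structure_model"))
  res <- unique(structure$atoms[structure$atoms$residue_type %in% AA3,
                                c("chain_id", "seq_pos")])
  res <- res[order(res$chain_id, res$seq_pos), ]
  rownames(res) <- NULL
  if (backend == "precomputed") {
    tab <- utils::read.table(precomputed_file, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chain_id", "seq_pos", "letter"))
    st <- SS_LETTER_MAP[toupper(tab$letter)]
    if (anyNA(st)) stop("unknown state letter in ", precomputed_file,
                        call. = FALSE)
    idx <- match(paste(res$chain_id, res$seq_pos),
                 paste(tab$chain_id, tab$seq_pos))
    res$ss_state <- ifelse(is.na(idx), "coil", unname(st[idx]))
    return(res)
  }
  out <- lapply(split(res, res$chain_id), function(ch) {
    ch$ss_state <- ss_one_chain(structure, ch$chain_id[1], ch$seq_pos)
    ch
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chain_id, out$seq_pos), ]
}

ss_one_chain <- function(structure, chain, positions) {
  n <- length(positions)
  if (n < 3L) return(rep("coil", n))
  a <- structure$atoms[structure$atoms$chain_id == chain, ]
  getbb <- function(name) {
    idx <- match(paste(positions, name), paste(a$seq_pos, a$atom_name))
    m <- as.matrix(a[idx, c("x", "y", "z")])
    rownames(m) <- NULL
    m
  }
  bb <- list(N = getbb("N"), CA = getbb("CA"), C = getbb("C"), O = getbb("O"))
  complete <- Reduce(`&`, lapply(bb, function(m) apply(is.finite(m), 1, all)))
  complete[is.na(complete)] <- FALSE
  if (sum(complete) < 3L) return(rep("coil", n))
  # work on the complete stretch only; chain breaks (non-consecutive author
  # numbering) sever hydrogen-bond turn patterns implicitly via geometry
  for (k in names(bb)) bb[[k]][!complete, ] <- 1e6  # park incomplete residues
  E <- hbond_energy_matrix(bb)
  hb <- E < -0.5
  turn_at <- function(d) {  # turn of span d starting at i: CO(i) .. NH(i+d)
    v <- rep(FALSE, n)
    idx <- seq_len(n - d)
    v[idx] <- hb[cbind(idx, idx + d)]
    v
  }
  t3 <- turn_at(3); t4 <- turn_at(4); t5 <- if (n > 5) turn_at(5) else rep(FALSE, n)
  state <- rep("coil", n)
  mark_helix <- function(state, tn, d, label) {
    # two consecutive n-turns at i-1 and i start a helix i .. i+d-1
    for (i in 2:(n - d)) {
      if (tn[i] && tn[i - 1]) state[i:(i + d - 1)] <-
          ifelse(state[i:(i + d - 1)] == "coil", label, state[i:(i + d - 1)])
    }
    state
  }
  state <- mark_helix(state, t4, 4, "alpha_helix")
  state <- mark_helix(state, t3, 3, "helix_310")
  if (n > 6) state <- mark_helix(state, t5, 5, "helix_pi")
  # bridges: parallel (CO(i-1)->NH(j) and CO(j)->NH(i+1), or symmetric) /
  # antiparallel (CO(i)->NH(j) and CO(j)->NH(i), or CO(i-1)->NH(j+1) and
  # CO(j-1)->NH(i+1)) with |i-j| >= 3
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3) next
    para <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
    anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
    if (para || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
  }
  state[bridge & state == "coil"] <- "beta_strand"
  # turn (any): residues covered by an isolated hydrogen-bonded n-turn
  inturn <- rep(FALSE, n)
  for (d in c(3, 4, 5)) {
    tn <- if (d == 3) t3 else if (d == 4) t4 else t5
    for (i in which(tn)) inturn[i:min(n, i + d)] <- TRUE
  }
  state[inturn & state == "coil"] <- "turn"
  state
}
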
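# Global (Needleman-Wunsch) alignment of the shift-list sequence against the
# structure sequence, reduced to a one-to-one residue mapping. Scoring:
# match +1, mismatch -1, linear gap -2. Only identically typed aligned
# positions become mapping pairs; mismatches and gaps are excluded.

NW_MATCH <- 1; NW_MISMATCH <- -1; NW_GAP <- -2

# DP + traceback on character vectors; returns aligned index pairs
# (0 = gap) and the optimal score.
nw_align <- function(s1, s2) {
  n <- length(s1); m <- length(s2)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- NW_GAP * (0:n)
  F[1, ] <- NW_GAP * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(s2 == s1[i] & s1[i] != "-", NW_MATCH, NW_MISMATCH)
    for (j in seq_len(m)) {
      F[i + 1, j + 1] <- max(F[i, j] + sub[j],
                             F[i, j + 1] + NW_GAP,
                             F[i + 1, j] + NW_GAP)
    }
  }
  i <- n; j <- m; a1 <- integer(0); a2 <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        F[i + 1, j + 1] == F[i, j] +
          (if (s1[i] == s2[j] && s1[i] != "-") NW_MATCH else NW_MISMATCH)) {
      a1 <- c(i, a1); a2 <- c(j, a2); i <- i - 1; j <- j - 1
    } else if (i > 0 && F[i + 1, j + 1] == F[i, j + 1] + NW_GAP) {
      a1 <- c(i, a1); a2 <- c(0L, a2); i <- i - 1
    } else {
      a1 <- c(0L, a1); a2 <- c(j, a2); j <- j - 1
    }
  }
  list(i1 = a1, i2 = a2, score = F[n + 1, m + 1])
}

nw_score_alignment <- function(s1, s2, i1, i2) {
  sum(ifelse(i1 == 0L | i2 == 0L, NW_GAP,
             ifelse(s1[pmax(i1, 1)] == s2[pmax(i2, 1)] &
                      s1[pmax(i1, 1)] != "-", NW_MATCH, NW_MISMATCH)))
}

#' Map shift-list residue numbering onto structure numbering
#'
#' Globally aligns the two one-letter sequences (Needleman-Wunsch, match +1,
#' mismatch -1, gap -2) and pairs positions whose residue types agree;
#' mismatched and gapped positions are excluded from the mapping, so the
#' result is one-to-one and strictly increasing in both numberings.
#' Gap letters (`-`, unassigned positions) never count as matches.
#'
#' @param shift_seq result of [shift_sequence()] (or a list with `seq`,
#'   `positions`).
#' @param structure_seq result of [structure_sequence()].
#' @param identity_floor minimum aligned identity (matches / aligned
#'   columns, gaps excluded) below which the mapping is rejected.
#' @return a `residue_mapping`: data.frame `pairs`
#'   (shift_seq_pos, structure_seq_pos) with attributes `aligned_identity`
#'   and `score`.
#' @export
map_sequences <- function(shift_seq, structure_seq,
                          identity_floor = sr_config()$identity_floor) {
  s1 <- toupper(shift_seq$seq); s2 <- toupper(structure_seq$seq)
  if (!length(s1) || !length(s2)) stop("empty sequence", call. = FALSE)
  al <- nw_align(s1, s2)
  aligned <- al$i1 != 0L & al$i2 != 0L
  ident <- aligned & s1[pmax(al$i1, 1)] == s2[pmax(al$i2, 1)] &
    s1[pmax(al$i1, 1)] != "-"
  n_aligned <- sum(aligned & s1[pmax(al$i1, 1)] != "-" &
                     s2[pmax(al$i2, 1)] != "-")
  identity <- if (n_aligned > 0) sum(ident) / n_aligned else 0
  if (identity < identity_floor) {
    stop(sprintf(paste0("sequences do not correspond: aligned identity ",
                        "%.3f below floor %.2f"), identity, identity_floor),
         call. = FALSE)
  }
  pairs <- data.frame(
    shift_seq_pos = shift_seq$positions[al$i1[ident]],
    structure_seq_pos = structure_seq$positions[al$i2[ident]])
  structure(list(pairs = pairs, aligned_identity = identity,
                 score = al$score),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("<residue_mapping> %d pairs, aligned identity %.3f\n",
              nrow(x$pairs), x$aligned_identity))
  invisible(x)
}

#' Annotate structure atoms for classification
#'
#' Convenience wrapper combining [compute_asa()] and
#' [assign_secondary_structure()]: one row per heavy atom with its exposed
#' surface fraction and its parent residue's secondary structure state.
#'
#' @param structure a `structure_model`.
#' @param ... passed to [compute_asa()].
#' @param ss_backend,precomputed_file passed to
#'   [assign_secondary_structure()].
#' @return data.frame: chain_id, seq_pos, atom_name, asa_fraction, ss_state.
#' @export
annotate_structure <- function(structure, ..., ss_backend = "builtin",
                               precomputed_file = NULL) {
  asa <- compute_asa(structure, ...)
  ss <- assign_secondary_structure(structure, ss_backend, precomputed_file)
  asa$ss_state <- ss$ss_state[match(paste(asa$chain_id, asa$seq_pos),
                                    paste(ss$chain_id, ss$seq_pos))]
  asa$ss_state[is.na(asa$ss_state)] <- "coil"
  asa
}
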
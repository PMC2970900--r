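# Inference core: per-entry, per-nucleus-group posterior correction factors,
# the 3-sigma retention rule, and per-atom Z-scores.
#
# Model: a measured shift is delta_i = s_a(i) + c_g(i) + eps_i with
# eps_i ~ N(0, 1/k_a(i)), where class a has database mean s_a and precision
# k_a, and c_g is one unknown offset per nucleus group g. Under a flat prior
# the posterior for c_g is Gaussian with precision K = sum_a n_a k_a and
# mean (sum_a n_a k_a rbar_a) / K, rbar_a the mean residual delta - s_a of
# the entry's class-a shifts; the posterior sd is K^(-1/2). A correction is
# retained (applied) only when |mean| >= 3 * sd.

#' Pair each shift with its reference class
#'
#' A shift is classifiable when (i) its residue is paired in the
#' shift-to-structure mapping, (ii) its (heavy) atom has an annotation, and
#' (iii) its (atom type, ss state, ASA bin) class is present in the
#' reference database. Protons inherit the ASA annotation of their bonded
#' heavy atom. Unclassifiable shifts are excluded and counted.
#'
#' @param table a `shift_table`.
#' @param annotations data.frame from [annotate_structure()] (structure
#'   numbering).
#' @param mapping a `residue_mapping`.
#' @param refdb a `reference_db`.
#' @return data.frame of classified shifts: the shift columns plus group,
#'   atom_type, ss_state, bin_index, mean_ppm, precision; attribute
#'   `excluded` holds per-reason counts.
#' @export
classify_shifts <- function(table, annotations, mapping, refdb) {
  rec <- table$records
  rec$structure_seq_pos <- mapping$pairs$structure_seq_pos[
    match(rec$seq_pos, mapping$pairs$shift_seq_pos)]
  n_unmapped <- sum(is.na(rec$structure_seq_pos))
  rec <- rec[!is.na(rec$structure_seq_pos), , drop = FALSE]
  # protons carry their bonded heavy atom's annotation
  rec$anno_atom <- heavy_parent(rec$residue_type, rec$atom_name)
  akey <- paste(annotations$seq_pos, annotations$atom_name)
  ai <- match(paste(rec$structure_seq_pos, rec$anno_atom), akey)
  n_unannotated <- sum(is.na(ai))
  rec$asa_fraction <- annotations$asa_fraction[ai]
  rec$ss_state <- annotations$ss_state[ai]
  rec <- rec[!is.na(ai), , drop = FALSE]
  n_no_class <- 0L
  out <- rec[0, , drop = FALSE]
  if (nrow(rec)) {
    cls <- lookup_class(rec, refdb)
    keep <- !is.na(cls$class_mean_ppm)
    n_no_class <- sum(!keep)
    out <- cbind(rec[keep, , drop = FALSE], cls[keep, , drop = FALSE])
  }
  if (nrow(out) == 0L) {
    stop("no classifiable shifts (unmapped: ", n_unmapped,
         ", unannotated: ", n_unannotated, ", no class: ", n_no_class, ")",
         call. = FALSE)
  }
  out$group <- assign_group(out$residue_type, out$atom_name)
  rownames(out) <- NULL
  attr(out, "excluded") <- list(unmapped = n_unmapped,
                                unannotated = n_unannotated,
                                no_class = n_no_class)
  out
}

# Reference-class lookup for annotated shifts. The class atom type is the
# shift's own atom name (a proton class is an H class); only the ASA/SS
# annotation is inherited from the bonded heavy atom upstream.
lookup_class <- function(rec, refdb) {
  atom_type <- atom_type_key(rec$residue_type, rec$atom_name,
                             refdb$scheme$mode)
  bins <- assign_bins(data.frame(atom_type = atom_type,
                                 ss_state = rec$ss_state,
                                 asa_fraction = rec$asa_fraction),
                      refdb$scheme)
  si <- match(paste(atom_type, rec$ss_state, bins),
              paste(refdb$stats$atom_type, refdb$stats$ss_state,
                    refdb$stats$bin_index))
  data.frame(atom_type = atom_type, bin_index = bins,
             class_mean_ppm = refdb$stats$mean_ppm[si],
             class_precision = refdb$stats$precision[si])
}

#' Posterior correction factor for one nucleus group
#'
#' Closed-form Gaussian posterior under a flat prior: precision
#' K = sum n_a k_a, mean = precision-weighted mean residual, uncertainty =
#' K^(-1/2). `retained` is TRUE when |mean| >= `retention_sigma` *
#' uncertainty; non-retained corrections are applied as zero.
#'
#' @param classified data.frame from [classify_shifts()] (any subset).
#' @param group group label; only that group's rows are used.
#' @param retention_sigma retention threshold in posterior sds (default 3).
#' @param min_group_shifts below this count the correction is additionally
#'   flagged `low_confidence`.
#' @return one-row data.frame: group, mean_ppm, uncertainty_ppm,
#'   total_precision, n_shifts_used, retained, low_confidence.
#' @export
posterior_correction <- function(classified, group,
                                 retention_sigma = sr_config()$retention_sigma,
                                 min_group_shifts = sr_config()$min_group_shifts) {
  rows <- classified[classified$group == group, , drop = FALSE]
  n <- nrow(rows)
  if (n == 0L) {
    return(data.frame(group = group, mean_ppm = 0, uncertainty_ppm = Inf,
                      total_precision = 0, n_shifts_used = 0L,
                      retained = FALSE, low_confidence = TRUE))
  }
  k <- rows$class_precision
  r <- rows$value_ppm - rows$class_mean_ppm
  K <- sum(k)                       # == sum_a n_a k_a over classes
  cbar <- sum(k * r) / K            # == sum_a n_a k_a rbar_a / K
  sigma <- 1 / sqrt(K)
  data.frame(group = group, mean_ppm = cbar, uncertainty_ppm = sigma,
             total_precision = K, n_shifts_used = n,
             retained = abs(cbar) >= retention_sigma * sigma,
             low_confidence = n < min_group_shifts)
}

#' Corrections for all five nucleus groups
#'
#' @inheritParams posterior_correction
#' @return five-row data.frame (one per group, absent groups with
#'   n_shifts_used = 0 and retained = FALSE).
#' @export
group_corrections <- function(classified,
                              retention_sigma = sr_config()$retention_sigma,
                              min_group_shifts = sr_config()$min_group_shifts) {
  out <- do.call(rbind, lapply(NUCLEUS_GROUPS, function(g)
    posterior_correction(classified, g, retention_sigma, min_group_shifts)))
  rownames(out) <- NULL
  out
}

# Group corrections straight from annotated observations (used by the
# iterative reference build, where there is no shift_table/mapping).
corrections_for_observations <- function(obs, refdb,
                                         retention_sigma =
                                           sr_config()$retention_sigma) {
  cls <- lookup_class(
    data.frame(residue_type = obs$residue_type, atom_name = obs$atom_name,
               ss_state = obs$ss_state, asa_fraction = obs$asa_fraction),
    refdb)
  keep <- !is.na(cls$class_mean_ppm)
  classified <- cbind(obs[keep, , drop = FALSE], cls[keep, , drop = FALSE])
  classified$group <- if (nrow(classified))
    assign_group(classified$residue_type, classified$atom_name) else character(0)
  group_corrections(classified, retention_sigma)
}

#' Apply retained corrections to a shift table
#'
#' The correction factor is the offset contained in the measured shifts, so
#' the corrected value is `original - correction`. Non-retained corrections
#' leave shifts unchanged. Originals are preserved in `value_ppm_original`.
#'
#' @param table a `shift_table`.
#' @param corrections data.frame from [group_corrections()].
#' @return the `shift_table` with corrected `value_ppm` and an added
#'   `value_ppm_original` column.
#' @export
apply_corrections <- function(table, corrections) {
  rec <- table$records
  g <- assign_group(rec$residue_type, rec$atom_name)
  i <- match(g, corrections$group)
  adj <- ifelse(corrections$retained[i], corrections$mean_ppm[i], 0)
  rec$value_ppm_original <- rec$value_ppm
  rec$value_ppm <- rec$value_ppm - adj
  table$records <- rec
  table
}

#' Per-atom Z-scores of corrected shifts
#'
#' z = (corrected - s_a) * sqrt(k_a) for every classified shift, against its
#' class distribution.
#'
#' @param classified data.frame from [classify_shifts()].
#' @param corrections data.frame from [group_corrections()]; retained
#'   corrections are subtracted before standardization.
#' @return data.frame: chain_id, seq_pos, residue_type, atom_name, group,
#'   atom_type, ss_state, bin_index, value_ppm, corrected_ppm, z.
#' @export
zscore_shifts <- function(classified, corrections = NULL) {
  adj <- 0
  if (!is.null(corrections)) {
    i <- match(classified$group, corrections$group)
    adj <- ifelse(corrections$retained[i], corrections$mean_ppm[i], 0)
  }
  corrected <- classified$value_ppm - adj
  data.frame(chain_id = classified$chain_id, seq_pos = classified$seq_pos,
             residue_type = classified$residue_type,
             atom_name = classified$atom_name, group = classified$group,
             atom_type = classified$atom_type,
             ss_state = classified$ss_state,
             bin_index = classified$bin_index,
             value_ppm = classified$value_ppm, corrected_ppm = corrected,
             z = (corrected - classified$class_mean_ppm) *
               sqrt(classified$class_precision),
             stringsAsFactors = FALSE)
}

#' Stability under random shift deletion
#'
#' For each removal fraction, repeatedly deletes that fraction of the
#' entry's classified shifts uniformly at random, recomputes the group
#' corrections, and counts the samples in which a correction is retained
#' ("erroneously found", for an entry requiring no correction). Deterministic
#' under a fixed seed.
#'
#' @param classified data.frame from [classify_shifts()].
#' @param removal_fractions fractions in (0, 1) (0 allowed: no deletion).
#' @param n_samples random samples per fraction.
#' @param seed RNG seed.
#' @param retention_sigma retention threshold.
#' @return data.frame: fraction, group, n_samples, n_retained,
#'   mean_n_shifts.
#' @export
stability_experiment <- function(classified, removal_fractions,
                                 n_samples = 1000L, seed = 1L,
                                 retention_sigma = sr_config()$retention_sigma) {
  if (any(removal_fractions < 0 | removal_fractions >= 1)) {
    stop("removal fractions must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(classified)
  k <- classified$class_precision
  r <- classified$value_ppm - classified$class_mean_ppm
  gi <- match(classified$group, NUCLEUS_GROUPS)
  out <- list()
  for (f in removal_fractions) {
    keep_n <- n - floor(f * n)
    ret <- matrix(0L, length(NUCLEUS_GROUPS), 1)
    counts <- numeric(length(NUCLEUS_GROUPS))
    nret <- integer(length(NUCLEUS_GROUPS))
    for (s in seq_len(n_samples)) {
      idx <- if (keep_n == n) seq_len(n) else sample.int(n, keep_n)
      K <- unname(rowsum_fixed(k[idx], gi[idx], 5L))
      S <- unname(rowsum_fixed(k[idx] * r[idx], gi[idx], 5L))
      cbar <- ifelse(K > 0, S / K, 0)
      sig <- ifelse(K > 0, 1 / sqrt(K), Inf)
      nret <- nret + as.integer(K > 0 & abs(cbar) >= retention_sigma * sig)
      counts <- counts + tabulate(gi[idx], 5L)
    }
    out[[length(out) + 1L]] <- data.frame(
      fraction = f, group = NUCLEUS_GROUPS, n_samples = n_samples,
      n_retained = nret, mean_n_shifts = counts / n_samples)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# rowsum with a fixed number of output slots (groups absent from x give 0)
rowsum_fixed <- function(x, g, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
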
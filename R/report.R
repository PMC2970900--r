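# Correction/validation report: a plain-text file with a per-group
# correction block and a per-atom block (original shift, corrected shift,
# class id, Z-score). Round-trippable via read_report().

#' Write a correction/validation report
#'
#' Emits all five nucleus groups (absent ones with zero counts), then one
#' row per classified atom. The stated correction factor is the offset
#' contained in the measured shifts; the applied operation is
#' corrected = original - correction (retained groups only).
#'
#' @param corrections data.frame from [group_corrections()].
#' @param zscores data.frame from [zscore_shifts()] (may have zero rows).
#' @param dest output path.
#' @param entry_id identifier written into the header.
#' @export
write_report <- function(corrections, zscores, dest, entry_id = "entry") {
  stopifnot(all(NUCLEUS_GROUPS %in% corrections$group))
  corrections <- corrections[match(NUCLEUS_GROUPS, corrections$group), ]
  grp <- sprintf("%s\t%a\t%a\t%a\t%d\t%d\t%d",
                 corrections$group, corrections$mean_ppm,
                 corrections$uncertainty_ppm, corrections$total_precision,
                 corrections$n_shifts_used, as.integer(corrections$retained),
                 as.integer(corrections$low_confidence))
  lines <- c(sprintf("# shiftref report v1 entry=%s", entry_id),
             "[groups]",
             paste("group", "correction_ppm", "uncertainty_ppm",
                   "total_precision", "n_shifts_used", "retained",
                   "low_confidence", sep = "\t"),
             grp,
             "[atoms]",
             paste("chain_id", "seq_pos", "residue_type", "atom_name",
                   "group", "atom_type", "ss_state", "bin_index",
                   "value_ppm", "corrected_ppm", "z", sep = "\t"))
  if (nrow(zscores)) {
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%d\t%a\t%a\t%a",
                              zscores$chain_id, zscores$seq_pos,
                              zscores$residue_type, zscores$atom_name,
                              zscores$group, zscores$atom_type,
                              zscores$ss_state, zscores$bin_index,
                              zscores$value_ppm, zscores$corrected_ppm,
                              zscores$z))
  }
  writeLines(lines, dest)
  invisible(dest)
}

#' @rdname write_report
#' @param source report file path.
#' @return list with `entry_id`, `corrections`, `zscores`.
#' @export
read_report <- function(source) {
  lines <- readLines(source, warn = FALSE)
  entry_id <- sub(".*entry=", "", lines[1])
  gi <- which(lines == "[groups]"); ai <- which(lines == "[atoms]")
  if (!length(gi) || !length(ai)) stop("not a report file: ", source,
                                       call. = FALSE)
  gbody <- lines[(gi + 2):(ai - 1)]
  gm <- do.call(rbind, strsplit(gbody, "\t", fixed = TRUE))
  corrections <- data.frame(
    group = gm[, 1], mean_ppm = strtoi_hexfloat(gm[, 2]),
    uncertainty_ppm = strtoi_hexfloat(gm[, 3]),
    total_precision = strtoi_hexfloat(gm[, 4]),
    n_shifts_used = as.integer(gm[, 5]),
    retained = gm[, 6] == "1", low_confidence = gm[, 7] == "1",
    stringsAsFactors = FALSE)
  abody <- if (ai + 1 < length(lines) || (ai + 1) <= length(lines))
    lines[seq(ai + 2, length.out = max(0, length(lines) - ai - 1))] else
      character(0)
  zscores <- if (length(abody)) {
    am <- do.call(rbind, strsplit(abody, "\t", fixed = TRUE))
    data.frame(chain_id = am[, 1], seq_pos = as.integer(am[, 2]),
               residue_type = am[, 3], atom_name = am[, 4], group = am[, 5],
               atom_type = am[, 6], ss_state = am[, 7],
               bin_index = as.integer(am[, 8]),
               value_ppm = strtoi_hexfloat(am[, 9]),
               corrected_ppm = strtoi_hexfloat(am[, 10]),
               z = strtoi_hexfloat(am[, 11]), stringsAsFactors = FALSE)
  } else {
    zscore_shifts(data.frame(chain_id = character(0), seq_pos = integer(0),
                             residue_type = character(0),
                             atom_name = character(0), group = character(0),
                             atom_type = character(0), ss_state = character(0),
                             bin_index = integer(0), value_ppm = numeric(0),
                             class_mean_ppm = numeric(0),
                             class_precision = numeric(0)))
  }
  list(entry_id = entry_id, corrections = corrections, zscores = zscores)
}
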
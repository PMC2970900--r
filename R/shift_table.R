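# Shift-list IO: a simple 5-column TSV dialect and the NMR-STAR v3
# assigned-chemical-shift loop. Both produce a `shift_table`.

new_shift_table <- function(entry_id, records, parse_report = NULL) {
  stopifnot(is.data.frame(records))
  records <- records[, c("chain_id", "seq_pos", "residue_type",
                         "atom_name", "value_ppm")]
  records$seq_pos <- as.integer(records$seq_pos)
  records$value_ppm <- as.numeric(records$value_ppm)
  rownames(records) <- NULL
  structure(list(entry_id = entry_id, records = records,
                 parse_report = parse_report %||%
                   list(rows_in = nrow(records), kept = nrow(records),
                        dropped = 0L)),
            class = "shift_table")
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("<shift_table> entry %s: %d shifts, %d chain(s)\n",
              x$entry_id, nrow(x$records),
              length(unique(x$records$chain_id))))
  invisible(x)
}

validate_shift_records <- function(rec, on_duplicate = c("reject", "last")) {
  on_duplicate <- match.arg(on_duplicate)
  rows_in <- nrow(rec)
  rec$residue_type <- toupper(rec$residue_type)
  rec$atom_name <- canonicalize_atom_name(rec$atom_name, rec$residue_type)
  at <- atom_table()
  known <- paste(rec$residue_type, rec$atom_name) %in%
    paste(at$residue, at$atom)
  ok <- rec$residue_type %in% AA3 & known &
    is.finite(rec$value_ppm) & nzchar(rec$atom_name)
  dropped <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  key <- paste(rec$chain_id, rec$seq_pos, rec$atom_name)
  if (anyDuplicated(key)) {
    if (on_duplicate == "reject") {
      stop(sprintf("duplicate shift for (chain %s, pos %s, atom %s)",
                   rec$chain_id[duplicated(key)][1],
                   rec$seq_pos[duplicated(key)][1],
                   rec$atom_name[duplicated(key)][1]), call. = FALSE)
    }
    rec <- rec[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("empty shift table after filtering", call. = FALSE)
  list(records = rec,
       report = list(rows_in = rows_in, kept = nrow(rec), dropped = dropped))
}

#' Read an assigned chemical shift list
#'
#' The `tsv` dialect is a headered tab-separated file with columns
#' `chain_id`, `seq_pos`, `residue_type`, `atom_name`, `value_ppm`. The
#' `nmrstar` dialect reads the first `_Atom_chem_shift` loop of an NMR-STAR
#' v3 file (tags: Entity_assembly_ID/Auth_asym_ID, Seq_ID, Comp_ID,
#' Atom_ID, Val). Rows with non-standard residues, unknown atom names or
#' non-finite values are dropped and counted in the parse report.
#'
#' @param source path to the file.
#' @param dialect `"tsv"` or `"nmrstar"`.
#' @param entry_id identifier stored in the table (default: file stem).
#' @param on_duplicate `"reject"` (default) or `"last"` for duplicate
#'   (chain, position, atom) rows.
#' @return a `shift_table`.
#' @export
read_shift_table <- function(source, dialect = c("tsv", "nmrstar"),
                             entry_id = NULL,
                             on_duplicate = c("reject", "last")) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("no such file: ", source, call. = FALSE)
  entry_id <- entry_id %||% sub("\\.[^.]*$", "", basename(source))
  rec <- if (dialect == "tsv") parse_shift_tsv(source) else
    parse_shift_star(source)
  if (nrow(rec) == 0L) stop("empty shift table: ", source, call. = FALSE)
  v <- validate_shift_records(rec, on_duplicate)
  new_shift_table(entry_id, v$records, v$report)
}

parse_shift_tsv <- function(source) {
  tab <- utils::read.table(source, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chain_id", "seq_pos", "residue_type", "atom_name", "value_ppm")
  if (!all(need %in% names(tab))) {
    stop("malformed shift TSV (need columns ",
         paste(need, collapse = ", "), "): ", source, call. = FALSE)
  }
  data.frame(chain_id = tab$chain_id,
             seq_pos = suppressWarnings(as.integer(tab$seq_pos)),
             residue_type = tab$residue_type, atom_name = tab$atom_name,
             value_ppm = suppressWarnings(as.numeric(tab$value_ppm)),
             stringsAsFactors = FALSE)
}

# Minimal STAR loop reader: finds the loop_ whose tags include
# _Atom_chem_shift.Val and tokenizes its data rows.
parse_shift_star <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines <- trimws(lines)
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (lines[i] == "loop_") {
      j <- i + 1L; tags <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        tags <- c(tags, lines[j]); j <- j + 1L
      }
      if (any(grepl("^_Atom_chem_shift\\.", tags))) {
        rows <- list()
        while (j <= n && !lines[j] %in% c("stop_", "loop_") &&
               !startsWith(lines[j], "_")) {
          if (nzchar(lines[j]) && !startsWith(lines[j], "#")) {
            tok <- scan(text = lines[j], what = character(),
                        quiet = TRUE, quote = "\"'")
            if (length(tok) == length(tags)) rows[[length(rows) + 1L]] <- tok
            else stop(sprintf("malformed NMR-STAR row at line %d of %s",
                              j, source), call. = FALSE)
          }
          j <- j + 1L
        }
        if (!length(rows)) stop("empty _Atom_chem_shift loop: ", source,
                                call. = FALSE)
        m <- do.call(rbind, rows)
        colnames(m) <- sub("^_Atom_chem_shift\\.", "", tags)
        pick <- function(...) {
          for (nm in c(...)) if (nm %in% colnames(m)) return(m[, nm])
          rep(NA_character_, nrow(m))
        }
        chain <- pick("Auth_asym_ID", "Entity_assembly_ID")
        chain[is.na(chain) | chain == "."] <- "A"
        return(data.frame(
          chain_id = chain,
          seq_pos = suppressWarnings(as.integer(pick("Seq_ID", "Comp_index_ID"))),
          residue_type = pick("Comp_ID"),
          atom_name = pick("Atom_ID"),
          value_ppm = suppressWarnings(as.numeric(pick("Val"))),
          stringsAsFactors = FALSE))
      }
      i <- j
    } else i <- i + 1L
  }
  stop("no _Atom_chem_shift loop found in ", source, call. = FALSE)
}

#' Write a shift table in the TSV dialect
#' @param table a `shift_table`.
#' @param dest output path.
#' @export
write_shift_table <- function(table, dest) {
  stopifnot(inherits(table, "shift_table"))
  utils::write.table(table$records, dest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dest)
}

#' One-letter sequence of a shift table chain
#'
#' Derived from residue types at each assigned position; unassigned
#' positions inside the observed range become gaps (`-`).
#'
#' @param table a `shift_table`.
#' @param chain chain id (default: first chain).
#' @return list with `seq` (character vector, one letter per position),
#'   `positions` (author numbering of each letter).
#' @export
shift_sequence <- function(table, chain = NULL) {
  rec <- table$records
  chain <- chain %||% rec$chain_id[1]
  rec <- rec[rec$chain_id == chain, ]
  if (!nrow(rec)) stop("no such chain: ", chain, call. = FALSE)
  pos <- sort(unique(rec$seq_pos))
  full <- seq(min(pos), max(pos))
  res <- rec$residue_type[match(full, rec$seq_pos)]
  letters1 <- ifelse(is.na(res), "-", seq1(res))
  list(seq = letters1, positions = full)
}
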
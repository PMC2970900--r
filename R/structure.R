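# PDB coordinate reading. Fixed-column ATOM/HETATM parsing, MODEL selection,
# altloc resolution by occupancy.

new_structure_model <- function(entry_id, atoms, model_index = 0L,
                                n_models = 1L) {
  stopifnot(is.data.frame(atoms))
  atoms <- atoms[, c("chain_id", "seq_pos", "residue_type", "atom_name",
                     "x", "y", "z", "element")]
  rownames(atoms) <- NULL
  structure(list(entry_id = entry_id, atoms = atoms,
                 model_index = as.integer(model_index),
                 n_models = as.integer(n_models)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: model %d/%d, %d atoms, %d residues\n",
              x$entry_id, x$model_index + 1L, x$n_models, nrow(x$atoms),
              length(unique(paste(x$atoms$chain_id, x$atoms$seq_pos)))))
  invisible(x)
}

#' Read a PDB coordinate file
#'
#' Parses ATOM records (HETATM skipped except for selenomethionine-style
#' standard residues) of one model of a possibly multi-model file.
#' Alternate locations are resolved to the highest occupancy (ties: first
#' encountered). Hydrogens are retained when present.
#'
#' @param source PDB file path.
#' @param model_index 0-based model to load (default 0 = first model).
#' @param entry_id identifier (default: file stem).
#' @return a `structure_model`.
#' @export
read_structure <- function(source, model_index = 0L, entry_id = NULL) {
  if (!file.exists(source)) stop("no such file: ", source, call. = FALSE)
  entry_id <- entry_id %||% sub("\\.[^.]*$", "", basename(source))
  lines <- readLines(source, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  n_models <- max(1L, length(model_starts))
  if (model_index < 0L || model_index >= n_models) {
    stop(sprintf("model_index %d out of range: file has models 0..%d",
                 model_index, n_models - 1L), call. = FALSE)
  }
  if (length(model_starts)) {
    ends <- c(grep("^ENDMDL", lines), length(lines))
    from <- model_starts[model_index + 1L]
    to <- ends[ends > from][1]
    lines <- lines[from:to]
  }
  rec <- lines[startsWith(lines, "ATOM  ")]
  if (!length(rec)) stop("no ATOM records in ", source, call. = FALSE)
  fx <- function(a, b) trimws(substring(rec, a, b))
  atoms <- data.frame(
    atom_name = fx(13, 16),
    altloc = fx(17, 17),
    residue_type = fx(18, 20),
    chain_id = fx(22, 22),
    seq_pos = as.integer(fx(23, 26)),
    x = as.numeric(fx(31, 38)),
    y = as.numeric(fx(39, 46)),
    z = as.numeric(fx(47, 54)),
    occupancy = suppressWarnings(as.numeric(fx(55, 60))),
    element = fx(77, 78),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # element column may be absent in minimal files; infer from the name
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- ifelse(
    grepl("^[0-9]*H", atoms$atom_name[noel]), "H",
    substring(gsub("[0-9]", "", atoms$atom_name[noel]), 1, 1))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in ", source, call. = FALSE)
  }
  # altloc: keep the highest-occupancy location per atom, first on ties
  key <- paste(atoms$chain_id, atoms$seq_pos, atoms$atom_name)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
    atoms <- atoms[ord, ][!duplicated(sort(key)), ]
    atoms <- atoms[order(as.integer(rownames(atoms))), ]
  }
  new_structure_model(entry_id, atoms, model_index, n_models)
}

#' Write a structure model as a minimal PDB file
#' @param model a `structure_model`.
#' @param dest output path.
#' @export
write_structure <- function(model, dest) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  pad_name <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name),
                     a$atom_name)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), pad_name, a$residue_type, a$chain_id, a$seq_pos,
    a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), dest)
  invisible(dest)
}

#' One-letter sequence of a structure chain
#' @param model a `structure_model`.
#' @param chain chain id (default first).
#' @return list with `seq` and `positions`, as [shift_sequence()].
#' @export
structure_sequence <- function(model, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain_id[1]
  a <- a[a$chain_id == chain & a$residue_type %in% AA3, ]
  if (!nrow(a)) stop("no standard residues in chain ", chain, call. = FALSE)
  pos <- sort(unique(a$seq_pos))
  full <- seq(min(pos), max(pos))
  res <- a$residue_type[match(full, a$seq_pos)]
  list(seq = ifelse(is.na(res), "-", seq1(res)), positions = full)
}
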
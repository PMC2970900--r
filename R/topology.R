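# Residue topology: heavy atoms of the 20 standard amino acids with element,
# attached-hydrogen count and aromatic-ring membership, plus derived proton
# names. Drives nucleus-group assignment and atom-name validation.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Heavy-atom topology table
#'
#' @return data.frame with columns residue, atom, element, n_h, aromatic.
#' @export
residue_topology <- function() {
  if (is.null(.sr_cache$topology)) {
    path <- system.file("extdata", "residue_topology.tsv", package = "shiftref",
                        mustWork = TRUE)
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("residue", "atom", "element",
                                           "n_h", "aromatic"))
    tab$aromatic <- tab$aromatic == 1L
    .sr_cache$topology <- tab
  }
  .sr_cache$topology
}

# IUPAC proton names for one heavy atom. Methylene carbons take suffixes 2/3,
# amide/guanidino nitrogens 1/2, methyls and NH3 1/2/3; single protons drop
# the index (backbone N -> H, CA -> HA, TYR OH -> HH).
proton_names_for <- function(atom, element, n_h) {
  if (n_h == 0L) return(character(0))
  base <- sub("^[A-Z]", "", atom)          # strip element letter: CB -> B
  if (n_h == 1L) return(paste0("H", base))
  idx <- if (n_h == 2L && element == "C") c("2", "3") else seq_len(n_h)
  paste0("H", base, idx)
}

#' Full atom-name table (heavy atoms and protons)
#'
#' One row per valid IUPAC atom name per residue. Protons carry the name of
#' the heavy atom they are bonded to in `parent`, used for ASA inheritance.
#'
#' @return data.frame with columns residue, atom, element, n_h, aromatic, parent.
#' @export
atom_table <- function() {
  if (is.null(.sr_cache$atoms)) {
    topo <- residue_topology()
    topo$parent <- NA_character_
    h_rows <- do.call(rbind, lapply(seq_len(nrow(topo)), function(i) {
      nm <- proton_names_for(topo$atom[i], topo$element[i], topo$n_h[i])
      if (!length(nm)) return(NULL)
      data.frame(residue = topo$residue[i], atom = nm, element = "H",
                 n_h = 0L, aromatic = FALSE, parent = topo$atom[i],
                 stringsAsFactors = FALSE)
    }))
    .sr_cache$atoms <- rbind(topo, h_rows)
  }
  .sr_cache$atoms
}

#' Canonicalize an atom name to the package's IUPAC dialect
#'
#' Maps common shift-list variants onto one representative name:
#' alternation lists (`HB2|HB3`), wildcard pseudo-atoms (`HB#`, `HB*`,
#' `HB%`), methyl (`MB`) and pair (`QB`) pseudo-atoms, and old-style
#' digit-first names (`2HB`). Unrecognized names pass through unchanged and
#' fail validation downstream.
#'
#' @param atom_name character vector of raw atom names.
#' @param residue_type matching 3-letter residue codes.
#' @return character vector of canonical names.
#' @export
canonicalize_atom_name <- function(atom_name, residue_type) {
  stopifnot(length(atom_name) == length(residue_type))
  at <- atom_table()
  vapply(seq_along(atom_name), function(i) {
    nm <- toupper(trimws(atom_name[i]))
    res <- toupper(residue_type[i])
    nm <- sub("[|/].*$", "", nm)                       # HB2|HB3 -> HB2
    if (grepl("^[0-9]H", nm)) {                        # 2HB -> HB2
      nm <- paste0(substring(nm, 2), substring(nm, 1, 1))
    }
    if (grepl("^[MQ][A-Z0-9]+$", nm)) {                # MB/QB -> first HB*
      nm <- paste0("H", substring(nm, 2), "#")
    }
    if (grepl("[#*%]$", nm)) {                         # HB# -> first match
      stem <- sub("[#*%]+$", "", nm)
      cand <- at$atom[at$residue == res & at$element == "H" &
                        startsWith(at$atom, stem)]
      if (length(cand)) nm <- sort(cand)[1]
    }
    nm
  }, character(1))
}

#' Assign a chemical shift to its nucleus group
#'
#' Every proton maps to group `H` and every nitrogen to `N`. Carbons split
#' three ways: members of an aromatic ring are `C_aro` (aromaticity takes
#' precedence even for ring carbons without protons, e.g. PHE CG), other
#' carbons without attached protons are `C_noH` (carbonyl C, ASP/ASN CG,
#' GLU/GLN CD, ARG CZ), and the rest are `C_ali`.
#'
#' @param residue_type 3-letter code(s).
#' @param atom_name IUPAC atom name(s), canonicalized if needed.
#' @return character vector of group labels.
#' @export
#' @examples
#' assign_group("ALA", "CA")   # C_ali
#' assign_group("GLY", "C")    # C_noH
#' assign_group("PHE", "CD1")  # C_aro
#' assign_group("LYS", "HA")   # H
assign_group <- function(residue_type, atom_name) {
  n <- max(length(residue_type), length(atom_name))
  residue_type <- rep_len(toupper(residue_type), n)
  atom_name <- rep_len(toupper(atom_name), n)
  at <- atom_table()
  key <- paste(at$residue, at$atom)
  idx <- match(paste(residue_type, atom_name), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown atom name for residue: (%s, %s)",
                 residue_type[bad], atom_name[bad]), call. = FALSE)
  }
  el <- at$element[idx]
  if (any(el %in% c("O", "S"))) {
    bad <- which(el %in% c("O", "S"))[1]
    stop(sprintf("atom (%s, %s) is not a shift-bearing nucleus (element %s)",
                 residue_type[bad], atom_name[bad], el[bad]), call. = FALSE)
  }
  out <- character(n)
  out[el == "H"] <- "H"
  out[el == "N"] <- "N"
  isc <- el == "C"
  out[isc & at$aromatic[idx]] <- "C_aro"
  out[isc & !at$aromatic[idx] & at$n_h[idx] == 0L] <- "C_noH"
  out[isc & !at$aromatic[idx] & at$n_h[idx] > 0L] <- "C_ali"
  out
}

# Heavy atom whose ASA a proton inherits; heavy atoms map to themselves.
# NA for unknown names.
heavy_parent <- function(residue_type, atom_name) {
  at <- atom_table()
  idx <- match(paste(toupper(residue_type), toupper(atom_name)),
               paste(at$residue, at$atom))
  out <- ifelse(is.na(idx), NA_character_,
                ifelse(is.na(at$parent[idx]), at$atom[idx], at$parent[idx]))
  out
}

seq1 <- function(residue_type) unname(AA1[toupper(residue_type)])
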
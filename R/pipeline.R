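# End-to-end orchestration: read -> annotate -> map -> classify -> correct
# -> apply -> Z-score -> report, plus the command-line front end.

#' Run the full correction/validation pipeline on one entry
#'
#' @param shifts path to a shift list, or a `shift_table`.
#' @param structure path to a PDB file, or a `structure_model`.
#' @param refdb path to a reference database file, or a `reference_db`.
#' @param out optional report destination; when NULL nothing is written.
#' @param dialect shift-list dialect for file input.
#' @param model_index 0-based model of a multi-model structure file.
#' @param ss_backend,precomputed_ss secondary-structure backend selection.
#' @param identity_floor minimum aligned sequence identity.
#' @param retention_sigma retention threshold in posterior sds.
#' @param dry_run validate inputs and stop before computing (writes nothing).
#' @return list: `corrections`, `zscores`, `corrected` (shift_table),
#'   `mapping`, `excluded` counts; invisibly NULL under `dry_run`.
#' @export
run_entry <- function(shifts, structure, refdb, out = NULL,
                      dialect = "tsv", model_index = 0L,
                      ss_backend = "builtin", precomputed_ss = NULL,
                      identity_floor = sr_config()$identity_floor,
                      retention_sigma = sr_config()$retention_sigma,
                      dry_run = FALSE) {
  table <- if (inherits(shifts, "shift_table")) shifts else
    read_shift_table(shifts, dialect)
  model <- if (inherits(structure, "structure_model")) structure else
    read_structure(structure, model_index)
  db <- if (inherits(refdb, "reference_db")) refdb else
    read_reference_db(refdb)
  if (dry_run) {
    message("dry run: inputs valid (", nrow(table$records), " shifts, ",
            nrow(model$atoms), " atoms, ", nrow(db$stats), " classes)")
    return(invisible(NULL))
  }
  anno <- annotate_structure(model, ss_backend = ss_backend,
                             precomputed_file = precomputed_ss)
  mapping <- map_sequences(shift_sequence(table), structure_sequence(model),
                           identity_floor)
  classified <- classify_shifts(table, anno, mapping, db)
  corrections <- group_corrections(classified, retention_sigma)
  corrected <- apply_corrections(table, corrections)
  zs <- zscore_shifts(classified, corrections)
  if (!is.null(out)) write_report(corrections, zs, out, table$entry_id)
  list(corrections = corrections, zscores = zs, corrected = corrected,
       mapping = mapping, excluded = attr(classified, "excluded"))
}

#' Command-line interface
#'
#' Subcommands: `run` (per-entry correction/validation), `refdb-build`
#' (iterative reference build from annotated observation files),
#' `stability` (random-deletion robustness experiment), `synth`
#' (`refdb`/`entry`/`structure` fixture generation). Flags override config
#' file values, which override defaults; the config file is flat
#' `key=value` text. Returns the exit code instead of calling `quit()` so
#' the function is testable in-process; the installed `shiftref` script
#' wraps it.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success).
#' @export
shiftref_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: shiftref <run|refdb-build|stability|synth> ...",
                            call. = FALSE)
    cmd <- args[1]
    opts <- parse_cli_opts(args[-1])
    cfg <- load_cli_config(opts)
    switch(cmd,
           run = cli_run(opts, cfg),
           `refdb-build` = cli_refdb_build(opts, cfg),
           stability = cli_stability(opts, cfg),
           synth = cli_synth(opts, cfg),
           stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}

# --flag value pairs plus bare switches (--dry-run)
parse_cli_opts <- function(args) {
  opts <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else { positional <- c(positional, a); i <- i + 1L }
  }
  opts$positional <- positional
  opts
}

load_cli_config <- function(opts) {
  cfg <- sr_config()
  if (!is.null(opts$config)) {
    lines <- readLines(opts$config, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) cfg[[trimws(kv[1])]] <-
          utils::type.convert(trimws(kv[2]), as.is = TRUE)
    }
  }
  num_keys <- c("retention_sigma", "identity_floor", "asa_step",
                "target_bin_count", "n_iterations")
  for (k in num_keys) if (!is.null(opts[[k]])) cfg[[k]] <-
      as.numeric(opts[[k]])
  cfg
}

cli_run <- function(opts, cfg) {
  for (k in c("shifts", "structure", "refdb"))
    if (is.null(opts[[k]])) stop("run: missing --", k, call. = FALSE)
  res <- run_entry(opts$shifts, opts$structure, opts$refdb,
                   out = opts$out,
                   dialect = opts$dialect %||% "tsv",
                   model_index = as.integer(opts$model %||% 0L),
                   ss_backend = opts$`ss-backend` %||% "builtin",
                   precomputed_ss = opts$`ss-file`,
                   identity_floor = cfg$identity_floor,
                   retention_sigma = cfg$retention_sigma,
                   dry_run = isTRUE(opts$`dry-run`))
  if (!is.null(res)) {
    message(sprintf("excluded shifts: unmapped=%d unannotated=%d no_class=%d",
                    res$excluded$unmapped, res$excluded$unannotated,
                    res$excluded$no_class))
    ret <- res$corrections[res$corrections$retained, ]
    message(sprintf("%d retained correction(s)%s", nrow(ret),
                    if (nrow(ret)) paste0(": ",
                      paste(sprintf("%s %+0.3f ppm", ret$group, ret$mean_ppm),
                            collapse = ", ")) else ""))
  }
  invisible(NULL)
}

cli_refdb_build <- function(opts, cfg) {
  if (is.null(opts$out) || !length(opts$positional)) {
    stop("refdb-build: usage: shiftref refdb-build --out F obs1.tsv obs2.tsv ...",
         call. = FALSE)
  }
  entries <- lapply(opts$positional, function(p)
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  db <- iterative_build(entries,
                        n_iterations = as.integer(cfg$n_iterations),
                        target_bin_count = as.integer(cfg$target_bin_count),
                        mode = opts$mode %||% "residue_atom")
  write_reference_db(db, opts$out)
  message("wrote ", nrow(db$stats), " classes to ", opts$out)
}

cli_stability <- function(opts, cfg) {
  for (k in c("entry", "structure", "refdb"))
    if (is.null(opts[[k]])) stop("stability: missing --", k, call. = FALSE)
  spec <- strsplit(opts$fractions %||% "0.1:0.9:0.1", ":")[[1]]
  fractions <- seq(as.numeric(spec[1]), as.numeric(spec[2]),
                   by = as.numeric(spec[3]))
  res <- run_entry(opts$entry, opts$structure, opts$refdb,
                   identity_floor = cfg$identity_floor,
                   retention_sigma = cfg$retention_sigma)
  table <- read_shift_table(opts$entry)
  model <- read_structure(opts$structure)
  db <- read_reference_db(opts$refdb)
  anno <- annotate_structure(model)
  mapping <- map_sequences(shift_sequence(table), structure_sequence(model),
                           cfg$identity_floor)
  classified <- classify_shifts(table, anno, mapping, db)
  tab <- stability_experiment(classified, fractions,
                              n_samples = as.integer(opts$samples %||% 1000L),
                              seed = as.integer(opts$seed %||% 42L),
                              retention_sigma = cfg$retention_sigma)
  dest <- opts$out %||% stdout()
  utils::write.table(tab, dest, sep = "\t", quote = FALSE, row.names = FALSE)
}

cli_synth <- function(opts, cfg) {
  what <- opts$positional[1] %||% ""
  seed <- as.integer(opts$seed %||% 1L)
  if (what == "refdb") {
    db <- make_refdb(seed = seed, mode = opts$mode %||% "direct")
    write_reference_db(db, opts$out %||% stop("synth refdb: missing --out",
                                              call. = FALSE))
  } else if (what == "entry") {
    db <- read_reference_db(opts$refdb %||% stop("synth entry: missing --refdb",
                                                 call. = FALSE))
    offs <- c()
    if (!is.null(opts$offsets)) {  # e.g. "C_ali=2.0,N=-1"
      kv <- strsplit(strsplit(opts$offsets, ",")[[1]], "=")
      offs <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                              vapply(kv, `[`, "", 1))
    }
    e <- make_entry(db, n_shifts = as.integer(opts$n %||% 200L),
                    offsets = offs, seed = seed)
    write_shift_table(e$table, opts$out %||% stop("synth entry: missing --out",
                                                  call. = FALSE))
  } else if (what == "structure") {
    m <- make_toy_structure(opts$kind %||% "ideal_helix",
                            n_residues = as.integer(opts$n %||% 12L))
    write_structure(m, opts$out %||% stop("synth structure: missing --out",
                                          call. = FALSE))
  } else stop("synth: expected refdb|entry|structure", call. = FALSE)
}
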
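# Class-conditional Gaussian reference statistics. A class is
# (atom type, secondary structure state, ASA bin); within each
# (atom type, ss) stratum, shifts are binned by solvent accessibility so
# that interior bins hold `target_bin_count` observations each: the
# zero-ASA bin may hold more, the highest-ASA bin may hold fewer, and tied
# (discretized) ASA values are never split across bins. Classes with fewer
# than `target_bin_count` observations are excluded from inference.

atom_type_key <- function(residue_type, atom_name, mode) {
  if (mode == "atom") toupper(atom_name)
  else paste(toupper(residue_type), toupper(atom_name))
}

#' Build an ASA binning scheme
#'
#' Per (atom type, secondary structure) stratum: observations at exactly
#' zero ASA form bin 0; the rest, sorted by ASA, are cut into consecutive
#' runs of `target_bin_count`, extending a run to the right so that one
#' discretized ASA value always stays in one bin; the highest bin keeps the
#' remainder.
#'
#' @param observations data.frame with columns residue_type, atom_name,
#'   ss_state, asa_fraction (plus value_ppm, ignored here).
#' @param target_bin_count interior bin size (default 200).
#' @param mode `"residue_atom"` (atom type = residue + atom name) or
#'   `"atom"` (atom name only, for small synthetic populations).
#' @return a `binning_scheme`: data.frame bins (atom_type, ss_state,
#'   bin_index, bin_low, bin_high, build_count) with attributes.
#' @export
build_binning <- function(observations,
                          target_bin_count = sr_config()$target_bin_count,
                          mode = c("residue_atom", "atom")) {
  mode <- match.arg(mode)
  stopifnot(nrow(observations) > 0)
  obs <- observations
  obs$atom_type <- atom_type_key(obs$residue_type, obs$atom_name, mode)
  strata <- split(obs$asa_fraction, list(obs$atom_type, obs$ss_state),
                  drop = TRUE, sep = "\r")
  bins <- lapply(names(strata), function(key) {
    asa <- strata[[key]]
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    b <- bin_one_stratum(asa, target_bin_count)
    if (is.null(b)) return(NULL)
    b$atom_type <- parts[1]; b$ss_state <- parts[2]
    b
  })
  bins <- do.call(rbind, bins)
  if (is.null(bins)) {
    bins <- data.frame(bin_index = integer(0), bin_low = numeric(0),
                       bin_high = numeric(0), build_count = integer(0),
                       atom_type = character(0), ss_state = character(0))
  }
  bins <- bins[, c("atom_type", "ss_state", "bin_index", "bin_low",
                   "bin_high", "build_count")]
  rownames(bins) <- NULL
  structure(list(bins = bins, target_bin_count = as.integer(target_bin_count),
                 mode = mode),
            class = "binning_scheme")
}

# Bin one stratum's ASA values. Returns NULL when the stratum cannot yield
# any bin (fewer than target observations and no zero-ASA pile of that size
# would still be emitted -- bins are emitted whenever the stratum is
# nonempty; undersized bins are dropped later at the class-stats stage,
# except the scheme itself records them so bin lookup stays total).
bin_one_stratum <- function(asa, target) {
  zero <- sum(asa == 0)
  pos <- sort(asa[asa > 0])
  rows <- list()
  if (zero > 0) {
    rows[[1]] <- data.frame(bin_index = 0L, bin_low = 0, bin_high = 0,
                            build_count = zero)
  }
  if (length(pos)) {
    # runs over distinct values: close a bin when it reaches `target`
    vals <- rle(pos)
    sizes <- integer(0); cur <- 0L; lows <- numeric(0); cur_low <- vals$values[1]
    for (k in seq_along(vals$values)) {
      cur <- cur + vals$lengths[k]
      if (cur >= target) {
        sizes <- c(sizes, cur); lows <- c(lows, cur_low)
        cur <- 0L
        if (k < length(vals$values)) cur_low <- vals$values[k + 1]
      }
    }
    if (cur > 0L) { sizes <- c(sizes, cur); lows <- c(lows, cur_low) }
    k <- length(sizes)
    start <- if (zero > 0) 1L else 0L
    highs <- c(lows[-1], Inf)
    rows[[length(rows) + 1L]] <- data.frame(
      bin_index = seq(start, start + k - 1L),
      bin_low = lows, bin_high = highs, build_count = sizes)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

# Locate the bin index for discretized ASA values within one stratum's bins
# (data.frame ordered by bin_index). Exact zeros go to the zero bin when it
# exists; otherwise intervals are half-open [low, high), last bin closed,
# with out-of-range values clamped to the nearest bin.
lookup_bin <- function(stratum_bins, asa) {
  has_zero <- stratum_bins$bin_low[1] == 0 && stratum_bins$bin_high[1] == 0
  interior <- if (has_zero) stratum_bins[-1, , drop = FALSE] else stratum_bins
  out <- integer(length(asa))
  if (nrow(interior) == 0L) {
    out[] <- if (has_zero) 0L else NA_integer_
    return(out)
  }
  idx <- findInterval(asa, interior$bin_low)   # 0 => below first low: clamp
  idx[idx < 1L] <- 1L
  out <- interior$bin_index[idx]
  if (has_zero) out[asa == 0] <- 0L
  out
}

#' Fit per-class Gaussian statistics
#'
#' Mean and precision (inverse unbiased variance) of the shift values in
#' each (atom type, ss state, ASA bin) class. Classes with fewer than the
#' scheme's `target_bin_count` observations, or with zero variance, are
#' excluded.
#'
#' @param observations data.frame with residue_type, atom_name, ss_state,
#'   asa_fraction, value_ppm.
#' @param scheme a `binning_scheme`.
#' @param min_count minimum class size (default: the scheme's target).
#' @return data.frame of class statistics: atom_type, ss_state, bin_index,
#'   bin_low, bin_high, count, mean_ppm, variance_ppm2, precision.
#' @export
fit_class_stats <- function(observations, scheme,
                            min_count = scheme$target_bin_count) {
  obs <- observations
  obs$atom_type <- atom_type_key(obs$residue_type, obs$atom_name, scheme$mode)
  obs$bin_index <- assign_bins(obs, scheme)
  obs <- obs[!is.na(obs$bin_index), , drop = FALSE]
  if (!nrow(obs)) return(empty_class_stats())
  key <- paste(obs$atom_type, obs$ss_state, obs$bin_index, sep = "\r")
  agg <- lapply(split(obs$value_ppm, key), function(v) {
    c(n = length(v), mean = mean(v), var = stats::var(v))
  })
  m <- do.call(rbind, agg)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  st <- data.frame(atom_type = parts[, 1], ss_state = parts[, 2],
                   bin_index = as.integer(parts[, 3]),
                   count = as.integer(m[, "n"]), mean_ppm = m[, "mean"],
                   variance_ppm2 = m[, "var"], stringsAsFactors = FALSE)
  bk <- paste(scheme$bins$atom_type, scheme$bins$ss_state,
              scheme$bins$bin_index)
  bi <- match(paste(st$atom_type, st$ss_state, st$bin_index), bk)
  st$bin_low <- scheme$bins$bin_low[bi]
  st$bin_high <- scheme$bins$bin_high[bi]
  keep <- st$count >= min_count & is.finite(st$variance_ppm2) &
    st$variance_ppm2 > 0
  st <- st[keep, , drop = FALSE]
  st$precision <- 1 / st$variance_ppm2
  st <- st[order(st$atom_type, st$ss_state, st$bin_index), ,
           drop = FALSE]
  rownames(st) <- NULL
  st[, c("atom_type", "ss_state", "bin_index", "bin_low", "bin_high",
         "count", "mean_ppm", "variance_ppm2", "precision")]
}

empty_class_stats <- function() {
  data.frame(atom_type = character(0), ss_state = character(0),
             bin_index = integer(0), bin_low = numeric(0),
             bin_high = numeric(0), count = integer(0),
             mean_ppm = numeric(0), variance_ppm2 = numeric(0),
             precision = numeric(0))
}

# Vector bin assignment against a scheme; NA for unknown strata.
assign_bins <- function(obs, scheme) {
  out <- rep(NA_integer_, nrow(obs))
  skey <- paste(scheme$bins$atom_type, scheme$bins$ss_state, sep = "\r")
  okey <- paste(obs$atom_type, obs$ss_state, sep = "\r")
  for (key in unique(okey)) {
    sb <- scheme$bins[skey == key, , drop = FALSE]
    if (!nrow(sb)) next
    sel <- okey == key
    out[sel] <- lookup_bin(sb[order(sb$bin_index), , drop = FALSE],
                           obs$asa_fraction[sel])
  }
  out
}

new_reference_db <- function(scheme, stats, metadata = list()) {
  structure(list(scheme = scheme, stats = stats, metadata = metadata),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf(paste0("<reference_db> %d classes (%s mode, bin size %d), ",
                     "built from %s entries, %s iteration(s)\n"),
              nrow(x$stats), x$scheme$mode, x$scheme$target_bin_count,
              x$metadata$n_entries %||% "?", x$metadata$n_iterations %||% "?"))
  invisible(x)
}

#' Build a reference database from pooled observations (single pass)
#'
#' @param observations pooled annotated shifts: residue_type, atom_name,
#'   ss_state, asa_fraction, value_ppm.
#' @inheritParams build_binning
#' @return a `reference_db`.
#' @export
build_reference_db <- function(observations,
                               target_bin_count = sr_config()$target_bin_count,
                               mode = c("residue_atom", "atom")) {
  mode <- match.arg(mode)
  scheme <- build_binning(observations, target_bin_count, mode)
  stats <- fit_class_stats(observations, scheme)
  new_reference_db(scheme, stats,
                   list(n_entries = length(unique(observations$entry_id %||%
                                                    "pooled")),
                        n_iterations = 1L))
}

#' Iterative self-consistent reference build
#'
#' Pass 1 builds the scheme and statistics from the raw shifts. Each later
#' pass computes per-entry group corrections against the current statistics,
#' subtracts the retained corrections from that entry's shifts, and rebuilds
#' the scheme and statistics, so that systematically mis-referenced entries
#' stop distorting the reference distributions. Two passes are the default;
#' more have no significant effect.
#'
#' @param entries list of annotated entry data.frames (columns entry_id,
#'   residue_type, atom_name, ss_state, asa_fraction, value_ppm).
#' @param n_iterations total build passes (default 2).
#' @inheritParams build_binning
#' @return a `reference_db` whose metadata records entry and iteration
#'   counts.
#' @export
iterative_build <- function(entries,
                            n_iterations = sr_config()$n_iterations,
                            target_bin_count = sr_config()$target_bin_count,
                            mode = c("residue_atom", "atom")) {
  mode <- match.arg(mode)
  stopifnot(length(entries) >= 2, n_iterations >= 1)
  pool <- function(es) do.call(rbind, es)
  cur <- entries
  db <- build_reference_db(pool(cur), target_bin_count, mode)
  if (n_iterations > 1) for (it in seq_len(n_iterations - 1)) {
    cur <- lapply(entries, function(e) {
      corr <- corrections_for_observations(e, db)
      g <- assign_group(e$residue_type, e$atom_name)
      adj <- corr$mean_ppm[match(g, corr$group)]
      adj[is.na(adj) | !corr$retained[match(g, corr$group)]] <- 0
      e$value_ppm <- e$value_ppm - adj
      e
    })
    db <- build_reference_db(pool(cur), target_bin_count, mode)
  }
  db$metadata <- list(n_entries = length(entries),
                      n_iterations = as.integer(n_iterations))
  db
}

#' Write / read a reference database (versioned tabular text)
#'
#' Full-precision (hex float) serialization so that write/read round-trips
#' bit-exactly.
#'
#' @param db a `reference_db`.
#' @param dest,source file path.
#' @export
write_reference_db <- function(db, dest) {
  stopifnot(inherits(db, "reference_db"))
  hdr <- c("# shiftref reference database v1",
           sprintf("# mode=%s target_bin_count=%d n_entries=%s n_iterations=%s",
                   db$scheme$mode, db$scheme$target_bin_count,
                   db$metadata$n_entries %||% NA,
                   db$metadata$n_iterations %||% NA))
  st <- db$stats
  body <- sprintf("%s\t%s\t%d\t%a\t%a\t%d\t%a\t%a",
                  st$atom_type, st$ss_state, st$bin_index, st$bin_low,
                  st$bin_high, st$count, st$mean_ppm, st$variance_ppm2)
  cols <- paste("atom_type", "ss_state", "bin_index", "bin_low", "bin_high",
                "count", "mean_ppm", "variance_ppm2", sep = "\t")
  writeLines(c(hdr, cols, body), dest)
  invisible(dest)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(source) {
  lines <- readLines(source, warn = FALSE)
  meta_line <- grep("^# mode=", lines, value = TRUE)[1]
  if (is.na(meta_line)) stop("not a reference database file: ", source,
                             call. = FALSE)
  get <- function(k) sub(sprintf(".*%s=([^ ]+).*", k), "\\1", meta_line)
  body <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  stats <- if (length(body) > 1) {
    m <- do.call(rbind, strsplit(body[-1], "\t", fixed = TRUE))
    colnames(m) <- hdr
    data.frame(atom_type = m[, "atom_type"], ss_state = m[, "ss_state"],
               bin_index = as.integer(m[, "bin_index"]),
               bin_low = strtoi_hexfloat(m[, "bin_low"]),
               bin_high = strtoi_hexfloat(m[, "bin_high"]),
               count = as.integer(m[, "count"]),
               mean_ppm = strtoi_hexfloat(m[, "mean_ppm"]),
               variance_ppm2 = strtoi_hexfloat(m[, "variance_ppm2"]),
               stringsAsFactors = FALSE)
  } else empty_class_stats()[, 1:8]
  stats$precision <- 1 / stats$variance_ppm2
  tbc <- as.integer(get("target_bin_count"))
  scheme <- structure(
    list(bins = data.frame(atom_type = stats$atom_type,
                           ss_state = stats$ss_state,
                           bin_index = stats$bin_index,
                           bin_low = stats$bin_low,
                           bin_high = stats$bin_high,
                           build_count = stats$count),
         target_bin_count = tbc, mode = get("mode")),
    class = "binning_scheme")
  new_reference_db(scheme, stats,
                   list(n_entries = suppressWarnings(as.integer(get("n_entries"))),
                        n_iterations = suppressWarnings(
                          as.integer(get("n_iterations")))))
}

strtoi_hexfloat <- function(x) {
  vapply(x, function(s) {
    if (s %in% c("Inf", "inf")) Inf
    else if (s %in% c("-Inf", "-inf")) -Inf
    else strtod_c(s)
  }, numeric(1), USE.NAMES = FALSE)
}

# base R parses C99 hex floats via scan(dec = ".") only through as.numeric
strtod_c <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("cannot parse number: ", s, call. = FALSE)
  v
}
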
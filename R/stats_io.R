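# Per-residue fit statistics: a TSV dialect emulating the per-residue data
# served by the electron-density databanks (RSR, RSCC, average occupancy,
# occupancy-weighted B), plus model-level lines.
#
# Layout:
#   #meta resolution 1.80        (optional)
#   #meta r_free 0.220           (optional)
#   #meta source PDB_REDO        (optional, default PDB)
#   chain res_seq icode comp_id rsr rscc occ owab   <- tab-separated header
#   A     1       .     GLY     0.120 0.950 1.000 18.000
# Missing values are '.'; icode '.' means no insertion code.

.STATS_COLS <- c("chain", "res_seq", "icode", "comp_id",
                 "rsr", "rscc", "occ", "owab")

#' Per-residue statistics record
#'
#' Convenience constructor for a single residue's fit statistics, as consumed
#' by [evaluate_component()].  Use `NA` for absent values.
#'
#' @param rsr Real-space R-value, `>= 0`.
#' @param rscc Real-space correlation coefficient, in `[-1, 1]`.
#' @param avg_occupancy Residue average occupancy, in `[0, 1]`.
#' @param owab Occupancy-weighted average B-factor, in square angstrom.
#' @return list with class `ligqc_residue_stats`.
#' @export
residue_stats <- function(rsr = NA_real_, rscc = NA_real_,
                          avg_occupancy = NA_real_, owab = NA_real_) {
  if (!is.na(rsr) && (!is.finite(rsr) || rsr < 0)) stop("rsr must be finite and >= 0")
  if (!is.na(rscc) && abs(rscc) > 1) stop("rscc must lie in [-1,1]")
  structure(list(rsr = rsr, rscc = rscc, avg_occupancy = avg_occupancy,
                 owab = owab), class = "ligqc_residue_stats")
}

#' Bundle per-residue and model-level statistics
#'
#' @param per_residue data.frame with columns `chain`, `res_seq`, `icode`,
#'   `comp_id`, `rsr`, `rscc`, `occ`, `owab` (NA for absent).
#' @param resolution,r_free Model-level numbers, `NA` when unknown.
#' @param source Databank dialect, `"PDB"` or `"PDB_REDO"`; downstream the
#'   profile's source must match.
#' @return A `ligqc_stats_bundle`.
#' @export
stats_bundle <- function(per_residue,
                         resolution = NA_real_, r_free = NA_real_,
                         source = c("PDB", "PDB_REDO")) {
  source <- match.arg(source)
  missing_cols <- setdiff(.STATS_COLS, names(per_residue))
  if (length(missing_cols)) {
    stop("stats table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  per_residue$res_key <- .residue_key(per_residue$comp_id, per_residue$chain,
                                      as.integer(per_residue$res_seq),
                                      ifelse(per_residue$icode %in% c(".", ""),
                                             "", per_residue$icode))
  dup <- per_residue$res_key[duplicated(per_residue$res_key)]
  if (length(dup)) {
    stop("duplicate residue key in stats table: ", dup[1])
  }
  rownames(per_residue) <- NULL
  structure(list(per_residue = per_residue,
                 model_stats = list(resolution = resolution, r_free = r_free),
                 source = source),
            class = "ligqc_stats_bundle")
}

#' Parse a per-residue statistics table
#'
#' @param text Path, single string, or character vector of lines in the TSV
#'   dialect described under [write_stats_table()].
#' @return A `ligqc_stats_bundle`.
#' @export
parse_stats_table <- function(text) {
  lines <- .as_lines(text)
  meta <- list(resolution = NA_real_, r_free = NA_real_, source = "PDB")
  mlines <- grep("^#meta\\s", lines, value = TRUE)
  for (ml in mlines) {
    parts <- strsplit(trimws(ml), "\\s+")[[1]]
    if (length(parts) != 3L) stop("malformed #meta line: ", ml)
    key <- parts[2]; val <- parts[3]
    if (key == "source") {
      if (!val %in% c("PDB", "PDB_REDO")) stop("unknown source: ", val)
      meta$source <- val
    } else if (key %in% c("resolution", "r_free")) {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) stop("non-numeric #meta value: ", ml)
      meta[[key]] <- v
    } else {
      stop("unknown #meta key: ", key)
    }
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("stats table has no header row")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  unknown <- setdiff(header, .STATS_COLS)
  if (length(unknown)) stop("unknown column: ", paste(unknown, collapse = ", "))
  if (!setequal(header, .STATS_COLS)) {
    stop("stats table must have columns: ", paste(.STATS_COLS, collapse = ", "))
  }
  rows <- body[-1]
  if (length(rows)) {
    cells <- strsplit(rows, "\t", fixed = TRUE)
    nc <- lengths(cells)
    if (any(nc != length(header))) {
      stop("row with wrong field count: ", rows[which(nc != length(header))[1]])
    }
    mat <- do.call(rbind, cells)
    colnames(mat) <- header
    df <- as.data.frame(mat, stringsAsFactors = FALSE)[, .STATS_COLS]
  } else {
    df <- as.data.frame(setNames(rep(list(character()), length(.STATS_COLS)),
                                 .STATS_COLS), stringsAsFactors = FALSE)
  }
  df$res_seq <- suppressWarnings(as.integer(df$res_seq))
  if (anyNA(df$res_seq)) stop("non-numeric res_seq in stats table")
  for (col in c("rsr", "rscc", "occ", "owab")) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & raw != ".")
    if (length(bad)) stop(sprintf("non-numeric %s value: '%s'", col, raw[bad[1]]))
    df[[col]] <- v
  }
  stats_bundle(df, resolution = meta$resolution, r_free = meta$r_free,
               source = meta$source)
}

#' Write a per-residue statistics table
#'
#' Inverse of [parse_stats_table()].  Numeric values are written at 3
#' decimals; absent values as `.`.
#'
#' @param bundle A `ligqc_stats_bundle`.
#' @param path Optional output path.
#' @return Character vector of lines (invisibly when `path` is given).
#' @export
write_stats_table <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "ligqc_stats_bundle"))
  num <- function(v) ifelse(is.na(v), ".", sprintf("%.3f", v))
  hdr <- character()
  if (!is.na(bundle$model_stats$resolution)) {
    hdr <- c(hdr, sprintf("#meta resolution %.3f", bundle$model_stats$resolution))
  }
  if (!is.na(bundle$model_stats$r_free)) {
    hdr <- c(hdr, sprintf("#meta r_free %.3f", bundle$model_stats$r_free))
  }
  hdr <- c(hdr, paste("#meta source", bundle$source),
           paste(.STATS_COLS, collapse = "\t"))
  p <- bundle$per_residue
  rows <- if (nrow(p)) {
    paste(p$chain, p$res_seq,
          ifelse(p$icode %in% c("", "."), ".", p$icode), p$comp_id,
          num(p$rsr), num(p$rscc), num(p$occ), num(p$owab), sep = "\t")
  } else character()
  lines <- c(hdr, rows)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Look up statistics for a set of residues
#'
#' For each requested key, returns the table entry; when the table carries
#' no occupancy the residue average occupancy is recomputed from the model
#' coordinates; keys with no table entry yield empty stats (only the
#' coordinate-derived occupancy), which the classifier's missing-data policy
#' then scores as unmet.
#'
#' @param model A `ligqc_model`.
#' @param bundle A `ligqc_stats_bundle`.
#' @param keys Character vector of residue keys.
#' @return data.frame keyed by `res_key` with `rsr`, `rscc`,
#'   `avg_occupancy`, `owab`.
#' @export
stats_for <- function(model, bundle, keys) {
  keys <- as.character(keys)
  if (!length(keys)) {
    return(data.frame(res_key = character(), rsr = numeric(),
                      rscc = numeric(), avg_occupancy = numeric(),
                      owab = numeric(), stringsAsFactors = FALSE))
  }
  out <- data.frame(res_key = keys,
                    rsr = NA_real_, rscc = NA_real_,
                    avg_occupancy = NA_real_, owab = NA_real_,
                    stringsAsFactors = FALSE)
  m <- match(keys, bundle$per_residue$res_key)
  hit <- !is.na(m)
  out$rsr[hit] <- bundle$per_residue$rsr[m[hit]]
  out$rscc[hit] <- bundle$per_residue$rscc[m[hit]]
  out$avg_occupancy[hit] <- bundle$per_residue$occ[m[hit]]
  out$owab[hit] <- bundle$per_residue$owab[m[hit]]
  need_occ <- which(is.na(out$avg_occupancy) & keys %in% model$atoms$res_key)
  for (i in need_occ) {
    out$avg_occupancy[i] <- residue_average_occupancy(model, keys[i])
  }
  out
}
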
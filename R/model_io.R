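# Fixed-column PDB (v3.3) coordinate I/O and the internal structure model.
#
# A structure model is a list with class "ligqc_model":
#   model_id : 4-character structure code
#   atoms    : data.frame, one row per atom after alt-loc resolution
#   meta     : list(resolution, r_free, source) -- NA when unknown
#
# Atom columns: serial, name, alt_loc, comp_id, chain, res_seq, icode,
# x, y, z, occupancy, b_factor, element, is_hetero, is_water, is_polymer,
# res_key.  res_key is "<comp_id>:<chain>:<res_seq><icode>" and identifies a
# residue uniquely within a model.

.WATER_CODES <- c("HOH", "DOD", "WAT")

.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (any(grepl("\n", text))) {
    return(unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE))
  }
  text
}

.residue_key <- function(comp_id, chain, res_seq, icode) {
  sprintf("%s:%s:%d%s", comp_id, chain, res_seq, icode)
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [parse_structure()] and the fixture
#' generator.  Derives water/polymer flags and residue keys, validates the
#' model invariants, and clamps out-of-range occupancies with a warning.
#'
#' @param atoms data.frame with columns `serial`, `name`, `alt_loc`,
#'   `comp_id`, `chain`, `res_seq`, `icode`, `x`, `y`, `z`, `occupancy`,
#'   `b_factor`, `element`, `is_hetero`.
#' @param model_id 4-character structure code.
#' @param meta list with optional `resolution`, `r_free`, `source`.
#' @return A `ligqc_model` object.
#' @export
structure_model <- function(atoms, model_id = "XXXX",
                            meta = list(resolution = NA_real_,
                                        r_free = NA_real_,
                                        source = "PDB")) {
  required <- c("serial", "name", "alt_loc", "comp_id", "chain", "res_seq",
                "icode", "x", "y", "z", "occupancy", "b_factor", "element",
                "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(atoms)) stop("a structure model must contain at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  bad_occ <- atoms$occupancy < 0 | atoms$occupancy > 1
  if (any(bad_occ, na.rm = TRUE)) {
    warning(sprintf("%d occupancies outside [0,1] clamped", sum(bad_occ)))
    atoms$occupancy <- pmin(pmax(atoms$occupancy, 0), 1)
  }
  if (any(atoms$b_factor < 0, na.rm = TRUE)) {
    warning("negative B-factors clamped to 0")
    atoms$b_factor <- pmax(atoms$b_factor, 0)
  }
  atoms$is_water <- atoms$comp_id %in% .WATER_CODES
  atoms$is_polymer <- !atoms$is_hetero
  atoms$res_key <- .residue_key(atoms$comp_id, atoms$chain,
                                atoms$res_seq, atoms$icode)
  rownames(atoms) <- NULL
  meta$resolution <- if (is.null(meta$resolution)) NA_real_ else meta$resolution
  meta$r_free <- if (is.null(meta$r_free)) NA_real_ else meta$r_free
  meta$source <- if (is.null(meta$source)) "PDB" else meta$source
  if (!is.na(meta$resolution) && meta$resolution <= 0) {
    stop("resolution must be positive")
  }
  if (!is.na(meta$r_free) && (meta$r_free < 0 || meta$r_free > 1)) {
    stop("r_free must lie in [0,1]")
  }
  structure(list(model_id = model_id, atoms = atoms, meta = meta),
            class = "ligqc_model")
}

#' @export
print.ligqc_model <- function(x, ...) {
  res <- model_residues(x)
  cat(sprintf("<ligqc_model %s: %d atoms, %d residues (%d polymer, %d hetero, %d water)>\n",
              x$model_id, nrow(x$atoms), nrow(res),
              sum(res$is_polymer), sum(res$is_hetero & !res$is_water),
              sum(res$is_water)))
  invisible(x)
}

.parse_num_field <- function(lines, lnums, lo, hi, what,
                             default = NA_real_) {
  raw <- trimws(substr(lines, lo, hi))
  v <- suppressWarnings(as.numeric(raw))
  blank <- raw == ""
  if (!is.na(default)) v[blank] <- default
  bad <- which(is.na(v) & !blank | (blank & is.na(default)))
  if (length(bad)) {
    stop(sprintf("malformed %s field at line %d", what, lnums[bad[1]]))
  }
  v
}

.infer_element <- function(name, comp_id) {
  two <- c("NA", "MG", "CL", "ZN", "MN", "FE", "CU", "NI", "CO", "CD",
           "HG", "BR", "SE", "CA", "K", "LI", "RB", "CS", "SR", "BA")
  stripped <- gsub("[0-9']", "", name)
  out <- substr(stripped, 1, 1)
  # metal/ion convention: residue named after the element itself
  ion <- toupper(comp_id) == toupper(stripped) & toupper(stripped) %in% two
  out[ion] <- stripped[ion]
  out
}

#' Parse a PDB-format coordinate file
#'
#' Reads ATOM/HETATM records of the first coordinate model (records after the
#' first `ENDMDL` are ignored), resolves alternate locations by keeping, per
#' atom name within a residue, the conformer with the highest occupancy (ties
#' broken by alphabetically first alt-loc identifier), and flags waters
#' (`HOH`/`DOD`/`WAT`).  `ANISOU`, `CONECT`, `REMARK`, `TER` and all other
#' records are ignored.  A residue is treated as polymer when its record type
#' is `ATOM` and as hetero when `HETATM`.
#'
#' @param text Path to a PDB file, a single string with embedded newlines, or
#'   a character vector of lines.
#' @param model_id Structure code stored on the model.
#' @param source Databank dialect the coordinates came from, `"PDB"` or
#'   `"PDB_REDO"`.
#' @return A `ligqc_model`.
#' @examples
#' lines <- c(
#'  "HETATM    1  C1  LIG A 101      10.000  10.000  10.000  1.00 20.00           C",
#'  "END")
#' m <- parse_structure(lines, "TEST")
#' nrow(m$atoms)
#' @export
parse_structure <- function(text, model_id = "XXXX",
                            source = c("PDB", "PDB_REDO")) {
  source <- match.arg(source)
  lines <- .as_lines(text)
  lnums <- seq_along(lines)
  # keep only the first coordinate model
  mstart <- grep("^MODEL", lines)
  if (length(mstart)) {
    mend <- grep("^ENDMDL", lines)
    last <- if (length(mend)) mend[1] else length(lines)
    sel <- seq(mstart[1], last)
    lines <- lines[sel]
    lnums <- lnums[sel]
  }
  is_coord <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  lines <- lines[is_coord]
  lnums <- lnums[is_coord]
  if (!length(lines)) stop("no parsable ATOM/HETATM coordinate record found")

  res_seq_raw <- trimws(substr(lines, 23, 26))
  res_seq <- suppressWarnings(as.integer(res_seq_raw))
  if (anyNA(res_seq)) {
    stop(sprintf("malformed residue sequence field at line %d",
                 lnums[which(is.na(res_seq))[1]]))
  }
  serial <- suppressWarnings(as.integer(trimws(substr(lines, 7, 11))))
  serial[is.na(serial)] <- 0L

  atoms <- data.frame(
    serial = serial,
    name = trimws(substr(lines, 13, 16)),
    alt_loc = trimws(substr(lines, 17, 17)),
    comp_id = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    res_seq = res_seq,
    icode = trimws(substr(lines, 27, 27)),
    x = .parse_num_field(lines, lnums, 31, 38, "x-coordinate"),
    y = .parse_num_field(lines, lnums, 39, 46, "y-coordinate"),
    z = .parse_num_field(lines, lnums, 47, 54, "z-coordinate"),
    occupancy = .parse_num_field(lines, lnums, 55, 60, "occupancy",
                                 default = 1.0),
    b_factor = .parse_num_field(lines, lnums, 61, 66, "B-factor",
                                default = 0.0),
    element = trimws(substr(lines, 77, 78)),
    is_hetero = startsWith(lines, "HETATM"),
    stringsAsFactors = FALSE
  )
  noel <- atoms$element == ""
  if (any(noel)) {
    atoms$element[noel] <- .infer_element(atoms$name[noel], atoms$comp_id[noel])
  }
  atoms <- .resolve_alt_locs(atoms)
  structure_model(atoms, model_id = model_id,
                  meta = list(resolution = NA_real_, r_free = NA_real_,
                              source = source))
}

# keep, per (residue, atom name), the conformer with highest occupancy;
# ties broken by alphabetically first alt-loc id ("" sorts first)
.resolve_alt_locs <- function(atoms) {
  key <- paste(atoms$comp_id, atoms$chain, atoms$res_seq, atoms$icode,
               atoms$name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  keep <- vapply(split(seq_len(nrow(atoms)), key), function(ix) {
    if (length(ix) == 1L) return(ix)
    ix[order(-atoms$occupancy[ix], atoms$alt_loc[ix])][1]
  }, integer(1))
  atoms <- atoms[sort(keep), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Write a structure model as PDB-format text
#'
#' Emits fixed-column v3.3 `ATOM`/`HETATM` records (coordinates at 3
#' decimals, occupancy and B-factor at 2) such that
#' `parse_structure(write_structure(m))` reproduces `m` on all retained
#' fields.  Serial numbers are renumbered sequentially.
#'
#' @param model A `ligqc_model`.
#' @param path Optional file path; when given, lines are written there.
#' @return Character vector of PDB lines (invisibly when `path` is given).
#' @export
write_structure <- function(model, path = NULL) {
  stopifnot(inherits(model, "ligqc_model"))
  a <- model$atoms
  if (!nrow(a)) stop("cannot write an empty model")
  if (any(nchar(a$name) > 4L)) {
    stop("atom name longer than the 4-character PDB field")
  }
  nm <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$is_hetero, "HETATM", "ATOM"),
    seq_len(nrow(a)), nm, a$alt_loc, a$comp_id, a$chain, a$res_seq, a$icode,
    a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Residue-level summary of a model
#'
#' @param model A `ligqc_model`.
#' @return data.frame with one row per residue, in order of first
#'   appearance: `res_key`, `comp_id`, `chain`, `res_seq`, `icode`,
#'   `is_hetero`, `is_water`, `is_polymer`, `n_atoms`.
#' @export
model_residues <- function(model) {
  a <- model$atoms
  first <- !duplicated(a$res_key)
  out <- a[first, c("res_key", "comp_id", "chain", "res_seq", "icode",
                    "is_hetero", "is_water", "is_polymer")]
  out$n_atoms <- as.vector(table(a$res_key)[out$res_key])
  rownames(out) <- NULL
  out
}

#' Average occupancy of a residue
#'
#' Arithmetic mean of per-atom occupancies after alternate-location
#' resolution; one of the classifier's default conditions falls back to this
#' value when the stats table carries no occupancy.
#'
#' @param model A `ligqc_model`.
#' @param res_key Residue key (see [model_residues()]).
#' @return Fraction in `[0, 1]`.
#' @export
residue_average_occupancy <- function(model, res_key) {
  occ <- model$atoms$occupancy[model$atoms$res_key == res_key]
  if (!length(occ)) stop("unknown residue key: ", res_key)
  mean(occ)
}

# n x 3 coordinate matrix for a subset of atoms (all by default)
.atom_xyz <- function(model, rows = NULL) {
  a <- model$atoms
  if (!is.null(rows)) a <- a[rows, , drop = FALSE]
  cbind(a$x, a$y, a$z)
}
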
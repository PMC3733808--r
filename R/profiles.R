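# Threshold profiles: a named set of pass/fail thresholds plus the score
# tolerance and the geometric cutoffs, tied to a stats dialect (PDB or
# PDB_REDO).  Disabled thresholds are NA in memory and 'off' on disk.

.PROFILE_KEYS <- c("name", "source", "rscc_min", "occupancy_min",
                   "rsr_good_max", "rsr_max", "owab_max", "r_free_max",
                   "resolution_max", "tolerance", "site_cutoff",
                   "bond_cutoff")

#' Construct a threshold profile
#'
#' @param name Profile name.
#' @param source Stats dialect the thresholds were calibrated for, `"PDB"`
#'   or `"PDB_REDO"`.  The good-RSR cutoff differs between dialects because
#'   the two databanks compute RSR with different software.
#' @param rscc_min Minimum RSCC (`NA` disables the condition).
#' @param occupancy_min Minimum residue average occupancy.
#' @param rsr_good_max Maximum RSR for a residue to pass the RSR condition.
#' @param rsr_max Hard RSR cap: above it a component is forced `Bad`
#'   regardless of the other conditions.  Must be `>= rsr_good_max`.
#' @param owab_max Maximum occupancy-weighted B (square angstrom); `NA` off.
#' @param r_free_max Maximum model R-free; `NA` off.
#' @param resolution_max Maximum resolution (angstrom); `NA` off.
#' @param tolerance Non-negative integer: scores in `(0, tolerance]` are
#'   `Dubious`, above it `Bad`.
#' @param site_cutoff Binding-site distance cutoff (angstrom, inclusive).
#' @param bond_cutoff Covalent-distance cutoff (angstrom, strict `<`).
#' @return A `ligqc_profile`.
#' @export
profile <- function(name, source = c("PDB", "PDB_REDO"),
                    rscc_min = 0.9, occupancy_min = 1.0,
                    rsr_good_max = 0.24, rsr_max = 0.4,
                    owab_max = NA_real_, r_free_max = NA_real_,
                    resolution_max = NA_real_, tolerance = 1L,
                    site_cutoff = 4.5, bond_cutoff = 2.1) {
  source <- match.arg(source)
  p <- structure(list(name = name, source = source, rscc_min = rscc_min,
                      occupancy_min = occupancy_min,
                      rsr_good_max = rsr_good_max, rsr_max = rsr_max,
                      owab_max = owab_max, r_free_max = r_free_max,
                      resolution_max = resolution_max,
                      tolerance = as.integer(tolerance),
                      site_cutoff = site_cutoff, bond_cutoff = bond_cutoff),
                 class = "ligqc_profile")
  validate_profile(p)
  p
}

#' Validate a profile's invariants
#'
#' @param p A `ligqc_profile`.
#' @return `p` invisibly; errors on violation.
#' @export
validate_profile <- function(p) {
  stopifnot(inherits(p, "ligqc_profile"))
  num_ok <- function(v) is.na(v) || is.finite(v)
  for (k in c("rscc_min", "occupancy_min", "rsr_good_max", "rsr_max",
              "owab_max", "r_free_max", "resolution_max")) {
    if (!num_ok(p[[k]])) stop("profile threshold not finite: ", k)
  }
  if (!is.na(p$rsr_good_max) && !is.na(p$rsr_max) &&
      p$rsr_good_max > p$rsr_max) {
    stop("profile invariant violated: rsr_good_max > rsr_max")
  }
  if (is.na(p$tolerance) || p$tolerance < 0) stop("tolerance must be >= 0")
  if (!isTRUE(p$site_cutoff > 0)) stop("site_cutoff must be > 0")
  if (!isTRUE(p$bond_cutoff > 0)) stop("bond_cutoff must be > 0")
  invisible(p)
}

#' @export
print.ligqc_profile <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "off" else format(v)
  cat(sprintf("<ligqc_profile '%s' [%s]>\n", x$name, x$source))
  cat(sprintf("  rscc >= %s, occupancy >= %s, rsr <= %s (hard cap %s)\n",
              fmt(x$rscc_min), fmt(x$occupancy_min), fmt(x$rsr_good_max),
              fmt(x$rsr_max)))
  cat(sprintf("  owab <= %s, r_free <= %s, resolution <= %s\n",
              fmt(x$owab_max), fmt(x$r_free_max), fmt(x$resolution_max)))
  cat(sprintf("  tolerance %d, site cutoff %.2f A, bond cutoff %.2f A\n",
              x$tolerance, x$site_cutoff, x$bond_cutoff))
  invisible(x)
}

#' The two shipped default profiles
#'
#' Both require RSCC >= 0.9 and average occupancy >= 1.0, cap RSR hard at
#' 0.4, and differ only in the good-RSR cutoff: 0.24 for the PDB dialect,
#' 0.165 for PDB_REDO (the two databanks compute RSR with different
#' software, so the scale differs).  Site cutoff 4.5 angstrom, covalent
#' cutoff 2.1 angstrom, tolerance 1.
#'
#' @return Named list with elements `"Default (PDB)"` and
#'   `"Default (PDB_REDO)"`.
#' @examples
#' default_profiles()[["Default (PDB)"]]
#' @export
default_profiles <- function() {
  list(
    "Default (PDB)" = profile("Default (PDB)", source = "PDB",
                              rsr_good_max = 0.24),
    "Default (PDB_REDO)" = profile("Default (PDB_REDO)", source = "PDB_REDO",
                                   rsr_good_max = 0.165)
  )
}

#' Load a profile from a key=value file
#'
#' One `key=value` per line; keys are exactly the [profile()] argument
#' names; `off` disables a threshold; `#` starts a comment.  Unknown keys
#' and invariant violations are errors.
#'
#' @param path File path.
#' @return A `ligqc_profile`.
#' @export
load_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed profile line: ", lines[bad[1]])
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  unknown <- setdiff(keys, .PROFILE_KEYS)
  if (length(unknown)) stop("unknown profile key: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys)) stop("duplicate profile key")
  get <- function(k, default = NULL) {
    if (!k %in% keys) {
      if (is.null(default)) stop("profile file lacks key: ", k)
      return(default)
    }
    vals[match(k, keys)]
  }
  numval <- function(k, default = NULL) {
    v <- get(k, default)
    if (identical(v, "off")) return(NA_real_)
    if (is.numeric(v)) return(v)
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) stop("non-numeric profile value for ", k, ": ", v)
    out
  }
  profile(name = get("name"),
          source = get("source"),
          rscc_min = numval("rscc_min"),
          occupancy_min = numval("occupancy_min"),
          rsr_good_max = numval("rsr_good_max"),
          rsr_max = numval("rsr_max"),
          owab_max = numval("owab_max", NA_real_),
          r_free_max = numval("r_free_max", NA_real_),
          resolution_max = numval("resolution_max", NA_real_),
          tolerance = numval("tolerance"),
          site_cutoff = numval("site_cutoff"),
          bond_cutoff = numval("bond_cutoff"))
}

#' Save a profile to a key=value file
#'
#' Inverse of [load_profile()]; disabled thresholds are written as `off`.
#'
#' @param p A `ligqc_profile`.
#' @param path Output path.
#' @return The lines, invisibly.
#' @export
save_profile <- function(p, path) {
  validate_profile(p)
  fmt <- function(v) if (is.na(v)) "off" else format(v, digits = 15)
  lines <- c(
    paste0("name=", p$name),
    paste0("source=", p$source),
    paste0("rscc_min=", fmt(p$rscc_min)),
    paste0("occupancy_min=", fmt(p$occupancy_min)),
    paste0("rsr_good_max=", fmt(p$rsr_good_max)),
    paste0("rsr_max=", fmt(p$rsr_max)),
    paste0("owab_max=", fmt(p$owab_max)),
    paste0("r_free_max=", fmt(p$r_free_max)),
    paste0("resolution_max=", fmt(p$resolution_max)),
    paste0("tolerance=", p$tolerance),
    paste0("site_cutoff=", fmt(p$site_cutoff)),
    paste0("bond_cutoff=", fmt(p$bond_cutoff)))
  writeLines(lines, path)
  invisible(lines)
}
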
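# Exclusion lists: compound codes never treated as ligands.
#
# blacklist       -- solvents, buffers, cryoprotectants and other additives;
#                    covalent contact (< bond cutoff) with one of these
#                    rejects a ligand.
# non_propagating -- mainly metal ions; these are not ligands, but contact
#                    with them neither rejects a ligand nor merges ligand
#                    components.

#' Read an exclusion list file
#'
#' Plain text, one compound code per line; `#` starts a comment; blank lines
#' ignored; codes are upper-cased.
#'
#' @param path File path.
#' @return Character vector of compound codes.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- toupper(trimws(lines))
  unique(lines[nzchar(lines)])
}

#' Bundle two exclusion lists
#'
#' @param blacklist Character vector of solvent/buffer/additive codes.
#' @param non_propagating Character vector of codes (mainly metal ions) that
#'   neither reject ligands nor propagate covalent connectivity.
#' @return A `ligqc_exclusion_lists` object. The two sets must be disjoint.
#' @export
exclusion_lists <- function(blacklist, non_propagating) {
  blacklist <- unique(toupper(blacklist))
  non_propagating <- unique(toupper(non_propagating))
  both <- intersect(blacklist, non_propagating)
  if (length(both)) {
    stop("codes present in both lists: ", paste(both, collapse = ", "))
  }
  structure(list(blacklist = blacklist, non_propagating = non_propagating),
            class = "ligqc_exclusion_lists")
}

#' Default exclusion lists shipped with the package
#'
#' The blacklist unites the common crystallization solvents, buffers and
#' additives seen in PDB entries (sulfate, glycerol, PEG fragments, ...);
#' the non-propagating list holds the common metal ions.  Both are stored as
#' editable plain-text files under `inst/extdata/` and can be extended or
#' replaced per run (see [run_config()]).
#'
#' @return A `ligqc_exclusion_lists` object.
#' @examples
#' lists <- default_exclusion_lists()
#' "SO4" %in% lists$blacklist
#' "ZN" %in% lists$non_propagating
#' @export
default_exclusion_lists <- function() {
  bl <- system.file("extdata", "blacklist.txt", package = "ligqc",
                    mustWork = TRUE)
  np <- system.file("extdata", "non_propagating.txt", package = "ligqc",
                    mustWork = TRUE)
  exclusion_lists(read_exclusion_list(bl), read_exclusion_list(np))
}
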
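# Distance-cutoff binding-site detection, backed by a cell-list neighbour
# search (spatial binning with cell edge >= cutoff, 27-cell sweep).

#' Cell-list neighbour search between two point sets
#'
#' Returns exactly the pairs with Euclidean distance `<= cutoff` (inclusive
#' boundary), computed by spatial binning rather than the O(n^2) double
#' loop.  The test-suite verifies identity with the brute-force oracle.
#'
#' @param xyz_a,xyz_b Numeric matrices with 3 columns (x, y, z in angstrom).
#' @param cutoff Non-negative distance in angstrom.
#' @return data.frame with columns `i` (row in `xyz_a`), `j` (row in
#'   `xyz_b`), `dist`.
#' @export
neighbor_search <- function(xyz_a, xyz_b, cutoff) {
  xyz_a <- rbind(xyz_a)
  xyz_b <- rbind(xyz_b)
  stopifnot(ncol(xyz_a) == 3L, ncol(xyz_b) == 3L, cutoff >= 0)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (!nrow(xyz_a) || !nrow(xyz_b)) return(empty)
  edge <- max(cutoff, 1e-6)  # cell edge >= cutoff; >0 even at cutoff 0
  cell_a <- floor(xyz_a / edge)
  cell_b <- floor(xyz_b / edge)
  keyify <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  b_by_cell <- split(seq_len(nrow(xyz_b)), keyify(cell_b))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  a_by_cell <- split(seq_len(nrow(xyz_a)), keyify(cell_a))
  out_i <- out_j <- out_d <- vector("list", length(a_by_cell))
  k <- 0L
  for (ai in a_by_cell) {
    base <- cell_a[ai[1], ]
    nb_keys <- keyify(sweep(offsets, 2, base, "+"))
    cand <- unlist(b_by_cell[nb_keys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    d2 <- outer(rowSums(xyz_a[ai, , drop = FALSE]^2),
                rowSums(xyz_b[cand, , drop = FALSE]^2), "+") -
      2 * tcrossprod(xyz_a[ai, , drop = FALSE], xyz_b[cand, , drop = FALSE])
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    if (!nrow(hit)) next
    k <- k + 1L
    out_i[[k]] <- ai[hit[, 1]]
    out_j[[k]] <- cand[hit[, 2]]
    out_d[[k]] <- sqrt(d2[hit])
  }
  if (!k) return(empty)
  res <- data.frame(i = unlist(out_i[seq_len(k)]),
                    j = unlist(out_j[seq_len(k)]),
                    dist = unlist(out_d[seq_len(k)]))
  # the tcrossprod expansion suffers catastrophic cancellation far from the
  # origin; recompute candidate distances from coordinate differences and
  # re-apply the inclusive boundary on the exact value
  res$dist <- sqrt(rowSums((xyz_a[res$i, , drop = FALSE] -
                            xyz_b[res$j, , drop = FALSE])^2))
  res <- res[res$dist <= cutoff, , drop = FALSE]
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find the binding site of a ligand
#'
#' All residues with any atom at distance `<= cutoff` (default 4.5 angstrom,
#' inclusive boundary) of any ligand atom form the binding site.  Candidate
#' residues are every polymer residue plus every non-water, non-blacklisted
#' hetero residue — non-propagating metals and other hetero neighbours such
#' as a boric acid molecule count as site residues.  The ligand's own
#' components are excluded.
#'
#' @param model A `ligqc_model`.
#' @param ligand A `ligqc_ligand` (see [extract_ligands()]).
#' @param lists Exclusion lists, see [default_exclusion_lists()].
#' @param cutoff Site distance cutoff in angstrom.
#' @return A `ligqc_site`: list with `ligand`, `residues` (sorted residue
#'   keys), `cutoff`.
#' @export
find_binding_site <- function(model, ligand,
                              lists = default_exclusion_lists(),
                              cutoff = 4.5) {
  stopifnot(inherits(model, "ligqc_model"), cutoff > 0)
  a <- model$atoms
  comp_keys <- ligand$components
  if (!all(comp_keys %in% a$res_key)) {
    stop("ligand component(s) missing from model: ",
         paste(setdiff(comp_keys, a$res_key), collapse = ", "))
  }
  lig_rows <- which(a$res_key %in% comp_keys)
  cand_rows <- which((a$is_polymer |
                        (a$is_hetero & !a$is_water &
                           !(a$comp_id %in% lists$blacklist))) &
                       !(a$res_key %in% comp_keys))
  residues <- character()
  if (length(cand_rows)) {
    hits <- neighbor_search(.atom_xyz(model, cand_rows),
                            .atom_xyz(model, lig_rows), cutoff)
    residues <- sort(unique(a$res_key[cand_rows[hits$i]]))
  }
  structure(list(ligand = ligand, residues = residues, cutoff = cutoff),
            class = "ligqc_site")
}

#' @export
print.ligqc_site <- function(x, ...) {
  cat(sprintf("<ligqc_site of %s: %d residues within %.2f A>\n",
              x$ligand$group_id, length(x$residues), x$cutoff))
  invisible(x)
}
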
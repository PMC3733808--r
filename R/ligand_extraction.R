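# Candidate-ligand extraction: group covalently connected hetero residues
# into multi-component ligands, reject per the exclusion-list / covalency
# rules, and record the reason for every rejection.

.REJECTION_REASONS <- c("no_stats_data", "covalent_to_polymer",
                        "blacklisted", "covalent_to_blacklisted")

.rejection_record <- function(subject, reason) {
  stopifnot(reason %in% .REJECTION_REASONS)
  data.frame(subject = subject, reason = reason, stringsAsFactors = FALSE)
}

#' All covalent-range residue pairs of a model
#'
#' Unordered pairs of distinct residues having at least one inter-atomic
#' distance strictly below `cutoff` (default 2.1 angstrom, the covalent-bond
#' heuristic; note the strict `<`, unlike the inclusive site cutoff).
#'
#' @param model A `ligqc_model`.
#' @param cutoff Positive distance in angstrom.
#' @return data.frame with columns `key1`, `key2` (`key1 < key2`), sorted.
#' @export
covalent_pairs <- function(model, cutoff = 2.1) {
  stopifnot(cutoff > 0)
  xyz <- .atom_xyz(model)
  hits <- neighbor_search(xyz, xyz, cutoff)
  hits <- hits[hits$dist < cutoff, , drop = FALSE]  # strict <
  k1 <- model$atoms$res_key[hits$i]
  k2 <- model$atoms$res_key[hits$j]
  keep <- k1 != k2
  p1 <- pmin(k1[keep], k2[keep])
  p2 <- pmax(k1[keep], k2[keep])
  out <- unique(data.frame(key1 = p1, key2 = p2, stringsAsFactors = FALSE))
  out <- out[order(out$key1, out$key2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# union-find over character keys
.uf_groups <- function(keys, pairs) {
  parent <- setNames(seq_along(keys), keys)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (nrow(pairs)) {
    i1 <- match(pairs$key1, keys)
    i2 <- match(pairs$key2, keys)
    for (r in seq_len(nrow(pairs))) {
      a <- find(i1[r]); b <- find(i2[r])
      if (a != b) parent[[b]] <- a
    }
  }
  roots <- vapply(seq_along(keys), find, integer(1))
  split(keys, roots)
}

#' Extract candidate ligands from a model
#'
#' Candidate components are hetero, non-water residues whose compound code
#' is on neither exclusion list.  Components are grouped into connected
#' components under the covalent-distance relation (< `bond_cutoff`); edges
#' through non-propagating residues (metal ions) do not merge groups, so a
#' ligand–metal–ligand bridge stays two ligands.  A group is rejected when
#' any of its atoms lies within covalent range of a polymer-residue atom
#' (`covalent_to_polymer`) or of a blacklisted, non-water residue's atom
#' (`covalent_to_blacklisted`); contact with a non-propagating metal never
#' rejects.  Blacklisted residues themselves are never emitted as ligands.
#'
#' @param model A `ligqc_model`.
#' @param lists Exclusion lists ([default_exclusion_lists()]).
#' @param bond_cutoff Covalent-distance cutoff in angstrom (strict `<`).
#' @return list with `ligands` (list of `ligqc_ligand`, sorted by group id)
#'   and `rejections` (data.frame `subject`, `reason`).
#' @examples
#' \dontrun{
#' ext <- extract_ligands(model)
#' vapply(ext$ligands, function(l) l$group_id, "")
#' }
#' @export
extract_ligands <- function(model, lists = default_exclusion_lists(),
                            bond_cutoff = 2.1) {
  stopifnot(inherits(model, "ligqc_model"), bond_cutoff > 0)
  a <- model$atoms
  res <- model_residues(model)
  cand <- res$res_key[res$is_hetero & !res$is_water &
                        !(res$comp_id %in% lists$blacklist) &
                        !(res$comp_id %in% lists$non_propagating)]
  if (!length(cand)) {
    return(list(ligands = list(),
                rejections = .rejection_record(character(), character())))
  }
  pairs <- covalent_pairs(model, bond_cutoff)
  # connectivity only among candidates: edges touching non-candidates
  # (metals, polymer, solvents) never propagate
  cpairs <- pairs[pairs$key1 %in% cand & pairs$key2 %in% cand, , drop = FALSE]
  groups <- .uf_groups(cand, cpairs)
  groups <- lapply(groups, sort)
  ids <- vapply(groups, paste, "", collapse = "+")
  groups <- groups[order(ids)]

  blk_keys <- res$res_key[res$is_hetero & !res$is_water &
                            res$comp_id %in% lists$blacklist]
  poly_keys <- res$res_key[res$is_polymer]
  # covalent-range partners per candidate, straight from the pair table
  partner <- function(keys) {
    sel <- pairs$key1 %in% keys | pairs$key2 %in% keys
    setdiff(unique(c(pairs$key1[sel], pairs$key2[sel])), keys)
  }
  ligands <- list()
  rejections <- .rejection_record(character(), character())
  for (g in groups) {
    gid <- paste(g, collapse = "+")
    nb <- partner(g)
    if (any(nb %in% poly_keys)) {
      rejections <- rbind(rejections,
                          .rejection_record(gid, "covalent_to_polymer"))
    } else if (any(nb %in% blk_keys)) {
      rejections <- rbind(rejections,
                          .rejection_record(gid, "covalent_to_blacklisted"))
    } else {
      ligands <- c(ligands, list(structure(
        list(components = g, group_id = gid), class = "ligqc_ligand")))
    }
  }
  rownames(rejections) <- NULL
  list(ligands = ligands, rejections = rejections)
}

#' @export
print.ligqc_ligand <- function(x, ...) {
  cat(sprintf("<ligqc_ligand %s (%d component%s)>\n", x$group_id,
              length(x$components),
              if (length(x$components) > 1) "s" else ""))
  invisible(x)
}
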
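# Test helpers: an independent fixed-column PDB line builder (deliberately
# not write_structure, so parser tests have their own oracle for the
# format), tiny model builders, and brute-force oracles.

pdb_line <- function(record, serial, name, alt, comp, chain, seq, icode,
                     x, y, z, occ = 1, b = 20, elem = "C") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, comp, chain, seq, icode, x, y, z, occ, b,
          elem)
}

# one-atom-per-residue model from a coordinate table
point_model <- function(df, model_id = "TEST") {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    pdb_line(if (df$het[i]) "HETATM" else "ATOM", i,
             df$name[i] %||% "C1", "", df$comp[i], df$chain[i] %||% "A",
             df$seq[i], "", df$x[i], df$y[i], df$z[i],
             df$occ[i] %||% 1, df$b[i] %||% 20, df$elem[i] %||% "C")
  }, "")
  parse_structure(c(lines, "END"), model_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force O(n^2) neighbour oracle (inclusive boundary)
brute_pairs <- function(xyz_a, xyz_b, cutoff) {
  out <- NULL
  for (i in seq_len(nrow(xyz_a))) {
    for (j in seq_len(nrow(xyz_b))) {
      d <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
      if (d <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# brute-force connected components by iterated set merging
brute_groups <- function(keys, pairs) {
  groups <- as.list(keys)
  if (nrow(pairs)) {
    repeat {
      merged <- FALSE
      for (r in seq_len(nrow(pairs))) {
        gi <- which(vapply(groups, function(g) pairs$key1[r] %in% g, TRUE))
        gj <- which(vapply(groups, function(g) pairs$key2[r] %in% g, TRUE))
        if (length(gi) && length(gj) && gi != gj) {
          groups[[gi]] <- c(groups[[gi]], groups[[gj]])
          groups[[gj]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  sorted <- lapply(groups, sort)
  sorted[order(vapply(sorted, paste, "", collapse = "+"))]
}

# independent condition counter for the classifier oracle
brute_score <- function(rsr, rscc, occ, owab, r_free, resolution, p) {
  unmet <- 0L
  chk <- function(value, thr, op) {
    if (is.na(thr)) return(0L)
    if (is.na(value)) return(1L)
    if (op == "ge" && value >= thr) 0L else
      if (op == "le" && value <= thr) 0L else 1L
  }
  unmet <- chk(rscc, p$rscc_min, "ge") + chk(occ, p$occupancy_min, "ge") +
    chk(rsr, p$rsr_good_max, "le") + chk(owab, p$owab_max, "le") +
    chk(r_free, p$r_free_max, "le") + chk(resolution, p$resolution_max, "le")
  forced <- !is.na(p$rsr_max) && !is.na(rsr) && rsr > p$rsr_max
  if (forced) unmet <- max(unmet, p$tolerance + 1L)
  unmet
}
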
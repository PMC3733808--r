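# Offline density engine: a calculated map from a Gaussian atom model, and
# RSR / RSCC evaluated over per-residue masks.  This exists so the whole
# classification pipeline can be exercised end-to-end without databank
# statistics; it does not aim at numerical parity with MAPMAN or EDSTATS,
# which themselves disagree with each other.

# atomic numbers for elements seen in typical protein/ligand models
.ELEMENT_Z <- c(H = 1, D = 1, B = 5, C = 6, N = 7, O = 8, F = 9, NA. = 11,
                MG = 12, AL = 13, P = 15, S = 16, CL = 17, K = 19, CA = 20,
                MN = 25, FE = 26, CO = 27, NI = 28, CU = 29, ZN = 30,
                SE = 34, BR = 35, RB = 37, SR = 38, AG = 47, CD = 48,
                I = 53, CS = 55, BA = 56, PT = 78, AU = 79, HG = 80)

.element_z <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."   # avoid the R missing-value name
  z <- .ELEMENT_Z[key]
  z[is.na(z)] <- 6            # unknown element: treat as carbon
  unname(z)
}

#' Construct a density grid
#'
#' Orthogonal-axis grid; `values[i, j, k]` is the density at
#' `origin + (c(i, j, k) - 1) * spacing` (voxel centers).
#'
#' @param origin 3-vector, angstrom.
#' @param spacing 3-vector (or scalar) of positive voxel edges, angstrom.
#' @param dims 3 positive integers.
#' @param values Array of dimension `dims`, or `NULL` for zeros.
#' @return A `ligqc_grid`.
#' @export
density_grid <- function(origin, spacing, dims, values = NULL) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  dims <- as.integer(rep_len(dims, 3L))
  stopifnot(length(origin) == 3L, all(spacing > 0), all(dims > 0))
  if (is.null(values)) values <- array(0, dims)
  stopifnot(identical(dim(values), dims), all(is.finite(values)))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, values = values), class = "ligqc_grid")
}

#' @export
print.ligqc_grid <- function(x, ...) {
  cat(sprintf("<ligqc_grid %dx%dx%d, spacing %.2f/%.2f/%.2f A>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

.grid_axes <- function(grid) {
  lapply(1:3, function(d) {
    grid$origin[d] + (seq_len(grid$dims[d]) - 1) * grid$spacing[d]
  })
}

.grids_congruent <- function(a, b) {
  identical(a$dims, b$dims) &&
    max(abs(a$origin - b$origin)) < 1e-6 &&
    max(abs(a$spacing - b$spacing)) < 1e-6
}

#' Smearing and masking parameters for the density engine
#'
#' @param b_added Extra isotropic B (square angstrom) added to each atom's
#'   B-factor before computing its Gaussian width; default 10.
#' @param mask_radius Radius (angstrom) around atom centers defining a
#'   residue's integration region; default 1.5.
#' @return A `ligqc_density_params` list.
#' @export
atom_density_params <- function(b_added = 10, mask_radius = 1.5) {
  stopifnot(b_added > 0, mask_radius > 0)
  structure(list(b_added = b_added, mask_radius = mask_radius),
            class = "ligqc_density_params")
}

#' Grid geometry enclosing a model
#'
#' @param model A `ligqc_model`.
#' @param spacing Voxel edge, angstrom.
#' @param margin Padding beyond the model bounding box, angstrom.
#' @return A zero-filled `ligqc_grid`.
#' @export
grid_from_model <- function(model, spacing = 0.5, margin = 3) {
  xyz <- .atom_xyz(model)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  density_grid(lo, spacing, dims)
}

#' Calculated density of a model on a grid
#'
#' Each atom contributes a normalized isotropic Gaussian with amplitude
#' proportional to occupancy times atomic number and width set by its
#' B-factor plus `b_added`:
#' \deqn{\rho(r) = occ \cdot Z \cdot (4\pi/(B+B_a))^{3/2}
#'       \exp(-4\pi^2 |r - r_0|^2 / (B + B_a))}
#' so that the integral of one atom's contribution equals `occ * Z`.
#'
#' @param model A `ligqc_model`; every atom must lie inside the grid.
#' @param grid Grid geometry (values ignored), e.g. [grid_from_model()].
#' @param params [atom_density_params()].
#' @return A `ligqc_grid` with the summed density.
#' @export
rho_calc <- function(model, grid, params = atom_density_params()) {
  stopifnot(inherits(model, "ligqc_model"), inherits(grid, "ligqc_grid"))
  a <- model$atoms
  axes <- .grid_axes(grid)
  hi <- grid$origin + (grid$dims - 1) * grid$spacing
  inside <- a$x >= grid$origin[1] & a$x <= hi[1] &
    a$y >= grid$origin[2] & a$y <= hi[2] &
    a$z >= grid$origin[3] & a$z <= hi[3]
  if (!all(inside)) {
    stop(sprintf("atom outside grid bounds (first: %s atom %d)",
                 a$res_key[!inside][1], a$serial[!inside][1]))
  }
  vals <- array(0, grid$dims)
  zs <- .element_z(a$element)
  for (n in seq_len(nrow(a))) {
    occ <- a$occupancy[n]
    if (occ == 0) next
    beff <- a$b_factor[n] + params$b_added
    alpha <- 4 * pi^2 / beff
    amp <- occ * zs[n] * (4 * pi / beff)^1.5
    rcut <- sqrt(36 / alpha)          # exp(-36) ~ 2e-16: negligible beyond
    ctr <- c(a$x[n], a$y[n], a$z[n])
    ix <- which(abs(axes[[1]] - ctr[1]) <= rcut)
    iy <- which(abs(axes[[2]] - ctr[2]) <= rcut)
    iz <- which(abs(axes[[3]] - ctr[3]) <= rcut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((axes[[1]][ix] - ctr[1])^2,
                      (axes[[2]][iy] - ctr[2])^2, "+"),
                (axes[[3]][iz] - ctr[3])^2, "+")
    vals[ix, iy, iz] <- vals[ix, iy, iz] + amp * exp(-alpha * d2)
  }
  density_grid(grid$origin, grid$spacing, grid$dims, vals)
}

#' Voxel mask around a set of atoms
#'
#' All voxels whose center lies within `mask_radius` of any atom center.
#'
#' @param grid A `ligqc_grid` (geometry only).
#' @param xyz n-by-3 matrix of atom positions.
#' @param mask_radius Positive radius, angstrom.
#' @return Sorted integer vector of linear voxel indices.  An empty mask is
#'   an error (it signals a geometry mismatch).
#' @export
residue_mask <- function(grid, xyz, mask_radius) {
  stopifnot(mask_radius > 0)
  xyz <- rbind(xyz)
  axes <- .grid_axes(grid)
  mask <- array(FALSE, grid$dims)
  for (n in seq_len(nrow(xyz))) {
    ctr <- xyz[n, ]
    ix <- which(abs(axes[[1]] - ctr[1]) <= mask_radius)
    iy <- which(abs(axes[[2]] - ctr[2]) <= mask_radius)
    iz <- which(abs(axes[[3]] - ctr[3]) <= mask_radius)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((axes[[1]][ix] - ctr[1])^2,
                      (axes[[2]][iy] - ctr[2])^2, "+"),
                (axes[[3]][iz] - ctr[3])^2, "+")
    mask[ix, iy, iz] <- mask[ix, iy, iz] | (d2 <= mask_radius^2)
  }
  idx <- which(mask)
  if (!length(idx)) stop("empty residue mask: grid/geometry mismatch")
  idx
}

#' Real-space R-value over a mask
#'
#' `sum |obs - calc| / sum (|obs| + |calc|)` over the masked voxels; 0 for a
#' perfect fit, 1 for maximal disagreement.
#'
#' @param obs,calc Congruent `ligqc_grid`s.
#' @param mask Integer voxel indices from [residue_mask()].
#' @return Value in `[0, 1]`.
#' @export
rsr <- function(obs, calc, mask) {
  if (!.grids_congruent(obs, calc)) stop("grids are not congruent")
  if (!length(mask)) stop("empty mask")
  o <- obs$values[mask]
  c_ <- calc$values[mask]
  den <- sum(abs(o) + abs(c_))
  if (den == 0) stop("empty density under mask (zero denominator)")
  sum(abs(o - c_)) / den
}

#' Real-space correlation coefficient over a mask
#'
#' Pearson correlation of observed and calculated density over the masked
#' voxels.
#'
#' @inheritParams rsr
#' @return Value in `[-1, 1]`.
#' @export
rscc <- function(obs, calc, mask) {
  if (!.grids_congruent(obs, calc)) stop("grids are not congruent")
  if (length(mask) < 2L) stop("mask must cover at least 2 voxels")
  o <- obs$values[mask]
  c_ <- calc$values[mask]
  if (stats::sd(o) == 0 || stats::sd(c_) == 0) {
    stop("zero variance under mask")
  }
  stats::cor(o, c_)
}

#' Per-residue fit statistics from a density map
#'
#' Computes, for every residue of the model, RSR and RSCC of the observed
#' map against the full-model calculated map over the residue's mask, the
#' average occupancy from the coordinates, and the occupancy-weighted
#' average B-factor `sum(occ * B) / sum(occ)`.
#'
#' @param model A `ligqc_model`.
#' @param obs Observed `ligqc_grid` (congruent with the model's grid).
#' @param params [atom_density_params()].
#' @return data.frame with `res_key`, `rsr`, `rscc`, `occ`, `owab` plus the
#'   key columns needed by [stats_bundle()].
#' @export
compute_residue_stats <- function(model, obs,
                                  params = atom_density_params()) {
  calc <- rho_calc(model, obs, params)
  res <- model_residues(model)
  out <- data.frame(chain = res$chain, res_seq = res$res_seq,
                    icode = ifelse(res$icode == "", ".", res$icode),
                    comp_id = res$comp_id,
                    rsr = NA_real_, rscc = NA_real_,
                    occ = NA_real_, owab = NA_real_,
                    res_key = res$res_key, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    rows <- which(model$atoms$res_key == res$res_key[i])
    xyz <- .atom_xyz(model, rows)
    mask <- residue_mask(obs, xyz, params$mask_radius)
    out$rsr[i] <- rsr(obs, calc, mask)
    out$rscc[i] <- rscc(obs, calc, mask)
    occ <- model$atoms$occupancy[rows]
    b <- model$atoms$b_factor[rows]
    out$occ[i] <- mean(occ)
    out$owab[i] <- if (sum(occ) > 0) sum(occ * b) / sum(occ) else NA_real_
  }
  out
}

#' Write a density grid as text
#'
#' Internal plain-text format: three `#grid` header lines (origin, spacing,
#' dims) followed by whitespace-separated values with the first grid index
#' varying fastest.
#'
#' @param grid A `ligqc_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#grid origin %.6g %.6g %.6g", grid$origin[1],
                       grid$origin[2], grid$origin[3]),
               sprintf("#grid spacing %.6g %.6g %.6g", grid$spacing[1],
                       grid$spacing[2], grid$spacing[3]),
               sprintf("#grid dims %d %d %d", grid$dims[1], grid$dims[2],
                       grid$dims[3])), con)
  v <- as.vector(grid$values)
  chunks <- split(v, ceiling(seq_along(v) / 8))
  writeLines(vapply(chunks, function(x) paste(sprintf("%.8g", x),
                                              collapse = " "), ""), con)
  invisible(path)
}

#' Read a density grid written by [write_density_grid()]
#'
#' @param path File path.
#' @return A `ligqc_grid`.
#' @export
read_density_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#grid ", lines, value = TRUE)
  take <- function(what) {
    ln <- grep(paste0("^#grid ", what, " "), hdr, value = TRUE)
    if (length(ln) != 1L) stop("grid file lacks header line: ", what)
    as.numeric(strsplit(trimws(sub(paste0("^#grid ", what), "", ln)),
                        "\\s+")[[1]])
  }
  origin <- take("origin")
  spacing <- take("spacing")
  dims <- as.integer(take("dims"))
  body <- lines[!startsWith(lines, "#")]
  v <- as.numeric(unlist(strsplit(trimws(body[nzchar(body)]), "\\s+")))
  if (length(v) != prod(dims)) {
    stop(sprintf("grid value count %d does not match dims (%d expected)",
                 length(v), prod(dims)))
  }
  density_grid(origin, spacing, dims, array(v, dims))
}
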
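# Deterministic synthetic complexes with known ground truth.  The geometry
# is deliberately unphysical -- only inter-residue distances matter to the
# engine under test: a glycine-like polymer on a jittered helix, ligand
# components chained outward from an anchor residue, decoy residues
# (solvents, metals) at controlled distances, and stats tables / maps
# engineered to yield chosen Good/Dubious/Bad labels.

#' Specification of a synthetic complex
#'
#' @param seed Integer seed; same spec, same seed, identical outputs.
#' @param n_polymer_residues Number of glycine-like residues on the helix.
#' @param ligands List of ligand plans, each a list with `comp_ids`
#'   (character vector, one per component; components are chained 1.45
#'   angstrom apart so they group covalently), `anchor_res` (polymer residue
#'   index the first component is placed against) and `distance` (realized
#'   minimum atom distance from the first component to the anchor residue).
#' @param site_plan Optional data.frame with `res_index`, `distance`:
#'   polymer residues translated so their minimum atom distance to the first
#'   ligand is exactly `distance` (for binding-site membership tests).
#' @param decoys List of decoy plans, each a list with `comp_id` (e.g.
#'   `"SO4"`, `"ZN"`) and `distance` to the first ligand's nearest atom.
#' @param target_labels Named character vector mapping residue keys to
#'   `"Good"`, `"Dubious"` or `"Bad"`; unnamed residues default to Good.
#'   Keys follow `comp:chain:seq` (polymer chain A seq 1..n, ligand chain L
#'   seq 101.., decoys chain D seq 201..).
#' @return A `ligqc_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_polymer_residues = 10L,
                         ligands = NULL,
                         site_plan = NULL, decoys = list(),
                         target_labels = character()) {
  stopifnot(n_polymer_residues >= 1L)
  if (is.null(ligands)) {
    # default plan: one single-component ligand against the middle residue
    ligands <- list(list(comp_ids = "LIG",
                         anchor_res = max(1L, n_polymer_residues %/% 2L),
                         distance = 3.5))
  }
  for (lg in ligands) {
    stopifnot(length(lg$comp_ids) >= 1L, lg$distance > 0,
              lg$anchor_res >= 1L, lg$anchor_res <= n_polymer_residues)
  }
  if (!is.null(site_plan)) stopifnot(all(site_plan$distance > 0))
  for (d in decoys) stopifnot(d$distance > 0)
  stopifnot(all(target_labels %in% c("Good", "Dubious", "Bad")))
  structure(list(seed = as.integer(seed),
                 n_polymer_residues = as.integer(n_polymer_residues),
                 ligands = ligands, site_plan = site_plan, decoys = decoys,
                 target_labels = target_labels),
            class = "ligqc_fixture_spec")
}

# translate the atom block `rows` of `atoms` so that its minimum atom
# distance to the fixed block `ref_xyz` equals `target` (within 0.01 A)
.place_at_distance <- function(atoms, rows, ref_xyz, target) {
  for (iter in 1:8) {
    xyz <- cbind(atoms$x[rows], atoms$y[rows], atoms$z[rows])
    d2 <- outer(rowSums(xyz^2), rowSums(ref_xyz^2), "+") -
      2 * tcrossprod(xyz, ref_xyz)
    d2[d2 < 0] <- 0
    mi <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    dcur <- sqrt(d2[mi[1], mi[2]])
    if (abs(dcur - target) <= 0.005) break
    v <- xyz[mi[1], ] - ref_xyz[mi[2], ]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-9) v <- c(1, 0, 0) else v <- v / nv
    shift <- v * (target - dcur)
    atoms$x[rows] <- atoms$x[rows] + shift[1]
    atoms$y[rows] <- atoms$y[rows] + shift[2]
    atoms$z[rows] <- atoms$z[rows] + shift[3]
  }
  xyz <- cbind(atoms$x[rows], atoms$y[rows], atoms$z[rows])
  d2 <- outer(rowSums(xyz^2), rowSums(ref_xyz^2), "+") -
    2 * tcrossprod(xyz, ref_xyz)
  d2[d2 < 0] <- 0
  if (abs(sqrt(min(d2)) - target) > 0.01) {
    stop(sprintf("infeasible fixture geometry: wanted %.3f A, got %.3f A",
                 target, sqrt(min(d2))))
  }
  atoms
}

.fixture_atom <- function(serial, name, comp, chain, seq, xyz, elem,
                          hetero, occ = 1, b = 20) {
  data.frame(serial = serial, name = name, alt_loc = "", comp_id = comp,
             chain = chain, res_seq = seq, icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = occ, b_factor = b, element = elem,
             is_hetero = hetero, stringsAsFactors = FALSE)
}

#' Build the synthetic complex described by a fixture spec
#'
#' Polymer residues (comp `GLY`, chain A, 4 atoms N/CA/C/O) sit on a
#' jittered helix; each ligand's first component is placed radially outward
#' from its anchor residue at the requested minimum distance (realized
#' within 0.01 angstrom), further components chained 1.45 angstrom apart;
#' decoys are placed at their requested distances from the first ligand.
#'
#' @param spec A [fixture_spec()].
#' @return A `ligqc_model`.
#' @export
make_complex <- function(spec) {
  stopifnot(inherits(spec, "ligqc_fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_polymer_residues
  radius <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  offsets <- rbind(N = c(-1.0, 0.3, -0.2), CA = c(0, 0, 0),
                   C = c(1.0, -0.2, 0.3), O = c(1.4, 0.8, 0.6))
  elems <- c("N", "C", "C", "O")
  atoms <- list()
  serial <- 0L
  centers <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    th <- i * turn
    ctr <- c(radius * cos(th), radius * sin(th), rise * i) +
      runif(3, -0.15, 0.15)
    centers[i, ] <- ctr
    b <- 18 + runif(1, 0, 6)
    for (k in 1:4) {
      serial <- serial + 1L
      atoms[[serial]] <- .fixture_atom(serial, rownames(offsets)[k], "GLY",
                                       "A", i, ctr + offsets[k, ], elems[k],
                                       hetero = FALSE, b = b)
    }
  }
  atoms <- do.call(rbind, atoms)

  lig_elems <- c("C", "N", "O")
  seq_no <- 100L
  first_lig_rows <- NULL
  for (lg in spec$ligands) {
    anchor_ctr <- centers[lg$anchor_res, ]
    u <- c(anchor_ctr[1], anchor_ctr[2], 0)
    u <- u / sqrt(sum(u^2))
    anchor_rows <- which(atoms$chain == "A" & atoms$res_seq == lg$anchor_res)
    ref_xyz <- cbind(atoms$x[anchor_rows], atoms$y[anchor_rows],
                     atoms$z[anchor_rows])
    start <- anchor_ctr + u * (lg$distance + 1.5)
    prev_tip <- NULL
    for (ci in seq_along(lg$comp_ids)) {
      seq_no <- seq_no + 1L
      base <- if (is.null(prev_tip)) start else prev_tip + u * 1.45
      pos <- rbind(base, base + u * 1.3, base + u * 2.6)
      rows <- integer(3)
      for (k in 1:3) {
        serial <- serial + 1L
        rows[k] <- serial
        atoms <- rbind(atoms, .fixture_atom(
          serial, paste0(lig_elems[k], k), lg$comp_ids[ci], "L", seq_no,
          pos[k, ], lig_elems[k], hetero = TRUE, b = 22 + runif(1, 0, 4)))
      }
      if (ci == 1L) {
        # realize the requested minimum distance to the anchor residue,
        # dragging any already-placed earlier components is not needed
        # because each ligand starts a fresh chain
        atoms <- .place_at_distance(atoms, rows, ref_xyz, lg$distance)
        if (is.null(first_lig_rows)) first_lig_rows <- rows
      }
      prev_tip <- c(atoms$x[rows[3]], atoms$y[rows[3]], atoms$z[rows[3]])
    }
  }

  # per-residue exact distances to the first ligand component
  if (!is.null(spec$site_plan) && nrow(spec$site_plan)) {
    lig_xyz <- cbind(atoms$x[first_lig_rows], atoms$y[first_lig_rows],
                     atoms$z[first_lig_rows])
    for (r in seq_len(nrow(spec$site_plan))) {
      ri <- spec$site_plan$res_index[r]
      rows <- which(atoms$chain == "A" & atoms$res_seq == ri)
      atoms <- .place_at_distance(atoms, rows, lig_xyz,
                                  spec$site_plan$distance[r])
    }
  }

  # decoys at controlled distances from the first ligand, on spread-out
  # directions so they do not collide with each other
  if (length(spec$decoys)) {
    lig_xyz <- cbind(atoms$x[first_lig_rows], atoms$y[first_lig_rows],
                     atoms$z[first_lig_rows])
    lig_ctr <- colMeans(lig_xyz)
    dseq <- 200L
    for (di in seq_along(spec$decoys)) {
      dc <- spec$decoys[[di]]
      dseq <- dseq + 1L
      phi <- 2.4 * di          # golden-angle spread
      w <- c(cos(phi), sin(phi), 0.6 * ((di %% 3) - 1))
      w <- w / sqrt(sum(w^2))
      base <- lig_ctr + w * (dc$distance + 2)
      if (toupper(dc$comp_id) == "SO4") {
        off <- rbind(S = c(0, 0, 0), O1 = c(1.45, 0, 0), O2 = c(-1.45, 0, 0),
                     O3 = c(0, 1.45, 0), O4 = c(0, -1.45, 0))
        el <- c("S", "O", "O", "O", "O")
      } else {
        off <- rbind(X = c(0, 0, 0))
        el <- dc$comp_id
      }
      rows <- integer(nrow(off))
      for (k in seq_len(nrow(off))) {
        serial <- serial + 1L
        rows[k] <- serial
        atoms <- rbind(atoms, .fixture_atom(
          serial, rownames(off)[k], toupper(dc$comp_id), "D", dseq,
          base + off[k, ], el[k], hetero = TRUE, b = 25))
      }
      atoms <- .place_at_distance(atoms, rows, lig_xyz, dc$distance)
    }
  }
  structure_model(atoms, model_id = sprintf("FX%02d", spec$seed %% 100),
                  meta = list(resolution = 1.8, r_free = 0.22,
                              source = "PDB"))
}

# draw stats placing a component in the region of stat-space that maps to
# `label` under `profile` (tolerance-aware)
.stats_for_label <- function(label, p) {
  good <- list(rsr = runif(1, 0.03, max(0.031, p$rsr_good_max * 0.95)),
               rscc = runif(1, min(p$rscc_min + 0.02, 0.99), 0.995),
               occ = p$occupancy_min)
  fail_one <- function(s, which) {
    if (which == "rscc") s$rscc <- runif(1, 0.55, p$rscc_min - 0.02)
    if (which == "occ") s$occ <- runif(1, 0.5, p$occupancy_min - 0.05)
    if (which == "rsr") s$rsr <- runif(1, p$rsr_good_max + 0.005,
                                       p$rsr_max - 0.005)
    s
  }
  if (label == "Good") return(good)
  if (label == "Dubious") {
    if (p$tolerance < 1L) stop("Dubious is unreachable at tolerance 0")
    return(fail_one(good, sample(c("rscc", "occ", "rsr"), 1)))
  }
  # Bad: either break the hard RSR cap, or fail tolerance+1 scored conditions
  routes <- "hard"
  if (p$tolerance + 1L <= 3L) routes <- c(routes, "multi")
  if (sample(routes, 1) == "hard") {
    s <- good
    s$rsr <- runif(1, p$rsr_max + 0.01, p$rsr_max + 0.2)
    return(s)
  }
  s <- good
  for (w in sample(c("rscc", "occ", "rsr"), p$tolerance + 1L)) {
    s <- fail_one(s, w)
  }
  s
}

#' Generate a stats table realizing the spec's target labels
#'
#' Builds the model with [make_complex()], then draws per-residue (rsr,
#' rscc, occ) values from within the region of stat-space that the profile
#' maps to each residue's target label (default Good).  Residues on the
#' exclusion lists and waters get no entry (they are never scored).
#'
#' @param spec A [fixture_spec()].
#' @param profile A `ligqc_profile`.
#' @param lists Exclusion lists.
#' @return A `ligqc_stats_bundle` whose `source` matches the profile.
#' @export
make_stats <- function(spec, profile, lists = default_exclusion_lists()) {
  model <- make_complex(spec)
  set.seed(spec$seed + 1000L)
  res <- model_residues(model)
  scored <- res[!res$is_water & !(res$comp_id %in% lists$blacklist), ,
                drop = FALSE]
  rows <- lapply(seq_len(nrow(scored)), function(i) {
    key <- scored$res_key[i]
    label <- if (key %in% names(spec$target_labels)) {
      spec$target_labels[[key]]
    } else "Good"
    s <- .stats_for_label(label, profile)
    data.frame(chain = scored$chain[i], res_seq = scored$res_seq[i],
               icode = ".", comp_id = scored$comp_id[i],
               rsr = round(s$rsr, 3), rscc = round(s$rscc, 3),
               occ = round(s$occ, 3), owab = round(runif(1, 15, 35), 3),
               stringsAsFactors = FALSE)
  })
  stats_bundle(do.call(rbind, rows), resolution = 1.8, r_free = 0.22,
               source = profile$source)
}

#' Ground-truth pair labels implied by a fixture spec
#'
#' Recomputes, independently of the classifier, what the target labels imply
#' for each ligand/site pair: the ligand label is the worst target among its
#' components, the site label the worst target among the residues that
#' actually fall within the profile's site cutoff of the ligand.
#'
#' @param spec A [fixture_spec()].
#' @param profile A `ligqc_profile`.
#' @param lists Exclusion lists.
#' @return data.frame with `group_id`, `ligand_label`, `site_label`.
#' @export
fixture_truth <- function(spec, profile,
                          lists = default_exclusion_lists()) {
  model <- make_complex(spec)
  ext <- extract_ligands(model, lists, profile$bond_cutoff)
  target <- function(key) {
    if (key %in% names(spec$target_labels)) spec$target_labels[[key]]
    else "Good"
  }
  rows <- lapply(ext$ligands, function(lig) {
    site <- find_binding_site(model, lig, lists, profile$site_cutoff)
    data.frame(group_id = lig$group_id,
               ligand_label = worst_label(vapply(lig$components, target, "")),
               site_label = worst_label(vapply(site$residues, target, "")),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(group_id = character(), ligand_label = character(),
                      site_label = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Observed map: calculated density plus seeded noise
#'
#' Adds Gaussian noise of standard deviation `noise_sd` to every voxel of
#' the model's calculated density; voxels inside the masks of `degraded`
#' residues receive additional noise at five times `noise_sd`.
#'
#' @param model A `ligqc_model`.
#' @param params [atom_density_params()].
#' @param noise_sd Non-negative noise level (same units as the map).
#' @param degraded Character vector of residue keys to degrade.
#' @param seed Integer seed.
#' @param grid Optional grid geometry; defaults to [grid_from_model()].
#' @param spacing Voxel edge used when `grid` is NULL.
#' @return A `ligqc_grid`.
#' @export
make_observed_map <- function(model, params = atom_density_params(),
                              noise_sd = 0, degraded = character(),
                              seed = 1L, grid = NULL, spacing = 0.5) {
  stopifnot(noise_sd >= 0)
  if (is.null(grid)) grid <- grid_from_model(model, spacing = spacing)
  calc <- rho_calc(model, grid, params)
  set.seed(seed)
  vals <- calc$values
  if (noise_sd > 0) {
    vals <- vals + rnorm(length(vals), 0, noise_sd)
  }
  for (key in degraded) {
    rows <- which(model$atoms$res_key == key)
    if (!length(rows)) stop("degraded key not in model: ", key)
    mask <- residue_mask(grid, .atom_xyz(model, rows), params$mask_radius)
    vals[mask] <- vals[mask] + rnorm(length(mask), 0, 5 * noise_sd)
  }
  density_grid(grid$origin, grid$spacing, grid$dims, vals)
}

#' Write a ready-to-run fixture data directory
#'
#' Emits, for each spec, `<id>.pdb` and `<id>.tsv` (and optionally
#' `<id>.grid` maps), plus `manifest.tsv` with the ground-truth pair labels,
#' in the layout [run_validation()] consumes.
#'
#' @param specs List of [fixture_spec()]s.
#' @param dir Output directory (created if needed).
#' @param profile A `ligqc_profile`.
#' @param lists Exclusion lists.
#' @param include_maps Write density maps too (slower, larger).
#' @return data.frame manifest (id, group_id, ligand_label, site_label),
#'   invisibly.
#' @export
write_fixture_set <- function(specs, dir, profile,
                              lists = default_exclusion_lists(),
                              include_maps = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    id <- sprintf("FX%02d", i)
    model <- make_complex(spec)
    model$model_id <- id
    write_structure(model, file.path(dir, paste0(id, ".pdb")))
    write_stats_table(make_stats(spec, profile, lists),
                      file.path(dir, paste0(id, ".tsv")))
    if (include_maps) {
      write_density_grid(make_observed_map(model, seed = spec$seed),
                         file.path(dir, paste0(id, ".grid")))
    }
    tr <- fixture_truth(spec, profile, lists)
    if (nrow(tr)) manifest[[i]] <- cbind(id = id, tr)
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(id = character(), group_id = character(),
               ligand_label = character(), site_label = character())
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
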
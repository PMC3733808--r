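# The scoring algorithm: every ligand component and binding-site residue
# starts at score 0; each enabled, unmet condition adds 1; score 0 is Good,
# score > tolerance is Bad, anything between is Dubious; ligands and sites
# take the worst label of their components.

.LABELS <- c("Good", "Dubious", "Bad")

#' Label from a score and tolerance
#'
#' @param score Non-negative integer count of unmet conditions.
#' @param tolerance Non-negative integer.
#' @return `"Good"` (score 0), `"Bad"` (score > tolerance) or `"Dubious"`.
#' @examples
#' label_from_score(0, 1)  # Good
#' label_from_score(1, 1)  # Dubious
#' label_from_score(2, 1)  # Bad
#' @export
label_from_score <- function(score, tolerance) {
  stopifnot(score >= 0, tolerance >= 0)
  ifelse(score == 0, "Good", ifelse(score > tolerance, "Bad", "Dubious"))
}

#' Worst of a set of labels
#'
#' Aggregation on the order Good < Dubious < Bad; an empty set aggregates to
#' `"Good"` (vacuous truth: no component failed).
#'
#' @param labels Character vector of labels.
#' @return A single label.
#' @export
worst_label <- function(labels) {
  if (!length(labels)) return("Good")
  stopifnot(all(labels %in% .LABELS))
  .LABELS[max(match(labels, .LABELS))]
}

#' Score one component against a profile
#'
#' The score starts at 0 and is increased by 1 for each enabled, unmet
#' condition among: `rscc >= rscc_min`, `avg_occupancy >= occupancy_min`,
#' `rsr <= rsr_good_max`, `owab <= owab_max`, `r_free <= r_free_max`,
#' `resolution <= resolution_max` (comparisons inclusive: meeting the
#' printed threshold passes).  An enabled condition whose input is absent
#' counts as unmet and is additionally listed in `missing_conditions`.
#' Independently, `rsr > rsr_max` forces the label `Bad` by flooring the
#' score at `tolerance + 1` (recorded as condition `"rsr_max"`).
#'
#' @param stats A [residue_stats()] or a single row of [stats_for()] output.
#' @param model_stats list with `resolution` and `r_free` (`NA` allowed).
#' @param profile A `ligqc_profile`.
#' @param key Residue key carried through to the result.
#' @return A `ligqc_component_result`: list with `key`, `score`, `label`,
#'   `failed_conditions`, `missing_conditions`.
#' @examples
#' p <- default_profiles()[["Default (PDB_REDO)"]]
#' evaluate_component(residue_stats(rsr = 0.065, rscc = 0.97,
#'                                  avg_occupancy = 1.0), profile = p)$score
#' @export
evaluate_component <- function(stats,
                               model_stats = list(resolution = NA_real_,
                                                  r_free = NA_real_),
                               profile, key = NA_character_) {
  validate_profile(profile)
  val <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)
  conditions <- list(
    rscc = list(value = val(stats$rscc), threshold = profile$rscc_min,
                pass = function(v, t) v >= t),
    avg_occupancy = list(value = val(stats$avg_occupancy),
                         threshold = profile$occupancy_min,
                         pass = function(v, t) v >= t),
    rsr = list(value = val(stats$rsr), threshold = profile$rsr_good_max,
               pass = function(v, t) v <= t),
    owab = list(value = val(stats$owab), threshold = profile$owab_max,
                pass = function(v, t) v <= t),
    r_free = list(value = val(model_stats$r_free),
                  threshold = profile$r_free_max,
                  pass = function(v, t) v <= t),
    resolution = list(value = val(model_stats$resolution),
                      threshold = profile$resolution_max,
                      pass = function(v, t) v <= t)
  )
  failed <- character()
  missing <- character()
  score <- 0L
  for (nm in names(conditions)) {
    cond <- conditions[[nm]]
    if (is.na(cond$threshold)) next   # disabled
    if (is.na(cond$value)) {
      score <- score + 1L
      failed <- c(failed, nm)
      missing <- c(missing, nm)
    } else if (!cond$pass(cond$value, cond$threshold)) {
      score <- score + 1L
      failed <- c(failed, nm)
    }
  }
  rsr_v <- val(stats$rsr)
  if (!is.na(profile$rsr_max) && !is.na(rsr_v) && rsr_v > profile$rsr_max) {
    # hard cap: force Bad whatever the rest says
    score <- max(score, profile$tolerance + 1L)
    failed <- c(failed, "rsr_max")
  }
  structure(list(key = key, score = as.integer(score),
                 label = label_from_score(score, profile$tolerance),
                 failed_conditions = failed,
                 missing_conditions = missing),
            class = "ligqc_component_result")
}

#' Classify a ligand / binding-site pair
#'
#' Scores every ligand component and every binding-site residue with
#' [evaluate_component()], then labels the ligand and the site by the worst
#' label among their respective components — a site with one Bad residue is
#' Bad regardless of the rest, and a site is Good only when every residue
#' is Good.  An empty binding site yields a Good site label with a warning.
#'
#' @param ligand A `ligqc_ligand`.
#' @param site A `ligqc_site` from [find_binding_site()].
#' @param stats data.frame from [stats_for()] covering all components.
#' @param model_stats list with `resolution`, `r_free`.
#' @param profile A `ligqc_profile`.
#' @return A `ligqc_pair_result`: `ligand_components`, `site_components`
#'   (lists of component results), `ligand_label`, `site_label`,
#'   `ligand_worst_score`, `site_worst_score`.
#' @export
classify_pair <- function(ligand, site, stats,
                          model_stats = list(resolution = NA_real_,
                                             r_free = NA_real_),
                          profile) {
  eval_keys <- function(keys) {
    lapply(keys, function(k) {
      row <- stats[match(k, stats$res_key), , drop = FALSE]
      if (!nrow(row) || is.na(match(k, stats$res_key))) {
        row <- residue_stats()
      }
      evaluate_component(row, model_stats, profile, key = k)
    })
  }
  lig_res <- eval_keys(ligand$components)
  if (!length(site$residues)) {
    warning("empty binding site for ", ligand$group_id)
  }
  site_res <- eval_keys(site$residues)
  lab <- function(res) worst_label(vapply(res, `[[`, "", "label"))
  sc <- function(res) {
    if (!length(res)) return(0L)
    max(vapply(res, `[[`, integer(1), "score"))
  }
  structure(list(ligand = ligand,
                 ligand_components = lig_res, site_components = site_res,
                 ligand_label = lab(lig_res), site_label = lab(site_res),
                 ligand_worst_score = sc(lig_res),
                 site_worst_score = sc(site_res)),
            class = "ligqc_pair_result")
}

#' @export
print.ligqc_pair_result <- function(x, ...) {
  cat(sprintf("<ligqc_pair %s: ligand %s (worst score %d), site %s (%d residues, worst score %d)>\n",
              x$ligand$group_id, x$ligand_label, x$ligand_worst_score,
              x$site_label, length(x$site_components), x$site_worst_score))
  invisible(x)
}
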
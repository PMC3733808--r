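# End-to-end driver: ids -> structures -> ligands -> sites -> classification
# -> results CSV + per-component CSV + rejection report.

#' Configuration of a validation run
#'
#' @param ids Character vector of structure codes, or `NULL` with `id_file`.
#' @param id_file Plain-text list of ids, one per line, `#` comments.
#' @param data_dir Directory holding `<id>.pdb` and `<id>.tsv` per id.
#' @param profile A `ligqc_profile`; its `source` must match the stats
#'   dialect found in `data_dir`.
#' @param lists Exclusion lists.
#' @param overrides Optional path to a label-override file (`component key
#'   TAB label`), applied after automatic classification; this replaces the
#'   interactive visual re-classification step of GUI workflows.
#' @param out_dir Output directory for `results.csv`, `components.csv` and
#'   `rejections.tsv`.
#' @return A `ligqc_run_config`.
#' @export
run_config <- function(ids = NULL, id_file = NULL, data_dir,
                       profile = default_profiles()[["Default (PDB_REDO)"]],
                       lists = default_exclusion_lists(),
                       overrides = NULL, out_dir = NULL) {
  if (is.null(ids)) {
    if (is.null(id_file)) stop("either ids or id_file must be given")
    lines <- readLines(id_file, warn = FALSE)
    lines <- toupper(trimws(sub("#.*$", "", lines)))
    ids <- lines[nzchar(lines)]
  }
  if (!dir.exists(data_dir)) stop("data_dir not readable: ", data_dir)
  validate_profile(profile)
  structure(list(ids = ids, data_dir = data_dir, profile = profile,
                 lists = lists, overrides = overrides, out_dir = out_dir),
            class = "ligqc_run_config")
}

.read_overrides <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(key = character(), label = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed override line")
  out <- data.frame(key = vapply(parts, `[`, "", 1),
                    label = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  if (!all(out$label %in% .LABELS)) stop("unknown label in override file")
  out
}

#' Run the whole classification pipeline
#'
#' Every id is processed independently: ids whose stats table is missing are
#' rejected with reason `no_stats_data`; per-id failures are recorded on
#' standard error and do not stop the run.  When `config$out_dir` is set,
#' [write_results()] and [write_rejections()] are called on the collected
#' output.
#'
#' @param config A [run_config()].
#' @return list with `results` (main per-pair data.frame), `components`
#'   (per-scored-residue data.frame), `rejections` (subject/reason
#'   data.frame), and `pair_results` (list of `ligqc_pair_result`).
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "ligqc_run_config"))
  p <- config$profile
  results <- list()
  components <- list()
  rejections <- list()
  pair_results <- list()
  overrides <- if (!is.null(config$overrides)) {
    .read_overrides(config$overrides)
  } else NULL
  for (id in config$ids) {
    pdb_path <- file.path(config$data_dir, paste0(id, ".pdb"))
    tsv_path <- file.path(config$data_dir, paste0(id, ".tsv"))
    if (!file.exists(tsv_path)) {
      rejections <- c(rejections, list(.rejection_record(id, "no_stats_data")))
      next
    }
    out <- tryCatch({
      model <- parse_structure(pdb_path, model_id = id,
                               source = if (p$source == "PDB_REDO")
                                 "PDB_REDO" else "PDB")
      bundle <- parse_stats_table(tsv_path)
      if (bundle$source != p$source) {
        stop(sprintf("stats dialect %s does not match profile source %s",
                     bundle$source, p$source))
      }
      model$meta$resolution <- bundle$model_stats$resolution
      model$meta$r_free <- bundle$model_stats$r_free
      ext <- extract_ligands(model, config$lists, p$bond_cutoff)
      id_rej <- ext$rejections
      if (nrow(id_rej)) id_rej$subject <- paste(id, id_rej$subject)
      pieces <- lapply(ext$ligands, function(lig) {
        site <- find_binding_site(model, lig, config$lists, p$site_cutoff)
        st <- stats_for(model, bundle, c(lig$components, site$residues))
        pr <- withCallingHandlers(
          classify_pair(lig, site, st, bundle$model_stats, p),
          warning = function(w) {
            message(id, ": ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        pr <- .apply_overrides(pr, overrides, id)
        list(pair = pr,
             result = .pair_row(id, p$source, pr, site),
             comps = .component_rows(id, pr))
      })
      list(rej = id_rej, pieces = pieces)
    }, error = function(e) {
      message(sprintf("error processing %s: %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(out)) next
    if (nrow(out$rej)) rejections <- c(rejections, list(out$rej))
    for (pc in out$pieces) {
      results <- c(results, list(pc$result))
      components <- c(components, list(pc$comps))
      pair_results <- c(pair_results, list(pc$pair))
    }
  }
  bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  res <- list(
    results = bind(results, .pair_row(character(), character(), NULL, NULL)),
    components = bind(components, .component_rows(character(), NULL)),
    rejections = bind(rejections,
                      .rejection_record(character(), character())),
    pair_results = pair_results)
  rownames(res$results) <- rownames(res$components) <-
    rownames(res$rejections) <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(res, config$out_dir)
    write_rejections(res$rejections,
                     file.path(config$out_dir, "rejections.tsv"))
  }
  res
}

# non-interactive replacement for visual re-classification: override
# component labels by key ("<id> <res_key>" or plain res_key), then
# re-aggregate the pair labels
.apply_overrides <- function(pr, overrides, id) {
  if (is.null(overrides) || !nrow(overrides)) return(pr)
  fix <- function(res) {
    lapply(res, function(cr) {
      hit <- match(TRUE, overrides$key %in% c(cr$key, paste(id, cr$key)))
      if (!is.na(hit)) cr$label <- overrides$label[hit]
      cr
    })
  }
  pr$ligand_components <- fix(pr$ligand_components)
  pr$site_components <- fix(pr$site_components)
  lab <- function(res) worst_label(vapply(res, `[[`, "", "label"))
  pr$ligand_label <- lab(pr$ligand_components)
  pr$site_label <- lab(pr$site_components)
  pr
}

.pair_row <- function(id, source, pr, site) {
  if (is.null(pr)) {
    return(data.frame(model_id = character(), source = character(),
                      ligand_id = character(), ligand_label = character(),
                      ligand_worst_score = integer(),
                      site_label = character(),
                      site_worst_score = integer(),
                      n_site_residues = integer(),
                      failed_conditions = character(),
                      missing_conditions = character(),
                      stringsAsFactors = FALSE))
  }
  collect <- function(res, what) {
    v <- unique(unlist(lapply(res, `[[`, what)))
    paste(v, collapse = ";")
  }
  all_comp <- c(pr$ligand_components, pr$site_components)
  data.frame(model_id = id, source = source,
             ligand_id = pr$ligand$group_id,
             ligand_label = pr$ligand_label,
             ligand_worst_score = pr$ligand_worst_score,
             site_label = pr$site_label,
             site_worst_score = pr$site_worst_score,
             n_site_residues = length(site$residues),
             failed_conditions = collect(all_comp, "failed_conditions"),
             missing_conditions = collect(all_comp, "missing_conditions"),
             stringsAsFactors = FALSE)
}

.component_rows <- function(id, pr) {
  if (is.null(pr)) {
    return(data.frame(model_id = character(), ligand_id = character(),
                      role = character(), res_key = character(),
                      score = integer(), label = character(),
                      failed_conditions = character(),
                      missing_conditions = character(),
                      stringsAsFactors = FALSE))
  }
  one <- function(cr, role) {
    data.frame(model_id = id, ligand_id = pr$ligand$group_id, role = role,
               res_key = cr$key, score = cr$score, label = cr$label,
               failed_conditions = paste(cr$failed_conditions,
                                         collapse = ";"),
               missing_conditions = paste(cr$missing_conditions,
                                          collapse = ";"),
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(pr$ligand_components, one, role = "ligand"),
            lapply(pr$site_components, one, role = "site"))
  do.call(rbind, rows)
}

#' Write the results CSV files
#'
#' `results.csv` holds one row per ligand/site pair with the aggregate
#' labels and worst scores; `components.csv` one row per scored residue.
#' Both use RFC-4180 quoting, so the label columns filter as plain strings
#' in any spreadsheet.
#'
#' @param res Output of [run_validation()] (or a list with `results` and
#'   `components` data.frames).
#' @param out_dir Directory to write into.
#' @return Paths of the two files, invisibly.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  main <- file.path(out_dir, "results.csv")
  comp <- file.path(out_dir, "components.csv")
  utils::write.csv(res$results, main, row.names = FALSE, quote = TRUE)
  utils::write.csv(res$components, comp, row.names = FALSE, quote = TRUE)
  invisible(c(main, comp))
}

#' Write the rejection report
#'
#' One line per rejected structure or ligand: `subject TAB reason`, after a
#' header line, in stable (input) order.
#'
#' @param rejections data.frame with `subject`, `reason`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rejections <- function(rejections, path) {
  lines <- c("subject\treason",
             if (nrow(rejections)) {
               paste(rejections$subject, rejections$reason, sep = "\t")
             })
  writeLines(lines, path)
  invisible(path)
}
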
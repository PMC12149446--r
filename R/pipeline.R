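#' Pipeline orchestration
#'
#' Runs the full comparison for a configured set of experimental/predicted
#' structure pairs and writes the report tables (one CSV per stage plus a
#' summary). The configuration is a YAML file (or an equivalent list)
#' mapping each comparison unit to its files, chains, domain spans, ligand
#' identifiers and numbering offsets.
#'
#' @name pipeline
NULL

PIPELINE_STAGES <- c("rmsd", "sse", "geometry", "pockets", "tracks", "torsions")

#' Validate a run configuration
#'
#' @param config a list (e.g. from `yaml::read_yaml`) with `units` (list of
#'   comparison units) and optional `options`.
#' @return character vector of problems; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  say <- function(...) problems <<- c(problems, paste0(...))
  units <- config$units
  if (is.null(units) || length(units) == 0) {
    say("config has no comparison units")
    return(problems)
  }
  for (i in seq_along(units)) {
    u <- units[[i]]
    id <- if (!is.null(u$name)) u$name else paste0("unit ", i)
    for (f in c("experimental_file", "predicted_file")) {
      if (is.null(u[[f]])) say(id, ": missing field ", f)
      else if (!file.exists(u[[f]])) say(id, ": file not found: ", u[[f]])
    }
    if (is.null(u$chain)) say(id, ": missing field chain")
    for (sp in c("dbd_span", "lbd_span")) {
      s <- u[[sp]]
      if (is.null(s) || length(s) != 2) { say(id, ": ", sp,
                                              " must be [start, end]"); next }
      if (s[1] > s[2]) say(id, ": ", sp, " has start > end")
    }
    if (!is.null(u$dbd_span) && !is.null(u$lbd_span) &&
        length(u$dbd_span) == 2 && length(u$lbd_span) == 2 &&
        max(u$dbd_span[1], u$lbd_span[1]) <= min(u$dbd_span[2], u$lbd_span[2]))
      say(id, ": DBD and LBD spans overlap")
    if (!is.null(u$pocket_cutoff) && u$pocket_cutoff <= 0)
      say(id, ": pocket cutoff must be positive")
  }
  opts <- config$options
  if (!is.null(opts$voxel) && (opts$voxel <= 0 || opts$voxel > 1.4))
    say("options: voxel must lie in (0, 1.4]")
  if (!is.null(opts$alpha) && (opts$alpha <= 0 || opts$alpha >= 1))
    say("options: alpha must lie in (0, 1)")
  problems
}

#' Run the comparison pipeline
#'
#' Executes the selected stages in order for every configured unit and
#' writes `rmsd.csv`, `sse.csv`, `geometry.csv`, `pockets.csv`,
#' `tracks.csv`, `torsions.csv` and `summary.csv` (plus a JSON run manifest
#' echoing every parameter) into `out_dir`. A failing unit is reported and
#' skipped; partial outputs are retained.
#'
#' @param config configuration list or path to a YAML file.
#' @param stages subset of `c("rmsd","sse","geometry","pockets","tracks",
#'   "torsions")`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the result data.frames; errors per unit are
#'   collected in the `errors` attribute.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  problems <- validate_config(config)
  if (length(problems) > 0)
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- config$options
  voxel <- if (!is.null(opts$voxel)) opts$voxel else DEFAULT_VOXEL
  res <- list()
  errors <- character(0)
  add <- function(stage, df) res[[stage]] <<- rbind(res[[stage]], df)

  for (u in config$units) {
    id <- if (!is.null(u$name)) u$name else basename(u$experimental_file)
    ok <- tryCatch({
      exp_model <- read_structure(u$experimental_file,
                                  source_kind = "experimental")
      pred_model <- read_structure(u$predicted_file, source_kind = "predicted")
      exp_chain <- exp_model$chains[[u$chain]]
      pred_chain_id <- if (!is.null(u$predicted_chain)) u$predicted_chain
                       else names(pred_model$chains)[1]
      pred_chain <- pred_model$chains[[pred_chain_id]]
      if (is.null(exp_chain)) stop("chain ", u$chain, " absent from ", id)
      spans <- list(DBD = domain_span("DBD", u$dbd_span[1], u$dbd_span[2]),
                    LBD = domain_span("LBD", u$lbd_span[1], u$lbd_span[2]))

      if ("rmsd" %in% stages) {
        for (sp in spans) {
          tr <- rmsd_triple(exp_chain, pred_chain, sp)
          add("rmsd", data.frame(unit = id, domain = sp$domain_name,
                                 all_atom = tr$all_atom, backbone = tr$backbone,
                                 c_alpha = tr$c_alpha,
                                 hierarchy_ok = hierarchy_check(tr)))
        }
      }
      if ("sse" %in% stages) {
        for (who in c("experimental", "predicted")) {
          ch <- if (who == "experimental") exp_chain else pred_chain
          labels <- assign_sse(ch)
          for (sp in spans) {
            comp <- sse_composition(labels, sp)
            add("sse", data.frame(unit = id, source = who,
                                  domain = sp$domain_name,
                                  helix_pct = comp$helix_pct,
                                  sheet_pct = comp$sheet_pct,
                                  loop_pct = comp$loop_pct))
          }
        }
      }
      if ("geometry" %in% stages) {
        for (who in c("experimental", "predicted")) {
          ch <- if (who == "experimental") exp_chain else pred_chain
          geo <- domain_geometry(ch, spans$DBD, spans$LBD)
          add("geometry", data.frame(unit = id, source = who,
                                     epsilon = geo$epsilon, theta = geo$theta,
                                     dihedral = geo$dihedral))
        }
      }
      if ("pockets" %in% stages) {
        lig <- exp_model$hetero_groups
        if (!is.null(u$ligand))
          lig <- lig[lig$res_name %in% u$ligand, , drop = FALSE]
        if (!is.null(lig) && nrow(lig) > 0) {
          pm <- pocket_metrics(exp_model, lig,
                               cutoff = u$pocket_cutoff %||% 5.0,
                               voxel = voxel)
          add("pockets", data.frame(unit = id, found = pm$found,
                                    leaked = pm$leaked, volume = pm$volume,
                                    area = pm$area, sphericity = pm$sphericity,
                                    effective_radius = pm$effective_radius))
        } else {
          add("pockets", data.frame(unit = id, found = FALSE, leaked = FALSE,
                                    volume = NA, area = NA, sphericity = NA,
                                    effective_radius = NA))
        }
      }
      if ("tracks" %in% stages) {
        plddt <- load_plddt_track(pred_model, pred_chain_id)
        bfac <- load_bfactor_track(exp_model, u$chain)
        tracks <- list(pLDDT = plddt, b_factor = bfac)
        offsets <- c(0, u$numbering_offset %||% 0)
        if (!is.null(u$validation_file)) {
          tracks$RSCC <- read_validation_rscc(u$validation_file, u$chain)
          offsets <- c(offsets, u$numbering_offset %||% 0)
        }
        paired <- align_tracks(tracks, offsets)
        for (m in names(paired$series))
          add("tracks", data.frame(unit = id, residue = paired$residues,
                                   metric = m, value = paired$series[[m]]))
      }
      if ("torsions" %in% stages) {
        te <- backbone_torsions(exp_chain)
        tp <- backbone_torsions(pred_chain)
        cmp <- torsion_comparison(te, tp)
        tal_e <- ramachandran_tally(te)
        tal_p <- ramachandran_tally(tp)
        add("torsions", data.frame(
          unit = id,
          rmsd_phi = cmp$phi$rmsd, rmsd_psi = cmp$psi$rmsd,
          mae_phi = cmp$phi$mae, mae_psi = cmp$psi$mae,
          wasserstein_phi = cmp$phi$wasserstein,
          wasserstein_psi = cmp$psi$wasserstein,
          pearson_phi = cmp$phi$pearson, pearson_psi = cmp$psi$pearson,
          n_paired = cmp$n_paired,
          favored_pct_exp = tal_e$favored_pct,
          favored_pct_pred = tal_p$favored_pct,
          outliers_exp = tal_e$outlier_count,
          outliers_pred = tal_p$outlier_count))
      }
      TRUE
    }, error = function(e) {
      errors <<- c(errors, paste0(id, ": ", conditionMessage(e)))
      FALSE
    })
    if (!ok) next
  }

  for (stage in intersect(stages, names(res)))
    utils::write.csv(res[[stage]], file.path(out_dir, paste0(stage, ".csv")),
                     row.names = FALSE)
  if (!is.null(res$rmsd)) {
    s <- res$rmsd
    summary_df <- do.call(rbind, lapply(split(s, s$domain), function(d)
      data.frame(domain = d$domain[1], n = nrow(d),
                 mean_all_atom = mean(d$all_atom), sd_all_atom = stats::sd(d$all_atom),
                 cv_all_atom = if (nrow(d) >= 2)
                   coefficient_of_variation(d$all_atom) else NA_real_)))
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    res$summary <- summary_df
  }
  manifest <- list(timestamp = format(Sys.time()), stages = stages,
                   options = list(voxel = voxel),
                   units = vapply(config$units, function(u)
                     u$name %||% basename(u$experimental_file), character(1)),
                   errors = errors)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(errors) > 0)
    warning("pipeline finished with errors:\n  ",
            paste(errors, collapse = "\n  "))
  attr(res, "errors") <- errors
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
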
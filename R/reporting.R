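# Structured result export: base-case report tables, sensitivity-analysis
# CSVs, and a run manifest written alongside every result set.

#' Run manifest
#'
#' A small provenance record written next to every exported result set.
#'
#' @param command Name of the analysis ("base-case", "dsa", "psa", ...).
#' @param params_source Parameter file path, or "defaults".
#' @param life_table_source Life-table file path, or "synthetic".
#' @param seed Integer seed, or `NA` for deterministic analyses.
#' @return A named list.
#' @export
run_manifest <- function(command, params_source = "defaults",
                         life_table_source = "synthetic", seed = NA) {
  list(command = command,
       params_source = params_source,
       life_table_source = life_table_source,
       seed = seed,
       package_version = as.character(utils::packageVersion("strokecea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Export base-case results
#'
#' Writes the per-strategy report (cumulative discounted cost and QALYs
#' plus interpretation and deltas) as both JSON and CSV, the full cohort
#' occupancy traces as CSV, and a manifest.
#'
#' @param fit A `stroke_cea` object.
#' @param out_dir Output directory (created if needed).
#' @param manifest A [run_manifest()]; a default one is built if omitted.
#' @return `out_dir`, invisibly.
#' @export
write_base_case <- function(fit, out_dir,
                            manifest = run_manifest("base-case")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- summary(fit)
  utils::write.csv(tab, file.path(out_dir, "base_case.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(strategies = tab[tab$strategy != "delta", ],
         delta = as.list(tab[tab$strategy == "delta",
                             c("cumulative_cost", "cumulative_effectiveness")]),
         dominance = fit$comparison$dominance,
         icer = fit$comparison$icer,
         nmb = as.list(fit$comparison$nmb),
         wtp = fit$comparison$wtp),
    file.path(out_dir, "base_case.json"),
    auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows")
  for (nm in names(fit$results)) {
    occ <- as.data.frame(fit$results[[nm]]$trace$occupancy)
    occ <- cbind(cycle = 0:fit$params$n_cycles, occ)
    utils::write.csv(occ, file.path(out_dir, paste0("trace_", nm, ".csv")),
                     row.names = FALSE)
  }
  .write_manifest(manifest, out_dir)
  invisible(out_dir)
}

#' Export a tornado table
#'
#' @param tornado A `tornado` data frame from [one_way_dsa()].
#' @param out_dir Output directory.
#' @param manifest A [run_manifest()].
#' @return `out_dir`, invisibly.
#' @export
write_dsa <- function(tornado, out_dir, manifest = run_manifest("dsa")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tornado, file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)
  .write_manifest(manifest, out_dir)
  invisible(out_dir)
}

#' Export an ICER-versus-parameter curve
#'
#' @param curve Data frame from [icer_vs_parameter()].
#' @param out_dir Output directory.
#' @param manifest A [run_manifest()].
#' @return `out_dir`, invisibly.
#' @export
write_icer_curve <- function(curve, out_dir,
                             manifest = run_manifest("icer-curve")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(curve, file.path(out_dir, "icer_curve.csv"),
                   row.names = FALSE)
  .write_manifest(manifest, out_dir)
  invisible(out_dir)
}

#' Export PSA results
#'
#' Writes the per-iteration cost/effect cloud, the CEAC points, and a
#' summary JSON.
#'
#' @param psa A `psa_result`.
#' @param out_dir Output directory.
#' @param manifest A [run_manifest()].
#' @return `out_dir`, invisibly.
#' @export
write_psa <- function(psa, out_dir,
                      manifest = run_manifest("psa", seed = psa$seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(psa$iterations, file.path(out_dir, "psa_cloud.csv"),
                   row.names = FALSE)
  utils::write.csv(psa$ceac, file.path(out_dir, "ceac.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_iterations = psa$n_iterations, seed = psa$seed,
         spread_cv = psa$spread_cv,
         fraction_intervention_dominant = psa$fraction_intervention_dominant,
         mean_cost = as.list(psa$mean_cost),
         mean_effect = as.list(psa$mean_effect)),
    file.path(out_dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA)
  .write_manifest(manifest, out_dir)
  invisible(out_dir)
}
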
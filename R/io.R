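#' Write analysis outputs to CSV plus a reproducibility manifest
#'
#' Writes whichever results are supplied: the base-case cost-effectiveness
#' table (presentation-rounded: costs/ICERs 2 decimals, effects 3), itemized
#' cost components, a tornado table, the CEAC, and the CE-plane cloud, plus a
#' JSON manifest recording the seed, package version and an MD5 hash of the
#' registry file so any run can be reproduced from its manifest.
#'
#' @param outdir output directory (created if missing).
#' @param cea_table optional `cea_table`.
#' @param items optional [itemized_costs()] data.frame.
#' @param tornado optional `tornado` data.frame.
#' @param ceac_curve optional `ceac_curve`.
#' @param cloud optional [ce_plane_cloud()] data.frame.
#' @param seed seed recorded in the manifest.
#' @param registry_path path of the registry config hashed into the manifest.
#' @return invisible character vector of files written.
#' @export
write_results <- function(outdir, cea_table = NULL, items = NULL,
                          tornado = NULL, ceac_curve = NULL, cloud = NULL,
                          seed = NA, registry_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  written <- character(0)
  emit <- function(d, file) {
    path <- file.path(outdir, file)
    utils::write.csv(d, path, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(cea_table)) emit(format_cea(cea_table), "base_case.csv")
  if (!is.null(items)) emit(items, "itemized_costs.csv")
  if (!is.null(tornado)) emit(as.data.frame(tornado), "tornado.csv")
  if (!is.null(ceac_curve)) emit(as.data.frame(ceac_curve), "ceac.csv")
  if (!is.null(cloud)) emit(cloud, "ce_plane_cloud.csv")
  manifest <- list(
    package = "sedcea",
    version = as.character(utils::packageVersion("sedcea")),
    seed = seed,
    registry_md5 = if (!is.null(registry_path) && file.exists(registry_path))
      as.character(tools::md5sum(registry_path)) else NA,
    files = basename(written),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, mpath))
}
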
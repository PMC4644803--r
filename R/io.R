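#' Write a dataset directory
#'
#' Serializes a `map_dataset` to a plain-text directory: `protocol.json`
#' (stimulus protocol with a format version), `sites.csv` (site coordinates),
#' `spikes.csv` (sparse long-format spike counts; only nonzero bins are
#' stored, and absent (site, frequency, intensity, trial, bin) combinations
#' are zero by convention), and `truth.csv` when ground truth is available.
#'
#' @param ds A `map_dataset`.
#' @param dir Output directory.
#' @param overwrite Refuse an existing directory unless TRUE.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, overwrite = FALSE) {
  stopifnot(is.list(ds), inherits(ds$protocol, "stim_protocol"))
  if (dir.exists(dir) && !overwrite)
    stop("output directory exists (use overwrite = TRUE): ", dir,
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proto <- unclass(ds$protocol)
  jsonlite::write_json(proto, file.path(dir, "protocol.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(ds$sites, file.path(dir, "sites.csv"), na = "")
  readr::write_csv(ds$spikes, file.path(dir, "spikes.csv"), na = "")
  if (!is.null(ds$truth))
    readr::write_csv(ds$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}

#' Read a dataset directory
#'
#' Loads and validates a directory written by [write_dataset()] (or prepared
#' externally in the same format). Referential integrity is enforced: every
#' spike row must reference a known site, stimuli must lie on the protocol
#' grid, and counts must be nonnegative integers. The reader rejects unknown
#' major format versions.
#'
#' @param dir Dataset directory.
#' @return A `map_dataset` list: `protocol`, `sites`, `spikes`, `truth`
#'   (NULL when absent).
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such dataset directory: ", dir, call. = FALSE)
  for (f in c("protocol.json", "sites.csv", "spikes.csv"))
    if (!file.exists(file.path(dir, f)))
      stop("dataset is missing ", f, call. = FALSE)
  pj <- jsonlite::read_json(file.path(dir, "protocol.json"),
                            simplifyVector = TRUE)
  ver <- if (is.null(pj$version)) "0" else as.character(pj$version)
  if (strsplit(ver, ".", fixed = TRUE)[[1]][1] != "1")
    stop("unsupported dataset format version: ", ver, call. = FALSE)
  protocol <- make_protocol(
    frequencies_hz = pj$frequencies_hz, intensities_db = pj$intensities_db,
    n_trials = pj$n_trials, tone_ms = pj$tone_ms, ramp_ms = pj$ramp_ms,
    isi_ms = pj$isi_ms, bin_ms = pj$bin_ms)

  sites <- readr::read_csv(file.path(dir, "sites.csv"),
                           show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "penetration_id", "x_um", "y_um")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("sites.csv is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sites$site_id))
    stop("sites.csv contains duplicate site_id values", call. = FALSE)

  spikes <- readr::read_csv(file.path(dir, "spikes.csv"),
                            show_col_types = FALSE, progress = FALSE)
  need <- c("site_id", "freq_hz", "intensity_db", "trial", "bin_ms", "count")
  miss <- setdiff(need, names(spikes))
  if (length(miss))
    stop("spikes.csv is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  orphan <- which(!spikes$site_id %in% sites$site_id)
  if (length(orphan))
    stop("spikes.csv row ", orphan[1], " references unknown site_id '",
         spikes$site_id[orphan[1]], "'", call. = FALSE)
  bad_f <- which(!vapply(spikes$freq_hz, function(v)
    any(abs(protocol$frequencies_hz - v) <= 1e-6 * max(1, abs(v))),
    logical(1)))
  if (length(bad_f))
    stop("spikes.csv row ", bad_f[1], ": freq_hz ", spikes$freq_hz[bad_f[1]],
         " is not on the protocol grid", call. = FALSE)
  bad_i <- which(!spikes$intensity_db %in% protocol$intensities_db)
  if (length(bad_i))
    stop("spikes.csv row ", bad_i[1], ": intensity_db ",
         spikes$intensity_db[bad_i[1]], " is not on the protocol grid",
         call. = FALSE)
  if (any(spikes$count < 0) || any(spikes$count != round(spikes$count)))
    stop("spikes.csv counts must be nonnegative integers", call. = FALSE)

  truth <- NULL
  if (file.exists(file.path(dir, "truth.csv")))
    truth <- readr::read_csv(file.path(dir, "truth.csv"),
                             show_col_types = FALSE, progress = FALSE)
  structure(list(protocol = protocol, sites = sites, spikes = spikes,
                 truth = truth), class = "map_dataset")
}

#' Write the result tables of an analysis
#'
#' Writes `site_metrics.csv`, `map_summary.csv`, `animal_summaries.csv`,
#' `group_comparisons.csv`, the fully resolved analysis options
#' (`config.json`) and a short `run.log` into `dir`. Missing values are
#' written as empty cells; identical analyses produce byte-identical files.
#'
#' @param analysis A [analyze_dataset()] result (possibly partial).
#' @param dir Output directory (created if needed).
#' @param overwrite Refuse an existing directory unless TRUE.
#' @return `dir`, invisibly.
#' @export
write_results <- function(analysis, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite &&
      length(list.files(dir)) > 0)
    stop("results directory exists and is not empty (use overwrite = TRUE): ",
         dir, call. = FALSE)
  parent <- dirname(normalizePath(dir, mustWork = FALSE))
  if (!dir.exists(parent) || file.access(parent, 2) != 0)
    stop("cannot write results under ", parent, call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(analysis$site_metrics, file.path(dir, "site_metrics.csv"),
                   na = "")
  readr::write_csv(analysis$map_summary, file.path(dir, "map_summary.csv"),
                   na = "")
  readr::write_csv(analysis$animal_summaries,
                   file.path(dir, "animal_summaries.csv"), na = "")
  readr::write_csv(analysis$group_comparisons,
                   file.path(dir, "group_comparisons.csv"), na = "")
  jsonlite::write_json(unclass(analysis$opts), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    "tonomapr analysis run",
    sprintf("sites: %d", nrow(analysis$site_metrics)),
    sprintf("animals: %d", nrow(analysis$map_summary)),
    sprintf("ai_sites: %d", sum(analysis$site_metrics$in_ai, na.rm = TRUE)),
    sprintf("comparisons: %d", nrow(analysis$group_comparisons)))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}
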
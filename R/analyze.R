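#' Analyze a whole multiunit mapping dataset
#'
#' Runs the full pipeline on a dataset (generated by [generate_cohort()] or
#' loaded with [read_dataset()]): per-site receptive-field metrics, per-animal
#' AI delineation and tonotopy, per-animal summaries and, when two groups are
#' present, group comparisons.
#'
#' @param ds A `map_dataset` (list with `protocol`, `sites`, `spikes`, and
#'   optionally `truth`).
#' @param opts An [analysis_options()] object.
#' @return Object of class `map_analysis`: list with
#'   `site_metrics` (one row per site, including `in_ai`, `pos_norm`,
#'   `cf_norm`), `map_summary` (one row per animal), `animal_summaries`,
#'   `group_comparisons`, and the resolved `opts`.
#' @export
analyze_dataset <- function(ds, opts = analysis_options()) {
  stopifnot(is.list(ds), !is.null(ds$protocol), !is.null(ds$sites),
            !is.null(ds$spikes))
  protocol <- ds$protocol
  sites <- ds$sites
  spikes <- ds$spikes
  idx_by_site <- split(seq_len(nrow(spikes)), spikes$site_id)
  rows <- vector("list", nrow(sites))
  empty <- spikes[integer(0), , drop = FALSE]
  for (s in seq_len(nrow(sites))) {
    sid <- sites$site_id[s]
    sp <- if (!is.null(idx_by_site[[sid]]))
      spikes[idx_by_site[[sid]], , drop = FALSE] else empty
    rows[[s]] <- analyze_site(sp, protocol, opts, site_id = sid)
  }
  metrics <- dplyr::bind_rows(rows)
  metrics <- dplyr::left_join(sites, metrics, by = "site_id")

  if (!"animal_id" %in% names(metrics)) metrics$animal_id <- "A01"
  if (!"group" %in% names(metrics)) metrics$group <- "all"

  metrics$in_ai <- FALSE
  metrics$pos_norm <- NA_real_
  metrics$cf_norm <- NA_real_
  map_rows <- list()
  summ_rows <- list()
  for (a in unique(metrics$animal_id)) {
    sel <- which(metrics$animal_id == a)
    tono <- map_tonotopy(metrics[sel, ], opts)
    metrics$in_ai[sel] <- tono$in_ai
    metrics$pos_norm[sel] <- tono$pos_norm
    metrics$cf_norm[sel] <- tono$cf_norm
    map_rows[[a]] <- tibble::tibble(
      animal_id = a,
      group = metrics$group[sel][1],
      n_sites = length(sel),
      n_responsive = sum(metrics$responsive[sel]),
      n_ai = tono$n_ai,
      tonotopic_index = tono$tonotopic_index)
    summ_rows[[a]] <- summarize_animal(metrics[sel, ],
                                       tonotopic_index = tono$tonotopic_index,
                                       opts = opts)
  }
  analysis <- list(
    site_metrics = metrics,
    map_summary = dplyr::bind_rows(map_rows),
    animal_summaries = dplyr::bind_rows(summ_rows),
    opts = opts)
  rep <- cohort_report(analysis, opts)
  analysis$group_comparisons <- rep$group_comparisons
  structure(analysis, class = "map_analysis")
}

#' @export
print.map_analysis <- function(x, ...) {
  cat(sprintf("<map_analysis> %d sites, %d animals; %d AI sites\n",
              nrow(x$site_metrics), nrow(x$map_summary),
              sum(x$site_metrics$in_ai)))
  if (nrow(x$group_comparisons) > 0) {
    cat("group comparisons:\n")
    print(as.data.frame(x$group_comparisons[, c("metric", "mean1", "mean2",
                                                "t", "df", "p")]),
          digits = 4, row.names = FALSE)
  }
  invisible(x)
}
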
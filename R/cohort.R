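#' Per-animal summary of AI receptive-field metrics
#'
#' Aggregates one animal's site metrics over its responsive AI sites: the
#' percentage of sites per frequency band, the percentage of irregular sites
#' (irregularity index above the cutoff), single- versus multi/flat-peaked
#' shape percentages, the percentage of high-threshold sites (> 50 dB SPL),
#' mean BW10, mean onset latency and the map's tonotopic index.
#'
#' @param metrics Site-metrics tibble for one animal, with `in_ai` set (see
#'   [map_tonotopy()]).
#' @param tonotopic_index The animal's tonotopic index.
#' @param opts An [analysis_options()] object (band edges and cutoff).
#' @return A one-row tibble (`animal_summary`). All percentage fields are
#'   `NA` when the animal has no AI sites.
#' @export
summarize_animal <- function(metrics, tonotopic_index = NA_real_,
                             opts = analysis_options()) {
  stopifnot("in_ai" %in% names(metrics))
  ai <- metrics[metrics$in_ai & metrics$responsive, , drop = FALSE]
  n_ai <- nrow(ai)
  pct <- function(x) if (n_ai > 0) 100 * mean(x, na.rm = TRUE) else NA_real_
  edges <- opts$band_edges_khz
  bands <- band_labels(edges)
  band_pct <- rep(NA_real_, length(bands))
  if (n_ai > 0) {
    cf_khz <- ai$cf_hz / 1000
    idx <- findInterval(cf_khz, edges, rightmost.closed = TRUE)
    idx[idx < 1 | idx > length(bands)] <- NA
    band_pct <- 100 * vapply(seq_along(bands),
                             function(b) mean(idx == b, na.rm = TRUE),
                             numeric(1))
  }
  out <- tibble::tibble(
    animal_id = if ("animal_id" %in% names(metrics) && nrow(metrics) > 0)
      metrics$animal_id[1] else NA_character_,
    group = if ("group" %in% names(metrics) && nrow(metrics) > 0)
      metrics$group[1] else NA_character_,
    n_sites = nrow(metrics),
    n_responsive = sum(metrics$responsive),
    n_ai = n_ai,
    pct_irregular = pct(ai$irregularity > opts$irregularity_cutoff),
    pct_single = pct(ai$shape == "single_v"),
    pct_multiflat = pct(ai$shape != "single_v"),
    pct_hi_thr = pct(ai$threshold_db > 50),
    mean_bw10_oct = if (n_ai > 0) mean(ai$bw10_oct, na.rm = TRUE) else NA_real_,
    mean_latency_ms = if (n_ai > 0) mean(ai$latency_ms, na.rm = TRUE) else NA_real_,
    tonotopic_index = tonotopic_index
  )
  for (b in seq_along(bands)) out[[bands[b]]] <- band_pct[b]
  out
}

band_labels <- function(edges) {
  fmt <- function(x) sub("\\.", "p", sub("\\.?0+$", "", sprintf("%.2f", x)))
  paste0("pct_band_", fmt(head(edges, -1)), "_", fmt(tail(edges, -1)), "khz")
}

#' Two-group comparison of a per-animal metric
#'
#' Pooled-variance two-sample two-tailed Student's t-test on per-animal
#' values; the animal is the unit of analysis. Animals with a missing value
#' are dropped (with correspondingly reduced degrees of freedom). When both
#' groups have zero variance the test degenerates: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0`.
#'
#' @param summaries Tibble of animal summaries with a `group` column
#'   containing exactly two levels.
#' @param metric Name of the summary column to compare.
#' @return A one-row tibble: metric name, per-group n, mean and SEM, pooled
#'   `t`, `df` and two-tailed `p`.
#' @export
compare_groups <- function(summaries, metric) {
  if (!metric %in% names(summaries))
    stop("unknown metric: ", metric, call. = FALSE)
  groups <- sort(unique(summaries$group))
  if (length(groups) != 2)
    stop("compare_groups needs exactly 2 groups", call. = FALSE)
  x <- summaries[[metric]][summaries$group == groups[1]]
  y <- summaries[[metric]][summaries$group == groups[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop("need >= 2 animals with defined '", metric, "' per group",
         call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  dmean <- mean(x) - mean(y)
  if (se == 0) {
    tstat <- if (dmean == 0) 0 else sign(dmean) * Inf
    p <- if (dmean == 0) 1 else 0
  } else {
    tstat <- dmean / se
    p <- 2 * pt(-abs(tstat), df)
  }
  tibble::tibble(
    metric = metric,
    group1 = groups[1], n1 = n1, mean1 = mean(x),
    sem1 = if (n1 > 1) sd(x) / sqrt(n1) else NA_real_,
    group2 = groups[2], n2 = n2, mean2 = mean(y),
    sem2 = if (n2 > 1) sd(y) / sqrt(n2) else NA_real_,
    t = tstat, df = df, p = p)
}

default_comparison_metrics <- function(opts = analysis_options()) {
  bands <- band_labels(opts$band_edges_khz)
  hi_band <- bands[grepl("_10_50khz$", bands)]
  c("tonotopic_index", "mean_bw10_oct", "mean_latency_ms",
    "pct_single", "pct_multiflat", "pct_hi_thr", "pct_irregular",
    if (length(hi_band)) hi_band[1] else bands[length(bands) - 1])
}

#' Group-level report of a cohort analysis
#'
#' Builds the tidy per-animal summary table and, when two groups are
#' present, the table of pooled t comparisons over the standard metric set
#' (tonotopic index, mean BW10, mean latency, shape percentages,
#' high-threshold percentage, irregularity percentage and the 10--50 kHz
#' band percentage).
#'
#' @param analysis A [analyze_dataset()] result.
#' @param opts An [analysis_options()] object.
#' @param metrics Character vector of summary columns to compare.
#' @return List with `animal_summaries` and `group_comparisons` tibbles
#'   (the latter empty with 0 rows when fewer than 2 groups). With
#'   `pooled_percentages = TRUE` a `group_pooled` tibble is added whose
#'   percentages pool all AI sites of a group instead of averaging
#'   per-animal percentages (the t comparisons always stay per-animal).
#' @export
cohort_report <- function(analysis, opts = analysis_options(),
                          metrics = default_comparison_metrics(opts)) {
  summaries <- analysis$animal_summaries
  groups <- unique(summaries$group)
  comparisons <-
    if (length(groups) == 2 && all(table(summaries$group) >= 2)) {
      dplyr::bind_rows(lapply(metrics, function(m)
        compare_groups(summaries, m)))
    } else {
      tibble::tibble(metric = character(), group1 = character(),
                     n1 = integer(), mean1 = numeric(), sem1 = numeric(),
                     group2 = character(), n2 = integer(), mean2 = numeric(),
                     sem2 = numeric(), t = numeric(), df = numeric(),
                     p = numeric())
    }
  out <- list(animal_summaries = summaries, group_comparisons = comparisons)
  if (isTRUE(opts$pooled_percentages) && !is.null(analysis$site_metrics)) {
    sm <- analysis$site_metrics
    out$group_pooled <- dplyr::bind_rows(lapply(unique(sm$group), function(g) {
      pooled <- sm[sm$group == g, ]
      pooled$animal_id <- g
      summarize_animal(pooled, opts = opts)[
        , c("group", "n_sites", "n_ai", "pct_irregular", "pct_single",
            "pct_multiflat", "pct_hi_thr")]
    }))
  }
  out
}
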
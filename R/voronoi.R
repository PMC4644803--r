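#' Voronoi tessellation of a cortical map
#'
#' Partitions the mapped cortical surface into one polygon per recording
#' site, clipped to a map outline. Polygon area is proportional to the local
#' spacing of penetrations, as in standard tonotopic map renderings. The
#' default outline is the convex hull of the sites buffered outward by half
#' the median nearest-neighbor spacing.
#'
#' Cells are constructed by half-plane intersection: each site's polygon is
#' the hull clipped by the perpendicular bisector against every other site,
#' so the cells tile the hull exactly and each site lies inside its own cell.
#'
#' @param x_um,y_um Site coordinates; at least 3 non-collinear sites.
#' @param site_id Optional site labels.
#' @param hull Optional outline polygon (2-column matrix, vertices in order).
#' @param buffer_um Outward hull offset; default half the median
#'   nearest-neighbor distance.
#' @return Object of class `voronoi_map`: list with `sites` (tibble of
#'   `site_id`, `x_um`, `y_um`, `area_um2`), `cells` (list of 2-column vertex
#'   matrices), `hull`, `hull_area_um2`.
#' @examples
#' v <- voronoi_map(c(0, 0, 1, 1), c(0, 1, 0, 1),
#'                  hull = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' v$sites$area_um2 # four cells of 0.25
#' @export
voronoi_map <- function(x_um, y_um, site_id = NULL, hull = NULL,
                        buffer_um = NULL) {
  n <- length(x_um)
  stopifnot(length(y_um) == n)
  if (n < 3) stop("Voronoi tessellation needs at least 3 sites", call. = FALSE)
  pts <- cbind(x_um, y_um)
  if (anyDuplicated(round(pts, 9)))
    stop("duplicate site coordinates", call. = FALSE)
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 2)
    stop("sites are collinear; Voronoi tessellation is degenerate",
         call. = FALSE)
  if (is.null(site_id)) site_id <- sprintf("s%03d", seq_len(n))
  if (is.null(hull)) {
    if (is.null(buffer_um)) {
      d <- as.matrix(stats::dist(pts))
      diag(d) <- Inf
      buffer_um <- median(apply(d, 1, min)) / 2
    }
    hull <- buffered_hull(pts, buffer_um)
  } else {
    hull <- as.matrix(hull)
    if (polygon_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), ]
  }
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- hull
    for (j in seq_len(n)) {
      if (i == j) next
      # keep the side of the bisector closer to site i:
      # (p - m) . (pj - pi) <= 0
      dvec <- pts[j, ] - pts[i, ]
      m <- (pts[i, ] + pts[j, ]) / 2
      poly <- clip_halfplane(poly, dvec[1], dvec[2], sum(dvec * m))
      if (nrow(poly) == 0) break
    }
    cells[[i]] <- poly
  }
  areas <- vapply(cells, function(p) abs(polygon_area(p)), numeric(1))
  structure(list(
    sites = tibble::tibble(site_id = site_id, x_um = x_um, y_um = y_um,
                           area_um2 = areas),
    cells = cells,
    hull = hull,
    hull_area_um2 = abs(polygon_area(hull))
  ), class = "voronoi_map")
}

# signed area (positive for counter-clockwise vertex order)
polygon_area <- function(p) {
  if (is.null(p) || nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  i2 <- c(seq_len(nrow(p))[-1], 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

# Sutherland-Hodgman clip of polygon p by half-plane a*x + b*y <= c
clip_halfplane <- function(p, a, b, c) {
  np <- nrow(p)
  if (np == 0) return(p)
  val <- a * p[, 1] + b * p[, 2] - c
  inside <- val <= 1e-9 * max(1, abs(c))
  if (all(inside)) return(p)
  if (!any(inside)) return(p[integer(0), , drop = FALSE])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(np)) {
    j <- if (i == np) 1L else i + 1L
    if (inside[i]) out <- rbind(out, p[i, ])
    if (inside[i] != inside[j]) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, p[i, ] + t * (p[j, ] - p[i, ]))
    }
  }
  out
}

# convex hull offset outward by d (miter joins via half-plane intersection)
buffered_hull <- function(pts, d) {
  h <- grDevices::chull(pts)          # clockwise order
  hp <- pts[rev(h), , drop = FALSE]   # counter-clockwise
  nh <- nrow(hp)
  span <- max(apply(pts, 2, function(v) diff(range(v)))) + 4 * d + 1
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  poly <- cbind(c(cx - span, cx + span, cx + span, cx - span),
                c(cy - span, cy - span, cy + span, cy + span))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    nrm <- c(e[2], -e[1])             # outward normal for CCW order
    nrm <- nrm / sqrt(sum(nrm^2))
    cc <- sum(nrm * hp[i, ]) + d
    poly <- clip_halfplane(poly, nrm[1], nrm[2], cc)
  }
  poly
}

#' @export
print.voronoi_map <- function(x, ...) {
  cat(sprintf("<voronoi_map> %d cells, hull area %.4g um^2\n",
              nrow(x$sites), x$hull_area_um2))
  invisible(x)
}

#' Render a tonotopic Voronoi map
#'
#' Draws the tessellation with AI cells colored by CF on a log scale,
#' unresponsive sites marked X and responsive non-AI sites marked O.
#'
#' @param vor A [voronoi_map()] object.
#' @param metrics Site-metrics tibble aligned with `vor$sites` (columns
#'   `responsive`, `in_ai`, `cf_hz`).
#' @return A ggplot object.
#' @export
map_figure <- function(vor, metrics) {
  stopifnot(inherits(vor, "voronoi_map"), nrow(metrics) == nrow(vor$sites))
  polys <- dplyr::bind_rows(lapply(seq_along(vor$cells), function(i) {
    p <- vor$cells[[i]]
    if (nrow(p) == 0) return(NULL)
    tibble::tibble(site_id = vor$sites$site_id[i], vx = p[, 1], vy = p[, 2])
  }))
  polys$cf_khz <- metrics$cf_hz[match(polys$site_id, vor$sites$site_id)] / 1000
  polys$in_ai <- metrics$in_ai[match(polys$site_id, vor$sites$site_id)]
  polys$cf_khz[!polys$in_ai] <- NA
  marks <- tibble::tibble(
    x = vor$sites$x_um, y = vor$sites$y_um,
    mark = dplyr::case_when(!metrics$responsive ~ "X",
                            !metrics$in_ai ~ "O",
                            TRUE ~ NA_character_))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = polys,
      ggplot2::aes(x = .data$vx, y = .data$vy, group = .data$site_id,
                   fill = .data$cf_khz),
      colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(trans = "log2", na.value = "white",
                                  name = "CF (kHz)") +
    ggplot2::geom_point(
      data = marks[!is.na(marks$mark) & marks$mark == "X", ],
      ggplot2::aes(x = .data$x, y = .data$y), shape = 4, size = 2) +
    ggplot2::geom_point(
      data = marks[!is.na(marks$mark) & marks$mark == "O", ],
      ggplot2::aes(x = .data$x, y = .data$y), shape = 1, size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "rostro-caudal (um)", y = "dorso-ventral (um)") +
    ggplot2::theme_minimal()
}
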
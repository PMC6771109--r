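#' Colour position on the atlas diverging scale
#'
#' The colour gradient is linear in the logarithm of the ratio-scale
#' estimate, anchored at 1.5 (darkest red, position 1), its inverse
#' 1/1.5 (approximately 0.67; darkest blue, position 0), and 1 (the
#' national average; yellow, position 0.5).  Estimates beyond the anchors
#' are clamped.  Log symmetry holds by construction:
#' `colour_position(v) + colour_position(1/v) = 1` inside the anchors.
#'
#' @param v ratio-scale estimate(s), > 0.
#' @param upper upper anchor (default 1.5); the lower anchor is `1/upper`.
#' @return position(s) in `[0, 1]`.
#' @export
colour_position <- function(v, upper = 1.5) {
  if (any(v <= 0)) stop("estimates must be positive")
  # (log v - log(1/upper)) / (log upper - log(1/upper)), written so the
  # midpoint v = 1 is exactly 0.5 in floating point
  pmin(pmax(0.5 + log(v) / (2 * log(upper)), 0), 1)
}

# default diverging stops, blue -> yellow -> red, usable under most forms
# of colour blindness (monochromatism excepted)
.atlas_stops <- c("#2C7BB6", "#ABD9E9", "#FFFFBF", "#FDAE61", "#D7191C")

#' Map estimates to atlas colours
#' @param v ratio-scale estimate(s).
#' @param stops hex colour stops, evenly spaced across positions 0..1.
#' @param upper upper colour anchor.
#' @return hex colours.
#' @export
atlas_colour <- function(v, stops = .atlas_stops, upper = 1.5) {
  pos <- colour_position(v, upper)
  ramp <- grDevices::colorRamp(stops, space = "Lab")
  grDevices::rgb(ramp(pos), maxColorValue = 255)
}

#' Opacity of the uncertainty (pale-yellow) mask
#'
#' Linear between the two defining endpoints: 0% opacity when the
#' difference in posterior probabilities is 1 (certain difference from the
#' average) and 100% when it is 0 (no evidence of difference), so highly
#' uncertain estimates fade into the average colour.
#'
#' @param dpp difference in posterior probabilities, in `[0, 1]`.
#' @return opacity percentage in `[0, 100]`.
#' @export
opacity_percent <- function(dpp) {
  if (any(dpp < 0 | dpp > 1)) stop("dpp must lie in [0, 1]")
  100 * (1 - dpp)
}

#' V-plot data
#'
#' One point per area: x the posterior median estimate (relative to the
#' national average of 1), y the DPP.  Areas near the top are likely to
#' reflect real differences; areas near the bottom are not.
#'
#' @param estimates data frame from [atlas_estimates()].
#' @return data frame with `area`, `estimate`, `dpp`.
#' @export
vplot_data <- function(estimates) {
  data.frame(area = estimates$area, estimate = estimates$point,
             dpp = estimates$dpp, stringsAsFactors = FALSE)
}

#' Wave-plot data for one area
#'
#' Kernel density estimate of the posterior on the log scale (Silverman
#' bandwidth), with tick positions at the logs of round ratio values and
#' the 60%/80% credible-interval bounds shared with [summarise_draws()].
#' Working on the log scale avoids the misleading areas-under-the-curve
#' that ratio-scale densities produce.
#'
#' @param draws ratio-scale posterior draws for one area (length >= 100).
#' @param ticks ratio-scale tick values to label.
#' @param n number of density grid points.
#' @return list with `x` (log-scale grid), `density`, `ticks` (data frame
#'   `value`, `at`), `cri60`, `cri80` (ratio scale).
#' @export
waveplot_data <- function(draws,
                          ticks = c(0.5, 0.67, 0.8, 1, 1.25, 1.5, 2),
                          n = 512) {
  if (length(draws) < 100) stop("need at least 100 draws")
  if (stats::var(draws) == 0) stop("degenerate draws")
  lx <- log(draws)
  dens <- density(lx, bw = "nrd0", n = n)
  s <- summarise_draws(draws)
  list(x = dens$x, density = dens$y,
       ticks = data.frame(value = ticks, at = log(ticks)),
       cri60 = s$cri60, cri80 = s$cri80)
}

#' Regional summaries of area estimates
#'
#' For display groupings (socioeconomic quintiles, remoteness, states,
#' capital cities — any labelled partition): the five-number summary of
#' point estimates per group and the percentage of areas falling in each
#' colour band of the diverging scale.
#'
#' @param estimates data frame from [atlas_estimates()].
#' @param grouping data frame with columns `area`, `group`; every area
#'   must be assigned to exactly one group.
#' @param band_breaks colour-position band edges (default quintile bands
#'   of the gradient).
#' @return list with `boxstats` (per-group five-number summaries) and
#'   `band_percent` (per-group percentage of areas per band; rows sum to
#'   100).
#' @export
region_summary <- function(estimates, grouping,
                           band_breaks = seq(0, 1, by = 0.2)) {
  m <- match(estimates$area, grouping$area)
  if (anyNA(m)) stop("unassigned areas: ",
                     paste(estimates$area[is.na(m)], collapse = ", "))
  if (anyDuplicated(grouping$area)) stop("areas assigned to multiple groups")
  grp <- as.character(grouping$group[m])
  fv <- t(vapply(split(estimates$point, grp), fivenum, numeric(5)))
  colnames(fv) <- c("min", "q1", "median", "q3", "max")
  boxstats <- data.frame(group = rownames(fv), fv, row.names = NULL)
  pos <- colour_position(estimates$point)
  band <- cut(pos, band_breaks, include.lowest = TRUE)
  bp <- 100 * prop.table(table(group = grp, band = band), margin = 1)
  list(boxstats = boxstats, band_percent = bp)
}

#' Attach atlas style properties and write GeoJSON
#'
#' Emits a GeoJSON FeatureCollection whose per-area properties carry
#' exactly what the map layers need: the estimate, its colour position and
#' colour, and the uncertainty-mask opacity.
#'
#' @param estimates data frame from [atlas_estimates()].
#' @param polygons named list of polygons (as in [build_adjacency()]),
#'   one per area.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
encode_geojson <- function(estimates, polygons, path) {
  feats <- lapply(seq_len(nrow(estimates)), function(i) {
    id <- estimates$area[i]
    poly <- polygons[[id]]
    if (is.null(poly)) stop("no polygon for area ", id)
    rings <- lapply(.poly_rings(poly), function(r) {
      lapply(seq_len(nrow(r)), function(k) as.numeric(r[k, ]))
    })
    list(type = "Feature",
         properties = list(area = id,
                           estimate = estimates$point[i],
                           dpp = estimates$dpp[i],
                           colour_position = colour_position(estimates$point[i]),
                           colour = atlas_colour(estimates$point[i]),
                           opacity = opacity_percent(estimates$dpp[i])),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Unit-square lattice polygons for a synthetic geography
#'
#' Polygons matching [generate_lattice_geography()] centroids, for map
#' encoding of synthetic runs.
#'
#' @param graph an [area_graph] from [generate_lattice_geography()].
#' @return named list of single-ring polygons.
#' @export
lattice_polygons <- function(graph) {
  out <- lapply(seq_along(graph$area_ids), function(i) {
    cx <- graph$centroids[i, 1]; cy <- graph$centroids[i, 2]
    rbind(c(cx - 0.5, cy - 0.5), c(cx + 0.5, cy - 0.5),
          c(cx + 0.5, cy + 0.5), c(cx - 0.5, cy + 0.5),
          c(cx - 0.5, cy - 0.5))
  })
  names(out) <- graph$area_ids
  out
}
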
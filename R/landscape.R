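#' Configuration for the procedural archipelago landscape
#'
#' Builds the parameter set for [generate_landscape()]. The defaults describe
#' the full-scale study system: a 120 x 208 km grid (1 site = 1 x 1 km^2)
#' holding four islands whose central points are laid out as a rhombus with
#' equal lateral spacing, simulated over 5 Myr in 10-kyr steps. Islands A, B
#' and C are static Gaussian cones on a flat seafloor; island D uplifts in
#' discrete pulses from `d_emergence_ma` onwards. A shallow ridge between A
#' and B forms a land bridge whenever the sea level drops below
#' `bridge_saddle_m`. Sea level oscillates with a 100-kyr period whose
#' amplitude intensifies in the Quaternary; site temperatures follow the sea
#' level (warm highstands, cold lowstands) and a lapse rate, and are
#' calibrated so that the minimum and maximum temperatures over all suitable
#' sites and time steps equal `temp_range` exactly.
#'
#' @param grid integer vector `c(nx, ny)`, landscape extent in km.
#' @param n_steps number of time steps (default 501; 1 step = 10 kyr).
#' @param start_ma age of the first step in Ma; the last step is 0 Ma.
#' @param island_target_sites suitable sites per island at 0-Ma sea level.
#' @param peak_elevations_m named vector of summit elevations for islands
#'   A-D (m, relative to 0-Ma sea level). The maximum fixes the highest
#'   rendered elevation.
#' @param seafloor_m flat seafloor elevation (m); the lowest rendered point.
#' @param bridge_saddle_m crest elevation of the A-B ridge (m); the bridge
#'   is exposed exactly when the sea level is below this value.
#' @param bridge_width_km lateral Gaussian half-width of the ridge.
#' @param crest_length_km open crest length of the exposed bridge at the
#'   glacial lowstand; fixes the A-B spacing.
#' @param channel_width_km open-water gap between the bridge corridor and
#'   islands C/D at the glacial lowstand; fixes the lateral spacing.
#' @param d_emergence_ma age at which island D starts to uplift.
#' @param d_uplift_pulses number of discrete uplift pulses for island D.
#' @param lapse_rate_c_km decrease of mean temperature with elevation
#'   (degrees C per km).
#' @param sea_amp_pre_m,sea_amp_quat_m sea-level oscillation amplitudes (m)
#'   before and after the Quaternary transition.
#' @param sea_period_kyr oscillation period (kyr).
#' @param quaternary_ma age of the amplitude transition.
#' @param ramp_myr width of the smooth amplitude ramp around the transition.
#' @param temp_range_c target span of suitable-site temperatures (degrees C).
#' @param trange_max_c maximum Tmax - Tmin spread (degrees C), reached at the
#'   highest summit.
#' @param unsuitable_cost,suitable_cost landscape resistance per km for
#'   ocean and land steps.
#' @param slope_cost_per_100m additional resistance per 100 m of elevation
#'   difference between adjacent suitable sites.
#' @param rng_seed seed recorded with the configuration. The generator is
#'   fully deterministic, so regeneration is always bit-identical.
#' @param file optional YAML file of key-value pairs overriding the above.
#' @param ... further overrides applied after `file`.
#' @return A list of class `isle_landscape_config`.
#' @export
landscape_config <- function(grid = c(120L, 208L),
                             n_steps = 501L,
                             start_ma = 5,
                             island_target_sites = 250L,
                             peak_elevations_m = c(A = 803, B = 720, C = 650, D = 600),
                             seafloor_m = -115,
                             bridge_saddle_m = -65,
                             bridge_width_km = 1,
                             crest_length_km = 150,
                             channel_width_km = 20,
                             d_emergence_ma = 1.5,
                             d_uplift_pulses = 6L,
                             lapse_rate_c_km = 5.5,
                             sea_amp_pre_m = 50,
                             sea_amp_quat_m = 100,
                             sea_period_kyr = 100,
                             quaternary_ma = 2.6,
                             ramp_myr = 0.4,
                             temp_range_c = c(9, 26),
                             trange_max_c = 5,
                             unsuitable_cost = 4,
                             suitable_cost = 1,
                             slope_cost_per_100m = 0.1,
                             rng_seed = 1L,
                             file = NULL,
                             ...) {
  cfg <- as.list(environment())
  cfg$file <- NULL
  if (!is.null(file)) {
    overrides <- yaml::read_yaml(file)
    cfg[names(overrides)] <- overrides
  }
  dots <- list(...)
  cfg[names(dots)] <- dots

  cfg$grid <- as.integer(cfg$grid)
  cfg$n_steps <- as.integer(cfg$n_steps)
  stopifnot(
    length(cfg$grid) == 2, all(cfg$grid >= 20),
    cfg$n_steps >= 2,
    cfg$trange_max_c > 0,
    cfg$sea_amp_quat_m > cfg$sea_amp_pre_m,
    cfg$seafloor_m < cfg$bridge_saddle_m,
    cfg$bridge_saddle_m < 0,
    cfg$bridge_saddle_m > -cfg$sea_amp_quat_m,
    cfg$temp_range_c[1] < cfg$temp_range_c[2],
    all(cfg$peak_elevations_m > 0),
    cfg$island_target_sites >= 4
  )
  if (is.null(names(cfg$peak_elevations_m))) {
    names(cfg$peak_elevations_m) <- c("A", "B", "C", "D")
  }
  class(cfg) <- "isle_landscape_config"
  cfg
}

#' Scaled-down landscape preset
#'
#' A smaller configuration used for desk-scale experiments: a 78 x 186 km
#' grid, 80 suitable sites per island, and 251 time steps covering the last
#' 2.5 Myr. Island geometry (bridge crest, channel widths) is unchanged in
#' kilometres, so dispersal-cost physics match the full-scale landscape.
#'
#' @param grid,n_steps,start_ma,island_target_sites scaled-down defaults,
#'   overridable.
#' @param ... further overrides forwarded to [landscape_config()].
#' @export
desk_landscape_config <- function(grid = c(78L, 186L), n_steps = 251L,
                                  start_ma = 2.5, island_target_sites = 80L,
                                  ...) {
  landscape_config(grid = grid, n_steps = n_steps, start_ma = start_ma,
                   island_target_sites = island_target_sites, ...)
}

# ---- sea level and climate forcing -----------------------------------------

#' Sea level relative to 0 Ma
#'
#' Periodic lowstand-biased oscillation: `-A(t) * (1 - cos(2 pi t / P)) / 2`,
#' zero at every 100-kyr cycle top (and at 0 Ma), dropping to `-A(t)` at the
#' glacial maximum. The amplitude `A(t)` ramps smoothly from the
#' pre-Quaternary to the larger Quaternary value around `quaternary_ma`.
#'
#' @param landscape an `isle_landscape`, or an `isle_landscape_config`.
#' @param steps time steps (1-based); default all steps.
#' @return numeric vector of sea levels (m).
#' @export
sea_level <- function(landscape, steps = NULL) {
  cfg <- if (inherits(landscape, "isle_landscape")) landscape$config else landscape
  if (is.null(steps)) steps <- seq_len(cfg$n_steps)
  sea_level_at(step_time_ma(cfg, steps), cfg)
}

step_time_ma <- function(cfg, steps) cfg$start_ma - (steps - 1) * 0.01

sea_amplitude_at <- function(t_ma, cfg) {
  w <- cfg$ramp_myr
  frac <- pmin(1, pmax(0, (cfg$quaternary_ma + w / 2 - t_ma) / w))
  smooth <- frac^2 * (3 - 2 * frac)
  cfg$sea_amp_pre_m + (cfg$sea_amp_quat_m - cfg$sea_amp_pre_m) * smooth
}

sea_level_at <- function(t_ma, cfg) {
  period_myr <- cfg$sea_period_kyr / 1000
  phase <- 2 * pi * t_ma / period_myr
  -sea_amplitude_at(t_ma, cfg) * (1 - cos(phase)) / 2
}

d_uplift_at <- function(t_ma, cfg) {
  raw <- (cfg$d_emergence_ma - t_ma) / cfg$d_emergence_ma
  pulses <- ceiling(pmax(0, raw) * cfg$d_uplift_pulses)
  pmin(1, pulses / cfg$d_uplift_pulses)
}

# ---- topography -------------------------------------------------------------

# squared distance of every cell centre to a point (km^2)
cell_dist2 <- function(nx, ny, cx, cy) {
  dx2 <- (seq_len(nx) - cx)^2
  dy2 <- (seq_len(ny) - cy)^2
  outer(dx2, dy2, `+`)
}

# Gaussian cone elevation field. sigma is calibrated elsewhere so that the
# cone holds a target number of cells above 0-Ma sea level.
cone_field <- function(d2, peak, floor, sigma) {
  floor + (peak - floor) * exp(-d2 / (2 * sigma^2))
}

# choose sigma so that the count of cells strictly above 0 m is as close as
# possible to `target` (exact up to ties in lattice distances)
calibrate_sigma <- function(d2, peak, floor, target) {
  ds <- sort(d2[d2 < (sqrt(target) * 4)^2])
  if (length(ds) <= target) stop("island does not fit in the grid", call. = FALSE)
  vals <- unique(ds)
  counts <- cumsum(tabulate(match(ds, vals)))  # cells with d2 <= vals[i]
  best <- which.min(abs(counts - target))
  upper <- if (best < length(vals)) vals[best + 1] else vals[best] + 1
  r2 <- (vals[best] + upper) / 2
  sqrt(r2 / (2 * log((peak - floor) / (0 - floor))))
}

# island radius (km) at a given water level
cone_radius <- function(sigma, peak, floor, level) {
  sigma * sqrt(2 * log((peak - floor) / (level - floor)))
}

island_centres <- function(cfg) {
  r0 <- sqrt(cfg$island_target_sites / pi)
  floor <- cfg$seafloor_m
  low <- -cfg$sea_amp_quat_m
  # sigma ~ r0 / sqrt(2 log((peak - floor) / -floor)); radius at the glacial
  # lowstand scales the 0-Ma radius accordingly
  r_low <- vapply(c("A", "B", "C", "D"), function(i) {
    sigma <- r0 / sqrt(2 * log((cfg$peak_elevations_m[[i]] - floor) / -floor))
    cone_radius(sigma, cfg$peak_elevations_m[[i]], floor, low)
  }, numeric(1))

  ab <- 2 * round((cfg$crest_length_km + r_low[["A"]] + r_low[["B"]]) / 2)
  lat <- round(2 + cfg$channel_width_km + max(r_low[["C"]], r_low[["D"]]))

  x0 <- round(cfg$grid[1] / 2)
  y0 <- round(cfg$grid[2] / 2)
  centres <- rbind(
    A = c(x0, y0 - ab / 2),
    B = c(x0, y0 + ab / 2),
    C = c(x0 - lat, y0),
    D = c(x0 + lat, y0)
  )
  colnames(centres) <- c("x", "y")
  margin <- ceiling(max(r_low)) + 1
  if (centres["A", "y"] - margin < 1 || centres["B", "y"] + margin > cfg$grid[2] ||
      centres["C", "x"] - margin < 1 || centres["D", "x"] + margin > cfg$grid[1]) {
    stop("grid too small for the configured island geometry", call. = FALSE)
  }
  centres
}

build_topography <- function(cfg) {
  nx <- cfg$grid[1]
  ny <- cfg$grid[2]
  floor <- cfg$seafloor_m
  centres <- island_centres(cfg)

  d2 <- lapply(rownames(centres), function(i) {
    cell_dist2(nx, ny, centres[i, "x"], centres[i, "y"])
  })
  names(d2) <- rownames(centres)

  sigmas <- vapply(rownames(centres), function(i) {
    calibrate_sigma(d2[[i]], cfg$peak_elevations_m[[i]], floor, cfg$island_target_sites)
  }, numeric(1))

  cones <- lapply(rownames(centres), function(i) {
    cone_field(d2[[i]], cfg$peak_elevations_m[[i]], floor, sigmas[[i]])
  })
  names(cones) <- rownames(centres)

  # A-B ridge: flat crest at the saddle elevation with lateral Gaussian flanks
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  x0 <- centres["A", "x"]
  in_corridor <- ys >= centres["A", "y"] & ys <= centres["B", "y"]
  ridge <- floor + (cfg$bridge_saddle_m - floor) *
    exp(-(xs - x0)^2 / (2 * cfg$bridge_width_km^2)) * in_corridor
  ridge[!in_corridor] <- floor

  base <- pmax(cones$A, cones$B, cones$C, ridge)
  list(
    centres = centres, sigmas = sigmas,
    base = base,          # static topography: islands A-C plus ridge
    cone_d = cones$D,     # island D at full uplift
    island_map = terrain_island_map(cones, ridge, ys, centres, floor)
  )
}

# attribute each cell to the island whose terrain dominates there; ridge
# cells (the A-B land bridge) go to the nearer of A and B
terrain_island_map <- function(cones, ridge, ys, centres, floor) {
  fields <- cbind(c(cones$A), c(cones$B), c(cones$C), c(cones$D))
  nm <- c("A", "B", "C", "D")
  map <- nm[max.col(fields, ties.method = "first")]
  ridge_dominant <- c(ridge) > apply(fields, 1, max)
  mid_y <- (centres["A", "y"] + centres["B", "y"]) / 2
  map[ridge_dominant] <- ifelse(c(ys)[ridge_dominant] <= mid_y, "A", "B")
  matrix(map, nrow(ridge), ncol(ridge))
}

# ---- generation -------------------------------------------------------------

#' Generate the dynamic archipelago landscape
#'
#' Builds the full time-indexed landscape: static topography for islands A-C
#' and the A-B ridge, pulsed uplift for island D, the sea-level series, and
#' temperature anchors calibrated so that, over all suitable sites and time
#' steps, minimum and maximum temperature hit `temp_range_c` exactly.
#'
#' @param config an [landscape_config()] object (default: full-scale).
#' @return An object of class `isle_landscape`. Per-step grids are derived
#'   on demand via [elevation_grid()], [suitability()],
#'   [site_temperatures()], [island_labels()] and [cost_matrix()];
#'   least-cost matrices are cached per distinct geometry.
#' @export
generate_landscape <- function(config = landscape_config()) {
  cfg <- config
  topo <- build_topography(cfg)

  steps <- seq_len(cfg$n_steps)
  t_ma <- step_time_ma(cfg, steps)
  sea <- sea_level_at(t_ma, cfg)
  uplift <- d_uplift_at(t_ma, cfg)
  lambda <- pmin(1, pmax(0, -sea / cfg$sea_amp_quat_m))

  anchors <- calibrate_temperature(cfg, topo, sea, uplift, lambda)

  manifest <- tibble::tibble(
    step = steps,
    time_ma = t_ma,
    sea_level = sea,
    d_uplift = uplift,
    t_sea = anchors$warm - lambda * (anchors$warm - anchors$cold)
  )

  structure(
    list(
      config = cfg,
      topo = topo,
      manifest = manifest,
      anchors = anchors,
      cache = new.env(parent = emptyenv())
    ),
    class = "isle_landscape"
  )
}

#' @export
print.isle_landscape <- function(x, ...) {
  cfg <- x$config
  cat("<isle_landscape> ", cfg$grid[1], "x", cfg$grid[2], " km, ",
      cfg$n_steps, " steps (", cfg$start_ma, " -> 0 Ma)\n", sep = "")
  cat("  islands A-D at", cfg$island_target_sites, "target sites;",
      "temperatures", cfg$temp_range_c[1], "-", cfg$temp_range_c[2], "C\n")
  invisible(x)
}

elevation_for <- function(landscape, uplift) {
  base <- landscape$topo$base
  if (uplift <= 0) return(base)
  floor <- landscape$config$seafloor_m
  pmax(base, floor + uplift * (landscape$topo$cone_d - floor))
}

#' Elevation grid at one time step
#'
#' @param landscape an `isle_landscape`.
#' @param step time step (1-based).
#' @return matrix of elevations (m relative to 0-Ma sea level).
#' @export
elevation_grid <- function(landscape, step) {
  elevation_for(landscape, landscape$manifest$d_uplift[step])
}

#' Suitability mask at one time step
#'
#' A site is suitable exactly when its elevation exceeds the current sea
#' level.
#'
#' @inheritParams elevation_grid
#' @return logical matrix.
#' @export
suitability <- function(landscape, step) {
  elevation_grid(landscape, step) > landscape$manifest$sea_level[step]
}

#' Minimum and maximum site temperatures at one time step
#'
#' Mean temperature decreases with altitude above the current sea level at
#' the configured lapse rate; the diurnal/seasonal spread `Tmax - Tmin`
#' grows linearly with elevation from zero at sea level (0-Ma datum) up to
#' `trange_max_c` at the highest summit.
#'
#' @inheritParams elevation_grid
#' @param elevation optional elevation grid overriding the landscape's own
#'   (must match the grid extent).
#' @return list with matrices `tmin` and `tmax` (degrees C).
#' @export
site_temperatures <- function(landscape, step, elevation = NULL) {
  cfg <- landscape$config
  man <- landscape$manifest
  if (is.null(elevation)) elevation <- elevation_grid(landscape, step)
  alt <- elevation - man$sea_level[step]
  tmean <- man$t_sea[step] - cfg$lapse_rate_c_km * alt / 1000
  spread <- trange_spread(cfg, elevation)
  list(tmin = tmean - spread / 2, tmax = tmean + spread / 2)
}

trange_spread <- function(cfg, elevation) {
  peak <- max(cfg$peak_elevations_m)
  cfg$trange_max_c * pmin(pmax(elevation, 0), peak) / peak
}

#' Map temperatures in degrees C to the normalized trait scale
#'
#' The thermal-trait scale maps the overall temperature span onto `[0, 1]`,
#' with 1 the warmest available temperature.
#'
#' @param x temperatures (degrees C).
#' @param range overall span, default `c(9, 26)`.
#' @export
norm_temperature <- function(x, range = c(9, 26)) {
  (x - range[1]) / (range[2] - range[1])
}

# Two-parameter affine calibration of the warm/cold sea-level temperature
# anchors. Extremes over (site, step) are piecewise linear in the anchors,
# so a short fixed-point iteration lands on the targets exactly.
calibrate_temperature <- function(cfg, topo, sea, uplift, lambda) {
  lo <- cfg$temp_range_c[1]
  hi <- cfg$temp_range_c[2]
  peak <- max(cfg$peak_elevations_m)
  warm <- hi
  cold <- lo + cfg$lapse_rate_c_km * (peak + cfg$sea_amp_quat_m) / 1000 +
    cfg$trange_max_c / 2

  geom <- unique(data.frame(sea = sea, uplift = uplift, lambda = lambda))
  landscape_stub <- list(config = cfg, topo = topo)

  for (iter in 1:12) {
    mn <- Inf
    mx <- -Inf
    for (g in seq_len(nrow(geom))) {
      elev <- elevation_for(landscape_stub, geom$uplift[g])
      suit <- elev > geom$sea[g]
      if (!any(suit)) next
      e <- elev[suit]
      alt <- e - geom$sea[g]
      t_sea <- warm - geom$lambda[g] * (warm - cold)
      tmean <- t_sea - cfg$lapse_rate_c_km * alt / 1000
      spread <- cfg$trange_max_c * pmin(pmax(e, 0), peak) / peak
      mn <- min(mn, min(tmean - spread / 2))
      mx <- max(mx, max(tmean + spread / 2))
    }
    if (!is.finite(mn) || !is.finite(mx)) {
      stop("temperature calibration failed: no suitable sites", call. = FALSE)
    }
    if (abs(mx - hi) < 1e-9 && abs(mn - lo) < 1e-9) {
      if (warm <= cold) {
        stop("temperature calibration failed: cannot span the target range",
             call. = FALSE)
      }
      return(list(warm = warm, cold = cold))
    }
    warm <- warm + (hi - mx)
    cold <- cold + (lo - mn)
  }
  stop("temperature calibration failed: iteration did not converge", call. = FALSE)
}

# ---- island labelling -------------------------------------------------------

#' Label islands as connected components of the suitability mask
#'
#' @inheritParams elevation_grid
#' @return integer matrix: component id (1-based) for suitable cells, NA for
#'   ocean. Components use 8-neighbour connectivity.
#' @export
island_labels <- function(landscape, step) {
  suit <- suitability(landscape, step)
  label_components(suit)
}

label_components <- function(suit) {
  nx <- nrow(suit)
  ny <- ncol(suit)
  ids <- which(suit)
  lab <- matrix(NA_integer_, nx, ny)
  if (length(ids) == 0) return(lab)
  adj <- grid_adjacency(nx, ny)
  keep <- suit[adj$from] & suit[adj$to]
  g <- igraph::graph_from_edgelist(
    cbind(match(adj$from[keep], ids), match(adj$to[keep], ids)),
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0, length(ids) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[ids] <- as.integer(comp)
  lab
}

#' Number of islands at one time step
#'
#' @inheritParams elevation_grid
#' @export
n_islands <- function(landscape, step) {
  lab <- island_labels(landscape, step)
  length(unique(lab[!is.na(lab)]))
}

#' Static island assignment
#'
#' Assigns every cell to the nearest island centre (A-D); used to attribute
#' populations and events to islands irrespective of transient land bridges.
#'
#' @param landscape an `isle_landscape`.
#' @return character matrix of island names.
#' @export
island_assignment <- function(landscape) landscape$topo$island_map

# ---- resistance and least-cost distances ------------------------------------

# 8-neighbour adjacency of an nx x ny grid: from < to, with step lengths
grid_adjacency <- function(nx, ny) {
  idx <- matrix(seq_len(nx * ny), nx, ny)
  right <- cbind(c(idx[-nx, ]), c(idx[-1, ]))
  up <- cbind(c(idx[, -ny]), c(idx[, -1]))
  diag1 <- cbind(c(idx[-nx, -ny]), c(idx[-1, -1]))
  diag2 <- cbind(c(idx[-1, -ny]), c(idx[-nx, -1]))
  list(
    from = c(right[, 1], up[, 1], diag1[, 1], diag2[, 1]),
    to = c(right[, 2], up[, 2], diag1[, 2], diag2[, 2]),
    len = c(rep(1, nrow(right) + nrow(up)), rep(sqrt(2), nrow(diag1) + nrow(diag2)))
  )
}

#' Landscape-resistance edge costs
#'
#' The cost of moving between two adjacent sites: `suitable_cost` per km
#' between suitable sites, plus `slope_cost_per_100m` per 100 m of elevation
#' difference between source and destination; `unsuitable_cost` per km when
#' either end is unsuitable (ocean matrix). Diagonal steps are sqrt(2) km.
#'
#' @param elevation elevation matrix (m).
#' @param suitable logical matrix of the same extent.
#' @param unsuitable_cost,suitable_cost,slope_cost_per_100m cost parameters.
#' @return tibble with columns `from`, `to` (cell indices), `len` and `cost`.
#' @export
edge_costs <- function(elevation, suitable,
                       unsuitable_cost = 4, suitable_cost = 1,
                       slope_cost_per_100m = 0.1) {
  adj <- grid_adjacency(nrow(elevation), ncol(elevation))
  land <- suitable[adj$from] & suitable[adj$to]
  cost <- ifelse(
    land,
    suitable_cost * adj$len +
      slope_cost_per_100m * abs(elevation[adj$from] - elevation[adj$to]) / 100,
    unsuitable_cost * adj$len
  )
  tibble::tibble(from = adj$from, to = adj$to, len = adj$len, cost = cost)
}

#' Per-site resistance surface
#'
#' @inheritParams elevation_grid
#' @return matrix holding the per-km resistance of each site
#'   (`suitable_cost` on land, `unsuitable_cost` on ocean).
#' @export
resistance_surface <- function(landscape, step) {
  cfg <- landscape$config
  suit <- suitability(landscape, step)
  out <- matrix(cfg$unsuitable_cost, nrow(suit), ncol(suit))
  out[suit] <- cfg$suitable_cost
  out
}

#' Least-cost distances between sites
#'
#' Minimal accumulated resistance cost over 8-neighbour paths, computed with
#' Dijkstra's algorithm on the weighted adjacency graph.
#'
#' @param elevation elevation matrix (m).
#' @param suitable logical matrix.
#' @param sites cell indices between which distances are required; default
#'   all suitable cells.
#' @inheritParams edge_costs
#' @return symmetric matrix of least-cost distances; `Inf` for unreachable
#'   pairs; row/column names are the cell indices.
#' @export
least_cost_distances <- function(elevation, suitable, sites = NULL,
                                 unsuitable_cost = 4, suitable_cost = 1,
                                 slope_cost_per_100m = 0.1) {
  ec <- edge_costs(elevation, suitable, unsuitable_cost, suitable_cost,
                   slope_cost_per_100m)
  if (is.null(sites)) sites <- which(suitable)
  g <- igraph::make_empty_graph(n = length(elevation), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ec$from, ec$to))
  d <- igraph::distances(g, v = sites, to = sites, weights = ec$cost,
                         algorithm = "dijkstra")
  dimnames(d) <- list(sites, sites)
  d
}

#' Cached least-cost matrix for one landscape step
#'
#' Geometry repeats across time steps (sea-level phases times uplift
#' pulses), so matrices are cached per distinct geometry and shared by every
#' simulation run on the same landscape object.
#'
#' @inheritParams elevation_grid
#' @return list with `sites` (suitable cell indices) and `cost` (matrix).
#' @export
cost_matrix <- function(landscape, step) {
  man <- landscape$manifest
  key <- sprintf("g_%.6f_%.6f", man$sea_level[step], man$d_uplift[step])
  hit <- landscape$cache[[key]]
  if (!is.null(hit)) return(hit)
  cfg <- landscape$config
  elev <- elevation_grid(landscape, step)
  suit <- elev > man$sea_level[step]
  sites <- which(suit)
  d <- least_cost_distances(elev, suit, sites,
                            cfg$unsuitable_cost, cfg$suitable_cost,
                            cfg$slope_cost_per_100m)
  out <- list(sites = sites, cost = d)
  assign(key, out, envir = landscape$cache)
  out
}

# ---- summaries and export ---------------------------------------------------

#' Per-step landscape summary
#'
#' @param landscape an `isle_landscape`.
#' @return tibble with one row per step: time, sea level, uplift, number of
#'   islands (connected components), suitable-site counts per island (by
#'   nearest centre) and mean suitable-site temperature.
#' @export
landscape_summary <- function(landscape) {
  man <- landscape$manifest
  imap <- landscape$topo$island_map
  geom_key <- paste(man$sea_level, man$d_uplift)
  uniq <- !duplicated(geom_key)
  per_geom <- lapply(which(uniq), function(s) {
    elev <- elevation_grid(landscape, s)
    suit <- elev > man$sea_level[s]
    temps <- site_temperatures(landscape, s, elev)
    counts <- table(factor(imap[suit], levels = c("A", "B", "C", "D")))
    list(
      n_islands = n_islands(landscape, s),
      counts = as.integer(counts),
      mean_temp = mean((temps$tmin[suit] + temps$tmax[suit]) / 2)
    )
  })
  names(per_geom) <- geom_key[uniq]
  rows <- per_geom[geom_key]
  dplyr::bind_cols(
    man,
    tibble::tibble(
      n_islands = vapply(rows, `[[`, integer(1), "n_islands"),
      sites_a = vapply(rows, function(r) r$counts[1], integer(1)),
      sites_b = vapply(rows, function(r) r$counts[2], integer(1)),
      sites_c = vapply(rows, function(r) r$counts[3], integer(1)),
      sites_d = vapply(rows, function(r) r$counts[4], integer(1)),
      mean_suitable_temp = vapply(rows, `[[`, numeric(1), "mean_temp")
    )
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname landscape_summary
#' @param x an `isle_landscape`.
#' @param ... unused.
#' @method tidy isle_landscape
#' @export
tidy.isle_landscape <- function(x, ...) landscape_summary(x)

#' Write landscape grids and manifest to disk
#'
#' Writes per-step tab-delimited grids (elevation, tmin, tmax, suitability,
#' island label) and a CSV manifest.
#'
#' @param landscape an `isle_landscape`.
#' @param dir output directory (created if needed).
#' @param steps steps to export; default all.
#' @export
write_landscape <- function(landscape, dir, steps = NULL) {
  if (is.null(steps)) steps <- seq_len(landscape$config$n_steps)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in steps) {
    elev <- elevation_grid(landscape, s)
    temps <- site_temperatures(landscape, s, elev)
    grids <- list(
      elevation = elev, tmin = temps$tmin, tmax = temps$tmax,
      suitability = suitability(landscape, s) * 1L,
      island = island_labels(landscape, s)
    )
    for (nm in names(grids)) {
      utils::write.table(
        grids[[nm]],
        file.path(dir, sprintf("%s_step%04d.tsv", nm, s)),
        sep = "\t", row.names = FALSE, col.names = FALSE
      )
    }
  }
  utils::write.csv(landscape_summary(landscape),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
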
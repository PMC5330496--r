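## Synthetic nested-transect generator. Emulates a 10-location sandplain
## transect: ~870 km end-to-end, adjacent location spacings 45-265 km
## (mean 109) along a gently bent path, four 1-ha sites per location at
## cumulative offsets 0/1.5/4.5/10.5 km, four 20x20 m quadrats at the
## corners of each 100 m square (160 quadrats), a south->north
## per-quadrat richness gradient (~61 -> ~14), replacement-dominated
## local turnover (16-quadrat multiple-site Sorensen ~0.84), ~23%
## singleton taxa, climate varying smoothly with latitude and soil
## varying locally.
##
## Community model: each species has a 1-D range envelope along the
## transect axis (plateau with logistic shoulders) and a lottery
## occupancy - a single per-species Bernoulli thinning, constant within
## location. "Core" species have the occupancy solved in closed form from
## the iid multiple-site expectation so the 16-quadrat beta_SOR hits its
## target; a "rare" class with low occupancy and narrower ranges supplies
## the singleton tail. Per-location availability is thinned (nested,
## per-species uniform scores) so expected quadrat richness follows the
## gradient without disturbing the occupancy that sets beta.

KM_PER_DEG_LAT <- 111.19508   # pi * 6371.0088 / 180

#' Configuration of a synthetic transect scenario
#'
#' Defaults reproduce the nested design and statistical structure the
#' package's analyses assume; see the package vignette for the rationale
#' behind each value. All downstream generators are pure functions of
#' (config, seed).
#'
#' @param n_locations number of locations along the transect.
#' @param adjacent_spacing_km along-path distances between adjacent
#'   locations; default nine spacings in 45-265 km with mean 109.
#' @param zigzag_deg alternating deviation of the path bearing from due
#'   north; the default bends the 981 km path so its end-to-end
#'   great-circle extent is ~870 km.
#' @param site_offsets_km cumulative eastward site positions within a
#'   location (consecutive gaps 1.5, 3 and 6 km).
#' @param quadrat_square_m side of the square whose corners hold the four
#'   quadrats of a site.
#' @param origin_lon,origin_lat coordinates of the southern end.
#' @param richness_south,richness_north target mean quadrat richness at
#'   the two ends of the transect.
#' @param pool_size total species pool.
#' @param rare_fraction fraction of the pool in the rare class.
#' @param p_rare per-quadrat occupancy of rare species.
#' @param core_width_km,core_width_sdlog median and log-sd of the
#'   lognormal core range-width distribution (km).
#' @param rare_width_km,rare_width_sdlog same for the rare class.
#' @param shoulder_km softness of the range-envelope shoulders.
#' @param beta_sor_target 16-quadrat multiple-site Sorensen dissimilarity
#'   the core occupancy is calibrated to.
#' @param singleton_target intended fraction of recorded taxa occurring
#'   in exactly one quadrat (reached through the rare-class defaults, not
#'   enforced).
#' @param turnover_mode \code{"replacement"} (lottery + range turnover;
#'   the default), \code{"nested"} (deterministic south->north dropout,
#'   no lottery), \code{"distance_only"} (replacement with environmental
#'   effects forced off), \code{"env_filtered"} (adds a soil filter) or
#'   \code{"mixed"} (alias of env_filtered with a weaker filter).
#' @param env_filter_var soil column filtering occupancy in env_filtered
#'   mode.
#' @param env_filter_sd niche breadth of the soil filter (in the soil
#'   variable's units); smaller = stronger filtering.
#' @param climate_noise_sd relative noise of the climate columns around
#'   their latitudinal trend.
#' @param arid_range_multiplier factor widening occurrence scatter for
#'   species centred in the arid (northern two locations) zone.
#' @return A list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_locations = 10L,
                            adjacent_spacing_km = c(45, 70, 265, 95, 120,
                                                    85, 110, 126, 65),
                            zigzag_deg = 27.5,
                            site_offsets_km = c(0, 1.5, 4.5, 10.5),
                            quadrat_square_m = 100,
                            origin_lon = 119.0, origin_lat = -34.3,
                            richness_south = 61, richness_north = 14,
                            pool_size = 750L,
                            rare_fraction = 0.5,
                            p_rare = 0.04,
                            core_width_km = 700, core_width_sdlog = 0.4,
                            rare_width_km = 60, rare_width_sdlog = 1,
                            shoulder_km = 20,
                            beta_sor_target = 0.84,
                            singleton_target = 0.23,
                            turnover_mode = c("replacement", "nested",
                                              "distance_only",
                                              "env_filtered", "mixed"),
                            env_filter_var = "pH",
                            env_filter_sd = 0.6,
                            climate_noise_sd = 0.02,
                            arid_range_multiplier = 2) {
  turnover_mode <- match.arg(turnover_mode)
  if (length(adjacent_spacing_km) != n_locations - 1L)
    stop("need ", n_locations - 1L, " adjacent spacings")
  if (any(adjacent_spacing_km <= 0) || pool_size < 1L)
    stop("spacings and pool size must be positive")
  if (p_rare <= 0 || p_rare >= 1 || rare_fraction < 0 || rare_fraction > 1)
    stop("probabilities must lie in (0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  expr
}

#' Occupancy that yields a target multiple-site Sorensen value
#'
#' Under iid per-quadrat occupancy p over a shared pool, the expected
#' multiple-site Sorensen dissimilarity of n quadrats is
#' \deqn{\beta(p) = \frac{\binom{n}{2} p(1-p)}
#'   {\binom{n}{2} p(1-p) + np - 1 + (1-p)^n}}
#' (the pool size cancels). This solves \eqn{\beta(p) = } target for p on
#' the decreasing branch \eqn{p \in (1/n, 1)}.
#'
#' @param n quadrats per location.
#' @param target multiple-site Sorensen dissimilarity.
#' @return Occupancy probability p.
#' @export
calibrate_occupancy <- function(n, target) {
  beta_of_p <- function(p) {
    a <- choose(n, 2) * p * (1 - p)
    a / (a + n * p - 1 + (1 - p)^n)
  }
  if (target >= beta_of_p(1 / n + 1e-6) || target <= beta_of_p(1 - 1e-9))
    stop("beta target ", target, " not attainable with ", n, " quadrats")
  stats::uniroot(function(p) beta_of_p(p) - target,
                 c(1 / n + 1e-6, 1 - 1e-9), tol = 1e-10)$root
}

#' Generate the nested spatial design
#'
#' Lays the locations along a gently zig-zagging south-to-north path
#' (alternating bearing deviations of \code{zigzag_deg}), sites eastward
#' within each location, and quadrats at the corners of each site square.
#'
#' @param config a \code{scenario_config}.
#' @return A \code{site_table} skeleton (no predictors yet) with
#'   attributes \code{axis_km} (along-path coordinate of each quadrat)
#'   and \code{location_axis_km}.
#' @export
generate_design <- function(config) {
  nl <- config$n_locations
  ## location centres laid geodesically along the bent path: bearings
  ## alternate about due north so segment lengths equal the configured
  ## spacings exactly while the end-to-end chord stays shorter
  centres <- matrix(NA_real_, nl, 2L)
  centres[1L, ] <- c(config$origin_lon, config$origin_lat)
  for (k in seq_len(nl)[-1L]) {
    bear <- config$zigzag_deg * if (k %% 2L == 0L) 1 else -1
    centres[k, ] <- geosphere::destPoint(
      centres[k - 1L, ], bear, config$adjacent_spacing_km[k - 1L] * 1000,
      r = EARTH_RADIUS_M)
  }
  axis <- c(0, cumsum(config$adjacent_spacing_km))
  sq <- config$quadrat_square_m / 1000
  rows <- list(); i <- 0L
  for (l in seq_len(nl)) for (s in seq_along(config$site_offsets_km))
    for (q in 1:4) {
      i <- i + 1L
      e <- config$site_offsets_km[s] + (q %in% c(2L, 4L)) * sq  # km east
      n <- (q %in% c(3L, 4L)) * sq                              # km north
      lat <- centres[l, 2L] + n / KM_PER_DEG_LAT
      lon <- centres[l, 1L] + e / (KM_PER_DEG_LAT * cos(lat * pi / 180))
      rows[[i]] <- data.frame(
        quadrat_id = sprintf("L%02dS%dQ%d", l, s, q),
        location_id = l, site_id = s, lon = lon, lat = lat,
        axis_km = axis[l] + n)
    }
  df <- do.call(rbind, rows)
  st <- df[, c("quadrat_id", "location_id", "site_id", "lon", "lat")]
  st <- as_site_table(st)
  attr(st, "axis_km") <- stats::setNames(df$axis_km, df$quadrat_id)
  attr(st, "location_axis_km") <- axis
  st
}

CLIMATE_VARS <- c("mean_temp_wettest_q", "mean_temp_driest_q",
                  "precip_wettest_q", "precip_driest_q",
                  "precip_warmest_q", "precip_cv")
SOIL_VARS <- c("pH", "organic_C", "P", "Ca", "K", "Mg", "Na", "EC",
               "surface_sand")

#' Generate climate and soil predictor columns
#'
#' Climate columns are smooth monotone functions of latitude (temperature
#' rising, precipitation falling toward the arid north) with small
#' relative noise. Soil columns are location-level means plus a
#' site-level random effect and quadrat noise, so most soil variance
#' sits within rather than between locations.
#'
#' @param design a \code{site_table} from [generate_design()].
#' @param config a \code{scenario_config}.
#' @param seed integer seed.
#' @return The design with predictor columns appended and the group map
#'   filled in; all other attributes preserved.
#' @export
generate_environment <- function(design, config, seed = NULL) {
  with_seed(seed, {
    n <- nrow(design)
    z <- (design$lat - min(design$lat)) /
         (max(design$lat) - min(design$lat))   # 0 south -> 1 north
    clim <- list(
      mean_temp_wettest_q = 12 + 8 * z,
      mean_temp_driest_q  = 20 + 9 * z,
      precip_wettest_q    = 220 - 160 * z,
      precip_driest_q     = 90 - 70 * z,
      precip_warmest_q    = 70 - 45 * z,
      precip_cv           = 30 + 45 * z)
    for (v in names(clim)) {
      scale <- diff(range(clim[[v]]))
      design[[v]] <- clim[[v]] +
        stats::rnorm(n, 0, config$climate_noise_sd * scale)
    }
    soil_mean <- c(pH = 5.8, organic_C = 1.1, P = 6, Ca = 320, K = 55,
                   Mg = 48, Na = 20, EC = 4.5, surface_sand = 88)
    soil_bsd <- c(pH = 0.45, organic_C = 0.30, P = 2.0, Ca = 90, K = 16,
                  Mg = 15, Na = 7, EC = 1.4, surface_sand = 4)
    locs <- design$location_id
    sites <- interaction(design$location_id, design$site_id, drop = TRUE)
    for (v in SOIL_VARS) {
      if (config$turnover_mode == "distance_only") {
        ## no spatial structure at all: soil is exchangeable noise, so a
        ## selection procedure should reject it
        design[[v]] <- soil_mean[[v]] + stats::rnorm(n, 0, soil_bsd[[v]])
      } else {
        loc_eff <- stats::rnorm(max(locs), 0, soil_bsd[[v]])[locs]
        site_eff <- stats::rnorm(nlevels(sites), 0, soil_bsd[[v]])[as.integer(sites)]
        design[[v]] <- soil_mean[[v]] + loc_eff + site_eff +
          stats::rnorm(n, 0, 0.5 * soil_bsd[[v]])
      }
    }
    gm <- c(stats::setNames(rep("climate", length(CLIMATE_VARS)), CLIMATE_VARS),
            stats::setNames(rep("soil", length(SOIL_VARS)), SOIL_VARS))
    attr(design, "group_map") <- gm
    design
  })
}

## Range envelope: plateau of half-width w/2 with logistic shoulders.
envelope <- function(axis, centre, width, shoulder) {
  stats::plogis((width / 2 - abs(axis - centre)) / shoulder)
}

## Linear-with-plateau density of range centres along the axis: ratio
## rich_south/rich_north between the transect ends, constant beyond.
sample_centres <- function(n_sp, L, margin, ratio) {
  lo <- -margin; hi <- L + margin
  dens <- function(c) {
    cc <- pmin(pmax(c, 0), L)
    ratio + (1 - ratio) * cc / L
  }
  ## rejection sampling against the constant envelope `ratio`
  out <- numeric(0)
  while (length(out) < n_sp) {
    cand <- stats::runif(2L * n_sp, lo, hi)
    keep <- stats::runif(length(cand)) < dens(cand) / ratio
    out <- c(out, cand[keep])
  }
  out[seq_len(n_sp)]
}

#' Generate a community matrix with known structure
#'
#' Draws species incidences from the range-envelope x lottery model
#' described at the top of this file, according to
#' \code{config$turnover_mode}. The returned truth ledger records every
#' latent quantity needed for recovery tests.
#'
#' @param design a \code{site_table} with predictors (from
#'   [generate_environment()]); the bare design suffices for modes
#'   without an environmental filter.
#' @param config a \code{scenario_config}.
#' @param seed integer seed.
#' @return List: \code{community} (a \code{community_matrix}) and
#'   \code{truth} (centres, widths, class, occupancy, per-location
#'   availability, the calibrated core occupancy \code{p_core}).
#' @export
generate_community <- function(design, config, seed = NULL) {
  with_seed(seed, {
    axis <- attr(design, "axis_km")[design$quadrat_id]
    loc_axis <- attr(design, "location_axis_km")
    L <- max(loc_axis)
    nl <- config$n_locations
    n_q <- nrow(design)
    qpl <- n_q / nl
    rich_target <- config$richness_south +
      (config$richness_north - config$richness_south) * loc_axis / L

    if (config$turnover_mode == "nested") {
      ## deterministic dropout south -> north: quadrats within a location
      ## identical, poorer locations strict subsets of richer ones
      pool_per_loc <- round(rich_target)
      pres <- matrix(0L, n_q, max(pool_per_loc))
      for (l in seq_len(nl))
        pres[design$location_id == l, seq_len(pool_per_loc[l])] <- 1L
      colnames(pres) <- sprintf("sp%04d", seq_len(ncol(pres)))
      rownames(pres) <- design$quadrat_id
      cm <- as_community_matrix(pres)
      return(list(community = cm,
                  truth = list(mode = "nested",
                               pool_per_location = pool_per_loc)))
    }

    p_core <- calibrate_occupancy(qpl, config$beta_sor_target)
    n_rare <- round(config$pool_size * config$rare_fraction)
    n_core <- config$pool_size - n_rare
    ratio <- config$richness_south / config$richness_north

    margin_core <- 0.75 * config$core_width_km
    centres <- c(sample_centres(n_core, L, margin_core, ratio),
                 sample_centres(n_rare, L, 2 * config$rare_width_km, ratio))
    widths <- c(stats::rlnorm(n_core, log(config$core_width_km),
                              config$core_width_sdlog),
                stats::rlnorm(n_rare, log(config$rare_width_km),
                              config$rare_width_sdlog))
    is_rare <- rep(c(FALSE, TRUE), c(n_core, n_rare))
    p_sp <- ifelse(is_rare, config$p_rare, p_core)
    u_sp <- stats::runif(n_core + n_rare)   # nested availability scores

    ## availability of each species at each location (envelope at the
    ## location's axis position; within-location axis spread is ~0.1 km)
    env_loc <- outer(loc_axis, seq_along(centres), function(y, s)
      envelope(y, centres[s], widths[s], config$shoulder_km))

    ## thin core availability so expected richness follows the gradient:
    ## at each location, keep core species in order of their shared
    ## nested-availability score u until the kept availability reaches
    ## the target. Deterministic given u, so expected richness is pinned;
    ## shared u keeps the kept sets spatially coherent.
    core_cols <- which(!is_rare)
    core_avail <- rowSums(env_loc[, core_cols, drop = FALSE])
    rare_rich <- rowSums(env_loc[, is_rare, drop = FALSE]) * config$p_rare
    need <- pmax(rich_target - rare_rich, 1) / p_core
    if (any(need > core_avail * 1.02))
      warning("core species supply short of the richness target at ",
              sum(need > core_avail * 1.02), " location(s); ",
              "widen core ranges or enlarge the pool")
    ord <- order(u_sp[core_cols])
    keep <- matrix(FALSE, nl, length(core_cols))
    for (l in seq_len(nl)) {
      cum <- cumsum(env_loc[l, core_cols][ord])
      keep[l, ord[seq_len(min(findInterval(need[l], cum) + 1L,
                                length(ord)))]] <- TRUE
    }

    ## per-quadrat presence probabilities
    env_q <- outer(axis, seq_along(centres), function(y, s)
      envelope(y, centres[s], widths[s], config$shoulder_km))
    avail_q <- env_q
    for (l in seq_len(nl)) {
      qs <- which(design$location_id == l)
      avail_q[qs, core_cols[!keep[l, ]]] <- 0
    }

    filter_mult <- 1
    if (config$turnover_mode %in% c("env_filtered", "mixed")) {
      v <- design[[config$env_filter_var]]
      if (is.null(v)) stop("env filter variable '", config$env_filter_var,
                           "' absent; generate the environment first")
      opt <- stats::runif(length(centres), min(v), max(v))
      sdv <- config$env_filter_sd * if (config$turnover_mode == "mixed") 2 else 1
      filter_mult <- exp(-0.5 * (outer(v, opt, "-") / sdv)^2)
      ## rescale per species so filtering does not depress overall richness
      filter_mult <- sweep(filter_mult, 2L, colMeans(filter_mult), "/")
      filter_mult <- pmin(filter_mult, 1 / max(p_sp))
    }

    prob <- avail_q * rep(p_sp, each = n_q) * filter_mult
    prob <- pmin(prob, 1)
    pres <- matrix(stats::rbinom(length(prob), 1L, prob), n_q,
                   dimnames = list(design$quadrat_id,
                                   sprintf("sp%04d", seq_along(centres))))
    cm <- as_community_matrix(pres)
    list(community = cm,
         truth = list(mode = config$turnover_mode, centres = centres,
                      widths = widths, is_rare = is_rare, p_species = p_sp,
                      p_core = p_core, kept_core = keep,
                      availability = env_loc, u_species = u_sp,
                      rich_target = rich_target))
  })
}

#' Generate occurrence records from the truth ledger
#'
#' Scatters records inside each species' true range band: along-axis
#' positions uniform within the range, east-west offsets Gaussian with
#' spread proportional to the range width. Species centred in the arid
#' zone (the northern two locations) get their scatter widened by
#' \code{config$arid_range_multiplier}, reproducing the step in mean
#' range size.
#'
#' @param truth the truth ledger from [generate_community()].
#' @param config a \code{scenario_config}.
#' @param seed integer seed.
#' @param taxa which taxa to emit; default all in the ledger.
#' @return Data.frame of occurrence records (\code{taxon}, \code{lon},
#'   \code{lat}) with at least 3 records per taxon.
#' @export
generate_occurrences <- function(truth, config, seed = NULL, taxa = NULL) {
  if (is.null(truth$centres))
    stop("truth ledger has no range information (nested mode?)")
  with_seed(seed, {
    axis_total <- sum(config$adjacent_spacing_km)
    arid_start <- axis_total * (config$n_locations - 2) /
                  (config$n_locations - 1)
    ids <- sprintf("sp%04d", seq_along(truth$centres))
    if (is.null(taxa)) taxa <- ids
    rows <- lapply(match(taxa, ids), function(s) {
      w <- truth$widths[s]
      if (truth$centres[s] >= arid_start) w <- w * config$arid_range_multiplier
      n_rec <- 3L + stats::rpois(1L, 7)
      along <- stats::runif(n_rec, truth$centres[s] - w / 2,
                            truth$centres[s] + w / 2)
      east <- stats::rnorm(n_rec, 0, pmax(w / 6, 2))
      lat <- config$origin_lat + along / KM_PER_DEG_LAT
      lon <- config$origin_lon + east / (KM_PER_DEG_LAT * cos(lat * pi / 180))
      data.frame(taxon = ids[s], lon = lon, lat = lat)
    })
    do.call(rbind, rows)
  })
}

#' Generate a full synthetic scenario
#'
#' Convenience wrapper: design, environment, community and occurrence
#' records from one config and seed.
#'
#' @param config a \code{scenario_config}; default
#'   \code{scenario_config()}.
#' @param seed integer seed.
#' @param occurrences logical; also generate occurrence records (skipped
#'   automatically in nested mode).
#' @return List: \code{community}, \code{sites}, \code{occurrences} (or
#'   \code{NULL}), \code{truth}, \code{config}.
#' @export
generate_scenario <- function(config = scenario_config(), seed = 1L,
                              occurrences = TRUE) {
  st <- generate_design(config)
  st <- generate_environment(st, config, seed = seed + 1L)
  com <- generate_community(st, config, seed = seed + 2L)
  occ <- if (occurrences && !is.null(com$truth$centres))
    generate_occurrences(com$truth, config, seed = seed + 3L,
                         taxa = colnames(com$community)[colSums(com$community) > 0L])
  else NULL
  list(community = com$community, sites = st, occurrences = occ,
       truth = com$truth, config = config)
}
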
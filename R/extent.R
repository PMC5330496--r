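## Per-location multiple-site dissimilarity, its latitudinal trend, and
## the turnover-versus-extent resampling profile that holds sample size
## constant while geographic extent grows.

#' Midpoint of a location's quadrats
#'
#' Component-wise mean of the quadrat coordinates — adequate over the
#' longitudinal spans this package targets; inputs spanning the
#' antimeridian are rejected.
#'
#' @param st a \code{site_table}.
#' @param location_id a location identifier present in \code{st}.
#' @return \code{c(lon, lat)}.
#' @export
location_midpoint <- function(st, location_id) {
  sub <- st[st$location_id == location_id, , drop = FALSE]
  if (!nrow(sub)) stop("no quadrats for location ", location_id)
  if (diff(range(sub$lon)) > 180)
    stop("quadrats span the antimeridian; outside supported domain")
  c(lon = mean(sub$lon), lat = mean(sub$lat))
}

#' Resampled multiple-site dissimilarity at fixed sample size
#'
#' Draws \code{n_samples} random subsets of \code{sample_size} quadrats
#' (without replacement within each subset, independently across subsets)
#' from a pool, computes the multiple-site Sorensen family and Whittaker's
#' turnover on each, and summarizes. Holding \code{sample_size} constant
#' removes the sample-size dependence of the multiple-site measures when
#' pools of different sizes are compared.
#'
#' @param cm a \code{community_matrix}.
#' @param quadrat_pool character vector of quadrat ids to sample from.
#' @param sample_size quadrats per subset (>= 2).
#' @param n_samples number of random subsets.
#' @param seed integer seed for the sampling stream; \code{NULL} uses the
#'   current RNG state.
#' @return A list of class \code{resample_summary}: \code{mean} and
#'   \code{sd} (named vectors over beta_sor, beta_sim, beta_nes,
#'   beta_w_minus1), \code{n_samples}, \code{sample_size}. With one
#'   sample the sd is \code{NA}. When the pool size equals
#'   \code{sample_size} every draw is the full pool, so the mean equals
#'   the direct computation and sd is 0.
#' @export
beta_sample <- function(cm, quadrat_pool = rownames(cm), sample_size,
                        n_samples = 100L, seed = NULL) {
  pool <- intersect(quadrat_pool, rownames(cm))
  if (length(pool) < length(quadrat_pool))
    stop("pool contains quadrat ids absent from the community matrix")
  if (sample_size < 2L) stop("sample_size must be >= 2")
  if (length(pool) < sample_size)
    stop("pool (", length(pool), ") smaller than sample_size (", sample_size, ")")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  comp <- c("beta_sor", "beta_sim", "beta_nes", "beta_w_minus1")
  draws <- matrix(NA_real_, n_samples, length(comp), dimnames = list(NULL, comp))
  for (r in seq_len(n_samples)) {
    take <- if (length(pool) == sample_size) pool else sample(pool, sample_size)
    sub <- cm[take, , drop = FALSE]
    ms <- multisite_sorensen_family(sub)
    draws[r, ] <- c(ms$beta_sor, ms$beta_sim, ms$beta_nes,
                    whittaker_beta(sub)$beta_w_minus1)
  }
  structure(list(mean = colMeans(draws),
                 sd = if (n_samples > 1L) apply(draws, 2L, stats::sd)
                      else stats::setNames(rep(NA_real_, length(comp)), comp),
                 n_samples = n_samples, sample_size = sample_size),
            class = "resample_summary")
}

#' Multiple-site dissimilarity for each location
#'
#' Computes the multiple-site Sorensen family and Whittaker's
#' \eqn{\beta_{W-1}} separately from each location's quadrats, ordered
#' south to north by \code{location_id}, with the location midpoint
#' latitude attached for trend fitting.
#'
#' @param cm a \code{community_matrix}.
#' @param st a \code{site_table} covering the same quadrats.
#' @return Data.frame: \code{location_id}, \code{latitude},
#'   \code{n_quadrats}, \code{beta_sor}, \code{beta_sim}, \code{beta_nes},
#'   \code{beta_w_minus1}.
#' @export
location_betas <- function(cm, st) {
  check_alignment(cm, st)
  cm <- cm[st$quadrat_id, , drop = FALSE]
  locs <- sort(unique(st$location_id))
  rows <- lapply(locs, function(l) {
    sub <- cm[st$location_id == l, , drop = FALSE]
    if (nrow(sub) < 2L) stop("location ", l, " has fewer than 2 quadrats")
    ms <- multisite_sorensen_family(sub)
    data.frame(location_id = l,
               latitude = location_midpoint(st, l)[["lat"]],
               n_quadrats = nrow(sub),
               beta_sor = ms$beta_sor, beta_sim = ms$beta_sim,
               beta_nes = ms$beta_nes,
               beta_w_minus1 = whittaker_beta(sub)$beta_w_minus1)
  })
  do.call(rbind, rows)
}

#' Test a beta-diversity component for a latitudinal trend
#'
#' Ordinary least-squares regression of a per-location beta component on
#' latitude, with the F-test of zero slope on (1, n - 2) degrees of
#' freedom.
#'
#' @param values per-location beta values.
#' @param latitudes matching location latitudes.
#' @return List: \code{slope}, \code{intercept}, \code{F}, \code{df},
#'   \code{p_value}.
#' @export
beta_latitude_trend <- function(values, latitudes) {
  if (length(values) != length(latitudes)) stop("length mismatch")
  if (length(values) < 3L) stop("need at least 3 locations")
  if (stats::var(latitudes) == 0) stop("latitudes are constant")
  if (stats::var(values) == 0)    # flat response: slope exactly zero
    return(list(slope = 0, intercept = values[1L], F = 0,
                df = c(1L, length(values) - 2L), p_value = 1))
  fit <- stats::lm(values ~ latitudes)
  an <- stats::anova(fit)
  Fv <- an[["F value"]][1L]
  if (is.na(Fv)) Fv <- 0          # constant response: zero model SS
  p <- an[["Pr(>F)"]][1L]
  if (is.na(p)) p <- 1
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       F = Fv, df = c(1L, length(values) - 2L), p_value = p)
}

## Anchor extents of the nested design (km): the 1-ha site diagonal
## (100*sqrt(2) m), the closest-site pair, and the full within-location
## span. Used as row labels when the observed layout matches them.
DESIGN_EXTENTS_KM <- c(0.141, 1.5, 10.5)

snap_extent <- function(observed, anchor) {
  if (is.finite(observed) && abs(observed - anchor) / anchor < 0.05) anchor
  else observed
}

#' Turnover as a function of geographic extent at constant sample size
#'
#' Builds the dissimilarity-versus-extent profile of a nested transect.
#' Within the start location the profile has three direct rows: (i) the
#' mean over its four sites of the 4-quadrat multiple-site dissimilarity
#' (site-diagonal extent), (ii) one computation on the 8 quadrats of its
#' two closest sites, (iii) one computation on all its quadrats. Extent
#' then grows by adding whole locations along the transect; at each step
#' the multiple-site measures are means over \code{n_samples} random
#' subsets of \code{sample_size} quadrats from the cumulative pool, so
#' that sample size never varies with extent. Extent for those rows is the
#' great-circle distance between the start location's midpoint and the
#' newest location's midpoint. Whittaker's \eqn{\beta_{W-1}} is averaged
#' over the same subsets. Components are computed per subset and then
#' averaged, so the reported means satisfy
#' \code{beta_nes = beta_sor - beta_sim} exactly.
#'
#' @param cm a \code{community_matrix}.
#' @param st a \code{site_table} covering the same quadrats.
#' @param sample_size quadrats per random subset (default 16, one
#'   location's worth).
#' @param n_samples random subsets per extent step (default 100).
#' @param direction \code{"south_to_north"} (start at the lowest
#'   \code{location_id}) or \code{"north_to_south"}.
#' @param seed integer seed for the profile's sampling stream.
#' @return Data.frame of class \code{extent_profile}: \code{extent_km},
#'   \code{beta_sor_mean}, \code{beta_sim_mean}, \code{beta_nes_mean},
#'   \code{beta_w_minus1}, \code{n_quadrats_per_sample}, \code{n_samples},
#'   \code{direction}.
#' @export
incremental_extent_profile <- function(cm, st, sample_size = 16L,
                                       n_samples = 100L,
                                       direction = c("south_to_north",
                                                     "north_to_south"),
                                       seed = NULL) {
  direction <- match.arg(direction)
  check_alignment(cm, st)
  cm <- cm[st$quadrat_id, , drop = FALSE]
  locs <- sort(unique(st$location_id))
  if (direction == "north_to_south") locs <- rev(locs)
  start <- locs[1L]
  st0 <- st[st$location_id == start, , drop = FALSE]
  if (!("site_id" %in% colnames(st0)) || length(unique(st0$site_id)) < 2L)
    stop("start location lacks the nested site structure")

  rows <- list()
  ## (i) mean over the start location's sites of the within-site value
  sites <- sort(unique(st0$site_id))
  per_site <- vapply(sites, function(s) {
    q <- st0$quadrat_id[st0$site_id == s]
    if (length(q) < 2L) stop("site ", s, " has fewer than 2 quadrats")
    sub <- cm[q, , drop = FALSE]
    ms <- multisite_sorensen_family(sub)
    c(ms$beta_sor, ms$beta_sim, ms$beta_nes,
      whittaker_beta(sub)$beta_w_minus1)
  }, numeric(4L))
  site_diag <- max(vapply(sites, function(s) {
    q <- st0[st0$site_id == s, , drop = FALSE]
    max(great_circle_km(cbind(q$lon, q$lat)))
  }, numeric(1L)))
  rows[[1L]] <- c(snap_extent(site_diag, DESIGN_EXTENTS_KM[1L]),
                  rowMeans(per_site),
                  sum(st0$site_id == sites[1L]), length(sites))

  ## (ii) the two closest sites of the start location (8 quadrats)
  mids <- t(vapply(sites, function(s) {
    q <- st0[st0$site_id == s, , drop = FALSE]
    c(mean(q$lon), mean(q$lat))
  }, numeric(2L)))
  dm <- great_circle_km(mids)
  dm[lower.tri(dm, diag = TRUE)] <- Inf
  best <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
  q8 <- st0$quadrat_id[st0$site_id %in% sites[best]]
  sub8 <- cm[q8, , drop = FALSE]
  ms8 <- multisite_sorensen_family(sub8)
  rows[[2L]] <- c(snap_extent(min(dm), DESIGN_EXTENTS_KM[2L]),
                  ms8$beta_sor, ms8$beta_sim, ms8$beta_nes,
                  whittaker_beta(sub8)$beta_w_minus1, length(q8), 1L)

  ## (iii) all quadrats of the start location
  subL <- cm[st0$quadrat_id, , drop = FALSE]
  msL <- multisite_sorensen_family(subL)
  spanL <- max(great_circle_km(cbind(st0$lon, st0$lat)))
  rows[[3L]] <- c(snap_extent(spanL, DESIGN_EXTENTS_KM[3L]),
                  msL$beta_sor, msL$beta_sim, msL$beta_nes,
                  whittaker_beta(subL)$beta_w_minus1, nrow(subL), 1L)

  ## (iv+) cumulative locations, resampled at constant sample size
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mid_start <- location_midpoint(st, start)
  for (k in seq_along(locs)[-1L]) {
    pool <- st$quadrat_id[st$location_id %in% locs[seq_len(k)]]
    if (length(pool) < sample_size)
      stop("cumulative pool smaller than sample_size at step ", k)
    rs <- beta_sample(cm, pool, sample_size, n_samples, seed = NULL)
    extent <- great_circle_km(mid_start, location_midpoint(st, locs[k]))
    rows[[k + 2L]] <- c(extent, rs$mean[["beta_sor"]], rs$mean[["beta_sim"]],
                        rs$mean[["beta_nes"]], rs$mean[["beta_w_minus1"]],
                        sample_size, n_samples)
  }

  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- c("extent_km", "beta_sor_mean", "beta_sim_mean",
                     "beta_nes_mean", "beta_w_minus1",
                     "n_quadrats_per_sample", "n_samples")
  out$direction <- direction
  if (is.unsorted(out$extent_km, strictly = TRUE))
    warning("extent values are not strictly increasing; check the design layout")
  class(out) <- c("extent_profile", "data.frame")
  out
}
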
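## One-call orchestration of the full transect analysis, mirroring the
## survey workflow: richness summaries, per-location multiple-site
## dissimilarity, extent profiles in both directions, the transect-wide
## dissimilarity model with variable elimination and deviance
## partitioning, per-location models, and range sizes. Every artifact is
## a tidy CSV; plots are drawn from the CSVs only.

write_artifact <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full transect analysis
#'
#' @param community a \code{community_matrix} or path to a community CSV.
#' @param sites a \code{site_table}, or path to a site CSV (then
#'   \code{group_config} is required).
#' @param occurrences optional occurrence data.frame or CSV path; enables
#'   the range-size artifacts.
#' @param output_dir directory for the CSV artifacts (created if absent).
#' @param group_config predictor group mapping, only when \code{sites} is
#'   a path.
#' @param n_perm permutations per elimination test.
#' @param alpha retention threshold for predictors.
#' @param sample_size,n_samples extent-profile resampling controls.
#' @param n_splines I-splines per predictor.
#' @param seed integer seed governing every stochastic stage.
#' @param per_location_gdm logical; also fit one eliminated model per
#'   location (slowest stage).
#' @return Invisibly, a list with the computed objects and the artifact
#'   paths.
#' @export
run_full_analysis <- function(community, sites, occurrences = NULL,
                              output_dir = "sandturn_results",
                              group_config = NULL,
                              n_perm = 500L, alpha = 0.05,
                              sample_size = 16L, n_samples = 100L,
                              n_splines = 3L, seed = 1L,
                              per_location_gdm = TRUE) {
  if (is.character(community)) community <- read_community_matrix(community)
  if (is.character(sites)) sites <- read_site_table(sites, group_config)
  if (is.character(occurrences)) occurrences <- read_occurrences(occurrences)
  check_alignment(community, sites)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  log_lines <- c(sprintf("sandturn %s", as.character(utils::packageVersion("sandturn"))),
                 sprintf("seed=%d n_perm=%d alpha=%g sample_size=%d n_samples=%d n_splines=%d",
                         seed, n_perm, alpha, sample_size, n_samples, n_splines))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("%-22s %.1fs", name,
                                       proc.time()[["elapsed"]] - t0))
    out
  }

  rich <- stage("richness", richness_summaries(community, sites))
  paths["richness"] <- write_artifact(rich, output_dir, "richness_summaries.csv")

  lb <- stage("location_betas", location_betas(community, sites))
  paths["location_betas"] <- write_artifact(lb, output_dir, "location_betas.csv")
  trend <- stage("beta_trend", {
    tr <- lapply(c("beta_sor", "beta_sim", "beta_w_minus1"), function(comp) {
      t <- beta_latitude_trend(lb[[comp]], lb$latitude)
      data.frame(component = comp, slope = t$slope, F = t$F,
                 df1 = t$df[1L], df2 = t$df[2L], p_value = t$p_value)
    })
    do.call(rbind, tr)
  })
  paths["beta_trend"] <- write_artifact(trend, output_dir, "beta_latitude_trend.csv")

  prof <- stage("extent_profiles", rbind(
    incremental_extent_profile(community, sites, sample_size, n_samples,
                               "south_to_north", seed = seed),
    incremental_extent_profile(community, sites, sample_size, n_samples,
                               "north_to_south", seed = seed + 1L)))
  paths["extent_profile"] <- write_artifact(prof, output_dir, "extent_profile.csv")

  spt <- stage("site_pairs", build_site_pairs(community, sites))
  model <- stage("gdm_elimination",
                 backward_eliminate(spt, alpha = alpha, n_perm = n_perm,
                                    seed = seed + 2L, n_splines = n_splines))
  imp <- variable_importance(model)
  paths["gdm_importance"] <- write_artifact(
    data.frame(predictor = names(imp), importance = unname(imp),
               p_value = if (length(imp)) unname(model$p_values[names(imp)])
                         else numeric(0),
               deviance_explained = rep(model$deviance_explained,
                                        length(imp))),
    output_dir, "gdm_importance.csv")
  paths["gdm_splines"] <- write_artifact(spline_curves(model), output_dir,
                                         "gdm_spline_curves.csv")
  paths["gdm_elimination"] <- write_artifact(model$elimination_log,
                                             output_dir, "gdm_elimination_log.csv")

  part <- stage("deviance_partition", {
    gm <- attr(spt, "group_map")
    kept <- setdiff(model$predictors, GEO_PREDICTOR)
    groups <- list(G = GEO_PREDICTOR,
                   C = intersect(kept, names(gm)[gm == "climate"]),
                   S = intersect(kept, names(gm)[gm == "soil"]))
    if (all(lengths(groups) > 0L)) deviance_partition(spt, groups) else NULL
  })
  if (!is.null(part))
    paths["partition"] <- write_artifact(
      data.frame(component = names(part$fractions),
                 fraction = unname(part$fractions), total = part$total),
      output_dir, "gdm_partition.csv")

  per_loc <- NULL
  if (per_location_gdm) {
    per_loc <- stage("per_location_gdm", {
      rows <- lapply(sort(unique(sites$location_id)), function(l) {
        stl <- sites[sites$location_id == l, , drop = FALSE]
        cml <- community[stl$quadrat_id, , drop = FALSE]
        m <- backward_eliminate(build_site_pairs(cml, stl), alpha = alpha,
                                n_perm = n_perm, seed = seed + 10L + l,
                                n_splines = n_splines)
        if (!length(m$predictors)) return(NULL)
        data.frame(location_id = l, predictor = m$predictors,
                   importance = unname(variable_importance(m)),
                   deviance_explained = m$deviance_explained)
      })
      do.call(rbind, rows)
    })
    if (!is.null(per_loc))
      paths["per_location_gdm"] <- write_artifact(per_loc, output_dir,
                                                  "per_location_gdm.csv")
  }

  ranges <- mean_ranges <- NULL
  if (!is.null(occurrences)) {
    ranges <- stage("range_sizes", range_size_table(occurrences))
    paths["range_sizes"] <- write_artifact(ranges, output_dir, "range_sizes.csv")
    mean_ranges <- stage("mean_range_per_location",
                         mean_range_size_per_location(community, sites, ranges))
    paths["mean_ranges"] <- write_artifact(mean_ranges, output_dir,
                                           "mean_range_per_location.csv")
  }

  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(list(richness = rich, location_betas = lb, trend = trend,
                 extent_profile = prof, gdm = model, partition = part,
                 per_location_gdm = per_loc, range_sizes = ranges,
                 mean_ranges = mean_ranges, paths = paths,
                 output_dir = output_dir))
}

#' Plot the report figures from a result directory
#'
#' Draws the standard panels (partial ecological-distance curves, beta
#' components versus latitude, beta versus extent, the deviance
#' partition, and mean range size when present) into a PDF, reading only
#' the CSV artifacts written by [run_full_analysis()] so every plotted
#' number is traceable to a file.
#'
#' @param output_dir directory holding the CSV artifacts.
#' @param file name of the PDF to write inside \code{output_dir}.
#' @return Invisibly, the PDF path.
#' @export
make_report <- function(output_dir, file = "report.pdf") {
  path <- file.path(output_dir, file)
  rd <- function(name) {
    f <- file.path(output_dir, name)
    if (!file.exists(f)) return(NULL)
    out <- utils::read.csv(f)
    if (nrow(out)) out else NULL
  }
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())

  sc <- rd("gdm_spline_curves.csv")
  if (!is.null(sc) && nrow(sc)) {
    preds <- unique(sc$predictor)
    graphics::par(mfrow = c(ceiling(length(preds) / 3), 3),
                  mar = c(4, 4, 2, 1))
    for (p in preds) {
      sub <- sc[sc$predictor == p, ]
      graphics::plot(sub$x, sub$partial_distance, type = "l", lwd = 2,
                     xlab = p, ylab = "partial ecological distance",
                     main = p, cex.main = 0.9)
    }
    graphics::par(mfrow = c(1, 1))
  }

  lb <- rd("location_betas.csv")
  if (!is.null(lb)) {
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    graphics::plot(lb$latitude, lb$beta_sor, pch = 15, ylim = c(0, 1),
                   xlab = "latitude", ylab = "multiple-site dissimilarity")
    graphics::points(lb$latitude, lb$beta_sim, pch = 1)
    graphics::legend("bottomleft", pch = c(15, 1),
                     legend = c("beta_SOR", "beta_SIM"), bty = "n")
    graphics::plot(lb$latitude, lb$beta_w_minus1, pch = 17,
                   xlab = "latitude", ylab = "beta_W - 1")
    graphics::par(mfrow = c(1, 1))
  }

  prof <- rd("extent_profile.csv")
  if (!is.null(prof)) {
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    for (dir in unique(prof$direction)) {
      sub <- prof[prof$direction == dir, ]
      graphics::plot(sub$extent_km, sub$beta_sor_mean, type = "b", pch = 15,
                     ylim = c(0, 1), log = "x", xlab = "extent (km)",
                     ylab = "dissimilarity", main = dir, cex.main = 0.9)
      graphics::points(sub$extent_km, sub$beta_sim_mean, type = "b", pch = 1)
    }
    graphics::par(mfrow = c(1, 1))
  }

  part <- rd("gdm_partition.csv")
  if (!is.null(part))
    graphics::barplot(stats::setNames(part$fraction, part$component),
                      ylab = "% deviance explained",
                      main = "deviance partition")

  mr <- rd("mean_range_per_location.csv")
  if (!is.null(mr))
    graphics::plot(mr$location_id, mr$mean_range_km2, type = "b", pch = 16,
                   xlab = "location", ylab = "mean range size (km^2)")
  invisible(path)
}
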
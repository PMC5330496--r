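## Tabular input/output and validation for the nested survey design.
##
## File contracts (comma-separated, UTF-8, header row mandatory):
##   community.csv   first column = quadrat id, remaining columns = taxa, cells 0/1
##   sites.csv       quadrat_id, location_id, site_id, lon, lat, <predictor columns>
##   occurrences.csv taxon, lon, lat

#' Read a quadrat-by-taxon incidence matrix
#'
#' Reads a CSV whose first column holds quadrat identifiers and whose
#' remaining columns hold 0/1 incidences for each taxon. Blank cells are
#' treated as absences. Abundance or cover values are rejected unless
#' \code{binarize = TRUE}, in which case any value > 0 becomes a presence;
#' incidence-only storage is deliberate, as all downstream dissimilarities
#' are incidence-based.
#'
#' @param path path to a CSV file.
#' @param binarize logical; if \code{TRUE}, positive numeric cells are
#'   converted to 1 instead of being rejected.
#' @return A \code{community_matrix}: an integer matrix with quadrat ids as
#'   row names and taxon ids as column names, cells in \{0, 1\}.
#' @export
read_community_matrix <- function(path, binarize = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("community file needs a quadrat-id column plus at least one taxon column")
  ids <- as.character(df[[1L]])
  taxa <- colnames(df)[-1L]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "numeric"
  mat[is.na(mat)] <- 0
  if (binarize) {
    mat <- (mat > 0) + 0L
  } else {
    bad <- which(!(mat %in% c(0, 1)))
    if (length(bad)) {
      i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
      j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
      stop(sprintf(
        "non-binary cell at quadrat '%s', taxon '%s' (value %s); use binarize = TRUE for cover data",
        ids[i], taxa[j], format(mat[i, j])))
    }
  }
  storage.mode(mat) <- "integer"
  dimnames(mat) <- list(ids, taxa)
  as_community_matrix(mat)
}

#' Construct a community matrix from an incidence matrix
#'
#' @param x numeric or integer matrix with quadrat row names and taxon
#'   column names; cells must be 0 or 1.
#' @return A validated \code{community_matrix}.
#' @export
as_community_matrix <- function(x) {
  if (!is.matrix(x)) stop("'x' must be a matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("Q", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate quadrat ids: ",
    paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x))) stop("duplicate taxon ids: ",
    paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!all(x %in% c(0L, 1L))) stop("incidence cells must be 0 or 1")
  storage.mode(x) <- "integer"
  class(x) <- c("community_matrix", class(unclass(x)))
  x
}

#' Write a community matrix to CSV
#'
#' Inverse of [read_community_matrix()]: the written file reads back to an
#' identical object.
#'
#' @param cm a \code{community_matrix}.
#' @param path output CSV path.
#' @export
write_community_matrix <- function(cm, path) {
  df <- data.frame(quadrat_id = rownames(cm), unclass(cm),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a site table
#'
#' The site table carries the nested design (quadrat within site within
#' location), WGS84 coordinates in decimal degrees, and the numeric
#' predictor columns used by the dissimilarity model. Every predictor
#' column must be assigned to the "climate" or "soil" group through
#' \code{group_config}; unassigned numeric columns are an error so that no
#' variable silently enters or escapes the model.
#'
#' @param path path to a CSV file with columns \code{quadrat_id},
#'   \code{location_id}, \code{site_id}, \code{lon}, \code{lat} plus
#'   predictors.
#' @param group_config named character vector or list mapping each
#'   predictor column to \code{"climate"} or \code{"soil"}.
#' @return A \code{site_table}: a data.frame with a \code{group_map}
#'   attribute (named character vector).
#' @export
read_site_table <- function(path, group_config) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_site_table(df, group_config)
}

#' Construct a site table from a data.frame
#'
#' @param df data.frame with the columns documented in [read_site_table()].
#' @param group_config named mapping of predictor columns to
#'   \code{"climate"} or \code{"soil"}.
#' @return A validated \code{site_table}.
#' @export
as_site_table <- function(df, group_config = NULL) {
  required <- c("quadrat_id", "location_id", "site_id", "lon", "lat")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols))
    stop("site table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  df$quadrat_id <- as.character(df$quadrat_id)
  if (anyDuplicated(df$quadrat_id))
    stop("duplicate quadrat ids in site table")
  if (any(!is.finite(df$lon)) || any(!is.finite(df$lat)))
    stop("site table has missing or non-finite coordinates")
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180)) stop("longitude outside [-180, 180]")
  preds <- setdiff(colnames(df), required)
  preds <- preds[vapply(df[preds], is.numeric, logical(1L))]
  gm <- character(0)
  if (length(preds)) {
    if (is.null(group_config))
      stop("numeric predictor column(s) present but no group_config given: ",
           paste(preds, collapse = ", "))
    gm <- unlist(group_config)
    unassigned <- setdiff(preds, names(gm))
    if (length(unassigned))
      stop("predictor column(s) not assigned to climate or soil: ",
           paste(unassigned, collapse = ", "))
    gm <- gm[names(gm) %in% preds]
    if (!all(gm %in% c("climate", "soil")))
      stop("group_config values must be 'climate' or 'soil'")
    novar <- names(gm)[vapply(df[names(gm)], function(v) stats::var(v) == 0, logical(1L))]
    if (length(novar))
      warning("predictor(s) with zero variance will be dropped by the model: ",
              paste(novar, collapse = ", "))
  }
  attr(df, "group_map") <- gm
  class(df) <- c("site_table", "data.frame")
  df
}

#' Write a site table to CSV
#'
#' @param st a \code{site_table}.
#' @param path output CSV path.
#' @export
write_site_table <- function(st, path) {
  utils::write.csv(as.data.frame(st), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predictor-to-group mapping of a site table
#'
#' @param st a \code{site_table}.
#' @return Named character vector mapping predictor columns to
#'   \code{"climate"} or \code{"soil"}.
#' @export
group_map <- function(st) attr(st, "group_map")

#' Check that a community matrix and site table describe the same quadrats
#'
#' @param cm a \code{community_matrix}.
#' @param st a \code{site_table}.
#' @return Invisibly \code{TRUE}; errors listing the id differences otherwise.
#' @export
check_alignment <- function(cm, st) {
  a <- rownames(cm); b <- st$quadrat_id
  if (!setequal(a, b)) {
    only_cm <- setdiff(a, b); only_st <- setdiff(b, a)
    stop("quadrat ids differ between community matrix and site table.",
         if (length(only_cm)) paste0(" Only in community matrix: ",
                                     paste(utils::head(only_cm, 5L), collapse = ", "), ".") else "",
         if (length(only_st)) paste0(" Only in site table: ",
                                     paste(utils::head(only_st, 5L), collapse = ", "), ".") else "")
  }
  invisible(TRUE)
}

#' Drop quadrats with no recorded taxa
#'
#' Pairwise Sorensen dissimilarity is undefined against an empty quadrat
#' (the denominator is zero), so empty quadrats are excluded from all
#' dissimilarity computations, with a warning naming them.
#'
#' @param cm a \code{community_matrix}.
#' @return The matrix restricted to non-empty quadrats.
#' @export
drop_empty_quadrats <- function(cm) {
  empty <- rowSums(cm) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty quadrat(s): ",
            paste(utils::head(rownames(cm)[empty], 10L), collapse = ", "))
    cm <- cm[!empty, , drop = FALSE]
    class(cm) <- c("community_matrix", class(unclass(cm)))
  }
  cm
}

#' Summarize the spatial design of a survey
#'
#' Reports, for each location, the number of quadrats and the maximum
#' pairwise great-circle distance among them, and the great-circle
#' distances between midpoints of adjacent locations (ordered by
#' \code{location_id}). Location midpoints are component-wise means of the
#' quadrat coordinates, adequate at sub-continental longitudinal spans.
#'
#' @param st a \code{site_table}.
#' @return A list with elements \code{n_locations},
#'   \code{per_location} (data.frame: location_id, n_quadrats,
#'   max_within_km), and \code{adjacent_km} (numeric vector, length
#'   \code{n_locations - 1}).
#' @export
summarize_design <- function(st) {
  locs <- sort(unique(st$location_id))
  per <- lapply(locs, function(l) {
    sub <- st[st$location_id == l, , drop = FALSE]
    maxd <- if (nrow(sub) < 2L) NA_real_ else {
      dm <- great_circle_km(cbind(sub$lon, sub$lat))
      max(dm)
    }
    data.frame(location_id = l, n_quadrats = nrow(sub), max_within_km = maxd)
  })
  per <- do.call(rbind, per)
  mids <- t(vapply(locs, function(l) location_midpoint(st, l), numeric(2L)))
  adjacent <- if (length(locs) < 2L) numeric(0) else
    vapply(seq_len(length(locs) - 1L), function(i)
      great_circle_km(mids[i, ], mids[i + 1L, ]), numeric(1L))
  list(n_locations = length(locs), per_location = per, adjacent_km = adjacent)
}

#' Per-location richness summaries
#'
#' For each location: mean quadrat richness (alpha-bar), the local species
#' pool (taxa pooled over the location's quadrats), and the number and
#' fraction of the location's pool that are transect-wide singletons
#' (taxa recorded in exactly one quadrat anywhere on the transect).
#'
#' @param cm a \code{community_matrix}.
#' @param st a \code{site_table} covering the same quadrats.
#' @return A data.frame with one row per location, ordered by
#'   \code{location_id}, plus attributes \code{total_richness} and
#'   \code{singleton_fraction} (transect-wide fraction of taxa that are
#'   singletons).
#' @export
richness_summaries <- function(cm, st) {
  check_alignment(cm, st)
  cm <- cm[st$quadrat_id, , drop = FALSE]
  occ <- colSums(cm)
  singletons <- colnames(cm)[occ == 1L]
  locs <- sort(unique(st$location_id))
  rows <- lapply(locs, function(l) {
    sub <- cm[st$location_id == l, , drop = FALSE]
    pool_taxa <- colnames(sub)[colSums(sub) > 0L]
    data.frame(location_id = l,
               n_quadrats = nrow(sub),
               mean_richness = mean(rowSums(sub)),
               local_pool = length(pool_taxa),
               n_singletons = sum(pool_taxa %in% singletons))
  })
  out <- do.call(rbind, rows)
  out$singleton_fraction <- ifelse(out$local_pool > 0,
                                   out$n_singletons / out$local_pool, NA_real_)
  recorded <- sum(occ > 0L)
  attr(out, "total_richness") <- recorded
  attr(out, "singleton_fraction") <- if (recorded > 0)
    length(singletons) / recorded else NA_real_
  out
}

#' Read an occurrence-record table
#'
#' @param path CSV with columns \code{taxon}, \code{lon}, \code{lat}.
#' @return A data.frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "lon", "lat")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("occurrence table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$lon)) || any(!is.finite(df$lat)))
    stop("occurrence table has non-finite coordinates")
  df
}
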
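# Fixture builders and an independent set-operation oracle for the
# multiple-site dissimilarities. The oracle works on explicit taxon-name
# sets (union/setdiff/intersect), never touching the package's integer
# matrix algebra, so the two routes are independent.

# community matrix from a named list of taxon-id character vectors
cm_from_sets <- function(sets, taxa = sort(unique(unlist(sets)))) {
  m <- t(vapply(sets, function(s) as.integer(taxa %in% s),
                integer(length(taxa))))
  dimnames(m) <- list(names(sets) %||% paste0("Q", seq_along(sets)), taxa)
  as_community_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random binary community with non-empty quadrats
random_cm <- function(n_quadrats, n_taxa, p = 0.4) {
  repeat {
    m <- matrix(rbinom(n_quadrats * n_taxa, 1L, p), n_quadrats, n_taxa)
    if (all(rowSums(m) > 0L)) break
  }
  dimnames(m) <- list(paste0("Q", seq_len(n_quadrats)),
                      paste0("sp", seq_len(n_taxa)))
  as_community_matrix(m)
}

# brute-force multiple-site Sorensen family via explicit set operations
bf_multisite <- function(cm) {
  sets <- lapply(seq_len(nrow(cm)), function(i)
    colnames(cm)[unclass(cm)[i, ] == 1L])
  n <- length(sets)
  S_T <- length(Reduce(union, sets))
  sum_S <- sum(lengths(sets))
  smin <- smax <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bij <- length(setdiff(sets[[i]], sets[[j]]))
    bji <- length(setdiff(sets[[j]], sets[[i]]))
    smin <- smin + min(bij, bji)
    smax <- smax + max(bij, bji)
  }
  nest <- sum_S - S_T
  list(beta_sim = if (nest + smin == 0) 0 else smin / (nest + smin),
       beta_sor = if (2 * nest + smin + smax == 0) 0 else
         (smin + smax) / (2 * nest + smin + smax))
}

# minimal site table wrapping a set of quadrats at given coordinates
toy_site_table <- function(ids, lon, lat, location = 1L, site = 1L, ...) {
  df <- data.frame(quadrat_id = ids, location_id = location, site_id = site,
                   lon = lon, lat = lat, ...)
  preds <- setdiff(colnames(df),
                   c("quadrat_id", "location_id", "site_id", "lon", "lat"))
  gc <- if (length(preds)) setNames(rep("soil", length(preds)), preds)
  as_site_table(df, gc)
}
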
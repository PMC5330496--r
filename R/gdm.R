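## Generalized dissimilarity modelling: compositional dissimilarity
## between quadrat pairs regressed on monotone I-spline transforms of
## environmental differences and geographic distance, through the link
## mu = 1 - exp(-eta) with non-negative coefficients.
##
## The deviance is the binomial-form deviance for continuous proportions,
##   D = 2 sum[ d log(d/mu) + (1-d) log((1-d)/(1-mu)) ],  0 log 0 = 0,
## minimized by iteratively reweighted non-negative least squares; the
## inner step solves the weighted normal equations with Lawson-Hanson
## NNLS (pracma::lsqnonneg), so fits are deterministic given the data.

#' Name under which geographic distance enters the dissimilarity model
#' @export
GEO_PREDICTOR <- "geographic_distance"

#' Build the site-pair table for dissimilarity modelling
#'
#' One row per unordered quadrat pair: observed Sorensen dissimilarity,
#' great-circle distance between the quadrats, and the predictor values at
#' both ends. Empty quadrats are dropped first (with a warning) because
#' their pairwise dissimilarity is undefined.
#'
#' @param cm a \code{community_matrix}.
#' @param st a \code{site_table} covering the same quadrats.
#' @param predictors predictor columns of \code{st} to carry; default all
#'   columns in the table's group map.
#' @return A data.frame of class \code{site_pair_table} with columns
#'   \code{quadrat_1}, \code{quadrat_2}, \code{dissimilarity},
#'   \code{distance_km} and \code{<predictor>_1}/\code{<predictor>_2}
#'   pairs, plus attributes used by the fitting functions.
#' @export
build_site_pairs <- function(cm, st, predictors = names(group_map(st))) {
  check_alignment(cm, st)
  cm <- cm[st$quadrat_id, , drop = FALSE]
  keep <- rowSums(cm) > 0L
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " empty quadrat(s) from the pair table: ",
            paste(utils::head(st$quadrat_id[!keep], 10L), collapse = ", "))
    cm <- cm[keep, , drop = FALSE]
    st <- st[keep, , drop = FALSE]
  }
  n <- nrow(cm)
  if (n < 3L) stop("need at least 3 non-empty quadrats")
  missing_p <- setdiff(predictors, colnames(st))
  if (length(missing_p))
    stop("predictor(s) absent from site table: ", paste(missing_p, collapse = ", "))

  dmat <- dissimilarity_matrix(cm, "sorensen")
  gmat <- great_circle_km(cbind(st$lon, st$lat))
  idx <- which(upper.tri(dmat), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- data.frame(quadrat_1 = st$quadrat_id[idx[, 1L]],
                    quadrat_2 = st$quadrat_id[idx[, 2L]],
                    dissimilarity = dmat[idx],
                    distance_km = gmat[idx])
  qv <- as.matrix(st[, predictors, drop = FALSE])
  rownames(qv) <- st$quadrat_id
  for (p in predictors) {
    out[[paste0(p, "_1")]] <- qv[idx[, 1L], p]
    out[[paste0(p, "_2")]] <- qv[idx[, 2L], p]
  }
  attr(out, "predictors") <- predictors
  attr(out, "group_map") <- group_map(st)[predictors]
  attr(out, "quadrat_values") <- qv
  attr(out, "dist_mat") <- gmat
  attr(out, "pair_idx") <- idx
  class(out) <- c("site_pair_table", "data.frame")
  out
}

#' Monotone I-spline basis for one predictor
#'
#' Order-2 (piecewise quadratic) I-splines: each basis function is the
#' integral of a normalized piecewise-linear density on consecutive
#' knots, hence non-decreasing, 0 at the range minimum and 1 at the
#' maximum. Knots sit at evenly spaced quantiles of the observed values
#' (minimum, median, maximum for the default of three splines); tied
#' knots are spread by a small jitter so the basis stays well defined.
#'
#' @param values observed predictor values (quadrat-level, or pairwise
#'   distances for the geographic predictor).
#' @param n_splines number of basis functions (default 3).
#' @return An object of class \code{ispline_basis} with the knot vector.
#' @export
ispline_basis <- function(values, n_splines = 3L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 3L)
    stop("predictor has fewer than 3 distinct values; drop it")
  knots <- unname(stats::quantile(values, seq(0, 1, length.out = n_splines),
                                  type = 7))
  if (any(diff(knots) <= 0)) {          # tied quantiles: spread minimally
    eps <- diff(range(values)) * 1e-6
    for (k in seq_along(knots)[-1L])
      if (knots[k] <= knots[k - 1L]) knots[k] <- knots[k - 1L] + eps
  }
  structure(list(knots = knots, n_splines = n_splines), class = "ispline_basis")
}

## Integrated triangular bump on (u, v, w); degenerate ends allowed.
itri <- function(x, u, v, w) {
  x <- pmin(pmax(x, u), w)
  out <- numeric(length(x))
  if (u < v) {
    lo <- x <= v
    out[lo] <- (x[lo] - u)^2 / ((w - u) * (v - u))
    out[!lo] <- 1 - (w - x[!lo])^2 / ((w - u) * (w - v))
  } else {                              # u == v: left-degenerate
    out <- 1 - ((w - x) / (w - u))^2
  }
  if (v == w) out <- ((x - u) / (w - u))^2
  out
}

#' Evaluate an I-spline basis
#'
#' @param basis an \code{ispline_basis}.
#' @param x values to evaluate at (clamped to the knot range).
#' @return Matrix \code{length(x) x n_splines}; each column non-decreasing
#'   in \code{x}, 0 at the first knot, 1 at the last.
#' @export
eval_ispline <- function(basis, x) {
  k <- basis$knots
  s <- basis$n_splines
  ext <- c(k[1L], k, k[s])
  matrix(vapply(seq_len(s), function(j)
    itri(x, ext[j], ext[j + 1L], ext[j + 2L]), numeric(length(x))),
    nrow = length(x), ncol = s)
}

## Pair-level design columns: |I(x1) - I(x2)| per environmental
## predictor, I(distance) for the geographic predictor. Returns the
## design matrix, the bases, and a column -> predictor map.
build_design <- function(spt, predictors, n_splines = 3L) {
  qv <- attr(spt, "quadrat_values")
  idx <- attr(spt, "pair_idx")
  env <- setdiff(predictors, GEO_PREDICTOR)
  bases <- list(); cols <- character(0); blocks <- list()
  dropped <- character(0)
  for (p in env) {
    v <- qv[, p]
    if (length(unique(v)) < 3L) { dropped <- c(dropped, p); next }
    b <- ispline_basis(v, n_splines)
    Tq <- eval_ispline(b, v)
    blocks[[p]] <- abs(Tq[idx[, 1L], , drop = FALSE] -
                       Tq[idx[, 2L], , drop = FALSE])
    bases[[p]] <- b
    cols <- c(cols, rep(p, n_splines))
  }
  if (GEO_PREDICTOR %in% predictors) {
    dvec <- spt$distance_km
    if (length(unique(dvec)) < 3L) dropped <- c(dropped, GEO_PREDICTOR)
    else {
      b <- ispline_basis(dvec, n_splines)
      blocks[[GEO_PREDICTOR]] <- eval_ispline(b, dvec)
      bases[[GEO_PREDICTOR]] <- b
      cols <- c(cols, rep(GEO_PREDICTOR, n_splines))
    }
  }
  if (length(dropped))
    warning("dropping predictor(s) with fewer than 3 distinct values: ",
            paste(dropped, collapse = ", "))
  X <- if (length(blocks)) do.call(cbind, blocks[unique(cols)]) else
    matrix(0, nrow(spt), 0L)
  list(X = X, bases = bases, cols = cols)
}

gdm_deviance <- function(d, mu) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  t1 <- ifelse(d > 0, d * log(d / mu), 0)
  t2 <- ifelse(d < 1, (1 - d) * log((1 - d) / (1 - mu)), 0)
  2 * sum(t1 + t2)
}

## One weighted NNLS step on the normal equations: minimizes
## ||sqrt(W)(z - Xf b)|| over b >= 0 via a Cholesky factor of Xf'WXf.
nnls_step <- function(Xf, w, z) {
  M <- crossprod(Xf, Xf * w)
  v <- crossprod(Xf, w * z)
  M <- M + diag(1e-10 * (mean(diag(M)) + 1), ncol(M))
  R <- chol(M)
  b <- forwardsolve(t(R), v)
  as.vector(pracma::lsqnonneg(R, as.vector(b))$x)
}

fit_gdm_design <- function(X, d, max_iter = 200L, tol = 1e-8) {
  Xf <- cbind(`(Intercept)` = 1, X)
  mu <- pmin(pmax(d, 0.02), 0.98)
  eta <- -log(1 - mu)
  beta <- NULL
  dev <- gdm_deviance(d, mu)
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- (1 - mu) / mu
    z <- eta + (d - mu) / (1 - mu)
    beta_new <- nnls_step(Xf, w, z)
    ## step-halving guards the IRLS against deviance increases
    step <- 1
    repeat {
      beta_try <- if (is.null(beta)) beta_new else
        beta + step * (beta_new - beta)
      eta_try <- as.vector(Xf %*% beta_try)
      dev_try <- gdm_deviance(d, 1 - exp(-eta_try))
      if (dev_try <= dev + 1e-12 || step < 1e-4 || is.null(beta)) break
      step <- step / 2
    }
    beta <- beta_try
    eta <- eta_try
    mu <- pmin(pmax(1 - exp(-eta), 1e-10), 1 - 1e-10)
    rel <- abs(dev - dev_try) / (abs(dev_try) + 0.1)
    dev <- dev_try
    trace <- c(trace, dev)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 5L)
    stop("GDM fit did not converge in ", max_iter,
         " iterations; last deviances: ",
         paste(format(utils::tail(trace, 5L), digits = 8), collapse = ", "))
  list(beta = beta, eta = eta, deviance = dev, n_iter = length(trace),
       converged = converged)
}

#' Fit a generalized dissimilarity model
#'
#' Regresses observed pairwise dissimilarity \eqn{d} on monotone I-spline
#' transforms of the predictors through
#' \eqn{\mu = 1 - \exp(-\eta)}, \eqn{\eta = a_0 + \sum_{p,k} w_{p,k}
#' x_{p,k}}, with every coefficient (including the intercept)
#' constrained non-negative, by iteratively reweighted non-negative
#' least squares on the binomial-form deviance. Environmental predictors
#' enter as \eqn{|I_k(x_1) - I_k(x_2)|}; geographic distance (predictor
#' name \code{"geographic_distance"}) as \eqn{I_k} of the distance
#' itself. The null deviance comes from the intercept-only fit, and
#' \code{deviance_explained = 100 (1 - D_model / D_null)}.
#'
#' @param spt a \code{site_pair_table} from [build_site_pairs()].
#' @param predictors predictors to include; default all environmental
#'   predictors in the table plus \code{"geographic_distance"}.
#' @param n_splines I-splines per predictor (default 3).
#' @param max_iter,tol IRLS controls: stop when the relative deviance
#'   change drops below \code{tol} (default 1e-8) or after
#'   \code{max_iter} iterations (non-convergence is an error carrying
#'   the deviance trace).
#' @return An object of class \code{gdm_model}: intercept, per-predictor
#'   coefficient matrix and knots, deviances, percentage of deviance
#'   explained, fitted values.
#' @export
fit_gdm <- function(spt, predictors = NULL, n_splines = 3L,
                    max_iter = 200L, tol = 1e-8) {
  if (is.null(predictors))
    predictors <- c(attr(spt, "predictors"), GEO_PREDICTOR)
  des <- build_design(spt, predictors, n_splines)
  d <- spt$dissimilarity
  null_fit <- fit_gdm_design(matrix(0, length(d), 0L), d,
                             max_iter = max_iter, tol = tol)
  fit <- if (ncol(des$X)) fit_gdm_design(des$X, d, max_iter, tol) else null_fit
  used <- unique(des$cols)
  coef_mat <- if (length(used))
    matrix(fit$beta[-1L], nrow = n_splines,
           dimnames = list(paste0("spline", seq_len(n_splines)), used))
  else matrix(0, n_splines, 0L)
  structure(list(
    intercept = fit$beta[1L],
    coefficients = coef_mat,
    bases = des$bases,
    predictors = used,
    requested = predictors,
    n_splines = n_splines,
    null_deviance = null_fit$deviance,
    model_deviance = fit$deviance,
    ## a vanishing null deviance (constant dissimilarity) leaves nothing
    ## to explain
    deviance_explained = if (null_fit$deviance < 1e-8) 0 else
      100 * (1 - fit$deviance / null_fit$deviance),
    fitted = 1 - exp(-fit$eta),
    eta = fit$eta,
    observed = d,
    n_pairs = length(d),
    n_iter = fit$n_iter,
    converged = fit$converged,
    intercept_only = length(used) == 0L
  ), class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat("Generalized dissimilarity model\n")
  cat(sprintf("  %d site pairs, %d predictor(s), %d I-splines each\n",
              x$n_pairs, length(x$predictors), x$n_splines))
  cat(sprintf("  null deviance:  %.3f\n", x$null_deviance))
  cat(sprintf("  model deviance: %.3f\n", x$model_deviance))
  cat(sprintf("  deviance explained: %.1f%%\n", x$deviance_explained))
  if (length(x$predictors)) {
    cat("  importance (I-spline coefficient sums):\n")
    print(round(sort(variable_importance(x), decreasing = TRUE), 3))
  } else cat("  intercept-only model\n")
  invisible(x)
}

#' Predict dissimilarity from a fitted model
#'
#' @param object a \code{gdm_model}.
#' @param newdata optional \code{site_pair_table}; default the training
#'   pairs.
#' @param ... unused.
#' @return Predicted dissimilarities in [0, 1).
#' @export
predict.gdm_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  qv <- attr(newdata, "quadrat_values")
  idx <- attr(newdata, "pair_idx")
  eta <- rep(object$intercept, nrow(newdata))
  for (p in object$predictors) {
    b <- object$bases[[p]]
    wk <- object$coefficients[, p]
    if (p == GEO_PREDICTOR) {
      eta <- eta + as.vector(eval_ispline(b, newdata$distance_km) %*% wk)
    } else {
      Tq <- eval_ispline(b, qv[, p])
      eta <- eta + as.vector(abs(Tq[idx[, 1L], , drop = FALSE] -
                                 Tq[idx[, 2L], , drop = FALSE]) %*% wk)
    }
  }
  1 - exp(-eta)
}

#' Predictor importance as the I-spline coefficient sum
#'
#' A predictor's importance is the sum of its fitted I-spline
#' coefficients — the height its partial ecological-distance curve
#' reaches at the predictor's maximum, i.e. the total turnover
#' attributable to that predictor holding the others constant.
#'
#' @param model a \code{gdm_model}.
#' @return Named numeric vector of importances.
#' @export
variable_importance <- function(model) {
  if (!length(model$predictors))
    return(stats::setNames(numeric(0), character(0)))
  colSums(model$coefficients)
}

#' Partial ecological-distance curves
#'
#' Evaluates each predictor's fitted monotone transform
#' \eqn{f_p(x) = \sum_k w_{p,k} I_k(x)} on a grid over its observed
#' range; \eqn{f_p} is non-decreasing, 0 at the range minimum, and
#' reaches the predictor's importance at the maximum.
#'
#' @param model a \code{gdm_model}.
#' @param n_grid grid points per predictor.
#' @return Long data.frame: \code{predictor}, \code{x},
#'   \code{partial_distance}.
#' @export
spline_curves <- function(model, n_grid = 200L) {
  if (!length(model$predictors))
    return(data.frame(predictor = character(0), x = numeric(0),
                      partial_distance = numeric(0)))
  rows <- lapply(model$predictors, function(p) {
    b <- model$bases[[p]]
    x <- seq(b$knots[1L], b$knots[length(b$knots)], length.out = n_grid)
    f <- as.vector(eval_ispline(b, x) %*% model$coefficients[, p])
    data.frame(predictor = p, x = x, partial_distance = f)
  })
  do.call(rbind, rows)
}

## Permute quadrat-level information for one predictor and return the
## permuted design block. Permuting quadrat labels leaves the pooled
## value set (and hence the knots) unchanged, so only the pair-level
## arrangement moves.
permuted_block <- function(spt, predictor, basis, perm) {
  idx <- attr(spt, "pair_idx")
  if (predictor == GEO_PREDICTOR) {
    dmat <- attr(spt, "dist_mat")
    dvec <- dmat[cbind(perm[idx[, 1L]], perm[idx[, 2L]])]
    eval_ispline(basis, dvec)
  } else {
    v <- attr(spt, "quadrat_values")[, predictor][perm]
    Tq <- eval_ispline(basis, v)
    abs(Tq[idx[, 1L], , drop = FALSE] - Tq[idx[, 2L], , drop = FALSE])
  }
}

#' Permutation significance of one predictor in a GDM
#'
#' Shuffles the predictor's quadrat-level values across quadrats (for
#' geographic distance, shuffles the quadrat coordinates), rebuilds that
#' predictor's pair design columns, refits, and records the permuted
#' model's deviance explained. The p-value is
#' \eqn{(1 + \#\{D^{perm}_{expl} \ge D^{obs}_{expl}\}) / (n_{perm} + 1)}.
#' Quadrats, not pair rows, are the exchangeable units: permuting pair
#' rows would break the pair structure shared with the other predictors.
#'
#' @param spt a \code{site_pair_table}.
#' @param predictor name of the predictor to test (may be
#'   \code{"geographic_distance"}).
#' @param predictors the predictor set defining the model under test;
#'   default all predictors in the table plus geographic distance.
#' @param n_perm number of permutations (default 500).
#' @param seed integer seed for the permutation stream.
#' @param n_splines,max_iter,tol passed to the fitter.
#' @return List: \code{p_value}, \code{observed} (deviance explained),
#'   \code{permuted} (vector of permuted deviance-explained values).
#' @export
permutation_significance <- function(spt, predictor, predictors = NULL,
                                     n_perm = 500L, seed = NULL,
                                     n_splines = 3L, max_iter = 200L,
                                     tol = 1e-8) {
  if (is.null(predictors))
    predictors <- c(attr(spt, "predictors"), GEO_PREDICTOR)
  if (!predictor %in% predictors)
    stop("'", predictor, "' is not in the model's predictor set")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  des <- build_design(spt, predictors, n_splines)
  if (!predictor %in% des$cols)
    stop("predictor '", predictor, "' was dropped during basis construction")
  d <- spt$dissimilarity
  null_dev <- fit_gdm_design(matrix(0, length(d), 0L), d,
                             max_iter = max_iter, tol = tol)$deviance
  obs_fit <- fit_gdm_design(des$X, d, max_iter, tol)
  observed <- 100 * (1 - obs_fit$deviance / null_dev)
  target_cols <- which(des$cols == predictor)
  n_q <- nrow(attr(spt, "quadrat_values"))
  permuted <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(n_q)
    Xp <- des$X
    Xp[, target_cols] <- permuted_block(spt, predictor,
                                        des$bases[[predictor]], perm)
    100 * (1 - fit_gdm_design(Xp, d, max_iter, tol)$deviance / null_dev)
  }, numeric(1L))
  list(p_value = (1 + sum(permuted >= observed)) / (n_perm + 1),
       observed = observed, permuted = permuted)
}

#' Backward elimination of GDM predictors by permutation testing
#'
#' Starting from the full predictor set, repeatedly tests every current
#' predictor by permutation; while any predictor has \eqn{p \ge \alpha},
#' the one with the largest p (ties broken by smallest importance) is
#' dropped and the model refitted, until every retained predictor is
#' significant. If everything is eliminated an intercept-only model is
#' returned, flagged.
#'
#' @param spt a \code{site_pair_table}.
#' @param predictors starting predictor set; default all plus geographic
#'   distance.
#' @param alpha retention threshold on the permutation p-value
#'   (default 0.05).
#' @param n_perm permutations per test (default 500).
#' @param seed integer seed; the full elimination uses one permutation
#'   stream, so results are reproducible.
#' @param n_splines,max_iter,tol passed to the fitter.
#' @return The final \code{gdm_model}, with components
#'   \code{elimination_log} (data.frame: step, predictor, p_value,
#'   importance, action) and \code{p_values} (retained predictors).
#' @export
backward_eliminate <- function(spt, predictors = NULL, alpha = 0.05,
                               n_perm = 500L, seed = NULL, n_splines = 3L,
                               max_iter = 200L, tol = 1e-8) {
  if (is.null(predictors))
    predictors <- c(attr(spt, "predictors"), GEO_PREDICTOR)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  current <- predictors
  log_rows <- list(); step <- 0L
  repeat {
    model <- fit_gdm(spt, current, n_splines, max_iter, tol)
    current <- model$predictors       # constant predictors fall out here
    if (!length(current)) {
      model$intercept_only <- TRUE
      break
    }
    step <- step + 1L
    imp <- variable_importance(model)
    pvals <- vapply(current, function(p)
      permutation_significance(spt, p, predictors = current,
                               n_perm = n_perm, seed = NULL,
                               n_splines = n_splines, max_iter = max_iter,
                               tol = tol)$p_value, numeric(1L))
    if (all(pvals < alpha)) {
      log_rows[[step]] <- data.frame(step = step, predictor = current,
                                     p_value = unname(pvals),
                                     importance = unname(imp[current]),
                                     action = "retain")
      model$p_values <- pvals
      break
    }
    worst <- current[pvals == max(pvals)]
    if (length(worst) > 1L) worst <- worst[which.min(imp[worst])]
    log_rows[[step]] <- data.frame(step = step, predictor = worst,
                                   p_value = unname(pvals[worst]),
                                   importance = unname(imp[worst]),
                                   action = "drop")
    current <- setdiff(current, worst)
    if (!length(current)) {
      model <- fit_gdm(spt, character(0), n_splines, max_iter, tol)
      model$intercept_only <- TRUE
      model$p_values <- stats::setNames(numeric(0), character(0))
      break
    }
  }
  model$elimination_log <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(step = integer(0), predictor = character(0),
                    p_value = numeric(0), importance = numeric(0),
                    action = character(0))
  model
}

#' Deviance partitioning among geography, climate and soil
#'
#' Fits the seven models on the non-empty subsets of the three predictor
#' groups (G = geographic distance, C = climate, S = soil) and splits the
#' full model's percentage of deviance explained into independent and
#' shared fractions by inclusion-exclusion: e.g. the independent G
#' fraction is \eqn{D(GCS) - D(CS)}, the three-way shared fraction is
#' \eqn{\sum D(single) - \sum D(pair) + D(GCS)}. The seven fractions sum
#' to the full model's deviance explained by construction; individual
#' shared fractions can be negative and are reported as computed.
#'
#' @param spt a \code{site_pair_table}.
#' @param groups named list with elements \code{G}, \code{C}, \code{S}
#'   giving the predictor names in each group; default G =
#'   geographic distance and C/S from the table's group map.
#' @param n_splines,max_iter,tol passed to the fitter.
#' @return List of class \code{deviance_partition}: \code{fractions}
#'   (named: G, C, S, GC, GS, CS, GCS), \code{total} (full-model
#'   deviance explained), \code{subset_deviance_explained} (the seven
#'   fitted values).
#' @export
deviance_partition <- function(spt, groups = NULL, n_splines = 3L,
                               max_iter = 200L, tol = 1e-8) {
  gm <- attr(spt, "group_map")
  if (is.null(groups))
    groups <- list(G = GEO_PREDICTOR,
                   C = names(gm)[gm == "climate"],
                   S = names(gm)[gm == "soil"])
  if (!all(c("G", "C", "S") %in% names(groups)))
    stop("groups must name elements G, C and S")
  empty <- names(groups)[!vapply(groups, length, integer(1L))]
  if (length(empty))
    stop("empty predictor group(s): ", paste(empty, collapse = ", "))
  subsets <- list(G = "G", C = "C", S = "S", GC = c("G", "C"),
                  GS = c("G", "S"), CS = c("C", "S"), GCS = c("G", "C", "S"))
  dev <- vapply(subsets, function(s) {
    preds <- unique(unlist(groups[s]))
    m <- tryCatch(fit_gdm(spt, preds, n_splines, max_iter, tol),
                  error = function(e) NULL)
    if (is.null(m)) { warning("sub-model on {", paste(s, collapse = ","),
                              "} failed; deviance explained taken as 0"); 0 }
    else m$deviance_explained
  }, numeric(1L))
  fr <- c(G = dev[["GCS"]] - dev[["CS"]],
          C = dev[["GCS"]] - dev[["GS"]],
          S = dev[["GCS"]] - dev[["GC"]])
  gcs <- dev[["G"]] + dev[["C"]] + dev[["S"]] -
         dev[["GC"]] - dev[["GS"]] - dev[["CS"]] + dev[["GCS"]]
  fr <- c(fr,
          GC = dev[["GCS"]] - dev[["S"]] - fr[["G"]] - fr[["C"]],
          GS = dev[["GCS"]] - dev[["C"]] - fr[["G"]] - fr[["S"]],
          CS = dev[["GCS"]] - dev[["G"]] - fr[["C"]] - fr[["S"]],
          GCS = gcs)
  structure(list(fractions = fr, total = dev[["GCS"]],
                 subset_deviance_explained = dev),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat("Deviance partition (% of null deviance)\n")
  print(round(x$fractions, 2))
  cat(sprintf("  total explained: %.2f%% (fractions sum to %.2f%%)\n",
              x$total, sum(x$fractions)))
  invisible(x)
}
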
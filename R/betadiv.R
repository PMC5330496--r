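## Pairwise and multiple-site incidence dissimilarities and their
## decompositions. All counts are kept as exact integers until the final
## division, so results do not depend on summation order.

#' Shared and unique taxon counts for a quadrat pair
#'
#' @param x_i,x_j equal-length binary incidence vectors.
#' @return A list with integer components \code{a} (shared taxa),
#'   \code{b} (taxa only in \code{x_i}) and \code{c} (taxa only in
#'   \code{x_j}).
#' @export
pair_components <- function(x_i, x_j) {
  if (length(x_i) != length(x_j)) stop("incidence vectors differ in length")
  x_i <- as.integer(x_i > 0); x_j <- as.integer(x_j > 0)
  list(a = sum(x_i & x_j), b = sum(x_i & !x_j), c = sum(!x_i & x_j))
}

check_nonempty_pair <- function(pc) {
  if (pc$a + pc$b + pc$c == 0L)
    stop("dissimilarity undefined for a pair of empty quadrats (a + b + c = 0)")
}

#' Pairwise Sorensen dissimilarity
#'
#' \deqn{\beta_{sor} = (b + c) / (2a + b + c)}
#'
#' @param pc a pair-component list from [pair_components()].
#' @return Dissimilarity in [0, 1].
#' @export
sorensen_pair <- function(pc) {
  check_nonempty_pair(pc)
  (pc$b + pc$c) / (2 * pc$a + pc$b + pc$c)
}

#' Pairwise Jaccard dissimilarity
#'
#' \deqn{\beta_{jac} = (b + c) / (a + b + c)}
#'
#' @inheritParams sorensen_pair
#' @return Dissimilarity in [0, 1].
#' @export
jaccard_pair <- function(pc) {
  check_nonempty_pair(pc)
  (pc$b + pc$c) / (pc$a + pc$b + pc$c)
}

#' Pairwise Simpson dissimilarity
#'
#' The richness-independent turnover component,
#' \eqn{\min(b,c) / (a + \min(b,c))}.
#'
#' @inheritParams sorensen_pair
#' @return Dissimilarity in [0, 1].
#' @export
simpson_pair <- function(pc) {
  check_nonempty_pair(pc)
  m <- min(pc$b, pc$c)
  if (pc$a + m == 0L) return(1)   # disjoint non-empty pair
  m / (pc$a + m)
}

#' Turnover/nestedness decomposition of pairwise Sorensen dissimilarity
#'
#' Splits Sorensen dissimilarity into a richness-independent spatial
#' turnover component (Simpson dissimilarity, species replacement) and a
#' nestedness-resultant remainder.
#'
#' @inheritParams sorensen_pair
#' @return List with \code{beta_sim} and \code{beta_nes};
#'   \code{beta_sim + beta_nes} equals [sorensen_pair()].
#' @export
baselga_pair_decomposition <- function(pc) {
  bsim <- simpson_pair(pc)
  list(beta_sim = bsim, beta_nes = sorensen_pair(pc) - bsim)
}

#' Replacement/richness-difference decomposition of Jaccard dissimilarity
#'
#' The alternative split of pairwise dissimilarity: relativized species
#' replacement \eqn{2\min(b,c)/(a+b+c)} plus absolute richness difference
#' \eqn{|b-c|/(a+b+c)}; the two sum exactly to Jaccard dissimilarity.
#' The Jaccard-family denominator is used; the Sorensen-family form
#' (denominator \eqn{2a+b+c}) differs only by that constant choice.
#'
#' @inheritParams sorensen_pair
#' @return List with \code{replacement} and \code{richness_difference}.
#' @export
podani_pair_decomposition <- function(pc) {
  check_nonempty_pair(pc)
  n <- pc$a + pc$b + pc$c
  repl <- 2 * min(pc$b, pc$c) / n
  ## complement of the same division, so the decomposition identity
  ## repl + richdiff == Jaccard holds to the last bit
  list(replacement = repl,
       richness_difference = (pc$b + pc$c) / n - repl)
}

## Integer building blocks of the multiple-site measures: for incidence
## matrix X, A = X X^T gives shared counts, b_ij = S_i - a_ij.
multisite_sums <- function(x) {
  x <- unclass(x)
  storage.mode(x) <- "integer"
  n <- nrow(x)
  S <- rowSums(x)
  ST <- sum(colSums(x) > 0L)
  A <- tcrossprod(x)                 # a_ij
  bij <- matrix(S, n, n) - A         # taxa in i not in j
  bji <- t(bij)
  ut <- upper.tri(bij)
  list(n = n,
       sum_S = sum(S),
       S_T = ST,
       sum_min = sum(pmin(bij[ut], bji[ut])),
       sum_max = sum(pmax(bij[ut], bji[ut])))
}

#' Multiple-site Sorensen dissimilarity and its decomposition
#'
#' Computes the multiple-site Sorensen dissimilarity over all quadrats at
#' once and decomposes it into a richness-independent spatial turnover
#' component (multiple-site Simpson) and a nestedness-resultant component:
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
#'   {(\sum_i S_i - S_T) + \sum_{i<j}\min(b_{ij},b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum\min + \sum\max}
#'   {2(\sum_i S_i - S_T) + \sum\min + \sum\max}}
#' with \eqn{\beta_{NES} = \beta_{SOR} - \beta_{SIM}}; \eqn{S_i} is the
#' richness of quadrat \eqn{i}, \eqn{S_T} the pooled richness and
#' \eqn{b_{ij}} the number of taxa present in \eqn{i} but not \eqn{j}.
#'
#' @param cm a \code{community_matrix} (or plain binary matrix) restricted
#'   to the quadrat set of interest; every quadrat must be non-empty (see
#'   [drop_empty_quadrats()]).
#' @return A list of class \code{multisite_beta} with \code{beta_sor},
#'   \code{beta_sim}, \code{beta_nes} and \code{n_sites}.
#' @export
multisite_sorensen_family <- function(cm) {
  if (nrow(cm) < 2L) stop("multiple-site dissimilarity needs at least 2 quadrats")
  if (any(rowSums(cm) == 0L))
    stop("empty quadrat(s) present; drop them first (drop_empty_quadrats)")
  ms <- multisite_sums(cm)
  nest <- ms$sum_S - ms$S_T          # sum over taxa of (occurrences - 1)
  denom_sim <- nest + ms$sum_min
  beta_sim <- if (denom_sim == 0L) 0 else ms$sum_min / denom_sim
  denom_sor <- 2 * nest + ms$sum_min + ms$sum_max
  beta_sor <- if (denom_sor == 0L) 0 else (ms$sum_min + ms$sum_max) / denom_sor
  structure(list(beta_sor = beta_sor, beta_sim = beta_sim,
                 beta_nes = beta_sor - beta_sim, n_sites = ms$n),
            class = "multisite_beta")
}

#' Multiple-site Jaccard dissimilarity and its decomposition
#'
#' The Jaccard-family analogue of [multisite_sorensen_family()]:
#' \eqn{\beta_{JTU}} (turnover), \eqn{\beta_{JAC}} and
#' \eqn{\beta_{JNE} = \beta_{JAC} - \beta_{JTU}}.
#'
#' @inheritParams multisite_sorensen_family
#' @return A list of class \code{multisite_beta} with \code{beta_jac},
#'   \code{beta_jtu}, \code{beta_jne} and \code{n_sites}.
#' @export
multisite_jaccard_family <- function(cm) {
  if (nrow(cm) < 2L) stop("multiple-site dissimilarity needs at least 2 quadrats")
  if (any(rowSums(cm) == 0L))
    stop("empty quadrat(s) present; drop them first (drop_empty_quadrats)")
  ms <- multisite_sums(cm)
  nest <- ms$sum_S - ms$S_T
  denom_jtu <- nest + 2 * ms$sum_min
  beta_jtu <- if (denom_jtu == 0L) 0 else 2 * ms$sum_min / denom_jtu
  denom_jac <- nest + ms$sum_min + ms$sum_max
  beta_jac <- if (denom_jac == 0L) 0 else (ms$sum_min + ms$sum_max) / denom_jac
  structure(list(beta_jac = beta_jac, beta_jtu = beta_jtu,
                 beta_jne = beta_jac - beta_jtu, n_sites = ms$n),
            class = "multisite_beta")
}

#' @export
print.multisite_beta <- function(x, ...) {
  vals <- unlist(x[names(x) != "n_sites"])
  cat("Multiple-site dissimilarity over", x$n_sites, "quadrats:\n")
  print(round(vals, 4))
  invisible(x)
}

#' Whittaker's effective species turnover
#'
#' \deqn{\beta_{W-1} = \gamma/\bar\alpha - 1} where \eqn{\gamma} is the
#' pooled richness of the quadrat set and \eqn{\bar\alpha} the mean
#' quadrat richness: the number of complete effective species turnovers
#' among the quadrats.
#'
#' @inheritParams multisite_sorensen_family
#' @return List with \code{gamma}, \code{alpha_bar} and
#'   \code{beta_w_minus1}.
#' @export
whittaker_beta <- function(cm) {
  alpha_bar <- mean(rowSums(cm))
  if (alpha_bar == 0) stop("all quadrats empty; beta_W-1 undefined")
  gamma <- sum(colSums(cm) > 0L)
  list(gamma = gamma, alpha_bar = alpha_bar,
       beta_w_minus1 = gamma / alpha_bar - 1)
}

#' Pairwise dissimilarity matrix
#'
#' @param cm a \code{community_matrix}; empty quadrats are rejected.
#' @param metric one of \code{"sorensen"}, \code{"jaccard"},
#'   \code{"simpson"}.
#' @return A symmetric matrix with zero diagonal and values in [0, 1],
#'   quadrat ids as dimnames.
#' @export
dissimilarity_matrix <- function(cm, metric = c("sorensen", "jaccard", "simpson")) {
  metric <- match.arg(metric)
  if (nrow(cm) < 2L) stop("need at least 2 quadrats")
  if (any(rowSums(cm) == 0L))
    stop("empty quadrat(s) present; drop them first (drop_empty_quadrats)")
  x <- unclass(cm); storage.mode(x) <- "integer"
  S <- rowSums(x)
  A <- tcrossprod(x)
  B <- matrix(S, nrow(x), nrow(x)) - A   # b_ij
  C <- t(B)
  d <- switch(metric,
    sorensen = (B + C) / (2 * A + B + C),
    jaccard  = (B + C) / (A + B + C),
    simpson  = {
      m <- pmin(B, C)
      out <- m / (A + m)
      out[A + m == 0] <- 1           # disjoint non-empty pairs
      out
    })
  diag(d) <- 0
  dimnames(d) <- list(rownames(cm), rownames(cm))
  d
}
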
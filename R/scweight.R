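# Single-cell integration: per-cell-type gene activity in [0,1], geometric
# mean edge weights, and a two-component Gaussian mixture on the edge weight
# distribution whose posterior-0.5 crossing separates weak from retained
# interactions, per cell type.

#' Gene activity per cell type
#'
#' Expression is library-size normalized per cell and log1p transformed; the
#' per-type mean is z-scored across cell types per gene and min-max rescaled
#' to [0,1]. Genes constant across types get activity 0 and a flag. Cell
#' types with fewer than `min_cells` cells are excluded.
#'
#' @param sc_expr cells x genes matrix of non-negative expression.
#' @param cell_labels factor/character of length nrow(sc_expr).
#' @param min_cells minimum cells per retained type.
#' @return list of class `ActivityMatrix` with `activity` (genes x types),
#'   `flagged` (zero-variance genes), `excluded_types`.
#' @export
gene_activity <- function(sc_expr, cell_labels, min_cells = 10L) {
  sc_expr <- as.matrix(sc_expr)
  cell_labels <- as.character(cell_labels)
  stopifnot(length(cell_labels) == nrow(sc_expr))
  sizes <- table(cell_labels)
  excluded <- names(sizes)[sizes < min_cells]
  keep_types <- setdiff(names(sizes), excluded)
  if (length(keep_types) < 2L) stop("need >= 2 cell types with >= ", min_cells, " cells")
  keep <- cell_labels %in% keep_types
  x <- sc_expr[keep, , drop = FALSE]
  lab <- cell_labels[keep]
  lib <- rowSums(x)
  lib[lib == 0] <- 1
  xn <- log1p(x / lib * median(rowSums(x)))
  means <- vapply(keep_types, function(t)
    colMeans(xn[lab == t, , drop = FALSE]), numeric(ncol(xn)))
  # genes x types: z-score then min-max rescale per gene
  mu <- rowMeans(means)
  s <- apply(means, 1L, sd)
  flagged <- colnames(sc_expr)[s == 0 | !is.finite(s)]
  z <- (means - mu) / ifelse(s > 0, s, 1)
  rng_min <- apply(z, 1L, min)
  rng <- apply(z, 1L, max) - rng_min
  act <- (z - rng_min) / ifelse(rng > 0, rng, 1)
  act[flagged, ] <- 0
  structure(list(activity = act, flagged = flagged,
                 excluded_types = excluded), class = "ActivityMatrix")
}

#' Weight network edges by endpoint activity in one cell type
#'
#' w = sqrt(a_i * a_j), the geometric mean of the endpoint activities
#' (symmetric, in [0,1], zero when either endpoint is inactive). Arithmetic
#' mean and minimum are available for sensitivity analysis. Edges with an
#' endpoint absent from the activity matrix get NA and are excluded from
#' mixture fitting.
#'
#' @param edges an [edge_list()] (e.g. `grn$edges`).
#' @param activity an `ActivityMatrix` from [gene_activity()].
#' @param cell_type column of the activity matrix.
#' @param combine "geometric", "mean", or "min".
#' @return the edge list with a `weight` column for this cell type.
#' @export
weight_edges <- function(edges, activity, cell_type,
                         combine = c("geometric", "mean", "min")) {
  combine <- match.arg(combine)
  a <- activity$activity
  if (!cell_type %in% colnames(a)) stop("unknown cell type: ", cell_type)
  ai <- a[match(edges$node_a, rownames(a)), cell_type]
  aj <- a[match(edges$node_b, rownames(a)), cell_type]
  w <- switch(combine, geometric = sqrt(ai * aj), mean = (ai + aj) / 2,
              min = pmin(ai, aj))
  out <- edges
  out$weight <- as.numeric(w)
  out
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Initialized from k-means (k = 2) under the given seed; components are
#' ordered mu1 < mu2 and convergence is declared when the log-likelihood
#' improves by less than `tol`. A degenerate component (sigma < 1e-6)
#' triggers one jittered restart; a second failure returns
#' `converged = FALSE`.
#'
#' @param values numeric vector (>= 50 finite values).
#' @param seed integer seed for initialization.
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance.
#' @return list of class `MixtureFit`: pi1, pi2, mu1, mu2, sigma1, sigma2,
#'   loglik (trace), converged, n_points.
#' @export
fit_gmm2 <- function(values, seed = 1L, max_iter = 1000L, tol = 1e-8) {
  x <- values[is.finite(values)]
  if (length(x) < 50L) stop("need >= 50 finite values for a mixture fit")
  set.seed(seed)
  run_em <- function(mu, sg, pi1) {
    trace <- numeric(0L)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- pi1 * dnorm(x, mu[1L], sg[1L])
      d2 <- (1 - pi1) * dnorm(x, mu[2L], sg[2L])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
      g1 <- d1 / tot
      n1 <- sum(g1); n2 <- length(x) - n1
      if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
      mu <- c(sum(g1 * x) / n1, sum((1 - g1) * x) / n2)
      sg <- sqrt(c(sum(g1 * (x - mu[1L])^2) / n1,
                   sum((1 - g1) * (x - mu[2L])^2) / n2))
      if (any(sg < 1e-6)) return(NULL)
      pi1 <- n1 / length(x)
    }
    list(mu = mu, sg = sg, pi1 = pi1, trace = trace, converged = converged)
  }
  km <- kmeans(x, centers = 2L, nstart = 5L)
  ord <- order(km$centers)
  mu0 <- as.numeric(km$centers[ord])
  sg0 <- pmax(vapply(ord, function(c) sd(x[km$cluster == c]), numeric(1L)),
              1e-3, na.rm = TRUE)
  sg0[!is.finite(sg0)] <- sd(x) / 2
  pi0 <- mean(km$cluster == ord[1L])
  fit <- run_em(mu0, sg0, pi0)
  if (is.null(fit)) {
    jit <- sd(x) * 0.25
    fit <- run_em(mu0 + rnorm(2L, 0, jit), rep(sd(x) / 2, 2L), 0.5)
  }
  if (is.null(fit)) {
    return(structure(list(pi1 = NA_real_, pi2 = NA_real_, mu1 = NA_real_,
                          mu2 = NA_real_, sigma1 = NA_real_, sigma2 = NA_real_,
                          loglik = numeric(0L), converged = FALSE,
                          n_points = length(x)), class = "MixtureFit"))
  }
  ord <- order(fit$mu)
  pis <- c(fit$pi1, 1 - fit$pi1)[ord]
  structure(list(pi1 = pis[1L], pi2 = pis[2L],
                 mu1 = fit$mu[ord[1L]], mu2 = fit$mu[ord[2L]],
                 sigma1 = fit$sg[ord[1L]], sigma2 = fit$sg[ord[2L]],
                 loglik = fit$trace, converged = fit$converged,
                 n_points = length(x)), class = "MixtureFit")
}

#' Posterior probability of the lower-mean component
#' @param fit a `MixtureFit`.
#' @param x numeric values.
#' @return posterior P(component 1 | x).
#' @export
posterior_lower <- function(fit, x) {
  d1 <- fit$pi1 * dnorm(x, fit$mu1, fit$sigma1)
  d2 <- fit$pi2 * dnorm(x, fit$mu2, fit$sigma2)
  d1 / (d1 + d2)
}

#' Weak-interaction threshold from a mixture fit
#'
#' The threshold is the smallest crossing in [mu1, mu2] where the posterior
#' of the lower-mean component equals 0.5; edges with posterior > 0.5 are
#' weak and discarded (the boundary itself is retained). When the components
#' are not separated (|mu2 - mu1| < 2 max(sigma)) or the fit did not
#' converge, no threshold is set and all edges are kept, flagged.
#'
#' @param fit a `MixtureFit`.
#' @return list with `threshold` (numeric or NA), `separated`, `keep_all`.
#' @export
threshold_from_fit <- function(fit) {
  if (!isTRUE(fit$converged))
    return(list(threshold = NA_real_, separated = FALSE, keep_all = TRUE))
  if (abs(fit$mu2 - fit$mu1) < 2 * max(fit$sigma1, fit$sigma2))
    return(list(threshold = NA_real_, separated = FALSE, keep_all = TRUE))
  # posterior = 0.5 <=> log(pi1 phi1) = log(pi2 phi2): quadratic in t
  a <- 1 / fit$sigma2^2 - 1 / fit$sigma1^2
  b <- 2 * (fit$mu1 / fit$sigma1^2 - fit$mu2 / fit$sigma2^2)
  cc <- fit$mu2^2 / fit$sigma2^2 - fit$mu1^2 / fit$sigma1^2 +
    2 * log((fit$pi1 * fit$sigma2) / (fit$pi2 * fit$sigma1))
  roots <- if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) numeric(0L) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0L)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[roots >= fit$mu1 & roots <= fit$mu2]
  t <- if (length(roots)) min(roots) else {
    f <- function(v) posterior_lower(fit, v) - 0.5
    if (sign(f(fit$mu1)) != sign(f(fit$mu2)))
      uniroot(f, c(fit$mu1, fit$mu2))$root else NA_real_
  }
  if (is.na(t)) return(list(threshold = NA_real_, separated = FALSE,
                            keep_all = TRUE))
  list(threshold = t, separated = TRUE, keep_all = FALSE)
}

#' Per-cell-type edge weighting and mixture thresholding
#'
#' For every cell type: weight the network's edges by endpoint activity, fit
#' the two-component mixture to the finite weights, derive the posterior-0.5
#' threshold, and record which edges are retained (posterior of the lower
#' component <= 0.5).
#'
#' @param grn a `GRNetwork` from [build_network()].
#' @param activity an `ActivityMatrix`.
#' @param seed base seed; each cell type uses seed + its column index.
#' @param combine weight combination rule (see [weight_edges()]).
#' @return list of class `WeightedGRN`: `weights` (edges x types matrix),
#'   `thresholds` (data.frame per type: threshold, separated, keep_all,
#'   converged), `retained` (logical edges x types), `edges`.
#' @export
per_celltype_filter <- function(grn, activity, seed = 1L,
                                combine = "geometric") {
  types <- colnames(activity$activity)
  if (length(types) < 2L) stop("need >= 2 cell types")
  edges <- grn$edges
  wmat <- matrix(NA_real_, nrow = nrow(edges), ncol = length(types),
                 dimnames = list(edges$edge_id, types))
  ret <- matrix(FALSE, nrow = nrow(edges), ncol = length(types),
                dimnames = dimnames(wmat))
  thr <- data.frame(cell_type = types, threshold = NA_real_,
                    separated = FALSE, keep_all = TRUE, converged = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(types)) {
    we <- weight_edges(edges, activity, types[j], combine = combine)
    wmat[, j] <- we$weight
    finite <- is.finite(we$weight)
    if (sum(finite) >= 50L && sd(we$weight[finite]) > 1e-8) {
      fit <- fit_gmm2(we$weight[finite], seed = seed + j)
      rule <- threshold_from_fit(fit)
      thr$threshold[j] <- rule$threshold
      thr$separated[j] <- rule$separated
      thr$keep_all[j] <- rule$keep_all
      thr$converged[j] <- isTRUE(fit$converged)
      if (rule$keep_all) {
        ret[finite, j] <- TRUE
      } else {
        ret[finite, j] <- posterior_lower(fit, we$weight[finite]) <= 0.5
      }
    } else {
      # degenerate (near-constant) weight distribution: no mixture to fit.
      # All-zero activity retains nothing; a uniformly active type keeps its
      # positive-weight edges, flagged as unseparated.
      ret[finite, j] <- we$weight[finite] > 0
      thr$keep_all[j] <- FALSE
    }
  }
  structure(list(weights = wmat, thresholds = thr, retained = ret,
                 edges = edges), class = "WeightedGRN")
}
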
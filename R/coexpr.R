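# Weighted co-expression network core: correlation (Pearson or biweight
# midcorrelation), soft-threshold selection by scale-free fit, adjacency,
# topological overlap, static-cut module detection, eigengenes/kME, and
# permutation-based module preservation Z statistics.

#' Gene-gene correlation matrix
#'
#' `bicor` is the biweight midcorrelation: observations are weighted by
#' (1 - u^2)^2 for |u| < 1 with u = (x - median) / (9 MAD) (MAD unscaled),
#' which discounts outlying samples. Genes whose MAD is zero cannot be
#' weighted and fall back to Pearson standardization; affected genes are
#' recorded in the `fallback` attribute.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param method "pearson" or "bicor".
#' @return symmetric correlation matrix over the variable genes, with
#'   attributes `method`, `dropped` (zero-variance genes) and `fallback`.
#' @export
correlation_matrix <- function(expr, method = c("pearson", "bicor")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  v <- apply(expr, 1L, var)
  dropped <- rownames(expr)[v == 0 | !is.finite(v)]
  expr <- expr[setdiff(rownames(expr), dropped), , drop = FALSE]
  fallback <- character(0L)
  if (method == "pearson") {
    cc <- cor(t(expr))
  } else {
    z <- t(apply(expr, 1L, function(x) {
      med <- median(x)
      madr <- median(abs(x - med))
      if (madr == 0) return(rep(NA_real_, length(x)))
      u <- (x - med) / (9 * madr)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      (x - med) * w
    }))
    bad <- apply(z, 1L, function(r) anyNA(r) || sum(r^2) == 0)
    fallback <- rownames(expr)[bad]
    if (any(bad)) z[bad, ] <- expr[bad, , drop = FALSE] - rowMeans(expr[bad, , drop = FALSE])
    z <- z / sqrt(rowSums(z^2))
    cc <- tcrossprod(z)
    cc <- pmin(pmax(cc, -1), 1)
  }
  diag(cc) <- 1
  attr(cc, "method") <- method
  attr(cc, "dropped") <- dropped
  attr(cc, "fallback") <- fallback
  cc
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power, connectivity k_i = sum_j |cor_ij|^beta is binned
#' (10 bins) and log10 frequency is regressed on log10 mean connectivity;
#' the signed fit index is -sign(slope) * R^2. The smallest power reaching
#' `r2_target` is chosen; if none does, the argmax power is returned and
#' flagged.
#'
#' @param cor_mat correlation matrix (>= 50 genes).
#' @param powers candidate integer powers.
#' @param r2_target signed R^2 required for scale-free fit.
#' @param n_bins histogram bins for the degree distribution.
#' @return list with `beta`, `fit` (power, r_squared, slope, mean_k), and
#'   `reached_target`.
#' @export
pick_soft_threshold <- function(cor_mat, powers = 1:20, r2_target = 0.8,
                                n_bins = 10L) {
  n <- nrow(cor_mat)
  if (n < 50L) stop("need >= 50 genes for a degree-distribution fit")
  ac <- abs(cor_mat)
  rows <- lapply(powers, function(b) {
    k <- colSums(ac^b) - 1
    if (all(k == 0)) stop("all-zero connectivity at power ", b)
    cuts <- cut(k, breaks = n_bins)
    mean_k <- tapply(k, cuts, mean)
    freq <- tapply(k, cuts, length) / n
    ok <- !is.na(mean_k) & mean_k > 0 & !is.na(freq)
    if (sum(ok) < 3L)
      return(data.frame(power = b, r_squared = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[2L]
    data.frame(power = b, r_squared = -sign(slope) * r2, slope = slope,
               mean_k = mean(k))
  })
  fit <- do.call(rbind, rows)
  hit <- which(!is.na(fit$r_squared) & fit$r_squared >= r2_target)
  if (length(hit)) {
    list(beta = fit$power[hit[1L]], fit = fit, reached_target = TRUE)
  } else {
    list(beta = fit$power[which.max(fit$r_squared)], fit = fit,
         reached_target = FALSE)
  }
}

#' Soft-thresholded adjacency matrix
#'
#' @param cor_mat correlation matrix.
#' @param beta soft-threshold power (>= 1).
#' @param type "unsigned" (|cor|^beta) or "signed" (((1+cor)/2)^beta).
#' @return an adjacency matrix in [0,1] with unit diagonal and attributes
#'   `beta`, `type`.
#' @export
adjacency_matrix <- function(cor_mat, beta, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (beta < 1) stop("beta must be >= 1")
  a <- if (type == "unsigned") abs(cor_mat)^beta else ((1 + cor_mat) / 2)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "type") <- type
  a
}

#' Topological overlap similarity
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_{u != i,j} a_iu a_uj and k_i = sum_{u != i} a_iu; the diagonal
#' is 1. Dissimilarity is 1 - TOM.
#'
#' @param adj adjacency matrix with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adj) {
  a <- as.matrix(adj)
  a2 <- a %*% a
  ell <- a2 - 2 * a            # removes the u = i and u = j terms (diag 1)
  k <- rowSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (ell + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module detection by average-linkage clustering of TOM dissimilarity
#'
#' A static cut of the dendrogram. By default the cut height is placed in
#' the middle of the largest gap between consecutive sorted merge heights:
#' well-separated modules merge internally at low heights and with each
#' other only near the top, so the widest gap separates within-module from
#' between-module merges; a quantile of the heights proved unreliable
#' because it always isolates a fixed number of top merges regardless of
#' how many modules the data contain. Clusters smaller than `min_size` are
#' unassigned (label 0); surviving modules are labeled 1, 2, ... by
#' decreasing size.
#'
#' @param diss_tom dissimilarity matrix (1 - TOM).
#' @param min_size minimum module size.
#' @param cut_height dendrogram cut height; `NULL` for the largest-gap
#'   default.
#' @return named integer vector of module labels (0 = unassigned), with the
#'   `cut_height` used as an attribute.
#' @export
detect_modules <- function(diss_tom, min_size = 30L, cut_height = NULL) {
  if (nrow(diss_tom) < 2L * min_size)
    warning("fewer than 2 * min_size genes; partition may be trivial")
  hc <- hclust(as.dist(diss_tom), method = "average")
  h <- cut_height %||% {
    # within-cluster merges occupy the lower heights; the separating gap is
    # searched above the median so a stray gap between two early merges
    # cannot shatter the tree into singletons
    hs <- sort(hc$height)
    gaps <- diff(hs)
    cand <- which(hs[-length(hs)] >= median(hs))
    i <- cand[which.max(gaps[cand])]
    (hs[i] + hs[i + 1L]) / 2
  }
  raw <- cutree(hc, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- integer(length(raw))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  names(labels) <- rownames(diss_tom)
  attr(labels, "cut_height") <- h
  labels
}

#' Module eigengenes and kME
#'
#' The eigengene of a module is the first right singular vector of its
#' z-scored gene x sample submatrix — the per-sample first principal
#' component — scaled to unit variance and oriented so the mean correlation
#' with its member genes is non-negative. kME is each gene's Pearson
#' correlation with each module eigengene; constant genes are dropped from
#' the SVD and get kME 0.
#'
#' @param expr genes x samples matrix.
#' @param partition named module labels from [detect_modules()].
#' @return list with `eigengenes` (samples x modules), `kme`
#'   (genes x modules), and `dropped` (constant genes).
#' @export
eigengenes_kme <- function(expr, partition) {
  expr <- as.matrix(expr)
  partition <- partition[rownames(expr)]
  mods <- sort(unique(partition[partition > 0]))
  if (!length(mods)) stop("no assigned modules")
  v <- apply(expr, 1L, var)
  dropped <- rownames(expr)[v == 0 | !is.finite(v)]
  eig <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
                dimnames = list(colnames(expr), paste0("ME", mods)))
  for (j in seq_along(mods)) {
    members <- setdiff(names(partition)[partition == mods[j]], dropped)
    x0 <- t(scale(t(expr[members, , drop = FALSE])))
    e <- if (length(members) == 1L) as.numeric(x0) else svd(x0, nu = 0L, nv = 1L)$v[, 1L]
    e <- e / sd(e)
    if (mean(cor(t(expr[members, , drop = FALSE]), e)) < 0) e <- -e
    eig[, j] <- e
  }
  kme <- matrix(0, nrow = nrow(expr), ncol = length(mods),
                dimnames = list(rownames(expr), colnames(eig)))
  ok <- setdiff(rownames(expr), dropped)
  kme[ok, ] <- cor(t(expr[ok, , drop = FALSE]), eig)
  list(eigengenes = eig, kme = kme, dropped = dropped)
}

#' Permutation Z statistics for module preservation
#'
#' For each reference module, observed preservation in the test data is
#' measured as (i) density: the mean off-diagonal intramodular adjacency and
#' (ii) connectivity: the correlation between reference and test intramodular
#' connectivity over the module's genes. Both are compared with `n_perm`
#' random same-size gene sets drawn from the test network, giving
#' Z = (obs - mean_null) / sd_null and Z_summary = (Z_density +
#' Z_connectivity) / 2. Values above 2 are read as evidence of preservation
#' and above 10 as strong evidence.
#'
#' @param ref_expr,test_expr genes x samples matrices; genes shared by name
#'   (map orthologs to reference ids beforehand).
#' @param partition module labels on the reference genes.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation draw.
#' @param beta soft-threshold power used for both networks.
#' @param method correlation method, "bicor" (default) or "pearson".
#' @return data.frame: module, size, Z_density, Z_connectivity, Z_summary,
#'   obs_density, obs_connectivity, n_perm.
#' @export
module_preservation <- function(ref_expr, test_expr, partition, n_perm = 200L,
                                seed = 1L, beta = 6,
                                method = c("bicor", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(rownames(ref_expr), rownames(test_expr))
  ref <- as.matrix(ref_expr)[shared, , drop = FALSE]
  test <- as.matrix(test_expr)[shared, , drop = FALSE]
  aref <- adjacency_matrix(correlation_matrix(ref, method), beta)
  atest <- adjacency_matrix(correlation_matrix(test, method), beta)
  shared <- intersect(rownames(aref), rownames(atest))
  aref <- aref[shared, shared]; atest <- atest[shared, shared]
  # genes without a module label stay in the permutation background
  part <- partition[shared]
  part[is.na(part)] <- 0L
  names(part) <- shared
  mods <- sort(unique(part[part > 0]))
  dens <- function(a, idx) {
    s <- a[idx, idx, drop = FALSE]
    (sum(s) - length(idx)) / (length(idx) * (length(idx) - 1L))
  }
  kim <- function(a, idx) rowSums(a[idx, idx, drop = FALSE]) - 1
  rows <- list()
  for (m in mods) {
    members <- which(part == m)
    if (length(members) < 3L) next
    sz <- length(members)
    # a content-derived stream makes Z independent of module numbering
    set.seed((seed + sum(utf8ToInt(paste(sort(shared[members]),
                                         collapse = "")))) %%
             .Machine$integer.max)
    obs_d <- dens(atest, members)
    obs_c <- suppressWarnings(cor(kim(aref, members), kim(atest, members)))
    null_d <- null_c <- numeric(n_perm)
    kref <- kim(aref, members)
    for (p in seq_len(n_perm)) {
      idx <- sample(length(shared), sz)
      null_d[p] <- dens(atest, idx)
      null_c[p] <- suppressWarnings(cor(kref, kim(atest, idx)))
    }
    null_c[is.na(null_c)] <- 0
    zd <- (obs_d - mean(null_d)) / sd(null_d)
    zc <- (obs_c - mean(null_c)) / sd(null_c)
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, size = sz, Z_density = zd, Z_connectivity = zc,
      Z_summary = (zd + zc) / 2, obs_density = obs_d,
      obs_connectivity = obs_c, n_perm = n_perm)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = integer(), size = integer(), Z_density = numeric(),
               Z_connectivity = numeric(), Z_summary = numeric(),
               obs_density = numeric(), obs_connectivity = numeric(),
               n_perm = integer())
  class(out) <- c("PreservationResult", class(out))
  out
}
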
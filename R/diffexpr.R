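# Differential expression over zonated bulk counts: median-of-ratios size
# factors, CPM filtering, method-of-moments NB dispersion, and a Wald test
# against a fold-change threshold null, as used to call the meristem-specific
# gene set by intersecting the two MZ contrasts.

#' Differential expression configuration
#'
#' @param lfcThreshold composite null boundary: H0 is |log2FC| <= lfcThreshold.
#' @param alpha adjusted-p significance level.
#' @param min_cpm,min_samples retain genes with CPM > `min_cpm` in at least
#'   `min_samples` samples.
#' @param dispersion_floor lower bound for the NB dispersion estimate.
#' @return a list of class `DEConfig`.
#' @export
de_config <- function(lfcThreshold = 1, alpha = 0.05, min_cpm = 1,
                      min_samples = 3L, dispersion_floor = 1e-8) {
  stopifnot(lfcThreshold >= 0, alpha > 0, alpha < 1, dispersion_floor > 0)
  structure(list(lfcThreshold = lfcThreshold, alpha = alpha,
                 min_cpm = min_cpm, min_samples = as.integer(min_samples),
                 dispersion_floor = dispersion_floor), class = "DEConfig")
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over reference genes of the ratio of its count to
#' the gene's geometric mean across samples. Reference genes are rows with
#' strictly positive counts everywhere (the geometric mean is undefined with
#' zeros).
#'
#' @param counts a [count_table()] or integer matrix.
#' @return named numeric vector of per-sample factors.
#' @export
compute_size_factors <- function(counts) {
  m <- unclass(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no gene with all-positive counts; pre-filter low-count genes first")
  lg <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- exp(apply(lg - loggeo, 2L, median))
  setNames(sf, colnames(m))
}

#' Filter genes by counts-per-million support
#'
#' Retains genes with CPM above `min_cpm` in at least `min_samples` samples;
#' CPM is computed on the raw counts against each sample's column total.
#'
#' @param counts a [count_table()].
#' @param config a [de_config()].
#' @return the filtered [count_table()].
#' @export
cpm_filter <- function(counts, config = de_config()) {
  m <- unclass(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) stop("library size must be positive in every sample")
  cpm <- sweep(m, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm > config$min_cpm) >= config$min_samples
  count_table(m[keep, , drop = FALSE])
}

#' Method-of-moments NB dispersion per gene
#'
#' On normalized counts, moments are pooled across within-group residuals:
#' alpha_hat = max(floor, sum_k df_k (s2_k - mu_k) / sum_k df_k mu_k^2) over
#' zones k, so a gene whose zone means differ (a true effect) does not
#' inflate its own dispersion. Constant genes fall to the floor.
#'
#' @param counts a [count_table()].
#' @param design a [sample_design()] (groups = zones).
#' @param size_factors from [compute_size_factors()]; recomputed if `NULL`.
#' @param config a [de_config()].
#' @return named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, design, size_factors = NULL,
                                config = de_config()) {
  design <- check_design(counts, design)
  sf <- size_factors %||% compute_size_factors(counts)
  y <- sweep(unclass(counts), 2L, sf[colnames(counts)], "/")
  groups <- split(seq_len(ncol(y)), design$zone)
  if (any(lengths(groups) < 2L)) stop("each zone needs >= 2 replicates")
  num <- 0; den <- 0
  for (idx in groups) {
    gm <- rowMeans(y[, idx, drop = FALSE])
    dfk <- length(idx) - 1L
    s2k <- rowSums((y[, idx, drop = FALSE] - gm)^2) / dfk
    num <- num + dfk * (s2k - gm)
    den <- den + dfk * gm^2
  }
  a <- num / den
  a[!is.finite(a)] <- config$dispersion_floor
  setNames(pmax(config$dispersion_floor, a), rownames(counts))
}

# Newton solve of the per-group NB mean on the log scale, vectorized over
# genes: finds x = log q with sum_j (y_j - s_j e^x) / (1 + alpha s_j e^x) = 0.
nb_group_fit <- function(y, sf, alpha, iter = 50L) {
  q0 <- rowSums(y) / sum(sf)
  x <- log(pmax(q0, 1e-8))
  for (it in seq_len(iter)) {
    mu <- exp(x) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((y - mu) / denom)
    # -d(score)/dx: mu (1 + alpha y) / (1 + alpha mu)^2 summed over samples
    info <- rowSums(mu * (1 + alpha * y) / denom^2)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    x <- x + step
    if (max(abs(step)) < 1e-10) break
  }
  mu <- exp(x) %o% sf
  fisher <- rowSums(mu / (1 + alpha * mu))
  list(logq = x, se = 1 / sqrt(pmax(fisher, 1e-12)), zero = rowSums(y) == 0)
}

#' NB Wald differential expression against a threshold null
#'
#' Fits a per-gene two-group negative-binomial model with log link and size
#' factor offsets (exact MLE via Newton iteration), then tests the composite
#' null |log2FC| <= lfcThreshold with the doubled one-sided tail of the Wald
#' statistic (|beta_hat| - theta) / se, clamped to p = 1 inside the null
#' region. log2FC is `zoneA` minus `zoneB`.
#'
#' When `dispersions` is not supplied, the across-gene median of the
#' gene-wise method-of-moments estimates is used for every gene: with three
#' replicates per group the gene-wise estimator is noisy enough that plugging
#' it in directly both inflates the type-I error (underestimates) and costs
#' power (overestimates), while the pooled median is stable. The Wald
#' standard error additionally carries the small-sample residual-df
#' correction sqrt(n / (n - 2)) over the n samples of the contrast.
#'
#' @param counts a filtered [count_table()].
#' @param design a [sample_design()].
#' @param contrast length-2 character, e.g. `c("MZ", "EZ")`.
#' @param config a [de_config()].
#' @param size_factors,dispersions optional precomputed values; explicit
#'   `dispersions` are used as given (no moderation).
#' @return a `data.frame` of class `DEResult`: gene_id, baseMean, log2FC,
#'   se_log2FC, wald_stat, p_value, p_adj, flag (up/down/ns).
#' @export
wald_de <- function(counts, design, contrast, config = de_config(),
                    size_factors = NULL, dispersions = NULL) {
  design <- check_design(counts, design)
  stopifnot(length(contrast) == 2L)
  if (!all(contrast %in% design$zone)) stop("contrast zones absent from design")
  sf <- size_factors %||% compute_size_factors(counts)
  sf <- sf[colnames(counts)]
  disp <- dispersions %||% {
    d <- estimate_dispersion(counts, design, sf, config)
    setNames(rep(median(d), length(d)), names(d))
  }
  ia <- which(design$zone == contrast[1L])
  ib <- which(design$zone == contrast[2L])
  if (length(ia) < 2L || length(ib) < 2L) stop("each contrast zone needs >= 2 replicates")
  y <- unclass(counts)
  fa <- nb_group_fit(y[, ia, drop = FALSE], sf[ia], disp)
  fb <- nb_group_fit(y[, ib, drop = FALSE], sf[ib], disp)
  log2fc <- (fa$logq - fb$logq) / log(2)
  n_con <- length(ia) + length(ib)
  se_ln <- sqrt(fa$se^2 + fb$se^2) * sqrt(n_con / (n_con - 2))
  se_log2 <- se_ln / log(2)
  singular <- fa$zero & fb$zero
  log2fc[singular] <- 0
  excess <- abs(log2fc) - config$lfcThreshold
  stat <- pmax(excess, 0) / se_log2
  p <- 2 * pnorm(-stat)
  p[excess <= 0] <- 1
  p[singular] <- 1
  padj <- p.adjust(p, method = "BH")
  flag <- rep("ns", nrow(y))
  flag[padj < config$alpha & log2fc > config$lfcThreshold] <- "up"
  flag[padj < config$alpha & log2fc < -config$lfcThreshold] <- "down"
  flag[singular] <- "ns"
  base_mean <- rowMeans(sweep(y, 2L, sf, "/"))
  out <- data.frame(gene_id = rownames(y), baseMean = base_mean,
                    log2FC = log2fc, se_log2FC = se_log2,
                    wald_stat = sign(log2fc) * stat, p_value = p, p_adj = padj,
                    flag = flag, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  class(out) <- c("DEResult", class(out))
  out
}

#' Meristem-specific gene set from two MZ contrasts
#'
#' The genes called up in the meristematic zone in both the MZ-vs-EZ and
#' MZ-vs-DZ comparisons.
#'
#' @param de_mz_ez,de_mz_dz `DEResult` tables over the same gene universe.
#' @return sorted character vector of gene ids.
#' @export
meristem_specific_set <- function(de_mz_ez, de_mz_dz) {
  if (!setequal(de_mz_ez$gene_id, de_mz_dz$gene_id))
    stop("DE tables cover different gene universes")
  sort(intersect(de_mz_ez$gene_id[de_mz_ez$flag == "up"],
                 de_mz_dz$gene_id[de_mz_dz$flag == "up"]))
}

#' Variance-stabilizing log transform
#'
#' log2(count / size factor + 1): a homoscedasticity-improving transform of
#' the normalized counts used for co-expression analysis.
#'
#' @param counts a [count_table()].
#' @param size_factors from [compute_size_factors()]; recomputed if `NULL`.
#' @return numeric matrix, genes x samples.
#' @export
vst <- function(counts, size_factors = NULL) {
  sf <- size_factors %||% compute_size_factors(counts)
  log2(sweep(unclass(counts), 2L, sf[colnames(counts)], "/") + 1)
}
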
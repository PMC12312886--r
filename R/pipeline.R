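# End-to-end orchestration over an in-memory dataset (typically from
# simulate_dataset): differential expression -> promoter scan -> target
# calling and network assembly -> co-expression modules and cross-species
# preservation -> single-cell weighting/thresholding -> enrichment.

#' Pipeline parameters
#'
#' @param seed global seed; stochastic stages derive their own as
#'   seed + fixed offsets so perturbing one stage cannot ripple into others.
#' @param de a [de_config()].
#' @param scan_pval per-hit motif p-value cutoff.
#' @param window,noorf promoter extraction settings.
#' @param motif_mode "any" or "matched" (see [call_targets()]).
#' @param beta soft-threshold power, or `NULL` to select by scale-free fit.
#' @param min_module_size minimum co-expression module size.
#' @param cor_method "pearson" or "bicor".
#' @param n_perm preservation permutations.
#' @param combine edge-weight combination rule.
#' @param enrich_p,enrich_q enrichment thresholds.
#' @return list of class `PipelineParams`.
#' @export
pipeline_params <- function(seed = 1L, de = de_config(), scan_pval = 1e-4,
                            window = 3000L, noorf = TRUE,
                            motif_mode = "any", beta = NULL,
                            min_module_size = 30L,
                            cor_method = "pearson", n_perm = 200L,
                            combine = "geometric",
                            enrich_p = 0.05, enrich_q = 0.01) {
  structure(list(seed = as.integer(seed), de = de, scan_pval = scan_pval,
                 window = as.integer(window), noorf = noorf,
                 motif_mode = motif_mode, beta = beta,
                 min_module_size = as.integer(min_module_size),
                 cor_method = cor_method, n_perm = as.integer(n_perm),
                 combine = combine, enrich_p = enrich_p,
                 enrich_q = enrich_q), class = "PipelineParams")
}

# order-insensitive content fingerprint for the run manifest
object_checksum <- function(x) {
  r <- serialize(x, NULL, version = 2L)
  sprintf("%d-%.0f", length(r), sum(as.integer(r)))
}

#' Run the full inference pipeline
#'
#' Stages run in order on the dataset's inputs: CPM filtering and NB Wald DE
#' for both MZ contrasts, the meristem-specific intersection, background
#' training and promoter motif scanning, triple-intersection target calling
#' and network assembly, co-expression modules over the meristem genes,
#' module preservation against a second species when the dataset provides
#' one, single-cell activity weighting with per-cell-type mixture thresholds,
#' and term enrichment of the network nodes.
#'
#' @param dataset a [simulate_dataset()] result (or any list with the same
#'   fields: `bulk`, `genome_set`, `induction`, `sc`, `pwms`, optional
#'   `orthologs`, `test_bulk`, `terms`).
#' @param params a [pipeline_params()].
#' @return list of class `PipelineResult` with per-stage outputs and a
#'   `manifest` (stage timings, checksums, warnings).
#' @export
run_pipeline <- function(dataset, params = pipeline_params()) {
  manifest <- list(); t0 <- proc.time()[["elapsed"]]
  stamp <- function(name, obj) {
    manifest[[name]] <<- list(checksum = object_checksum(obj),
                              elapsed = proc.time()[["elapsed"]] - t0)
    obj
  }
  # -- differential expression ------------------------------------------
  counts <- cpm_filter(dataset$bulk$counts, params$de)
  design <- dataset$bulk$design
  sf <- compute_size_factors(counts)
  de_ez <- wald_de(counts, design, c("MZ", "EZ"), params$de, sf)
  de_dz <- wald_de(counts, design, c("MZ", "DZ"), params$de, sf)
  meristem <- meristem_specific_set(de_ez, de_dz)
  de_out <- stamp("de", list(counts = counts, size_factors = sf,
                             de_mz_ez = de_ez, de_mz_dz = de_dz,
                             meristem_set = meristem))
  # -- promoter scan -----------------------------------------------------
  bg <- train_markov_background(dataset$genome_set$genome)
  promoters <- extract_promoters(dataset$genome_set$annotation,
                                 dataset$genome_set$genome,
                                 window = params$window, noorf = params$noorf)
  motif_sets <- genes_with_motif(promoters, dataset$pwms, bg,
                                 p_threshold = params$scan_pval)
  scan_out <- stamp("scan", list(background = bg, promoters = promoters,
                                 motif_sets = motif_sets))
  # -- target calling and network ---------------------------------------
  bundle <- evidence_bundle(meristem, dataset$induction, motif_sets)
  targets <- call_targets(bundle, params$motif_mode)
  grn <- build_network(bundle, targets, params$motif_mode)
  grn_out <- stamp("grn", list(bundle = bundle, targets = targets, grn = grn))
  # -- co-expression and preservation ------------------------------------
  expr <- vst(counts, sf)
  mod_genes <- intersect(meristem, rownames(expr))
  coexpr_out <- NULL
  if (length(mod_genes) >= 2L * params$min_module_size) {
    cm <- correlation_matrix(expr[mod_genes, , drop = FALSE],
                             params$cor_method)
    beta <- params$beta %||% pick_soft_threshold(cm)$beta
    adj <- adjacency_matrix(cm, beta)
    tom <- tom_similarity(adj)
    modules <- detect_modules(1 - tom, min_size = params$min_module_size)
    eig <- if (any(modules > 0))
      eigengenes_kme(expr[rownames(tom), , drop = FALSE], modules) else NULL
    preservation <- NULL
    if (!is.null(dataset$test_bulk) && any(modules > 0)) {
      test_counts <- cpm_filter(dataset$test_bulk$counts, params$de)
      test_expr <- vst(test_counts)
      if (!is.null(dataset$test_bulk$ortholog_map)) {
        om <- dataset$test_bulk$ortholog_map
        lut <- setNames(om$gene_a[om$bbh], om$gene_b[om$bbh])
        keep <- rownames(test_expr) %in% names(lut)
        test_expr <- test_expr[keep, , drop = FALSE]
        rownames(test_expr) <- lut[rownames(test_expr)]
      }
      # full filtered universe as permutation background, labels on modules
      preservation <- module_preservation(
        expr, test_expr, modules,
        n_perm = params$n_perm, seed = params$seed + 1000L, beta = beta,
        method = "bicor")
    }
    coexpr_out <- stamp("coexpr", list(beta = beta, modules = modules,
                                       eigengenes = eig,
                                       preservation = preservation))
  }
  # -- single-cell weighting ---------------------------------------------
  sc_out <- NULL
  if (!is.null(dataset$sc) && nrow(grn$edges) > 0L) {
    activity <- gene_activity(dataset$sc$expr, dataset$sc$cell_types)
    weighted <- per_celltype_filter(grn, activity,
                                    seed = params$seed + 2000L,
                                    combine = params$combine)
    sc_out <- stamp("scweight", list(activity = activity,
                                     weighted = weighted))
  }
  # -- enrichment --------------------------------------------------------
  enrich_out <- NULL
  if (!is.null(dataset$terms)) {
    enrich_out <- stamp("enrich", hypergeom_enrich(
      intersect(grn$targets, rownames(counts)), rownames(counts),
      dataset$terms, params$enrich_p, params$enrich_q))
  }
  structure(list(de = de_out, scan = scan_out, grn = grn_out,
                 coexpr = coexpr_out, scweight = sc_out,
                 enrichment = enrich_out, params = params,
                 manifest = manifest), class = "PipelineResult")
}

precision_recall <- function(called, truth) {
  tp <- length(intersect(called, truth))
  c(precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}

true_edge_ids <- function(truth) {
  pairs <- unlist(lapply(names(truth$targets_by_regulator), function(r) {
    tt <- truth$targets_by_regulator[[r]]
    ifelse(r < tt, paste(r, tt, sep = "|"), paste(tt, r, sep = "|"))
  }))
  sort(unique(pairs))
}

#' Adjusted Rand index between two partitions
#' @param a,b label vectors over the same elements.
#' @return numeric scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

#' Score a pipeline run against the planted ground truth
#'
#' Reports recovery metrics wherever the ground truth defines them: the
#' meristem-specific set, motif presence on planted promoters, called
#' targets, network edges, and (when available) the per-cell-type mixture
#' threshold in the meristem type.
#'
#' @param dataset the [simulate_dataset()] input.
#' @param result the [run_pipeline()] output for it.
#' @return data.frame with `metric` and `value` columns.
#' @export
benchmark_pipeline <- function(dataset, result) {
  truth <- dataset$truth
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             value = as.numeric(value),
                                             stringsAsFactors = FALSE)
  pr <- precision_recall(result$de$meristem_set, truth$meristem_genes)
  add("meristem_precision", pr["precision"]); add("meristem_recall", pr["recall"])
  planted <- unique(dataset$genome_set$placements$gene_id)
  if (length(planted))
    add("motif_recovery",
        mean(planted %in% result$scan$motif_sets$union))
  pr <- precision_recall(result$grn$targets, truth$true_targets)
  add("target_precision", pr["precision"]); add("target_recall", pr["recall"])
  pr <- precision_recall(result$grn$grn$edges$edge_id, true_edge_ids(truth))
  add("edge_precision", pr["precision"]); add("edge_recall", pr["recall"])
  if (!is.null(result$coexpr)) {
    add("n_modules", max(result$coexpr$modules))
    if (!is.null(result$coexpr$preservation))
      add("min_Z_summary", min(result$coexpr$preservation$Z_summary))
  }
  if (!is.null(result$scweight)) {
    thr <- result$scweight$weighted$thresholds
    mt <- dataset$sc$meristem_type
    add("meristem_type_retained_edges",
        sum(result$scweight$weighted$retained[, mt]))
    if (mt %in% thr$cell_type && !is.na(thr$threshold[thr$cell_type == mt]))
      add("meristem_type_threshold", thr$threshold[thr$cell_type == mt])
  }
  do.call(rbind, rows)
}
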
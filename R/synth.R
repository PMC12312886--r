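# Synthetic data generators. Every pipeline input can be produced here with
# known ground truth: zone-structured NB counts, a Markov-background genome
# with planted motif instances, induction-response gene lists, cell-type
# structured single-cell expression, and cross-species ortholog hit tables.

#' Simulation configuration
#'
#' Defaults describe the benchmark dataset used throughout the package:
#' 2,000 genes in a 3-zone x 3-replicate bulk design, 4 regulators with 150
#' planted targets inside a 300-gene meristem-specific set, NB dispersion 0.1,
#' a meristem log2 effect of 3, full motif planting, 10% induction noise, 5
#' cell types, and 3 species at 80% module conservation.
#'
#' @param seed integer seed; mandatory, every generator is a pure function of
#'   the configuration.
#' @param n_genes,n_regulators,n_meristem_genes,n_true_targets design sizes.
#' @param zone_lfc log2 fold change of planted meristem genes (MZ vs EZ and
#'   MZ vs DZ); must be >= 0 (MZ-up convention).
#' @param nb_dispersion NB dispersion alpha in Var = mu + alpha * mu^2, shared
#'   across genes; 0 gives Poisson counts.
#' @param library_sizes optional length-9 vector of sample scaling factors;
#'   `NULL` draws mild log-normal depth variation.
#' @param promoter_len upstream window length in bp (default 3000).
#' @param markov_order background Markov order; fixed at 2.
#' @param motif_planting_rate fraction of true targets receiving a planted
#'   motif instance.
#' @param induction_noise fraction of extra non-meristem genes added to each
#'   regulator's induction-response set.
#' @param n_cell_types number of cell types (the first is the meristem /
#'   quiescent-centre type); `cells_per_type` cells each.
#' @param cells_per_type cells simulated per type (>= 50).
#' @param activity_separation log-scale elevation of regulators and true
#'   targets in the meristem cell type; must be >= 0.
#' @param n_species number of species for ortholog simulation (>= 2; species 1
#'   is the reference).
#' @param conservation_rate fraction of genes with a conserved ortholog.
#' @param pwm_width width of generated binding motifs.
#' @param gene_length simulated gene span length in bp.
#' @return a validated list of class `SimulationConfig`.
#' @export
sim_config <- function(seed,
                       n_genes = 2000L, n_regulators = 4L,
                       n_meristem_genes = 300L, n_true_targets = 150L,
                       zone_lfc = 3, nb_dispersion = 0.1,
                       library_sizes = NULL,
                       promoter_len = 3000L, markov_order = 2L,
                       motif_planting_rate = 1, induction_noise = 0.1,
                       n_cell_types = 5L, cells_per_type = 60L,
                       activity_separation = 2,
                       n_species = 3L, conservation_rate = 0.8,
                       pwm_width = 12L, gene_length = 400L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_regulators = as.integer(n_regulators),
              n_meristem_genes = as.integer(n_meristem_genes),
              n_true_targets = as.integer(n_true_targets),
              zone_lfc = zone_lfc, nb_dispersion = nb_dispersion,
              library_sizes = library_sizes,
              promoter_len = as.integer(promoter_len),
              markov_order = as.integer(markov_order),
              motif_planting_rate = motif_planting_rate,
              induction_noise = induction_noise,
              n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              activity_separation = activity_separation,
              n_species = as.integer(n_species),
              conservation_rate = conservation_rate,
              pwm_width = as.integer(pwm_width),
              gene_length = as.integer(gene_length))
  stopifnot(cfg$n_genes > 0L, cfg$n_regulators > 0L,
            cfg$n_true_targets <= cfg$n_meristem_genes,
            cfg$n_meristem_genes <= cfg$n_genes,
            cfg$markov_order == 2L,
            cfg$motif_planting_rate >= 0, cfg$motif_planting_rate <= 1,
            cfg$induction_noise >= 0, cfg$induction_noise <= 1,
            cfg$conservation_rate >= 0, cfg$conservation_rate <= 1,
            cfg$n_cell_types >= 2L, cfg$cells_per_type >= 50L,
            cfg$n_species >= 2L, cfg$nb_dispersion >= 0)
  if (cfg$zone_lfc < 0) stop("zone_lfc must be >= 0 (MZ-up convention)")
  if (cfg$activity_separation < 0) stop("activity_separation must be >= 0")
  class(cfg) <- "SimulationConfig"
  cfg
}

gene_ids_for <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))
regulator_ids_for <- function(cfg) sprintf("REG%d", seq_len(cfg$n_regulators))

# Stage-specific seeds: perturbing one stage must not ripple into others.
stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Planted regulator/target truth shared by all generators
#'
#' Draws the meristem-specific gene set, the true target subset, and the
#' assignment of targets to regulators. Deterministic in the config seed, so
#' every generator sees the same truth.
#'
#' @param config a [sim_config()].
#' @return a list of class `GroundTruth` with `meristem_genes`,
#'   `true_targets`, `regulators`, and `targets_by_regulator`.
#' @export
ground_truth <- function(config) {
  set.seed(stage_seed(config, 11L))
  genes <- gene_ids_for(config)
  meristem <- sort(sample(genes, config$n_meristem_genes))
  targets <- sort(sample(meristem, config$n_true_targets))
  regs <- regulator_ids_for(config)
  primary <- sample(regs, length(targets), replace = TRUE)
  by_reg <- lapply(regs, function(r) {
    extra <- targets[primary != r & runif(length(targets)) < 0.2]
    sort(unique(c(targets[primary == r], extra)))
  })
  names(by_reg) <- regs
  structure(list(meristem_genes = meristem, true_targets = targets,
                 regulators = regs, targets_by_regulator = by_reg),
            class = "GroundTruth")
}

#' Generate one binding motif per regulator
#'
#' Motifs are informative but not deterministic: each column concentrates
#' 0.95 of mass on a consensus base and spreads the rest, so column-wise
#' sampled instances have a realistic score spread yet remain recoverable as
#' strong sites at the default scan threshold.
#'
#' @param config a [sim_config()].
#' @return named list of [pwm_record()]s, one per regulator.
#' @export
simulate_pwms <- function(config) {
  set.seed(stage_seed(config, 23L))
  regs <- regulator_ids_for(config)
  conc <- 0.95
  out <- lapply(regs, function(r) {
    cons <- sample(1:4, config$pwm_width, replace = TRUE)
    m <- matrix((1 - conc) / 3, nrow = 4L, ncol = config$pwm_width)
    m[cbind(cons, seq_len(config$pwm_width))] <- conc
    pwm_record(paste0("M_", r), r, m)
  })
  names(out) <- regs
  out
}

#' Simulate zone-structured bulk RNA-seq counts
#'
#' Nine samples (MZ, EZ, DZ x 3 replicates). Counts are NB with
#' Var = mu + alpha mu^2; planted meristem genes carry a log2 effect of
#' `zone_lfc` in MZ relative to both EZ and DZ, all other genes are null.
#'
#' @param config a [sim_config()].
#' @param truth optional precomputed [ground_truth()].
#' @return list with `counts` ([count_table()]), `design`
#'   ([sample_design()]), and `truth`.
#' @export
simulate_zone_counts <- function(config, truth = ground_truth(config)) {
  set.seed(stage_seed(config, 37L))
  genes <- gene_ids_for(config)
  zones <- rep(c("MZ", "EZ", "DZ"), each = 3L)
  reps <- rep(1:3, times = 3L)
  samples <- paste0(zones, "_", reps)
  baseline <- rlnorm(config$n_genes, meanlog = log(100), sdlog = 1.2)
  names(baseline) <- genes
  # planted genes get a healthier baseline so the effect is detectable
  baseline[truth$meristem_genes] <- rlnorm(length(truth$meristem_genes),
                                           meanlog = log(200), sdlog = 0.5)
  libf <- config$library_sizes %||% rlnorm(9L, meanlog = 0, sdlog = 0.15)
  if (length(libf) != 9L) stop("library_sizes must have length 9")
  lfc <- setNames(rep(0, config$n_genes), genes)
  lfc[truth$meristem_genes] <- config$zone_lfc
  mu <- outer(baseline, libf) * 2^outer(lfc, as.numeric(zones == "MZ"))
  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           nrow = nrow(mu))
  } else {
    matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu))
  }
  dimnames(counts) <- list(genes, samples)
  list(counts = count_table(counts),
       design = sample_design(samples, zones, reps),
       truth = truth)
}

#' Default AT-rich background chain
#'
#' Order-2 representation whose conditionals equal the stationary base
#' distribution (A = T = 0.3, C = G = 0.2): a non-uniform background without
#' context dependence, so order-0 p-value calibration is exact. Pass a
#' context-dependent 16 x 4 matrix to exercise true order-2 structure.
#'
#' @return a `MarkovBackground` (see [markov_background()]).
#' @export
default_background <- function() {
  base <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  trans <- matrix(rep(base, each = 16L), nrow = 16L,
                  dimnames = list(dinucleotides(), names(base)))
  stat2 <- setNames(as.numeric(outer(base, base)[cbind(
    match(substr(dinucleotides(), 1L, 1L), names(base)),
    match(substr(dinucleotides(), 2L, 2L), names(base)))]), dinucleotides())
  markov_background(trans, stat2)
}

#' Sample a sequence from an order-2 background chain
#' @param n sequence length.
#' @param bg a `MarkovBackground`.
#' @return a character scalar of length-`n` DNA.
#' @export
generate_markov_seq <- function(n, bg = default_background()) {
  bases <- colnames(bg$trans)
  ctx_indep <- all(abs(sweep(bg$trans, 2L, bg$trans[1L, ], "-")) < 1e-12)
  if (ctx_indep) {
    return(paste(sample(bases, n, replace = TRUE, prob = bg$trans[1L, ]),
                 collapse = ""))
  }
  out <- character(n)
  first <- sample(names(bg$stationary2), 1L, prob = bg$stationary2)
  out[1L] <- substr(first, 1L, 1L)
  if (n >= 2L) out[2L] <- substr(first, 2L, 2L)
  if (n >= 3L) for (i in 3:n) {
    ctx <- paste0(out[i - 2L], out[i - 1L])
    out[i] <- sample(bases, 1L, prob = bg$trans[ctx, ])
  }
  paste(out, collapse = "")
}

sample_pwm_instance <- function(pwm) {
  paste(apply(pwm$matrix, 2L, function(p) sample(rownames(pwm$matrix), 1L, prob = p)),
        collapse = "")
}

#' Simulate a genome with promoters and planted motif instances
#'
#' Genes are laid out on one chromosome over an order-2 Markov background.
#' Most intergenic gaps exceed the promoter window but at least one pair is
#' deliberately closer than `promoter_len`, so neighbour-overlap truncation is
#' always exercised. Motif instances are sampled column-wise from the
#' regulator's PWM and written into true-target promoters (post-truncation
#' windows) at `motif_planting_rate`, on a random local strand.
#'
#' @param config a [sim_config()].
#' @param pwms named list of `PWMRecord`s (one per regulator), e.g. from
#'   [simulate_pwms()].
#' @param truth optional precomputed [ground_truth()].
#' @param bg background chain used to draw the genome.
#' @return list with `genome` (named character), `annotation`
#'   ([annotation_table()]), `placements` (data.frame: gene_id, motif_id,
#'   offset, strand, instance), `bg`, and `truth`.
#' @export
simulate_genome_promoters <- function(config, pwms,
                                      truth = ground_truth(config),
                                      bg = default_background()) {
  if (!length(pwms)) stop("pwms must be non-empty")
  L <- ncol(pwms[[1L]]$matrix)
  if (config$promoter_len < L) stop("promoter_len shorter than PWM width")
  set.seed(stage_seed(config, 59L))
  n <- config$n_genes
  glen <- config$gene_length
  gaps <- sample(seq(config$promoter_len + 200L, config$promoter_len + 1200L),
                 n, replace = TRUE)
  # force one close pair (< promoter_len spacing) to exercise truncation
  gaps[2L] <- max(L + 50L, config$promoter_len %/% 3L)
  starts <- cumsum(c(config$promoter_len + 500L, gaps[-1L] + glen))
  ends <- starts + glen - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.5, 0.5))
  strand[1:2] <- "+"  # the forced close pair truncates on the + side
  chrom_len <- ends[n] + config$promoter_len + 500L
  genome_seq <- generate_markov_seq(chrom_len, bg)
  ann <- annotation_table(gene_ids_for(config), "chr1", strand, starts, ends)

  placements <- NULL
  if (config$motif_planting_rate > 0 && length(truth$true_targets)) {
    proms <- extract_promoters(ann, setNames(chrom_len, "chr1"),
                               window = config$promoter_len, noorf = TRUE,
                               coords_only = TRUE)
    reg_of <- lapply(truth$true_targets, function(g) {
      hit <- names(Filter(function(s) g %in% s, truth$targets_by_regulator))
      sample(hit, 1L)
    })
    rows <- list()
    for (i in seq_along(truth$true_targets)) {
      if (runif(1L) > config$motif_planting_rate) next
      g <- truth$true_targets[i]
      w <- proms[proms$gene_id == g, ]
      if (!nrow(w) || w$length < L) next
      pwm <- pwms[[reg_of[[i]]]]
      off <- sample.int(w$length - L + 1L, 1L)
      s_local <- sample(c("+", "-"), 1L)
      inst <- sample_pwm_instance(pwm)
      local_str <- if (s_local == "+") inst else revcomp(inst)
      gs <- ann$strand[ann$gene_id == g]
      if (gs == "+") {
        gstart <- w$start + off - 1L
        substr(genome_seq, gstart, gstart + L - 1L) <- local_str
      } else {
        gend <- w$end - off + 1L
        substr(genome_seq, gend - L + 1L, gend) <- revcomp(local_str)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, motif_id = pwm$motif_id, regulator_id = pwm$regulator_id,
        offset = off, strand = s_local, instance = inst,
        stringsAsFactors = FALSE)
    }
    placements <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (is.null(placements))
    placements <- data.frame(gene_id = character(), motif_id = character(),
                             regulator_id = character(), offset = integer(),
                             strand = character(), instance = character(),
                             stringsAsFactors = FALSE)
  list(genome = setNames(genome_seq, "chr1"), annotation = ann,
       placements = placements, bg = bg, truth = truth)
}

#' Simulate per-regulator induction-response gene sets
#'
#' Each regulator's set is its true targets plus a configured fraction of
#' noise genes drawn from the non-meristem pool (so induction noise does not
#' masquerade as meristem-specific signal).
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()].
#' @return named list of character vectors, one per regulator.
#' @export
simulate_induction_sets <- function(config, truth = ground_truth(config)) {
  set.seed(stage_seed(config, 71L))
  pool <- setdiff(gene_ids_for(config), truth$meristem_genes)
  out <- lapply(truth$targets_by_regulator, function(tt) {
    n_noise <- round(config$induction_noise * max(length(tt), 1L))
    sort(unique(c(tt, sample(pool, min(n_noise, length(pool))))))
  })
  names(out) <- truth$regulators
  out
}

#' Simulate single-cell expression with cell-type structure
#'
#' Log-normal expression over `n_cell_types` types (>= 50 cells each); the
#' first type is the designated meristem / quiescent-centre type, in which
#' regulators and true targets are elevated by `activity_separation` on the
#' log scale.
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()].
#' @return list with `expr` (cells x genes matrix; genes include regulators),
#'   `cell_types` (factor per cell), and `meristem_type` (its label).
#' @export
simulate_single_cell <- function(config, truth = ground_truth(config)) {
  set.seed(stage_seed(config, 83L))
  genes <- c(truth$regulators, gene_ids_for(config))
  types <- paste0("ct", seq_len(config$n_cell_types))
  labels <- rep(types, each = config$cells_per_type)
  n_cells <- length(labels)
  base <- rnorm(length(genes), mean = 1, sd = 0.4)
  names(base) <- genes
  elevated <- c(truth$regulators, truth$true_targets)
  shift <- matrix(0, nrow = n_cells, ncol = length(genes),
                  dimnames = list(NULL, genes))
  shift[labels == types[1L], elevated] <- config$activity_separation
  meanlog <- sweep(shift, 2L, base, "+")
  expr <- matrix(rlnorm(n_cells * length(genes), meanlog = as.numeric(meanlog),
                        sdlog = 0.5), nrow = n_cells)
  dimnames(expr) <- list(paste0("cell", seq_len(n_cells)), genes)
  list(expr = expr, cell_types = factor(labels, levels = types),
       meristem_type = types[1L])
}

#' Simulate cross-species protein hit tables
#'
#' Species 1 is the reference. Conserved genes receive mutual top hits with
#' identity drawn around 70%; non-conserved genes get shifted (asymmetric)
#' best hits or none, so they can never form a mutual best pair.
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()].
#' @return list per non-reference species, each with `ab` (reference ->
#'   species hits), `ba` (species -> reference), and `conserved` (reference
#'   gene ids planted as conserved).
#' @export
simulate_ortholog_scores <- function(config, truth = ground_truth(config)) {
  set.seed(stage_seed(config, 97L))
  ref_genes <- gene_ids_for(config)
  out <- list()
  for (sp in paste0("sp", 2:config$n_species)) {
    other <- paste0(sp, "_", ref_genes)
    conserved <- runif(length(ref_genes)) < config$conservation_rate
    nc_idx <- which(!conserved)
    mk <- function(q, s, bs) {
      ident <- pmin(100, pmax(30, rnorm(length(q), 70, 10)))
      data.frame(query = q, subject = s, identity = ident,
                 similarity = pmin(100, ident + runif(length(q), 5, 15)),
                 bitscore = bs, evalue = 2^(-bs), stringsAsFactors = FALSE)
    }
    top <- 300 + runif(length(ref_genes), 0, 500)
    second <- top * runif(length(ref_genes), 0.3, 0.8)
    decoy_s <- other[sample.int(length(other))]
    ab <- rbind(mk(ref_genes[conserved], other[conserved], top[conserved]),
                mk(ref_genes, decoy_s, second))
    ba <- rbind(mk(other[conserved], ref_genes[conserved], top[conserved]),
                mk(other, ref_genes[sample.int(length(ref_genes))],
                   second * runif(length(second), 0.5, 0.9)))
    if (length(nc_idx) >= 3L) {
      shift1 <- nc_idx[c(2:length(nc_idx), 1L)]
      shift2 <- nc_idx[c(3:length(nc_idx), 1:2)]
      ab <- rbind(ab, mk(ref_genes[nc_idx], other[shift1], top[nc_idx]))
      ba <- rbind(ba, mk(other[nc_idx], ref_genes[shift2], top[nc_idx]))
    }
    out[[sp]] <- list(ab = ab, ba = ba, conserved = ref_genes[conserved])
  }
  out
}

#' Simulate module-structured expression
#'
#' Planted latent-factor modules: each module has a per-sample factor and its
#' genes load on it with correlation `within_r`; remaining genes are
#' independent noise (label 0 in the truth). The factors are drawn mutually
#' orthogonal and mean-centred (QR of a Gaussian matrix): with few samples,
#' unconstrained random factors themselves correlate strongly, which would
#' blur the planted modules into each other rather than represent distinct
#' expression programmes.
#'
#' @param n_genes,n_modules,n_samples design sizes.
#' @param within_r within-module correlation of member genes.
#' @param frac_noise fraction of genes left unassigned (independent).
#' @param seed integer seed.
#' @return list with `expr` (genes x samples) and `truth_modules`
#'   (integer labels, 0 = unassigned noise).
#' @export
simulate_module_expression <- function(n_genes = 200L, n_modules = 4L,
                                       n_samples = 9L, within_r = 0.7,
                                       frac_noise = 0, seed = 1L) {
  set.seed(seed)
  if (n_modules > n_samples - 1L)
    stop("need n_samples > n_modules for distinct module factors")
  n_noise <- round(frac_noise * n_genes)
  labels <- c(rep(0L, n_noise),
              rep(seq_len(n_modules), length.out = n_genes - n_noise))
  labels <- sort(labels)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n_samples * n_modules), n_samples))))
  factors <- t(q[, 1L + seq_len(n_modules), drop = FALSE])
  factors <- factors / apply(factors, 1L, sd)
  load <- sqrt(within_r)
  expr <- t(vapply(labels, function(m) {
    if (m == 0L) rnorm(n_samples)
    else load * factors[m, ] + sqrt(1 - within_r) * rnorm(n_samples)
  }, numeric(n_samples)))
  dimnames(expr) <- list(sprintf("mg%04d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples)))
  list(expr = expr, truth_modules = setNames(labels, rownames(expr)))
}

#' Simulate a flat annotation term collection
#'
#' Random terms over the gene universe plus one term equal to the planted
#' meristem set, so enrichment of recovered targets has a positive control.
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()].
#' @param n_terms number of random terms.
#' @return named list of gene-id vectors.
#' @export
simulate_gene_sets <- function(config, truth = ground_truth(config),
                               n_terms = 20L) {
  set.seed(stage_seed(config, 113L))
  genes <- gene_ids_for(config)
  out <- lapply(seq_len(n_terms), function(i)
    sort(sample(genes, sample(50:200, 1L))))
  names(out) <- sprintf("T%03d", seq_len(n_terms))
  out$T_meristem <- truth$meristem_genes
  out
}

#' Materialize the full synthetic dataset
#'
#' Runs every generator off one configuration, returning all pipeline
#' inputs plus the shared ground truth. A second species' bulk counts are
#' generated from the same truth (so conserved co-expression structure is
#' planted), with gene ids renamed and an ortholog map derived by
#' bidirectional best hits over the simulated hit tables.
#'
#' @param config a [sim_config()].
#' @return list with `pwms`, `bulk` (counts/design), `genome_set`
#'   (genome/annotation/placements/bg), `induction`, `sc`, `orthologs`,
#'   `test_bulk` (second species counts + ortholog_map), `terms`, `truth`,
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- ground_truth(config)
  pwms <- simulate_pwms(config)
  orthologs <- simulate_ortholog_scores(config, truth)
  test_cfg <- config
  test_cfg$seed <- config$seed + 7L
  test_bulk <- simulate_zone_counts(test_cfg, truth)
  sp2 <- names(orthologs)[1L]
  m <- unclass(test_bulk$counts)
  rownames(m) <- paste0(sp2, "_", rownames(m))
  test_bulk$counts <- count_table(m)
  test_bulk$ortholog_map <- bbh(orthologs[[sp2]]$ab, orthologs[[sp2]]$ba)
  list(pwms = pwms,
       bulk = simulate_zone_counts(config, truth),
       genome_set = simulate_genome_promoters(config, pwms, truth),
       induction = simulate_induction_sets(config, truth),
       sc = simulate_single_cell(config, truth),
       orthologs = orthologs,
       test_bulk = test_bulk,
       terms = simulate_gene_sets(config, truth),
       truth = truth, config = config)
}
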
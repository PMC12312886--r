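test_that("median-of-ratios size factors match hand-derived values", {
  m <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  expect_equal(compute_size_factors(count_table(m)),
               c(A = 1, B = 1))

  # B = 2 x A on a 3-gene all-positive table: factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(A = c(10L, 30L, 50L), B = c(20L, 60L, 100L))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(compute_size_factors(count_table(m2)),
               c(A = 1 / sqrt(2), B = sqrt(2)), tolerance = 1e-12)

  zero <- matrix(c(0L, 1L, 1L, 0L), 2, dimnames = list(c("g1", "g2"),
                                                       c("A", "B")))
  expect_error(compute_size_factors(count_table(zero)), "pre-filter")
})

test_that("size factors obey the single-sample scaling covariance", {
  set.seed(12)
  for (rep in 1:20) {
    m <- matrix(rpois(8 * 5, 60) + 1L, nrow = 8,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    sf <- compute_size_factors(count_table(m))
    cc <- sample(c(2L, 3L, 5L), 1L)
    j <- sample(5L, 1L)
    m2 <- m
    m2[, j] <- m2[, j] * cc
    sf2 <- compute_size_factors(count_table(m2))
    scale_all <- cc^(-1 / 5)       # gene geometric means absorb c^(1/n_samples)
    expect_equal(sf2[j], sf[j] * cc * scale_all, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sf2[-j], sf[-j] * scale_all, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("CPM filter keeps genes supported in at least min_samples samples", {
  set.seed(2)
  base <- matrix(rpois(5 * 9, 2000), nrow = 5)
  # row 6: above 1 CPM in exactly 3 samples; row 7: exactly 2; row 8: zeros
  probe3 <- c(rep(60L, 3), rep(0L, 6))
  probe2 <- c(rep(60L, 2), rep(0L, 7))
  m <- rbind(base, probe3, probe2, 0L)
  dimnames(m) <- list(paste0("g", 1:8), paste0("s", 1:9))
  ct <- count_table(m)
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  expect_equal(sum(cpm["g6", ] > 1), 3L)
  expect_equal(sum(cpm["g7", ] > 1), 2L)
  kept <- rownames(cpm_filter(ct, de_config()))
  expect_true("g6" %in% kept)
  expect_false("g7" %in% kept)
  expect_false("g8" %in% kept)
})

test_that("MoM dispersion recovers planted values and floors constants", {
  des <- sample_design(paste0("s", 1:6), rep(c("MZ", "EZ"), each = 3),
                       rep(1:3, 2))
  set.seed(31)
  n <- 2000L
  mu <- rlnorm(n, log(200), 0.7)
  y <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 1 / 0.2), nrow = n,
              dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:6)))
  d <- estimate_dispersion(count_table(y), des,
                           size_factors = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_gte(median(d), 0.1)
  expect_lte(median(d), 0.4)

  yp <- matrix(rpois(n * 6, rep(mu, 6)), nrow = n,
               dimnames = dimnames(y))
  dp <- estimate_dispersion(count_table(yp), des,
                            size_factors = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_lt(median(dp), 0.01)

  const <- matrix(7L, 2, 6, dimnames = list(c("c1", "c2"), paste0("s", 1:6)))
  dc <- estimate_dispersion(count_table(const), des,
                            size_factors = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_equal(unname(dc), rep(de_config()$dispersion_floor, 2))
})

test_that("Wald test clamps inside the threshold null and recovers planted effects", {
  des <- zone_design_3x3()
  m <- matrix(rep(c(100L, 50L, 25L, 200L), each = 9), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), des$sample_id))
  de <- wald_de(count_table(m), des, c("MZ", "EZ"), de_config(lfcThreshold = 1))
  expect_true(all(de$p_value == 1))
  expect_true(all(de$flag == "ns"))

  cfg <- sim_config(seed = 44L, n_genes = 1500L, zone_lfc = 3)
  truth <- ground_truth(cfg)
  zc <- simulate_zone_counts(cfg, truth)
  ct <- cpm_filter(zc$counts, de_config())
  de1 <- wald_de(ct, zc$design, c("MZ", "EZ"), de_config())
  planted <- de1[de1$gene_id %in% truth$meristem_genes & de1$baseMean >= 100, ]
  expect_gte(mean(planted$flag == "up"), 0.9)
})

test_that("DE results are invariant to sample order and antisymmetric in contrast", {
  cfg <- sim_config(seed = 13L, n_genes = 300L, n_meristem_genes = 60L,
                    n_true_targets = 30L)
  zc <- simulate_zone_counts(cfg)
  ct <- cpm_filter(zc$counts, de_config())
  de <- wald_de(ct, zc$design, c("MZ", "EZ"), de_config())

  perm <- sample(ncol(ct))
  ctp <- count_table(unclass(ct)[, perm])
  dep <- wald_de(ctp, zc$design, c("MZ", "EZ"), de_config())
  expect_equal(dep$log2FC, de$log2FC, tolerance = 1e-8)
  expect_equal(dep$p_value, de$p_value, tolerance = 1e-8)

  rev_de <- wald_de(ct, zc$design, c("EZ", "MZ"), de_config())
  expect_equal(rev_de$log2FC, -de$log2FC, tolerance = 1e-8)
  expect_equal(rev_de$p_value, de$p_value, tolerance = 1e-8)
})

test_that("BH adjustment equals the sorted cumulative-minimum construction", {
  set.seed(99)
  for (i in 1:10) {
    p <- runif(sample(50:500, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("meristem-specific set is the intersection of up-called genes", {
  mk <- function(genes, up) {
    data.frame(gene_id = genes, baseMean = 1, log2FC = 0, se_log2FC = 1,
               wald_stat = 0, p_value = 1, p_adj = 1,
               flag = ifelse(genes %in% up, "up", "ns"),
               stringsAsFactors = FALSE)
  }
  genes <- c("a", "b", "c", "d")
  expect_identical(meristem_specific_set(mk(genes, c("a", "b")),
                                         mk(genes, c("b", "c"))), "b")
  expect_identical(meristem_specific_set(mk(genes, character(0)),
                                         mk(genes, c("b"))), character(0))
  expect_error(meristem_specific_set(mk(genes, "a"), mk(genes[-1], "b")),
               "universe")
})

test_that("vst is zero-preserving, depth-invariant, and stabilizes variance", {
  m <- random_count_table(50, 6, seed = 21)
  sf <- compute_size_factors(m)
  v <- vst(m, sf)
  m0 <- unclass(m); m0[1, ] <- 0L
  expect_equal(unname(vst(count_table(m0), sf)[1, ]), rep(0, 6))

  doubled <- count_table(sweep(unclass(m), 2, c(2, rep(1, 5)), "*"))
  sf2 <- sf * c(2, rep(1, 5))
  expect_equal(vst(doubled, sf2), vst(m, sf), tolerance = 1e-12)

  set.seed(77)
  mu <- rlnorm(800, log(50), 1.5)
  libf <- seq(0.5, 2, length.out = 9)       # uneven sequencing depth
  mus <- outer(mu, libf)
  y <- matrix(rnbinom(length(mus), mu = mus, size = 10), nrow = 800,
              dimnames = list(sprintf("g%03d", 1:800), paste0("s", 1:9)))
  ct <- count_table(y)
  slope <- function(x) {
    mn <- rowMeans(x); vr <- apply(x, 1, var)
    ok <- vr > 0
    coef(lm(log10(vr[ok]) ~ log10(mn[ok] + 1e-9)))[2]
  }
  expect_lte(slope(vst(ct)), slope(log2(y + 1)) + 1e-8)
})
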
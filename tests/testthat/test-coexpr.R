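test_that("bicor agrees with Pearson on clean data and resists outliers", {
  set.seed(14)
  n <- 200L
  f <- rnorm(n)
  expr <- rbind(a = f + rnorm(n, 0, 0.5), b = f + rnorm(n, 0, 0.5),
                c = rnorm(n), d = rnorm(n))
  cp <- correlation_matrix(expr, "pearson")
  cb <- correlation_matrix(expr, "bicor")
  expect_equal(diag(cp), rep(1, 4), ignore_attr = TRUE)
  expect_lt(max(abs(cp - cb)), 0.02)

  # one gross outlier sample: Pearson moves substantially, bicor barely
  set.seed(15)
  g <- rnorm(60)
  x <- g + rnorm(60, 0, 0.45); y <- g + rnorm(60, 0, 0.45)
  r0 <- cor(x, y)
  x[1] <- 30; y[1] <- -30
  out <- rbind(x = x, y = y)
  pear <- correlation_matrix(out, "pearson")["x", "y"]
  bic <- correlation_matrix(out, "bicor")["x", "y"]
  expect_gt(abs(pear - r0), 0.2)
  expect_lt(abs(bic - r0), 0.05)

  # zero-MAD gene falls back and is reported
  expr2 <- rbind(k = c(rep(0, 55), 1:5), m = rnorm(60))
  cb2 <- correlation_matrix(expr2, "bicor")
  expect_true("k" %in% attr(cb2, "fallback"))
})

test_that("soft threshold selection reaches scale-free fit on modular data", {
  sim <- simulate_module_expression(n_genes = 300L, n_modules = 4L,
                                    n_samples = 30L, within_r = 0.7, seed = 5L)
  cc <- correlation_matrix(sim$expr)
  pick <- pick_soft_threshold(cc)
  expect_true(pick$reached_target)
  expect_gte(max(pick$fit$r_squared, na.rm = TRUE), 0.8)
  expect_identical(pick_soft_threshold(cc)$beta, pick$beta)

  # independent genes only reach an apparent scale-free fit at much higher
  # powers (vanishing connectivity), so modular structure is selected earlier
  set.seed(9)
  indep <- matrix(rnorm(300 * 30), nrow = 300,
                  dimnames = list(sprintf("i%03d", 1:300), NULL))
  pick0 <- pick_soft_threshold(correlation_matrix(indep))
  expect_lt(pick0$fit$mean_k[pick0$fit$power == pick0$beta], 1)
})

test_that("adjacency is the |cor|^beta transform with unit diagonal", {
  cc <- matrix(c(1, 0.5, -1, 0.5, 1, 0.2, -1, 0.2, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  a2 <- adjacency_matrix(cc, 2)
  expect_equal(a2["a", "b"], 0.25)
  expect_equal(a2["a", "c"], 1)
  expect_equal(diag(a2), rep(1, 3), ignore_attr = TRUE)
  a5 <- adjacency_matrix(cc, 5)
  off <- upper.tri(cc) & abs(cc) < 1
  expect_true(all(a5[off] <= a2[off]))
  expect_error(adjacency_matrix(cc, 0.5), "beta")
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  n <- 6L
  ones <- matrix(1, n, n)
  tom1 <- tom_similarity(ones)
  expect_equal(tom1, matrix(1, n, n), ignore_attr = TRUE)

  two <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(tom_similarity(two)[1, 2], 0.5)

  tom_oracle <- function(a) {
    n <- nrow(a)
    k <- rowSums(a) - 1
    t <- diag(n)
    for (i in 1:n) for (j in 1:n) if (i != j) {
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      t[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
    t
  }
  set.seed(19)
  for (rep in 1:3) {
    a <- matrix(runif(50 * 50), 50)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    got <- tom_similarity(a)
    expect_lt(max(abs(got - tom_oracle(a))), 1e-12)
    expect_true(all(got >= 0 & got <= 1 + 1e-12))
    expect_equal(got, t(got), tolerance = 1e-12)
  }
})

test_that("module detection recovers planted modules and ignores noise", {
  sim <- simulate_module_expression(n_genes = 200L, n_modules = 4L,
                                    n_samples = 9L, within_r = 0.7, seed = 3L)
  cc <- correlation_matrix(sim$expr)
  adj <- adjacency_matrix(cc, 6)
  mods <- detect_modules(1 - tom_similarity(adj), min_size = 30L)
  expect_gte(adjusted_rand_index(mods, sim$truth_modules[names(mods)]), 0.9)

  set.seed(29)
  indep <- matrix(rnorm(200 * 9), nrow = 200,
                  dimnames = list(sprintf("i%03d", 1:200), NULL))
  adj0 <- adjacency_matrix(correlation_matrix(indep), 6)
  mods0 <- detect_modules(1 - tom_similarity(adj0), min_size = 30L)
  expect_gte(mean(mods0 == 0), 0.9)

  # permuting gene order permutes labels consistently
  perm <- sample(nrow(sim$expr))
  modp <- detect_modules(1 - tom_similarity(adj)[perm, perm], min_size = 30L)
  expect_gte(adjusted_rand_index(modp[names(mods)], mods), 0.999)
})

test_that("eigengenes match the SVD oracle and kME behaves at the extremes", {
  sim <- simulate_module_expression(n_genes = 120L, n_modules = 3L,
                                    n_samples = 12L, within_r = 0.8, seed = 6L)
  part <- sim$truth_modules
  ek <- eigengenes_kme(sim$expr, part)
  # oracle: full SVD of the standardized module submatrix
  for (m in 1:3) {
    x0 <- t(scale(t(sim$expr[part == m, ])))
    sv <- svd(x0)
    e_oracle <- sv$v[, 1]
    e_oracle <- e_oracle / sd(e_oracle)
    got <- ek$eigengenes[, paste0("ME", m)]
    expect_lt(min(max(abs(got - e_oracle)), max(abs(got + e_oracle))), 1e-9)
    members <- names(part)[part == m]
    non <- setdiff(rownames(sim$expr), members)
    expect_gt(median(ek$kme[members, paste0("ME", m)]) -
              median(ek$kme[non, paste0("ME", m)]), 0.3)
  }

  # singleton module: eigengene is the gene's z-scores, kME 1
  expr1 <- matrix(rnorm(24), 2, 12, dimnames = list(c("g1", "g2"), NULL))
  ek1 <- eigengenes_kme(expr1, setNames(c(1L, 0L), c("g1", "g2")))
  z <- as.numeric(scale(expr1["g1", ]))
  z <- z / sd(z)
  expect_equal(unname(ek1$eigengenes[, "ME1"]), z, tolerance = 1e-9)
  expect_equal(unname(ek1$kme["g1", "ME1"]), 1, tolerance = 1e-9)

  # two perfectly correlated genes both have kME 1
  base <- rnorm(12)
  expr2 <- rbind(g1 = base, g2 = 2 * base + 3)
  ek2 <- eigengenes_kme(expr2, setNames(c(1L, 1L), c("g1", "g2")))
  expect_equal(unname(ek2$kme[, "ME1"]), c(1, 1), tolerance = 1e-9)
})

test_that("preservation Z is invariant to module relabeling and sample order", {
  sim <- simulate_module_expression(n_genes = 150L, n_modules = 3L,
                                    n_samples = 12L, within_r = 0.7,
                                    frac_noise = 0.2, seed = 7L)
  test_sim <- simulate_module_expression(n_genes = 150L, n_modules = 3L,
                                         n_samples = 12L, within_r = 0.7,
                                         frac_noise = 0.2, seed = 8L)
  pres <- module_preservation(sim$expr, test_sim$expr, sim$truth_modules,
                              n_perm = 50L, seed = 10L, beta = 6)
  relabeled <- c(0L, 3L, 1L, 2L)[sim$truth_modules + 1L]
  names(relabeled) <- names(sim$truth_modules)
  pres2 <- module_preservation(sim$expr, test_sim$expr, relabeled,
                               n_perm = 50L, seed = 10L, beta = 6)
  expect_equal(sort(pres$Z_summary), sort(pres2$Z_summary), tolerance = 1e-9)

  perm <- sample(ncol(test_sim$expr))
  pres3 <- module_preservation(sim$expr, test_sim$expr[, perm],
                               sim$truth_modules, n_perm = 50L, seed = 10L,
                               beta = 6)
  expect_equal(pres$Z_summary, pres3$Z_summary, tolerance = 1e-9)
})
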
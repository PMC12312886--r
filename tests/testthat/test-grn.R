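mk_bundle <- function(meristem, induction, per_reg_motif) {
  evidence_bundle(meristem, induction,
                  list(per_regulator = per_reg_motif,
                       union = sort(unique(unlist(per_reg_motif)))))
}

test_that("target calling is the triple intersection with both motif modes", {
  b <- mk_bundle(c("a", "b"), list(R1 = c("b", "c")), list(R1 = "b"))
  expect_identical(call_targets(b, "any"), "b")

  # induced by R1 but only R2's motif present: excluded under matched
  b2 <- mk_bundle(c("g"), list(R1 = "g", R2 = "x"),
                  list(R1 = character(0), R2 = "g"))
  expect_identical(call_targets(b2, "any"), "g")
  expect_identical(call_targets(b2, "matched"), character(0))

  expect_warning(out <- call_targets(mk_bundle(character(0), list(R1 = "a"),
                                               list(R1 = "a"))),
                 "empty")
  expect_length(out, 0L)
})

test_that("target calling is monotone in every evidence set", {
  set.seed(41)
  pool <- sprintf("g%02d", 1:40)
  for (i in 1:20) {
    mer <- sample(pool, 15); ind <- sample(pool, 15); mot <- sample(pool, 15)
    b <- mk_bundle(mer, list(R1 = ind), list(R1 = mot))
    base <- call_targets(b, "any")
    grow <- function(s) unique(c(s, sample(pool, 5)))
    b2 <- mk_bundle(grow(mer), list(R1 = grow(ind)), list(R1 = grow(mot)))
    expect_true(all(base %in% call_targets(b2, "any")))
  }
})

test_that("network assembly matches the brute-force predicate evaluation", {
  b <- mk_bundle("b", list(R1 = "b"), list(R1 = "b"))
  g <- build_network(b, motif_mode = "any")
  expect_equal(nrow(g$edges), 1L)
  expect_identical(g$edges$node_a, "R1")

  b3 <- mk_bundle("t", list(R1 = "t", R2 = "t", R3 = "t"), list(R1 = "t"))
  g3 <- build_network(b3, motif_mode = "any")
  expect_equal(nrow(g3$edges), 3L)
  # regulators are nodes even when edgeless
  expect_true(all(c("R1", "R2", "R3") %in% g3$nodes$node))

  set.seed(42)
  pool <- sprintf("g%02d", 1:30)
  regs <- paste0("R", 1:3)
  for (i in 1:10) {
    ind <- setNames(lapply(regs, function(r) sample(pool, 12)), regs)
    mot <- setNames(lapply(regs, function(r) sample(pool, 12)), regs)
    mer <- sample(pool, 15)
    b <- mk_bundle(mer, ind, mot)
    for (mode in c("any", "matched")) {
      tg <- call_targets(b, mode)
      got <- sort(build_network(b, tg, mode)$edges$edge_id)
      exp <- character(0)
      for (r in regs) for (g in tg) {
        okm <- if (mode == "any") g %in% unlist(mot) else g %in% mot[[r]]
        if (g %in% ind[[r]] && okm)
          exp <- c(exp, if (r < g) paste(r, g, sep = "|") else paste(g, r, sep = "|"))
      }
      expect_identical(got, sort(exp))
    }
  }
})

test_that("BBH flags exactly the mutual best pairs", {
  ab <- data.frame(query = c("a1", "a1", "a2"), subject = c("b1", "b2", "b2"),
                   bitscore = c(100, 50, 80), evalue = c(1e-30, 1e-10, 1e-20))
  ba <- data.frame(query = c("b1", "b2"), subject = c("a1", "a9"),
                   bitscore = c(90, 70), evalue = c(1e-25, 1e-15))
  m <- bbh(ab, ba)
  expect_true(m$bbh[m$gene_a == "a1"])    # mutual
  expect_false(m$bbh[m$gene_a == "a2"])   # a2 -> b2 best, but b2 -> a9

  # exhaustive oracle over random score tables
  for (s in 1:5) {
    set.seed(200 + s)
    qa <- sprintf("a%03d", 1:100); qb <- sprintf("b%03d", 1:100)
    ab <- data.frame(query = sample(qa, 400, TRUE), subject = sample(qb, 400, TRUE),
                     bitscore = round(runif(400, 40, 500)),
                     evalue = signif(10^-runif(400, 3, 50), 3))
    ba <- data.frame(query = sample(qb, 400, TRUE), subject = sample(qa, 400, TRUE),
                     bitscore = round(runif(400, 40, 500)),
                     evalue = signif(10^-runif(400, 3, 50), 3))
    got <- bbh(ab, ba)
    best_of <- function(h, q) {
      rows <- h[h$query == q, ]
      rows <- rows[order(-rows$bitscore, rows$evalue, rows$subject), ]
      rows$subject[1]
    }
    for (i in seq_len(nrow(got))) {
      qa_i <- got$gene_a[i]
      expect_identical(got$gene_b[i], best_of(ab, qa_i))
      expect_identical(got$bbh[i],
                       isTRUE(best_of(ba, got$gene_b[i]) == qa_i))
    }
    # symmetric in species order: same unordered mutual pairs
    rev_map <- bbh(ba, ab)
    expect_setequal(paste(got$gene_a[got$bbh], got$gene_b[got$bbh]),
                    paste(rev_map$gene_b[rev_map$bbh], rev_map$gene_a[rev_map$bbh]))
  }
})

test_that("low-variance edge selection ranks and tie-breaks deterministically", {
  e_ref <- edge_list(c("R1", "R1", "R2"), c("t1", "t2", "t3"),
                     weight = c(0.5, 0.7, 0.9))
  sp_edges <- edge_list(paste0("s_", c("R1", "R1", "R2")),
                        paste0("s_", c("t1", "t2", "t3")),
                        weight = c(0.5, 0.9, 0.9))
  om <- data.frame(gene_a = c("R1", "R2", "t1", "t2", "t3"),
                   gene_b = paste0("s_", c("R1", "R2", "t1", "t2", "t3")),
                   bbh = TRUE, stringsAsFactors = FALSE)
  sel <- conserved_low_variance_edges(list(ref = e_ref, sp = sp_edges),
                                      list(sp = om), top_k = 2L)
  # R1|t1 and R2|t3 have zero variance; R1|t2 differs across species
  expect_setequal(sel$edges$edge_id, c("R1|t1", "R2|t3"))
  expect_setequal(sel$nodes, c("R1", "t1", "R2", "t3"))

  expect_warning(conserved_low_variance_edges(
    list(ref = e_ref, sp = sp_edges), list(sp = om), top_k = 50L), "top_k")

  # brute-force sort oracle on random weights
  set.seed(77)
  n <- 40L
  nm <- sprintf("n%02d", 1:20)
  pairs <- t(combn(nm, 2))[sample(190, n), ]
  w1 <- runif(n); w2 <- runif(n)
  eref <- edge_list(pairs[, 1], pairs[, 2], weight = w1)
  esp <- edge_list(paste0("s_", pairs[, 1]), paste0("s_", pairs[, 2]),
                   weight = w2)
  omap <- data.frame(gene_a = nm, gene_b = paste0("s_", nm), bbh = TRUE)
  sel3 <- conserved_low_variance_edges(list(ref = eref, sp = esp),
                                       list(sp = omap), top_k = 10L)
  v <- apply(cbind(w1, w2), 1, var)
  key <- eref$edge_id
  oracle <- key[order(v, key)][1:10]
  expect_identical(sel3$edges$edge_id, oracle)
})

test_that("hypergeometric enrichment matches combinatorial closed forms", {
  bgn <- sprintf("g%02d", 1:20)
  sel <- bgn[1:5]
  terms <- list(Tfull = bgn[1:5], Tmiss = bgn[6:10])
  res <- hypergeom_enrich(sel, bgn, terms)
  expect_equal(res$p_value[res$term_id == "Tfull"], 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$term_id == "Tmiss"], 1)

  # upper tail at k = 0 is 1
  expect_equal(hypergeom_enrich(bgn[11:15], bgn,
                                list(T0 = bgn[1:5]))$p_value, 1)

  # direct pmf summation oracle over random configurations
  set.seed(33)
  for (i in 1:50) {
    N <- sample(20:200, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    uni <- sprintf("u%03d", 1:N)
    term <- uni[1:K]
    selec <- sample(uni, n)
    k <- length(intersect(term, selec))
    oracle <- sum(dhyper(k:min(K, n), K, N - K, n))
    got <- hypergeom_enrich(selec, uni, list(T = term))
    expect_equal(got$p_value, oracle, tolerance = 1e-10)
    expect_equal(got$k, k)
  }

  expect_error(hypergeom_enrich("zz", bgn, terms), "background")
})
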
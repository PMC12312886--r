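# Regulator-target network assembly from three evidence sets (meristem
# specificity, induction response, promoter motif presence), cross-species
# node conservation via bidirectional best hits, low-variance conserved
# edges, and hypergeometric term enrichment.

#' Bundle the three evidence sets
#'
#' @param meristem_set genes called meristem-specific.
#' @param induction_sets named list: regulator -> induction-response genes.
#' @param motif_sets from [genes_with_motif()]: list with `per_regulator`
#'   and `union`.
#' @return list of class `EvidenceBundle`.
#' @export
evidence_bundle <- function(meristem_set, induction_sets, motif_sets) {
  if (!all(names(motif_sets$per_regulator) %in% names(induction_sets)))
    warning("motif sets name regulators absent from induction sets")
  structure(list(meristem_set = sort(unique(meristem_set)),
                 induction_sets = lapply(induction_sets, function(s) sort(unique(s))),
                 motif_sets = motif_sets), class = "EvidenceBundle")
}

#' Call putative regulator targets by triple intersection
#'
#' Targets are genes that are (i) meristem-specific, (ii) responsive in at
#' least one regulator's induction set, and (iii) carry a binding motif —
#' any regulator's motif in `"any"` mode, or, in `"matched"` mode, the motif
#' of at least one regulator whose induction set contains the gene.
#'
#' @param bundle an [evidence_bundle()].
#' @param motif_mode "any" or "matched".
#' @return sorted character vector of target gene ids.
#' @export
call_targets <- function(bundle, motif_mode = c("any", "matched")) {
  motif_mode <- match.arg(motif_mode)
  if (!length(bundle$meristem_set)) {
    warning("empty meristem-specific set; no targets can be called")
    return(character(0L))
  }
  induced <- sort(unique(unlist(bundle$induction_sets, use.names = FALSE)))
  if (motif_mode == "any") {
    motif <- bundle$motif_sets$union
    return(sort(intersect(intersect(bundle$meristem_set, induced), motif)))
  }
  regs <- names(bundle$induction_sets)
  cand <- intersect(bundle$meristem_set, induced)
  ok <- vapply(cand, function(g) {
    any(vapply(regs, function(r)
      g %in% bundle$induction_sets[[r]] &&
        g %in% (bundle$motif_sets$per_regulator[[r]] %||% character(0L)),
      logical(1L)))
  }, logical(1L))
  sort(cand[ok])
}

#' Assemble the undirected regulator-target network
#'
#' An edge (regulator, target) exists iff the target passed [call_targets()]
#' and is in that regulator's induction set, and (in `"matched"` mode) has
#' that regulator's motif. Regulators are always nodes even if edgeless.
#'
#' @param bundle an [evidence_bundle()].
#' @param targets called target set.
#' @param motif_mode "any" or "matched".
#' @return list of class `GRNetwork` with `nodes` (data.frame: node, type),
#'   `edges` (an [edge_list()] with evidence tags), `regulators`, `targets`.
#' @export
build_network <- function(bundle, targets = call_targets(bundle, motif_mode),
                          motif_mode = c("any", "matched")) {
  motif_mode <- match.arg(motif_mode)
  regs <- names(bundle$induction_sets)
  a <- character(0L); b <- character(0L); ev <- character(0L)
  for (r in regs) {
    tg <- intersect(targets, bundle$induction_sets[[r]])
    if (motif_mode == "matched")
      tg <- intersect(tg, bundle$motif_sets$per_regulator[[r]] %||% character(0L))
    tg <- setdiff(tg, r)
    if (!length(tg)) next
    has_own <- tg %in% (bundle$motif_sets$per_regulator[[r]] %||% character(0L))
    a <- c(a, rep(r, length(tg))); b <- c(b, tg)
    ev <- c(ev, paste0("meristem;induced", ifelse(has_own, ";motif_matched",
                                                 ";motif_any")))
  }
  edges <- if (length(a)) edge_list(a, b, weight = NA_real_, evidence = ev)
           else edge_list(character(0L), character(0L))
  connected_targets <- sort(unique(b))
  nodes <- data.frame(node = c(regs, connected_targets),
                      type = c(rep("regulator", length(regs)),
                               rep("target", length(connected_targets))),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, regulators = regs,
                 targets = connected_targets, motif_mode = motif_mode),
            class = "GRNetwork")
}

#' Bidirectional best hits from two hit tables
#'
#' The best hit per query is the row with maximal bitscore (ties broken by
#' smaller evalue, then lexicographic subject id). A pair is flagged `bbh`
#' when each member is the other's best hit.
#'
#' @param hits_ab,hits_ba data.frames with columns query, subject, bitscore,
#'   evalue (identity/similarity carried through when present).
#' @return data.frame of class `OrthologMap`: gene_a, gene_b, bitscore_ab,
#'   and `bbh` flag; one row per A-side query with a best hit.
#' @export
bbh <- function(hits_ab, hits_ba) {
  best <- function(h) {
    h <- h[is.finite(h$bitscore), , drop = FALSE]
    ord <- order(h$query, -h$bitscore, h$evalue, h$subject)
    h <- h[ord, , drop = FALSE]
    h[!duplicated(h$query), , drop = FALSE]
  }
  ab <- best(hits_ab)
  ba <- best(hits_ba)
  back <- setNames(ba$subject, ba$query)
  flag <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query
  out <- data.frame(gene_a = ab$query, gene_b = ab$subject,
                    bitscore_ab = ab$bitscore, bbh = as.logical(flag),
                    stringsAsFactors = FALSE, row.names = NULL)
  if ("identity" %in% names(ab)) out$identity <- ab$identity
  class(out) <- c("OrthologMap", class(out))
  out
}

#' Nodes on the lowest-variance conserved edges
#'
#' Each species' weighted edge list is first mapped to reference gene ids via
#' its ortholog map (non-bbh genes drop out); only edges present in every
#' species are kept. Edges are ranked by the variance of their weights
#' across species and the `top_k` lowest-variance edges selected, ties broken
#' by lexicographic edge id; the incident nodes are returned.
#'
#' @param networks named list of [edge_list()]s; the first is the reference
#'   species and is used as is.
#' @param ortholog_maps named list of `OrthologMap`s for the non-reference
#'   species (mapping their gene ids in `gene_b` to reference ids `gene_a`).
#' @param top_k number of edges to select.
#' @return list with `edges` (data.frame: edge_id, variance) and `nodes`
#'   (sorted incident node ids).
#' @export
conserved_low_variance_edges <- function(networks, ortholog_maps, top_k = 100L) {
  stopifnot(length(networks) >= 2L)
  ref_name <- names(networks)[1L]
  canon <- function(e) {
    key <- ifelse(e$node_a < e$node_b, paste(e$node_a, e$node_b, sep = "|"),
                  paste(e$node_b, e$node_a, sep = "|"))
    setNames(e$weight, key)
  }
  mapped <- list(canon(networks[[ref_name]]))
  for (sp in setdiff(names(networks), ref_name)) {
    om <- ortholog_maps[[sp]]
    lut <- setNames(om$gene_a[om$bbh], om$gene_b[om$bbh])
    e <- networks[[sp]]
    na <- lut[e$node_a]; nb <- lut[e$node_b]
    ok <- !is.na(na) & !is.na(nb) & na != nb
    key <- ifelse(na[ok] < nb[ok], paste(na[ok], nb[ok], sep = "|"),
                  paste(nb[ok], na[ok], sep = "|"))
    w <- e$weight[ok]
    mapped[[length(mapped) + 1L]] <- tapply(w, key, mean)
  }
  shared <- Reduce(intersect, lapply(mapped, names))
  if (!length(shared))
    return(list(edges = data.frame(edge_id = character(), variance = numeric()),
                nodes = character(0L)))
  wmat <- vapply(mapped, function(m) as.numeric(m[shared]), numeric(length(shared)))
  wmat <- matrix(wmat, nrow = length(shared))
  variance <- apply(wmat, 1L, var)
  ord <- order(variance, shared)
  if (length(shared) < top_k)
    warning("only ", length(shared), " shared edges (< top_k); returning all")
  sel <- head(ord, top_k)
  edges <- data.frame(edge_id = shared[sel], variance = variance[sel],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(unlist(strsplit(edges$edge_id, "|", fixed = TRUE))))
  list(edges = edges, nodes = nodes)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value per term (P(X >= k) including k), BH
#' adjustment across tested terms, and pass flags at the configured p and q
#' thresholds.
#'
#' @param selection gene set of interest (subset of `background`).
#' @param background gene universe.
#' @param terms named list of term gene sets; each is intersected with the
#'   background, and empty terms are dropped.
#' @param p_max,q_max significance thresholds on p and BH q.
#' @return data.frame: term_id, k (overlap), K (term size), n (selection
#'   size), N (background size), p_value, q_value, pass.
#' @export
hypergeom_enrich <- function(selection, background, terms,
                             p_max = 0.05, q_max = 0.01) {
  background <- unique(background)
  selection <- unique(selection)
  if (!all(selection %in% background)) stop("selection must be within background")
  if (!length(selection))
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), pass = logical()))
  terms <- lapply(terms, function(s) intersect(unique(s), background))
  terms <- terms[lengths(terms) > 0L]
  N <- length(background); n <- length(selection)
  k <- vapply(terms, function(s) length(intersect(s, selection)), integer(1L))
  K <- lengths(terms)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(term_id = names(terms), k = k, K = K, n = n, N = N,
                    p_value = as.numeric(p), q_value = as.numeric(q),
                    pass = p <= p_max & q <= q_max,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}
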
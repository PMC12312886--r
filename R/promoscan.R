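# Promoter extraction and PWM scanning. Windows cover the 3 kb upstream of
# the TSS, truncated where a neighbouring gene's span intrudes (noorf) and
# clipped at chromosome ends. Scores are log-odds in nats of the PWM against
# an order-2 Markov background; p-values come from an exact DP over the
# order-0 marginal null.

BASES <- c("A", "C", "G", "T")

#' All 16 dinucleotide contexts, in row order of the transition matrix
#' @return character vector "AA", "AC", ..., "TT".
#' @export
dinucleotides <- function() {
  as.vector(t(outer(BASES, BASES, paste0)))
}

#' Construct an order-2 Markov background model
#'
#' @param trans 16 x 4 matrix of conditional probabilities p(base | 2-base
#'   context); rows named by [dinucleotides()], columns A,C,G,T.
#' @param stationary2 named length-16 probability vector over dinucleotides
#'   (the context distribution used at window starts).
#' @return a list of class `MarkovBackground` with `trans`, `stationary2`,
#'   and the order-0 `marginal` base distribution (second letter of the
#'   stationary dinucleotide law).
#' @export
markov_background <- function(trans, stationary2) {
  trans <- as.matrix(trans)
  stopifnot(nrow(trans) == 16L, ncol(trans) == 4L)
  rownames(trans) <- rownames(trans) %||% dinucleotides()
  colnames(trans) <- BASES
  trans <- trans[dinucleotides(), ]
  if (any(trans <= 0)) stop("all conditional probabilities must be > 0")
  if (any(abs(rowSums(trans) - 1) > 1e-9)) stop("context rows must sum to 1")
  stationary2 <- stationary2[dinucleotides()]
  stationary2 <- stationary2 / sum(stationary2)
  marginal <- vapply(BASES, function(b)
    sum(stationary2[substr(names(stationary2), 2L, 2L) == b]), numeric(1L))
  structure(list(order = 2L, trans = trans, stationary2 = stationary2,
                 marginal = marginal), class = "MarkovBackground")
}

encode_dna <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1L]], BASES)
}

#' Train an order-2 Markov background on a genome
#'
#' Trinucleotide counts are accumulated on both strands; ambiguity codes are
#' skipped. Conditionals get a pseudocount: p(b|xy) = (c(xyb) + pc) /
#' (c(xy.) + 4 pc). The stationary dinucleotide distribution is the
#' (pseudocounted) empirical dinucleotide frequency.
#'
#' @param genome named character vector of chromosome sequences.
#' @param order must be 2.
#' @param pseudocount added to every trinucleotide count.
#' @return a [markov_background()].
#' @export
train_markov_background <- function(genome, order = 2L, pseudocount = 1) {
  if (order != 2L) stop("only order 2 is supported")
  if (sum(nchar(genome)) < 1000L) stop("genome too short to train a background")
  tri <- matrix(0, nrow = 16L, ncol = 4L,
                dimnames = list(dinucleotides(), BASES))
  din <- setNames(numeric(16L), dinucleotides())
  tally <- function(s) {
    e <- encode_dna(s)
    n <- length(e)
    if (n >= 3L) {
      i1 <- e[1:(n - 2L)]; i2 <- e[2:(n - 1L)]; i3 <- e[3:n]
      ok <- !(is.na(i1) | is.na(i2) | is.na(i3))
      code <- (i1[ok] - 1L) * 16L + (i2[ok] - 1L) * 4L + i3[ok]
      tab <- tabulate(code, nbins = 64L)
      tri <<- tri + matrix(tab, nrow = 16L, byrow = TRUE)
    }
    if (n >= 2L) {
      j1 <- e[1:(n - 1L)]; j2 <- e[2:n]
      ok <- !(is.na(j1) | is.na(j2))
      dcode <- (j1[ok] - 1L) * 4L + j2[ok]
      din <<- din + tabulate(dcode, nbins = 16L)
    }
    invisible(NULL)
  }
  for (s in genome) { tally(s); tally(revcomp(s)) }
  trans <- (tri + pseudocount) / (rowSums(tri) + 4 * pseudocount)
  stat2 <- (din + pseudocount) / sum(din + pseudocount)
  markov_background(trans, stat2)
}

#' Extract upstream promoter windows
#'
#' For a + strand gene the window is genomic `[tss - window, tss - 1]`; for a
#' - strand gene it is the reverse complement of `[tss + 1, tss + window]`.
#' With `noorf`, the window is truncated at the nearest boundary of any other
#' gene's span overlapping it; windows are clipped at chromosome ends. Genes
#' whose window is empty after truncation are emitted with length 0 and no
#' sequence (and should be excluded from scanning).
#'
#' @param annotation an [annotation_table()].
#' @param genome named character vector of chromosome sequences, or (with
#'   `coords_only = TRUE`) a named vector of chromosome lengths.
#' @param window upstream window size in bp.
#' @param noorf truncate at overlapping neighbour spans?
#' @param coords_only skip sequence extraction.
#' @return data.frame of class `PromoterSet`: gene_id, chrom, start, end,
#'   strand, length, truncated, truncation_cause, and (unless `coords_only`)
#'   sequence in gene-local orientation.
#' @export
extract_promoters <- function(annotation, genome, window = 3000L,
                              noorf = TRUE, coords_only = FALSE) {
  chrom_len <- if (is.character(genome)) nchar(genome) else genome
  if (!all(annotation$chrom %in% names(chrom_len)))
    stop("annotation chromosome(s) missing from genome")
  n <- nrow(annotation)
  start <- end <- len <- integer(n)
  trunc <- logical(n)
  cause <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- annotation[i, ]
    clen <- chrom_len[[g$chrom]]
    if (g$strand == "+") { a <- g$tss - window; b <- g$tss - 1L }
    else { a <- g$tss + 1L; b <- g$tss + window }
    a <- max(a, 1L); b <- min(b, clen)
    if (noorf && b >= a) {
      others <- annotation[annotation$chrom == g$chrom &
                           annotation$gene_id != g$gene_id, , drop = FALSE]
      ov <- others[others$span_start <= b & others$span_end >= a, , drop = FALSE]
      if (nrow(ov)) {
        if (g$strand == "+") {
          j <- which.max(ov$span_end)
          a2 <- max(a, ov$span_end[j] + 1L)
          if (a2 > a) { a <- a2; trunc[i] <- TRUE; cause[i] <- ov$gene_id[j] }
        } else {
          j <- which.min(ov$span_start)
          b2 <- min(b, ov$span_start[j] - 1L)
          if (b2 < b) { b <- b2; trunc[i] <- TRUE; cause[i] <- ov$gene_id[j] }
        }
      }
    }
    if (b < a) { start[i] <- g$tss; end[i] <- g$tss - 1L; len[i] <- 0L }
    else { start[i] <- a; end[i] <- b; len[i] <- b - a + 1L }
  }
  out <- data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
                    start = start, end = end, strand = annotation$strand,
                    length = len, truncated = trunc, truncation_cause = cause,
                    stringsAsFactors = FALSE)
  if (!coords_only) {
    if (!is.character(genome)) stop("sequence extraction requires genome sequences")
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (len[i] == 0L) { seqs[i] <- ""; next }
      s <- substr(genome[[out$chrom[i]]], out$start[i], out$end[i])
      seqs[i] <- if (out$strand[i] == "+") s else revcomp(s)
    }
    out$sequence <- seqs
  }
  class(out) <- c("PromoterSet", class(out))
  out
}

# ---- scoring -------------------------------------------------------------

# Per-window PWM log-probability and order-2 background log-probability for
# one encoded strand; returns NA where a window touches an ambiguity code.
strand_scores <- function(enc, pwm, bg) {
  L <- ncol(pwm$matrix)
  n <- length(enc)
  if (n < L) return(list(score2 = numeric(0L), s0 = numeric(0L)))
  noff <- n - L + 1L
  offs <- seq_len(noff)
  lf <- log(pwm$matrix)
  pwm_lp <- numeric(noff)
  for (i in seq_len(L)) pwm_lp <- pwm_lp + lf[cbind(enc[offs + i - 1L], i)]
  # order-0 background over the window
  lq <- log(bg$marginal)[enc]
  cq <- cumsum(ifelse(is.na(lq), 0, lq))
  bg0 <- cq[offs + L - 1L] - c(0, cq)[offs]
  # order-2: stationary dinucleotide at the first two positions, then
  # conditionals along the scanned strand
  lt <- log(bg$trans)
  dcode <- (enc[seq_len(n - 1L)] - 1L) * 4L + enc[-1L]
  lstat2 <- log(bg$stationary2)[dcode[offs]]
  lp <- rep(NA_real_, n)
  if (n >= 3L) {
    i3 <- 3:n
    ctx <- (enc[i3 - 2L] - 1L) * 4L + enc[i3 - 1L]
    lp[i3] <- lt[cbind(ctx, enc[i3])]
  }
  cp <- cumsum(ifelse(is.na(lp), 0, lp))
  bg2 <- lstat2 + if (L >= 3L) cp[offs + L - 1L] - cp[offs + 1L] else 0
  cumna <- cumsum(is.na(enc))
  bad <- (cumna[offs + L - 1L] - c(0, cumna)[offs]) > 0L
  score2 <- pwm_lp - bg2
  s0 <- pwm_lp - bg0
  score2[bad] <- NA_real_
  s0[bad] <- NA_real_
  list(score2 = score2, s0 = s0)
}

#' Exact null score distribution of a PWM by dynamic programming
#'
#' The null draws each window position independently from the order-0
#' marginal of the background; per-column log-odds contributions are
#' discretized to `bin` nats and convolved exactly.
#'
#' @param pwm a `PWMRecord`.
#' @param bg a `MarkovBackground`.
#' @param bin discretization width in nats.
#' @return list with integer `keys` (sorted score bins), `tailp`
#'   (P(K >= key)), `bin`, and the PWM width `L`.
#' @export
pwm_null_distribution <- function(pwm, bg, bin = 1e-3) {
  lf <- log(pwm$matrix)
  lq <- log(bg$marginal)
  contrib <- round(sweep(lf, 1L, lq, "-") / bin)
  keys <- 0; probs <- 1
  for (i in seq_len(ncol(lf))) {
    nk <- as.vector(outer(keys, contrib[, i], "+"))
    np <- as.vector(outer(probs, bg$marginal, "*"))
    agg <- rowsum(np, group = nk)
    keys <- as.numeric(rownames(agg))
    probs <- agg[, 1L]
  }
  ord <- order(keys)
  keys <- keys[ord]; probs <- probs[ord]
  list(keys = keys, tailp = rev(cumsum(rev(probs))), bin = bin,
       L = ncol(lf))
}

# Tail probability lookup: P(K*bin >= score - L*bin/2), the DP image of
# P(S >= score) up to discretization. Monotone non-increasing and
# right-continuous in score.
null_tail <- function(null, score) {
  k <- round((score - null$L * null$bin / 2) / null$bin)
  idx <- findInterval(k - 0.5, null$keys) + 1L
  ifelse(idx > length(null$keys), 0, null$tailp[pmin(idx, length(null$keys))])
}

#' Calibrated p-value for a PWM log-odds score
#'
#' P(S >= score) under the order-0 marginal null of the background, computed
#' by exact DP over discretized per-column contributions.
#'
#' @param pwm a `PWMRecord`.
#' @param bg a `MarkovBackground`.
#' @param score log-odds score in nats (scalar or vector).
#' @param bin discretization width in nats.
#' @return numeric p-values in (0, 1].
#' @export
score_pvalue <- function(pwm, bg, score, bin = 1e-3) {
  stopifnot(all(is.finite(score)))
  null_tail(pwm_null_distribution(pwm, bg, bin), score)
}

#' Scan one promoter with a PWM
#'
#' At each offset (and on the reverse complement when `both_strands`), the
#' score is the log-probability of the window under the PWM minus its
#' log-probability under the order-2 background (the first two positions use
#' the stationary dinucleotide distribution). p-values are calibrated against
#' the order-0 marginal null; windows containing ambiguity codes are skipped.
#'
#' @param prom one-row `PromoterSet` slice, or a list with `gene_id` and
#'   `sequence`.
#' @param pwm a `PWMRecord`.
#' @param bg a `MarkovBackground`.
#' @param both_strands scan the reverse complement too?
#' @param p_threshold report hits with p_value <= this (1 reports every
#'   window).
#' @param null optional precomputed [pwm_null_distribution()].
#' @return data.frame of hits: gene_id, motif_id, offset (1-based, leftmost
#'   base of the window in the stored promoter), strand, score (nats),
#'   p_value.
#' @export
scan_promoter <- function(prom, pwm, bg, both_strands = TRUE,
                          p_threshold = 1e-4, null = NULL) {
  seqv <- prom$sequence
  L <- ncol(pwm$matrix)
  if (nchar(seqv) < L) stop("promoter shorter than PWM width")
  null <- null %||% pwm_null_distribution(pwm, bg)
  enc <- encode_dna(seqv)
  res <- list()
  fwd <- strand_scores(enc, pwm, bg)
  pf <- null_tail(null, fwd$s0)
  keep <- which(!is.na(fwd$s0) & pf <= p_threshold)
  if (length(keep))
    res[["+"]] <- data.frame(gene_id = prom$gene_id, motif_id = pwm$motif_id,
                             offset = keep, strand = "+",
                             score = fwd$score2[keep], p_value = pf[keep],
                             stringsAsFactors = FALSE)
  if (both_strands) {
    enc_rc <- rev(5L - enc)
    rcs <- strand_scores(enc_rc, pwm, bg)
    pr <- null_tail(null, rcs$s0)
    keep <- which(!is.na(rcs$s0) & pr <= p_threshold)
    if (length(keep)) {
      n <- length(enc)
      res[["-"]] <- data.frame(gene_id = prom$gene_id, motif_id = pwm$motif_id,
                               offset = n - (keep + L - 1L) + 1L, strand = "-",
                               score = rcs$score2[keep], p_value = pr[keep],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(gene_id = character(), motif_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Gene sets with a significant motif hit per regulator
#'
#' A gene enters a regulator's set when at least one window of its promoter,
#' on either strand, scores at p <= `p_threshold` for that regulator's PWM.
#'
#' @param promoters a `PromoterSet` with sequences.
#' @param pwms named list of `PWMRecord`s.
#' @param bg a `MarkovBackground`.
#' @param p_threshold per-hit p-value cutoff.
#' @return list with `per_regulator` (regulator -> sorted gene ids) and
#'   `union` (genes with any regulator's motif).
#' @export
genes_with_motif <- function(promoters, pwms, bg, p_threshold = 1e-4) {
  scannable <- promoters[promoters$length > 0L, , drop = FALSE]
  per_reg <- list()
  for (pwm in pwms) {
    L <- ncol(pwm$matrix)
    null <- pwm_null_distribution(pwm, bg)
    found <- character(0L)
    if (p_threshold > 0) {
      for (i in seq_len(nrow(scannable))) {
        if (scannable$length[i] < L) next
        enc <- encode_dna(scannable$sequence[i])
        s0 <- strand_scores(enc, pwm, bg)$s0
        hit <- any(null_tail(null, s0[!is.na(s0)]) <= p_threshold)
        if (!hit) {
          s0r <- strand_scores(rev(5L - enc), pwm, bg)$s0
          hit <- any(null_tail(null, s0r[!is.na(s0r)]) <= p_threshold)
        }
        if (hit) found <- c(found, scannable$gene_id[i])
      }
    }
    reg <- pwm$regulator_id
    per_reg[[reg]] <- sort(unique(c(per_reg[[reg]], found)))
  }
  list(per_regulator = per_reg,
       union = sort(unique(unlist(per_reg, use.names = FALSE))))
}
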
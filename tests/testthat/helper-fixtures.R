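# Small programmatic fixtures shared across test files.

random_count_table <- function(n_genes = 20L, n_samples = 6L, seed = 1L,
                               lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_table(m)
}

uniform_background <- function() {
  trans <- matrix(0.25, 16L, 4L, dimnames = list(dinucleotides(),
                                                 c("A", "C", "G", "T")))
  markov_background(trans, setNames(rep(1 / 16, 16L), dinucleotides()))
}

random_pwm <- function(width = 6L, seed = 1L, conc = NULL) {
  set.seed(seed)
  m <- matrix(runif(4L * width, 0.05, 1), nrow = 4L)
  if (!is.null(conc)) {
    m <- matrix((1 - conc) / 3, nrow = 4L, ncol = width)
    m[cbind(sample(1:4, width, replace = TRUE), seq_len(width))] <- conc
  }
  pwm_record("pwm_test", "REGT", m)
}

zone_design_3x3 <- function() {
  zones <- rep(c("MZ", "EZ", "DZ"), each = 3L)
  sample_design(paste0(zones, "_", rep(1:3, 3L)), zones, rep(1:3, 3L))
}

# independent brute-force BH for comparison with the package's adjustment
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- (n / seq_len(n)) * p[o]
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
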
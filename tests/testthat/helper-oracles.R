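# Shared fixtures and independent oracles. Oracles deliberately use brute
# force / closed forms and never touch the implementation paths they check.

tiny_counts <- function() {
  m <- matrix(c(5L, 0L, 2L,
                0L, 7L, 1L,
                3L, 3L, 0L,
                0L, 0L, 0L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("prot", 1:4), paste0("s", 1:3)))
  m
}

tiny_design <- function(n_a = 3, n_b = 3) {
  study_design(c(sprintf("a%d", seq_len(n_a)), sprintf("b%d", seq_len(n_b))),
               rep(c("A", "B"), c(n_a, n_b)))
}

# brute-force spectral index straight from the definition, scalar code
oracle_si <- function(a, b) {
  m_a <- mean(a); m_b <- mean(b)
  if (m_a + m_b == 0) return(0)
  r_a <- m_a / (m_a + m_b)
  r_a * mean(a > 0) - (1 - r_a) * mean(b > 0)
}

# all-assignments permutation null for one matrix, enumerated by combn
oracle_exhaustive_null <- function(counts, n_a) {
  n <- ncol(counts)
  combs <- utils::combn(n, n_a)
  out <- matrix(NA_real_, nrow(counts), ncol(combs))
  for (j in seq_len(ncol(combs))) {
    in_a <- seq_len(n) %in% combs[, j]
    for (i in seq_len(nrow(counts))) {
      out[i, j] <- oracle_si(counts[i, in_a], counts[i, !in_a])
    }
  }
  out
}

# pairwise Mann-Whitney AUC with tie = 1/2
oracle_auc_u <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# plain nearest-centroid with pooled standardization (the delta = 0 oracle)
oracle_nearest_centroid <- function(x, groups, newx) {
  grp <- levels(factor(groups))
  cent <- sapply(grp, function(g) rowMeans(x[, groups == g, drop = FALSE]))
  n <- ncol(x)
  ss <- 0
  for (g in grp) {
    ss <- ss + rowSums((x[, groups == g, drop = FALSE] - cent[, g])^2)
  }
  s <- sqrt(ss / (n - length(grp)))
  s0 <- stats::median(s)
  pri <- table(groups)[grp] / n
  apply(newx, 2, function(v) {
    d <- vapply(grp, function(g) {
      sum((v - cent[, g])^2 / (s + s0)^2) - 2 * log(pri[[g]])
    }, 0)
    grp[which.min(d)]
  })
}

# hypergeometric upper-tail p: P(overlap >= k)
oracle_hyper_p <- function(k, set_size, list_size, bg_size) {
  stats::phyper(k - 1, set_size, bg_size - set_size, list_size,
                lower.tail = FALSE)
}

# small planted dataset used across classifier tests
planted_dataset <- function(seed = 11, lfc = 4, n_proteins = 80) {
  generate_counts(synthetic_config(
    n_proteins = n_proteins, n_A = 14, n_B = 16, n_up_A = 12, n_up_B = 4,
    lfc = 2, n_signature = 3, signature_lfc = lfc, seed = seed))
}
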
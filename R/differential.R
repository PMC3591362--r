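#' Presence filter: keep proteins detected in at least half of one group
#'
#' A protein is retained when its non-zero detections cover at least half the
#' subjects of at least one group; with odd group sizes "half" rounds up
#' (ceiling), so a group of 5 needs 3 detections. Protein order is preserved.
#'
#' @param counts validated count matrix (proteins x samples).
#' @param design `study_design` covering all samples.
#' @return the filtered count matrix (possibly 0 rows, with a warning).
#' @export
apply_presence_filter <- function(counts, design) {
  counts <- validate_count_matrix(counts)
  d <- pair_design(counts, design)
  keep <- rep(FALSE, nrow(counts))
  for (g in levels(d$group)) {
    in_g <- d$group == g
    need <- ceiling(sum(in_g) / 2)
    keep <- keep | rowSums(counts[, in_g, drop = FALSE] > 0) >= need
  }
  msg("presence filter: ", sum(keep), " of ", nrow(counts),
      " proteins retained")
  if (!any(keep)) warning("presence filter removed every protein",
                          call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Spectral index for one protein
#'
#' The spectral index (SI) compares relative abundance between two groups on a
#' \[-1, +1\] scale. With per-group mean counts `m_A`, `m_B`, relative
#' abundances `r_A = m_A / (m_A + m_B)`, `r_B = 1 - r_A`, and detection
#' fractions `f_A`, `f_B` (share of samples with a non-zero count),
#'
#'   `SI = r_A * f_A - r_B * f_B`.
#'
#' SI is +1 exactly when detection is exclusive to group A and universal within
#' it, -1 for the mirror case, and 0 for identically balanced abundance. When
#' both groups are all-zero, SI = 0 and `r_A = r_B = 0`. Group means (not
#' pooled sums) are used so unequal group sizes do not bias the index.
#'
#' @param counts_a,counts_b non-negative integer count vectors for the two
#'   groups.
#' @return list with `si`, `r_A`, `r_B`, `f_A`, `f_B`.
#' @export
compute_spectral_index <- function(counts_a, counts_b) {
  if (length(counts_a) == 0 || length(counts_b) == 0) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop("negative counts", call. = FALSE)
  }
  m_a <- mean(counts_a)
  m_b <- mean(counts_b)
  if (m_a + m_b == 0) {
    r_a <- r_b <- 0
  } else {
    r_a <- m_a / (m_a + m_b)
    r_b <- 1 - r_a
  }
  f_a <- mean(counts_a > 0)
  f_b <- mean(counts_b > 0)
  list(si = r_a * f_a - r_b * f_b, r_A = r_a, r_B = r_b, f_A = f_a, f_B = f_b)
}

# SI for every protein under many label assignments at once.
# counts: p x n; a_ind: n x m 0/1 matrix marking group-A membership per
# assignment. Returns p x m matrix of SI values.
si_matrix <- function(counts, a_ind) {
  n_a <- colSums(a_ind)
  n_b <- nrow(a_ind) - n_a
  det <- (counts > 0) * 1
  m_a <- sweep(counts %*% a_ind, 2, n_a, "/")
  m_b <- sweep(counts %*% (1 - a_ind), 2, n_b, "/")
  f_a <- sweep(det %*% a_ind, 2, n_a, "/")
  f_b <- sweep(det %*% (1 - a_ind), 2, n_b, "/")
  tot <- m_a + m_b
  r_a <- m_a / tot
  si <- r_a * f_a - (1 - r_a) * f_b
  si[tot == 0] <- 0            # both groups all-zero: r_A = r_B = 0
  si
}

# All C(n, n_a) group-A membership indicators (n x choose(n, n_a)).
exhaustive_assignments <- function(n, n_a) {
  combs <- utils::combn(n, n_a)
  ind <- matrix(0, n, ncol(combs))
  ind[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n_a))] <- 1
  ind
}

#' Permutation null distribution for the spectral index
#'
#' Reassigns group labels uniformly at random (sampling without replacement,
#' preserving group sizes) and recomputes SI for every protein in each
#' permutation. When `n_perm` is at least the number of distinct label
#' assignments, the null switches to exhaustive enumeration (with a notice).
#'
#' With `mode = "global"` all permuted SI values are pooled into a single null
#' distribution and the significance band is its central `confidence` interval
#' (type-7 empirical quantiles); with `mode = "per_protein"` each protein keeps
#' its own null. Empirical p-values use the add-one estimator
#' `p = (1 + #\{|null| >= |si|\}) / (n_null + 1)`.
#'
#' @param counts presence-filtered count matrix.
#' @param design two-group `study_design`.
#' @param n_perm number of permutations (>= 1).
#' @param confidence two-sided coverage of the null band, in (0, 1].
#' @param mode `"global"` (pooled null, the default) or `"per_protein"`.
#' @param seed integer seed for the permutation stream.
#' @return list with `si` (observed per protein), `perm_si` (proteins x
#'   permutations), `null_band`, `p_empirical`, `n_permutations`, `exhaustive`.
#' @export
build_permutation_null <- function(counts, design, n_perm = 10000,
                                   confidence = 0.95,
                                   mode = c("global", "per_protein"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  counts <- validate_count_matrix(counts)
  d <- pair_design(counts, design)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (confidence <= 0 || confidence > 1) {
    stop("confidence must be in (0, 1]", call. = FALSE)
  }
  n <- ncol(counts)
  n_a <- sum(d$group == levels(d$group)[1])
  obs_ind <- matrix(as.numeric(d$group == levels(d$group)[1]), ncol = 1)
  si_obs <- drop(si_matrix(counts, obs_ind))

  n_distinct <- choose(n, n_a)
  exhaustive <- n_perm >= n_distinct
  if (exhaustive) {
    msg("n_perm (", n_perm, ") >= distinct assignments (", n_distinct,
        "): using exhaustive enumeration")
    a_ind <- exhaustive_assignments(n, n_a)
  } else {
    set.seed(as.integer(seed))
    a_ind <- vapply(seq_len(n_perm), function(i) {
      ind <- numeric(n)
      ind[sample.int(n, n_a)] <- 1
      ind
    }, numeric(n))
  }
  perm_si <- si_matrix(counts, a_ind)
  dimnames(perm_si) <- list(rownames(counts), NULL)

  alpha <- 1 - confidence
  if (mode == "global") {
    pooled <- as.vector(perm_si)
    band <- stats::quantile(pooled, c(alpha / 2, 1 - alpha / 2),
                            names = FALSE, type = 7)
    abs_null <- sort(abs(pooled))
    n_null <- length(abs_null)
    ge <- n_null - findInterval(abs(si_obs) - 1e-12, abs_null)
    p <- (1 + ge) / (n_null + 1)
  } else {
    band <- t(apply(perm_si, 1, stats::quantile,
                    probs = c(alpha / 2, 1 - alpha / 2), names = FALSE,
                    type = 7))
    colnames(band) <- c("lower", "upper")
    n_null <- ncol(perm_si)
    p <- vapply(seq_len(nrow(perm_si)), function(i) {
      (1 + sum(abs(perm_si[i, ]) >= abs(si_obs[i]) - 1e-12)) / (n_null + 1)
    }, 0)
  }
  list(si = si_obs, perm_si = perm_si, null_band = band, p_empirical = p,
       n_permutations = ncol(a_ind), exhaustive = exhaustive, mode = mode,
       confidence = confidence, seed = as.integer(seed))
}

#' Differential expression by spectral index with permutation significance
#'
#' Runs [build_permutation_null()] and assembles per-protein records. In
#' global mode a protein is significant iff its observed SI falls strictly
#' outside the pooled null band; in per-protein mode, outside its own band.
#' Direction is `up_in_A` for significant SI > 0, `up_in_B` for significant
#' SI < 0, `none` otherwise (group A = first level of the design's group
#' factor). Records are sorted by |SI| descending.
#'
#' @inheritParams build_permutation_null
#' @return object of class `differential_result`: list with `records`
#'   (data.frame: protein, si, r_A, r_B, f_A, f_B, p_empirical, significant,
#'   direction), `null_band`, `n_permutations`, `confidence`, `mode`, `seed`,
#'   `groups`.
#' @export
call_differential <- function(counts, design, n_perm = 10000,
                              confidence = 0.95,
                              mode = c("global", "per_protein"), seed = 1L) {
  mode <- match.arg(mode)
  counts <- validate_count_matrix(counts)
  d <- pair_design(counts, design)
  perm <- build_permutation_null(counts, design, n_perm = n_perm,
                                 confidence = confidence, mode = mode,
                                 seed = seed)
  grp <- levels(d$group)
  in_a <- d$group == grp[1]
  parts <- apply(counts, 1, function(row) {
    compute_spectral_index(row[in_a], row[!in_a])
  })
  rec <- data.frame(
    protein = rownames(counts),
    si = perm$si,
    r_A = vapply(parts, `[[`, 0, "r_A"),
    r_B = vapply(parts, `[[`, 0, "r_B"),
    f_A = vapply(parts, `[[`, 0, "f_A"),
    f_B = vapply(parts, `[[`, 0, "f_B"),
    p_empirical = perm$p_empirical,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (mode == "global") {
    rec$significant <- rec$si < perm$null_band[1] | rec$si > perm$null_band[2]
  } else {
    rec$significant <- rec$si < perm$null_band[, "lower"] |
      rec$si > perm$null_band[, "upper"]
  }
  rec$direction <- ifelse(!rec$significant, "none",
                          ifelse(rec$si > 0, "up_in_A", "up_in_B"))
  rec <- rec[order(-abs(rec$si)), , drop = FALSE]
  rownames(rec) <- NULL
  msg("differential: ", sum(rec$significant), " significant of ", nrow(rec),
      " (up in ", grp[1], ": ", sum(rec$direction == "up_in_A"),
      ", up in ", grp[2], ": ", sum(rec$direction == "up_in_B"), ")")
  structure(
    list(records = rec, null_band = perm$null_band,
         n_permutations = perm$n_permutations, confidence = confidence,
         mode = mode, seed = as.integer(seed), exhaustive = perm$exhaustive,
         groups = grp),
    class = "differential_result"
  )
}

#' @export
print.differential_result <- function(x, ...) {
  cat("Spectral-index differential result\n")
  cat(sprintf("  groups: %s (A) vs %s (B)\n", x$groups[1], x$groups[2]))
  cat(sprintf("  %d proteins, %d permutations (%s mode%s), confidence %.3g\n",
              nrow(x$records), x$n_permutations, x$mode,
              if (x$exhaustive) ", exhaustive" else "", x$confidence))
  if (x$mode == "global") {
    cat(sprintf("  null band: [%.4f, %.4f]\n",
                x$null_band[1], x$null_band[2]))
  }
  cat(sprintf("  significant: %d (up_in_A %d, up_in_B %d)\n",
              sum(x$records$significant),
              sum(x$records$direction == "up_in_A"),
              sum(x$records$direction == "up_in_B")))
  invisible(x)
}
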
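test_that("presence filter keeps 'at least half of one group' with ceiling", {
  n_a <- 14; n_b <- 16
  d <- tiny_design(n_a, n_b)
  mk <- function(det_a, det_b) {
    c(rep(1L, det_a), rep(0L, n_a - det_a), rep(1L, det_b),
      rep(0L, n_b - det_b))
  }
  m <- rbind(keep_b  = mk(0, 8),    # 8 of 16 = exactly half -> keep
             drop_it = mk(6, 7),    # needs 7 of 14 or 8 of 16 -> drop
             keep_a  = mk(7, 0),    # ceiling(14/2) = 7 -> keep
             allzero = mk(0, 0))    # -> drop
  colnames(m) <- d$sample
  f <- suppressMessages(apply_presence_filter(m, d))
  expect_identical(rownames(f), c("keep_b", "keep_a"))

  # odd group: 3 of 5 satisfies "at least half"
  d5 <- tiny_design(5, 4)
  m5 <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), nrow = 1,
               dimnames = list("p", d5$sample))
  expect_identical(nrow(suppressMessages(apply_presence_filter(m5, d5))), 1L)
})

test_that("presence filter on all-absent matrix warns, returns empty", {
  d <- tiny_design(4, 4)
  m <- matrix(0L, 2, 8, dimnames = list(c("p1", "p2"), d$sample))
  expect_warning(f <- suppressMessages(apply_presence_filter(m, d)),
                 "removed every protein")
  expect_identical(nrow(f), 0L)
})

test_that("spectral index matches its defining algebra", {
  ex <- compute_spectral_index(c(5, 3, 4), c(0, 0, 0))
  expect_identical(ex$si, 1)                       # exclusive + universal
  expect_identical(compute_spectral_index(c(0, 0, 0), c(5, 3, 4))$si, -1)
  expect_identical(compute_spectral_index(c(2, 2), c(2, 2))$si, 0)
  expect_equal(compute_spectral_index(c(4, 0), c(1, 1))$si, 0,
               tolerance = 1e-12)                  # hand-derived zero
  z <- compute_spectral_index(c(0, 0), c(0, 0))
  expect_identical(c(z$si, z$r_A, z$r_B), c(0, 0, 0))
  expect_error(compute_spectral_index(c(-1, 2), c(1, 1)), "negative")
})

test_that("SI antisymmetry, bounds, and the |si| = 1 characterization hold", {
  set.seed(71)
  for (i in 1:200) {
    n_a <- sample(2:8, 1); n_b <- sample(2:8, 1)
    a <- rpois(n_a, sample(c(0.5, 2, 10), 1))
    b <- rpois(n_b, sample(c(0.5, 2, 10), 1))
    si_ab <- compute_spectral_index(a, b)$si
    si_ba <- compute_spectral_index(b, a)$si
    expect_equal(si_ab, -si_ba, tolerance = 1e-12)
    expect_lte(abs(si_ab), 1)
    exclusive <- (all(a > 0) && all(b == 0)) || (all(b > 0) && all(a == 0))
    expect_identical(abs(si_ab) == 1, exclusive)
  }
})

test_that("2v2 and 3v3 permutation nulls equal exhaustive enumeration", {
  set.seed(12)
  for (n_half in 2:3) {
    d <- tiny_design(n_half, n_half)
    m <- matrix(rpois(5 * 2 * n_half, 4), nrow = 5,
                dimnames = list(paste0("p", 1:5), d$sample))
    res <- suppressMessages(
      build_permutation_null(m, d, n_perm = 10000, seed = 1))
    expect_true(res$exhaustive)
    oracle <- oracle_exhaustive_null(m, n_half)
    expect_identical(ncol(res$perm_si), ncol(oracle))
    # same multiset per protein (column order may differ)
    for (i in 1:5) {
      expect_equal(sort(res$perm_si[i, ]), sort(oracle[i, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("constant-count proteins are never significant; confidence 1 kills all", {
  d <- tiny_design(5, 5)
  set.seed(4)
  m <- rbind(flat = rep(3L, 10),
             matrix(rpois(40, 5), nrow = 4))
  rownames(m) <- c("flat", paste0("p", 1:4))
  colnames(m) <- d$sample
  de <- suppressMessages(call_differential(m, d, n_perm = 500, seed = 2))
  expect_false(de$records$significant[de$records$protein == "flat"])

  de1 <- suppressMessages(call_differential(m, d, n_perm = 500,
                                            confidence = 1, seed = 2))
  expect_identical(sum(de1$records$significant), 0L)
})

test_that("swapping group labels negates SI and preserves the calls", {
  sim <- generate_counts(synthetic_config(n_proteins = 50, n_A = 5, n_B = 6,
                                          n_up_A = 8, n_up_B = 3, seed = 9))
  # same labels, reversed level order: group roles A/B are exchanged
  d_swap <- study_design(sim$design$sample,
                         factor(sim$design$group, levels = c("B", "A")))
  de1 <- suppressMessages(call_differential(sim$counts, sim$design,
                                            n_perm = 2000, seed = 5))
  de2 <- suppressMessages(call_differential(sim$counts, d_swap,
                                            n_perm = 2000, seed = 5))
  r1 <- de1$records[order(de1$records$protein), ]
  r2 <- de2$records[order(de2$records$protein), ]
  expect_equal(r1$si, -r2$si, tolerance = 1e-12)
  expect_identical(r1$significant, r2$significant)
})

test_that("permutation analysis is deterministic under a fixed seed", {
  sim <- generate_counts(synthetic_config(n_proteins = 40, n_A = 6, n_B = 6,
                                          n_up_A = 5, n_up_B = 2,
                                          n_signature = 0, seed = 13))
  de1 <- suppressMessages(call_differential(sim$counts, sim$design,
                                            n_perm = 300, seed = 99))
  de2 <- suppressMessages(call_differential(sim$counts, sim$design,
                                            n_perm = 300, seed = 99))
  expect_identical(de1, de2)
})

test_that("planted exclusive-detection proteins are all recovered", {
  set.seed(21)
  n_a <- 7; n_b <- 7
  d <- tiny_design(n_a, n_b)
  null_part <- matrix(rpois(100 * 14, 5), nrow = 100)
  planted <- t(vapply(1:10, function(i) {
    c(rpois(n_a, 20) + 1L, rep(0L, n_b))      # exclusive to A
  }, integer(14)))
  m <- rbind(planted, null_part)
  dimnames(m) <- list(c(paste0("hit", 1:10), paste0("null", 1:100)),
                      d$sample)
  de <- suppressMessages(call_differential(m, d, n_perm = 2000, seed = 3))
  rec <- de$records
  expect_identical(
    sort(rec$protein[rec$direction == "up_in_A"][1:10]),
    sort(paste0("hit", 1:10)))
  expect_true(all(rec$significant[match(paste0("hit", 1:10), rec$protein)]))
})

test_that("per-protein mode produces one null band per protein", {
  sim <- generate_counts(synthetic_config(n_proteins = 20, n_A = 5, n_B = 5,
                                          n_up_A = 3, n_up_B = 0,
                                          n_signature = 0, seed = 2))
  de <- suppressMessages(call_differential(sim$counts, sim$design,
                                           n_perm = 200,
                                           mode = "per_protein", seed = 1))
  expect_identical(nrow(de$null_band), nrow(de$records))
  expect_true(all(de$null_band[, "lower"] <= de$null_band[, "upper"]))
})
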
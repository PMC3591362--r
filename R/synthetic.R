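#' Configuration for the synthetic spectral-count generator
#'
#' Defaults emulate a two-group BALF shotgun-proteomics cohort: 394 quantified
#' proteins across groups of 14 ("A", e.g. pneumonia-positive) and 16 ("B"),
#' with 75 truly differential proteins (60 up in A, 15 up in B) and a small
#' 3-protein signature carrying a stronger effect. Counts are negative
#' binomial (overdispersed) around a log-normal protein baseline with
#' per-sample depth factors, followed by independent dropout so the matrix is
#' zero-rich.
#'
#' @param n_proteins total proteins (default 394).
#' @param n_A,n_B group sizes (defaults 14 and 16).
#' @param n_up_A,n_up_B truly differential proteins up in each group
#'   (defaults 60 and 15).
#' @param lfc log2 fold change of differential proteins (default 2).
#' @param n_signature how many of the up-in-A proteins carry the stronger
#'   signature effect (default 3). Signature proteins are always
#'   abundance-shift archetype: they emulate validated diagnostic markers —
#'   abundant, measurable in both groups, strongly shifted — rather than
#'   sporadic presence/absence patterns.
#' @param signature_lfc log2 fold change of signature proteins (default 10:
#'   the down-group mean falls below the detection floor, so a signature
#'   protein is abundant in its up group and essentially undetected in the
#'   other — the behavior of a pus-derived diagnostic marker. A panel this
#'   strong is the only regime in which "the strongest 3 proteins" is a
#'   well-posed target at 30 samples; see the methods vignette).
#' @param baseline_log_mean,baseline_log_sd log-normal baseline abundance
#'   parameters (natural-log scale; defaults log(10) and 1).
#' @param dispersion negative-binomial size parameter (default 2; smaller is
#'   more overdispersed).
#' @param dropout probability a cell is independently zeroed (default 0).
#'   This models abundance-independent technical loss on top of the
#'   structural zeros the abundance model already produces; real
#'   spectral-count missingness is abundance-driven, so the extra flat
#'   component defaults to off.
#' @param depth_sd SD of per-sample log-normal depth factors (default 0.15).
#' @param presence_fraction fraction of differential proteins realized as
#'   presence/absence patterns rather than pure abundance shifts
#'   (default 0.5).
#' @param seed integer seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 394, n_A = 14, n_B = 16,
                             n_up_A = 60, n_up_B = 15, lfc = 2,
                             n_signature = 3, signature_lfc = 10,
                             baseline_log_mean = log(10),
                             baseline_log_sd = 1, dispersion = 2,
                             dropout = 0, depth_sd = 0.15,
                             presence_fraction = 0.5, seed = 1L) {
  cfg <- list(n_proteins = n_proteins, n_A = n_A, n_B = n_B,
              n_up_A = n_up_A, n_up_B = n_up_B, lfc = lfc,
              n_signature = n_signature, signature_lfc = signature_lfc,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd, dispersion = dispersion,
              dropout = dropout, depth_sd = depth_sd,
              presence_fraction = presence_fraction, seed = as.integer(seed))
  stopifnot(n_proteins >= 1, n_A >= 2, n_B >= 2,
            n_up_A >= 0, n_up_B >= 0, lfc >= 0, signature_lfc >= 0,
            n_signature >= 0, n_signature <= n_up_A + n_up_B)
  if (n_up_A + n_up_B > n_proteins) {
    stop("n_up_A + n_up_B exceeds n_proteins", call. = FALSE)
  }
  if (dropout < 0 || dropout > 1 || presence_fraction < 0 ||
      presence_fraction > 1) {
    stop("dropout and presence_fraction must be in [0, 1]", call. = FALSE)
  }
  if (dispersion <= 0 || baseline_log_sd < 0 || depth_sd < 0) {
    stop("dispersion must be > 0; SDs must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic spectral-count dataset with known truth
#'
#' Protein baselines `mu_p` are log-normal; per-sample depth factors `d_i`
#' are log-normal with SD `depth_sd`. A differential protein with log2 fold
#' change `L` has its expected count multiplied by `2^(+L/2)` in its up group
#' and `2^(-L/2)` in the other, so the group-mean ratio is exactly `2^L`.
#' "Presence/absence" differential proteins instead keep the up-group shift
#' and realize the down-group reduction by Bernoulli thinning (each cell kept
#' with probability `2^-L`), planting detection asymmetry at the same mean
#' ratio. Counts are negative binomial with size `dispersion`, then each cell
#' is independently zeroed with probability `dropout`. Fully deterministic
#' given the config (which includes the seed).
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` (count matrix), `design` (`study_design`,
#'   groups "A" and "B"), `truth` (data.frame: protein, is_differential,
#'   direction, lfc, archetype).
#' @export
generate_counts <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  set.seed(config$seed)
  p <- config$n_proteins
  n <- config$n_A + config$n_B
  proteins <- sprintf("P%04d", seq_len(p))
  samples <- c(sprintf("A%02d", seq_len(config$n_A)),
               sprintf("B%02d", seq_len(config$n_B)))
  group <- rep(c("A", "B"), c(config$n_A, config$n_B))

  mu <- stats::rlnorm(p, config$baseline_log_mean, config$baseline_log_sd)
  depth <- stats::rlnorm(n, 0, config$depth_sd)

  direction <- rep("none", p)
  lfc <- rep(0, p)
  archetype <- rep("null", p)
  idx_a <- seq_len(config$n_up_A)
  idx_b <- seq_len(config$n_up_B) + config$n_up_A
  direction[idx_a] <- "up_in_A"
  direction[idx_b] <- "up_in_B"
  lfc[c(idx_a, idx_b)] <- config$lfc
  sig_idx <- integer(0)
  if (config$n_signature > 0) {
    sig_idx <- utils::head(c(idx_a, idx_b), config$n_signature)
    lfc[sig_idx] <- config$signature_lfc
  }
  diff_idx <- c(idx_a, idx_b)
  if (length(diff_idx) > 0) {
    archetype[diff_idx] <- "abundance"
    # signature proteins stay abundance-archetype; the rest interleave
    pa_pool <- setdiff(diff_idx, sig_idx)
    n_pa <- round(config$presence_fraction * length(pa_pool))
    if (n_pa > 0) {
      pa_pick <- pa_pool[seq(1, length(pa_pool), by = 2)][seq_len(min(
        n_pa, ceiling(length(pa_pool) / 2)))]
      archetype[pa_pick] <- "presence"
    }
  }

  mean_mat <- outer(mu, depth)
  up_mult <- 2^(lfc / 2)
  for (g in c("A", "B")) {
    cols <- group == g
    up_here <- direction == paste0("up_in_", g)
    down_here <- direction != "none" & !up_here
    shift <- rep(1, p)
    shift[up_here] <- up_mult[up_here]
    # abundance archetype: symmetric down-shift; presence archetype: mean
    # kept at the up level, reduction applied later by thinning
    shift[down_here & archetype == "abundance"] <-
      1 / up_mult[down_here & archetype == "abundance"]
    shift[down_here & archetype == "presence"] <-
      up_mult[down_here & archetype == "presence"]
    mean_mat[, cols] <- mean_mat[, cols] * shift
  }
  counts <- matrix(stats::rnbinom(p * n, size = config$dispersion,
                                  mu = as.vector(mean_mat)), p, n)
  # presence/absence thinning of the down group
  for (g in c("A", "B")) {
    other <- setdiff(c("A", "B"), g)
    rows <- which(direction == paste0("up_in_", other) &
                    archetype == "presence")
    cols <- which(group == g)
    if (length(rows) > 0) {
      keep_p <- 2^(-lfc[rows])
      keep <- matrix(stats::rbinom(length(rows) * length(cols), 1,
                                   rep(keep_p, length(cols))),
                     length(rows), length(cols))
      counts[rows, cols] <- counts[rows, cols] * keep
    }
  }
  if (config$dropout > 0) {
    drop <- matrix(stats::rbinom(p * n, 1, config$dropout), p, n)
    counts <- counts * (1 - drop)
  }
  dimnames(counts) <- list(proteins, samples)
  storage.mode(counts) <- "integer"
  truth <- data.frame(protein = proteins,
                      is_differential = direction != "none",
                      direction = direction, lfc = lfc,
                      archetype = archetype, stringsAsFactors = FALSE)
  list(counts = counts, design = study_design(samples, group), truth = truth)
}

#' Generate a null dataset (no differential proteins)
#'
#' Same generative model as [generate_counts()] with `n_up_A = n_up_B = 0`:
#' samples are exchangeable between groups.
#'
#' @param config a [synthetic_config()]; its differential fields are zeroed.
#' @return as [generate_counts()].
#' @export
generate_null_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  config$n_up_A <- 0
  config$n_up_B <- 0
  config$n_signature <- 0
  generate_counts(config)
}
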
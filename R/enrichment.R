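#' Over-representation analysis with permutation p-values
#'
#' For each annotation category (intersected with the background), the
#' observed overlap `k` with the hit list is compared against a null built by
#' drawing `length(hits)` proteins from the background without replacement,
#' `n_perm` times. Empirical p-values use the add-one estimator
#' `p = (1 + #\{null >= k\}) / (n_perm + 1)` and are converted to FDR by
#' Benjamini-Hochberg across categories. A category is significant when it
#' has at least 3 overlapping members and FDR < 5%.
#'
#' The natural background for spectral-count studies is the set of proteins
#' surviving the presence filter; any superset of the hits is accepted.
#'
#' @param hits character vector of hit proteins (must be within background).
#' @param background character vector, the tested protein universe.
#' @param annotations `annotation_collection` (named list of protein sets).
#' @param n_perm number of null draws (default 10000).
#' @param seed integer seed.
#' @param min_members overlap required for significance (default 3).
#' @param fdr_threshold FDR cut for significance (default 0.05).
#' @return data.frame (class `enrichment_result`) with columns `category`,
#'   `overlap`, `category_size`, `list_size`, `background_size`,
#'   `p_empirical`, `fdr`, `significant`, sorted by p.
#' @export
test_enrichment <- function(hits, background, annotations, n_perm = 10000,
                            seed = 1L, min_members = 3,
                            fdr_threshold = 0.05) {
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  if (!all(hits %in% background)) {
    stop("hits not contained in background: ",
         paste(utils::head(setdiff(hits, background), 5), collapse = ", "),
         call. = FALSE)
  }
  sets <- lapply(annotations, intersect, background)
  keep <- lengths(sets) > 0
  sets <- sets[keep]
  if (length(sets) == 0) {
    stop("no annotation category overlaps the background", call. = FALSE)
  }
  n_bg <- length(background)
  n_hit <- length(hits)
  membership <- vapply(sets, function(s) background %in% s,
                       logical(n_bg))                     # n_bg x n_cat
  obs <- colSums(membership[background %in% hits, , drop = FALSE])

  set.seed(as.integer(seed))
  exceed <- numeric(length(sets))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_bg, n_hit)
    exceed <- exceed + (colSums(membership[idx, , drop = FALSE]) >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  fdr <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    category = names(sets),
    overlap = as.integer(obs),
    category_size = lengths(sets),
    list_size = n_hit,
    background_size = n_bg,
    p_empirical = p,
    fdr = fdr,
    significant = obs >= min_members & fdr < fdr_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- res[order(res$p_empirical, -res$overlap), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
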
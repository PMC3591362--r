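#' Correspondence analysis of a spectral-count table
#'
#' Classical CA: with `P = counts / N` (N the grand total), row and column
#' masses `r`, `c`, the standardized residual matrix
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by SVD. Principal
#' coordinates are the mass-standardized singular vectors scaled by their
#' singular values; each axis inertia is the squared singular value, and total
#' inertia equals the Pearson chi-square statistic divided by N. All-zero rows
#' or columns are dropped with a warning. The SVD sign ambiguity is fixed by
#' forcing the largest-magnitude sample coordinate on each axis positive.
#'
#' @param counts count matrix (proteins x samples), grand total > 0.
#' @param n_axes number of principal axes to return (default 3).
#' @return object of class `ca_embedding`: `sample_coordinates` (samples x k),
#'   `protein_coordinates` (proteins x k), `axis_inertias`, `total_inertia`.
#' @export
correspondence_analysis <- function(counts, n_axes = 3) {
  counts <- validate_count_matrix(counts)
  if (sum(counts) == 0) stop("grand total is zero", call. = FALSE)
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s) before CA", call. = FALSE)
    counts <- counts[!zr, !zc, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("CA needs >= 2 non-zero rows and columns", call. = FALSE)
  }
  x <- counts / sum(counts)
  r <- rowSums(x)
  cc <- colSums(x)
  s <- sweep(sweep(x - outer(r, cc), 1, sqrt(r), "/"), 2, sqrt(cc), "/")
  dec <- svd(s)
  k_max <- min(nrow(counts), ncol(counts)) - 1
  sv <- dec$d[seq_len(k_max)]
  k <- min(n_axes, k_max)
  # principal coordinates
  row_pc <- sweep(dec$u[, seq_len(k), drop = FALSE], 1, sqrt(r), "/")
  row_pc <- sweep(row_pc, 2, sv[seq_len(k)], "*")
  col_pc <- sweep(dec$v[, seq_len(k), drop = FALSE], 1, sqrt(cc), "/")
  col_pc <- sweep(col_pc, 2, sv[seq_len(k)], "*")
  for (j in seq_len(k)) {
    if (col_pc[which.max(abs(col_pc[, j])), j] < 0) {
      col_pc[, j] <- -col_pc[, j]
      row_pc[, j] <- -row_pc[, j]
    }
  }
  dimnames(row_pc) <- list(rownames(counts), paste0("axis", seq_len(k)))
  dimnames(col_pc) <- list(colnames(counts), paste0("axis", seq_len(k)))
  structure(
    list(sample_coordinates = col_pc, protein_coordinates = row_pc,
         axis_inertias = sv[seq_len(k)]^2, total_inertia = sum(sv^2),
         row_mass = r, col_mass = cc),
    class = "ca_embedding"
  )
}

#' Log/z-score transform for clustering and classification
#'
#' `log2(count + 1)` per cell, optionally followed by a per-protein (row)
#' z-score across samples. Raw spectral counts are heavily right-skewed;
#' this is the conventional expression-heatmap transform.
#'
#' @param counts count matrix.
#' @param zscore z-score each row after the log transform (default TRUE).
#'   Zero-variance rows are left at 0.
#' @return real matrix, same shape.
#' @export
transform_counts <- function(counts, zscore = TRUE) {
  x <- log2(counts + 1)
  if (zscore) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    x <- sweep(x, 1, mu)
    x <- sweep(x, 1, ifelse(sdv == 0, 1, sdv), "/")
  }
  x
}

# 1 - Pearson correlation distance between rows; zero-variance rows get
# maximal distance 1 to everything (with a warning).
correlation_distance <- function(x) {
  sdv <- apply(x, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance row(s): correlation distance set to 1",
            call. = FALSE)
    x[flat, ] <- 0
  }
  cm <- suppressWarnings(stats::cor(t(x)))
  cm[flat, ] <- 0
  cm[, flat] <- 0
  diag(cm) <- 1
  stats::as.dist(1 - cm)
}

#' Hierarchical clustering of an expression matrix
#'
#' Agglomerative clustering of rows, columns, or both (a "two-dimensional"
#' clustering, as used for expression heatmaps). Default distance is
#' 1 - Pearson correlation with average linkage. Input should already be
#' transformed (see [transform_counts()]).
#'
#' @param x real matrix.
#' @param axis `"rows"`, `"columns"`, or `"both"` (default).
#' @param distance `"correlation"` (1 - Pearson, default) or `"euclidean"`.
#' @param linkage any `stats::hclust` method; default `"average"`.
#' @return for a single axis an `hclust` object; for `"both"` a list with
#'   `rows` and `columns`.
#' @export
hierarchical_cluster <- function(x, axis = c("both", "rows", "columns"),
                                 distance = c("correlation", "euclidean"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  one <- function(m) {
    if (nrow(m) < 2) stop("need >= 2 items to cluster", call. = FALSE)
    d <- if (distance == "correlation") correlation_distance(m)
         else stats::dist(m)
    stats::hclust(d, method = linkage)
  }
  switch(axis,
         rows = one(x),
         columns = one(t(x)),
         both = list(rows = one(x), columns = one(t(x))))
}

#' K-medians clustering (L1 Lloyd iterations with restarts)
#'
#' Observations are rows. Each restart initializes centers at `k` distinct
#' data points, then alternates L1 (Manhattan) assignment with coordinate-wise
#' median updates until assignments stabilize. Ties in assignment go to the
#' lowest cluster index; a cluster emptied during iteration is re-seeded at
#' the point farthest (L1) from its current center. The best of `n_restarts`
#' runs by total L1 objective is returned; the whole procedure is
#' deterministic under `seed`.
#'
#' @param x numeric matrix, observations in rows.
#' @param k number of clusters (2 <= k <= nrow(x)).
#' @param n_restarts random restarts (default 50).
#' @param seed integer seed.
#' @param max_iter iteration cap per restart.
#' @return object of class `kmedians_result`: `assignments` (named integer),
#'   `medians` (k x p), `objective`, `n_iterations`, `seed`, `restarts`.
#' @export
kmedians <- function(x, k = 2, n_restarts = 50, seed = 1L, max_iter = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2 || k > n) stop("need 2 <= k <= number of observations",
                           call. = FALSE)
  set.seed(as.integer(seed))
  l1_to_centers <- function(centers) {
    vapply(seq_len(nrow(centers)), function(j) {
      rowSums(abs(sweep(x, 2, centers[j, ])))
    }, numeric(n))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- x[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    it <- 0
    repeat {
      it <- it + 1
      dmat <- l1_to_centers(centers)
      assign_cur <- max.col(-dmat, ties.method = "first")
      for (j in seq_len(k)) {
        if (!any(assign_cur == j)) {          # empty cluster: re-seed
          far <- which.max(dmat[cbind(seq_len(n), assign_cur)])
          assign_cur[far] <- j
          msg("kmedians: empty cluster ", j, " re-seeded")
        }
      }
      if (identical(assign_cur, assign_prev) || it >= max_iter) {
        obj <- sum(dmat[cbind(seq_len(n), assign_cur)])
        break
      }
      assign_prev <- assign_cur
      for (j in seq_len(k)) {
        centers[j, ] <- apply(x[assign_cur == j, , drop = FALSE], 2,
                              stats::median)
      }
    }
    # objective at final assignment against final medians
    for (j in seq_len(k)) {
      centers[j, ] <- apply(x[assign_cur == j, , drop = FALSE], 2,
                            stats::median)
    }
    obj <- sum(l1_to_centers(centers)[cbind(seq_len(n), assign_cur)])
    if (is.null(best) || obj < best$objective) {
      best <- list(assignments = setNames(assign_cur, rownames(x)),
                   medians = centers, objective = obj, n_iterations = it)
    }
  }
  best$seed <- as.integer(seed)
  best$restarts <- n_restarts
  class(best) <- "kmedians_result"
  best
}

#' Agreement between a 2-cluster partition and the study groups
#'
#' Cluster identities are arbitrary, so accuracy is computed under the better
#' of the two cluster-to-group mappings.
#'
#' @param partition `kmedians_result` (or any named assignment vector) with 2
#'   clusters over the design's samples.
#' @param design two-group `study_design`.
#' @return list with `accuracy` (fraction correct), `n_correct`, `mapping`
#'   (cluster id -> group label).
#' @export
match_partition_to_labels <- function(partition, design) {
  assign <- if (inherits(partition, "kmedians_result")) partition$assignments
            else partition
  if (is.null(names(assign))) stop("assignments must be named by sample",
                                   call. = FALSE)
  d <- design[match(names(assign), design$sample), ]
  if (anyNA(d$sample)) stop("partition samples missing from design",
                            call. = FALSE)
  grp <- levels(droplevels(d$group))
  if (length(grp) != 2 || length(unique(assign)) > 2) {
    stop("two clusters and two groups required", call. = FALSE)
  }
  truth <- as.character(d$group)
  hits1 <- sum((assign == 1) == (truth == grp[1]))
  hits2 <- sum((assign == 2) == (truth == grp[1]))
  if (hits1 >= hits2) {
    mapping <- setNames(grp, c("1", "2"))
    n_correct <- hits1
  } else {
    mapping <- setNames(rev(grp), c("1", "2"))
    n_correct <- hits2
  }
  list(accuracy = n_correct / length(assign), n_correct = n_correct,
       mapping = mapping)
}
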
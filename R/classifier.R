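#' Fit a nearest-shrunken-centroid (PAM) classifier
#'
#' Standard shrunken-centroid model for two classes. Per protein `i` and class
#' `k`: overall centroid `xbar_i`, class centroid `xbar_ik`, pooled
#' within-class SD `s_i`, fudge constant `s_0 = median(s_i)`, and
#' `m_k = sqrt(1/n_k - 1/n)`. The standardized offset
#' `d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s_0))` is soft-thresholded,
#' `d'_ik = sign(d_ik) max(|d_ik| - delta, 0)`, and shrunken centroids are
#' `xbar'_ik = xbar_i + m_k (s_i + s_0) d'_ik`. Classification minimizes the
#' discriminant `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s_0)^2 -
#' 2 log pi_k` with priors `pi_k = n_k / n`.
#'
#' Features are expected on a variance-stabilized scale; for spectral counts
#' use [transform_counts()] with `zscore = FALSE` (log2(count + 1)).
#'
#' @param x real feature matrix, proteins x samples.
#' @param design two-group `study_design`.
#' @param delta shrinkage threshold, >= 0.
#' @return object of class `nsc_model`.
#' @export
fit_nsc <- function(x, design, delta = 0) {
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  x <- as.matrix(x)
  d <- pair_design(x, design)
  grp <- levels(d$group)
  n <- ncol(x)
  n_k <- setNames(as.vector(table(d$group)), grp)
  overall <- rowMeans(x)
  cls_cent <- vapply(grp, function(g) {
    rowMeans(x[, d$group == g, drop = FALSE])
  }, numeric(nrow(x)))
  if (!is.matrix(cls_cent)) {
    cls_cent <- matrix(cls_cent, nrow = 1,
                       dimnames = list(rownames(x), grp))
  }
  ss <- 0
  for (g in grp) {
    xg <- x[, d$group == g, drop = FALSE]
    ss <- ss + rowSums((xg - cls_cent[, g])^2)
  }
  pooled_sd <- sqrt(ss / (n - length(grp)))
  if (all(pooled_sd == 0)) {
    stop("all proteins have zero pooled within-class SD", call. = FALSE)
  }
  s0 <- stats::median(pooled_sd)
  m_k <- setNames(sqrt(1 / n_k - 1 / n), grp)
  d_ik <- sweep(cls_cent - overall, 1, pooled_sd + s0, "/")
  d_ik <- sweep(d_ik, 2, m_k, "/")
  d_shrunk <- sign(d_ik) * pmax(abs(d_ik) - delta, 0)
  shrunk_cent <- overall +
    sweep(sweep(d_shrunk, 2, m_k, "*"), 1, pooled_sd + s0, "*")
  structure(
    list(class_labels = grp,
         proteins = rownames(x),
         overall_centroid = overall,
         class_centroids = cls_cent,
         pooled_sd = pooled_sd,
         s0 = s0,
         m_k = m_k,
         delta = delta,
         shrunken_diff = d_shrunk,
         shrunken_centroids = shrunk_cent,
         priors = n_k / n),
    class = "nsc_model"
  )
}

#' Predict classes with a fitted shrunken-centroid model
#'
#' @param object an `nsc_model`.
#' @param newdata feature matrix (proteins x samples) on the training scale;
#'   proteins are matched by name.
#' @param type `"class"` (default) or `"score"` (the per-class discriminants).
#' @param ... unused.
#' @return character vector of class labels, or a samples x classes
#'   discriminant matrix.
#' @export
predict.nsc_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$proteins) && !is.null(rownames(x))) {
    if (!all(object$proteins %in% rownames(x))) {
      stop("newdata lacks model proteins", call. = FALSE)
    }
    x <- x[object$proteins, , drop = FALSE]
  }
  w <- 1 / (object$pooled_sd + object$s0)^2
  disc <- vapply(object$class_labels, function(g) {
    colSums(w * (x - object$shrunken_centroids[, g])^2) -
      2 * log(object$priors[[g]])
  }, numeric(ncol(x)))
  if (ncol(x) == 1L) disc <- matrix(disc, nrow = 1,
                                    dimnames = list(colnames(x),
                                                    object$class_labels))
  if (type == "score") return(disc)
  object$class_labels[max.col(-disc, ties.method = "first")]
}

#' Choose the shrinkage threshold by cross-validation
#'
#' Default scheme is leave-one-out (suited to cohorts of a few dozen
#' subjects); stratified k-fold is available. The chosen delta minimizes CV
#' misclassification error, with ties broken toward the largest delta (the
#' sparsest model).
#'
#' @param x feature matrix, proteins x samples.
#' @param design two-group `study_design`.
#' @param delta_grid candidate thresholds; default 30 values spanning 0 to the
#'   largest unshrunken |d_ik| of the full-data fit.
#' @param scheme `"loo"` (default) or `"kfold"`.
#' @param k_folds folds for `scheme = "kfold"`.
#' @param seed seed for fold assignment (k-fold only).
#' @param min_nonzero when > 0, the tie-break among error-minimizing deltas
#'   prefers the largest delta whose full-data fit still retains at least this
#'   many proteins with a non-zero shrunken score. Use this when a downstream
#'   signature of that size must be selectable from the fitted model; a
#'   fully-shrunk one-protein model cannot yield a 3-protein panel. Falls back
#'   to the unconstrained tie-break if no error-minimizing delta qualifies.
#' @return list with `delta` (chosen), `cv_table` (data.frame: delta, errors,
#'   error_rate, n_nonzero), `scheme`.
#' @export
cross_validate_delta <- function(x, design, delta_grid = NULL,
                                 scheme = c("loo", "kfold"), k_folds = 5,
                                 seed = 1L, min_nonzero = 0) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  d <- pair_design(x, design)
  n <- ncol(x)
  if (is.null(delta_grid)) {
    full <- fit_nsc(x, design, delta = 0)
    delta_grid <- seq(0, max(abs(full$shrunken_diff)), length.out = 30)
  }
  delta_grid <- sort(unique(delta_grid))
  if (scheme == "loo") {
    folds <- as.list(seq_len(n))
  } else {
    set.seed(as.integer(seed))
    fold_id <- integer(n)
    for (g in levels(d$group)) {               # stratified folds
      idx <- sample(which(d$group == g))
      fold_id[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    folds <- split(seq_len(n), fold_id)
  }
  errors <- numeric(length(delta_grid))
  for (fold in folds) {
    train_design <- study_design(colnames(x)[-fold],
                                 as.character(d$group[-fold]))
    if (nlevels(droplevels(factor(d$group[-fold]))) < 2) {
      stop("cross-validation fold left a single class in training; ",
           "use fewer folds or stratify", call. = FALSE)
    }
    for (j in seq_along(delta_grid)) {
      m <- fit_nsc(x[, -fold, drop = FALSE], train_design, delta_grid[j])
      pred <- predict(m, x[, fold, drop = FALSE])
      errors[j] <- errors[j] + sum(pred != as.character(d$group[fold]))
    }
  }
  full <- fit_nsc(x, design, delta = 0)
  n_nonzero <- vapply(delta_grid, function(del) {
    sum(apply(abs(full$shrunken_diff), 1, max) > del)
  }, 0)
  cv <- data.frame(delta = delta_grid, errors = errors,
                   error_rate = errors / n, n_nonzero = n_nonzero)
  minimal <- which(errors == min(errors))
  eligible <- minimal[n_nonzero[minimal] >= min_nonzero]
  best <- if (length(eligible) > 0) max(eligible) else max(minimal)
  list(delta = delta_grid[best], cv_table = cv, scheme = scheme)
}

#' Select a limited classifier signature
#'
#' Intersects proteins carrying a non-zero shrunken discrimination score
#' (`max_k |d'_ik| > 0`) with proteins significant in the paired
#' spectral-index differential result, ranks them by discrimination score
#' descending, and keeps the top `size`. Each member gets a direction sign:
#' +1 if up in the positive class (group A, SI > 0), -1 otherwise.
#'
#' @param model fitted `nsc_model`.
#' @param differential `differential_result` over the same protein universe.
#' @param size signature size (default 3).
#' @return object of class `signature`: data.frame with `protein`, `score`,
#'   `direction`.
#' @export
select_signature <- function(model, differential, size = 3) {
  rec <- differential$records
  score <- apply(abs(model$shrunken_diff), 1, max)
  names(score) <- model$proteins
  eligible <- names(score)[score > 0]
  sig_prot <- rec$protein[rec$significant]
  eligible <- intersect(eligible, sig_prot)
  if (length(eligible) < size) {
    warning("only ", length(eligible), " eligible proteins for a size-",
            size, " signature", call. = FALSE)
  }
  eligible <- eligible[order(-score[eligible])]
  chosen <- utils::head(eligible, size)
  dir <- ifelse(rec$si[match(chosen, rec$protein)] > 0, 1L, -1L)
  structure(
    data.frame(protein = chosen, score = unname(score[chosen]),
               direction = dir, stringsAsFactors = FALSE),
    class = c("signature", "data.frame")
  )
}

#' Combined classifier score for a protein signature
#'
#' For each signature protein the raw spectral counts are z-scored across all
#' samples (mean 0, SD 1), multiplied by the protein's direction sign, and
#' summed per sample into a single diagnostic score. A zero-variance protein
#' contributes 0 (with a warning). Set `log_scale = TRUE` to z-score
#' log2(count + 1) instead of raw counts.
#'
#' @param counts count matrix containing all signature proteins.
#' @param signature a `signature`.
#' @param log_scale z-score log-transformed counts instead of raw.
#' @return named numeric vector, one score per sample.
#' @export
combined_score <- function(counts, signature, log_scale = FALSE) {
  if (!all(signature$protein %in% rownames(counts))) {
    stop("signature proteins missing from count matrix", call. = FALSE)
  }
  x <- counts[signature$protein, , drop = FALSE]
  if (log_scale) x <- log2(x + 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0)) {
    warning("zero-variance signature protein(s) contribute 0: ",
            paste(signature$protein[sdv == 0], collapse = ", "),
            call. = FALSE)
  }
  z <- sweep(x, 1, mu)
  z <- sweep(z, 1, ifelse(sdv == 0, Inf, sdv), "/")
  colSums(z * signature$direction)
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' score >= threshold). AUC is the trapezoidal area under sensitivity vs
#' 1 - specificity, which equals the tie-corrected Mann-Whitney U statistic.
#' The Youden point maximizes sensitivity + specificity - 1; ties go to the
#' point with higher sensitivity.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param design two-group `study_design` covering the scored samples.
#' @param positive label of the positive class; default the design's first
#'   group level.
#' @return object of class `roc_curve`: `curve` (data.frame: threshold,
#'   sensitivity, specificity), `auc`, `youden` (threshold, sensitivity,
#'   specificity), `positive`.
#' @export
roc_curve <- function(scores, design, positive = NULL) {
  if (is.null(names(scores))) stop("scores must be named by sample",
                                   call. = FALSE)
  d <- design[match(names(scores), design$sample), ]
  if (anyNA(d$sample)) stop("scored samples missing from design",
                            call. = FALSE)
  d$group <- droplevels(d$group)
  if (nlevels(d$group) != 2) stop("two groups required", call. = FALSE)
  if (is.null(positive)) positive <- levels(d$group)[1]
  is_pos <- d$group == positive
  if (all(is_pos) || !any(is_pos)) stop("one class is empty", call. = FALSE)
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[is_pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!is_pos] < t), 0)
  ord <- order(1 - spec, sens)                  # left to right in ROC space
  fpr <- (1 - spec)[ord]
  tpr <- sens[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]
  structure(
    list(curve = data.frame(threshold = thr, sensitivity = sens,
                            specificity = spec),
         auc = auc,
         youden = c(threshold = thr[best], sensitivity = sens[best],
                    specificity = spec[best]),
         positive = positive),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC (positive = %s): AUC %.4f\n", x$positive, x$auc))
  cat(sprintf("  Youden point: threshold %.4g, sensitivity %.1f%%, specificity %.1f%%\n",
              x$youden[["threshold"]], 100 * x$youden[["sensitivity"]],
              100 * x$youden[["specificity"]]))
  invisible(x)
}
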
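#' Default pipeline configuration
#'
#' Parameters default to the study-scale conventions used throughout the
#' package: 10,000 permutations at 95% confidence, a size-3 signature, k = 2
#' clusters. `counts`/`design` may point at TSV inputs; when both are NULL a
#' synthetic dataset is generated (field `simulate` holds overrides for
#' [synthetic_config()]).
#'
#' @param out_dir output directory.
#' @param seed global seed; per-stage substream seeds are derived from it, so
#'   adding a stage never perturbs earlier stages' randomness.
#' @param ... overrides of any default field (unknown fields are rejected at
#'   validation).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "specount_run", seed = 1L, ...) {
  cfg <- list(
    counts = NULL, design = NULL, gmt = NULL,
    simulate = list(),
    n_perm = 10000, confidence = 0.95, mode = "global",
    signature_size = 3, k = 2, n_restarts = 50,
    cv_scheme = "loo",
    n_perm_enrichment = 10000,
    seed = as.integer(seed), out_dir = out_dir
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown pipeline config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Fields absent from `cfg` are filled with the package defaults, so a JSON
#' config file only needs the overrides; unknown fields are rejected.
#'
#' @param cfg list of pipeline fields (as from [pipeline_config()] or parsed
#'   from a JSON config file).
#' @return the validated config, classed `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  defaults <- list(counts = NULL, design = NULL, gmt = NULL,
                   simulate = list(), n_perm = 10000, confidence = 0.95,
                   mode = "global", signature_size = 3, k = 2,
                   n_restarts = 50, cv_scheme = "loo",
                   n_perm_enrichment = 10000, seed = 1L,
                   out_dir = "specount_run")
  template <- names(defaults)
  unknown <- setdiff(names(cfg), template)
  if (length(unknown) > 0) {
    stop("unknown pipeline config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_f <- setdiff(template, names(cfg))
  cfg[missing_f] <- defaults[missing_f]
  if (is.list(cfg$simulate)) cfg$simulate <- cfg$simulate[
    !vapply(cfg$simulate, is.null, NA)]
  if (cfg$confidence <= 0 || cfg$confidence > 1) {
    stop("confidence must be in (0, 1]", call. = FALSE)
  }
  if (!cfg$mode %in% c("global", "per_protein")) {
    stop("mode must be 'global' or 'per_protein'", call. = FALSE)
  }
  if (cfg$n_perm < 1 || cfg$signature_size < 1 || cfg$k < 2) {
    stop("n_perm >= 1, signature_size >= 1, k >= 2 required", call. = FALSE)
  }
  if (xor(is.null(cfg$counts), is.null(cfg$design))) {
    stop("provide both counts and design paths, or neither", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

# seed substream: stable per stage index, independent of other stages
stage_seed <- function(seed, stage) {
  ((as.integer(seed) %% 100000L) * 10007L + stage * 101L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or simulate counts + design; (2) presence filter;
#' (3) spectral-index differential expression; (4) correspondence analysis;
#' (5) two-dimensional hierarchical clustering of differential proteins;
#' (6) shrunken-centroid training with cross-validated shrinkage, signature
#' selection, combined score, ROC; (7) K-medians clustering of the signature
#' profiles; (8) optional over-representation analysis of the significant
#' proteins against a GMT file. Every stage's output is written as TSV/JSON
#' under `out_dir` and recorded in `manifest.json`; re-running the same
#' config reproduces byte-identical tables. On stage failure, outputs written
#' so far are renamed with a `.partial` suffix.
#'
#' @param config a `pipeline_config`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character(0)
  note <- function(path) written <<- c(written, path)
  manifest <- list(package_version = as.character(
    utils::packageVersion("specount")),
    config = unclass(config), stages = list())
  current_stage <- "setup"

  res <- tryCatch({
    # stage 1: inputs
    current_stage <- "input"
    if (is.null(config$counts)) {
      sim_args <- config$simulate
      sim_args$seed <- stage_seed(config$seed, 1L)
      sim <- generate_counts(do.call(synthetic_config, sim_args))
      counts <- sim$counts
      design <- sim$design
      write_count_matrix(counts, out("counts.tsv")); note(out("counts.tsv"))
      write_design(design, out("design.tsv"));       note(out("design.tsv"))
      write_tsv(sim$truth, out("truth.tsv"));        note(out("truth.tsv"))
      manifest$stages$input <- list(source = "simulated",
                                    seed = sim_args$seed,
                                    n_proteins = nrow(counts),
                                    n_samples = ncol(counts))
    } else {
      counts <- read_count_matrix(config$counts)
      design <- read_design(config$design)
      manifest$stages$input <- list(source = "files", counts = config$counts,
                                    design = config$design,
                                    n_proteins = nrow(counts),
                                    n_samples = ncol(counts))
    }

    # stage 2: presence filter
    current_stage <- "filter"
    filtered <- apply_presence_filter(counts, design)
    write_count_matrix(filtered, out("filtered_counts.tsv"))
    note(out("filtered_counts.tsv"))
    manifest$stages$filter <- list(before = nrow(counts),
                                   after = nrow(filtered))

    # stage 3: differential expression
    current_stage <- "differential"
    de_seed <- stage_seed(config$seed, 3L)
    de <- call_differential(filtered, design, n_perm = config$n_perm,
                            confidence = config$confidence,
                            mode = config$mode, seed = de_seed)
    write_differential_table(de, out("differential.tsv"))
    note(out("differential.tsv"))
    manifest$stages$differential <- list(
      seed = de_seed, n_permutations = de$n_permutations,
      null_band = as.vector(de$null_band),
      significant = sum(de$records$significant),
      up_in_A = sum(de$records$direction == "up_in_A"),
      up_in_B = sum(de$records$direction == "up_in_B"))

    # stage 4: correspondence analysis
    current_stage <- "ca"
    ca <- correspondence_analysis(filtered, n_axes = 3)
    write_tsv(data.frame(sample = rownames(ca$sample_coordinates),
                         ca$sample_coordinates, check.names = FALSE),
              out("ca_samples.tsv")); note(out("ca_samples.tsv"))
    write_tsv(data.frame(protein = rownames(ca$protein_coordinates),
                         ca$protein_coordinates, check.names = FALSE),
              out("ca_proteins.tsv")); note(out("ca_proteins.tsv"))
    manifest$stages$ca <- list(axis_inertias = ca$axis_inertias,
                               total_inertia = ca$total_inertia)

    # stage 5: hierarchical clustering of differential proteins
    current_stage <- "hcluster"
    sig_prot <- de$records$protein[de$records$significant]
    if (length(sig_prot) >= 2) {
      hm <- transform_counts(filtered[sig_prot, , drop = FALSE])
      hc <- hierarchical_cluster(hm, axis = "both")
      dend_json <- lapply(hc, function(h) {
        list(merge = h$merge, height = h$height, order = h$order,
             labels = h$labels, linkage = h$method, distance = "correlation")
      })
      jsonlite::write_json(dend_json, out("dendrograms.json"), digits = NA)
      note(out("dendrograms.json"))
      manifest$stages$hcluster <- list(n_proteins = length(sig_prot))
    } else {
      manifest$stages$hcluster <- list(skipped = "fewer than 2 significant")
    }

    # stage 6: classifier
    current_stage <- "classifier"
    feats <- transform_counts(filtered, zscore = FALSE)
    cv <- cross_validate_delta(feats, design, scheme = config$cv_scheme,
                               seed = stage_seed(config$seed, 6L),
                               min_nonzero = config$signature_size)
    write_tsv(cv$cv_table, out("cv_table.tsv")); note(out("cv_table.tsv"))
    model <- fit_nsc(feats, design, delta = cv$delta)
    save_model(model, out("model.json")); note(out("model.json"))
    sig <- select_signature(model, de, size = config$signature_size)
    write_signature(sig, out("signature.tsv")); note(out("signature.tsv"))
    scores <- combined_score(filtered, sig)
    write_tsv(data.frame(sample = names(scores),
                         score = fmt_num(scores)), out("scores.tsv"))
    note(out("scores.tsv"))
    roc <- roc_curve(scores, design)
    write_tsv(roc$curve, out("roc.tsv")); note(out("roc.tsv"))
    manifest$stages$classifier <- list(
      delta = cv$delta, cv_error_rate = min(cv$cv_table$error_rate),
      signature = sig$protein, auc = roc$auc,
      youden = as.list(roc$youden))

    # stage 7: K-medians on signature profiles
    current_stage <- "kmedians"
    km_seed <- stage_seed(config$seed, 7L)
    km_x <- t(transform_counts(filtered[sig$protein, , drop = FALSE]))
    km <- kmedians(km_x, k = config$k, n_restarts = config$n_restarts,
                   seed = km_seed)
    agree <- match_partition_to_labels(km, design)
    write_tsv(data.frame(sample = names(km$assignments),
                         cluster = km$assignments), out("kmedians.tsv"))
    note(out("kmedians.tsv"))
    manifest$stages$kmedians <- list(seed = km_seed,
                                     objective = km$objective,
                                     accuracy = agree$accuracy,
                                     n_correct = agree$n_correct)

    # stage 8: enrichment (optional)
    if (!is.null(config$gmt)) {
      current_stage <- "enrichment"
      ann <- read_gmt(config$gmt)
      enr <- test_enrichment(sig_prot, rownames(filtered), ann,
                             n_perm = config$n_perm_enrichment,
                             seed = stage_seed(config$seed, 8L))
      write_enrichment_table(enr, out("enrichment.tsv"))
      note(out("enrichment.tsv"))
      manifest$stages$enrichment <- list(
        n_categories = nrow(enr), significant = sum(enr$significant))
    }
    TRUE
  }, error = function(e) e)

  if (inherits(res, "error")) {
    for (f in written) if (file.exists(f)) {
      file.rename(f, paste0(f, ".partial"))
    }
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(res), call. = FALSE)
  }
  manifest$outputs <- written
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  msg("pipeline complete: ", length(written), " outputs in ", config$out_dir)
  invisible(manifest)
}
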
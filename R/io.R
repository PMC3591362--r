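#' Validate a spectral-count matrix
#'
#' A count matrix is an integer matrix with proteins as rows and samples as
#' columns, unique non-empty dimnames on both axes, and non-negative integer
#' entries. Missing detections are encoded as 0; there is no NA state, because
#' spectral counting cannot distinguish "absent" from "undetected".
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, with storage mode integer.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix", call. = FALSE)
  pid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(pid) || is.null(sid)) {
    stop("count matrix must have protein rownames and sample colnames",
         call. = FALSE)
  }
  if (any(!nzchar(pid)) || any(!nzchar(sid))) {
    stop("empty identifier in count matrix dimnames", call. = FALSE)
  }
  if (anyDuplicated(pid)) {
    stop("duplicate protein identifiers: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(counts))) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-numeric count at protein '%s', sample '%s'",
                 pid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at protein '%s', sample '%s'",
                 pid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at protein '%s', sample '%s'",
                 pid[bad[1]], sid[bad[2]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a protein-by-sample spectral-count matrix from TSV
#'
#' Expects a tab-delimited UTF-8 file whose first row is the sample header and
#' whose first column holds protein identifiers. Cells must be non-negative
#' integers; nothing is silently coerced.
#'
#' @param path file path.
#' @param sep field separator, default tab.
#' @return validated integer matrix (proteins x samples).
#' @export
read_count_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("count matrix needs >= 1 sample column", call. = FALSE)
  pid <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], function(x) as.numeric(x), numeric(nrow(df)))
  )
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1)
  counts <- matrix(num, nrow = nrow(df),
                   dimnames = list(pid, colnames(df)[-1]))
  validate_count_matrix(counts)
}

#' Write a spectral-count matrix as TSV
#'
#' Inverse of [read_count_matrix()]: integer cells are written bit-exactly.
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- validate_count_matrix(counts)
  df <- data.frame(protein = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Construct a two-group study design
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param groups group label per sample. Group order (hence which group plays
#'   "group A" in differential statistics) follows first appearance unless
#'   `groups` is already a factor.
#' @return data.frame with columns `sample`, `group` (factor), class
#'   `study_design`.
#' @export
study_design <- function(sample_ids, groups) {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(groups)) {
    stop("sample_ids and groups differ in length", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample in design: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (any(table(groups) < 2)) {
    stop("every group needs >= 2 samples", call. = FALSE)
  }
  structure(
    data.frame(sample = sample_ids, group = groups, stringsAsFactors = FALSE),
    class = c("study_design", "data.frame")
  )
}

#' Read a sample-to-group design table (TSV: sample_id, group)
#'
#' @param path file path.
#' @return a [study_design()] object; group sizes are reported via `message`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          quote = "", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("design table needs columns sample, group",
                         call. = FALSE)
  d <- study_design(df[[1]], df[[2]])
  msg("design: ", paste(sprintf("%s (n = %d)", levels(d$group),
                                tabulate(d$group)), collapse = ", "))
  d
}

#' Write a study design as TSV
#' @param design a `study_design`.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  write_tsv(data.frame(sample = design$sample,
                       group = as.character(design$group)), path)
}

# Pair a design with a matrix: checks coverage, returns design in matrix
# column order and restricted to two groups.
pair_design <- function(counts, design, require_two = TRUE) {
  if (!all(colnames(counts) %in% design$sample)) {
    stop("samples absent from design: ",
         paste(setdiff(colnames(counts), design$sample), collapse = ", "),
         call. = FALSE)
  }
  d <- design[match(colnames(counts), design$sample), , drop = FALSE]
  d$group <- droplevels(d$group)
  if (require_two && nlevels(d$group) != 2) {
    stop("two-group operation requires exactly 2 groups, found ",
         nlevels(d$group), call. = FALSE)
  }
  if (any(table(d$group) < 2)) {
    stop("every group needs >= 2 samples after pairing", call. = FALSE)
  }
  d
}

#' Read protein sets from a GMT file
#'
#' Standard GMT: one category per line, fields `name`, `description`,
#' `member...`, tab-separated. Duplicate members are de-duplicated; lines with
#' no members are skipped with a warning.
#'
#' @param path file path.
#' @return named list of character vectors with a `description` attribute
#'   (named character vector), class `annotation_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(fields) >= 3
  if (any(!keep)) {
    warning(sum(!keep), " GMT line(s) without members skipped", call. = FALSE)
  }
  fields <- fields[keep]
  if (length(fields) == 0) stop("no usable GMT categories in ", path,
                                call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicate GMT category names", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(fields, `[[`, "", 2)
  names(desc) <- nm
  structure(sets, description = desc, class = "annotation_collection")
}

#' Write an annotation collection as GMT
#' @param annotations `annotation_collection` (named list of protein sets).
#' @param path output path.
#' @export
write_gmt <- function(annotations, path) {
  desc <- attr(annotations, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(annotations)),
                                      names(annotations))
  lines <- vapply(names(annotations), function(nm) {
    paste(c(nm, desc[[nm]], annotations[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
}

#' Write a differential-expression result table as TSV
#'
#' Columns: protein, si, r_A, r_B, f_A, f_B, p, significant, direction.
#' Numeric fields are written at full precision (17 significant digits) so the
#' read/write pair is lossless.
#'
#' @param result a `differential_result` (see [call_differential()]).
#' @param path output path.
#' @export
write_differential_table <- function(result, path) {
  rec <- result$records
  df <- data.frame(protein = rec$protein,
                   si = fmt_num(rec$si),
                   r_A = fmt_num(rec$r_A), r_B = fmt_num(rec$r_B),
                   f_A = fmt_num(rec$f_A), f_B = fmt_num(rec$f_B),
                   p = fmt_num(rec$p_empirical),
                   significant = rec$significant,
                   direction = rec$direction,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a differential table written by [write_differential_table()]
#' @param path file path.
#' @return data.frame with the table's columns, `p` named `p_empirical`.
#' @export
read_differential_table <- function(path) {
  df <- utils::read.delim(path, quote = "", fileEncoding = "UTF-8")
  names(df)[names(df) == "p"] <- "p_empirical"
  df$protein <- as.character(df$protein)
  df$direction <- as.character(df$direction)
  df
}

#' Write a classifier signature as TSV
#' @param signature a `signature` (see [select_signature()]).
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  write_tsv(data.frame(protein = signature$protein,
                       score = fmt_num(signature$score),
                       direction = signature$direction), path)
}

#' Write enrichment records as TSV
#' @param records data.frame from [test_enrichment()].
#' @param path output path.
#' @export
write_enrichment_table <- function(records, path) {
  df <- records
  for (col in c("p_empirical", "fdr")) df[[col]] <- fmt_num(df[[col]])
  write_tsv(df, path)
}

#' Serialize a nearest-shrunken-centroid model to JSON
#' @param model an `nsc_model` (see [fit_nsc()]).
#' @param path output path.
#' @export
save_model <- function(model, path) {
  payload <- unclass(model)
  payload$class_centroids <- as.data.frame(payload$class_centroids)
  payload$shrunken_centroids <- as.data.frame(payload$shrunken_centroids)
  payload$shrunken_diff <- as.data.frame(payload$shrunken_diff)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model written by [save_model()]
#' @param path file path.
#' @return an `nsc_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(df) {
    m <- as.matrix(df)
    rownames(m) <- p$proteins
    colnames(m) <- p$class_labels
    m
  }
  model <- list(
    class_labels = p$class_labels,
    proteins = p$proteins,
    overall_centroid = setNames(p$overall_centroid, p$proteins),
    class_centroids = to_mat(p$class_centroids),
    pooled_sd = setNames(p$pooled_sd, p$proteins),
    s0 = p$s0,
    m_k = setNames(p$m_k, p$class_labels),
    delta = p$delta,
    shrunken_diff = to_mat(p$shrunken_diff),
    shrunken_centroids = to_mat(p$shrunken_centroids),
    priors = setNames(p$priors, p$class_labels)
  )
  class(model) <- "nsc_model"
  model
}

# ---- internal helpers -------------------------------------------------------

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

# full-precision numeric formatting for lossless TSV round-trips
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

msg <- function(...) message("[specount] ", ...)
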
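#' Expression matrix container
#'
#' Wraps a feature-by-sample numeric matrix together with a processing flag
#' and the set of constant (zero-variance) features detected during
#' preprocessing. Rows are features (miRNAs or mRNAs), columns are samples;
#' both must carry unique identifiers.
#'
#' @param values numeric matrix with rownames (feature IDs) and colnames
#'   (sample IDs).
#' @param processed logical; `TRUE` once values are log2-transformed and
#'   per-feature standardized.
#' @param constant_features character vector of feature IDs whose expression
#'   was constant across samples (their standardized rows are all zero).
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, processed = FALSE, constant_features = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(values = values, processed = isTRUE(processed),
         constant_features = constant_features),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$processed) "log2 + standardized" else "raw"))
  if (length(x$constant_features)) {
    cat(sprintf("  %d constant feature(s) zeroed\n", length(x$constant_features)))
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Read an expression matrix from TSV
#'
#' The file must be tab-separated with a header row and a leading identifier
#' column. By default rows are features and columns samples; transposed files
#' are handled via `orientation = "samples_in_rows"`.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @return an [expr_matrix()] in features-by-samples orientation.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs an ID column plus data columns", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1, 1]], colnames(vals)[bad[1, 2]],
                 vals[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  if (anyNA(num)) stop("missing values in expression TSV", call. = FALSE)
  if (orientation == "samples_in_rows") num <- t(num)
  expr_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' Values are written with a fixed decimal format so that a read/write/read
#' round-trip reproduces them exactly.
#'
#' @param m an [expr_matrix()].
#' @param path output path.
#' @param digits number of decimal digits kept in the fixed format.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, digits = 10) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- tibble::as_tibble(
    formatC(m$values, format = "f", digits = digits),
    .name_repair = "minimal"
  )
  df <- dplyr::bind_cols(tibble::tibble(feature_id = feature_ids(m)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Log2-transform and standardize expression values
#'
#' Applies `log2(value + pseudocount)` and then centers/scales every feature
#' row to mean 0 and standard deviation 1, using the population (divide-by-n)
#' standard deviation. Pearson correlations are invariant to the denominator
#' convention, so this choice only affects the stored values. Constant rows
#' are left at zero and recorded in `constant_features`; they are excluded
#' from downstream correlation testing.
#'
#' @param m an [expr_matrix()] of non-negative raw abundances.
#' @param pseudocount non-negative offset added before the log (default 1).
#' @return a processed [expr_matrix()].
#' @export
preprocess_expression <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$processed) stop("expression matrix is already preprocessed", call. = FALSE)
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  if (any(m$values < 0)) stop("negative expression values; expected raw abundances", call. = FALSE)
  x <- log2(m$values + pseudocount)
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  const <- sd_pop == 0
  z <- (x - mu) / ifelse(const, 1, sd_pop)
  z[const, ] <- 0
  expr_matrix(z, processed = TRUE, constant_features = rownames(x)[const])
}

#' Read a sample annotation table
#'
#' Expects a TSV with columns `sample_id`, `subtype`, `stage`. Empty subtype
#' cells mark samples without a subtype label; they are kept (for stage
#' classification) but excluded from subtype-based dysregulation analyses.
#'
#' @param path path to the annotation TSV.
#' @param label_order ordered character vector of admissible stage labels,
#'   coarsest first (e.g. `c("normal", "I", "II", "III", "IV")`).
#' @return a `group_design` tibble with columns `sample_id`, `subtype`
#'   (`NA` when unlabeled) and `stage` (ordered factor).
#' @export
read_group_design <- function(path, label_order = c("normal", "I", "II", "III", "IV")) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    subtype = readr::col_character(),
    stage = readr::col_character()
  ), progress = FALSE)
  group_design(df$sample_id, df$subtype, df$stage, label_order)
}

#' Construct a sample group design
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param subtype character vector of subtype labels (`NA`/`""` = unlabeled).
#' @param stage character vector of stage labels within `label_order`
#'   (`NA`/`""` allowed).
#' @param label_order ordered set of admissible stage labels.
#' @return a tibble of class `group_design`.
#' @export
group_design <- function(sample_ids, subtype = NA_character_, stage = NA_character_,
                         label_order = c("normal", "I", "II", "III", "IV")) {
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers in design", call. = FALSE)
  subtype <- as.character(subtype)
  stage <- as.character(stage)
  subtype[!is.na(subtype) & subtype == ""] <- NA_character_
  stage[!is.na(stage) & stage == ""] <- NA_character_
  bad <- stats::na.omit(setdiff(unique(stage), label_order))
  if (length(bad)) {
    stop("stage label(s) outside label_order: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(sample_ids),
    subtype = subtype,
    stage = factor(stage, levels = label_order, ordered = TRUE)
  )
  class(out) <- c("group_design", class(out))
  attr(out, "label_order") <- label_order
  out
}

#' Sizes of the subtype groups in a design
#'
#' @param design a `group_design`.
#' @return tibble with columns `subtype`, `n`.
#' @export
subtype_sizes <- function(design) {
  design |>
    dplyr::filter(!is.na(.data$subtype)) |>
    dplyr::count(.data$subtype, name = "n")
}

#' Write a sample annotation table
#' @param design a `group_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_design <- function(design, path) {
  out <- tibble::tibble(
    sample_id = design$sample_id,
    subtype = ifelse(is.na(design$subtype), "", design$subtype),
    stage = ifelse(is.na(design$stage), "", as.character(design$stage))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Restrict matched data to shared samples
#'
#' Intersects the sample IDs of the miRNA matrix, the mRNA matrix and the
#' design and reorders all three to an identical sample order. Idempotent.
#'
#' @param mirna,mrna [expr_matrix()] objects.
#' @param design a `group_design`.
#' @return list with elements `mirna`, `mrna`, `design`.
#' @export
align_samples <- function(mirna, mrna, design) {
  stopifnot(inherits(mirna, "expr_matrix"), inherits(mrna, "expr_matrix"))
  shared <- intersect(intersect(sample_ids(mirna), sample_ids(mrna)), design$sample_id)
  if (length(shared) == 0) stop("no samples shared across matrices and design", call. = FALSE)
  shared <- sort(shared)
  m1 <- mirna; m1$values <- mirna$values[, shared, drop = FALSE]
  m2 <- mrna; m2$values <- mrna$values[, shared, drop = FALSE]
  d <- design[match(shared, design$sample_id), , drop = FALSE]
  list(mirna = m1, mrna = m2, design = d)
}

#' Read a pipeline configuration file
#'
#' Reads a JSON configuration and merges it over the package defaults.
#' Recognised keys: `p_threshold`, `require_negative`, `beta`, `r2_min`,
#' `threshold_grid`, `threshold` (fixed hard threshold; overrides grid
#' selection when non-null), `sgl_lambda`, `sgl_alpha`, `seed`,
#' `label_order`, `pseudocount`.
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return a named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(
    p_threshold = 0.001,
    require_negative = TRUE,
    beta = 1,
    r2_min = 0.8,
    threshold_grid = seq(0.05, 0.95, by = 0.05),
    threshold = NULL,
    sgl_lambda = 1.0,
    sgl_alpha = 0.5,
    seed = 1L,
    label_order = c("normal", "I", "II", "III", "IV"),
    pseudocount = 1
  )
  if (is.null(path)) return(defaults)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
    user <- user[setdiff(names(user), unknown)]
  }
  utils::modifyList(defaults, user)
}
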
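#' Extract the full feature table from case records
#'
#' One row per case: identifiers, label, the four histogram-moment intensity
#' features and the 14 directional-mean GLCM texture features. This table is
#' the single hand-off artifact between feature extraction and modelling, so
#' the statistical stages are testable with hand-written tables too.
#'
#' @param cases List of `"case_record"` objects (see [load_manifest()] or
#'   [generate_dataset()]).
#' @param levels Gray levels for quantization (default 8).
#' @param d GLCM pixel distance (default 1).
#' @return A data.frame with columns `case_id`, `patient_id`, `label`, the
#'   intensity features (`Mean`, `Variance`, `Skewness`, `Kurtosis`) and the
#'   14 texture features.
#' @export
extract_features <- function(cases, levels = 8L, d = 1L) {
  stopifnot(length(cases) >= 1L)
  rows <- lapply(cases, function(cs) {
    stopifnot(inherits(cs, "case_record"))
    px <- masked_pixels(cs$image, cs$mask)
    mom <- compute_moments(px)
    tex <- glcm_features(cs$image, cs$mask, levels = levels, d = d)
    c(list(case_id = cs$case_id, patient_id = cs$patient_id,
           label = cs$label,
           Mean = mom$mean, Variance = mom$variance,
           Skewness = mom$skewness, Kurtosis = mom$kurtosis),
      as.list(tex))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Names of all feature columns in a feature table
#'
#' @param table A feature table data.frame.
#' @return Character vector of feature column names present.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("case_id", "patient_id", "label"))
}

.check_feature_table <- function(table, features = NULL) {
  if (!is.data.frame(table) || !"label" %in% names(table)) {
    stop("feature table must be a data.frame with a `label` column",
         call. = FALSE)
  }
  bad <- setdiff(unique(as.character(table$label)), c("tendinopathy", "tear"))
  if (length(bad) || anyNA(table$label)) {
    stop("labels must be 'tendinopathy' or 'tear' with no missing values",
         call. = FALSE)
  }
  if (!is.null(features)) {
    missing_cols <- setdiff(features, names(table))
    if (length(missing_cols)) {
      stop("feature table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  invisible(table)
}
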
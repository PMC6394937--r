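#' Run configuration for the end-to-end pipeline
#'
#' Defaults reproduce the reference analysis settings: 8 gray levels,
#' distance 1, all four directions, screening at alpha 0.05, classification
#' threshold 0.5.
#'
#' @param levels Gray levels for GLCM quantization.
#' @param d GLCM pixel distance.
#' @param alpha Screening significance level.
#' @param selection_mode `"inside"` (backward elimination repeated within
#'   each LOOCV training fold; leakage-free default) or `"pooled"` (selection
#'   once on all data, then LOOCV of the fixed set).
#' @param threshold Tear-probability classification threshold.
#' @param seed Seed for the phantom simulation.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(levels = 8L, d = 1L, alpha = 0.05,
                       selection_mode = c("inside", "pooled"),
                       threshold = 0.5, seed = 20190228L) {
  structure(
    list(levels = as.integer(levels), d = as.integer(d), alpha = alpha,
         selection_mode = match.arg(selection_mode), threshold = threshold,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# Drop features that are numerically aliased (exact linear combinations of
# the others plus the intercept) so that downstream fits are identifiable.
# With 8-level distance-1 GLCMs whose difference distribution is supported
# on few values, several inverse-difference-type statistics collapse to
# affine combinations of the same probabilities, so aliasing is a real
# occurrence on homogeneous data, not just a pathological input.
.prune_aliased <- function(table, features) {
  F <- as.matrix(table[, features, drop = FALSE])
  sds <- apply(F, 2, stats::sd)
  keep <- features[sds > 0]
  if (length(keep) < length(features)) {
    message("dropping constant feature(s): ",
            paste(setdiff(features, keep), collapse = ", "))
  }
  X <- cbind(1, scale(F[, keep, drop = FALSE]))
  q <- qr(X, tol = 1e-9)
  if (q$rank < ncol(X)) {
    kept_cols <- sort(q$pivot[seq_len(q$rank)])
    kept_cols <- setdiff(kept_cols, 1L) - 1L   # drop intercept index
    dropped <- setdiff(keep, keep[kept_cols])
    message("dropping aliased feature(s): ",
            paste(dropped, collapse = ", "))
    keep <- keep[kept_cols]
  }
  keep
}

# provenance block written next to every stage output
.write_provenance <- function(dir, extra = list()) {
  info <- c(list(
    package = "sonotear",
    version = as.character(utils::packageVersion("sonotear")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), extra)
  jsonlite::write_json(info, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(info)
}

#' Pipeline stage: simulate a phantom dataset
#'
#' @param out_dir Output directory for images, masks and manifest.
#' @param cfg A `"phantom_config"` (default configuration if omitted).
#' @return The manifest data.frame, invisibly.
#' @export
ctc_simulate <- function(out_dir, cfg = phantom_config()) {
  ds <- generate_dataset(cfg, dir = out_dir)
  .write_provenance(out_dir, list(stage = "simulate",
                                  config = unclass(cfg)))
  message("simulated ", length(ds$cases), " cases into ", out_dir)
  invisible(ds$manifest)
}

#' Pipeline stage: extract the feature table
#'
#' @param manifest_csv Manifest path.
#' @param image_dir Directory with the referenced files (manifest directory
#'   by default).
#' @param out_csv Output CSV for the feature table.
#' @param cfg A `"run_config"`.
#' @return The feature table, invisibly.
#' @export
ctc_extract <- function(manifest_csv, out_csv,
                        image_dir = dirname(manifest_csv),
                        cfg = run_config()) {
  cases <- load_manifest(manifest_csv, image_dir)
  tab <- extract_features(cases, levels = cfg$levels, d = cfg$d)
  utils::write.csv(tab, out_csv, row.names = FALSE)
  .write_provenance(dirname(out_csv), list(stage = "extract",
                                           config = unclass(cfg)))
  message("extracted ", nrow(tab), " x ", length(feature_columns(tab)),
          " feature table to ", out_csv)
  invisible(tab)
}

#' Pipeline stage: univariate feature screening
#'
#' @param features_csv Feature-table CSV from [ctc_extract()].
#' @param out_csv Output CSV for the screening report.
#' @param cfg A `"run_config"`.
#' @return The screening report, invisibly.
#' @export
ctc_screen <- function(features_csv, out_csv, cfg = run_config()) {
  tab <- utils::read.csv(features_csv)
  rep <- screen_features(tab, alpha = cfg$alpha)
  utils::write.csv(rep, out_csv, row.names = FALSE)
  message(sum(rep$significant), "/", nrow(rep),
          " features significant at alpha ", cfg$alpha)
  invisible(rep)
}

#' Pipeline stage: train, select and evaluate the classifier
#'
#' Runs the three standard feature sets (intensity, texture, combined)
#' through backward elimination and LOOCV, and writes the model, the
#' per-case predictions and a side-by-side performance report.
#'
#' Under `selection_mode = "pooled"` backward elimination runs once on the
#' full data and the surviving set is then assessed by plain LOOCV; under
#' `"inside"` the elimination is repeated inside every training fold, which
#' avoids selection leakage at substantially higher cost.
#'
#' @param features_csv Feature-table CSV.
#' @param out_dir Output directory.
#' @param cfg A `"run_config"`.
#' @param feature_sets Named list of starting feature sets; defaults to
#'   intensity, texture and combined.
#' @return List with `predictions` (named list), `models`, `report`,
#'   invisibly.
#' @export
ctc_train_eval <- function(features_csv, out_dir, cfg = run_config(),
                           feature_sets = NULL) {
  tab <- utils::read.csv(features_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(feature_sets)) {
    tex <- intersect(glcm_feature_names, names(tab))
    feature_sets <- list(
      intensity = intensity_feature_names,
      texture = tex,
      combined = c(intensity_feature_names, tex)
    )
  }
  models <- list(); preds <- list()
  for (nm in names(feature_sets)) {
    fs <- .prune_aliased(tab, feature_sets[[nm]])
    if (cfg$selection_mode == "pooled") {
      sel <- backward_eliminate(tab, fs, threshold = cfg$threshold)
      models[[nm]] <- sel$model
      preds[[nm]] <- loocv(tab, sel$features, select = "none",
                           threshold = cfg$threshold)
      utils::write.csv(sel$trace,
                       file.path(out_dir, paste0(nm, "_elimination.csv")),
                       row.names = FALSE)
    } else {
      preds[[nm]] <- loocv(tab, fs, select = "inside",
                           threshold = cfg$threshold)
      sel <- backward_eliminate(tab, fs, threshold = cfg$threshold)
      models[[nm]] <- sel$model   # reported model: full-data selection
    }
    write_model(models[[nm]], file.path(out_dir, paste0(nm, "_model.json")))
    utils::write.csv(preds[[nm]],
                     file.path(out_dir, paste0(nm, "_predictions.csv")),
                     row.names = FALSE)
  }
  report <- performance_table(preds)
  utils::write.csv(cbind(index = rownames(report), report),
                   file.path(out_dir, "performance.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "performance.txt"))
  .write_provenance(out_dir, list(stage = "train_eval",
                                  config = unclass(cfg)))
  invisible(list(predictions = preds, models = models, report = report))
}
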
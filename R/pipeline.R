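# ---- image / volume I/O -------------------------------------------------

#' Write / read an 8-bit RGB elastogram as PNG
#' @param image `H x W x 3` integer array (0-255), or for masks a logical
#'   `H x W` matrix (written as single-channel 0/255).
#' @param path File path.
#' @return `read_png_image()` returns an integer array (0-255);
#'   `read_png_mask()` a logical matrix.
#' @export
write_png_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname write_png_image
#' @export
write_png_mask <- function(image, path) {
  png::writePNG(matrix(as.numeric(image > 0), nrow = nrow(image)), path)
  invisible(path)
}

#' @rdname write_png_image
#' @export
read_png_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim = c(dim(a)[1], dim(a)[2], 3L))
}

#' @rdname write_png_image
#' @export
read_png_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' Write / read a PET volume as plain text with a JSON sidecar
#'
#' The voxel grid is stored as whitespace-separated activity values in
#' column-major order, the delineation as 0/1 integers, and the sidecar
#' records dimensions, voxel pitch, injected dose and body weight.
#'
#' @param voi A `pet_voi` (see [render_pet_voi()]).
#' @param stem Path stem; writes `<stem>.activity.txt`, `<stem>.mask.txt`
#'   and `<stem>.json`.
#' @return `read_pet_voi()` returns a `pet_voi` list.
#' @export
write_pet_voi <- function(voi, stem) {
  meta <- list(dims = dim(voi$activity), voxel_mm = voi$voxel_mm,
               dose_mbq = voi$dose_mbq, weight_g = voi$weight_g)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = FALSE,
                       digits = NA)
  writeLines(paste(format(as.vector(voi$activity), digits = 17),
                   collapse = " "), paste0(stem, ".activity.txt"))
  writeLines(paste(as.integer(voi$mask), collapse = " "),
             paste0(stem, ".mask.txt"))
  invisible(stem)
}

#' @rdname write_pet_voi
#' @export
read_pet_voi <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  act <- array(scan(paste0(stem, ".activity.txt"), quiet = TRUE), dims)
  msk <- array(scan(paste0(stem, ".mask.txt"), quiet = TRUE) > 0, dims)
  structure(list(activity = act, mask = msk,
                 voxel_mm = as.numeric(meta$voxel_mm),
                 dose_mbq = meta$dose_mbq, weight_g = meta$weight_g),
            class = "pet_voi")
}

# ---- pipeline stages ----------------------------------------------------

#' Simulate a cohort directory
#'
#' Writes `cohort.csv`, `raters.csv`, per-node elastogram and ROI PNGs,
#' PET voxel grids with JSON sidecars, and a `manifest.json` recording
#' the seed and per-node file paths. With `fixture = "validation"` or
#' `"model"` the deterministic fixture feature table is written instead
#' (fixtures are tabular; no images are rendered).
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param fixture `NULL`, `"validation"` or `"model"`.
#' @param image_size Elastogram frame size in pixels.
#' @param write_images Render and write PNGs / PET grids (`TRUE`) or
#'   write the tabular cohort only.
#' @return The manifest, invisibly.
#' @export
ln_simulate <- function(config = cohort_config(), dir,
                        fixture = NULL, image_size = 64,
                        write_images = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(fixture)) {
    fx <- switch(fixture, validation = validation_fixture(),
                 model = model_fixture(),
                 stop("unknown fixture: ", fixture))
    utils::write.csv(fx, file.path(dir, "cohort.csv"), row.names = FALSE)
    manifest <- list(kind = paste0("fixture_", fixture),
                     n_nodes = nrow(fx), seed = NA,
                     cohort_csv = "cohort.csv")
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }
  cohort <- generate_cohort(config)
  utils::write.csv(cohort$nodes, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$raters, file.path(dir, "raters.csv"),
                   row.names = FALSE)
  files <- NULL
  if (write_images && nrow(cohort$nodes) > 0) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "pet"), showWarnings = FALSE)
    files <- lapply(seq_len(nrow(cohort$nodes)), function(i) {
      rec <- cohort$nodes[i, ]
      el <- render_elastogram(rec, image_size, image_size)
      img <- file.path("images", paste0(rec$node_id, ".png"))
      msk <- file.path("images", paste0(rec$node_id, "_mask.png"))
      write_png_image(el$image, file.path(dir, img))
      write_png_mask(el$mask, file.path(dir, msk))
      stem <- file.path("pet", rec$node_id)
      write_pet_voi(render_pet_voi(rec), file.path(dir, stem))
      list(node_id = rec$node_id, image = img, mask = msk, pet = stem)
    })
  }
  manifest <- list(kind = "simulated", n_nodes = nrow(cohort$nodes),
                   seed = config$seed, cohort_csv = "cohort.csv",
                   raters_csv = "raters.csv", nodes = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Quantify a simulated cohort directory
#'
#' Reads the manifest, quantifies every node's elastogram (SAR, B/G,
#' B/R, mean hue, mean gray) and PET volume (SUVmax, SUVmean, MTV, TLG,
#' short axis), attaches the consensus grading score from the rater
#' panel, and writes `features.csv`. Per-node failures are warnings and
#' flag the row (`qc_ok = FALSE`); the run continues. For fixture
#' directories the stored feature table is returned as-is.
#'
#' @param dir Cohort directory from [ln_simulate()].
#' @param out Output CSV path (default `features.csv` inside `dir`).
#' @return The feature `data.frame`, invisibly.
#' @export
ln_quantify <- function(dir, out = file.path(dir, "features.csv")) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  nodes <- utils::read.csv(file.path(dir, manifest$cohort_csv),
                           stringsAsFactors = FALSE)
  if (startsWith(manifest$kind, "fixture")) {
    utils::write.csv(nodes, out, row.names = FALSE)
    return(invisible(nodes))
  }
  if (nrow(nodes) == 0L || is.null(manifest$nodes)) {
    utils::write.csv(nodes, out, row.names = FALSE)
    return(invisible(nodes))
  }
  raters <- utils::read.csv(file.path(dir, manifest$raters_csv),
                            stringsAsFactors = FALSE)
  grades <- panel_consensus(raters)
  info <- manifest$nodes  # data.frame after simplification
  feats <- lapply(seq_len(nrow(nodes)), function(i) {
    id <- nodes$node_id[i]
    j <- match(id, info$node_id)
    tryCatch({
      img <- read_png_image(file.path(dir, info$image[j]))
      roi <- read_png_mask(file.path(dir, info$mask[j]))
      ef <- quantify_elastogram(img, roi)
      pf <- quantify_pet(read_pet_voi(file.path(dir, info$pet[j])))
      cbind(ef, pf, qc_ok = TRUE)
    }, error = function(e) {
      warning("node ", id, " failed quantification: ",
              conditionMessage(e), call. = FALSE)
      bad <- as.data.frame(as.list(stats::setNames(
        rep(NA_real_, 11),
        c("sar", "bg_ratio", "br_ratio", "mean_hue", "mean_gray",
          "suv_max", "suv_mean", "suv_mean_mtv", "mtv_cm3", "tlg",
          "short_axis_mm"))))
      cbind(bad, qc_ok = FALSE)
    })
  })
  feats <- do.call(rbind, feats)
  feats$short_axis_mm <- NULL  # keep the CT value from the cohort table
  out_df <- cbind(nodes, feats)
  out_df$grade <- grades$grade[match(out_df$node_id, grades$node_id)]
  if (all(!out_df$qc_ok))
    stop("quantification failed for every node in ", dir)
  utils::write.csv(out_df, out, row.names = FALSE)
  invisible(out_df)
}

#' Fit per-feature ROC cutoffs on a feature table
#'
#' For each continuous feature, computes the empirical ROC curve, AUC
#' with DeLong 95% CI, and the Youden-optimal cutoff, mirroring a
#' cutoff/AUC summary table. Also runs the univariate screen on the
#' dichotomized calls at those cutoffs.
#'
#' @param features Feature `data.frame` including the truth column.
#' @param feature_cols Character vector of feature column names (default:
#'   the available quantitative indicators).
#' @param truth_col Truth column name.
#' @return List with `cutoffs` (`data.frame`: feature, cutoff, youden_j,
#'   sensitivity, specificity, auc, auc_lo, auc_hi) and `univariate`
#'   (screening p-values at those cutoffs).
#' @export
ln_fit <- function(features,
                   feature_cols = intersect(
                     c("suv_max", "suv_mean", "mtv_cm3", "tlg", "sar",
                       "bg_ratio", "br_ratio", "mean_hue", "mean_gray",
                       "grade"), names(features)),
                   truth_col = "true_class") {
  truth <- features[[truth_col]]
  rows <- lapply(feature_cols, function(f) {
    x <- features[[f]]
    ok <- is.finite(x)
    curve <- roc_points(x[ok], truth[ok])
    cut <- youden_cutoff(curve)
    data.frame(feature = f, cutoff = cut$cutoff,
               youden_j = cut$youden_j, sensitivity = cut$sensitivity,
               specificity = cut$specificity, auc = curve$auc,
               auc_lo = curve$auc_ci95[1], auc_hi = curve$auc_ci95[2],
               stringsAsFactors = FALSE)
  })
  cut_df <- do.call(rbind, rows)
  calls <- as.data.frame(lapply(stats::setNames(feature_cols, feature_cols),
    function(f) features[[f]] > cut_df$cutoff[cut_df$feature == f]))
  list(cutoffs = cut_df, univariate = univariate_screen(calls, truth))
}

#' Evaluate a feature table and write reports
#'
#' Runs [evaluate_cohort()] and optionally writes a machine-readable JSON
#' report (per-method confusion counts and metrics) and an aligned
#' two-decimal text table.
#'
#' @param features Feature table with the rule features and truth column.
#' @param cutoffs A [rule_cutoffs()].
#' @param out_json,out_txt Optional output paths.
#' @param truth_col Truth column name.
#' @return The `ln_evaluation`, invisibly.
#' @export
ln_evaluate <- function(features, cutoffs = rule_cutoffs(),
                        out_json = NULL, out_txt = NULL,
                        truth_col = "true_class") {
  ev <- evaluate_cohort(features, cutoffs, truth_col)
  if (!is.null(out_json)) {
    blocks <- lapply(ev, function(r) {
      cm <- r$confusion
      list(confusion = list(tp = cm$tp, fp = cm$fp, fn = cm$fn,
                            tn = cm$tn),
           metrics = r[metric_names])
    })
    jsonlite::write_json(c(blocks, list(cutoffs = unclass(cutoffs))),
                         out_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(out_txt)) {
    con <- file(out_txt, "w")
    sink(con); print(ev); sink()
    close(con)
  }
  invisible(ev)
}
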
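#' Score a directory of biopsy images
#'
#' Batch entry point: each subdirectory of `input_dir` is one liver; every
#' decodable TIFF/PNG/JPEG inside is segmented and scored, per-liver scores
#' are aggregated with the one-pass outlier rule, and results are written as
#' CSV together with a JSON run manifest (configuration, package version,
#' per-image warnings, skipped files). Images directly inside `input_dir` are
#' treated as a single liver named after the directory.
#'
#' @param input_dir Directory of liver subdirectories.
#' @param config A [seg_config()].
#' @param output_dir Where to write `image_scores.csv`, `liver_scores.csv`
#'   and `manifest.json`. Created if missing. `NULL` writes nothing.
#' @param overlays If `TRUE`, writes a green-tinted overlay PNG per image.
#' @return Invisibly, a list with `image_scores` and `liver_scores` data
#'   frames and the `manifest` list.
#' @export
run_score <- function(input_dir, config = seg_config(), output_dir = NULL,
                      overlays = FALSE) {
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  exts <- "\\.(tif|tiff|png|jpg|jpeg)$"
  subdirs <- list.dirs(input_dir, recursive = FALSE)
  livers <- if (length(subdirs)) subdirs else input_dir
  if (!is.null(output_dir) && !dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)

  image_rows <- list(); liver_rows <- list()
  warnings_log <- list(); skipped <- character(0)

  for (lv in sort(livers)) {
    liver_id <- basename(lv)
    files <- sort(list.files(lv, pattern = exts, ignore.case = TRUE,
                             full.names = TRUE))
    slide_scores <- list()
    for (f in files) {
      image_id <- basename(f)
      wmsgs <- character(0)
      seg <- withCallingHandlers(
        tryCatch(segment_image(f, config, image_id = image_id),
                 error = function(e) e),
        warning = function(w) {
          wmsgs <<- c(wmsgs, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (length(wmsgs))
        warnings_log[[paste(liver_id, image_id, sep = "/")]] <- wmsgs
      if (inherits(seg, "error")) {
        skipped <- c(skipped, paste0(liver_id, "/", image_id, ": ",
                                     conditionMessage(seg)))
        next
      }
      sc <- image_steatosis_fraction(seg)
      sc$liver_id <- liver_id
      slide_scores[[image_id]] <- sc
      if (overlays && !is.null(output_dir))
        write_overlay_png(f, seg$final_mask,
                          file.path(output_dir,
                                    paste0(liver_id, "_", image_id,
                                           "_overlay.png")))
    }
    if (!length(slide_scores)) next
    per_image <- do.call(rbind, slide_scores)
    ls <- liver_steatosis_score(per_image$steatosis_percent, liver_id)
    per_image$retained_flag <- ls$retained
    per_image$liver_final_percent <- ls$final_percent
    image_rows[[liver_id]] <- per_image
    liver_rows[[liver_id]] <- data.frame(
      liver_id = liver_id, n_images = length(ls$image_percents),
      n_retained = sum(ls$retained), liver_final_percent = ls$final_percent,
      stringsAsFactors = FALSE)
  }

  if (!length(image_rows))
    stop("no image in ", input_dir, " could be scored (",
         length(skipped), " skipped)")

  image_scores <- do.call(rbind, image_rows)
  image_scores <- image_scores[, c("liver_id", "image_id", "fat_pixels",
                                   "tissue_pixels", "steatosis_percent",
                                   "retained_flag", "liver_final_percent")]
  rownames(image_scores) <- NULL
  liver_scores <- do.call(rbind, liver_rows)
  rownames(liver_scores) <- NULL

  manifest <- list(
    package = "steatoscope",
    version = as.character(utils::packageVersion("steatoscope")),
    config = unclass(config),
    n_images_scored = nrow(image_scores),
    n_images_skipped = length(skipped),
    skipped = skipped,
    warnings = warnings_log
  )

  if (!is.null(output_dir)) {
    utils::write.csv(image_scores, file.path(output_dir, "image_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(liver_scores, file.path(output_dir, "liver_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(image_scores = image_scores, liver_scores = liver_scores,
                 manifest = manifest))
}

#' Generate a reproducible batch of phantom images
#'
#' @param output_dir Directory for the PNG images and JSON truth sidecars.
#' @param n Number of phantoms.
#' @param type `"he"` (H&E-like) or `"control"` (three-colour).
#' @param seed Master seed; phantom i uses `seed + i`.
#' @param ... Overrides passed to [phantom_spec()] (e.g.
#'   `target_fat_fraction`, `tears`, `clustering`).
#' @return Invisibly, a data frame of file names and true fractions.
#' @export
run_phantom <- function(output_dir, n = 10, type = c("he", "control"),
                        seed = 1, ...) {
  type <- match.arg(type)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  gen <- if (type == "he") generate_he_phantom else generate_control_phantom
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(seed = seed + i, ...)
    ph <- gen(spec)
    img <- file.path(output_dir, sprintf("%s_phantom_%03d.png", type, i))
    write_phantom(ph, img)
    rows[[i]] <- data.frame(file = basename(img),
                            fat_fraction_percent = ph$truth$fat_fraction_percent,
                            seed = spec$seed, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(output_dir, "phantom_truth.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' Full rater-agreement report for a score table
#'
#' Computes both ICC variants, the pairwise Pearson correlation matrix,
#' per-rater ordinary least squares against a designated reference column,
#' and the clinical threshold disagreement count.
#'
#' @param table Numeric subjects x raters matrix, or a CSV path readable by
#'   [read_rater_table()].
#' @param reference Optional name of a column used as the OLS predictor
#'   (e.g. the algorithm's estimates); that column is excluded from the ICC
#'   and disagreement computations over the remaining raters.
#' @param columns Optional character vector restricting which rater columns
#'   enter the ICC and disagreement statistics (e.g. only the strict-estimate
#'   columns of a table that also holds gestalt estimates).
#' @param threshold_percent Clinical decision threshold (default 30).
#' @param output_json Optional path for a JSON report.
#' @return List with `icc_consistency`, `icc_absolute`, `pearson_matrix`,
#'   `ols` (per-rater slope/intercept/r-squared vs the reference, if given),
#'   `disagreement_count`, `threshold_percent`.
#' @export
run_agreement <- function(table, reference = NULL, columns = NULL,
                          threshold_percent = 30, output_json = NULL) {
  if (is.character(table) && length(table) == 1L)
    table <- read_rater_table(table)
  m <- as.matrix(table)
  storage.mode(m) <- "numeric"
  ols <- NULL
  if (!is.null(reference)) {
    if (!reference %in% colnames(m))
      stop("reference column '", reference, "' not in table")
    xref <- m[, reference]
    raters <- m[, setdiff(colnames(m), reference), drop = FALSE]
    ols <- lapply(colnames(raters), function(cn) {
      fit <- linear_fit(xref, raters[, cn])
      c(list(rater = cn), fit)
    })
    names(ols) <- colnames(raters)
  } else {
    raters <- m
  }
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, colnames(raters))
    if (length(missing_cols))
      stop("column(s) not in table: ", paste(missing_cols, collapse = ", "))
    raters <- raters[, columns, drop = FALSE]
  }
  report <- list(
    icc_consistency = icc_two_way(raters, "consistency"),
    icc_absolute = icc_two_way(raters, "absolute"),
    pearson_matrix = stats::cor(m, method = "pearson"),
    ols = ols,
    disagreement_count = threshold_disagreement_count(raters,
                                                      threshold_percent),
    threshold_percent = threshold_percent,
    n_subjects = nrow(m)
  )
  if (!is.null(output_json)) {
    flat <- report
    flat$icc_consistency <- unclass(flat$icc_consistency)
    flat$icc_absolute <- unclass(flat$icc_absolute)
    flat$pearson_matrix <- as.data.frame(flat$pearson_matrix)
    jsonlite::write_json(flat, output_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  report
}
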
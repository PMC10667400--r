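#' Write a simulated cohort to disk
#'
#' Writes per-lesion NIfTI volumes and masks, a \code{clinical.csv}
#' (lesion_id, patient_id, psad, prostate_volume, pirads, isup, is_index)
#' and a \code{manifest.json} mapping lesions to their files.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param gzip Write .nii.gz instead of .nii.
#' @return Invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  manifest <- list(lesions = list())
  for (case in cohort) {
    id <- case$lesion_id
    files <- list(
      scan1_volume = paste0(id, "_scan1", ext),
      scan2_volume = paste0(id, "_scan2", ext),
      scan1_mask = paste0(id, "_mask1", ext),
      scan2_mask = paste0(id, "_mask2", ext),
      fat_mask = paste0(id, "_fat", ext),
      muscle_mask = paste0(id, "_muscle", ext))
    write_nifti(case$scan1_volume, file.path(dir, files$scan1_volume),
                case$spacing)
    write_nifti(case$scan2_volume, file.path(dir, files$scan2_volume),
                case$spacing)
    write_nifti(case$scan1_mask, file.path(dir, files$scan1_mask),
                case$spacing, datatype = "uint8")
    write_nifti(case$scan2_mask, file.path(dir, files$scan2_mask),
                case$spacing, datatype = "uint8")
    write_nifti(case$fat_mask, file.path(dir, files$fat_mask),
                case$spacing, datatype = "uint8")
    write_nifti(case$muscle_mask, file.path(dir, files$muscle_mask),
                case$spacing, datatype = "uint8")
    manifest$lesions[[id]] <- files
  }
  clinical <- attr(cohort, "clinical")
  utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  manifest$clinical <- "clinical.csv"
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing manifest.json.
#' @return List of `paired_lesion_case` with the clinical table attached.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  clinical <- utils::read.csv(file.path(dir, manifest$clinical),
                              stringsAsFactors = FALSE)
  cohort <- list()
  for (id in names(manifest$lesions)) {
    f <- manifest$lesions[[id]]
    v1 <- read_nifti(file.path(dir, f$scan1_volume))
    sp <- attr(v1, "spacing")
    cl <- clinical[clinical$lesion_id == id, , drop = FALSE]
    case <- structure(list(
      lesion_id = id, patient_id = cl$patient_id, spacing = sp,
      scan1_volume = v1,
      scan2_volume = read_nifti(file.path(dir, f$scan2_volume)),
      scan1_mask = read_nifti_mask(file.path(dir, f$scan1_mask), dim(v1)),
      scan2_mask = read_nifti_mask(file.path(dir, f$scan2_mask), dim(v1)),
      fat_mask = read_nifti_mask(file.path(dir, f$fat_mask), dim(v1)),
      muscle_mask = read_nifti_mask(file.path(dir, f$muscle_mask), dim(v1)),
      clinical = list(psad = cl$psad, prostate_volume = cl$prostate_volume,
                      pirads = cl$pirads, isup = cl$isup,
                      is_index = cl$is_index)),
      class = "paired_lesion_case")
    cohort[[length(cohort) + 1L]] <- case
  }
  attr(cohort, "clinical") <- clinical
  cohort
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages: feature extraction over the 48-setting grid, per-cell ICC(2,1),
#' good-feature counting and setting selection, then clinical-category
#' comparisons on the index lesions under the selected setting. Writes
#' features.csv (long), grid.csv (features x settings, mirroring the
#' reproducibility heatmap), selected_setting.json, comparisons.csv, and a
#' run manifest with warnings (degenerate cells, failures, tie-breaks).
#'
#' @param cohort List of `paired_lesion_case` (with clinical attribute) or a
#'   cohort directory path.
#' @param out_dir Output directory.
#' @param settings Setting grid (default all 48).
#' @param threshold Good-reproducibility ICC cutoff (default 0.75).
#' @param anchors Normalization anchors.
#' @param compare Run the clinical comparison stage (needs clinical table).
#' @param verbose Progress messages.
#' @return List with \code{features}, \code{grid}, \code{counts},
#'   \code{selected}, \code{icc_comparisons}, \code{value_comparisons}.
#' @export
run_pipeline <- function(cohort, out_dir, settings = enumerate_settings(),
                         threshold = 0.75, anchors = c(0, 1000),
                         compare = TRUE, verbose = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  clinical <- attr(cohort, "clinical")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  features <- withCallingHandlers(
    extract_cohort(cohort, settings, anchors = anchors, verbose = verbose),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  grid <- build_grid(features)
  gridcsv <- data.frame(feature = rownames(grid$icc),
                        grid$icc, check.names = FALSE)
  utils::write.csv(gridcsv, file.path(out_dir, "grid.csv"), row.names = FALSE)
  counts <- count_good(grid, threshold)
  selected <- withCallingHandlers(
    select_setting(counts, settings),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  jsonlite::write_json(
    c(as.list(selected), list(good_count = attr(selected, "count"),
                              label = setting_label(selected))),
    file.path(out_dir, "selected_setting.json"), auto_unbox = TRUE,
    pretty = TRUE)
  icc_cmp <- value_cmp <- NULL
  if (compare) {
    if (is.null(clinical))
      stop("clinical table required for the comparison stage")
    idx_ids <- clinical$lesion_id[clinical$is_index]
    idx_feats <- features[features$lesion_id %in% idx_ids, , drop = FALSE]
    icc_cmp <- compare_icc_by_category(idx_feats, clinical,
                                       selected$setting_index)
    value_cmp <- compare_values_by_category(idx_feats, clinical,
                                            selected$setting_index)
    cmp_out <- rbind(
      data.frame(variable = icc_cmp$variable, feature = "ICC-distribution",
                 test = icc_cmp$test, statistic = icc_cmp$statistic,
                 p_raw = icc_cmp$p_raw, p_adjusted = icc_cmp$p_adjusted,
                 significant = icc_cmp$significant,
                 stringsAsFactors = FALSE),
      value_cmp[, c("variable", "feature", "test", "statistic", "p_raw",
                    "p_adjusted", "significant")])
    utils::write.csv(cmp_out, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("radrepro")),
    n_lesions = length(cohort),
    n_settings = nrow(settings),
    threshold = threshold,
    anchors = anchors,
    selected_setting = selected$setting_index,
    selected_label = setting_label(selected),
    n_degenerate_cells = sum(grid$degenerate),
    warnings = warnings_log,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = features, grid = grid, counts = counts,
                 selected = selected, icc_comparisons = icc_cmp,
                 value_comparisons = value_cmp))
}
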
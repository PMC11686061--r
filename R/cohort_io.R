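#' Write a cohort to disk
#'
#' Lays a cohort out as plain-text files: `metadata.csv` (one row per
#' subject), tab-delimited FC matrices with ROI-label headers under
#' `matrices/`, a JSON `manifest.json` linking files, bands and conditions,
#' and — for synthetic cohorts — `ground_truth.json` kept separate so
#' analysis code never needs to touch it.
#'
#' @param cohort Cohort object.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  files <- list()
  for (s in cohort$subjects) {
    for (bn in names(s$fc)) {
      for (cond in names(s$fc[[bn]])) {
        fn <- sprintf("%s_%s_%s.tsv", s$id, bn, cond)
        m <- s$fc[[bn]][[cond]]
        colnames(m) <- cohort$spec$roi_labels
        utils::write.table(m, file.path(dir, "matrices", fn), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        files[[length(files) + 1]] <- list(
          subject = s$id, band = bn, condition = cond,
          file = file.path("matrices", fn))
      }
    }
  }
  manifest <- list(
    roi_labels = cohort$spec$roi_labels,
    bands = lapply(cohort$spec$bands, function(b) {
      list(name = b$name, lo = b$lo, hi = b$hi)
    }),
    conditions = c("ON", "OFF"),
    metadata = "metadata.csv",
    matrices = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(responder = gt$responder,
           motor_loading_subnet = gt$motor_loading_subnet,
           profile_edges = gt$profile_edges,
           cognition_pattern = gt$cognition_pattern),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file.path(dir, "manifest.json"))
}

#' Load a cohort from a manifest
#'
#' Reads the manifest, metadata and matrix files written by
#' [write_cohort()] (or prepared externally in the same layout), validating
#' every FC matrix invariant (symmetry, zero diagonal, entries in \[0,1\])
#' and the UPDRS_diff consistency on load. Ground truth files are never
#' read.
#'
#' @param manifest_path Path to `manifest.json`.
#' @param metadata_path Optional override for the metadata CSV.
#' @return Cohort object (class `fc_cohort`) with `subjects`, `metadata`,
#'   and a `spec` stub carrying `roi_labels`, `roi_count` and `bands`.
#' @export
load_cohort <- function(manifest_path, metadata_path = NULL) {
  root <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  roi_labels <- unlist(man$roi_labels)
  bands <- lapply(man$bands, function(b) band_spec(b$name, b$lo, b$hi))
  names(bands) <- vapply(bands, `[[`, "", "name")
  if (is.null(metadata_path)) {
    metadata_path <- file.path(root, man$metadata)
  }
  meta <- utils::read.csv(metadata_path)
  if (!all(meta$updrs_diff == meta$updrs_on - meta$updrs_off)) {
    stop("metadata inconsistent: updrs_diff != updrs_on - updrs_off")
  }
  subjects <- lapply(seq_len(nrow(meta)), function(s) {
    rec <- as.list(meta[s, ])
    rec$fc <- list()
    rec
  })
  names(subjects) <- meta$id
  for (entry in man$matrices) {
    path <- file.path(root, entry$file)
    if (!file.exists(path)) stop("manifest references missing file: ", path)
    m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     check.names = FALSE))
    dimnames(m) <- NULL
    validate_fc(m, what = entry$file)
    if (nrow(m) != length(roi_labels)) {
      stop(entry$file, ": matrix size does not match ROI label list")
    }
    subjects[[entry$subject]]$fc[[entry$band]][[entry$condition]] <-
      m
  }
  incomplete <- vapply(subjects, function(s) {
    !all(vapply(names(bands), function(bn) {
      all(c("ON", "OFF") %in% names(s$fc[[bn]]))
    }, TRUE))
  }, TRUE)
  if (any(incomplete)) {
    warning("subject(s) lacking a band/condition: ",
            paste(names(subjects)[incomplete], collapse = ", "))
  }
  structure(list(
    subjects = unname(subjects), metadata = meta,
    spec = list(roi_labels = roi_labels, roi_count = length(roi_labels),
                bands = bands)),
    class = "fc_cohort")
}
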
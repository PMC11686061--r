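#' AAL-90 region labels
#'
#' The 90 cerebral regions of the Automated Anatomical Labeling atlas in
#' standard numbering order (vermis and cerebellum excluded), as used for
#' source-space ROI connectivity matrices.
#'
#' @return Character vector of 90 ROI labels.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.txt", package = "dbsconnect",
                      mustWork = TRUE)
  readLines(path)
}

#' Bilateral motor subnetwork ROI set
#'
#' The 14-region basal-ganglia-thalamo-cortical motor subnetwork: bilateral
#' Precentral, Supplementary Motor Area, Postcentral (cortical), and Caudate,
#' Putamen, Pallidum, Thalamus (subcortical). Labels are ordered cortical
#' first, then subcortical, left before right within each region, the order
#' used to lay out loading matrices.
#'
#' @param roi_labels Character vector of atlas labels for the full network
#'   (default [aal90_labels()]).
#' @return Object of class `motor_roi_set`: list with `labels` (14 names) and
#'   `indices` (positions within `roi_labels`).
#' @export
motor_roi_set <- function(roi_labels = aal90_labels()) {
  wanted <- c("Precentral_L", "Precentral_R",
              "Supp_Motor_Area_L", "Supp_Motor_Area_R",
              "Postcentral_L", "Postcentral_R",
              "Caudate_L", "Caudate_R",
              "Putamen_L", "Putamen_R",
              "Pallidum_L", "Pallidum_R",
              "Thalamus_L", "Thalamus_R")
  idx <- match(wanted, roi_labels)
  if (anyNA(idx)) {
    stop("motor ROI label(s) not found in roi_labels: ",
         paste(wanted[is.na(idx)], collapse = ", "))
  }
  structure(list(labels = wanted, indices = idx), class = "motor_roi_set")
}

# indices (within the motor set ordering) of the six cortical regions
motor_cortical_positions <- function() 1:6
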
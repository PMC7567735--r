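#' Parcellated PET subject
#'
#' Container for one subject's per-region voxel-intensity samples (normalized
#' uptake units). `mean_uptake` is always recomputed from the samples, so the
#' two can never disagree.
#'
#' @param samples named list of numeric vectors, one per region; names are
#'   integer region labels (`"1"`..`"R"`) or region names.
#' @param subject_id single string identifying the subject.
#' @param min_voxels minimum usable voxels required per region (default 10).
#'
#' @return An object of class `klse_subject` with elements `subject_id`,
#'   `samples`, `mean_uptake` (named numeric) and `R`.
#' @export
parcellated_subject <- function(samples, subject_id = "subject", min_voxels = 10L) {
  if (!is.list(samples) || length(samples) == 0L) {
    abort("`samples` must be a non-empty list of numeric vectors.")
  }
  if (is.null(names(samples)) || anyDuplicated(names(samples))) {
    abort("`samples` must have unique region names.")
  }
  samples <- lapply(samples, function(x) x[is.finite(x)])
  short <- names(samples)[vapply(samples, length, 1L) < min_voxels]
  if (length(short) > 0L) {
    abort(sprintf(
      "region(s) %s have fewer than %d usable voxels.",
      paste(short, collapse = ", "), min_voxels
    ))
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      samples = samples,
      mean_uptake = vapply(samples, mean, numeric(1)),
      R = length(samples)
    ),
    class = "klse_subject"
  )
}

#' @export
print.klse_subject <- function(x, ...) {
  nv <- vapply(x$samples, length, 1L)
  cat(sprintf(
    "<klse_subject> %s: %d regions, %d-%d voxels/region, mean uptake %.3f\n",
    x$subject_id, x$R, min(nv), max(nv), mean(unlist(x$samples))
  ))
  invisible(x)
}

#' @method tidy klse_subject
#' @export
tidy.klse_subject <- function(x, ...) {
  tibble(
    region = rep(names(x$samples), vapply(x$samples, length, 1L)),
    intensity = unlist(x$samples, use.names = FALSE)
  )
}

read_volume <- function(x) {
  if (is.character(x)) RNifti::readNifti(x) else x
}

#' Extract per-region voxel samples from a subject volume and an atlas
#'
#' Splits the subject volume's voxels by integer atlas label (0 = background,
#' excluded). Non-finite and non-positive intensities are dropped per region;
#' a region left with fewer than `min_voxels` usable voxels is an error, since
#' a density estimate from a handful of voxels is meaningless.
#'
#' Both volumes must live on the same grid: matching dimensions and, when both
#' carry NIfTI metadata, matching affines to within `1e-4` (no resampling is
#' ever attempted).
#'
#' @param subject_volume NIfTI file path or 3-D array of intensities.
#' @param atlas NIfTI file path or 3-D integer array of region labels.
#' @param subject_id identifier stored on the result.
#' @param min_voxels minimum usable voxels per region (default 10).
#'
#' @return A [parcellated_subject()] object.
#' @export
load_parcellation <- function(subject_volume, atlas, subject_id = "subject",
                              min_voxels = 10L) {
  vol <- read_volume(subject_volume)
  atl <- read_volume(atlas)
  if (!identical(dim(vol), dim(atl))) {
    abort(sprintf(
      "subject grid (%s) and atlas grid (%s) differ.",
      paste(dim(vol), collapse = "x"), paste(dim(atl), collapse = "x")
    ))
  }
  if (inherits(vol, "niftiImage") && inherits(atl, "niftiImage")) {
    dx <- max(abs(RNifti::xform(vol) - RNifti::xform(atl)))
    if (dx > 1e-4) {
      abort(sprintf("subject and atlas affines differ (max |diff| = %g).", dx))
    }
  }
  lab <- as.integer(round(as.vector(atl)))
  val <- as.vector(vol)
  keep <- lab > 0L
  lab <- lab[keep]
  val <- val[keep]
  usable <- is.finite(val) & val > 0
  labels <- sort(unique(lab))
  samples <- lapply(labels, function(l) val[lab == l & usable])
  names(samples) <- as.character(labels)
  short <- labels[vapply(samples, length, 1L) < min_voxels]
  if (length(short) > 0L) {
    abort(sprintf(
      "region(s) %s have fewer than %d usable voxels after exclusion.",
      paste(short, collapse = ", "), min_voxels
    ))
  }
  parcellated_subject(samples, subject_id, min_voxels = min_voxels)
}

#' Normalize a subject to unit global mean uptake
#'
#' Divides every voxel intensity by the pooled mean over all in-atlas voxels
#' (the atlas support is the brain mask, so "global mean" means the mean over
#' labelled voxels). Idempotent: the pooled mean after normalization is 1.
#'
#' @param subject a [parcellated_subject()].
#' @return A normalized `klse_subject`.
#' @export
global_normalize <- function(subject) {
  stopifnot(inherits(subject, "klse_subject"))
  g <- mean(unlist(subject$samples, use.names = FALSE))
  if (!is.finite(g) || g <= 0) {
    abort(sprintf("global mean uptake must be > 0 (got %g).", g))
  }
  parcellated_subject(
    lapply(subject$samples, function(x) x / g),
    subject$subject_id,
    min_voxels = 1L
  )
}

#' Per-region mean uptake
#'
#' @param subject a [parcellated_subject()].
#' @return A tibble with `region` and `mean_uptake`.
#' @export
region_mean_uptake <- function(subject) {
  stopifnot(inherits(subject, "klse_subject"))
  tibble(region = names(subject$mean_uptake), mean_uptake = unname(subject$mean_uptake))
}

#' Mean uptake over a composite region of interest
#'
#' Voxel-count-weighted mean normalized uptake over the union of the listed
#' regions, e.g. an AD-meta-ROI. The composition of the ROI is the caller's
#' choice; no default label set is assumed.
#'
#' @param subject a [parcellated_subject()].
#' @param roi_labels character or integer vector of region labels.
#' @return A single number.
#' @export
meta_roi_uptake <- function(subject, roi_labels) {
  stopifnot(inherits(subject, "klse_subject"))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) == 0L) abort("`roi_labels` must be non-empty.")
  missing <- setdiff(roi_labels, names(subject$samples))
  if (length(missing) > 0L) {
    abort(sprintf("unknown region label(s): %s", paste(missing, collapse = ", ")))
  }
  mean(unlist(subject$samples[roi_labels], use.names = FALSE))
}

#' Mean-uptake table for a cohort
#'
#' @param cohort a cohort tibble as returned by [simulate_cohort()]: columns
#'   `subject_id`, `group`, and a list-column `subject` of
#'   [parcellated_subject()] objects.
#' @return A wide tibble, one row per subject, one column per region plus
#'   `subject_id` and `group`; input to [group_pearson_network()].
#' @export
cohort_mean_uptake <- function(cohort) {
  stopifnot(is.data.frame(cohort), "subject" %in% names(cohort))
  rows <- purrr::map2(
    cohort$subject, seq_len(nrow(cohort)),
    function(s, i) {
      tibble(
        subject_id = s$subject_id, group = cohort$group[i],
        region = names(s$mean_uptake), mean_uptake = unname(s$mean_uptake)
      )
    }
  )
  bind_rows(rows) |>
    tidyr::pivot_wider(names_from = "region", values_from = "mean_uptake")
}

#' Default AAL-90 lobe map
#'
#' A 90-row table (`label`, `name`, `lobe`) assigning each AAL region to a
#' coarse lobe (`frontal`, `parietal`, `occipital`, `temporal`, `other`).
#' Shipped as `inst/extdata/aal90_lobes.csv`; pass your own table of the same
#' shape to any function taking a `lobe_map`.
#'
#' @return A tibble with columns `label` (integer), `name`, `lobe`.
#' @export
aal90_lobe_map <- function() {
  path <- system.file("extdata", "aal90_lobes.csv", package = "klse")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df)
}
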
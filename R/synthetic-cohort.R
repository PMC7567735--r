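#' Region specification table for the synthetic-cohort generator
#'
#' One row per region: the location (`mu`) and scale (`sigma`) of the
#' voxel-intensity distribution and the voxel count. Intensities are drawn
#' Gaussian by default (globally normalized uptake is approximately Gaussian
#' within a region); a lognormal alternative is available via the `family`
#' argument of [simulate_subject()].
#'
#' @param region_id integer region labels (unique, >= 1).
#' @param mu location of the voxel-intensity distribution, in normalized
#'   uptake units.
#' @param sigma scale (> 0).
#' @param n_voxels voxels per region (>= 10).
#' @return A validated tibble with class `klse_region_spec`.
#' @export
region_spec <- function(region_id, mu, sigma, n_voxels = 500L) {
  spec <- tibble(
    region_id = as.integer(region_id),
    mu = as.numeric(mu),
    sigma = as.numeric(sigma),
    n_voxels = as.integer(n_voxels)
  )
  validate_region_spec(spec)
}

validate_region_spec <- function(spec) {
  stopifnot(is.data.frame(spec))
  need <- c("region_id", "mu", "sigma", "n_voxels")
  missing <- setdiff(need, names(spec))
  if (length(missing) > 0L) {
    abort(sprintf("region spec lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(spec$region_id)) abort("`region_id` must be unique.")
  if (any(!is.finite(spec$sigma) | spec$sigma <= 0)) abort("`sigma` must be > 0.")
  if (any(spec$n_voxels < 10L)) abort("`n_voxels` must be >= 10.")
  if (any(!is.finite(spec$mu))) abort("`mu` must be finite.")
  class(spec) <- c("klse_region_spec", class(spec))
  spec
}

#' Simulate one parcellated subject
#'
#' Draws per-region voxel intensities from the distribution stated in `spec`,
#' after adding a subject-level jitter `N(0, jitter_sd)` to each region's
#' location (between-subject variation acts on location only, keeping the
#' Gaussian closed-form divergence oracle exact).
#'
#' @param spec a [region_spec()] table.
#' @param jitter_sd between-subject jitter on `mu` (>= 0).
#' @param seed integer seed; the draw is fully deterministic given the seed.
#' @param subject_id identifier for the subject.
#' @param family `"gaussian"` (default) or `"lognormal"`; lognormal uses
#'   `meanlog = log(mu)`, `sdlog = sigma/mu` so location and relative scale
#'   are comparable.
#' @return A [parcellated_subject()].
#' @export
simulate_subject <- function(spec, jitter_sd = 0, seed = 1L,
                             subject_id = "subject",
                             family = c("gaussian", "lognormal")) {
  spec <- validate_region_spec(spec)
  family <- match.arg(family)
  stopifnot_scalar_number(jitter_sd, "jitter_sd")
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  samples <- withr::with_seed(as.integer(seed), {
    mu_s <- spec$mu + rnorm(nrow(spec), 0, jitter_sd)
    purrr::pmap(
      list(mu_s, spec$sigma, spec$n_voxels),
      function(m, s, nv) {
        if (family == "gaussian") {
          rnorm(nv, m, s)
        } else {
          if (m <= 0) abort("lognormal family requires mu > 0.")
          stats::rlnorm(nv, meanlog = log(m), sdlog = s / m)
        }
      }
    )
  })
  names(samples) <- as.character(spec$region_id)
  parcellated_subject(samples, subject_id)
}

#' Cohort specification
#'
#' @param base a [region_spec()] table shared by all groups.
#' @param groups named list; each element is `list(n = <subjects>, override =
#'   <tibble>)` where the optional `override` has `region_id` plus any of
#'   `mu`, `sigma` to replace in `base` for that group. Group differences are
#'   therefore injected only in overridden regions.
#' @param jitter_sd between-subject jitter on region locations.
#' @param seed cohort-level seed; per-subject sub-seeds are derived
#'   deterministically from it.
#' @return A list with class `klse_cohort_spec`.
#' @export
cohort_spec <- function(base, groups, jitter_sd = 0.02, seed = 1L) {
  base <- validate_region_spec(base)
  if (!is.list(groups) || length(groups) == 0L || is.null(names(groups))) {
    abort("`groups` must be a non-empty named list.")
  }
  for (g in names(groups)) {
    n <- groups[[g]]$n
    if (is.null(n) || n < 2L) abort(sprintf("group '%s' needs n >= 2 subjects.", g))
  }
  structure(
    list(base = base, groups = groups, jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "klse_cohort_spec"
  )
}

apply_override <- function(base, override) {
  if (is.null(override)) return(base)
  stopifnot(is.data.frame(override), "region_id" %in% names(override))
  unknown <- setdiff(override$region_id, base$region_id)
  if (length(unknown) > 0L) {
    abort(sprintf("override references unknown region(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- base
  idx <- match(override$region_id, out$region_id)
  for (col in intersect(c("mu", "sigma", "n_voxels"), names(override))) {
    out[[col]][idx] <- override[[col]]
  }
  validate_region_spec(as_tibble(out))
}

#' Simulate a cohort of parcellated subjects
#'
#' @param cohort a [cohort_spec()].
#' @return A tibble with `subject_id`, `group`, and list-column `subject` of
#'   [parcellated_subject()] objects. Identical seeds yield identical cohorts.
#' @export
simulate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "klse_cohort_spec"))
  ns <- vapply(cohort$groups, function(g) as.integer(g$n), 1L)
  seeds <- derive_seeds(cohort$seed, sum(ns))
  rows <- list()
  k <- 0L
  for (g in names(cohort$groups)) {
    spec_g <- apply_override(cohort$base, cohort$groups[[g]]$override)
    for (i in seq_len(cohort$groups[[g]]$n)) {
      k <- k + 1L
      sid <- sprintf("%s_%03d", g, i)
      rows[[k]] <- tibble(
        subject_id = sid, group = g,
        subject = list(simulate_subject(
          spec_g, jitter_sd = cohort$jitter_sd, seed = seeds[k], subject_id = sid
        ))
      )
    }
  }
  bind_rows(rows)
}

#' Hazard specification for synthetic conversion times
#'
#' @param beta named numeric vector of log-hazard coefficients per standard
#'   deviation of the named features.
#' @param baseline_rate exponential baseline hazard (events per month, > 0).
#' @param censor_time administrative censoring time in months (> 0).
#' @return A list with class `klse_hazard_spec`.
#' @export
hazard_spec <- function(beta, baseline_rate, censor_time) {
  if (length(beta) > 0 && is.null(names(beta))) abort("`beta` must be named.")
  stopifnot_scalar_number(baseline_rate, "baseline_rate", positive = TRUE)
  stopifnot_scalar_number(censor_time, "censor_time", positive = TRUE)
  structure(
    list(beta = beta, baseline_rate = baseline_rate, censor_time = censor_time),
    class = "klse_hazard_spec"
  )
}

#' Simulate conversion times from a proportional-hazards model
#'
#' Event times are drawn from an exponential hazard
#' `baseline_rate * exp(beta . z)` where `z` are the named feature columns
#' standardized across the table (so `beta` is a log hazard per SD). Times
#' beyond `censor_time` are administratively censored.
#'
#' @param features tibble with a `subject_id` column and numeric feature
#'   columns covering `names(hazard$beta)`.
#' @param hazard a [hazard_spec()].
#' @param seed integer seed.
#' @return A tibble `subject_id`, `time_months`, `event` (1 = converted).
#' @export
simulate_conversion <- function(features, hazard, seed = 1L) {
  stopifnot(inherits(hazard, "klse_hazard_spec"), is.data.frame(features))
  missing <- setdiff(names(hazard$beta), names(features))
  if (length(missing) > 0L) {
    abort(sprintf("feature(s) not in table: %s", paste(missing, collapse = ", ")))
  }
  n <- nrow(features)
  lp <- rep(0, n)
  for (f in names(hazard$beta)) {
    x <- features[[f]]
    s <- sd(x)
    z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
    lp <- lp + hazard$beta[[f]] * z
  }
  rate <- hazard$baseline_rate * exp(lp)
  t_event <- withr::with_seed(as.integer(seed), rexp(n, rate = rate))
  tibble(
    subject_id = if ("subject_id" %in% names(features)) features$subject_id
                 else sprintf("s%03d", seq_len(n)),
    time_months = pmin(t_event, hazard$censor_time),
    event = as.integer(t_event <= hazard$censor_time)
  )
}

#' Block atlas layout for NIfTI fixtures
#'
#' Assigns each region a contiguous run of voxels (linear order) in a small
#' 3-D grid; remaining voxels are background (label 0).
#'
#' @param n_regions number of regions.
#' @param n_voxels voxels per region (scalar or vector).
#' @param dim 3-D grid dimensions.
#' @return A list with class `klse_atlas_layout`: `dim` and integer `labels`
#'   array.
#' @export
block_atlas_layout <- function(n_regions, n_voxels, dim = c(12L, 12L, 12L)) {
  n_voxels <- rep_len(as.integer(n_voxels), n_regions)
  total <- sum(n_voxels)
  if (prod(dim) < total) {
    abort(sprintf("grid %s too small for %d voxels.",
                  paste(dim, collapse = "x"), total))
  }
  labels <- integer(prod(dim))
  stops <- cumsum(n_voxels)
  starts <- c(1L, head(stops, -1L) + 1L)
  for (r in seq_len(n_regions)) labels[starts[r]:stops[r]] <- r
  structure(
    list(dim = as.integer(dim), labels = array(labels, dim = dim)),
    class = "klse_atlas_layout"
  )
}

#' Write a subject volume and matching atlas volume as NIfTI fixtures
#'
#' The subject's per-region samples are placed into the layout's voxel blocks;
#' background voxels are 0. Round-tripping through [load_parcellation()]
#' recovers the per-region samples as multisets.
#'
#' @param subject a [parcellated_subject()]; region `i`'s sample count must
#'   equal the layout's voxel count for region `i`.
#' @param layout a [block_atlas_layout()].
#' @param dir directory to write into.
#' @param prefix file name prefix; writes `<prefix>_pet.nii` and
#'   `<prefix>_atlas.nii`.
#' @return Invisibly, a named character vector with paths `pet` and `atlas`.
#' @export
write_nifti_fixture <- function(subject, layout, dir, prefix = "fixture") {
  stopifnot(inherits(subject, "klse_subject"), inherits(layout, "klse_atlas_layout"))
  labs <- as.vector(layout$labels)
  counts <- tabulate(labs, nbins = subject$R)
  nv <- vapply(subject$samples, length, 1L)
  if (!all(counts == nv)) {
    abort("layout voxel counts do not match the subject's sample counts.")
  }
  vol <- numeric(length(labs))
  for (r in seq_len(subject$R)) {
    vol[labs == r] <- subject$samples[[r]]
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pet_path <- file.path(dir, paste0(prefix, "_pet.nii"))
  atlas_path <- file.path(dir, paste0(prefix, "_atlas.nii"))
  RNifti::writeNifti(RNifti::asNifti(array(vol, dim = layout$dim)), pet_path)
  RNifti::writeNifti(RNifti::asNifti(layout$labels), atlas_path)
  invisible(c(pet = pet_path, atlas = atlas_path))
}
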
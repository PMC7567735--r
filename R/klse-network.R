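#' Kernel density estimate of a region's voxel-intensity distribution
#'
#' Gaussian-kernel density on an explicit evaluation grid, renormalized so its
#' trapezoid integral over the grid is exactly 1. The bandwidth defaults to
#' Silverman's rule of thumb ([stats::bw.nrd0()]); zero-variance input falls
#' back to `1e-3 * max(|mean|, 1)` rather than failing, so a pathological
#' constant region still yields a (sharply peaked) density.
#'
#' @param samples numeric vector of at least 10 finite values.
#' @param grid increasing numeric vector of evaluation points, or `NULL` to
#'   span `range(samples) +/- 3 * bandwidth` with `n_grid` points.
#' @param bw bandwidth override (> 0), or `NULL` for Silverman's rule.
#' @param n_grid grid size when `grid` is `NULL` (default 512).
#' @return An object of class `klse_density`: list with `grid`, `density`,
#'   `bandwidth`.
#' @export
estimate_pdf <- function(samples, grid = NULL, bw = NULL, n_grid = 512L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 10L) abort("need at least 10 finite samples.")
  if (is.null(bw)) {
    bw <- silverman_bw(samples)
  }
  stopifnot_scalar_number(bw, "bw", positive = TRUE)
  if (is.null(grid)) {
    grid <- seq(min(samples) - 3 * bw, max(samples) + 3 * bw, length.out = n_grid)
  }
  if (length(grid) < 8L || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be a strictly increasing vector.")
  }
  d <- stats::density(samples, bw = bw, from = grid[1], to = grid[length(grid)],
                      n = length(grid))
  y <- pmax(d$y, 0)
  total <- trapz(grid, y)
  if (total <= 0) abort("density integrated to zero on the grid.")
  structure(
    list(grid = grid, density = y / total, bandwidth = bw),
    class = "klse_density"
  )
}

# Silverman's rule with a fallback for zero-variance samples (bw.nrd0 has
# its own internal fallback for constant data, which is far too wide here).
silverman_bw <- function(samples) {
  if (stats::sd(samples) == 0) {
    return(1e-3 * max(abs(mean(samples)), 1))
  }
  bw <- tryCatch(stats::bw.nrd0(samples), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) {
    bw <- 1e-3 * max(abs(mean(samples)), 1)
  }
  bw
}

#' @export
print.klse_density <- function(x, ...) {
  cat(sprintf(
    "<klse_density> %d grid points on [%.3g, %.3g], bandwidth %.3g\n",
    length(x$grid), x$grid[1], x$grid[length(x$grid)], x$bandwidth
  ))
  invisible(x)
}

#' Symmetric Kullback-Leibler divergence between two density estimates
#'
#' Trapezoid approximation of
#' `integral( P log(P/Q) + Q log(Q/P) )` over the shared grid. Before taking
#' logs, each density is floored at `floor_frac` times the larger of the two
#' density peaks: the divergence integrand is undefined where either density
#' is zero, and a kernel density estimate decays far faster than any true
#' tail beyond its sample range, so an unbounded log-ratio there would be
#' estimation artefact, not signal. The floor is relative to the peak so the
#' statistic is invariant under rescaling the intensity axis.
#'
#' @param P,Q `klse_density` objects on the same grid.
#' @param floor_frac density floor as a fraction of the pair's peak density
#'   (default `1e-5`).
#' @return A non-negative number; 0 when `P` and `Q` coincide on the grid.
#'   Symmetric in its arguments by construction.
#' @export
symmetric_kl <- function(P, Q, floor_frac = 1e-5) {
  stopifnot(inherits(P, "klse_density"), inherits(Q, "klse_density"))
  if (length(P$grid) != length(Q$grid) ||
      max(abs(P$grid - Q$grid)) > 1e-12 * max(1, abs(P$grid[length(P$grid)]))) {
    abort("`P` and `Q` must share the same grid.")
  }
  if (identical(P$density, Q$density)) return(0)
  eps <- floor_frac * max(max(P$density), max(Q$density))
  p <- pmax(P$density, eps)
  q <- pmax(Q$density, eps)
  d <- trapz(P$grid, p * log(p / q) + q * log(q / p))
  max(d, 0)
}

#' Connectivity strength from a divergence
#'
#' Maps a symmetric KL divergence `d >= 0` to the edge weight `exp(-d)`,
#' a strictly decreasing function with `kls_strength(0) = 1`.
#'
#' @param d non-negative divergence (vectorized).
#' @return Weights in `(0, 1]`.
#' @export
kls_strength <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) abort("`d` must be finite and >= 0.")
  exp(-d)
}

new_connectome <- function(weights, kind, region_labels) {
  dimnames(weights) <- list(region_labels, region_labels)
  diag(weights) <- 0
  structure(
    list(weights = weights, kind = kind, region_labels = region_labels),
    class = "klse_connectome"
  )
}

#' Individual metabolic network from a parcellated subject
#'
#' For every pair of regions, both intensity densities are estimated on a
#' pair-specific shared grid (spanning the pooled samples of the pair,
#' padded by 3 bandwidths) and the edge weight is
#' `exp(-symmetric_kl(P, Q))`. The result is a symmetric `R x R` matrix with
#' weights in `(0, 1]` off the diagonal. Mathematically the self-similarity
#' is 1, but the diagonal is stored as 0 so self-loops never enter graph
#' metrics.
#'
#' @param subject a (normalized) [parcellated_subject()].
#' @param n_grid grid points per pair (default 512).
#' @param bw optional fixed bandwidth applied to every region; default is
#'   Silverman's rule per region.
#' @param floor_frac density floor passed to [symmetric_kl()].
#' @return A `klse_connectome` object (`weights`, `kind = "KLS"`,
#'   `region_labels`).
#' @export
klse_connectome <- function(subject, n_grid = 512L, bw = NULL,
                            floor_frac = 1e-5) {
  stopifnot(inherits(subject, "klse_subject"))
  R <- subject$R
  labels <- names(subject$samples)
  h <- if (is.null(bw)) {
    vapply(subject$samples, silverman_bw, numeric(1))
  } else {
    rep(bw, R)
  }
  lo <- vapply(subject$samples, min, numeric(1))
  hi <- vapply(subject$samples, max, numeric(1))
  w <- matrix(1, R, R)
  for (i in seq_len(R - 1L)) {
    for (j in seq.int(i + 1L, R)) {
      hm <- max(h[i], h[j])
      grid <- seq(min(lo[i], lo[j]) - 3 * hm, max(hi[i], hi[j]) + 3 * hm,
                  length.out = n_grid)
      P <- estimate_pdf(subject$samples[[i]], grid = grid, bw = h[i])
      Q <- estimate_pdf(subject$samples[[j]], grid = grid, bw = h[j])
      w[i, j] <- w[j, i] <- kls_strength(symmetric_kl(P, Q, floor_frac))
    }
  }
  new_connectome(w, "KLS", labels)
}

#' Group-level Pearson metabolic network
#'
#' The conventional group-level comparator: Pearson correlation between
#' region mean-uptake columns across subjects.
#'
#' @param mean_uptake a subjects-by-regions table, e.g. from
#'   [cohort_mean_uptake()]; non-numeric columns (`subject_id`, `group`) are
#'   dropped.
#' @return A `klse_connectome` with `kind = "Pearson"`. Regions with zero
#'   variance across subjects get correlation 0 (with a warning).
#' @export
group_pearson_network <- function(mean_uptake) {
  stopifnot(is.data.frame(mean_uptake))
  num <- mean_uptake[vapply(mean_uptake, is.numeric, TRUE)]
  x <- as.matrix(num)
  if (nrow(x) < 3L) abort("need at least 3 subjects.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("zero-variance region(s) %s: correlations set to 0.",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  w <- suppressWarnings(cor(x))
  w[!is.finite(w)] <- 0
  new_connectome(w, "Pearson", colnames(x))
}

#' @export
print.klse_connectome <- function(x, ...) {
  v <- upper_tri_vec(x$weights)
  cat(sprintf(
    "<klse_connectome> kind=%s, %d regions, %d edges, weights [%.3f, %.3f] (median %.3f)\n",
    x$kind, length(x$region_labels), length(v), min(v), max(v), median(v)
  ))
  invisible(x)
}

#' Tidy a connectome into an edge table
#'
#' @param x a `klse_connectome`.
#' @param ... unused.
#' @return A tibble with `region_a`, `region_b`, `weight` — one row per
#'   unique (i < j) edge.
#' @method tidy klse_connectome
#' @export
tidy.klse_connectome <- function(x, ...) {
  R <- length(x$region_labels)
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble(
    region_a = x$region_labels[idx[, 1]],
    region_b = x$region_labels[idx[, 2]],
    weight = x$weights[idx]
  )
}

#' Write / read a connectome as CSV
#'
#' The CSV carries the full symmetric matrix with region labels as header row
#' and first column.
#'
#' @param net a `klse_connectome`.
#' @param path file path.
#' @return `write_connectome_csv()` returns `path` invisibly;
#'   `read_connectome_csv()` returns a `klse_connectome`.
#' @export
write_connectome_csv <- function(net, path) {
  stopifnot(inherits(net, "klse_connectome"))
  utils::write.csv(net$weights, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @param kind network kind to stamp on the read object.
#' @export
read_connectome_csv <- function(path, kind = "KLS") {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  new_connectome(m, kind, rownames(m))
}
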
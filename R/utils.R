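# Internal helpers shared across modules.

# Indices of the unique (i < j) edges of an R x R symmetric matrix, in
# column-major upper-triangle order. All edge-wise statistics use this order
# so that vectorised networks are comparable across subjects.
upper_tri_index <- function(R) which(upper.tri(matrix(0, R, R)))

# Vectorise the upper triangle of a symmetric matrix (column-major order).
upper_tri_vec <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix (zero diagonal) from an upper-triangle vector.
sym_from_upper <- function(v, R, dimnames = NULL) {
  m <- matrix(0, R, R, dimnames = dimnames)
  m[upper.tri(m)] <- v
  m + t(m)
}

# Deterministically derive `n` sub-seeds from one parent seed, all < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Trapezoid integral on an equally spaced or general grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}

# Coerce a connectome object or bare matrix to a validated weight matrix.
as_weight_matrix <- function(net) {
  w <- if (inherits(net, "klse_connectome")) net$weights else net
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    abort("`net` must be a `klse_connectome` or a square matrix.")
  }
  if (max(abs(w - t(w))) > 1e-8) abort("network weights must be symmetric.")
  w
}

region_labels_of <- function(net) {
  w <- as_weight_matrix(net)
  rownames(w) %||% sprintf("r%02d", seq_len(nrow(w)))
}
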
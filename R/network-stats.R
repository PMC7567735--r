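#' Fisher Z-transformation of a network
#'
#' Applies `atanh` elementwise to the off-diagonal weights after clipping at
#' `+/-(1 - 1e-7)` (KLS weights of exactly 1 would otherwise map to
#' infinity). The diagonal stays 0 and symmetry is preserved.
#'
#' @param net a `klse_connectome` or symmetric matrix.
#' @return A matrix of Z-transformed weights.
#' @export
fisher_z <- function(net) {
  w <- as_weight_matrix(net)
  w <- pmin(pmax(w, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(w)
  diag(z) <- 0
  z
}

stack_networks <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 1L)
  mats <- lapply(networks, as_weight_matrix)
  R <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 1L) == R)) abort("networks differ in size.")
  list(
    edges = do.call(rbind, lapply(mats, upper_tri_vec)),  # subjects x E
    R = R,
    labels = region_labels_of(networks[[1]])
  )
}

#' Edge-wise group difference pattern with FDR control
#'
#' For every unique edge, compares the two groups' (Fisher-Z transformed)
#' weights with a two-sample t test — Welch by default, pooled-variance
#' optionally — then adjusts the `R(R-1)/2` p-values by Benjamini-Hochberg.
#' An edge is flagged significant when its adjusted p-value is below `alpha`.
#'
#' @param nets_a,nets_b lists of `klse_connectome` objects (>= 2 per group).
#' @param alpha FDR significance level (default 0.05).
#' @param transform `"fisher"` (default) to compare Fisher-Z weights, or
#'   `"none"`.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return An object of class `klse_diff`: matrices `t_stat`, `p_value`,
#'   `q_value`, logical `significant`, plus `alpha` and region labels.
#'   Edges with zero variance in both groups get `t = 0`, `p = 1` (warned).
#' @export
edgewise_difference <- function(nets_a, nets_b, alpha = 0.05,
                                transform = c("fisher", "none"),
                                var_equal = FALSE) {
  transform <- match.arg(transform)
  if (length(nets_a) < 2L || length(nets_b) < 2L) {
    abort("need at least 2 networks per group.")
  }
  a <- stack_networks(nets_a)
  b <- stack_networks(nets_b)
  if (a$R != b$R) abort("groups have different region counts.")
  if (transform == "fisher") {
    a$edges <- atanh(pmin(pmax(a$edges, -(1 - 1e-7)), 1 - 1e-7))
    b$edges <- atanh(pmin(pmax(b$edges, -(1 - 1e-7)), 1 - 1e-7))
  }
  na <- nrow(a$edges); nb <- nrow(b$edges)
  ma <- colMeans(a$edges); mb <- colMeans(b$edges)
  va <- apply(a$edges, 2, var); vb <- apply(b$edges, 2, var)
  degenerate <- (va + vb) == 0
  if (any(degenerate)) {
    warn(sprintf("%d edge(s) with zero variance in both groups: p set to 1.",
                 sum(degenerate)))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tt <- ifelse(degenerate | se == 0, 0, (ma - mb) / se)
  pp <- ifelse(degenerate | se == 0, 1, 2 * pt(-abs(tt), df))
  qq <- p.adjust(pp, method = "BH")
  dn <- list(a$labels, a$labels)
  structure(
    list(
      t_stat = sym_from_upper(tt, a$R, dn),
      p_value = sym_from_upper(pp, a$R, dn),
      q_value = sym_from_upper(qq, a$R, dn),
      significant = sym_from_upper(as.numeric(qq < alpha), a$R, dn) > 0,
      alpha = alpha,
      region_labels = a$labels,
      n_a = na, n_b = nb
    ),
    class = "klse_diff"
  )
}

#' @export
print.klse_diff <- function(x, ...) {
  ns <- sum(upper_tri_vec(x$significant))
  ne <- length(upper_tri_vec(x$significant))
  cat(sprintf(
    "<klse_diff> %d x %d regions, %d/%d edges significant at q < %.3g (n = %d vs %d)\n",
    nrow(x$t_stat), ncol(x$t_stat), ns, ne, x$alpha, x$n_a, x$n_b
  ))
  invisible(x)
}

#' @method tidy klse_diff
#' @export
tidy.klse_diff <- function(x, ...) {
  idx <- which(upper.tri(x$t_stat), arr.ind = TRUE)
  tibble(
    region_a = x$region_labels[idx[, 1]],
    region_b = x$region_labels[idx[, 2]],
    t_stat = x$t_stat[idx],
    p_value = x$p_value[idx],
    q_value = x$q_value[idx],
    significant = x$significant[idx]
  )
}

resolve_lobe_of <- function(lobe_map, labels) {
  stopifnot(is.data.frame(lobe_map))
  key <- if ("label" %in% names(lobe_map)) as.character(lobe_map$label) else
    as.character(lobe_map$region)
  lobe <- as.character(lobe_map$lobe)
  names(lobe) <- key
  missing <- setdiff(labels, key)
  if (length(missing) > 0L) {
    abort(sprintf("lobe map lacks region(s): %s", paste(missing, collapse = ", ")))
  }
  lobe[labels]
}

#' Lobe-wise fraction of significant edges
#'
#' For each lobe, the number of significant unique edges touching the lobe
#' (`count = "touch"`, at least one endpoint; the default) or contained in it
#' (`count = "within"`, both endpoints) divided by the total number of
#' significant unique edges. Under `"touch"` an edge can contribute to two
#' lobes, so fractions need not sum to 1.
#'
#' @param pattern a [edgewise_difference()] result.
#' @param lobe_map data frame with columns `label` (matching the network's
#'   region labels) and `lobe`.
#' @param count `"touch"` or `"within"`.
#' @return A tibble `lobe`, `n_edges`, `fraction`, plus attribute
#'   `no_significant_edges` flag when there is nothing to count.
#' @export
lobe_alteration_fraction <- function(pattern, lobe_map,
                                     count = c("touch", "within")) {
  stopifnot(inherits(pattern, "klse_diff"))
  count <- match.arg(count)
  lobe_of <- resolve_lobe_of(lobe_map, pattern$region_labels)
  idx <- which(upper.tri(pattern$significant), arr.ind = TRUE)
  sig <- pattern$significant[idx]
  total <- sum(sig)
  lobes <- unname(sort(unique(lobe_of)))
  la <- lobe_of[idx[, 1]]; lb <- lobe_of[idx[, 2]]
  counts <- vapply(lobes, function(l) {
    inl <- if (count == "touch") (la == l | lb == l) else (la == l & lb == l)
    sum(sig & inl)
  }, numeric(1))
  out <- tibble(
    lobe = lobes,
    n_edges = as.integer(counts),
    fraction = unname(if (total == 0) rep(0, length(lobes)) else counts / total)
  )
  attr(out, "no_significant_edges") <- total == 0
  attr(out, "total_significant") <- as.integer(total)
  out
}

spearman_pairs <- function(x) {
  # x: variables in columns; returns upper-triangle Spearman correlations,
  # with constant columns contributing 0 (warned).
  const <- apply(x, 2, function(v) max(v) == min(v))
  if (any(const)) {
    warn(sprintf("%d constant network vector(s): their pair correlations set to 0.",
                 sum(const)))
  }
  r <- suppressWarnings(cor(x, method = "spearman"))
  r[!is.finite(r)] <- 0
  upper_tri_vec(r)
}

#' Inter-subject network similarity
#'
#' The stability statistic: the mean Spearman rank correlation between the
#' vectorized upper triangles of every unordered pair of networks
#' (`m(m-1)/2` pairs for `m` subjects).
#'
#' @param networks list of `klse_connectome` objects (>= 2).
#' @return An object of class `klse_similarity`: `r_bar` (the mean) and
#'   `pair_correlations`.
#' @export
network_similarity <- function(networks) {
  if (length(networks) < 2L) abort("need at least 2 networks.")
  s <- stack_networks(networks)
  pc <- spearman_pairs(t(s$edges))
  structure(
    list(r_bar = mean(pc), pair_correlations = pc, n_networks = length(networks)),
    class = "klse_similarity"
  )
}

#' @export
print.klse_similarity <- function(x, ...) {
  cat(sprintf("<klse_similarity> %d networks, %d pairs, mean Spearman r = %.3f\n",
              x$n_networks, length(x$pair_correlations), x$r_bar))
  invisible(x)
}

#' @method glance klse_similarity
#' @export
glance.klse_similarity <- function(x, ...) {
  tibble(r_bar = x$r_bar, n_networks = x$n_networks,
         n_pairs = length(x$pair_correlations))
}

#' Regional inter-individual dissimilarity map
#'
#' For each region `i`, `V_i` is the mean over unordered subject pairs of
#' `1 - Spearman correlation` between the subjects' region-`i` connectivity
#' rows (self-entry excluded, since the stored diagonal is a convention, not
#' data). `V_i` lies in `[0, 2]`. The spatial map is Z-normalized across
#' regions (`z` has mean 0 and sd 1 whenever the `V_i` are not all equal).
#'
#' @param networks list of `klse_connectome` objects (>= 2).
#' @return An object of class `klse_dissimilarity` wrapping a tibble with
#'   `region`, `V`, `z`.
#' @export
regional_dissimilarity <- function(networks) {
  if (length(networks) < 2L) abort("need at least 2 networks.")
  mats <- lapply(networks, as_weight_matrix)
  R <- nrow(mats[[1]])
  labels <- region_labels_of(networks[[1]])
  V <- vapply(seq_len(R), function(i) {
    rows <- vapply(mats, function(m) m[i, -i], numeric(R - 1L))  # (R-1) x m
    mean(1 - spearman_pairs(rows))
  }, numeric(1))
  s <- sd(V)
  z <- if (s > 0) (V - mean(V)) / s else rep(0, R)
  structure(
    list(map = tibble(region = labels, V = V, z = z)),
    class = "klse_dissimilarity"
  )
}

#' @export
print.klse_dissimilarity <- function(x, ...) {
  top <- x$map$region[which.max(x$map$z)]
  cat(sprintf("<klse_dissimilarity> %d regions, most dissimilar: %s (z = %.2f)\n",
              nrow(x$map), top, max(x$map$z)))
  invisible(x)
}

#' @method tidy klse_dissimilarity
#' @export
tidy.klse_dissimilarity <- function(x, ...) x$map

#' Lobe means of the dissimilarity Z-map, with pairwise tests
#'
#' Mean Z-normalized dissimilarity per lobe, and Welch t tests between every
#' pair of lobes' regional z values (lobes with fewer than 2 regions are
#' reported without tests).
#'
#' @param dissimilarity a [regional_dissimilarity()] result.
#' @param lobe_map data frame with `label` and `lobe` columns.
#' @return A list with tibbles `lobe_means` (`lobe`, `n_regions`, `mean_z`)
#'   and `pairwise` (`lobe_a`, `lobe_b`, `t_stat`, `p_value`).
#' @export
lobe_mean_z <- function(dissimilarity, lobe_map) {
  stopifnot(inherits(dissimilarity, "klse_dissimilarity"))
  map <- dissimilarity$map
  lobe_of <- resolve_lobe_of(lobe_map, map$region)
  z_by <- split(map$z, lobe_of)
  lobes <- names(z_by)
  means <- tibble(
    lobe = lobes,
    n_regions = unname(vapply(z_by, length, 1L)),
    mean_z = unname(vapply(z_by, mean, numeric(1)))
  )
  pairs <- utils::combn(lobes, 2, simplify = FALSE)
  pw <- purrr::map(pairs, function(p) {
    za <- z_by[[p[1]]]; zb <- z_by[[p[2]]]
    if (length(za) < 2L || length(zb) < 2L) {
      return(tibble(lobe_a = p[1], lobe_b = p[2], t_stat = NA_real_, p_value = NA_real_))
    }
    if (sd(za) == 0 && sd(zb) == 0 && mean(za) == mean(zb)) {
      return(tibble(lobe_a = p[1], lobe_b = p[2], t_stat = 0, p_value = 1))
    }
    ht <- stats::t.test(za, zb)
    tibble(lobe_a = p[1], lobe_b = p[2],
           t_stat = unname(ht$statistic), p_value = ht$p.value)
  })
  list(lobe_means = means, pairwise = bind_rows(pw))
}
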
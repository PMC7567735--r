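# Weighted graph metrics on KLS networks. Conventions follow the Brain
# Connectivity Toolbox: edge length = 1/weight for path-based metrics,
# Onnela geometric-mean clustering, strength-based assortativity,
# efficiency as mean inverse distance.

as_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' All-pairs shortest path lengths of a weighted network
#'
#' Edge lengths are the reciprocals of the weights (strong metabolic
#' similarity = short distance); absent (zero-weight) edges have infinite
#' length.
#'
#' @param net a `klse_connectome` or symmetric nonnegative matrix.
#' @return An `R x R` matrix of shortest path distances (0 on the diagonal,
#'   `Inf` between disconnected nodes).
#' @export
graph_distances <- function(net) {
  w <- as_weight_matrix(net)
  if (any(w < 0)) abort("weights must be nonnegative.")
  g <- as_igraph(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  unname(d)
}

efficiency_from_distances <- function(d) {
  off <- d[row(d) != col(d)]
  mean(1 / off)  # 1/Inf = 0 for disconnected pairs
}

global_efficiency_of <- function(w) {
  if (nrow(w) < 2L) return(0)
  efficiency_from_distances(graph_distances(w))
}

# Onnela weighted clustering: weights scaled by the network maximum; the
# per-node numerator is diag(W^(1/3) %^% 3), the denominator k(k-1) over
# the binary degree.
onnela_clustering <- function(w) {
  mx <- max(w)
  if (mx == 0) return(list(local = rep(0, nrow(w)), transitivity = 0))
  ws <- (w / mx)^(1 / 3)
  num <- diag(ws %*% ws %*% ws)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  local <- ifelse(denom > 0, num / denom, 0)
  transitivity <- if (sum(denom) > 0) sum(num) / sum(denom) else 0
  list(local = local, transitivity = transitivity)
}

# Strength assortativity: Pearson correlation of endpoint strengths over the
# edge list, counting each undirected edge in both orientations.
strength_assortativity <- function(w) {
  s <- rowSums(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) < 2L) return(NA_real_)
  x <- c(s[idx[, 1]], s[idx[, 2]])
  y <- c(s[idx[, 2]], s[idx[, 1]])
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

louvain_modularity <- function(w, seed = 1L, restarts = 10L) {
  g <- as_igraph(w)
  withr::with_seed(as.integer(seed), {
    best <- -Inf
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
      q <- max(igraph::modularity(cl))
      if (q > best) best <- q
    }
    best
  })
}

#' Topology-destroying null networks
#'
#' Each null permutes the upper-triangle weights uniformly at random
#' (preserving the weight multiset and total strength, destroying topology),
#' then mirrors to a symmetric matrix. Used as the reference for
#' small-worldness.
#'
#' @param net a `klse_connectome` or symmetric matrix.
#' @param m number of nulls.
#' @param seed integer seed; identical seeds give identical nulls.
#' @return A list of `m` symmetric matrices.
#' @export
null_networks <- function(net, m = 20L, seed = 1L) {
  w <- as_weight_matrix(net)
  if (m < 1L) abort("`m` must be >= 1.")
  v <- upper_tri_vec(w)
  R <- nrow(w)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(m), function(i) sym_from_upper(sample(v), R))
  })
}

#' The seven global network properties
#'
#' Weighted definitions: mean Onnela local clustering; characteristic path
#' length = mean finite off-diagonal shortest-path distance; small-worldness
#' `S = (C/C_null) / (L/L_null)` against `n_null` weight-permutation nulls;
#' global efficiency = mean inverse distance; weighted transitivity;
#' strength assortativity; Louvain modularity (resolution 1, best of
#' `restarts` seeded restarts).
#'
#' @param net a `klse_connectome` or symmetric nonnegative matrix.
#' @param n_null nulls for small-worldness (default 20).
#' @param seed seed controlling the nulls and Louvain restarts.
#' @param restarts Louvain restarts (default 10).
#' @return A named list of 7 scalars: `clustering_coefficient`,
#'   `char_path_length`, `small_worldness`, `global_efficiency`,
#'   `transitivity`, `assortativity`, `modularity`. If the network is
#'   disconnected, `char_path_length` averages finite pairs only and a
#'   `disconnected` attribute flags it.
#' @export
global_metrics <- function(net, n_null = 20L, seed = 1L, restarts = 10L) {
  w <- as_weight_matrix(net)
  d <- graph_distances(w)
  off <- d[row(d) != col(d)]
  disconnected <- any(!is.finite(off))
  L <- mean(off[is.finite(off)])
  oc <- onnela_clustering(w)
  C <- mean(oc$local)
  null_seeds <- derive_seeds(seed, 2L)
  nulls <- null_networks(w, m = n_null, seed = null_seeds[1])
  CL_null <- vapply(nulls, function(nw) {
    dn <- graph_distances(nw)
    offn <- dn[row(dn) != col(dn)]
    c(mean(onnela_clustering(nw)$local), mean(offn[is.finite(offn)]))
  }, numeric(2))
  C_null <- mean(CL_null[1, ])
  L_null <- mean(CL_null[2, ])
  S <- (C / C_null) / (L / L_null)
  out <- list(
    clustering_coefficient = C,
    char_path_length = L,
    small_worldness = S,
    global_efficiency = efficiency_from_distances(d),
    transitivity = oc$transitivity,
    assortativity = strength_assortativity(w),
    modularity = louvain_modularity(w, seed = null_seeds[2], restarts = restarts)
  )
  attr(out, "disconnected") <- disconnected
  out
}

#' The five regional network properties
#'
#' Per node: `degree` (strength = summed incident weight), `betweenness`
#' (on 1/weight edge lengths), `local_clustering` (Onnela),
#' `local_efficiency` (global efficiency of the node's neighborhood
#' subgraph), and `vulnerability` (relative drop in global efficiency when
#' the node is deleted). Isolated nodes score 0 on the local metrics.
#'
#' @param net a `klse_connectome` or symmetric nonnegative matrix.
#' @return A tibble with `region` and the five metric columns.
#' @export
regional_metrics <- function(net) {
  w <- as_weight_matrix(net)
  labels <- region_labels_of(net)
  R <- nrow(w)
  g <- as_igraph(w)
  btw <- if (igraph::ecount(g) > 0) {
    igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
  } else {
    rep(0, R)
  }
  oc <- onnela_clustering(w)
  e_glob <- global_efficiency_of(w)
  local_eff <- vapply(seq_len(R), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency_of(w[nb, nb, drop = FALSE])
  }, numeric(1))
  vulnerability <- vapply(seq_len(R), function(i) {
    if (e_glob == 0) return(0)
    (e_glob - global_efficiency_of(w[-i, -i, drop = FALSE])) / e_glob
  }, numeric(1))
  tibble(
    region = labels,
    degree = unname(rowSums(w)),
    betweenness = unname(btw),
    local_efficiency = local_eff,
    vulnerability = vulnerability,
    local_clustering = oc$local
  )
}

regional_metric_names <- c("betweenness", "degree", "local_efficiency",
                           "vulnerability", "local_clustering")

#' Full network property vector (7 global + 5 per region)
#'
#' Assembles the feature vector used for connectome-expression modelling:
#' the seven global properties followed by the five regional properties for
#' every region, named `global__<metric>` and `<metric>__<region>`. At the
#' standard 90-region parcellation this is 457 properties.
#'
#' @param net a `klse_connectome` or symmetric nonnegative matrix.
#' @param n_null,seed,restarts passed to [global_metrics()].
#' @return A named numeric vector of length `7 + 5 * R`, in a deterministic
#'   order (globals first, then regional metrics in the order betweenness,
#'   degree, local_efficiency, vulnerability, local_clustering, each across
#'   regions in atlas order). Any non-finite value is an error naming the
#'   property.
#' @export
feature_vector <- function(net, n_null = 20L, seed = 1L, restarts = 10L) {
  glob <- global_metrics(net, n_null = n_null, seed = seed, restarts = restarts)
  reg <- regional_metrics(net)
  out <- c(
    setNames(unlist(glob), paste0("global__", names(glob))),
    unlist(lapply(regional_metric_names, function(m) {
      setNames(reg[[m]], paste0(m, "__", reg$region))
    }))
  )
  bad <- names(out)[!is.finite(out)]
  if (length(bad) > 0L) {
    abort(sprintf("non-finite network propert%s: %s",
                  if (length(bad) == 1) "y" else "ies",
                  paste(bad, collapse = ", ")))
  }
  out
}

#' Feature table for a set of networks
#'
#' @param networks named list of `klse_connectome` objects (names become
#'   `subject_id`), or a cohort tibble carrying a `network` list-column.
#' @param n_null,seed,restarts passed to [global_metrics()].
#' @return A tibble: `subject_id` plus one column per network property.
#' @export
network_features <- function(networks, n_null = 20L, seed = 1L, restarts = 10L) {
  if (is.data.frame(networks)) {
    stopifnot("network" %in% names(networks))
    ids <- networks$subject_id %||% sprintf("s%03d", seq_len(nrow(networks)))
    nets <- networks$network
  } else {
    nets <- networks
    ids <- names(networks) %||% sprintf("s%03d", seq_along(networks))
  }
  rows <- purrr::map2(nets, seq_along(nets), function(nw, i) {
    fv <- feature_vector(nw, n_null = n_null, seed = seed, restarts = restarts)
    as_tibble(as.list(fv))
  })
  dplyr::bind_cols(tibble(subject_id = ids), bind_rows(rows))
}
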
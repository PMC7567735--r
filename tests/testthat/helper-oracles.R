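# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (loops, enumeration) and separate from the package's
# implementation paths.

# --- graph oracles ----------------------------------------------------------

# Floyd-Warshall all-pairs shortest paths on 1/weight edge lengths.
brute_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

brute_efficiency <- function(w) {
  d <- brute_distances(w)
  off <- d[row(d) != col(d)]
  mean(1 / off)
}

brute_char_path <- function(w) {
  d <- brute_distances(w)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# Betweenness by exhaustive enumeration of simple paths (small n only):
# for each ordered pair, find all shortest simple paths and credit interior
# nodes fractionally; undirected totals are halved.
brute_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1L]] <<- list(path = path, len = len)
        return()
      }
      for (v in seq_len(n)) {
        if (w[last, v] > 0 && !(v %in% path)) {
          walk(c(path, v), len + 1 / w[last, v])
        }
      }
    }
    walk(s, 0)
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- vapply(paths, function(p) p$len, numeric(1))
    short <- paths[lens <= min(lens) + tol]
    for (p in short) {
      interior <- setdiff(p$path, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(short)
    }
  }
  btw
}

brute_onnela_local <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  out <- numeric(n)
  if (mx == 0) return(out)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        acc <- acc + (w[i, j] / mx * w[i, h] / mx * w[j, h] / mx)^(1 / 3)
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

brute_transitivity <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    den <- den + k * (k - 1)
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        num <- num + (w[i, j] / mx * w[i, h] / mx * w[j, h] / mx)^(1 / 3)
      }
    }
  }
  if (den == 0) 0 else num / den
}

brute_vulnerability <- function(w) {
  e <- brute_efficiency(w)
  vapply(seq_len(nrow(w)), function(i) {
    (e - brute_efficiency(w[-i, -i, drop = FALSE])) / e
  }, numeric(1))
}

# Best modularity over all partitions (Bell-number enumeration; n <= 7).
brute_best_modularity <- function(w) {
  n <- nrow(w)
  two_m <- sum(w)
  strength <- rowSums(w)
  part_q <- function(member) {
    q <- 0
    for (c in unique(member)) {
      idx <- member == c
      q <- q + sum(w[idx, idx]) / two_m - (sum(strength[idx]) / two_m)^2
    }
    q
  }
  parts <- list(c(1L))
  for (v in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      ks <- max(p) + 1L
      lapply(seq_len(ks), function(k) c(p, k))
    }), recursive = FALSE)
  }
  max(vapply(parts, part_q, numeric(1)))
}

random_weight_graph <- function(n, seed, p_edge = 0.7) {
  set.seed(seed)
  v <- runif(n * (n - 1) / 2, 0.1, 1) * (runif(n * (n - 1) / 2) < p_edge)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

# --- statistics oracles -----------------------------------------------------

brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

brute_cindex <- function(pi, time, event) {
  n <- length(pi)
  num <- 0
  den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + if (pi[i] > pi[j]) 1 else if (pi[i] == pi[j]) 0.5 else 0
    }
  }
  num / den
}

# --- fixture builders -------------------------------------------------------

# A connectome object from a bare symmetric matrix.
as_net <- function(w) {
  labels <- sprintf("%d", seq_len(nrow(w)))
  dimnames(w) <- list(labels, labels)
  diag(w) <- 0
  structure(list(weights = w, kind = "KLS", region_labels = labels),
            class = "klse_connectome")
}

# Random connectivity matrices with Gaussian edge noise around a template.
random_nets <- function(m, R, seed, sd = 0.1, template = NULL) {
  set.seed(seed)
  E <- R * (R - 1) / 2
  if (is.null(template)) template <- runif(E, 0.2, 0.8)
  lapply(seq_len(m), function(i) {
    as_net(klse:::sym_from_upper(pmin(pmax(template + rnorm(E, 0, sd), 1e-4), 1), R))
  })
}

gauss_region_spec <- function(R, n_voxels = 200, mu = NULL, sigma = NULL) {
  frac <- seq(0, 1, length.out = R)
  region_spec(
    region_id = seq_len(R),
    mu = mu %||% (0.9 + 0.2 * frac),
    sigma = sigma %||% rep(0.1, R),
    n_voxels = n_voxels
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_records <- function(n, beta, seed, censor = 60) {
  set.seed(seed)
  feats <- tibble::tibble(subject_id = sprintf("s%04d", 1:n), f1 = rnorm(n))
  rec <- simulate_conversion(
    feats, hazard_spec(c(f1 = beta), baseline_rate = 1 / 40, censor_time = censor),
    seed = seed + 1
  )
  dplyr::bind_cols(rec, feats["f1"])
}

gauss_symkl <- function(dmu, s1, s2) {
  (s1^2 + dmu^2) / (2 * s2^2) + (s2^2 + dmu^2) / (2 * s1^2) - 1
}

# Symmetric KL between two Gaussian samples through the package's own
# estimator path (pair-specific shared grid, as klse_connectome builds it).
sample_symkl <- function(x, y) {
  hx <- klse:::silverman_bw(x)
  hy <- klse:::silverman_bw(y)
  hm <- max(hx, hy)
  grid <- seq(min(x, y) - 3 * hm, max(x, y) + 3 * hm, length.out = 512)
  symmetric_kl(estimate_pdf(x, grid = grid, bw = hx),
               estimate_pdf(y, grid = grid, bw = hy))
}
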
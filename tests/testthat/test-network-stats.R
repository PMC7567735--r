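test_that("Fisher Z transform has its closed-form values and monotonicity", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  z <- fisher_z(w)
  expect_equal(z[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(matrix(0, 2, 2))[1, 2], 0)
  # monotone in the weight
  w1 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  w2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  expect_lt(fisher_z(w1)[1, 2], fisher_z(w2)[1, 2])
  # weight 1 (identical densities) is clipped, not infinite
  expect_true(is.finite(fisher_z(matrix(c(0, 1, 1, 0), 2, 2))[1, 2]))
})

test_that("edge-wise differences vanish for identical groups and flag injected ones", {
  nets <- random_nets(10, 6, seed = 31)
  # groups that are permutations of one another: t = 0 everywhere
  pat <- edgewise_difference(nets[1:10], nets[10:1])
  expect_lt(max(abs(pat$t_stat)), 1e-8)
  expect_true(all(pat$p_value[upper.tri(pat$p_value)] > 1 - 1e-8))
  expect_false(any(pat$significant))

  # a strongly shifted edge is flagged; BH q-values match the brute force
  a <- random_nets(50, 6, seed = 32, sd = 0.05)
  b <- random_nets(50, 6, seed = 33, sd = 0.05)
  b <- lapply(b, function(n) {
    n$weights[1, 2] <- n$weights[2, 1] <- min(n$weights[1, 2] + 0.3, 0.999)
    n
  })
  pat2 <- edgewise_difference(a, b, alpha = 0.05)
  expect_true(pat2$significant[1, 2])
  expect_equal(
    pat2$q_value[upper.tri(pat2$q_value)],
    brute_bh(pat2$p_value[upper.tri(pat2$p_value)]),
    tolerance = 1e-12
  )

  # zero-variance edge: p = 1 with a warning
  c1 <- lapply(1:3, function(i) {
    n <- random_nets(1, 4, seed = 40 + i)[[1]]
    n$weights[1, 2] <- n$weights[2, 1] <- 0.5
    n
  })
  c2 <- lapply(4:6, function(i) {
    n <- random_nets(1, 4, seed = 40 + i)[[1]]
    n$weights[1, 2] <- n$weights[2, 1] <- 0.5
    n
  })
  expect_warning(pz <- edgewise_difference(c1, c2), "zero variance")
  expect_equal(pz$p_value[1, 2], 1)

  expect_error(edgewise_difference(nets[1], nets[2:4]), "at least 2")
})

test_that("lobe alteration fractions count touching edges over total significant", {
  # hand-built 6-region, 2-lobe pattern with 3 significant edges
  sig <- matrix(FALSE, 6, 6, dimnames = list(as.character(1:6), as.character(1:6)))
  mark <- function(i, j) sig[i, j] <<- sig[j, i] <<- TRUE
  mark(1, 2)  # inside lobe X
  mark(1, 4)  # touches X and Y
  mark(4, 5)  # inside lobe Y
  pattern <- structure(
    list(significant = sig, alpha = 0.05, region_labels = as.character(1:6)),
    class = "klse_diff"
  )
  lobe_map <- tibble::tibble(label = as.character(1:6),
                             lobe = rep(c("X", "Y"), each = 3))
  fr <- lobe_alteration_fraction(pattern, lobe_map)
  expect_equal(fr$fraction[fr$lobe == "X"], 2 / 3)
  expect_equal(fr$fraction[fr$lobe == "Y"], 2 / 3)
  frw <- lobe_alteration_fraction(pattern, lobe_map, count = "within")
  expect_equal(frw$fraction[frw$lobe == "X"], 1 / 3)

  # all significant edges inside one lobe
  sig2 <- sig & FALSE
  sig2[1, 2] <- sig2[2, 1] <- sig2[2, 3] <- sig2[3, 2] <- TRUE
  pattern2 <- structure(
    list(significant = sig2, alpha = 0.05, region_labels = as.character(1:6)),
    class = "klse_diff"
  )
  fr2 <- lobe_alteration_fraction(pattern2, lobe_map)
  expect_equal(fr2$fraction, c(1, 0))

  # empty pattern: zeros with the flag set
  pattern3 <- structure(
    list(significant = sig & FALSE, alpha = 0.05, region_labels = as.character(1:6)),
    class = "klse_diff"
  )
  fr3 <- lobe_alteration_fraction(pattern3, lobe_map)
  expect_true(all(fr3$fraction == 0))
  expect_true(attr(fr3, "no_significant_edges"))
})

test_that("inter-subject similarity averages all unordered pair correlations", {
  nets <- random_nets(5, 6, seed = 50)
  # identical networks: perfect similarity
  same <- rep(nets[1], 4)
  expect_equal(network_similarity(same)$r_bar, 1)

  # 20 subjects yield 190 pairs
  twenty <- random_nets(20, 8, seed = 51)
  sim <- network_similarity(twenty)
  expect_length(sim$pair_correlations, 190)
  expect_equal(sim$r_bar, mean(sim$pair_correlations))
  expect_true(all(abs(sim$pair_correlations) <= 1))

  # independently shuffled edge weights: similarity collapses toward zero
  shuffled <- lapply(1:20, function(i) {
    set.seed(600 + i)
    as_net(klse:::sym_from_upper(sample(runif(90 * 89 / 2)), 90))
  })
  expect_lt(abs(network_similarity(shuffled)$r_bar), 0.05)

  expect_error(network_similarity(nets[1]), "at least 2")
})

test_that("regional dissimilarity pinpoints the noisy region and Z-normalizes", {
  # identical networks: V = 0 everywhere
  nets <- rep(random_nets(1, 8, seed = 60), 5)
  dm <- regional_dissimilarity(nets)
  expect_lt(max(abs(dm$map$V)), 1e-12)

  # region k randomized per subject, everything else shared: argmax z = k
  k <- 3
  base <- random_nets(1, 10, seed = 61)[[1]]$weights
  noisy <- lapply(1:8, function(i) {
    set.seed(700 + i)
    w <- base
    w[k, -k] <- w[-k, k] <- runif(9, 0.1, 0.9)
    as_net(w)
  })
  dn <- regional_dissimilarity(noisy)
  expect_equal(which.max(dn$map$z), k)
  expect_equal(mean(dn$map$z), 0, tolerance = 1e-9)
  expect_equal(sd(dn$map$z), 1, tolerance = 1e-9)
  expect_true(all(dn$map$V >= 0 & dn$map$V <= 2))
})

test_that("lobe dissimilarity means match direct arithmetic", {
  map <- tibble::tibble(region = as.character(1:6),
                        V = c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8))
  map$z <- (map$V - mean(map$V)) / sd(map$V)
  dm <- structure(list(map = map), class = "klse_dissimilarity")
  lobe_map <- tibble::tibble(label = as.character(1:6),
                             lobe = rep(c("X", "Y"), each = 3))
  res <- lobe_mean_z(dm, lobe_map)
  expect_equal(res$lobe_means$mean_z[res$lobe_means$lobe == "X"],
               mean(map$z[1:3]))
  expect_equal(res$lobe_means$mean_z[res$lobe_means$lobe == "Y"],
               mean(map$z[4:6]))
  # shifted lobe is strictly the largest; test flags the difference
  expect_gt(res$lobe_means$mean_z[res$lobe_means$lobe == "Y"],
            res$lobe_means$mean_z[res$lobe_means$lobe == "X"])
  expect_lt(res$pairwise$p_value, 0.05)

  # constant map: equal means, p = 1
  mc <- tibble::tibble(region = as.character(1:6), V = rep(0.5, 6), z = rep(0, 6))
  dc <- structure(list(map = mc), class = "klse_dissimilarity")
  rc <- lobe_mean_z(dc, lobe_map)
  expect_equal(unique(rc$lobe_means$mean_z), 0)
  expect_equal(rc$pairwise$p_value, 1)
})

test_that("both similarity statistics equal their identity value on equal networks", {
  nets <- rep(random_nets(1, 7, seed = 70), 2)
  expect_equal(network_similarity(nets)$r_bar, 1)
  expect_lt(max(abs(regional_dissimilarity(nets)$map$V)), 1e-12)
})

test_that("edge statistics are invariant under simultaneous region relabeling", {
  a <- random_nets(6, 5, seed = 80)
  b <- random_nets(6, 5, seed = 81)
  perm <- c(3, 1, 5, 2, 4)
  permute <- function(n) as_net(n$weights[perm, perm])
  pat <- edgewise_difference(a, b)
  patp <- edgewise_difference(lapply(a, permute), lapply(b, permute))
  expect_equal(unname(patp$t_stat), unname(pat$t_stat[perm, perm]),
               tolerance = 1e-12)
  expect_equal(network_similarity(lapply(a, permute))$r_bar,
               network_similarity(a)$r_bar, tolerance = 1e-12)
  dm <- regional_dissimilarity(a)$map$V
  dmp <- regional_dissimilarity(lapply(a, permute))$map$V
  expect_equal(dmp, dm[perm], tolerance = 1e-12)
})
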
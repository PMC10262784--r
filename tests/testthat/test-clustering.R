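test_that("pairwise RMSD matrices are rigid-motion-free and definitional", {
  h <- build_ideal_helix(6)
  set.seed(41)
  frames <- lapply(1:6, function(f)
    apply_rigid(h$xyz, random_rotation(), rnorm(3, 0, 8)))
  tr <- make_trajectory(h, frames)
  m <- pairwise_rmsd_matrix(tr, "backbone")
  expect_lt(max(m), 1e-6)
  expect_equal(m, t(m), tolerance = 1e-9)

  # 3-frame toy with real displacements equals per-pair superposition calls
  f2 <- h$xyz + matrix(rnorm(length(h$xyz), 0, 0.5), ncol = 3)
  f3 <- h$xyz + matrix(rnorm(length(h$xyz), 0, 1.0), ncol = 3)
  tr3 <- make_trajectory(h, list(h$xyz, f2, f3))
  sel <- resolve_selection(h, "backbone")
  m3 <- pairwise_rmsd_matrix(tr3, sel)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(m3[i, j],
                 kabsch_superpose(tr3$frames[sel$indices, , i],
                                  tr3$frames[sel$indices, , j])$rmsd,
                 tolerance = 1e-9)
  expect_equal(diag(m3), rep(0, 3))
})

test_that("QT clustering separates well-spaced groups and saturates on identical frames", {
  d <- matrix(10, 6, 6)
  d[1:3, 1:3] <- 0.2; d[4:6, 4:6] <- 0.2; diag(d) <- 0
  cl <- qt_cluster(d, cutoff = 1)
  expect_length(cl$clusters, 2)
  expect_length(cl$rejected, 0)
  expect_equal(sort(unlist(lapply(cl$clusters, `[[`, "members"))), 1:6)

  ident <- matrix(0, 5, 5)
  cl1 <- qt_cluster(ident, cutoff = 0.5)
  expect_length(cl1$clusters, 1)
  expect_equal(cl1$clusters[[1]]$frequency, 1)
  expect_error(qt_cluster(ident, cutoff = -1), "cutoff")
})

test_that("QT equals the exhaustive brute-force oracle on random instances", {
  set.seed(43)
  for (rep in 1:25) {
    pts <- matrix(rnorm(50 * 2, sd = 2), 50, 2)
    d <- as.matrix(dist(pts))
    cut <- runif(1, 0.5, 3)
    got <- qt_cluster(d, cutoff = cut, min_size_frac = 0.02)
    want <- qt_oracle(d, cutoff = cut, min_size_frac = 0.02)
    expect_equal(partition_sets(lapply(got$clusters, `[[`, "members")),
                 partition_sets(want$clusters))
    expect_equal(got$rejected, want$rejected)
  }
})

test_that("cluster sets satisfy their partition invariants", {
  set.seed(44)
  pts <- matrix(rnorm(80), 40, 2)
  d <- as.matrix(dist(pts))
  cl <- suppressWarnings(qt_cluster(d, cutoff = 0.8, min_size_frac = 0.05))
  members <- lapply(cl$clusters, `[[`, "members")
  all_frames <- sort(c(unlist(members), cl$rejected))
  expect_equal(all_frames, 1:40)
  expect_equal(anyDuplicated(unlist(members)), 0)
  for (c_i in cl$clusters) {
    expect_gte(length(c_i$members), 0.05 * 40)
    expect_true(all(d[c_i$members, c_i$seed] <= cl$cutoff))
  }
  freqs <- vapply(cl$clusters, `[[`, numeric(1), "frequency")
  expect_equal(sum(freqs) + length(cl$rejected) / 40, 1, tolerance = 1e-12)
})

test_that("QT partitions are stable under frame permutation up to relabeling", {
  set.seed(45)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  pts <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(2 * c(12, 9, 6)[k], sd = 0.4), ncol = 2), 2,
          centers[k, ], "+")))
  d <- as.matrix(dist(pts))
  base <- qt_cluster(d, cutoff = 2)
  perm <- sample(nrow(pts))
  dp <- d[perm, perm]
  per <- qt_cluster(dp, cutoff = 2)
  mapped <- lapply(per$clusters, function(cl) perm[cl$members])
  expect_equal(partition_sets(mapped),
               partition_sets(lapply(base$clusters, `[[`, "members")))
})

test_that("cluster centers are row-sum argmins with deterministic ties", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[2, 3] <- d[3, 2] <- 1; d[1, 3] <- d[3, 1] <- 2
  expect_equal(cluster_center(1:3, d), 2)   # middle of the line
  expect_equal(cluster_center(2, d), 2)     # singleton
  set.seed(46)
  big <- as.matrix(dist(matrix(rnorm(40), 20, 2)))
  members <- sample(20, 12)
  want <- members[which.min(rowSums(big[members, members]))]
  expect_equal(cluster_center(members, big), want)
  expect_error(cluster_center(integer(0), big), "empty")
})

test_that("reference RMSD pairs residues, aligns, and labels nearest states", {
  h <- build_ideal_helix(13)  # 52 atoms; selection of 50 below
  sel <- resolve_selection(h, "resid 1-12 and backbone")  # 48 atoms
  expect_equal(rmsd_to_reference(h, h, selection = sel), 0, tolerance = 1e-9)

  # one atom of 48 displaced by 1 A: compare against the optimization oracle
  moved <- h
  moved$xyz[sel$indices[10], ] <- moved$xyz[sel$indices[10], ] + c(1, 0, 0)
  got <- rmsd_to_reference(moved, h, selection = sel)
  want <- optim_rmsd_oracle(moved$xyz[sel$indices, ], h$xyz[sel$indices, ])
  expect_equal(got, want, tolerance = 1e-3)
  expect_lte(got, 1 / sqrt(48) + 1e-9)
  expect_gt(got, 0.9 / sqrt(48))

  short <- build_ideal_helix(5)
  expect_error(rmsd_to_reference(h, short, selection = sel), "unpairable")

  # nearest-reference labels flip with the planted state of every frame
  st <- build_study_complexes()
  sp <- two_state_spec(st$state_common, st$state_cr, occupancy_B = 0.5,
                       seed = 47)
  tr <- simulate_two_state(sp, 60, jitter = 0.05)
  m <- pairwise_rmsd_matrix(tr, "chain U and backbone")
  cl <- qt_cluster(m, cutoff = 1.75)
  tab <- label_clusters(tr, cl, list(common = st$state_common,
                                     cr = st$state_cr),
                        selection = "chain U and backbone")
  states <- attr(tr, "planted")$states
  for (i in seq_len(nrow(tab))) {
    planted <- c("common", "cr")[states[tab$center[i]]]
    expect_equal(tab$label[i], planted)
  }
})
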
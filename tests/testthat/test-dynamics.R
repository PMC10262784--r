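test_that("kabsch superposition recovers constructed rigid transforms", {
  set.seed(1)
  cloud <- matrix(rnorm(60), 20, 3)
  sp <- kabsch_superpose(cloud, cloud)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_lt(sqrt(sum(sp$translation^2)), 1e-10)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)

  th <- 30 * pi / 180
  R0 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  t0 <- c(1, -2, 3)
  mobile <- apply_rigid(cloud, R0, t0)
  sp <- kabsch_superpose(mobile, cloud)
  expect_lt(max(abs(sp$rotation %*% R0 - diag(3))), 1e-8)
  expect_lt(sp$rmsd, 1e-8)

  expect_error(kabsch_superpose(cloud[1:2, ], cloud[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("kabsch RMSD matches an independent numerical-optimization oracle", {
  base <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2), 4, 3, byrow = TRUE)
  bent <- base
  bent[4, ] <- bent[4, ] + c(1, 0, 0)       # one atom displaced 1 A
  got <- kabsch_superpose(bent, base)$rmsd
  want <- optim_rmsd_oracle(bent, base)
  expect_equal(got, want, tolerance = 1e-3)
  set.seed(5)
  for (i in 1:3) {
    a <- matrix(rnorm(24), 8, 3)
    b <- a + matrix(rnorm(24, 0, 0.3), 8, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, optim_rmsd_oracle(a, b),
                 tolerance = 1e-3)
  }
})

test_that("fitted rotations are always proper-orthonormal", {
  set.seed(11)
  for (i in 1:50) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    R <- kabsch_superpose(a, b, weights = runif(10, 0.1, 2))$rotation
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
})

test_that("alignment removes rigid motion exactly and is idempotent", {
  h <- build_two_chain_complex(8, 6, gap = 4, seed = 6)
  set.seed(2)
  frames <- lapply(1:8, function(i)
    apply_rigid(h$xyz, random_rotation(), rnorm(3, 0, 5)))
  tr <- make_trajectory(h, frames)
  al <- align_trajectory(tr, "chain A and backbone")
  for (f in 1:8)
    expect_lt(sqrt(mean(rowSums((al$frames[, , f] - al$frames[, , 1])^2))),
              1e-6)
  al2 <- align_trajectory(al, "chain A and backbone")
  expect_equal(al2$frames, al$frames, tolerance = 1e-9)
  expect_error(align_trajectory(tr, "backbone", ref_frame = 99),
               "out of range")
})

test_that("the fit transform from one chain moves the other chain rigidly", {
  cx <- build_two_chain_complex(8, 6, gap = 4, seed = 6)
  R0 <- random_rotation(); t0 <- c(3, -1, 2)
  tr <- make_trajectory(cx, list(cx$xyz, apply_rigid(cx$xyz, R0, t0)))
  al <- align_trajectory(tr, "chain A and backbone")
  selA <- resolve_selection(cx, "chain A")
  sp <- kabsch_superpose(tr$frames[selA$indices, , 2], cx$xyz[selA$indices, ],
                         cx$atoms$mass[selA$indices])
  manual <- apply_superposition(sp, tr$frames[, , 2])
  expect_equal(al$frames[, , 2], manual, tolerance = 1e-9)
})

test_that("rmsd series obey the refit geometry identities", {
  h <- build_ideal_helix(6)
  tr <- make_trajectory(h, list(h$xyz, h$xyz, h$xyz))
  expect_equal(rmsd_series(tr, "backbone"), c(0, 0, 0))

  shifted <- sweep(h$xyz, 2, c(3, 4, 0), "+")
  tr2 <- make_trajectory(h, list(h$xyz, shifted))
  expect_equal(rmsd_series(tr2, "backbone", refit = FALSE)[2], 5)
  expect_equal(rmsd_series(tr2, "backbone", refit = TRUE)[2], 0,
               tolerance = 1e-6)
})

test_that("refit RMSD never exceeds the fixed-frame RMSD", {
  h <- build_ideal_helix(8)
  set.seed(3)
  frames <- lapply(1:40, function(i)
    apply_rigid(h$xyz + matrix(rnorm(length(h$xyz), 0, 0.3),
                               ncol = 3), random_rotation(), rnorm(3, 0, 2)))
  tr <- make_trajectory(h, frames)
  fixed <- rmsd_series(tr, "backbone", refit = FALSE)
  refit <- rmsd_series(tr, "backbone", refit = TRUE)
  expect_true(all(refit <= fixed + 1e-9))
})

test_that("rmsf matches closed-form fluctuation cases", {
  h <- build_ideal_helix(4)
  tr <- make_trajectory(h, list(h$xyz, h$xyz, h$xyz))
  expect_true(all(rmsf_profile(tr, "backbone")$rmsf == 0))

  # one atom alternating +/- a along x: rmsf exactly a
  a <- 0.7
  up <- h$xyz; up[1, 1] <- up[1, 1] + a
  dn <- h$xyz; dn[1, 1] <- dn[1, 1] - a
  tr2 <- make_trajectory(h, rep(list(up, dn), 10))
  atom_prof <- rmsf_profile(tr2, "backbone", group_by_residue = FALSE)
  expect_equal(atom_prof$rmsf[1], a, tolerance = 1e-12)
  expect_true(all(atom_prof$rmsf[-1] == 0))
  expect_error(rmsf_profile(make_trajectory(h, list(h$xyz)), "backbone"),
               "2 frames")
})

test_that("covariance hits the perfect-correlation limits and flags zero variance", {
  base <- make_structure(cbind(c(0, 10, 20, 30), 0, 0),
                         residue_index = 1:4)
  set.seed(8)
  z <- rnorm(30)
  frames <- lapply(seq_len(30), function(f) {
    x <- base$xyz
    x[1, 1] <- x[1, 1] + z[f]          # residues 1 and 2 move identically
    x[2, 1] <- x[2, 1] + z[f]
    x[3, 1] <- x[3, 1] - z[f]          # residue 3 moves oppositely
    x                                   # residue 4 static
  })
  tr <- make_trajectory(base, frames)
  expect_warning(cv <- covariance_matrix(tr, "name CA"), "zero variance")
  expect_equal(cv$values[1, 2], 1, tolerance = 1e-6)
  expect_equal(cv$values[1, 3], -1, tolerance = 1e-6)
  expect_equal(cv$values[1, 4], 0)
  expect_equal(diag(cv$values), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(cv$values) <= 1 + 1e-10))
  expect_equal(cv$values, t(cv$values))
})

test_that("covariance is invariant to global rigid motion removed by alignment", {
  base <- build_ideal_helix(6)
  spec <- fluctuation_spec(0.3, seed = 14)
  tr <- simulate_trajectory(base, spec, 300)
  cv_plain <- covariance_matrix(align_trajectory(tr, "backbone"), "name CA")
  set.seed(15)
  moved <- lapply(seq_len(n_frames(tr)), function(f)
    apply_rigid(tr$frames[, , f], random_rotation(), rnorm(3, 0, 4)))
  al <- align_trajectory(make_trajectory(base, moved), "backbone")
  cv_moved <- covariance_matrix(al, "name CA")
  expect_equal(cv_moved$values, cv_plain$values, tolerance = 1e-6)
})

test_that("correlated partners are thresholded and signed", {
  base <- make_structure(cbind(c(0, 10, 20), 0, 0), residue_index = 1:3)
  cv <- structure(list(
    values = matrix(c(1, 0.8, -0.76, 0.8, 1, 0.1, -0.76, 0.1, 1), 3, 3),
    residues = data.frame(chain_id = "A", residue_index = 1:3,
                          residue_name = "ALA")), class = "covariance_matrix")
  out <- correlated_partners(cv, 1)
  expect_equal(out$residue_index, c(2, 3))
  expect_equal(out$sign, c("positive", "negative"))
  cv$values[1, 2:3] <- cv$values[2:3, 1] <- 0
  expect_equal(nrow(correlated_partners(cv, 1)), 0)
  expect_error(correlated_partners(cv, 99), "not in covariance")
})
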
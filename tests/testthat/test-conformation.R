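test_that("backbone dihedrals follow the IUPAC convention and flag terminals", {
  h <- build_ideal_helix(8)
  d <- backbone_dihedrals(h, "A", 4)
  expect_equal(d$phi, -57, tolerance = 1 / 57)
  expect_equal(d$psi, -47, tolerance = 1 / 47)
  expect_true(all(d$defined))

  first <- backbone_dihedrals(h, "A", 1)
  expect_true(is.na(first$phi) && !first$defined["phi"])
  expect_false(is.na(first$psi))
  last <- backbone_dihedrals(h, "A", 8)
  expect_true(is.na(last$psi) && !last$defined["psi"])
  expect_error(backbone_dihedrals(h, "A", 99), "lacks backbone")

  # collinear degenerate geometry is an explicit error
  line <- make_structure(cbind(c(0:3) * 1.4, 0, 0),
                         atom_name = c("C", "N", "CA", "C"),
                         element = c("C", "N", "C", "C"),
                         residue_index = c(1, 2, 2, 2))
  line2 <- md_structure(rbind(line$atoms,
                              within(line$atoms[4, ], {
                                atom_name <- "N"; element <- "N"
                                residue_index <- 3; serial <- 5
                              })),
                        rbind(line$xyz, c(5.6, 0, 0)))
  expect_error(backbone_dihedrals(line2, "A", 2), "collinear")
})

test_that("dihedrals are internal coordinates, invariant to rigid motion", {
  h <- build_ideal_helix(8)
  set.seed(25)
  hm <- h
  hm$xyz <- apply_rigid(h$xyz, random_rotation(), c(7, 1, -4))
  d0 <- backbone_dihedrals(h, "A", 5)
  d1 <- backbone_dihedrals(hm, "A", 5)
  expect_equal(d1$phi, d0$phi, tolerance = 1e-9)
  expect_equal(d1$psi, d0$psi, tolerance = 1e-9)
})

test_that("rama distributions locate frames near references with a circular metric", {
  h <- build_ideal_helix(8)
  tr <- make_trajectory(h, list(h$xyz, h$xyz))
  rd <- rama_distribution(tr, "A", 4, references = list(self = h))
  expect_equal(unname(rd$near_fractions["self"]), 1)

  # wrap-around: phi 179 vs -179 differs by 2 degrees, not 358
  a <- build_peptide_chain(5, phi = 179, psi = 60)
  b <- build_peptide_chain(5, phi = -179, psi = 60)
  tra <- make_trajectory(a, list(a$xyz, a$xyz))
  rd2 <- rama_distribution(tra, "A", 3, references = list(wrap = b),
                           radius = 10)
  expect_equal(unname(rd2$near_fractions["wrap"]), 1)

  # a reference lacking the residue is skipped with a warning
  short <- build_ideal_helix(4)
  expect_warning(
    rama_distribution(tr, "A", 6, references = list(short = short)),
    "skipped")
})

test_that("two-state mixtures recover their occupancy from near-reference fractions", {
  st <- build_study_complexes()
  sp <- two_state_spec(st$state_common, st$state_cr, occupancy_B = 0.3,
                       seed = 33)
  tr <- simulate_two_state(sp, 800, jitter = 0.05)
  # residue 61 sits in the hinge whose dihedrals differ between states
  rd <- rama_distribution(tr, "U", 61,
                          references = list(common = st$state_common,
                                            cr = st$state_cr))
  occ <- attr(tr, "planted")$realized_occupancy_B
  expect_equal(unname(rd$near_fractions["cr"]), occ, tolerance = 0.05)
  expect_equal(unname(rd$near_fractions["common"]), 1 - occ,
               tolerance = 0.05)
})

test_that("distance series are exact Euclidean measurements", {
  s <- make_structure(rbind(c(0, 0, 0), c(3, 4, 0)), atom_name = "CA",
                      residue_index = 1:2)
  tr <- make_trajectory(s, list(s$xyz, s$xyz))
  d <- distance_series(tr, list(chain = "A", residue = 1),
                       list(chain = "A", residue = 2))
  expect_equal(as.numeric(d), c(5, 5))
  expect_error(distance_series(tr, list(chain = "A", residue = 1),
                               list(chain = "A", residue = 9)), "not in")

  st <- build_study_complexes()
  sp <- two_state_spec(st$state_common, st$state_cr, occupancy_B = 0.5,
                       seed = 35)
  trm <- simulate_two_state(sp, 40, jitter = 0)
  dm <- distance_series(trm, list(chain = "U", residue = 46, name = "CA"),
                        list(chain = "U", residue = 76, name = "CA"))
  planted <- vapply(list(st$state_common, st$state_cr), function(s) {
    ca <- function(r) s$xyz[s$atoms$residue_index == r &
                              s$atoms$atom_name == "CA" &
                              s$atoms$chain_id == "U", ]
    sqrt(sum((ca(46) - ca(76))^2))
  }, numeric(1))
  states <- attr(trm, "planted")$states
  expect_equal(as.numeric(dm), planted[states], tolerance = 1e-9)
})

test_that("the moving average follows the truncated centered-window rule", {
  expect_equal(moving_average(c(4, 4, 4), 750, 250), c(4, 4, 4))
  got <- moving_average(c(0, 10, 0, 10, 0), 3 * 250, 250)
  expect_equal(got, c(5, 10 / 3, 20 / 3, 10 / 3, 5), tolerance = 1e-12)
  x <- rnorm(20)
  expect_equal(moving_average(x, 250, 250), x)
  sm <- moving_average(x, 5000, 250)
  expect_true(all(sm >= min(x) - 1e-12 & sm <= max(x) + 1e-12))
  expect_length(sm, 20)
  expect_error(moving_average(x, 100, 250), "window")
})
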
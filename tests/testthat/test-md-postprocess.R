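test_that("charge_density integrates to the selection charge", {
  pos <- matrix(c(10, 10, 5), ncol = 3, byrow = TRUE)
  tr <- make_frame_traj(pos, role = "cation", charge = 1)
  prof <- charge_density(tr, "cation", bin_width = 0.5)
  expect_equal(profile_total_charge(prof), 1, tolerance = 1e-9)
  expect_equal(sum(prof$charge_density != 0), 1)  # one occupied bin
  hot <- prof[prof$charge_density != 0, ]
  expect_true(hot$z_lo <= 5 && 5 < hot$z_hi)

  tr2 <- make_frame_traj(pos, role = "cation", charge = 2)
  expect_equal(profile_total_charge(charge_density(tr2, "cation")), 2,
               tolerance = 1e-9)
  expect_error(charge_density(tr, "phosphate_O"), "no atoms")
})

test_that("a uniform species gives a flat profile within Poisson noise", {
  set.seed(14)
  n <- 2000
  pos <- cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, 0, 50))
  tr <- make_frame_traj(pos, role = rep("cation", n), charge = rep(1, n))
  prof <- charge_density(tr, "cation", bin_width = 5)
  expected <- n / nrow(prof)  # counts per bin
  counts <- prof$charge_density * 5
  expect_true(all(abs(counts - expected) < 3 * sqrt(expected)))
})

test_that("com_separation measures perpendicular distance in nm", {
  pos <- rbind(c(0, 0, 0), c(10, 10, 0), c(5, 5, 36), c(15, 15, 36))
  tr <- make_frame_traj(pos, role = c("other", "other", "phosphate_O",
                                      "phosphate_O"),
                        box = c(50, 50, 100))
  expect_equal(com_separation(tr, c(1, 2), "phosphate_O"), 3.6)
  expect_equal(com_separation(tr, c(1, 2), c(1, 2)), 0)
  # minimum image along z
  pos2 <- rbind(c(0, 0, 1), c(0, 0, 99))
  tr2 <- make_frame_traj(pos2, role = c("other", "cation"),
                         box = c(50, 50, 100))
  expect_equal(com_separation(tr2, 1, 2), 0.2)
})

test_that("classify_shell honours closed boundaries", {
  spec <- shell_spec(r1 = 3, r2 = 5)
  at <- function(d) c(0, 0, d)
  expect_equal(classify_shell(c(0, 0, 0), at(3), spec), "1st")
  expect_equal(classify_shell(c(0, 0, 0), at(4), spec), "2nd")
  expect_equal(classify_shell(c(0, 0, 0), at(10), spec), "none")
  # periodic wrap: 48 apart in a 50 box is a 2 A separation
  expect_equal(classify_shell(c(0, 0, 1), at(49), spec,
                              box = c(50, 50, 50)), "1st")
  expect_error(shell_spec(r1 = 5, r2 = 3), "r1 < r2")
})

test_that("find_bridges enumerates simultaneous complexation", {
  spec <- shell_spec(r1 = 3, r2 = 5)
  # cation at origin-ish, phosphate O 2 A above, silica O 2 A below: 1st-1st
  pos <- rbind(c(25, 25, 10), c(25, 25, 12), c(25, 25, 8))
  tr <- make_frame_traj(pos, role = c("cation", "phosphate_O", "silica_O"))
  br <- find_bridges(tr, 1, spec)
  expect_equal(nrow(br), 1)
  expect_equal(br$shell_pair, "1st-1st")

  # cation near the phosphate O only: no bridge
  pos2 <- rbind(c(25, 25, 10), c(25, 25, 12), c(25, 25, 40))
  expect_equal(nrow(find_bridges(make_frame_traj(
    pos2, role = c("cation", "phosphate_O", "silica_O")), 1, spec)), 0)

  # two cations sharing one silica O: two distinct triplets
  pos3 <- rbind(c(25, 25, 10), c(25, 28, 10), c(25, 26.5, 12),
                c(25, 26.5, 8))
  tr3 <- make_frame_traj(pos3, role = c("cation", "cation", "phosphate_O",
                                        "silica_O"))
  br3 <- find_bridges(tr3, 1, spec)
  expect_equal(nrow(br3), 2)
  expect_equal(length(unique(br3$cation)), 2)
})

test_that("bridge_census lifetimes follow scripted truth", {
  sb <- data.frame(start_ps = c(0, 1000), duration_ps = c(600, 100),
                   shell_pair = c("1st-1st", "2nd-2nd"))
  g <- gen_toy_trajectory(trajectory_recipe(scripted_bridges = sb,
                                            n_frames = 40,
                                            frame_interval = 50), seed = 3)
  cen <- bridge_census(g$traj, shell_spec("Ca"))
  expect_equal(unclass(cen)[, ], unclass(g$truth$census)[, ])
  # 600 ps bridge survives all thresholds; 100 ps only the shortest
  expect_equal(unname(cen["1st-1st", ]), c(1L, 1L, 1L))
  expect_equal(unname(cen["2nd-2nd", ]), c(1L, 0L, 0L))
  # monotone non-increasing across thresholds
  expect_true(all(apply(unclass(cen), 1, function(r) all(diff(r) <= 0))))

  # no scripted bridges: all zeros
  g0 <- gen_toy_trajectory(trajectory_recipe(n_frames = 10,
                                             frame_interval = 50), seed = 4)
  expect_true(all(bridge_census(g0$traj, shell_spec("Ca")) == 0))

  expect_error(bridge_census(g0$traj, shell_spec("Ca"), thresholds = c(10)),
               "too coarse")
})

test_that("gap tolerance merges interrupted runs", {
  spec <- shell_spec(r1 = 3, r2 = 5)
  near <- rbind(c(25, 25, 10), c(25, 25, 12), c(25, 25, 8))
  far <- rbind(c(25, 25, 30), c(25, 25, 12), c(25, 25, 8))
  roles <- c("cation", "phosphate_O", "silica_O")
  frames <- list(near, near, far, near, near)
  tr <- md_trajectory(frames, c("Ca", "OP", "OS"), c(2, -1, -1), roles,
                      box = c(50, 50, 50), frame_interval = 50,
                      surface_ref_z = 0)
  strict <- bridge_census(tr, spec, thresholds = c(50, 100, 150))
  expect_equal(unname(strict["1st-1st", ]), c(1L, 1L, 0L))  # longest run 2
  lenient <- bridge_census(tr, spec, thresholds = c(50, 100, 150), gap = 1L)
  expect_equal(unname(lenient["1st-1st", ]), c(1L, 1L, 1L))
})

test_that("energy_barrier is the peak above the far field", {
  prof <- energy_profile(c(3.6, 5, 8), c(0, 1700, 800))
  bar <- energy_barrier(prof, far_field_window = 0.5)
  expect_equal(bar$barrier, 900)
  expect_equal(bar$far_field, 800)
  # offset invariance
  prof2 <- energy_profile(c(3.6, 5, 8), c(0, 1700, 800) + 12345)
  expect_equal(energy_barrier(prof2, 0.5)$barrier, 900)
  # monotone decreasing toward contact: no interior barrier
  expect_equal(energy_barrier(energy_profile(1:5, c(0, 10, 20, 30, 40)),
                              0.5)$barrier, 0)
  expect_equal(energy_barrier(energy_profile(1:5, rep(7, 5)), 1)$barrier, 0)
})

test_that("energy density and setup arithmetic", {
  expect_equal(adhesion_energy_density(0, 100), 0)
  expect_equal(adhesion_energy_density(100, 100),
               100e3 / 6.02214076e23 / 1e-18 * 1e3)
  expect_equal(adhesion_energy_density(200, 100),
               2 * adhesion_energy_density(100, 100))
  expect_equal(adhesion_energy_density(100, 200),
               adhesion_energy_density(100, 100) / 2)

  expect_equal(deprotonation_count(0, 49, 39.5), 0)
  expect_equal(deprotonation_count(1.0, 100, 10), 10)

  expect_equal(neutralizing_cations(-38, 1), 38)
  expect_equal(neutralizing_cations(-38, 2), 19)
  expect_equal(neutralizing_cations(0, 1), 0)
  expect_error(neutralizing_cations(-37, 2), "not divisible")
})

test_that("pair_rdf peaks at a constructed shell distance", {
  # 40 neighbours on a sphere of radius 3 around one centre
  set.seed(21)
  n <- 40
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 3
  pos <- rbind(c(25, 25, 25), sweep(u, 2, c(25, 25, 25), "+"))
  tr <- make_frame_traj(pos, role = c("cation", rep("silica_O", n)))
  rdf <- pair_rdf(tr, "cation", "silica_O", r_max = 6, dr = 0.2)
  expect_equal(rdf$r[which.max(rdf$g)], 2.9, tolerance = 0.11)
})
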
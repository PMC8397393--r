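test_that("generators are pure functions of (recipe, seed)", {
  r <- curve_recipe_preset("na_2mM")
  a <- gen_force_curves(r, 3, seed = 42)
  b <- gen_force_curves(r, 3, seed = 42)
  expect_identical(a$truth, b$truth)
  expect_identical(a$curves[[2]]$force, b$curves[[2]]$force)
  expect_false(identical(a$curves[[2]]$force,
                         gen_force_curves(r, 3, seed = 43)$curves[[2]]$force))

  g1 <- gen_binding_data(binding_recipe(), seed = 5)
  g2 <- gen_binding_data(binding_recipe(), seed = 5)
  expect_identical(g1$data, g2$data)

  t1 <- gen_toy_trajectory(trajectory_recipe(n_frames = 5), seed = 9)
  t2 <- gen_toy_trajectory(trajectory_recipe(n_frames = 5), seed = 9)
  expect_identical(t1$traj$frames, t2$traj$frames)
})

test_that("curve ground truth is analytic", {
  # zero ruptures, zero noise: flat trace, zero work
  flat <- curve_recipe(baseline_sd = 0, ruptures = list())
  g <- gen_force_curves(flat, 1)
  expect_equal(g$truth$work_aJ, 0)
  expect_equal(g$truth$n_events, 0L)
  ret <- g$curves[[2]]
  expect_true(all(ret$force[ret$z > 0] == 0))

  # rectangular rupture 100 pN x 10 nm: exactly 1 aJ by unit definition
  rect <- curve_recipe(baseline_sd = 0, ruptures = list(
    list(position = 20, force = 100, model = "rect", width = 10)))
  expect_equal(gen_force_curves(rect, 1)$truth$work_aJ, 1)

  # triangular ramp: half base times height
  tri <- curve_recipe(baseline_sd = 0, ruptures = list(
    list(position = 10, force = 200, model = "linear_ramp")))
  expect_equal(gen_force_curves(tri, 1)$truth$work_aJ, 1)

  # wlc rupture: truth equals numeric quadrature of the generated trace
  wlc <- curve_recipe(baseline_sd = 0, n_points = 8192L, ruptures = list(
    list(position = 50, force = 150, model = "wlc", persistence = 50)))
  gw <- gen_force_curves(wlc, 1)
  expect_equal(work_of_adhesion(gw$curves[[2]]), gw$truth$work_aJ,
               tolerance = 5e-3)  # quadrature error at the rupture cusp

  # single deep pull-off vs multiple small ruptures by construction
  expect_equal(gen_force_curves(curve_recipe_preset("ca_1mM"),
                                1)$truth$n_events, 1L)
  expect_equal(gen_force_curves(curve_recipe_preset("na_2mM",
                                                    no_binding_fraction = 0),
                                1)$truth$n_events, 3L)
})

test_that("curve recipe validation rejects impossible ruptures", {
  expect_error(curve_recipe(ruptures = list(
    list(position = 600, force = 100))), "outside")
  expect_error(curve_recipe(ruptures = list(
    list(position = 10, force = 1e6))), "force range")
  expect_error(curve_recipe(ruptures = list(
    list(position = 10, force = 50, model = "wlc"))), "persistence")
  expect_error(curve_recipe(ruptures = list(
    list(position = 20, force = 50), list(position = 10, force = 50))),
    "increasing")
})

test_that("binding generator lies on the isotherm when noise-free", {
  r <- binding_recipe(noise_cv = 0)
  g <- gen_binding_data(r)
  expect_equal(g$data$bound_nM,
               r$Bmax * g$data$free_nM / (r$Kd + g$data$free_nM))
  # half-saturation identity at F = Kd
  r2 <- binding_recipe(noise_cv = 0, replicates = 1L,
                       free_ng_ml = molar_to_mass(1.3, 688))
  expect_equal(gen_binding_data(r2)$data$bound_nM, 1.9 / 2)
})

test_that("toy trajectory respects its stated geometry", {
  g <- gen_toy_trajectory(trajectory_recipe(n_frames = 20), seed = 2)
  tr <- g$traj
  # all positions inside the box
  for (fr in tr$frames) {
    expect_true(all(fr >= 0 & fr <= rep(tr$box, each = nrow(fr))))
  }
  # surface reference is the Si plane
  expect_equal(tr$surface_ref_z, 4)
  # scripted bound-state separation between slab and polymer strand
  expect_equal(mean(com_separation(tr, "Si", "phosphate_O")), 3.6,
               tolerance = 1e-6)
  # gaussian layer: histogram peak bin contains the scripted centre
  prof <- charge_density(tr, "cation", bin_width = 0.25)
  pk <- prof[which.max(prof$charge_density), ]
  expect_true(pk$z_lo <= g$truth$layer_center &&
                g$truth$layer_center < pk$z_hi)

  # diffuse (uniform) layer stays within its range
  gu <- gen_toy_trajectory(trajectory_recipe(
    cation = list(element = "Na", valence = 1),
    layer = list(model = "uniform", range = c(1, 3.5)),
    n_cations = 38L, n_frames = 10), seed = 6)
  zc <- unlist(lapply(gu$traj$frames,
                      function(fr) fr[gu$traj$role == "cation", 3]))
  expect_true(all(zc - 4 >= 1 & zc - 4 <= 3.5))
})

test_that("scripted bridge windows are validated", {
  expect_error(trajectory_recipe(scripted_bridges = data.frame(
    start_ps = 0, duration_ps = 1e6, shell_pair = "1st-1st")),
    "within the simulated time")
  expect_error(trajectory_recipe(scripted_bridges = data.frame(
    start_ps = c(0, 100), duration_ps = c(300, 100),
    shell_pair = "1st-1st", triplet = 1L)),
    "overlapping")
  expect_error(trajectory_recipe(scripted_bridges = data.frame(
    start_ps = 0, duration_ps = 100, shell_pair = "inner-outer")),
    "shell_pair")
})
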
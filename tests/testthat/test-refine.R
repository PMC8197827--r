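test_that("restraint_energy is harmonic in the displacement", {
  toy <- make_toy_complex(seed = 3, receptor_len = 8, peptide_len = 3)
  spec <- calpha_restraints(toy, k_restr = 1000)
  xyz <- model_coords(toy)
  expect_equal(restraint_energy(xyz, spec), 0)
  # one restrained atom displaced by 0.1 nm at k = 1000 kJ/(mol nm^2) -> 5 kJ/mol
  i <- spec$restrained_idx[1]
  xyz1 <- xyz
  xyz1[i, 1] <- xyz1[i, 1] + 1.0
  expect_equal(restraint_energy(xyz1, spec), 5)
  # doubling the displacement quadruples the energy
  xyz2 <- xyz
  xyz2[i, 1] <- xyz2[i, 1] + 2.0
  expect_equal(restraint_energy(xyz2, spec), 4 * restraint_energy(xyz1, spec))
})

test_that("minimizer leaves a Lennard-Jones pair at its minimum untouched", {
  m <- two_atom_model(2^(1 / 6) * 3, name = "CB")
  p <- uniform_params(2, epsilon = 1)
  cfg <- refine_config(minimize_steps = 500)
  res <- minimize_complex(m, p, cfg, fixed_idx = integer(0))
  expect_lt(max(abs(model_coords(res$model) - model_coords(m))), 1e-6)
})

test_that("minimizer drives a stretched LJ pair to the 2^(1/6) sigma minimum", {
  m <- two_atom_model(1.5 * 3, name = "CB")
  p <- uniform_params(2, epsilon = 1)
  res <- minimize_complex(m, p, refine_config(minimize_steps = 2000),
    fixed_idx = integer(0))
  r_final <- sqrt(sum((model_coords(res$model)[1, ] - model_coords(res$model)[2, ])^2))
  expect_equal(r_final, 2^(1 / 6) * 3, tolerance = 1e-3)
  expect_true(all(diff(res$trace) <= 0))
})

test_that("minimizer keeps C-alphas bit-identical and never raises the energy", {
  toy <- make_toy_complex(seed = 5)
  p <- assign_parameters(toy)
  res <- minimize_complex(toy, p, refine_config(minimize_steps = 300))
  expect_true(all(diff(res$trace) <= 0))
  ca <- which(toy$atoms$is_calpha)
  expect_identical(model_coords(res$model)[ca, ], model_coords(toy)[ca, ])
  # and the non-CA atoms actually moved
  expect_gt(max(abs(model_coords(res$model) - model_coords(toy))), 1e-3)
})

test_that("zero-temperature sampling from a stationary point is a fixed point", {
  m <- two_atom_model(2^(1 / 6) * 3, name = "CB")
  p <- uniform_params(2, epsilon = 1)
  spec <- list(
    restrained_idx = integer(0), target_coords = matrix(0, 0, 3),
    k_restr = 0, k_internal = 0
  )
  cfg <- refine_config(sample_steps = 500, frame_interval = 100,
    temperature = 0, seed = 1)
  traj <- sample_restrained(m, p, spec, cfg, warn_unminimized = FALSE)
  last <- traj$frames[[length(traj$frames)]]
  expect_lt(max(abs(last - model_coords(m))), 1e-6)
})

test_that("restrained sampling reproduces the harmonic positional variance", {
  m <- two_atom_model(50) # two far-apart, non-interacting restrained atoms
  p <- uniform_params(2, epsilon = 0)
  spec <- calpha_restraints(m, k_restr = 1000) # 10 kJ/(mol A^2)
  cfg <- refine_config(
    sample_steps = 1.5e6, frame_interval = 50, dt = 2,
    temperature = 300, friction = 2, seed = 7
  )
  traj <- sample_restrained(m, p, spec, cfg, warn_unminimized = FALSE)
  xs <- t(vapply(traj$frames, function(f) f[1, ], numeric(3)))
  v <- mean(apply(xs, 2, var))
  expect_equal(v, 0.00831446 * 300 / 10, tolerance = 0.1)
})

test_that("sampling is bitwise reproducible for a fixed seed", {
  toy0 <- make_toy_complex(seed = 6, receptor_len = 10, peptide_len = 3)
  p <- assign_parameters(toy0)
  toy <- minimize_complex(toy0, p, refine_config(minimize_steps = 200))$model
  cfg <- refine_config(sample_steps = 400, frame_interval = 100, seed = 123)
  t1 <- sample_restrained(toy, p, cfg = cfg, warn_unminimized = FALSE)
  t2 <- sample_restrained(toy, p, cfg = cfg, warn_unminimized = FALSE)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$potential, t2$potential)
  t3 <- sample_restrained(toy, p,
    cfg = refine_config(sample_steps = 400, frame_interval = 100, seed = 124),
    warn_unminimized = FALSE
  )
  expect_false(identical(t1$frames, t3$frames))
})

test_that("C-alpha restraints contain the backbone during sampling", {
  toy <- make_toy_complex(seed = 7)
  p <- assign_parameters(toy)
  cfg <- refine_config(seed = 7)
  mn <- minimize_complex(toy, p, cfg)
  traj <- sample_restrained(mn$model, p, cfg = cfg, warn_unminimized = FALSE)
  ca <- which(toy$atoms$is_calpha)
  tgt <- model_coords(mn$model)[ca, ]
  rms_per_frame <- vapply(traj$frames, function(f) {
    sqrt(mean(rowSums((f[ca, ] - tgt)^2)))
  }, numeric(1))
  expect_lt(max(rms_per_frame), 1.5)
})

test_that("an oversized time step is detected as unstable integration", {
  toy <- make_toy_complex(seed = 8, receptor_len = 10, peptide_len = 3)
  p <- assign_parameters(toy)
  cfg <- refine_config(sample_steps = 2000, frame_interval = 500, dt = 150,
    seed = 1)
  expect_error(
    sample_restrained(toy, p, cfg = cfg, warn_unminimized = FALSE),
    "unstable integration"
  )
})
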
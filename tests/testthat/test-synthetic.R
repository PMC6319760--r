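test_that("structure and ensemble generation are deterministic in the seed", {
  spec <- toy_system_spec(n_residues = 20, n_replicas = 2, n_frames = 8,
                          seed = 4, unstable_residues = 7L)
  s1 <- make_toy_structure(spec)
  s2 <- make_toy_structure(spec)
  expect_identical(structure_xyz(s1), structure_xyz(s2))
  expect_identical(s1$residues$residue_name, s2$residues$residue_name)
  e1 <- simulate_ensemble(s1, spec)
  e2 <- simulate_ensemble(s1, spec)
  expect_identical(e1$replicas[[2]]$coords, e2$replicas[[2]]$coords)
  # a different trajectory seed changes trajectories, not the structure
  spec_b <- toy_system_spec(n_residues = 20, n_replicas = 2, n_frames = 8,
                            seed = 4, traj_seed = 99L,
                            unstable_residues = 7L)
  expect_identical(structure_xyz(make_toy_structure(spec_b)),
                   structure_xyz(s1))
  e3 <- simulate_ensemble(s1, spec_b)
  expect_false(identical(e1$replicas[[1]]$coords, e3$replicas[[1]]$coords))
})

test_that("the default 60-residue fold exercises the exclusion rule", {
  spec <- toy_system_spec(seed = 1)
  s <- make_toy_structure(spec)
  nc <- build_native_contacts(s)
  counts <- nc$per_residue$n_contacts
  # a clear majority of residues are reliably contact-rich
  expect_gt(mean(counts >= 30), 0.8)
  # ... while some residue near a chain terminus falls below 30
  terminal_zone <- c(0:4, (spec$n_residues - 5):(spec$n_residues - 1))
  expect_true(any(excluded_residues(nc) %in% terminal_zone))
  # no steric clash
  expect_gte(min(dist(structure_xyz(s))), 1.0)
})

test_that("a zero profile reproduces the native structure exactly", {
  spec <- toy_system_spec(n_residues = 15, n_replicas = 2, n_frames = 5,
                          seed = 6, base_noise = 0)
  s <- make_toy_structure(spec)
  ens <- simulate_ensemble(s, spec)
  nc <- build_native_contacts(s)
  for (r in 1:2) {
    for (f in 1:5) {
      expect_identical(ens$replicas[[r]]$coords[, , f], structure_xyz(s))
    }
  }
  ser <- q_series(ens, nc)
  expect_true(all(ser$q > 0.99))
  rms <- backbone_rmsd_series(ens, s)
  expect_true(all(rms$rmsd_nm < 1e-12))
})

test_that("rigid-body drift is invisible after superposition", {
  spec <- toy_system_spec(n_residues = 15, n_replicas = 1, n_frames = 6,
                          seed = 8, base_noise = 0, rigid_body = TRUE)
  s <- make_toy_structure(spec)
  ens <- simulate_ensemble(s, spec)
  last <- ens$replicas[[1]]$coords[, , 6]
  raw_disp <- sqrt(mean(rowSums((last - structure_xyz(s))^2)))
  expect_gt(raw_disp, 1)    # the molecule really moved
  rms <- backbone_rmsd_series(ens, s)
  expect_true(all(rms$rmsd_nm < 1e-9))
  # and Q is built from internal distances, so it stays native
  nc <- build_native_contacts(s)
  expect_true(all(q_series(ens, nc)$q > 0.99))
})

test_that("designed displacement drives the residue's final-window Q down", {
  spec <- toy_system_spec(n_residues = 30, n_replicas = 4, n_frames = 30,
                          seed = 10, unstable_residues = 14L,
                          amplitude = 20, onset = 0.5)
  s <- make_toy_structure(spec)
  nc <- build_native_contacts(s)
  ens <- simulate_ensemble(s, spec)
  resq <- per_residue_q_series(ens, nc)
  wm <- final_window_means(resq, residue_index, replica_id)
  target <- wm[wm$residue_index == 14L, ]
  expect_true(all(target$mean_q < 0.6))
  # monotone response: a larger amplitude never raises the residue's Q
  spec_big <- toy_system_spec(n_residues = 30, n_replicas = 4,
                              n_frames = 30, seed = 10,
                              unstable_residues = 14L, amplitude = 40,
                              onset = 0.5)
  resq_big <- per_residue_q_series(simulate_ensemble(s, spec_big), nc)
  wm_big <- final_window_means(resq_big, residue_index, replica_id)
  expect_lte(mean(wm_big$mean_q[wm_big$residue_index == 14L]),
             mean(target$mean_q) + 1e-6)
})

test_that("onset controls when a residue starts losing contacts", {
  spec <- toy_system_spec(n_residues = 20, n_replicas = 1, n_frames = 40,
                          seed = 12, unstable_residues = 9L,
                          amplitude = 25, onset = 0.5, base_noise = 0)
  s <- make_toy_structure(spec)
  nc <- build_native_contacts(s)
  ens <- simulate_ensemble(s, spec)
  ser <- per_residue_q_series(ens, nc, residues = 9L)
  # before onset: native; after: decaying
  pre <- ser$q[ser$frame <= 19]
  expect_true(all(pre > 0.99))
  expect_lt(ser$q[40], 0.1)
  expect_true(ser$q[30] <= ser$q[25] + 1e-9)
})

test_that("benchmark suites encode a strictly decreasing instability", {
  suite <- make_benchmark_suite(n_systems = 5, seed = 3,
                                n_frames = 10, n_replicas = 2)
  expect_equal(nrow(suite), 5)
  expect_true(all(diff(suite$pseudo_tm) > 0))
  expect_true(all(diff(suite$n_unstable) < 0))
  expect_equal(purrr::map_int(suite$spec,
                              ~length(.x$unstable_residues)),
               suite$n_unstable)
  # distinct pseudo-Tm values
  expect_equal(anyDuplicated(suite$pseudo_tm), 0L)
  # default 7-system suite spans the realistic Tm range
  s7 <- make_benchmark_suite(seed = 1)
  expect_equal(nrow(s7), 7)
  expect_equal(range(s7$pseudo_tm), c(46.75, 85))
})
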
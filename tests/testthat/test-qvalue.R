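test_that("a single contact at lambda*r0 sits exactly at the midpoint", {
  # native distance 3.0; place the frame atom at lambda * r0
  s <- manual_structure(rbind(c(0, 0, 0), c(3, 0, 0)), c(0L, 8L))
  nc <- build_native_contacts(s)
  expect_equal(nrow(nc$pairs), 1)
  par <- q_parameters()
  frame <- rbind(c(0, 0, 0), c(par$lam * 3, 0, 0))
  expect_identical(soft_q(frame, nc, par), 0.5)
})

test_that("the native single-contact value matches the closed form", {
  # one contact with r0 = 4.4, beta = 5, lam = 1.8, evaluated at the native
  # frame: Q = 1 / (1 + exp(5 * (4.4 - 1.8 * 4.4))) = 1 / (1 + exp(-17.6))
  s <- manual_structure(rbind(c(0, 0, 0), c(4.4, 0, 0)), c(0L, 8L))
  nc <- build_native_contacts(s)
  expect_equal(soft_q(structure_xyz(s), nc), 1 / (1 + exp(-17.6)),
               tolerance = 1e-15)
})

test_that("fully separated frames give Q ~ 0 without numeric error", {
  s <- manual_structure(rbind(c(0, 0, 0), c(4.0, 0, 0)), c(0L, 8L))
  nc <- build_native_contacts(s)
  frame <- rbind(c(0, 0, 0), c(1e3, 0, 0))
  q <- soft_q(frame, nc)
  expect_true(is.finite(q))
  expect_lt(q, 1e-12)
})

test_that("soft_q matches the naive per-pair loop on random frames", {
  set.seed(21)
  s <- random_toy_structure(n_atoms = 40)
  nc <- build_native_contacts(s, cutoff = 8)  # wider cutoff for many pairs
  for (k in 1:10) {
    frame <- structure_xyz(s) + matrix(rnorm(40 * 3, sd = 2), ncol = 3)
    expect_equal(soft_q(frame, nc), bf_soft_q(frame, nc$pairs),
                 tolerance = 1e-12)
  }
})

test_that("uniform expansion strictly lowers Q", {
  s <- make_toy_structure(toy_system_spec(n_residues = 15, seed = 2))
  nc <- build_native_contacts(s)
  x <- structure_xyz(s)
  ctr <- colMeans(x)
  q0 <- soft_q(x, nc)
  q_prev <- q0
  for (f in c(1.2, 1.5, 2)) {
    xf <- sweep(sweep(x, 2, ctr) * f, 2, ctr, "+")
    qf <- soft_q(xf, nc)
    expect_lt(qf, q_prev)
    q_prev <- qf
  }
  expect_gt(q0, 0.99)   # native frame is essentially fully folded
})

test_that("q_series is deterministic, ordered, and equals per-frame soft_q", {
  s <- make_toy_structure(toy_system_spec(n_residues = 15, seed = 6))
  nc <- build_native_contacts(s)
  set.seed(3)
  frames <- lapply(1:5, function(i) {
    structure_xyz(s) + matrix(rnorm(nrow(s$atoms) * 3, sd = 0.5), ncol = 3)
  })
  ens <- frames_ensemble(frames)
  ser <- q_series(ens, nc)
  expect_equal(nrow(ser), 5)
  expect_equal(ser$frame, 1:5)
  expect_true(all(ser$q > 0 & ser$q < 1))
  for (i in 1:5) {
    expect_equal(ser$q[i], soft_q(frames[[i]], nc), tolerance = 1e-14)
  }
  expect_identical(ser, q_series(ens, nc))
  # a trajectory of native frames is constant and ~ Q(native)
  nat <- q_series(frames_ensemble(rep(list(structure_xyz(s)), 3)), nc)
  expect_true(all(abs(nat$q - nat$q[1]) < 1e-15))
  expect_true(all(nat$q > 0.99))
})

test_that("group-pair decomposition reconstructs the all-all Q per frame", {
  s <- make_toy_structure(toy_system_spec(n_residues = 30, seed = 8))
  nc <- build_native_contacts(s)
  set.seed(4)
  frames <- lapply(1:4, function(i) {
    structure_xyz(s) + matrix(rnorm(nrow(s$atoms) * 3, sd = 1), ncol = 3)
  })
  ens <- frames_ensemble(frames)
  all_ser <- q_series(ens, nc)
  gl <- group_labels()
  n_all <- nrow(nc$pairs)
  recon <- rep(0, 4)
  total_pairs <- 0
  for (i in seq_along(gl)) {
    for (j in i:length(gl)) {
      sub <- mask_by_groups(nc, gl[i], gl[j], allow_empty = TRUE)
      if (nrow(sub$pairs) == 0) next
      ser <- q_series(ens, sub)
      recon <- recon + nrow(sub$pairs) * ser$q
      total_pairs <- total_pairs + nrow(sub$pairs)
    }
  }
  expect_equal(total_pairs, n_all)
  expect_equal(recon / n_all, all_ser$q, tolerance = 1e-10)
  # ("all","all") series is the plain series
  expect_equal(group_pair_q_series(ens, nc, "all", "all")$q, all_ser$q)
})

test_that("contact-weighted mean of per-residue Q equals all-all Q", {
  s <- make_toy_structure(toy_system_spec(n_residues = 20, seed = 12))
  nc <- build_native_contacts(s)
  set.seed(5)
  frames <- lapply(1:3, function(i) {
    structure_xyz(s) + matrix(rnorm(nrow(s$atoms) * 3, sd = 1), ncol = 3)
  })
  ens <- frames_ensemble(frames)
  all_q <- q_series(ens, nc)$q
  resq <- per_residue_q_series(ens, nc)
  counts <- nc$per_residue
  joined <- dplyr::left_join(resq, counts, by = "residue_index")
  wmean <- joined |>
    dplyr::group_by(frame) |>
    dplyr::summarise(q = sum(q * n_contacts) / sum(n_contacts))
  # each pair is counted once in each of its two residues
  expect_equal(wmean$q, all_q, tolerance = 1e-10)
})

test_that("displacing one residue kills its Q and spares non-neighbors", {
  s <- make_toy_structure(toy_system_spec(n_residues = 30, seed = 10))
  nc <- build_native_contacts(s)
  k <- 14L  # an interior residue
  x <- structure_xyz(s)
  idx <- which(s$atoms$residue_index == k)
  x[idx, 1] <- x[idx, 1] + 20
  ens <- frames_ensemble(list(x))
  resq <- per_residue_q_series(ens, nc)
  qk <- resq$q[resq$residue_index == k]
  expect_lt(qk, 1e-6)
  expect_equal(qk, bf_soft_q(x, mask_by_residue(nc, k)$pairs),
               tolerance = 1e-12)
  # residues with no contacts to k keep essentially native Q
  touching <- unique(c(nc$pairs$res_i[nc$pairs$res_j == k],
                       nc$pairs$res_j[nc$pairs$res_i == k]))
  spared <- setdiff(unique(resq$residue_index), c(k, touching))
  expect_true(all(resq$q[resq$residue_index %in% spared] > 0.99))
})

test_that("degenerate Q inputs are rejected", {
  s <- manual_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)),
                        c(0L, 5L, 10L))
  nc <- build_native_contacts(s)
  empty <- mask_by_groups(nc, "hydrophilic", "hydrophilic",
                          allow_empty = TRUE)
  expect_error(soft_q(structure_xyz(s), empty), "empty contact")
  expect_error(soft_q(structure_xyz(s)[1:2, ], nc), "atoms")
  expect_error(q_parameters(beta = 0), "beta")
  expect_error(q_parameters(lam = 0.5), "lam")
  # residue with no contacts has no defined per-residue series
  ens <- frames_ensemble(list(structure_xyz(s)))
  expect_error(per_residue_q_series(ens, nc, residues = 99L), "unknown")
})
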
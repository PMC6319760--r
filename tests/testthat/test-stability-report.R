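test_that("unstable-residue flagging uses strict thresholds and exclusion", {
  s <- make_toy_structure(toy_system_spec(n_residues = 20, seed = 1))
  nc <- build_native_contacts(s)
  counts <- nc$per_residue$n_contacts
  rich <- which(counts >= 30) - 1L   # flaggable residues
  stopifnot(length(rich) >= 3)
  wm <- tibble::tibble(
    residue_index = c(rich[1], rich[1], rich[2], rich[3]),
    replica_id = c(1L, 3L, 1L, 1L),
    mean_q = c(0.59, 0.80, 0.60, 0.599999)
  )
  det <- detect_unstable_residues(wm, nc, s)
  # 0.59 flagged only in replica 1; 0.60 not flagged (strict <)
  expect_equal(det$flagged$residue_index, c(rich[1], rich[3]))
  expect_equal(det$flagged$replica_id, c(1L, 1L))
  expect_false(rich[2] %in% det$flagged$residue_index)
  # an excluded residue is never flagged, whatever its Q
  poor <- which(counts < 30) - 1L
  stopifnot(length(poor) >= 1)
  wm2 <- tibble::tibble(residue_index = poor[1], replica_id = 1L,
                        mean_q = 0.1)
  det2 <- detect_unstable_residues(wm2, nc, s)
  expect_equal(nrow(det2$flagged), 0)
  expect_true(poor[1] %in% det2$excluded$residue_index)
  expect_equal(det2$excluded$n_contacts,
               counts[det2$excluded$residue_index + 1L])
})

test_that("flagging is monotone in its two thresholds", {
  s <- make_toy_structure(toy_system_spec(n_residues = 20, seed = 5))
  nc <- build_native_contacts(s)
  set.seed(31)
  wm <- tidyr::expand_grid(residue_index = 0:19, replica_id = 1:4) |>
    dplyr::mutate(mean_q = runif(dplyr::n(), 0.3, 1))
  key <- function(det) paste(det$flagged$residue_index,
                             det$flagged$replica_id)
  d1 <- detect_unstable_residues(wm, nc, s, q_threshold = 0.5)
  d2 <- detect_unstable_residues(wm, nc, s, q_threshold = 0.7)
  expect_true(all(key(d1) %in% key(d2)))      # raising threshold only adds
  d3 <- detect_unstable_residues(wm, nc, s, min_contacts = 10)
  d4 <- detect_unstable_residues(wm, nc, s, min_contacts = 50)
  expect_true(all(key(d4) %in% key(d3)))      # raising min_contacts removes
})

test_that("composition percentages are trajectory-weighted and sum to 100", {
  pr <- tibble::tibble(
    residue_index = c(1L, 2L),
    residue = c("Asp2", "Gly3"),
    n_contacts = c(40L, 40L), in_cdr = FALSE,
    n_replicas_affected = c(2L, 2L), mean_q = 0.4,
    residue_name = c("ASP", "GLY")
  )
  comp <- composition_stats(pr)
  expect_equal(comp$percent[comp$group == "hydrophilic"], 50)
  expect_equal(comp$percent[comp$group == "hydrophobic"], 0)
  expect_equal(comp$percent[comp$group == "small"], 50)
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)
  # all hydrophobic
  pr2 <- dplyr::mutate(pr, residue_name = c("PHE", "TRP"))
  comp2 <- composition_stats(pr2)
  expect_equal(comp2$percent, c(0, 100, 0))
  # weighting: 3-replica residue counts three times
  pr3 <- dplyr::mutate(pr, n_replicas_affected = c(3L, 1L))
  comp3 <- composition_stats(pr3)
  expect_equal(comp3$percent[comp3$group == "hydrophilic"], 75)
  # empty -> undefined
  comp0 <- composition_stats(pr[0, ])
  expect_true(all(is.na(comp0$percent)))
})

test_that("group stability fraction matches hand computation", {
  s <- make_toy_structure(toy_system_spec(n_residues = 30, seed = 7))
  nc <- build_native_contacts(s)
  scheme <- residue_group_scheme()
  excl <- excluded_residues(nc, 30)
  grp <- classify_residue(s$residues$residue_name, scheme)
  g <- "hydrophilic"
  members <- s$residues$residue_index[grp == g &
                                        !s$residues$residue_index %in% excl]
  stopifnot(length(members) >= 2)
  # flag the first member in 4 of 10 replicas
  wm <- tibble::tibble(residue_index = rep(members[1], 4),
                       replica_id = 1:4, mean_q = 0.2)
  det <- detect_unstable_residues(wm, nc, s)
  pct <- group_stability_fraction(det, nc, s, g, n_replicas = 10)
  expect_equal(pct, 100 * (1 - 4 / (length(members) * 10)))
  # no flags -> 100%
  det0 <- detect_unstable_residues(wm[0, ], nc, s)
  expect_equal(group_stability_fraction(det0, nc, s, g, 10), 100)
})

test_that("pearson_r behaves as the textbook estimator with guards", {
  tm <- c(46.75, 58, 60, 69, 70.7, 79, 85)  # a realistic Tm spread
  expect_equal(pearson_r(tm, tm), 1.0)
  expect_equal(pearson_r(tm, -tm), -1.0)
  expect_equal(pearson_r(tm, 0.3 * tm + 7), 1.0, tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_r(x, y), cor(x, y))
  expect_error(pearson_r(1:3, 1:4), "length")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("correlation_table reproduces pearson_r and its edge policies", {
  summaries <- tidyr::expand_grid(
    system_id = sprintf("s%d", 1:5),
    selection = c("all-all", "hydrophilic-all")
  )
  set.seed(3)
  summaries$mean <- runif(nrow(summaries), 0.7, 1)
  tm <- tibble::tibble(system_id = sprintf("s%d", 1:5),
                       tm_celsius = c(47, 58, 66, 71, 85))
  ct <- correlation_table(summaries, tm)
  for (sel in unique(summaries$selection)) {
    d <- summaries[summaries$selection == sel, ]
    expect_equal(ct$r[ct$selection == sel],
                 pearson_r(d$mean, tm$tm_celsius))
    expect_equal(ct$n[ct$selection == sel], 5L)
  }
  # permuting system order changes nothing
  ct2 <- correlation_table(summaries[sample(nrow(summaries)), ], tm)
  expect_equal(ct2[order(ct2$selection), ]$r, ct[order(ct$selection), ]$r)
  # zero variance reported as undefined, not an error
  flat <- dplyr::mutate(summaries, mean = 0.9)
  ct3 <- correlation_table(flat, tm)
  expect_true(all(is.na(ct3$r)))
  expect_true(all(ct3$note == "zero variance"))
  # fewer than 3 systems is a hard error
  expect_error(correlation_table(summaries[summaries$system_id %in%
                                             c("s1", "s2"), ], tm),
               "fewer than 3")
  # a selection missing for some systems is dropped pairwise with a warning
  holey <- summaries[!(summaries$system_id == "s1" &
                         summaries$selection == "all-all"), ]
  expect_warning(ct4 <- correlation_table(holey, tm), "dropped pairwise")
  expect_equal(ct4$n[ct4$selection == "all-all"], 4L)
})

test_that("variant comparison reports deltas and refuses parameter drift", {
  spec <- toy_system_spec(n_residues = 20, n_replicas = 2, n_frames = 20,
                          seed = 11, unstable_residues = c(8L, 12L))
  s <- make_toy_structure(spec)
  ens <- simulate_ensemble(s, spec)
  wt <- suppressWarnings(analyze_system(s, ens, keep_series = FALSE))
  # WT vs itself: zero deltas
  self_cmp <- compare_variants(wt, wt)
  expect_equal(self_cmp$delta_q_all_all, c(0, 0))
  expect_equal(self_cmp$delta_rmsd_nm, c(0, 0))
  # a designed "mutant" with no unfolding residues is strictly more stable
  spec_mut <- toy_system_spec(n_residues = 20, n_replicas = 2,
                              n_frames = 20, seed = 11)
  mut <- suppressWarnings(
    analyze_system(s, simulate_ensemble(s, spec_mut, system_id = "mutant"),
                   keep_series = FALSE))
  cmp <- compare_variants(wt, mut)
  expect_gt(cmp$delta_q_all_all[2], 0)
  expect_gt(cmp$delta_q_hydrophilic_all[2], 0)
  expect_gt(cmp$delta_q_hydrophobic_small[2], 0)
  # differing lambda makes reports non-comparable
  mut2 <- suppressWarnings(
    analyze_system(s, simulate_ensemble(s, spec_mut),
                   params = q_parameters(lam = 1.5), keep_series = FALSE))
  expect_error(compare_variants(wt, mut2), "not comparable")
})

test_that("tidy and glance summarise a report", {
  spec <- toy_system_spec(n_residues = 15, n_replicas = 2, n_frames = 10,
                          seed = 13)
  s <- make_toy_structure(spec)
  rep <- suppressWarnings(
    analyze_system(s, simulate_ensemble(s, spec), keep_series = FALSE))
  td <- tidy(rep)
  expect_true(all(c("system_id", "selection", "mean", "sd") %in% names(td)))
  expect_true("all-all" %in% td$selection)
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$q_all_mean, td$mean[td$selection == "all-all"])
})
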
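test_that("mass tolerance follows the 50/150 ppm piecewise ramp", {
  p <- matching_params()
  expect_equal(mass_tolerance_ppm(2000, p), 50)
  expect_equal(mass_tolerance_ppm(3999, p), 50)
  expect_equal(mass_tolerance_ppm(8000, p), 150)
  expect_equal(mass_tolerance_ppm(5000, p), 100)   # ramp midpoint
  expect_equal(mass_tolerance_ppm(4500, p), 75)
  # exact linearity across the ramp
  ms <- seq(4000, 6000, by = 100)
  expect_equal(mass_tolerance_ppm(ms, p), 50 + (ms - 4000) / 2000 * 100)
  expect_error(mass_tolerance_ppm(0, p), "positive")
})

test_that("migration tolerance ramps linearly across the run span", {
  p <- matching_params()
  span <- c(20, 40)
  expect_equal(migration_tolerance_min(20, span, p), 1.0)
  expect_equal(migration_tolerance_min(40, span, p), 2.5)
  expect_equal(migration_tolerance_min(30, span, p), 1.75)
  # clamped outside the span
  expect_equal(migration_tolerance_min(10, span, p), 1.0)
  expect_equal(migration_tolerance_min(50, span, p), 2.5)
  expect_error(migration_tolerance_min(25, c(30, 30), p), "degenerate")
})

test_that("standard sets enforce their invariants", {
  expect_error(standard_set(1000, 20, 5), ">= 2")
  expect_error(standard_set(c(1000, 2000), c(25, 20), c(5, 5)),
               "increasing")
})

test_that("normalization inverts constructed distortions exactly", {
  ref <- standard_set(c(1500, 4000, 9000), c(20, 30, 40), c(100, 100, 100))
  prof <- peptide_profile(
    1:5, c(1500, 4000, 9000, 2500, 6000),
    c(20, 30, 40, 24, 36), c(100, 100, 100, 50, 80))

  # identity: already at reference coordinates
  out <- normalize_profile(prof, ref)
  expect_equal(out$migration_min, prof$migration_min, tolerance = 1e-12)
  expect_equal(attr(out, "amplitude_factor"), 1)

  # affine distortion: +2 min shift, amplitudes halved
  shifted <- prof
  shifted$migration_min <- prof$migration_min + 2
  shifted$amplitude <- prof$amplitude / 2
  out2 <- normalize_profile(shifted, ref)
  expect_equal(out2$migration_min[1:3], ref$migration_min, tolerance = 1e-9)
  expect_equal(out2$amplitude[1:3], ref$amplitude, tolerance = 1e-9)
  # non-standard peptides are carried along by the same map
  expect_equal(out2$migration_min[4:5], c(24, 36), tolerance = 1e-9)

  # fewer than 2 detected standards is an error naming what was found
  lone <- peptide_profile(1, 1500, 22, 90)
  expect_error(normalize_profile(lone, ref), "only 1")
})

test_that("quadratic per-sample warps are undone to < 0.01 min RMS", {
  cf <- simulation_config(n_per_group = 4, n_master_peptides = 40,
                          n_affected = 0, migration_warp_scale = 1.5,
                          seed = 5)
  sim <- generate_cohort(cf)
  errs <- unlist(lapply(sim$profiles, function(p) {
    np <- normalize_profile(p, sim$reference)
    idx <- attr(p, "true_ids") %in% seq_len(cf$n_standards)
    np$migration_min[idx] - sim$reference$migration_min
  }))
  expect_lt(sqrt(mean(errs^2)), 0.01)
})

test_that("observations within tolerance share one master peptide", {
  # 25 ppm apart, 0.3 min apart -> same peptide
  m <- match_profiles(tiny_profiles(2000.05),
                      matching_params(presence_threshold = 0),
                      run_span = c(15, 45))
  expect_equal(nrow(m$peptides), 1L)
  expect_false(anyNA(m$amplitude))
  # 150 ppm apart at 2 kDa -> distinct peptides
  m2 <- match_profiles(tiny_profiles(2000.30),
                       matching_params(presence_threshold = 0),
                       run_span = c(15, 45))
  expect_equal(nrow(m2$peptides), 2L)
})

test_that("consensus coordinates are amplitude-weighted means", {
  m <- match_profiles(tiny_profiles(2000.05),
                      matching_params(presence_threshold = 0),
                      run_span = c(15, 45))
  w <- c(100, 120)
  expect_equal(m$peptides$mass_da,
               sum(w * c(2000.00, 2000.05)) / sum(w), tolerance = 1e-4)
  expect_equal(m$peptides$migration_min,
               sum(w * c(20.0, 20.3)) / sum(w), tolerance = 1e-2)
})

test_that("sweep clustering equals the brute-force single-linkage oracle", {
  params <- matching_params(presence_threshold = 0)
  span <- c(15, 45)
  for (s in 1:30) {
    set.seed(s)
    n <- sample(10:30, 1)
    # masses concentrated so that collisions actually happen
    mass <- exp(runif(n, log(900), log(11000)))
    mass <- mass * (1 + sample(c(0, 1e-5, 5e-5), n, replace = TRUE))
    time <- runif(n, 16, 44)
    nsamp <- sample(2:4, 1)
    smp <- sample(paste0("s", seq_len(nsamp)), n, replace = TRUE)
    profs <- lapply(split(seq_len(n), smp), function(idx)
      peptide_profile(seq_along(idx), mass[idx], time[idx], 1))
    m <- match_profiles(profs, params, run_span = span)
    cl <- attr(m, "clusters")
    key <- paste(cl$sample, cl$local_id)
    # oracle on the same pooled observations, in the cluster table's order
    pooled_mass <- unlist(lapply(names(profs),
                                 function(s) profs[[s]]$mass_da))
    pooled_time <- unlist(lapply(names(profs),
                                 function(s) profs[[s]]$migration_min))
    pooled_key <- unlist(lapply(names(profs), function(s)
      paste(s, profs[[s]]$local_id)))
    ord <- match(key, pooled_key)
    want <- oracle_cluster(pooled_mass[ord], pooled_time[ord], span, params)
    expect_identical(canonical_partition(cl$cluster),
                     canonical_partition(want))
  }
})

test_that("matching is invariant to sample order and conserves counts", {
  cf <- simulation_config(n_per_group = 3, n_master_peptides = 50,
                          n_affected = 0, seed = 9)
  sim <- generate_cohort(cf)
  prof <- lapply(sim$profiles, normalize_profile, reference = sim$reference)
  m1 <- match_profiles(prof, reference = sim$reference)
  m2 <- match_profiles(rev(prof), reference = sim$reference)
  expect_equal(m1$peptides, m2$peptides)
  expect_equal(m1$amplitude[, m1$sample_ids],
               m2$amplitude[, m1$sample_ids])
  cnt <- attr(m1, "counts")
  expect_equal(unname(cnt["n_in"]),
               unname(cnt["n_assigned"] + cnt["n_dropped_duplicate"] +
                        cnt["n_dropped_presence"]))
  expect_equal(unname(cnt["n_in"]), sum(vapply(prof, nrow, integer(1))))
})

test_that("a noise-free cohort reconstructs the master list exactly", {
  cf <- simulation_config(n_per_group = 3, n_master_peptides = 60,
                          n_affected = 5, dropout_rate = 0,
                          mass_jitter_ppm = 0, migration_warp_scale = 0,
                          seed = 2)
  sim <- generate_cohort(cf)
  prof <- lapply(sim$profiles, normalize_profile, reference = sim$reference)
  m <- match_profiles(prof, reference = sim$reference)
  expect_equal(nrow(m$peptides), cf$n_master_peptides + cf$n_standards)
  expect_false(anyNA(m$amplitude))
  expect_equal(m$peptides$mass_da,
               round(sort(sim$truth$master$mass_da), 4), tolerance = 1e-9)
})

test_that("unnormalized profiles are rejected when a reference is given", {
  cf <- simulation_config(n_per_group = 2, n_master_peptides = 20,
                          n_affected = 0, migration_warp_scale = 2,
                          seed = 3)
  sim <- generate_cohort(cf)
  expect_error(match_profiles(sim$profiles, reference = sim$reference),
               "not normalized")
})
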
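# Synthetic CE-MS cohort generator with planted age effects.  Every
# downstream stage (normalization, matching, screening, classifier) is
# exercised against the ground truth this module records.

#' Simulation configuration for a synthetic CE-MS cohort
#'
#' Defaults emulate the reference mouse-aging cohort: 3 age groups of 13
#' animals each, a master list of 200 urinary peptides plus 5 internal
#' standards, log-normal amplitudes, a planted per-age-step log2 fold
#' change on a small subset of peptides, ppm-scale mass jitter, a smooth
#' monotone per-sample migration-time warp and missing-at-random dropout.
#'
#' @param n_per_group animals per age-by-treatment cell (default 13)
#' @param age_groups age labels, increasing age order
#' @param treatments treatment labels
#' @param n_master_peptides master peptides excluding standards
#' @param n_affected peptides carrying the planted age effect
#' @param effect_log2fc planted log2 fold change per age step
#' @param n_standards internal-standard peptides (present in every
#'   sample, never dropped, never affected)
#' @param mass_range_da master mass range, Da
#' @param migration_range_min CE run span, minutes
#' @param mass_jitter_ppm sd of per-observation relative mass error (ppm)
#' @param migration_warp_scale amplitude (min) of the smooth per-sample
#'   quadratic migration-time distortion
#' @param dropout_rate probability a non-standard peptide is unobserved
#'   in a sample
#' @param dropout_mode `"mar"` (amplitude-independent, default) or
#'   `"intensity"` (low-amplitude observations drop out preferentially,
#'   same marginal rate)
#' @param amplitude_sd_log per-observation log2 amplitude noise sd
#' @param sample_intensity_sd sd of the per-sample global log2 intensity
#'   factor (what amplitude normalization must undo)
#' @param base_log2_mean,base_log2_sd distribution of per-peptide
#'   baseline log2 amplitudes across the master list
#' @param treated_like optional age-group label: treated samples draw
#'   their affected-peptide means from this group's level instead of
#'   their own (models a treatment that shifts the peptidome toward
#'   another age)
#' @param seed RNG seed
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(n_per_group = 13,
                              age_groups = c("young", "middle", "old"),
                              treatments = "control",
                              n_master_peptides = 200,
                              n_affected = 10,
                              effect_log2fc = 2,
                              n_standards = 5,
                              mass_range_da = c(800, 15000),
                              migration_range_min = c(18, 45),
                              mass_jitter_ppm = 10,
                              migration_warp_scale = 1.0,
                              dropout_rate = 0.2,
                              dropout_mode = c("mar", "intensity"),
                              amplitude_sd_log = 1.0,
                              sample_intensity_sd = 0.5,
                              base_log2_mean = 10,
                              base_log2_sd = 2,
                              treated_like = NULL,
                              seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid configuration field '", field, "': ", msg)
  chk(n_per_group >= 1, "n_per_group", "must be >= 1")
  chk(length(age_groups) >= 1 && !anyDuplicated(age_groups),
      "age_groups", "must be distinct labels")
  chk(n_affected <= n_master_peptides, "n_affected",
      "must not exceed n_master_peptides")
  chk(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate",
      "must be in [0, 1)")
  chk(mass_range_da[1] > 0 && mass_range_da[1] < mass_range_da[2],
      "mass_range_da", "min must be positive and below max")
  chk(migration_range_min[1] > 0 &&
        migration_range_min[1] < migration_range_min[2],
      "migration_range_min", "min must be positive and below max")
  chk(n_standards >= 2, "n_standards", "must be >= 2")
  chk(mass_jitter_ppm >= 0, "mass_jitter_ppm", "must be >= 0")
  chk(migration_warp_scale >= 0, "migration_warp_scale", "must be >= 0")
  chk(amplitude_sd_log >= 0, "amplitude_sd_log", "must be >= 0")
  chk(is.null(treated_like) || treated_like %in% age_groups,
      "treated_like", "must be one of age_groups")
  structure(list(
    n_per_group = n_per_group, age_groups = age_groups,
    treatments = treatments, n_master_peptides = n_master_peptides,
    n_affected = n_affected, effect_log2fc = effect_log2fc,
    n_standards = n_standards, mass_range_da = mass_range_da,
    migration_range_min = migration_range_min,
    mass_jitter_ppm = mass_jitter_ppm,
    migration_warp_scale = migration_warp_scale,
    dropout_rate = dropout_rate, dropout_mode = dropout_mode,
    amplitude_sd_log = amplitude_sd_log,
    sample_intensity_sd = sample_intensity_sd,
    base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
    treated_like = treated_like, seed = as.integer(seed)),
    class = "simulation_config")
}

# Smooth monotone quadratic warp t' = t + s*(u0 + u1*x + u2*x^2) with
# x = (t - t0)/span in [0, 1]; |u| <= 1 so max distortion ~ 3*s and the
# map stays monotone for the spans used here.
.warp_time <- function(t, coef, range) {
  x <- (t - range[1]) / (range[2] - range[1])
  t + coef[1] + coef[2] * x + coef[3] * x^2
}

#' Generate a synthetic cohort
#'
#' Draws a master peptide list, plants an age effect on a subset, and
#' emits one raw (warped, jittered) peptide profile per sample together
#' with the cohort design and the ground truth needed to score every
#' downstream stage.
#'
#' @param config a [simulation_config()]
#' @return list with `profiles` (named list of [peptide_profile()]),
#'   `design` ([cohort_design()]), `reference` ([standard_set()] of the
#'   internal standards at true coordinates) and `truth` (master table,
#'   affected ids, per-age mean log2 amplitudes, per-sample warp
#'   coefficients and intensity factors)
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  n_tot <- cf$n_master_peptides + cf$n_standards

  ## master list: standards evenly spaced across the migration range
  std_t <- seq(cf$migration_range_min[1] + 1,
               cf$migration_range_min[2] - 1,
               length.out = cf$n_standards)
  std_m <- seq(cf$mass_range_da[1] * 1.1, cf$mass_range_da[2] * 0.9,
               length.out = cf$n_standards)
  pep_m <- stats::runif(cf$n_master_peptides,
                        cf$mass_range_da[1], cf$mass_range_da[2])
  pep_t <- stats::runif(cf$n_master_peptides,
                        cf$migration_range_min[1], cf$migration_range_min[2])
  master <- data.frame(
    true_id = seq_len(n_tot),
    mass_da = c(std_m, pep_m),
    migration_min = c(std_t, pep_t),
    is_standard = rep(c(TRUE, FALSE),
                      c(cf$n_standards, cf$n_master_peptides)))
  master$base_log2 <- stats::rnorm(n_tot, cf$base_log2_mean, cf$base_log2_sd)
  master$base_log2[master$is_standard] <- cf$base_log2_mean + 2  # bright, stable

  affected <- sample(master$true_id[!master$is_standard], cf$n_affected)

  n_age <- length(cf$age_groups)
  mean_log2 <- matrix(master$base_log2, n_tot, n_age,
                      dimnames = list(master$true_id, cf$age_groups))
  for (g in seq_len(n_age)) {
    step <- g - 1L
    mean_log2[affected, g] <- master$base_log2[affected] +
      cf$effect_log2fc * step
  }

  ## design
  grid <- expand.grid(rep = seq_len(cf$n_per_group),
                      treatment = cf$treatments,
                      age_group = cf$age_groups,
                      stringsAsFactors = FALSE)
  sample_ids <- sprintf("s%03d", seq_len(nrow(grid)))
  design <- cohort_design(sample_ids, grid$age_group, grid$treatment,
                          age_levels = cf$age_groups)

  reference <- standard_set(std_m, std_t,
                            2^(cf$base_log2_mean + 2))

  warp <- matrix(0, nrow(grid), 3,
                 dimnames = list(sample_ids, c("u0", "u1", "u2")))
  intensity <- stats::rnorm(nrow(grid), 0, cf$sample_intensity_sd)
  profiles <- vector("list", nrow(grid))
  names(profiles) <- sample_ids

  for (i in seq_len(nrow(grid))) {
    age_i <- grid$age_group[i]
    eff_age <- if (!is.null(cf$treated_like) &&
                   grid$treatment[i] != cf$treatments[1]) cf$treated_like
               else age_i
    # non-affected peptides are flat across ages, so taking the whole
    # eff_age column only redirects the planted (affected) means
    mu <- mean_log2[, eff_age]
    amp <- 2^(mu + intensity[i] +
                stats::rnorm(n_tot, 0, cf$amplitude_sd_log))
    amp[master$is_standard] <- 2^(master$base_log2[master$is_standard] +
                                    intensity[i])

    warp[i, ] <- cf$migration_warp_scale * stats::runif(3, -1, 1)
    tt <- .warp_time(master$migration_min, warp[i, ],
                     cf$migration_range_min)
    mm <- master$mass_da *
      (1 + stats::rnorm(n_tot, 0, cf$mass_jitter_ppm) * 1e-6)

    drop_u <- stats::runif(n_tot)
    if (cf$dropout_mode == "mar") {
      dropped <- drop_u < cf$dropout_rate
    } else {
      # intensity-dependent: drop probability decreasing in amplitude
      # rank, marginal rate preserved
      r <- rank(amp) / n_tot
      dropped <- drop_u < pmin(0.99, 2 * cf$dropout_rate * (1 - r))
    }
    dropped[master$is_standard] <- FALSE
    ok <- which(!dropped)
    profiles[[i]] <- peptide_profile(
      local_id = seq_along(ok),
      mass_da = mm[ok], migration_min = tt[ok], amplitude = amp[ok])
    attr(profiles[[i]], "true_ids") <- master$true_id[ok]
  }

  truth <- list(master = master, affected_ids = sort(affected),
                mean_log2 = mean_log2, warp = warp,
                intensity_log2 = stats::setNames(intensity, sample_ids))
  list(profiles = profiles, design = design, reference = reference,
       truth = truth)
}

#' Map matched master peptides back to generator ground truth
#'
#' Pairs each master peptide of a matched matrix with the nearest true
#' master peptide by consensus mass (within the ppm tolerance), so
#' recovery of planted effects can be scored.
#'
#' @param matrix a [matched_matrix()]
#' @param truth the `truth` element of [generate_cohort()]
#' @param params a [matching_params()]
#' @return integer vector, `true_id` per matrix row (NA if unmatched)
#' @export
map_to_truth <- function(matrix, truth, params = matching_params()) {
  vapply(matrix$peptides$mass_da, function(m) {
    d <- abs(truth$master$mass_da - m)
    k <- which.min(d)
    tol <- mass_tolerance_ppm(truth$master$mass_da[k], params) * 1e-6 *
      truth$master$mass_da[k]
    if (d[k] <= tol) truth$master$true_id[k] else NA_integer_
  }, integer(1))
}

#' Generate a synthetic qPCR Ct table
#'
#' Noise-free inversion of the relative-expression formula: `ct_gene =
#' ct_gapdh - log2(expression)`, with the no-reverse-transcriptase
#' control `ct_rt_minus = ct_gene + contamination_offset` (an infinite
#' offset means no detectable genomic contamination and is emitted as
#' `NA`).  Applying [qpcr_expression()] to noise-free output recovers
#' `expression * (1 - 2^-contamination_offset)`.
#'
#' @param n_samples rows to generate
#' @param true_expression relative expression level(s), recycled; > 0
#' @param contamination_offset Ct distance of the RT- control above the
#'   gene Ct; >= 0, may be `Inf`
#' @param sd_ct per-well Ct noise sd (applied independently to each Ct)
#' @param ct_gapdh reference-gene Ct
#' @param seed RNG seed
#' @return data.frame with `ct_gene`, `ct_gapdh`, `ct_rt_minus`
#' @export
generate_qpcr_table <- function(n_samples, true_expression,
                                contamination_offset = Inf,
                                sd_ct = 0, ct_gapdh = 20, seed = 1L) {
  if (any(true_expression <= 0)) stop("true_expression must be positive")
  if (any(contamination_offset < 0))
    stop("contamination_offset must be >= 0")
  set.seed(seed)
  e <- rep_len(true_expression, n_samples)
  off <- rep_len(contamination_offset, n_samples)
  ctg <- ct_gapdh - log2(e) + stats::rnorm(n_samples, 0, sd_ct)
  ctgap <- ct_gapdh + stats::rnorm(n_samples, 0, sd_ct)
  ctrt <- ifelse(is.finite(off), ctg + off, NA_real_)
  data.frame(sample = sprintf("q%03d", seq_len(n_samples)),
             ct_gene = ctg, ct_gapdh = ctgap, ct_rt_minus = ctrt)
}

#' Generate synthetic glomerular profile areas
#'
#' Log-normal areas with the requested mean and sd (moment-matched);
#' `sd_area = 0` returns `n` copies of the mean.
#'
#' @param n number of glomerular profiles (a typical slide carries ~180)
#' @param mean_area_um2 mean profile area, um^2; > 0
#' @param sd_area area sd, um^2
#' @param seed RNG seed
#' @return numeric vector of positive areas
#' @export
generate_glomeruli <- function(n, mean_area_um2 = 5000, sd_area = 1500,
                               seed = 1L) {
  if (n <= 0) stop("n must be positive")
  if (mean_area_um2 <= 0) stop("mean_area_um2 must be positive")
  if (sd_area < 0) stop("sd_area must be >= 0")
  set.seed(seed)
  if (sd_area == 0) return(rep(mean_area_um2, n))
  s2 <- log(1 + (sd_area / mean_area_um2)^2)
  stats::rlnorm(n, meanlog = log(mean_area_um2) - s2 / 2,
                sdlog = sqrt(s2))
}
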
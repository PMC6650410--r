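# Internal-standard normalization and cross-sample peptide matching.
#
# Two observations from different samples are considered the same peptide
# when their mass deviation is below a ppm tolerance (50 ppm under 4 kDa,
# 150 ppm above 6 kDa, linearly interpolated between) AND their migration
# times agree within a tolerance that grows linearly across the CE run
# from 1.0 min at the start to 2.5 min at the end.

#' Matching tolerance parameters
#'
#' @param ppm_low relative mass tolerance (ppm) below the lower
#'   interpolation bound; default 50
#' @param ppm_high relative mass tolerance (ppm) above the upper bound;
#'   default 150
#' @param interp_bounds_kda mass interval (kDa) over which the ppm
#'   tolerance ramps linearly; default `c(4, 6)`
#' @param mig_tol_min_low migration-time tolerance (min) at the start of
#'   the run; default 1.0
#' @param mig_tol_min_high migration-time tolerance (min) at the end of
#'   the run; default 2.5
#' @param presence_threshold minimum fraction of samples a master peptide
#'   must be observed in to be kept; default 0.3
#' @return a list of class `matching_params`
#' @export
matching_params <- function(ppm_low = 50, ppm_high = 150,
                            interp_bounds_kda = c(4, 6),
                            mig_tol_min_low = 1.0, mig_tol_min_high = 2.5,
                            presence_threshold = 0.3) {
  if (!(ppm_low > 0 && ppm_low <= ppm_high))
    stop("invalid ppm_low/ppm_high: need 0 < ppm_low <= ppm_high")
  if (!(mig_tol_min_low > 0 && mig_tol_min_low <= mig_tol_min_high))
    stop("invalid mig_tol_min_low/mig_tol_min_high")
  if (presence_threshold < 0 || presence_threshold > 1)
    stop("invalid presence_threshold: must be in [0, 1]")
  if (length(interp_bounds_kda) != 2 ||
      interp_bounds_kda[1] >= interp_bounds_kda[2])
    stop("invalid interp_bounds_kda")
  structure(list(ppm_low = ppm_low, ppm_high = ppm_high,
                 interp_bounds_kda = interp_bounds_kda,
                 mig_tol_min_low = mig_tol_min_low,
                 mig_tol_min_high = mig_tol_min_high,
                 presence_threshold = presence_threshold),
            class = "matching_params")
}

#' Mass tolerance in ppm at a given mass
#'
#' Piecewise: `ppm_low` below the lower interpolation bound, `ppm_high`
#' above the upper bound, linear in between (so e.g. 100 ppm at 5 kDa
#' with defaults).
#'
#' @param mass_da mass in Da (vectorized)
#' @param params a [matching_params()]
#' @return tolerance in ppm
#' @export
mass_tolerance_ppm <- function(mass_da, params = matching_params()) {
  if (any(mass_da <= 0)) stop("mass_da must be positive")
  lo <- params$interp_bounds_kda[1] * 1000
  hi <- params$interp_bounds_kda[2] * 1000
  frac <- pmin(1, pmax(0, (mass_da - lo) / (hi - lo)))
  params$ppm_low + frac * (params$ppm_high - params$ppm_low)
}

#' Migration-time tolerance at a given time
#'
#' Linear ramp from `mig_tol_min_low` at the start of the run span to
#' `mig_tol_min_high` at its end, clamped outside.
#'
#' @param migration_min migration time(s), minutes
#' @param run_span `c(t_min, t_max)` of the run (normally the reference
#'   standards' span), `t_max > t_min`
#' @param params a [matching_params()]
#' @return tolerance in minutes
#' @export
migration_tolerance_min <- function(migration_min, run_span,
                                    params = matching_params()) {
  if (length(run_span) != 2 || run_span[2] <= run_span[1])
    stop("degenerate run_span: need t_max > t_min")
  frac <- pmin(1, pmax(0, (migration_min - run_span[1]) /
                            (run_span[2] - run_span[1])))
  params$mig_tol_min_low +
    frac * (params$mig_tol_min_high - params$mig_tol_min_low)
}

#' Reference internal-standard set
#'
#' Endogenous peptides reliably present in every urine sample, used as
#' anchors for migration-time alignment and amplitude scaling.
#'
#' @param mass_da reference masses (Da)
#' @param migration_min reference migration times (min), strictly
#'   increasing
#' @param amplitude reference amplitudes
#' @return a `data.frame` of class `standard_set`
#' @export
standard_set <- function(mass_da, migration_min, amplitude) {
  if (length(mass_da) < 2)
    stop("need >= 2 internal standards to fit an alignment")
  if (any(diff(migration_min) <= 0))
    stop("reference standard migration times must be strictly increasing")
  out <- data.frame(mass_da = mass_da, migration_min = migration_min,
                    amplitude = amplitude)
  class(out) <- c("standard_set", "data.frame")
  out
}

#' Write / read a reference standard set (TSV)
#' @param standards a [standard_set()]
#' @param path file path
#' @export
write_standard_set <- function(standards, path) {
  lines <- c("mass\tmigration_time\tamplitude",
             paste(.fmt_mass(standards$mass_da),
                   .fmt_time(standards$migration_min),
                   .fmt_amp(standards$amplitude), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_standard_set
#' @export
read_standard_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  standard_set(df$mass, df$migration_time, df$amplitude)
}

# Locate the reference standards in a raw profile: candidates within the
# ppm mass tolerance, disambiguated by migration-time proximity to the
# reference (run-to-run warps are a few minutes at most, while an
# unrelated peptide that happens to share a standard's mass sits at an
# arbitrary time).  Returns the profile row index per standard, NA where
# a standard was not found.
detect_standards <- function(profile, reference, params = matching_params()) {
  vapply(seq_len(nrow(reference)), function(k) {
    m <- reference$mass_da[k]
    tol <- mass_tolerance_ppm(m, params) * 1e-6 * m
    d <- abs(profile$mass_da - m)
    cand <- which(d <= tol)
    if (!length(cand)) return(NA_integer_)
    dt <- abs(profile$migration_min[cand] - reference$migration_min[k])
    cand[order(dt, d[cand])][1]
  }, integer(1))
}

#' Normalize a profile against internal standards
#'
#' Migration times are mapped by monotone piecewise-linear interpolation
#' anchored at the (detected, reference) standard time pairs, with linear
#' extrapolation beyond the outermost anchors; detected standards land
#' exactly on the reference times.  Amplitudes are multiplied by one
#' global factor, the median of reference/detected amplitude ratios over
#' the standards.
#'
#' @param profile a [peptide_profile()]
#' @param reference a [standard_set()]
#' @param params a [matching_params()] (mass tolerance used to detect the
#'   standards)
#' @return the normalized profile; attributes `standards_used` (indices
#'   into the reference set) and `amplitude_factor`
#' @export
normalize_profile <- function(profile, reference,
                              params = matching_params()) {
  idx <- detect_standards(profile, reference, params)
  found <- which(!is.na(idx))
  if (length(found) < 2)
    stop("normalization error: only ", length(found),
         " internal standard(s) detected (found reference standards: ",
         if (length(found)) paste(found, collapse = ", ") else "none",
         "); >= 2 required")
  det_t <- profile$migration_min[idx[found]]
  ref_t <- reference$migration_min[found]
  if (any(diff(det_t) <= 0))
    stop("normalization error: detected standard times not increasing")
  new_t <- .piecewise_linear(profile$migration_min, det_t, ref_t)
  ratio <- reference$amplitude[found] / profile$amplitude[idx[found]]
  fac <- stats::median(ratio)
  out <- profile
  out$migration_min <- new_t
  out$amplitude <- profile$amplitude * fac
  attr(out, "standards_used") <- found
  attr(out, "amplitude_factor") <- fac
  out
}

# Monotone piecewise-linear map through anchors (x0, y0), linear
# extrapolation with the end-segment slopes outside [min(x0), max(x0)].
.piecewise_linear <- function(x, x0, y0) {
  n <- length(x0)
  if (n == 1) return(x + (y0 - x0))
  y <- stats::approx(x0, y0, xout = x, rule = 2)$y
  sl_lo <- (y0[2] - y0[1]) / (x0[2] - x0[1])
  sl_hi <- (y0[n] - y0[n - 1]) / (x0[n] - x0[n - 1])
  lo <- x < x0[1]
  hi <- x > x0[n]
  y[lo] <- y0[1] + sl_lo * (x[lo] - x0[1])
  y[hi] <- y0[n] + sl_hi * (x[hi] - x0[n])
  y
}

# Pairwise tolerance predicate: may observations i and j be the same
# peptide?  The ppm window is anchored at the smaller of the two masses;
# the migration tolerance is evaluated at the midpoint of the two times.
.same_peptide <- function(m1, t1, m2, t2, run_span, params) {
  msmall <- pmin(m1, m2)
  tol_m <- mass_tolerance_ppm(msmall, params) * 1e-6 * msmall
  tol_t <- migration_tolerance_min((t1 + t2) / 2, run_span, params)
  abs(m1 - m2) <= tol_m & abs(t1 - t2) <= tol_t
}

#' Match normalized profiles into a master-peptide matrix
#'
#' Observations from all samples are pooled and clustered with
#' single-linkage semantics under the tolerance predicate (same peptide
#' iff mass deviation within the ppm window of the smaller mass and
#' migration deviation within the time-dependent tolerance), implemented
#' as a mass-ordered sweep over a union-find structure.  Within a cluster
#' each sample contributes at most one observation: the one closest in
#' mass to the cluster consensus wins (ties: closest in time, then lowest
#' `local_id`).  Master peptides observed in fewer than
#' `presence_threshold` of the samples are dropped.  Master ids are
#' assigned in ascending consensus-mass order; consensus mass/time is the
#' amplitude-weighted mean over the retained members.
#'
#' @param profiles named list of normalized [peptide_profile()]s (names =
#'   sample ids)
#' @param params a [matching_params()]
#' @param run_span CE run span for the migration tolerance ramp; defaults
#'   to the pooled observed time range
#' @param reference optional [standard_set()]; when supplied, each
#'   profile's detected standards are checked to sit on the reference
#'   times within tolerance (i.e. the profile was normalized)
#' @return a [matched_matrix()]; attribute `counts` reconciles the
#'   observations (`n_in = n_assigned + n_dropped_duplicate +
#'   n_dropped_presence`)
#' @export
match_profiles <- function(profiles, params = matching_params(),
                           run_span = NULL, reference = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
    stop("profiles must be a named list with unique sample ids")
  if (!is.null(reference)) {
    for (s in names(profiles)) {
      idx <- detect_standards(profiles[[s]], reference, params)
      ok <- !is.na(idx)
      if (sum(ok) < 2)
        stop("profile ", s, " does not contain the internal standards")
      dev <- abs(profiles[[s]]$migration_min[idx[ok]] -
                   reference$migration_min[ok])
      if (any(dev > 1e-6))
        stop("profile ", s, " is not normalized: standard migration ",
             "times deviate from reference by up to ",
             format(max(dev)), " min")
    }
    if (is.null(run_span)) run_span <- range(reference$migration_min)
  }
  pool <- do.call(rbind, lapply(names(profiles), function(s) {
    p <- profiles[[s]]
    data.frame(sample = s, local_id = p$local_id, mass = p$mass_da,
               time = p$migration_min, amp = p$amplitude,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(pool)
  if (is.null(run_span)) run_span <- range(pool$time)
  if (run_span[2] <= run_span[1]) run_span <- run_span + c(-0.5, 0.5)

  ord <- order(pool$mass, pool$time, pool$sample, pool$local_id)
  pool <- pool[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # sweep in ascending mass; the widest possible window at mass m is
  # ppm_high of m, so only neighbours within that window need the full
  # predicate
  max_rel <- params$ppm_high * 1e-6
  mass <- pool$mass; time <- pool$time
  j0 <- 1L
  for (i in seq_len(n)) {
    while (mass[i] - mass[j0] > max_rel * mass[i] && j0 < i) j0 <- j0 + 1L
    if (j0 < i) {
      js <- j0:(i - 1L)
      hit <- js[.same_peptide(mass[i], time[i], mass[js], time[js],
                              run_span, params)]
      for (j in hit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))
  ncomp <- max(comp)

  # provisional consensus (amplitude-weighted), then per-sample dedup
  keep <- rep(TRUE, n)
  wsum <- tapply(pool$amp, comp, sum)
  wsum[wsum == 0] <- 1
  cmass <- tapply(pool$amp * pool$mass, comp, sum) / wsum
  ctime <- tapply(pool$amp * pool$time, comp, sum) / wsum
  for (k in seq_len(ncomp)) {
    rows <- which(comp == k)
    dup <- split(rows, pool$sample[rows])
    for (rr in dup) {
      if (length(rr) > 1) {
        best <- rr[order(abs(pool$mass[rr] - cmass[k]),
                         abs(pool$time[rr] - ctime[k]),
                         pool$local_id[rr])][1]
        keep[setdiff(rr, best)] <- FALSE
      }
    }
  }
  n_dup <- sum(!keep)

  samples <- names(profiles)
  nsamp <- length(samples)
  kept <- which(keep)
  presence <- tapply(pool$sample[kept], comp[kept],
                     function(s) length(unique(s)))
  pres_ok <- as.integer(names(presence))[presence / nsamp >=
                                           params$presence_threshold]
  n_pres_drop <- sum(keep & !(comp %in% pres_ok))

  # consensus over retained members, master ids ascending in mass
  rows_by_comp <- split(kept[comp[kept] %in% pres_ok],
                        comp[kept][comp[kept] %in% pres_ok])
  cons <- t(vapply(rows_by_comp, function(rr) {
    w <- pool$amp[rr]
    if (sum(w) == 0) w <- rep(1, length(rr))
    c(sum(w * pool$mass[rr]) / sum(w), sum(w * pool$time[rr]) / sum(w))
  }, numeric(2)))
  mord <- order(cons[, 1])
  rows_by_comp <- rows_by_comp[mord]
  cons <- cons[mord, , drop = FALSE]
  K <- length(rows_by_comp)
  amp <- matrix(NA_real_, K, nsamp, dimnames = list(NULL, samples))
  for (k in seq_len(K)) {
    rr <- rows_by_comp[[k]]
    amp[k, pool$sample[rr]] <- pool$amp[rr]
  }
  m <- matched_matrix(
    data.frame(master_id = seq_len(K),
               mass_da = cons[, 1], migration_min = cons[, 2]),
    amp, sample_ids = samples)
  attr(m, "counts") <- c(n_in = n,
                         n_assigned = n - n_dup - n_pres_drop,
                         n_dropped_duplicate = n_dup,
                         n_dropped_presence = n_pres_drop)
  ## observation-level bookkeeping: cluster id for every input
  ## observation, assigned master id (NA when dropped) and the reason
  comp_to_master <- rep(NA_integer_, ncomp)
  comp_to_master[as.integer(names(rows_by_comp))] <- seq_len(K)
  status <- rep("assigned", n)
  status[!keep] <- "dropped_duplicate"
  status[keep & !(comp %in% pres_ok)] <- "dropped_presence"
  master_of <- comp_to_master[comp]
  master_of[status != "assigned"] <- NA_integer_
  attr(m, "clusters") <- data.frame(
    sample = pool$sample, local_id = pool$local_id, cluster = comp,
    master_id = master_of, status = status, stringsAsFactors = FALSE)
  m
}
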
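# File dialect used throughout: tab-separated, UTF-8, '.' decimal separator,
# "NA" for missing amplitude cells; masses in Da to 4 decimals, migration
# times in minutes to 2 decimals; amplitudes at full double precision.

.fmt_mass <- function(x) sprintf("%.4f", x)
.fmt_time <- function(x) sprintf("%.2f", x)
.fmt_amp  <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Construct a peptide observation profile
#'
#' A profile is one sample's deconvolved CE-MS peptide list: one row per
#' detected peptide with its monoisotopic mass (Da), CE migration time
#' (min) and signal amplitude (arbitrary units).
#'
#' @param local_id observation identifiers, unique within the profile
#' @param mass_da monoisotopic masses in Da, all positive
#' @param migration_min CE migration times in minutes, all positive
#' @param amplitude signal amplitudes, all non-negative
#' @return a `data.frame` of class `peptide_profile`
#' @export
peptide_profile <- function(local_id, mass_da, migration_min, amplitude) {
  if (anyDuplicated(local_id))
    stop("duplicate local_id in profile: ",
         paste(unique(local_id[duplicated(local_id)]), collapse = ", "))
  if (any(mass_da <= 0)) stop("mass_da must be positive")
  if (any(migration_min <= 0)) stop("migration_min must be positive")
  if (any(amplitude < 0)) stop("amplitude must be non-negative")
  out <- data.frame(local_id = as.character(local_id),
                    mass_da = as.numeric(mass_da),
                    migration_min = as.numeric(migration_min),
                    amplitude = as.numeric(amplitude),
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_profile", "data.frame")
  out
}

#' Read a per-sample peptide list
#'
#' Expects a tab-separated file with a header naming the columns
#' `id`, `mass`, `migration_time`, `amplitude`.  Masses may be given in
#' kDa (set `mass_unit = "kda"`); they are stored in Da internally.
#'
#' @param path file path
#' @param mass_unit `"da"` (default) or `"kda"`
#' @return a [peptide_profile()]
#' @export
read_peptide_profile <- function(path, mass_unit = c("da", "kda")) {
  mass_unit <- match.arg(mass_unit)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("id", "mass", "migration_time", "amplitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  mass <- df$mass
  if (mass_unit == "kda") mass <- mass * 1000
  bad <- which(mass <= 0 | df$amplitude < 0)
  if (length(bad))
    stop("validation error: non-positive mass or negative amplitude at line ",
         bad[1] + 1L, " of ", path)
  peptide_profile(df$id, mass, df$migration_time, df$amplitude)
}

#' Write a peptide profile in the pipeline's TSV dialect
#'
#' @param profile a [peptide_profile()]
#' @param path output path
#' @export
write_peptide_profile <- function(profile, path) {
  lines <- c("id\tmass\tmigration_time\tamplitude",
             paste(profile$local_id,
                   .fmt_mass(profile$mass_da),
                   .fmt_time(profile$migration_min),
                   .fmt_amp(profile$amplitude),
                   sep = "\t"))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Construct a cohort design
#'
#' Maps each sample to an age group and a treatment.  The age-group
#' ordering (young to old) must be explicit: it drives the pairwise
#' comparisons and the poles of the age score.
#'
#' @param sample_id unique sample identifiers
#' @param age_group age-group label per sample
#' @param treatment treatment label per sample (default a single
#'   `"control"` arm)
#' @param age_levels age-group labels in increasing age order; defaults
#'   to order of first appearance
#' @return a `data.frame` of class `cohort_design` with an
#'   `age_levels` attribute
#' @export
cohort_design <- function(sample_id, age_group,
                          treatment = rep("control", length(sample_id)),
                          age_levels = unique(as.character(age_group))) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  age_group <- as.character(age_group)
  unknown <- setdiff(age_group, age_levels)
  if (length(unknown))
    stop("unknown age label(s): ", paste(unique(unknown), collapse = ", "))
  treatment <- as.character(treatment)
  out <- data.frame(sample_id = sample_id,
                    age_group = factor(age_group, levels = age_levels),
                    # levels in order of first appearance: the first arm
                    # declared (normally the untreated control) is the
                    # default training/screening arm downstream
                    treatment = factor(treatment, levels = unique(treatment)),
                    stringsAsFactors = FALSE)
  attr(out, "age_levels") <- age_levels
  class(out) <- c("cohort_design", "data.frame")
  out
}

#' Read a cohort design table
#'
#' Tab-separated with columns `sample`, `age_group` and optionally
#' `treatment`; a missing treatment column yields a single default
#' `"control"` arm.
#'
#' @param path file path
#' @param age_levels explicit age ordering; defaults to order of first
#'   appearance in the file
#' @return a [cohort_design()]
#' @export
read_cohort_design <- function(path, age_levels = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("sample", "age_group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  trt <- if ("treatment" %in% names(df)) df$treatment
         else rep("control", nrow(df))
  if (is.null(age_levels)) age_levels <- unique(as.character(df$age_group))
  cohort_design(df$sample, df$age_group, trt, age_levels = age_levels)
}

#' Write a cohort design table
#' @param design a [cohort_design()]
#' @param path output path
#' @export
write_cohort_design <- function(design, path) {
  lines <- c("sample\tage_group\ttreatment",
             paste(design$sample_id, as.character(design$age_group),
                   as.character(design$treatment), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a matched master-peptide matrix
#'
#' Master peptides (consensus mass/migration time) by samples, with
#' explicit missingness (`NA` amplitude where a sample did not yield an
#' observation for a master peptide).  Consensus coordinates conform to
#' the file dialect: mass rounded to 4 decimals (0.1 mDa, far below any
#' matching tolerance), migration time to 2.
#'
#' @param peptides `data.frame` with columns `master_id` (integer),
#'   `mass_da`, `migration_min`
#' @param amplitude numeric matrix, rows = master peptides, columns =
#'   samples; `NA` marks missing cells
#' @param sample_ids column (sample) identifiers
#' @return an object of class `matched_matrix`
#' @export
matched_matrix <- function(peptides, amplitude, sample_ids = colnames(amplitude)) {
  amplitude <- as.matrix(amplitude)
  if (nrow(peptides) != nrow(amplitude))
    stop("peptides and amplitude row counts differ")
  if (length(sample_ids) != ncol(amplitude))
    stop("sample_ids length does not match amplitude columns")
  peptides$master_id <- as.integer(peptides$master_id)
  peptides$mass_da <- round(peptides$mass_da, 4)
  peptides$migration_min <- round(peptides$migration_min, 2)
  rownames(amplitude) <- as.character(peptides$master_id)
  colnames(amplitude) <- as.character(sample_ids)
  structure(list(peptides = peptides, amplitude = amplitude,
                 sample_ids = as.character(sample_ids)),
            class = "matched_matrix")
}

#' @export
print.matched_matrix <- function(x, ...) {
  cat("matched_matrix:", nrow(x$amplitude), "master peptides x",
      ncol(x$amplitude), "samples;",
      sum(is.na(x$amplitude)), "missing cells\n")
  invisible(x)
}

#' @export
dim.matched_matrix <- function(x) dim(x$amplitude)

#' Write / read a matched matrix
#'
#' TSV with columns `master_id`, `mass_da`, `migration_min` followed by
#' one amplitude column per sample (`NA` = missing).  `read` after
#' `write` reproduces the object field for field, including the
#' missingness pattern.
#'
#' @param m a [matched_matrix()]
#' @param path file path
#' @export
write_matched_matrix <- function(m, path) {
  hdr <- paste(c("master_id", "mass_da", "migration_min", m$sample_ids),
               collapse = "\t")
  rows <- vapply(seq_len(nrow(m$peptides)), function(i) {
    paste(c(m$peptides$master_id[i],
            .fmt_mass(m$peptides$mass_da[i]),
            .fmt_time(m$peptides$migration_min[i]),
            .fmt_amp(m$amplitude[i, ])), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_matched_matrix
#' @export
read_matched_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) > 1)
    stop("format error: ragged rows in ", path)
  hdr <- fields[[1]]
  if (!identical(hdr[1:3], c("master_id", "mass_da", "migration_min")))
    stop("format error: unexpected header in ", path)
  samples <- hdr[-(1:3)]
  n <- length(lines) - 1L
  if (n == 0) {
    return(matched_matrix(
      data.frame(master_id = integer(0), mass_da = numeric(0),
                 migration_min = numeric(0)),
      matrix(numeric(0), 0, length(samples),
             dimnames = list(NULL, samples)),
      sample_ids = samples))
  }
  body <- do.call(rbind, fields[-1])
  amp <- matrix(suppressWarnings(as.numeric(body[, -(1:3), drop = FALSE])),
                nrow = n, dimnames = list(NULL, samples))
  matched_matrix(
    data.frame(master_id = as.integer(body[, 1]),
               mass_da = as.numeric(body[, 2]),
               migration_min = as.numeric(body[, 3])),
    amp, sample_ids = samples)
}
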
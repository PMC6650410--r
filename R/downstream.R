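# Closed-form renal quantifications and the group-comparison statistics
# used downstream of the peptidome pipeline.

#' Stereological glomerular volume (Weibel)
#'
#' Converts a 2-D glomerular profile area to an estimated volume,
#' `V = A^1.5 * 1.38 / 1.01` (sphere shape coefficient 1.38, size
#' distribution coefficient 1.01).
#'
#' @param area_um2 profile area(s), um^2, non-negative
#' @return volume(s), um^3
#' @export
glomerular_volume <- function(area_um2) {
  if (any(area_um2 < 0)) stop("area must be non-negative")
  area_um2^1.5 * 1.38 / 1.01
}

#' Per-animal glomerular volume summary
#'
#' One value per animal from all glomerular profiles on a slide.  The
#' default aggregates as the mean of per-glomerulus volumes; the
#' alternative applies the volume formula to the mean area.
#'
#' @param areas_um2 profile areas of one slide
#' @param aggregate `"mean_of_volumes"` (default) or `"volume_of_mean"`
#' @return scalar volume, um^3
#' @export
mean_glomerular_volume <- function(areas_um2,
                                   aggregate = c("mean_of_volumes",
                                                 "volume_of_mean")) {
  aggregate <- match.arg(aggregate)
  switch(aggregate,
         mean_of_volumes = mean(glomerular_volume(areas_um2)),
         volume_of_mean = glomerular_volume(mean(areas_um2)))
}

#' qPCR relative expression with genomic-contamination correction
#'
#' `2^(ct_gapdh - ct_gene) * (1 - 1/2^(ct_rt_minus - ct_gene))`.  The
#' no-reverse-transcriptase control `ct_rt_minus` quantifies genomic-DNA
#' contamination; when absent (`NA`) the bracket factor is 1 (pure
#' delta-Ct).  `ct_rt_minus = ct_gene` means the entire signal is
#' contamination and the expression is 0.
#'
#' @param ct_gene gene cycle threshold(s)
#' @param ct_gapdh reference-gene (GAPDH) cycle threshold(s)
#' @param ct_rt_minus RT- control Ct, `NA` for no detectable
#'   contamination; must be >= `ct_gene`
#' @return relative expression, dimensionless
#' @export
qpcr_expression <- function(ct_gene, ct_gapdh, ct_rt_minus = NA_real_) {
  if (any(c(ct_gene, ct_gapdh, ct_rt_minus[!is.na(ct_rt_minus)]) <= 0))
    stop("all Ct values must be positive")
  if (any(!is.na(ct_rt_minus) & ct_rt_minus < ct_gene))
    stop("ct_rt_minus < ct_gene: contamination cannot exceed signal")
  bracket <- ifelse(is.na(ct_rt_minus), 1,
                    1 - 1 / 2^(ct_rt_minus - ct_gene))
  2^(ct_gapdh - ct_gene) * bracket
}

#' Urinary albumin / creatinine ratio
#'
#' @param albumin_mg_per_l urinary albumin, mg/L
#' @param creatinine_g_per_l urinary creatinine, g/L (> 0)
#' @return ratio in mg/g
#' @export
albumin_creatinine_ratio <- function(albumin_mg_per_l, creatinine_g_per_l) {
  if (any(creatinine_g_per_l <= 0)) stop("creatinine must be positive")
  albumin_mg_per_l / creatinine_g_per_l
}

#' Stained area fraction
#'
#' Percentage of a reference area occupied by staining (e.g. fibrotic
#' fraction of the glomerular or tubular area).
#'
#' @param stained_area stained area (same units as `reference_area`)
#' @param reference_area total reference area (> 0)
#' @return percent
#' @export
area_fraction <- function(stained_area, reference_area) {
  if (any(reference_area <= 0)) stop("reference area must be positive")
  if (any(stained_area < 0)) stop("stained area must be non-negative")
  if (any(stained_area > reference_area))
    stop("stained area exceeds reference area")
  100 * stained_area / reference_area
}

.p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Two-way ANOVA with Tukey post test
#'
#' Two-factor ANOVA (age x treatment) with interaction.  Sums of squares
#' are Type II for unbalanced data (equal to the classical sequential
#' decomposition when the design is balanced), followed by Tukey HSD
#' over the cell means using the studentized-range distribution.
#' Significance flags follow the `*` < 0.05, `**` < 0.01, `***` < 0.001
#' convention.  A response with zero residual variance yields F = 0 and
#' p = 1 by convention.
#'
#' @param values numeric response
#' @param age_labels,treatment_labels factor labels per observation;
#'   every age x treatment cell must be non-empty
#' @param alpha significance level for the Tukey flags (default 0.05)
#' @return list of class `anova_tukey`: `table` (SS, df, F, p per factor
#'   plus residual), `tukey` (pairwise cell contrasts), `alpha`
#' @export
two_way_anova_tukey <- function(values, age_labels, treatment_labels,
                                alpha = 0.05) {
  age <- factor(age_labels)
  trt <- factor(treatment_labels)
  cells <- table(age, trt)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: age ", rownames(cells)[empty[1]],
         " x treatment ", colnames(cells)[empty[2]])
  }
  if (nlevels(age) < 2 || nlevels(trt) < 2)
    stop("need >= 2 levels per factor")
  df <- data.frame(y = values, age = age, trt = trt)

  if (stats::var(values) == 0) {
    tab <- data.frame(
      term = c("age", "treatment", "age:treatment", "residual"),
      sum_sq = 0,
      df = c(nlevels(age) - 1, nlevels(trt) - 1,
             (nlevels(age) - 1) * (nlevels(trt) - 1),
             length(values) - nlevels(age) * nlevels(trt)),
      F = c(0, 0, 0, NA), p = c(1, 1, 1, NA))
    tk <- data.frame(contrast = character(0), diff = numeric(0),
                     lwr = numeric(0), upr = numeric(0),
                     p_adj = numeric(0), flag = character(0))
    return(structure(list(table = tab, tukey = tk, alpha = alpha),
                     class = "anova_tukey"))
  }

  fit <- stats::lm(y ~ age * trt, data = df)
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) e)
  if (inherits(a2, "error")) {
    # an (almost) perfect fit: Type-II refuses a zero residual SS; the
    # sequential decomposition is identical here on balanced data and
    # well-defined either way
    a1 <- suppressWarnings(stats::anova(fit))  # perfect-fit warning is the point here
    a2 <- a1[c("age", "trt", "age:trt", "Residuals"), ]
  }
  rows <- c("age", "trt", "age:trt", "Residuals")
  tab <- data.frame(
    term = c("age", "treatment", "age:treatment", "residual"),
    sum_sq = a2[rows, "Sum Sq"],
    df = a2[rows, "Df"],
    F = c(a2[rows[1:3], "F value"], NA),
    p = c(a2[rows[1:3], "Pr(>F)"], NA))
  bad <- is.na(tab$F[1:3]) | is.nan(tab$F[1:3])
  tab$F[1:3][bad] <- 0
  tab$p[1:3][bad] <- 1
  rownames(tab) <- NULL

  cell <- interaction(age, trt, sep = ":")
  tk_fit <- stats::TukeyHSD(stats::aov(y ~ cell,
                                       data = data.frame(y = values,
                                                         cell = cell)))
  tkm <- tk_fit$cell
  tk <- data.frame(contrast = rownames(tkm), diff = tkm[, "diff"],
                   lwr = tkm[, "lwr"], upr = tkm[, "upr"],
                   p_adj = tkm[, "p adj"],
                   flag = .p_stars(tkm[, "p adj"]),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, tukey = tk, alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("Two-way ANOVA (Type II SS) with Tukey post test\n")
  tab <- x$table
  tab$p <- ifelse(is.na(tab$p), "", paste0(format.pval(tab$p, digits = 3),
                                           " ", .p_stars(tab$p)))
  print(tab, row.names = FALSE)
  sig <- x$tukey[x$tukey$p_adj < x$alpha, , drop = FALSE]
  cat("Tukey contrasts below alpha =", x$alpha, ":", nrow(sig), "\n")
  if (nrow(sig)) print(sig, row.names = FALSE)
  invisible(x)
}

#' Validate a peptide sequence annotation
#'
#' Checks that the stated stop residue position equals
#' `start + residue_count - 1`, where modified residues written as
#' single lowercase letters (e.g. hydroxyproline `p`, oxidized
#' methionine `m`) count as one residue each.
#'
#' @param sequence residue string
#' @param start_aa stated start position (>= 1)
#' @param stop_aa stated stop position
#' @return list with `computed_stop` and `consistent`
#' @export
validate_annotation <- function(sequence, start_aa, stop_aa) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  if (any(start_aa < 1)) stop("start_aa must be >= 1")
  computed <- start_aa + nchar(sequence) - 1L
  list(computed_stop = computed, consistent = computed == stop_aa)
}

#' Load the packaged aging-peptide sequence annotations
#'
#' The 12 sequenced peptides of the 40-peptide mouse aging panel
#' (fragment sequence, protein accession and name, start/stop residue
#' positions), shipped as a plain TSV fixture.
#'
#' @return data.frame with columns `peptide_id`, `sequence`,
#'   `accession`, `protein_name`, `start_aa`, `stop_aa`
#' @export
aging_peptide_annotations <- function() {
  path <- system.file("extdata", "aging_peptide_annotations.tsv",
                      package = "pepage", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
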
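# Per-peptide two-group screening: tie-corrected standardized Wilcoxon
# rank-sum statistic, Westfall-Young maxT step-down permutation
# adjustment, and consensus selection across the pairwise age
# comparisons.  The permutation stream is shared across peptides within
# a comparison, which is what makes the maxT adjustment valid (it uses
# the joint permutation distribution of the statistics).

#' Tie-corrected standardized Wilcoxon rank-sum statistic
#'
#' Rank-sum of group `a` standardized with the tie-corrected variance;
#' `|Z|` is the base statistic of the maxT screen so peptides with
#' different missingness patterns remain comparable.  The two-sided
#' large-sample normal p value is returned alongside.
#'
#' @param a,b numeric vectors (missing values removed); >= 2 non-missing
#'   values per group required
#' @return list with `z` (|Z|), `z_signed` (positive when `b` tends
#'   larger), `p`
#' @export
wilcoxon_standardized <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 non-missing values per group")
  z <- .wilcox_z(c(a, b), seq_along(a))
  list(z = abs(z), z_signed = -z, p = 2 * stats::pnorm(-abs(z)))
}

# signed Z for the rank sum of x[idx_a]; positive when group a tends
# larger.  Returns 0 when the variance vanishes (all values tied).
.wilcox_z <- function(x, idx_a) {
  n <- length(x)
  n1 <- length(idx_a)
  n2 <- n - n1
  r <- rank(x)
  W <- sum(r[idx_a])
  E <- n1 * (n + 1) / 2
  tie <- table(x)
  Tcorr <- sum(tie^3 - tie)
  V <- n1 * n2 / 12 * ((n + 1) - Tcorr / (n * (n - 1)))
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

# Draw B permutations of group-a membership among n samples as an
# n x B 0/1 indicator matrix.  One stream per comparison, keyed only to
# (seed, n, n1), never to peptide content or row order.
.perm_indicators <- function(n, n1, B, seed) {
  set.seed(seed)
  P <- matrix(0L, n, B)
  for (b in seq_len(B)) P[sample.int(n, n1), b] <- 1L
  P
}

#' Westfall-Young maxT step-down adjustment for one group pair
#'
#' Orders peptides by decreasing observed `|Z|`; for each label
#' permutation computes the successive maxima of permuted `|Z|` over the
#' step-down peptide sets; the adjusted p of the i-th ordered peptide is
#' the fraction of permutations whose step-down max reaches its observed
#' `|Z|` (with +1 smoothing in numerator and denominator, so p is never
#' exactly 0), made monotone by a cumulative maximum down the ordering.
#' Raw p values are per-peptide permutation p values from the same
#' stream.
#'
#' @param matrix a [matched_matrix()] or a numeric matrix (rows = master
#'   peptides, rownames = master ids; `NA` = missing, dropped pairwise
#'   per peptide)
#' @param labels two-level factor/character vector, one per column
#' @param n_permutations Monte-Carlo permutations (>= 100)
#' @param seed RNG seed for the permutation stream
#' @param pair_label label stored in the result
#' @return data.frame of class `comparison_result`: `master_id`, `z`
#'   (|Z|), `z_signed` (positive = second group larger), `p_raw`,
#'   `p_adj`, `testable` (FALSE when a peptide had fewer than 2
#'   non-missing values in a group and therefore keeps Z = 0, p = 1),
#'   plus attributes `pair`, `n_permutations`, `seed`
#' @export
maxt_adjust <- function(matrix, labels, n_permutations = 10000, seed = 1L,
                        pair_label = NULL) {
  X <- if (inherits(matrix, "matched_matrix")) matrix$amplitude
       else as.matrix(matrix)
  if (nrow(X) < 1) stop("matrix has no peptides")
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) > 2)
    stop("more than two group labels; use pairwise_screen() for ",
         "multi-group designs")
  if (length(lev) < 2) stop("need two groups")
  if (min(table(labels)) < 2) stop("each group needs >= 2 samples")
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  if (is.null(pair_label)) pair_label <- paste(lev, collapse = " vs ")

  n <- ncol(X); m <- nrow(X)
  grp_a <- labels == lev[1]
  n1 <- sum(grp_a)

  ## per-peptide fixed quantities over its non-missing sample set;
  ## peptides with < 2 non-missing values in either group cannot be
  ## tested: they keep Z = 0, p = 1 and are flagged in `testable`
  S <- !is.na(X)                       # m x n observed indicator
  np <- rowSums(S)
  testable <- rowSums(S[, grp_a, drop = FALSE]) >= 2 &
    rowSums(S[, !grp_a, drop = FALSE]) >= 2
  R <- matrix(0, m, n)                 # within-peptide ranks, 0 at NA
  Tcorr <- numeric(m)
  for (i in seq_len(m)) {
    v <- X[i, S[i, ]]
    R[i, S[i, ]] <- rank(v)
    tie <- table(v)
    Tcorr[i] <- sum(tie^3 - tie)
  }
  np[!testable] <- 4  # benign placeholder; Z rows are zeroed below

  z_of <- function(A) {                # A: n x B indicator of group a
    W <- R %*% A
    N1 <- (S * 1) %*% A
    N2 <- np - N1
    E <- N1 * (np + 1) / 2
    V <- N1 * N2 / 12 * ((np + 1) - Tcorr / (np * (np - 1)))
    Z <- (W - E) / sqrt(pmax(V, .Machine$double.eps))
    Z[V <= 0] <- 0
    Z[!testable, ] <- 0
    Z
  }

  z_obs_signed <- drop(z_of(cbind(as.integer(grp_a))))
  z_obs <- abs(z_obs_signed)

  P <- .perm_indicators(n, n1, n_permutations, seed)
  Zp <- abs(z_of(P))                   # m x B

  eps <- 1e-9
  p_raw <- (1 + rowSums(Zp >= z_obs - eps)) / (n_permutations + 1)

  ids <- if (!is.null(rownames(X))) as.integer(rownames(X)) else seq_len(m)
  ord <- order(-z_obs, ids)
  q <- matrix(0, m, n_permutations)    # step-down successive maxima
  run <- rep(-Inf, n_permutations)
  for (i in m:1) {
    run <- pmax(run, Zp[ord[i], ])
    q[i, ] <- run
  }
  p_sd <- (1 + rowSums(q >= matrix(z_obs[ord], m, n_permutations) - eps)) /
    (n_permutations + 1)
  p_sd <- cummax(p_sd)                 # enforce step-down monotonicity
  p_adj <- numeric(m)
  p_adj[ord] <- p_sd

  out <- data.frame(master_id = ids, z = z_obs,
                    z_signed = -z_obs_signed,
                    p_raw = p_raw, p_adj = pmax(p_adj, p_raw),
                    testable = testable)
  attr(out, "pair") <- pair_label
  attr(out, "n_permutations") <- n_permutations
  attr(out, "seed") <- seed
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Selection rule for the consensus differential screen
#'
#' @param alpha significance level on the adjusted p (default 0.05)
#' @param min_comparisons number of pairwise comparisons a peptide must
#'   be significant in to enter the consensus set (default 2)
#' @return list of class `selection_rule`
#' @export
selection_rule <- function(alpha = 0.05, min_comparisons = 2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_comparisons < 1) stop("min_comparisons must be >= 1")
  structure(list(alpha = alpha, min_comparisons = min_comparisons),
            class = "selection_rule")
}

#' Pairwise differential screen with consensus selection
#'
#' Runs the maxT-adjusted Wilcoxon screen for every pair of age groups
#' (in the declared age order) and selects the peptides whose adjusted p
#' falls below `alpha` in at least `min_comparisons` of the pairs.  Each
#' pair gets its own deterministic permutation stream derived from
#' `seed`.
#'
#' @param matrix a [matched_matrix()]
#' @param design a [cohort_design()]; only the requested `treatment_arm`
#'   samples are screened
#' @param rule a [selection_rule()]
#' @param n_permutations permutations per comparison
#' @param seed base RNG seed
#' @param treatment_arm treatment label to screen within (default the
#'   first arm)
#' @return list of class `age_screen`: `comparisons` (named list of
#'   [maxt_adjust()] results), `selected` (consensus master ids),
#'   `per_pair_significant`, `rule`
#' @export
pairwise_screen <- function(matrix, design, rule = selection_rule(),
                            n_permutations = 10000, seed = 1L,
                            treatment_arm = levels(design$treatment)[1]) {
  ages <- attr(design, "age_levels")
  if (length(ages) < 2) stop("need >= 2 age groups to screen")
  keep <- design$treatment == treatment_arm
  pairs <- utils::combn(ages, 2, simplify = FALSE)
  if (rule$min_comparisons > length(pairs))
    stop("min_comparisons exceeds the number of pairwise comparisons")
  comparisons <- list()
  sig <- list()
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    sel <- keep & design$age_group %in% pr
    sub <- matrix$amplitude[, design$sample_id[sel], drop = FALSE]
    res <- maxt_adjust(sub, as.character(design$age_group[sel]),
                       n_permutations = n_permutations,
                       seed = seed + k,
                       pair_label = paste(pr, collapse = " vs "))
    nm <- paste(pr, collapse = "_vs_")
    comparisons[[nm]] <- res
    sig[[nm]] <- res$master_id[res$p_adj < rule$alpha]
  }
  counts <- table(unlist(sig))
  selected <- sort(as.integer(names(counts)[counts >= rule$min_comparisons]))
  structure(list(comparisons = comparisons, selected = selected,
                 per_pair_significant = sig, rule = rule,
                 seed = seed, n_permutations = n_permutations),
            class = "age_screen")
}

#' @export
print.age_screen <- function(x, ...) {
  cat("age_screen:", length(x$comparisons), "pairwise comparisons,",
      x$n_permutations, "permutations each\n")
  for (nm in names(x$per_pair_significant))
    cat("  ", nm, ":", length(x$per_pair_significant[[nm]]),
        "significant peptides\n")
  cat("consensus (>=", x$rule$min_comparisons, "comparisons):",
      length(x$selected), "peptides\n")
  invisible(x)
}

#' Write screen results (per-pair TSVs and the consensus list)
#' @param screen an `age_screen`
#' @param dir output directory (created if needed)
#' @export
write_screen_results <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(screen$comparisons)) {
    r <- screen$comparisons[[nm]]
    lines <- c("master_id\tz\tz_signed\tp_raw\tp_adj",
               sprintf("%d\t%.17g\t%.17g\t%.17g\t%.17g", r$master_id,
                       r$z, r$z_signed, r$p_raw, r$p_adj))
    writeLines(lines, file.path(dir, paste0(nm, ".tsv")))
  }
  writeLines(as.character(screen$selected),
             file.path(dir, "selected_peptides.txt"))
  invisible(dir)
}
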
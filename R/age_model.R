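# RBF-kernel SVM age score.  A single maximal-margin hyperplane is
# trained on the extreme age groups (youngest vs oldest); every sample,
# including groups never seen in training, is scored by its signed
# Euclidean distance to that hyperplane in the kernel feature space
# (decision value divided by the kernel-space norm of the weight
# vector), oriented so positive scores point to the older pole.

.rbf_kernel <- function(X, Y, gamma) {
  # exp(-gamma * ||x - y||^2), rows of X vs rows of Y
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' Assemble the classifier feature table
#'
#' Per sample, `log2(1 + amplitude)` over the panel peptides in panel
#' order; missing amplitudes are imputed as 0 *before* the transform
#' (an unobserved peptide and a zero-amplitude one are equivalent to the
#' classifier, unlike at the screening stage where missingness is kept
#' explicit).
#'
#' @param matrix a [matched_matrix()]
#' @param panel master peptide ids, in panel order
#' @param log2_transform apply `log2(1 + a)` (default TRUE); FALSE keeps
#'   raw zero-imputed amplitudes
#' @return numeric matrix, samples x panel peptides
#' @export
prepare_features <- function(matrix, panel, log2_transform = TRUE) {
  ids <- matrix$peptides$master_id
  miss <- setdiff(panel, ids)
  if (length(miss))
    stop("panel peptide(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  A <- matrix$amplitude[match(panel, ids), , drop = FALSE]
  A[is.na(A)] <- 0
  feat <- t(A)
  if (log2_transform) feat <- log2(1 + feat)
  colnames(feat) <- as.character(panel)
  rownames(feat) <- matrix$sample_ids
  feat
}

# Core soft-margin RBF fit via libsvm; returns the pieces needed to
# score without retraining.
.svm_core <- function(features, labels, C, gamma) {
  fit <- e1071::svm(x = features, y = labels,
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  sv <- fit$SV
  coefs <- as.numeric(fit$coefs)
  K <- .rbf_kernel(sv, sv, gamma)
  wnorm <- sqrt(max(drop(t(coefs) %*% K %*% coefs), .Machine$double.eps))
  list(sv = sv, coefs = coefs, rho = fit$rho, wnorm = wnorm, fit = fit)
}

.decision_values <- function(core, features, gamma) {
  drop(.rbf_kernel(features, core$sv, gamma) %*% core$coefs) - core$rho
}

#' Train the RBF-kernel SVM on a prepared feature table
#'
#' @param features samples x peptides matrix from [prepare_features()]
#' @param labels two-level factor (the extreme age groups); the *second*
#'   level is taken as the older pole
#' @param C soft-margin cost (default 3.2)
#' @param gamma RBF kernel width (default 0.008)
#' @param panel master ids of the feature columns (default from
#'   colnames)
#' @return an object of class `age_model`
#' @export
train_svm <- function(features, labels, C = 3.2, gamma = 0.008,
                      panel = as.integer(colnames(features))) {
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop("need exactly two classes, got ", nlevels(labels))
  if (all(features == 0)) stop("degenerate all-zero feature matrix")
  core <- .svm_core(features, labels, C, gamma)
  d <- .decision_values(core, features, gamma)
  old <- levels(labels)[2]
  flip <- if (mean(d[labels == old]) >= mean(d[labels != old])) 1 else -1
  structure(list(panel = panel, sv = core$sv, coefs = core$coefs,
                 rho = core$rho, wnorm = core$wnorm, sign = flip,
                 C = C, gamma = gamma,
                 levels = levels(labels),
                 preprocessing = list(missing_to_zero = TRUE,
                                      log2_transform = TRUE)),
            class = "age_model")
}

#' SVM classification score: signed distance to the hyperplane
#'
#' `score = sign * (sum_i alpha_i y_i K(x_i, x) + b) / ||w||` with
#' `||w||` the kernel-space norm of the weight vector computed from the
#' dual coefficients and the support-vector Gram matrix; units are
#' kernel-space margin widths: an unbounded support vector sits at
#' distance 1/||w|| from the hyperplane (decision value +-1).  Positive
#' = older pole.
#'
#' @param model an `age_model`
#' @param features feature matrix (samples x panel) or a single feature
#'   vector of panel length
#' @param raw return unscaled decision values instead (default FALSE)
#' @return numeric score per sample
#' @export
classification_score <- function(model, features, raw = FALSE) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model$panel))
    stop("feature dimension ", ncol(features),
         " does not match panel size ", length(model$panel))
  d <- .decision_values(model, features, model$gamma)
  if (raw) model$sign * d else model$sign * d / model$wnorm
}

# Deterministic CV fold assignment: leave-one-out when the smaller
# class has <= 15 samples, else stratified k-fold (seeded).
.make_folds <- function(labels, cv, seed) {
  n <- length(labels)
  min_class <- min(table(labels))
  if (identical(cv, "auto")) cv <- if (min_class <= 15) "loo" else 5L
  if (identical(cv, "loo")) return(as.list(seq_len(n)))
  k <- as.integer(cv)
  if (k > min_class)
    stop("cv_folds (", k, ") exceeds the smaller class size (",
         min_class, ")")
  set.seed(seed)
  fold <- integer(n)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  split(seq_len(n), fold)
}

.cv_accuracy <- function(features, labels, folds, C, gamma) {
  correct <- 0L
  for (hold in folds) {
    tr <- setdiff(seq_along(labels), hold)
    if (nlevels(droplevels(labels[tr])) < 2) next
    fit <- e1071::svm(x = features[tr, , drop = FALSE],
                      y = droplevels(labels[tr]),
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, features[hold, , drop = FALSE])
    correct <- correct + sum(as.character(pred) ==
                               as.character(labels[hold]))
  }
  correct / length(labels)
}

#' Take-one-out panel reduction
#'
#' Greedy backward elimination: each round tentatively drops every
#' remaining peptide, evaluates cross-validated accuracy on the reduced
#' panel, and applies the best drop as long as CV accuracy does not
#' decrease (ties broken by dropping the lowest master id); stops when
#' every drop would strictly decrease CV accuracy or one peptide
#' remains.  CV folds are fixed once from `seed` so all candidate panels
#' are compared on identical splits.
#'
#' @param features full feature table (samples x all candidate peptides)
#' @param labels two-level factor
#' @param initial_panel starting master ids (>= 2)
#' @param C,gamma SVM hyperparameters
#' @param cv `"auto"` (LOO when the smaller class has <= 15 samples,
#'   else 5-fold stratified), `"loo"`, or an integer fold count
#' @param seed fold-assignment seed
#' @return an `age_model` retrained on the final panel, with attributes
#'   `cv_accuracy` and `elimination_trace`
#' @export
take_one_out_optimize <- function(features, labels, initial_panel,
                                  C = 3.2, gamma = 0.008,
                                  cv = "auto", seed = 1L) {
  if (length(initial_panel) < 2) stop("initial_panel must have >= 2 peptides")
  labels <- droplevels(as.factor(labels))
  panel <- sort(as.integer(initial_panel))
  folds <- .make_folds(labels, cv, seed)
  feat <- function(p) features[, as.character(p), drop = FALSE]
  acc <- .cv_accuracy(feat(panel), labels, folds, C, gamma)
  trace <- data.frame(dropped = NA_integer_, panel_size = length(panel),
                      cv_accuracy = acc)
  repeat {
    if (length(panel) <= 1) break
    cand_acc <- vapply(seq_along(panel), function(j)
      .cv_accuracy(feat(panel[-j]), labels, folds, C, gamma), numeric(1))
    best <- max(cand_acc)
    if (best < acc) break
    j <- which(cand_acc == best)[1]       # panel sorted: lowest id wins ties
    trace <- rbind(trace, data.frame(dropped = panel[j],
                                     panel_size = length(panel) - 1L,
                                     cv_accuracy = best))
    panel <- panel[-j]
    acc <- best
  }
  model <- train_svm(feat(panel), labels, C = C, gamma = gamma,
                     panel = panel)
  attr(model, "cv_accuracy") <- acc
  attr(model, "elimination_trace") <- trace
  model
}

#' Fit the urinary-peptidome age model
#'
#' The user-facing fitting interface: trains the RBF-SVM hyperplane on
#' the extreme age groups of one treatment arm (youngest vs oldest in
#' the declared age order), optionally reduced by the take-one-out
#' procedure, and stores everything needed to score new samples.
#'
#' @param matrix a [matched_matrix()]
#' @param design a [cohort_design()]
#' @param panel candidate master ids (normally the consensus set from
#'   [pairwise_screen()]); default all peptides in the matrix
#' @param C,gamma SVM hyperparameters (defaults 3.2 and 0.008)
#' @param reduce apply [take_one_out_optimize()] (default FALSE)
#' @param cv cross-validation spec for the reduction, see
#'   [take_one_out_optimize()]
#' @param seed seed for CV fold assignment
#' @param treatment_arm treatment label used for training (default the
#'   first arm)
#' @param log2_transform feature transform flag, see
#'   [prepare_features()]
#' @return an `age_model`; training metadata in attributes
#' @export
fit_age_model <- function(matrix, design, panel = NULL,
                          C = 3.2, gamma = 0.008, reduce = FALSE,
                          cv = "auto", seed = 1L,
                          treatment_arm = levels(design$treatment)[1],
                          log2_transform = TRUE) {
  ages <- attr(design, "age_levels")
  if (length(ages) < 2) stop("need >= 2 age groups")
  if (is.null(panel)) panel <- matrix$peptides$master_id
  if (!length(panel))
    stop("empty peptide panel: nothing survived selection; train on an ",
         "explicit panel or the full matrix (panel = NULL)")
  panel <- sort(as.integer(panel))
  extremes <- c(ages[1], ages[length(ages)])
  sel <- design$treatment == treatment_arm & design$age_group %in% extremes
  # fixed sample order => libsvm sees identical data regardless of the
  # caller's row order (determinism contract)
  sid <- sort(design$sample_id[sel])
  feats <- prepare_features(matrix, panel, log2_transform)[sid, , drop = FALSE]
  labels <- factor(as.character(design$age_group[match(sid, design$sample_id)]),
                   levels = extremes)
  model <- if (reduce)
    take_one_out_optimize(feats, labels, panel, C = C, gamma = gamma,
                          cv = cv, seed = seed)
  else
    train_svm(feats, labels, C = C, gamma = gamma, panel = panel)
  model$preprocessing$log2_transform <- log2_transform
  attr(model, "training_samples") <- sid
  model
}

#' Score every sample of a cohort
#'
#' Scores all samples of the matrix -- including age groups and
#' treatment arms never used in training -- and returns them grouped by
#' (age, treatment).
#'
#' @param model an `age_model`
#' @param matrix a [matched_matrix()] containing the panel peptides
#' @param design a [cohort_design()] covering the matrix samples
#' @param raw report unscaled decision values (default FALSE)
#' @return data.frame: `sample_id`, `age_group`, `treatment`, `score`
#' @export
score_cohort <- function(model, matrix, design, raw = FALSE) {
  feats <- prepare_features(matrix, model$panel,
                            model$preprocessing$log2_transform)
  sc <- classification_score(model, feats, raw = raw)
  i <- match(rownames(feats), design$sample_id)
  out <- data.frame(sample_id = rownames(feats),
                    age_group = design$age_group[i],
                    treatment = design$treatment[i],
                    score = sc, stringsAsFactors = FALSE)
  out[order(out$age_group, out$treatment, out$sample_id), ]
}

#' @export
predict.age_model <- function(object, matrix, design = NULL, raw = FALSE,
                              ...) {
  if (is.null(design))
    return(classification_score(object,
                                prepare_features(matrix, object$panel,
                                  object$preprocessing$log2_transform),
                                raw = raw))
  score_cohort(object, matrix, design, raw = raw)
}

#' @export
print.age_model <- function(x, ...) {
  cat("age_model: RBF-SVM age score\n")
  cat("  panel:", length(x$panel), "peptides; support vectors:",
      nrow(x$sv), "\n")
  cat("  C =", x$C, " gamma =", x$gamma, "\n")
  cat("  poles:", x$levels[1], "(-) ->", x$levels[2], "(+)\n")
  if (!is.null(attr(x, "cv_accuracy")))
    cat("  CV accuracy:", round(attr(x, "cv_accuracy"), 3), "\n")
  invisible(x)
}

#' @export
summary.age_model <- function(object, ...) {
  print(object)
  cat("  kernel-space |w| =", format(object$wnorm), "\n")
  cat("  dual coefficient range: [",
      format(min(object$coefs)), ", ", format(max(object$coefs)), "]\n",
      sep = "")
  tr <- attr(object, "elimination_trace")
  if (!is.null(tr)) {
    cat("  take-one-out trace:\n")
    print(tr, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.age_model <- function(object, ...) {
  stats::setNames(object$coefs, rep("alpha_y", length(object$coefs)))
}

#' Score distribution by age group
#'
#' Boxplot of classification scores grouped by age (and treatment when
#' more than one arm is present) -- the visual check that the score
#' separates the ages and tracks any treatment shift.
#'
#' @param x an `age_model`
#' @param matrix,design cohort to score
#' @param ... passed to [graphics::boxplot()]
#' @export
plot.age_model <- function(x, matrix, design, ...) {
  sc <- score_cohort(x, matrix, design)
  grp <- if (nlevels(sc$treatment) > 1)
    interaction(sc$age_group, sc$treatment, sep = "/")
  else sc$age_group
  graphics::boxplot(sc$score ~ grp, xlab = "group",
                    ylab = "SVM age score (margin widths)", ...)
  invisible(sc)
}

#' Serialize / load an age model (JSON text schema)
#'
#' Stores the panel, support vectors, dual coefficients, bias, sign,
#' kernel-space weight norm, hyperparameters and preprocessing flags at
#' full precision.
#'
#' @param model an `age_model`
#' @param path file path
#' @export
write_age_model <- function(model, path) {
  obj <- list(panel = model$panel, sv = model$sv, coefs = model$coefs,
              rho = model$rho, wnorm = model$wnorm, sign = model$sign,
              C = model$C, gamma = model$gamma, levels = model$levels,
              preprocessing = model$preprocessing)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(panel = as.integer(obj$panel),
                 sv = as.matrix(obj$sv), coefs = as.numeric(obj$coefs),
                 rho = obj$rho, wnorm = obj$wnorm, sign = obj$sign,
                 C = obj$C, gamma = obj$gamma, levels = obj$levels,
                 preprocessing = obj$preprocessing),
            class = "age_model")
}
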
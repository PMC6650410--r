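test_that("feature preparation imputes missing as zero before log2", {
  vals <- matrix(c(0, 1, NA, 3, 7, 15), nrow = 2, byrow = TRUE)
  m <- toy_matrix(vals)
  f <- prepare_features(m, panel = c(1, 2))
  expect_equal(dim(f), c(3L, 2L))
  # peptide 1 amplitudes: 0, 1, NA across s1..s3; peptide 2: 3, 7, 15
  expect_equal(f["s1", "1"], 0)          # amplitude 0 -> 0
  expect_equal(f["s2", "1"], 1)          # log2(1+1)
  expect_equal(f["s3", "1"], 0)          # missing -> 0
  expect_equal(unname(f[, "2"]), c(2, 3, 4))  # log2(1+a)
  expect_error(prepare_features(m, panel = c(1, 9)), "9")
})

test_that("features survive a matrix I/O round trip unchanged", {
  set.seed(30)
  vals <- matrix(rlnorm(6), 2, 3)
  vals[1, 2] <- NA
  m <- toy_matrix(vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matched_matrix(m, path)
  expect_equal(prepare_features(read_matched_matrix(path), c(1, 2)),
               prepare_features(m, c(1, 2)))
})

test_that("the two-point toy is symmetric and the midpoint scores zero", {
  f <- matrix(c(0, 1), ncol = 1, dimnames = list(c("a", "b"), "1"))
  lab <- factor(c("young", "old"), levels = c("young", "old"))
  mod <- train_svm(f, lab, C = 10, gamma = 1)
  expect_equal(nrow(mod$sv), 2L)         # both points are support vectors
  s <- unname(classification_score(mod, f))
  expect_equal(s[1], -s[2], tolerance = 1e-8)
  expect_lt(s[1], 0)                      # young pole negative
  expect_equal(classification_score(mod, matrix(0.5)), 0,
               tolerance = 1e-8)
})

test_that("an unbounded support vector sits one margin from the plane", {
  set.seed(31)
  f <- matrix(c(rnorm(8, 0, .1), rnorm(8, 3, .1)), ncol = 1,
              dimnames = list(sprintf("x%02d", 1:16), "1"))
  lab <- factor(rep(c("young", "old"), each = 8),
                levels = c("young", "old"))
  mod <- train_svm(f, lab, C = 100, gamma = 0.5)
  unbounded <- abs(mod$coefs) < 100 - 1e-6
  expect_true(any(unbounded))
  # KKT: unbounded SVs have decision value +-1, i.e. |score| = 1/||w||
  d_sv <- classification_score(mod, mod$sv, raw = TRUE)
  expect_equal(unname(abs(d_sv[unbounded])),
               rep(1, sum(unbounded)), tolerance = 1e-3)
  sc_sv <- classification_score(mod, mod$sv)
  expect_equal(unname(abs(sc_sv[unbounded])),
               rep(1 / mod$wnorm, sum(unbounded)), tolerance = 1e-3)
})

test_that("the RBF kernel separates the XOR pattern", {
  f <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2,
              dimnames = list(c("a", "b", "c", "d"), c("1", "2")))
  lab <- factor(c("young", "old", "old", "young"),
                levels = c("young", "old"))
  mod <- train_svm(f, lab, C = 100, gamma = 2)
  s <- classification_score(mod, f)
  expect_identical(unname(s > 0), lab == "old")   # 4/4 training accuracy
})

test_that("stored-model scoring equals libsvm's own decision values", {
  set.seed(33)
  f <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(sprintf("s%02d", 1:40), as.character(1:5)))
  lab <- factor(rep(c("young", "old"), each = 20),
                levels = c("young", "old"))
  f[lab == "old", ] <- f[lab == "old", ] + 1
  mod <- train_svm(f, lab, C = 3.2, gamma = 0.008)
  fit <- e1071::svm(x = f, y = lab, type = "C-classification",
                    kernel = "radial", cost = 3.2, gamma = 0.008,
                    scale = FALSE)
  new <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, 1:5))
  mine <- classification_score(mod, new, raw = TRUE)
  libsvm <- attr(predict(fit, new, decision.values = TRUE),
                 "decision.values")[, 1]
  # orientation-free comparison: identical up to the stored sign
  expect_equal(mine, mod$sign * unname(libsvm), tolerance = 1e-8)
  expect_error(classification_score(mod, matrix(0, 1, 3)), "dimension")
})

test_that("model JSON serialization preserves scores exactly", {
  set.seed(34)
  f <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(sprintf("s%02d", 1:20), as.character(1:3)))
  lab <- factor(rep(c("young", "old"), 10), levels = c("young", "old"))
  f[lab == "old", 1] <- f[lab == "old", 1] + 2
  mod <- train_svm(f, lab)
  path <- withr::local_tempfile(fileext = ".json")
  write_age_model(mod, path)
  mod2 <- read_age_model(path)
  expect_equal(classification_score(mod2, f),
               classification_score(mod, f), tolerance = 1e-12)
  expect_identical(mod2$panel, mod$panel)
})

test_that("take-one-out eliminates pure noise and respects stop rules", {
  removed <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 13
    lab <- factor(rep(c("young", "old"), each = n),
                  levels = c("young", "old"))
    f <- cbind(c(rnorm(n, 0), rnorm(n, 5)), rnorm(2 * n))
    colnames(f) <- c("1", "2")
    mod <- take_one_out_optimize(f, lab, c(1, 2), C = 3.2, gamma = 0.5,
                                 seed = s)
    removed <- removed + identical(mod$panel, 1L)
    tr <- attr(mod, "elimination_trace")
    expect_true(all(diff(tr$panel_size) <= 0))          # never grows
    expect_true(all(tr$cv_accuracy >= tr$cv_accuracy[1])) # never worse
  }
  expect_gte(removed, 9L)
})

test_that("redundant copies are dropped without requiring improvement", {
  set.seed(40)
  n <- 10
  lab <- factor(rep(c("young", "old"), each = n),
                levels = c("young", "old"))
  x <- c(rnorm(n, 0), rnorm(n, 5))
  f <- cbind(x, x, x)
  colnames(f) <- c("1", "2", "3")
  mod <- take_one_out_optimize(f, lab, 1:3, C = 10, gamma = 0.5, seed = 1)
  tr <- attr(mod, "elimination_trace")
  expect_gt(nrow(tr), 1)                  # at least one equal-CV drop
  expect_lt(length(mod$panel), 3L)
  expect_gte(attr(mod, "cv_accuracy"), tr$cv_accuracy[1])
})

test_that("a size-2 panel is kept when dropping either member hurts", {
  set.seed(41)
  n <- 12
  lab <- factor(rep(c("young", "old"), each = n),
                levels = c("young", "old"))
  # XOR-style: each feature alone is useless, together they separate
  x1 <- c(rep(c(0, 1), n / 2), rep(c(0, 1), n / 2))
  x2 <- c(rep(c(0, 1), n / 2), rep(c(1, 0), n / 2))
  f <- cbind(x1 + rnorm(2 * n, 0, .05), x2 + rnorm(2 * n, 0, .05))
  colnames(f) <- c("1", "2")
  mod <- take_one_out_optimize(f, lab, c(1, 2), C = 100, gamma = 2,
                               seed = 2)
  expect_identical(mod$panel, c(1L, 2L))
  expect_error(take_one_out_optimize(f, lab, 1, seed = 1), ">= 2")
  expect_error(take_one_out_optimize(f, lab, c(1, 2), cv = 50, seed = 1),
               "class size")
})

test_that("cohort scoring is monotone in age and treatment-aware", {
  cf <- simulation_config(n_per_group = 8, n_master_peptides = 50,
                          n_affected = 10, effect_log2fc = 2,
                          treatments = c("control", "apelin"),
                          treated_like = "young", seed = 50)
  pipe <- run_small_pipeline(cf)
  panel <- pipe$matrix$peptides$master_id[
    pipe$truth_map %in% pipe$sim$truth$affected_ids]
  mod <- fit_age_model(pipe$matrix, pipe$sim$design, panel = panel,
                       seed = 3)
  sc <- score_cohort(mod, pipe$matrix, pipe$sim$design)
  expect_setequal(sc$sample_id, pipe$sim$design$sample_id)
  ctrl <- sc[sc$treatment == "control", ]
  mm <- tapply(ctrl$score, ctrl$age_group, mean)
  expect_lt(mm["young"], mm["middle"])    # middle sits between the poles
  expect_lt(mm["middle"], mm["old"])
  # training samples score on the correct side
  tr <- sc[sc$sample_id %in% attr(mod, "training_samples"), ]
  expect_true(all(tr$score[tr$age_group == "old"] > 0))
  expect_true(all(tr$score[tr$age_group == "young"] < 0))
  # the young-like treated-old arm scores below untreated old
  expect_lt(mean(sc$score[sc$treatment == "apelin" &
                            sc$age_group == "old"]),
            mean(sc$score[sc$treatment == "control" &
                            sc$age_group == "old"]))
})

test_that("training is invariant to sample order", {
  cf <- simulation_config(n_per_group = 6, n_master_peptides = 30,
                          n_affected = 6, seed = 55)
  pipe <- run_small_pipeline(cf)
  d1 <- pipe$sim$design
  perm <- sample(nrow(d1))
  d2 <- cohort_design(d1$sample_id[perm], as.character(d1$age_group)[perm],
                      as.character(d1$treatment)[perm],
                      age_levels = attr(d1, "age_levels"))
  m1 <- fit_age_model(pipe$matrix, d1, seed = 4)
  m2 <- fit_age_model(pipe$matrix, d2, seed = 4)
  expect_identical(m1$panel, m2$panel)
  expect_equal(m1$coefs, m2$coefs)
  expect_equal(classification_score(m1, prepare_features(pipe$matrix,
                                                         m1$panel)),
               classification_score(m2, prepare_features(pipe$matrix,
                                                         m2$panel)))
})

test_that("degenerate training inputs are refused", {
  f <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("1", "2")))
  expect_error(train_svm(f, factor(rep("young", 5))), "two classes")
  expect_error(train_svm(matrix(0, 4, 2,
                                dimnames = list(NULL, c("1", "2"))),
                         factor(rep(c("a", "b"), 2))), "all-zero")
  expect_error(train_svm(f, factor(rep(c("a", "b"), c(2, 3))), C = -1),
               "positive")
})
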
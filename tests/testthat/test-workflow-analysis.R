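synthetic_quality_table <- function(n_datasets = 108, seed = 1,
                                    beta = NULL) {
  # a full factorial quality table over the 36 executable workflows with a
  # known generating model, for regression tests
  specs <- enumerate_workflow_design(executable_only = TRUE)
  withr::with_seed(seed, {
    info <- data.frame(
      dataset_id = sprintf("ds%03d", seq_len(n_datasets)),
      species = rep_len(c("human", "mouse"), n_datasets),
      n_samples = sample(20:400, n_datasets, replace = TRUE),
      n_batches = sample(2:12, n_datasets, replace = TRUE))
    tab <- merge(info, specs[, c("normalization", "correction",
                                 "correlation")])
    if (is.null(beta))
      beta <- list(b0 = -0.1, bn = 0.3, bb = -0.03, mouse = 0.05,
                   UQ = 0.08, combat = 0.05, linear = 0.04,
                   spearman = -0.01)
    tab$quality <- with(tab, beta$b0 + beta$bn * log10(n_samples) +
      beta$bb * log10(n_batches) + beta$mouse * (species == "mouse") +
      beta$UQ * (normalization == "UQ") +
      beta$combat * (correction == "combat") +
      beta$linear * (correction == "linear") +
      beta$spearman * (correlation == "spearman") +
      rnorm(nrow(tab), 0, 0.02))
    tab
  })
}

test_that("the workflow design enumerates 50 descriptors, 36 executable", {
  design <- enumerate_workflow_design()
  expect_equal(nrow(design), 50)
  expect_equal(sum(design$executable), 36)
  expect_equal(nrow(unique(design)), 50)
  # normalization 'none' occurs only with the count-based correction
  expect_true(all(design$correction[design$normalization == "none"] ==
                    "combatseq"))
  expect_true(all(design$normalization[design$correction != "combatseq"] !=
                    "none"))
  expect_equal(nrow(enumerate_workflow_design(executable_only = TRUE)), 36)
})

test_that("the grid yields one row per dataset-workflow pair", {
  datasets <- list(); anns <- list()
  for (d in 1:2) {
    cfg <- sim_config(n_genes = 150, n_samples = 24, n_batches = 2,
                      n_modules = 3, module_size = 15,
                      n_terms_per_domain = 8, seed = 600 + d)
    sim <- generate_dataset(cfg)
    datasets[[paste0("d", d)]] <- sim$dataset
    anns[[paste0("d", d)]] <- generate_annotations(cfg, sim$truth)
  }
  specs <- expand.grid(normalization = c("UQ", "CPM"),
                       correction = "none",
                       correlation = c("pearson", "spearman"),
                       stringsAsFactors = FALSE)
  res <- run_workflow_grid(datasets, specs, anns, k = 30)
  expect_equal(nrow(res$measures), 8)
  expect_equal(nrow(res$failures), 0)
  expect_s3_class(res$quality, "quality_score_table")
  expect_setequal(unique(res$measures$dataset_id), c("d1", "d2"))
  # failures are recorded, not fatal: an all-zero sample breaks UQ
  bad <- datasets
  bad$d1$counts[, 1] <- 0
  res2 <- run_workflow_grid(bad, specs[specs$normalization == "UQ", ],
                            anns, k = 30)
  expect_equal(nrow(res2$failures), 2)
  expect_equal(nrow(res2$measures), 2)
})

test_that("train/validation splits are stratified, exact and seeded", {
  info <- data.frame(
    dataset_id = c(sprintf("h%02d", 1:68), sprintf("m%02d", 1:76)),
    species = rep(c("human", "mouse"), c(68, 76)))
  sp <- split_train_validation(info, 0.75, seed = 5)
  expect_equal(sum(startsWith(sp$train, "h")), 51)
  expect_equal(sum(startsWith(sp$train, "m")), 57)
  expect_setequal(c(sp$train, sp$validation), info$dataset_id)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_identical(sp, split_train_validation(info, 0.75, seed = 5))
  # near-unity fractions still leave a validation set
  tiny <- data.frame(dataset_id = c("a", "b", "c", "d"), species = "x")
  sp2 <- split_train_validation(tiny, 0.999, seed = 1)
  expect_length(sp2$train, 3)
  expect_length(sp2$validation, 1)
})

test_that("the quality model recovers exact linear structure", {
  tab <- synthetic_quality_table(24, seed = 3)
  tab$quality <- -0.1 + 0.3 * log10(tab$n_samples) +
    0.05 * (tab$correction == "combat")
  qm <- suppressWarnings(fit_quality_model(tab))  # exact fit is intended
  expect_equal(qm$r_squared, 1)
  co <- qm$coefficients
  expect_equal(co$estimate[co$term == "log10_samples"], 0.3)
  expect_equal(co$estimate[co$term == "correctioncombat"], 0.05)
  expect_equal(co$estimate[co$term == "correctionlinear"], 0,
               tolerance = 1e-10)
})

test_that("the full factorial model has the expected degrees of freedom", {
  tab <- synthetic_quality_table(108, seed = 4)
  expect_equal(nrow(tab), 3888)
  qm <- fit_quality_model(tab)
  expect_equal(nrow(qm$coefficients), 12)
  expect_equal(qm$df_residual, 3876)
  expect_equal(qm$coefficients$t_value,
               qm$coefficients$estimate / qm$coefficients$std_error)
  expect_equal(qm$coefficients$p_value,
               2 * pt(abs(qm$coefficients$t_value), 3876,
                      lower.tail = FALSE))
})

test_that("OLS matches an independent pseudo-inverse solve", {
  tab <- synthetic_quality_table(20, seed = 7)
  tab <- tab[withr::with_seed(7, sample(nrow(tab), 200)), ]
  qm <- fit_quality_model(tab)
  X <- model.matrix(qm$fit)
  sv <- svd(X)
  beta_pinv <- sv$v %*% (crossprod(sv$u, tab$quality) / sv$d)
  expect_lt(max(abs(qm$coefficients$estimate - beta_pinv)), 1e-8)
})

test_that("model fitting is invariant to row order", {
  tab <- synthetic_quality_table(12, seed = 9)
  qm1 <- fit_quality_model(tab)
  qm2 <- fit_quality_model(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(qm1$coefficients$estimate, qm2$coefficients$estimate)
})

test_that("equivalent sample change follows the log10 conversion", {
  expect_equal(equivalent_sample_change(0, 0.3), 0)
  expect_equal(equivalent_sample_change(0.3, 0.3), 900)
  expect_error(equivalent_sample_change(0.1, 0), "positive")
  expect_error(equivalent_sample_change(0.1, -1), "positive")
  # strictly increasing in beta, inverse identity holds
  beta <- seq(-0.2, 0.2, by = 0.01)
  pct <- equivalent_sample_change(beta, 0.29)
  expect_true(all(diff(pct) > 0))
  expect_equal(0.29 * log10(1 + pct / 100), beta)
})

test_that("cross-validation folds partition datasets and keep signs", {
  tab <- synthetic_quality_table(32, seed = 11)
  cv <- cross_validate(tab, n_folds = 4, seed = 2)
  expect_setequal(names(cv$folds), unique(tab$dataset_id))
  expect_equal(sort(unique(cv$folds)), 1:4)
  # injected signs recovered in every fold
  est <- cv$coefficients
  expect_true(all(est["log10_samples", ] > 0))
  expect_true(all(est["log10_batches", ] < 0))
  expect_true(all(est["correctioncombat", ] > 0))
  expect_true(cv$sign_consistent[["log10_samples"]])
  # quality driven only by sample count: folds agree closely
  tab2 <- synthetic_quality_table(32, seed = 12)
  tab2$quality <- 0.3 * log10(tab2$n_samples)
  cv2 <- suppressWarnings(cross_validate(tab2, n_folds = 4, seed = 2))
  expect_lt(max(abs(cv2$coefficients["log10_samples", ] - 0.3)), 1e-10)
})

test_that("workflow ranking counts above-average networks", {
  # dominant workflow: above average on every dataset
  qt <- expand.grid(dataset_id = c("a", "b", "c"),
                    normalization = c("UQ", "CPM", "Med"),
                    correction = "none", correlation = "pearson",
                    stringsAsFactors = FALSE)
  qt$quality <- ifelse(qt$normalization == "UQ", 0.9,
                       ifelse(qt$normalization == "CPM", 0.5, 0.1))
  rk <- rank_workflows(qt)
  expect_equal(rk$workflow[1], "UQ+none+pearson")
  expect_equal(rk$n_above_average[1], 3)
  expect_equal(rk$n_above_average[3], 0)
  # brute-force check of the full ranking on a random table
  qt2 <- qt
  qt2$quality <- withr::with_seed(3, runif(nrow(qt2)))
  rk2 <- rank_workflows(qt2)
  lbl <- paste(qt2$normalization, qt2$correction, qt2$correlation, sep = "+")
  brute_mean <- sort(tapply(qt2$quality, lbl, mean), decreasing = TRUE)
  expect_equal(rk2$workflow, names(brute_mean))
  expect_equal(rk2$mean_quality, as.vector(brute_mean))
  ds_means <- tapply(qt2$quality, qt2$dataset_id, mean)
  brute_above <- tapply(qt2$quality > ds_means[qt2$dataset_id], lbl, sum)
  expect_equal(rk2$n_above_average,
               as.vector(brute_above[rk2$workflow]))
  # ties: symmetric wins resolve by workflow label
  qt3 <- expand.grid(dataset_id = c("a", "b"),
                     normalization = c("UQ", "CPM"), correction = "none",
                     correlation = "pearson", stringsAsFactors = FALSE)
  qt3$quality <- c(0.8, 0.2, 0.2, 0.8)
  rk3 <- rank_workflows(qt3)
  expect_equal(rk3$workflow, c("CPM+none+pearson", "UQ+none+pearson"))
})

test_that("paired workflow comparison handles degenerate differences", {
  base <- expand.grid(dataset_id = sprintf("v%02d", 1:6),
                      normalization = c("Rlog", "UQ"),
                      correction = c("none", "combat"),
                      correlation = c("pearson", "spearman"),
                      stringsAsFactors = FALSE)
  base$n_samples <- rep(c(20, 50), 24)[seq_len(nrow(base))]
  base$n_samples <- ifelse(base$dataset_id %in% c("v01", "v02"), 20, 50)
  m0 <- random_measures(nrow(base), seed = 5)
  tab <- cbind(base, m0)
  # optimized = default + 0.1 everywhere
  cols <- quality_measure_columns()
  for (i in seq_len(nrow(tab))) {
    if (tab$normalization[i] == "UQ" && tab$correction[i] == "combat") {
      match_row <- which(tab$dataset_id == tab$dataset_id[i] &
                           tab$normalization == "Rlog" &
                           tab$correction == "none" &
                           tab$correlation == "pearson")
      tab[i, cols] <- tab[match_row, cols] + 0.1
    }
  }
  res <- compare_workflows_paired(tab, sprintf("v%02d", 1:6))
  expect_equal(res$n_improved, rep(6L, 8))
  expect_equal(res$p_value, rep(0, 8))        # zero-variance constant gain
  # identical workflows: no improvement, p = 1
  tab2 <- tab
  for (i in which(tab2$normalization == "UQ" & tab2$correction == "combat")) {
    match_row <- which(tab2$dataset_id == tab2$dataset_id[i] &
                         tab2$normalization == "Rlog" &
                         tab2$correction == "none" &
                         tab2$correlation == "pearson")
    tab2[i, cols] <- tab2[match_row, cols]
  }
  res2 <- compare_workflows_paired(tab2, sprintf("v%02d", 1:6))
  expect_equal(res2$n_improved, rep(0L, 8))
  expect_equal(res2$t_statistic, rep(0, 8))
  expect_true(all(res2$p_value == 1))
  expect_error(compare_workflows_paired(tab, c("v01", "v02")), "3 paired")
})

test_that("paired t statistics match the closed form", {
  base <- expand.grid(dataset_id = sprintf("v%02d", 1:5),
                      normalization = c("Rlog", "UQ"),
                      correction = c("none", "combat"),
                      correlation = "pearson", stringsAsFactors = FALSE)
  base$n_samples <- 50
  tab <- cbind(base, random_measures(nrow(base), seed = 8))
  res <- compare_workflows_paired(tab, sprintf("v%02d", 1:5))
  cols <- quality_measure_columns()
  for (j in seq_along(cols)) {
    d <- vapply(sprintf("v%02d", 1:5), function(id) {
      opt <- tab[tab$dataset_id == id & tab$normalization == "UQ" &
                   tab$correction == "combat", cols[j]]
      def <- tab[tab$dataset_id == id & tab$normalization == "Rlog" &
                   tab$correction == "none", cols[j]]
      opt - def
    }, numeric(1))
    t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(res$t_statistic[j], t_manual)
    expect_equal(res$p_value[j],
                 pt(t_manual, length(d) - 1, lower.tail = FALSE))
  }
})

test_that("the reference coefficient table carries the published layout", {
  ref <- reference_model_coefficients()
  expect_true(all(c("term", "estimate", "std_error", "t_value", "p_value")
                  %in% names(ref)))
  # printed t values agree with estimate/SE up to table rounding
  expect_lt(max(abs(ref$t_value - ref$estimate / ref$std_error)), 0.5)
  expect_equal(sign(ref$t_value), sign(ref$estimate))
})
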
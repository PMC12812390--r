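make_profile <- function(id, betas, group = "unknown") {
  structure(list(sample_id = id, platform = "nanopore", group = group,
                 betas = betas, coverage = NULL,
                 missing_probes = character(0)), class = "beta_profile")
}

test_that("centroid score hits its exact anchor points", {
  mat <- toy_beta_matrix(seed = 13)
  ps <- probe_set(rownames(mat$values), name = "sig", source_version = "v2")
  fit <- episign_fit(mat, ps, svm = FALSE)

  case_centroid <- fit$centroids[, "case"]
  ctrl_centroid <- fit$centroids[, "control"]

  at_case <- make_profile("at_case", case_centroid)
  expect_equal(predict(fit, at_case)$centroid_score, 1)
  expect_equal(predict(fit, at_case)$label, "positive")

  at_ctrl <- make_profile("at_ctrl", ctrl_centroid)
  expect_equal(predict(fit, at_ctrl)$centroid_score, -1)
  expect_equal(predict(fit, at_ctrl)$label, "negative")

  # exact midpoint scores 0 and the tie resolves to negative
  mid <- make_profile("mid", (case_centroid + ctrl_centroid) / 2)
  res <- predict(fit, mid)
  expect_equal(res$centroid_score, 0)
  expect_equal(res$label, "negative")
})

test_that("centroid score is anti-symmetric under label swap", {
  mat <- toy_beta_matrix(seed = 29)
  ps <- probe_set(rownames(mat$values), name = "sig", source_version = "v2")
  swapped <- mat
  swapped$samples$group <- ifelse(mat$samples$group == "case",
                                  "control", "case")
  set.seed(41)
  for (i in 1:10) {
    prof <- make_profile("q", setNames(runif(nrow(mat$values)),
                                       rownames(mat$values)))
    s1 <- centroid_classify(prof, mat, ps)$centroid_score
    s2 <- centroid_classify(prof, swapped, ps)$centroid_score
    expect_equal(s1, -s2, tolerance = 1e-12)
  }
})

test_that("classification enforces signature coverage", {
  mat <- toy_beta_matrix(n_probes = 20, seed = 3)
  ps <- probe_set(rownames(mat$values), name = "sig", source_version = "v2")
  fit <- episign_fit(mat, ps, svm = FALSE)
  partial <- make_profile("partial",
                          setNames(rep(0.5, 10), rownames(mat$values)[1:10]))
  expect_error(predict(fit, partial), "50%")
  ok <- make_profile("ok", setNames(rep(0.5, 19), rownames(mat$values)[1:19]))
  expect_equal(predict(fit, ok)$n_probes_used, 19)
})

test_that("model fitting validates labels and reports structure", {
  mat <- toy_beta_matrix(seed = 3)
  ctrl_only <- mat[, mat$samples$group == "control"]
  ps <- probe_set(rownames(mat$values), name = "sig", source_version = "v2")
  expect_error(episign_fit(ctrl_only, ps), "both 'case' and 'control'")

  fit <- episign_fit(mat, ps)
  expect_s3_class(fit, "episign_model")
  expect_output(print(fit), "nearest-centroid")
  cf <- coef(fit)
  expect_length(cf, nrow(mat$values))
  expect_gt(mean(cf), 0.1)  # recovers the injected positive shift

  expect_warning(
    episign_fit(mat, probe_set(c(rownames(mat$values), "ghost"),
                               name = "sig2", source_version = "v2")),
    "absent")
})

test_that("linearly separable classes give perfect SVM leave-one-out accuracy", {
  mat <- toy_beta_matrix(n_probes = 179, n_controls = 10, n_cases = 10,
                         delta = 0.2, noise_sd = 0.03, seed = 55)
  ps <- probe_set(rownames(mat$values), name = "sig", source_version = "v2")
  res <- svm_loo_validate(mat, ps)
  expect_equal(res$accuracy, 1.0)
  expect_true(all(res$predictions$margin[res$predictions$group == "case"] > 0))
  expect_true(all(res$predictions$margin[res$predictions$group == "control"] < 0))

  small <- mat[, c(1:10, 11:12)]  # 2 cases only
  expect_error(svm_loo_validate(small, ps), "3 samples per class")
})

test_that("centroid leave-one-out separates shifted cases from controls", {
  mat <- toy_beta_matrix(n_probes = 179, n_controls = 20, n_cases = 5,
                         delta = 0.15, seed = 61)
  ps <- probe_set(rownames(mat$values), name = "sig", source_version = "v2")
  loo <- centroid_loo(mat, ps)
  expect_equal(loo$label[loo$group == "case"], rep("positive", 5))
  expect_equal(loo$label[loo$group == "control"], rep("negative", 20))
  s <- summary(episign_fit(mat, ps))
  expect_equal(s$centroid_loo_accuracy, 1.0)
  expect_output(print(s), "leave-one-out")
})

test_that("specificity check flags only the probe set carrying the signature", {
  set.seed(71)
  n_probes <- 400
  ids <- sprintf("p%03d", seq_len(n_probes))
  target_ids <- sample(ids, 100)
  decoy_ids <- sample(setdiff(ids, target_ids), 100)
  mu <- pmin(pmax(rbeta(n_probes, 2, 2), 0.01), 0.99)
  samples <- data.frame(
    sample_id = c(sprintf("c%02d", 1:12), sprintf("k%02d", 1:5)),
    group = rep(c("control", "case"), c(12, 5)), platform = "array")
  vals <- vapply(seq_len(17), function(j) {
    shift <- if (samples$group[j] == "case") 0.2 * (ids %in% target_ids) else 0
    pmin(pmax(mu + shift + rnorm(n_probes, 0, 0.03), 0), 1)
  }, numeric(n_probes))
  dimnames(vals) <- list(ids, samples$sample_id)
  mat <- beta_matrix(vals, samples)

  res <- specificity_check(mat,
                           probe_set(target_ids, name = "target",
                                     source_version = "v2"),
                           list(probe_set(decoy_ids, name = "decoy",
                                          source_version = "v2")))
  expect_equal(res$set_name, c("target", "decoy"))
  expect_gt(res$silhouette[1], 0)
  expect_lt(res$silhouette[2], res$silhouette[1])

  # identical decoy triggers the overlap warning but still computes
  expect_warning(
    res2 <- specificity_check(mat,
                              probe_set(target_ids, name = "target",
                                        source_version = "v2"),
                              list(probe_set(target_ids, name = "copy",
                                             source_version = "v2"))),
    "overlap")
  expect_equal(nrow(res2), 2)
  expect_equal(res2$silhouette[1], res2$silhouette[2])
})
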
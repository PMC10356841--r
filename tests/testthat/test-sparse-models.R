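# log-potency-style design: lower x means more potent, causal effect is a
# negative coefficient, matching the retention rule.
make_logistic_fixture <- function(n = 500, p = 10, beta = -2, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  eta <- -1 + beta * x[, 1]
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y)
}

test_that("1-SE selection invariants hold", {
  f <- make_logistic_fixture(seed = 3)
  fit <- fit_1se_lasso(f$x, f$y, n_trials = 30, seed = 3)
  best <- fit$best_index; ch <- fit$chosen_index
  expect_gte(fit$cv_metric_mean[ch],
             fit$cv_metric_mean[best] - fit$cv_metric_se[best])
  expect_lte(ch, best)  # chosen penalty is at least as large as the best
  # deterministic given the seed
  fit2 <- fit_1se_lasso(f$x, f$y, n_trials = 30, seed = 3)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_error(fit_1se_lasso(f$x, rep(1, nrow(f$x))), "single class")
  expect_error(fit_1se_lasso(f$x[, 1, drop = FALSE], f$y), "two predictor")
})

test_that("a single causal variable is selected against noise", {
  hit <- logical(20); n_spurious <- integer(20)
  for (s in 1:20) {
    f <- make_logistic_fixture(n = 500, p = 10, beta = -2, seed = s)
    fit <- fit_1se_lasso(f$x, f$y, n_trials = 25, seed = s)
    keep <- interpret_coefficients(fit)$retained
    hit[s] <- identical(keep, "v1")
    # all-noise design: selection noise along the penalty path lets a
    # stray variable through occasionally, but the retained set is empty
    # in most seeds and small in the rest
    y0 <- rbinom(500, 1, 0.3)
    fit0 <- tryCatch(fit_1se_lasso(f$x, y0, n_trials = 25, seed = s),
                     error = function(e) NULL)
    n_spurious[s] <- if (is.null(fit0)) 0L else
      length(interpret_coefficients(fit0)$retained)
  }
  expect_gte(mean(hit), 0.9)
  expect_gte(mean(n_spurious == 0), 0.6)
  expect_lte(mean(n_spurious), 1)
})

test_that("duplicated causal columns retain exactly one member", {
  f <- make_logistic_fixture(n = 600, p = 4, beta = -2, seed = 11)
  x <- cbind(f$x, v1_copy = f$x[, 1])
  fit <- fit_1se_lasso(x, f$y, n_trials = 25, seed = 11)
  keep <- interpret_coefficients(fit)$retained
  expect_equal(length(intersect(keep, c("v1", "v1_copy"))), 1)
})

test_that("coefficient interpretation applies the -0.08 rule", {
  fit <- structure(list(coefficients = c(a = -0.5, b = -0.05, c = 0.2,
                                         d = -0.081)),
                   class = "sparse_fit")
  k <- interpret_coefficients(fit)
  expect_setequal(k$retained, c("a", "d"))
  expect_equal(k$zeroed_positive, "c")
  expect_equal(unname(k$coefficients["c"]), 0)
})

test_that("design assembly drops low-coverage assays and imputes medians", {
  vals <- rbind(
    data.frame(drug_id = sprintf("d%02d", 1:20), variable = "full",
               value = 10^runif(20)),
    data.frame(drug_id = sprintf("d%02d", 1:16), variable = "ok",
               value = 10^runif(16)),
    data.frame(drug_id = sprintf("d%02d", 1:10), variable = "sparse",
               value = 10^runif(10)))
  d <- assemble_design(vals, min_coverage = 0.7)
  expect_equal(d$dropped, "sparse")  # 10/20 = 50% coverage
  expect_equal(colnames(d$x), c("full", "ok"))
  expect_false(anyNA(d$x))
  # imputed entries equal the column median of observed values
  obs <- log10(vals$value[vals$variable == "ok"])
  expect_equal(unname(d$x[17:20, "ok"]), rep(median(obs), 4))
  expect_equal(unname(d$n_imputed["ok"]), 4)
  # complete matrix: imputation is the identity
  d2 <- assemble_design(vals[vals$variable == "full", ])
  expect_equal(unname(d2$x[, 1]), log10(vals$value[vals$variable == "full"]))
})

test_that("redundancy elimination keeps single candidates untouched", {
  cand <- data.frame(term_code = "t1", source = "SIDER",
                     assay_group_id = "g1", measure = "ac50")
  er <- eliminate_redundant(cand, data.frame(drug_id = "d1",
                                             assay_group_id = "g1",
                                             measure = "ac50", value = 1),
                            data.frame(source = "SIDER", term_code = "t1",
                                       drug_id = "d1", label = "pos"))
  expect_equal(er$pairs$status, "retained")
})

test_that("perfectly collinear planted assays keep one of the pair", {
  set.seed(21)
  n <- 400
  x1 <- rnorm(n)
  vals <- rbind(
    data.frame(drug_id = sprintf("d%03d", 1:n), assay_group_id = "gA",
               measure = "ac50", value = 10^x1),
    data.frame(drug_id = sprintf("d%03d", 1:n), assay_group_id = "gB",
               measure = "ac50", value = 10^x1))
  y <- rbinom(n, 1, plogis(-1 - 2 * x1))
  labels <- data.frame(source = "SIDER", term_code = "t1",
                       drug_id = sprintf("d%03d", 1:n),
                       label = ifelse(y == 1, "pos", "neg"))
  cand <- data.frame(term_code = "t1", source = "SIDER",
                     assay_group_id = c("gA", "gB"), measure = "ac50")
  er <- eliminate_redundant(cand, vals, labels, n_trials = 25, seed = 4)
  expect_equal(sort(er$pairs$status), c("eliminated", "retained"))
})

test_that("literature features summarize potency and ontology position", {
  h <- toy_hierarchy()
  v <- rep(30, 40)
  f <- featurize_literature_assoc(v, "PT01", h, n_pos = 12, n_neg = 100)
  expect_equal(unname(f["pctl_5"]), 30)  # fully censored assay
  expect_equal(unname(f["n_le_1uM"]), 0)
  expect_equal(unname(f["soc_SOC1"]), 1)
  v2 <- c(0.05, 0.3, 0.9, 5, rep(30, 10))
  f2 <- featurize_literature_assoc(v2, "PT01", h, 10, 50)
  expect_equal(unname(f2["n_le_0.1uM"]), sum(v2 <= 0.1))
  expect_equal(unname(f2["n_le_0.5uM"]), sum(v2 <= 0.5))
  expect_equal(unname(f2["n_le_1uM"]), sum(v2 <= 1))
  expect_equal(unname(f2["pctl_25"]),
               unname(quantile(v2, 0.25, type = 7)))
})

test_that("prior model recovers a separable feature and nulls out on
           permuted labels", {
  set.seed(31)
  n <- 300
  feat <- cbind(pctl_5 = c(rnorm(n / 2, -1), rnorm(n / 2, 2)),
                noise1 = rnorm(n), noise2 = rnorm(n))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  pm <- fit_prior_model(feat, labels, n_trials = 25, seed = 31)
  expect_gte(mean((pm$class == "likely_significant") == labels), 0.9)
  # identical features: majority class everywhere
  pm0 <- fit_prior_model(matrix(1, 20, 3), rep(c(TRUE, FALSE), c(5, 15)))
  expect_true(all(pm0$class == "likely_non_significant"))
  # label permutation: cross-validated AUC near chance
  aucs <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    fit <- fit_1se_lasso(feat, sample(as.integer(labels)),
                         n_trials = 20, seed = s)
    fit$cv_metric_mean[fit$chosen_index]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
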
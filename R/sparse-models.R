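# Shared 1-SE L1-penalized model selector, multivariate de-confounding of
# assay-ADR associations, and the prior-likelihood classifier.

# Mann-Whitney AUC of scores for the positive class (ties count half).
auc_from_scores <- function(score, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit an L1-penalized model and select the 1-SE penalty
#'
#' Fits a lasso path with \pkg{glmnet} and scores every penalty with
#' `n_trials` random leave-`holdout`-out splits (stratified by class for
#' logistic models): holdout ROC AUC for `family = "binomial"`, holdout
#' mean squared error for `family = "gaussian"`. The chosen penalty is the
#' largest one whose mean score is within one standard error of the best
#' penalty's mean -- the sparsest model statistically indistinguishable
#' from the best. Coefficients are reported on the original predictor
#' scale (glmnet standardizes internally).
#'
#' @param x numeric matrix of predictors (>= 2 columns).
#' @param y response: 0/1 for binomial, numeric for gaussian.
#' @param family `"binomial"` or `"gaussian"`.
#' @param n_trials number of random holdout trials.
#' @param holdout holdout fraction per trial.
#' @param seed integer seed; the fit is deterministic given it.
#' @param nlambda length of the penalty path.
#' @return object of class `sparse_fit`: `penalty_path`, `cv_metric_mean`,
#'   `cv_metric_se`, `chosen_index`, `chosen_penalty`, `coefficients`
#'   (no intercept), `metric`, `family`.
#' @export
fit_1se_lasso <- function(x, y, family = c("binomial", "gaussian"),
                          n_trials = 50, holdout = 0.2, seed = 1,
                          nlambda = 50) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two predictor columns")
  if (family == "binomial" && length(unique(y)) < 2)
    stop("response has a single class")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  full <- glmnet::glmnet(x, y, family = family, nlambda = nlambda)
  lam <- full$lambda
  n <- nrow(x)
  metric <- matrix(NA_real_, n_trials, length(lam))
  for (t in seq_len(n_trials)) {
    if (family == "binomial") {
      i1 <- which(y == 1); i0 <- which(y == 0)
      te <- c(sample(i1, max(1, round(holdout * length(i1)))),
              sample(i0, max(1, round(holdout * length(i0)))))
    } else {
      te <- sample(n, max(2, round(holdout * n)))
    }
    tr <- setdiff(seq_len(n), te)
    fit_t <- tryCatch(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = family,
                     lambda = lam),
      error = function(e) NULL)
    if (is.null(fit_t)) next
    pred <- predict(fit_t, x[te, , drop = FALSE], s = lam, type = "link")
    metric[t, ] <- if (family == "binomial")
      apply(pred, 2, auc_from_scores, y = y[te])
    else colMeans((pred - y[te])^2)
  }
  mu <- colMeans(metric, na.rm = TRUE)
  se <- apply(metric, 2, function(z) stats::sd(z, na.rm = TRUE) /
                sqrt(sum(!is.na(z))))
  if (family == "binomial") {
    best <- which.max(mu)
    ok <- mu >= mu[best] - se[best]
  } else {
    best <- which.min(mu)
    ok <- mu <= mu[best] + se[best]
  }
  chosen <- which(ok)[1]  # lambda decreasing: first qualifying = largest penalty
  cf <- as.matrix(coef(full, s = lam[chosen]))[-1, 1]
  structure(list(penalty_path = lam, cv_metric_mean = mu, cv_metric_se = se,
                 best_index = best, chosen_index = chosen,
                 chosen_penalty = lam[chosen], coefficients = cf,
                 metric = if (family == "binomial") "auc" else "mse",
                 family = family),
            class = "sparse_fit")
}

#' @export
print.sparse_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("sparse_fit (%s): penalty %.4g (1-SE), %d/%d non-zero coefficients\n",
              x$family, x$chosen_penalty, nz, length(x$coefficients)))
  invisible(x)
}

#' Retained variables of a sparse logistic ADR model
#'
#' Activity predictors are log10 AC50s or margins, so a protective-looking
#' positive coefficient contradicts the direction of interest; positive
#' coefficients are treated as zero. A variable is retained when its
#' coefficient is below `threshold` (default -0.08, i.e. a 10-fold potency
#' increase raising the ADR odds by more than ~20%).
#'
#' @param fit a `sparse_fit` from [fit_1se_lasso()].
#' @param threshold retention threshold on the log10-scale coefficient.
#' @return list with `retained` (names), `coefficients` (positive values
#'   zeroed) and `zeroed_positive` (names of zeroed variables).
#' @export
interpret_coefficients <- function(fit, threshold = -0.08) {
  cf <- fit$coefficients
  zeroed <- names(cf)[cf > 0]
  cf[cf > 0] <- 0
  list(retained = names(cf)[cf < threshold], coefficients = cf,
       zeroed_positive = zeroed)
}

#' Assemble a design matrix from per-drug activity values
#'
#' Values are log10-transformed. Variables (assay x measure pairs) covering
#' fewer drugs than `min_coverage` times the best-covered variable are
#' dropped; remaining missing entries are imputed with the variable's
#' median.
#'
#' @param values long data.frame with `drug_id`, `variable`, `value`
#'   (positive, untransformed).
#' @param min_coverage coverage fraction relative to the best-covered
#'   variable.
#' @return list with `x` (drugs x variables matrix, complete),
#'   `drug_ids`, `dropped` (variable names), `n_imputed` per kept variable.
#' @export
assemble_design <- function(values, min_coverage = 0.7) {
  drugs <- sort(unique(values$drug_id))
  vars <- sort(unique(values$variable))
  x <- matrix(NA_real_, length(drugs), length(vars),
              dimnames = list(drugs, vars))
  x[cbind(match(values$drug_id, drugs), match(values$variable, vars))] <-
    log10(values$value)
  n_obs <- colSums(!is.na(x))
  keep <- n_obs >= min_coverage * max(n_obs)
  dropped <- vars[!keep]
  x <- x[, keep, drop = FALSE]
  n_imputed <- colSums(is.na(x))
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- stats::median(x[!miss, j])
  }
  list(x = x, drug_ids = drugs, dropped = dropped, n_imputed = n_imputed)
}

#' Eliminate redundant assay-ADR associations with sparse models
#'
#' For every ADR term and source with more than one univariately
#' significant (assay group, measure) candidate, fits a 1-SE lasso
#' logistic model of the ADR labels on the log10 activity values and keeps
#' only the variables retained by [interpret_coefficients()]; candidates
#' whose coefficient is shrunk away are recorded as eliminated (redundant
#' with the retained ones). Terms with a single candidate bypass modeling
#' and keep their pair.
#'
#' @param candidates data.frame with `term_code`, `source`,
#'   `assay_group_id`, `measure` (one row per candidate pair).
#' @param measure_values long data.frame with `drug_id`, `assay_group_id`,
#'   `measure`, `value` (truncated, positive) supplying the predictor
#'   values.
#' @param labels long data.frame with `source`, `term_code`, `drug_id`,
#'   `label` (`"pos"`/`"neg"`; other labels are ignored).
#' @param min_coverage,coef_threshold,n_trials,holdout see
#'   [assemble_design()], [interpret_coefficients()], [fit_1se_lasso()].
#' @param seed master seed; each term-source model derives its own.
#' @return list with `pairs` (data.frame of candidates with `status`
#'   retained/eliminated and `coefficient`) and `fits` (named list of
#'   `sparse_fit` objects).
#' @export
eliminate_redundant <- function(candidates, measure_values, labels,
                                min_coverage = 0.7, coef_threshold = -0.08,
                                n_trials = 50, holdout = 0.2, seed = 1) {
  candidates$variable <- paste(candidates$assay_group_id,
                               candidates$measure, sep = "|")
  measure_values$variable <- paste(measure_values$assay_group_id,
                                   measure_values$measure, sep = "|")
  groups <- split(candidates,
                  paste(candidates$term_code, candidates$source, sep = "\r"))
  fits <- list()
  out <- lapply(seq_along(groups), function(k) {
    cand <- groups[[k]]
    cand$status <- "retained"
    cand$coefficient <- NA_real_
    if (nrow(cand) < 2) return(cand)
    lab <- labels[labels$term_code == cand$term_code[1] &
                  labels$source == cand$source[1] &
                  labels$label %in% c("pos", "neg"), ]
    vals <- measure_values[measure_values$variable %in% cand$variable &
                           measure_values$drug_id %in% lab$drug_id, ]
    des <- assemble_design(vals[, c("drug_id", "variable", "value")],
                           min_coverage = min_coverage)
    cand$status[cand$variable %in% des$dropped] <- "eliminated"
    if (ncol(des$x) < 2) return(cand)
    y <- as.integer(lab$label[match(des$drug_ids, lab$drug_id)] == "pos")
    if (length(unique(y)) < 2) return(cand)
    fit <- fit_1se_lasso(des$x, y, family = "binomial",
                         n_trials = n_trials, holdout = holdout,
                         seed = seed + k)
    keep <- interpret_coefficients(fit, threshold = coef_threshold)
    in_model <- cand$variable %in% colnames(des$x)
    cand$coefficient[in_model] <-
      keep$coefficients[cand$variable[in_model]]
    cand$status[in_model & !cand$variable %in% keep$retained] <- "eliminated"
    fits[[paste(cand$term_code[1], cand$source[1])]] <<- fit
    cand
  })
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  list(pairs = pairs[, setdiff(names(pairs), "variable")], fits = fits)
}

#' Feature vector for a literature target-ADR association
#'
#' Summarizes the assay's truncated AC50 distribution (percentiles of the
#' values and counts of potent results) together with the ADR term's
#' system-organ-class membership and the training-set size.
#'
#' @param ac50_values truncated AC50 values (micromolar) for the assay.
#' @param term_code the ADR term.
#' @param hierarchy a [meddra_hierarchy()].
#' @param n_pos,n_neg training-set sizes for the term.
#' @param percentiles percentile probes of the AC50 distribution.
#' @param count_thresholds potency count thresholds in micromolar.
#' @param all_socs SOC universe for the dummy block (defaults to the
#'   hierarchy's SOCs).
#' @return named numeric feature vector.
#' @export
featurize_literature_assoc <- function(ac50_values, term_code, hierarchy,
                                       n_pos, n_neg,
                                       percentiles = c(0.025, 0.05, 0.1,
                                                       0.25, 0.5),
                                       count_thresholds = c(0.1, 0.5, 1),
                                       all_socs = NULL) {
  if (is.null(all_socs)) all_socs <- sort(meddra_terms(hierarchy, "SOC"))
  pct <- stats::quantile(ac50_values, percentiles, type = 7)
  names(pct) <- paste0("pctl_", percentiles * 100)
  cnt <- vapply(count_thresholds, function(th) sum(ac50_values <= th), 0)
  names(cnt) <- paste0("n_le_", count_thresholds, "uM")
  socs <- socs_of(hierarchy, term_code)
  soc_dummies <- as.numeric(all_socs %in% socs)
  names(soc_dummies) <- paste0("soc_", all_socs)
  c(pct, cnt, n_pos = n_pos, n_neg = n_neg, soc_dummies)
}

#' Prior-likelihood model for validating literature associations
#'
#' Fits a 1-SE lasso logistic model of association significance on the
#' feature vectors from [featurize_literature_assoc()] and assigns each
#' association a class at probability 0.5.
#'
#' @param features matrix (associations x features).
#' @param labels logical or 0/1 vector: association significant.
#' @param ... passed to [fit_1se_lasso()].
#' @return list with `fit`, `probability` and `class`
#'   (`"likely_significant"` / `"likely_non_significant"`).
#' @export
fit_prior_model <- function(features, labels, ...) {
  y <- as.integer(labels)
  const <- apply(features, 2, function(col) stats::sd(col) == 0)
  x <- features[, !const, drop = FALSE]
  if (ncol(x) < 2 || length(unique(y)) < 2) {
    maj <- if (mean(y) >= 0.5) "likely_significant" else "likely_non_significant"
    return(list(fit = NULL, probability = rep(mean(y), length(y)),
                class = rep(maj, length(y))))
  }
  fit <- fit_1se_lasso(x, y, family = "binomial", ...)
  full <- glmnet::glmnet(x, y, family = "binomial",
                         lambda = fit$penalty_path)
  prob <- drop(predict(full, x, s = fit$chosen_penalty, type = "response"))
  list(fit = fit,
       probability = prob,
       class = ifelse(prob >= 0.5, "likely_significant",
                      "likely_non_significant"))
}
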
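ref_tbl <- function() {
  data.frame(
    reference_id = c("R1", "R2", "R3"),
    key = c("AAAAAAAAAAAAAA-BBBBBBBBBB-N",
            "CCCCCCCCCCCCCC-DDDDDDDDDD-N",
            "EEEEEEEEEEEEEE-FFFFFFFFFF-N"),
    names = c("alpha|first", "beta", "gamma|shared"),
    stringsAsFactors = FALSE)
}

test_that("structure matching applies decreasing stringency", {
  ref <- ref_tbl()
  q <- data.frame(query_key = c(
    "AAAAAAAAAAAAAA-BBBBBBBBBB-N",   # level 1
    "CCCCCCCCCCCCCC-DDDDDDDDDD-M",   # level 2 (protonation differs)
    "EEEEEEEEEEEEEE-XXXXXXXXXX-N",   # level 3 (graph + shared name)
    "ZZZZZZZZZZZZZZ-ZZZZZZZZZZ-Z",   # level 4 (name only)
    "QQQQQQQQQQQQQQ-QQQQQQQQQQ-Q"),  # no match
    names = c("other", "other", "SHARED", "Beta", "nothing"),
    stringsAsFactors = FALSE)
  m <- match_structures(q, ref)
  expect_equal(m$level[m$query_key == q$query_key[1]], 1L)
  expect_equal(m$level[m$query_key == q$query_key[2]], 2L)
  expect_equal(m$level[m$query_key == q$query_key[3]], 3L)
  expect_equal(m$reference_id[m$query_key == q$query_key[3]], "R3")
  expect_equal(m$level[m$query_key == q$query_key[4]], 4L)
  expect_true(m$needs_review[m$level == 4])
  expect_false(any(m$needs_review[m$level < 4]))
  expect_false(q$query_key[5] %in% m$query_key)
  # reported level is the minimum achievable: a full-key match also
  # satisfies levels 2-4 but reports 1
  expect_true(all(m$level[m$query_key == q$query_key[1]] == 1L))
})

test_that("malformed keys are skipped with a warning but can name-match", {
  ref <- ref_tbl()
  q <- data.frame(query_key = "BADKEY", names = "alpha")
  expect_warning(m <- match_structures(q, ref), "malformed")
  expect_equal(m$level, 4L)
})

test_that("external records summarize as medians with ortholog pooling", {
  ext <- data.frame(drug_id = "d1", gene = c("G1", "G1", "G1", "Rn_G1"),
                    value = c(1, 10, 100, 4), type = "ac50",
                    stringsAsFactors = FALSE)
  s <- summarize_external(ext[1:3, ])
  expect_equal(s$median_ac50, 10)
  s1 <- summarize_external(ext[1, , drop = FALSE])
  expect_equal(s1$median_ac50, 1)
  # rat record mapped to the human gene before pooling
  om <- data.frame(gene = "Rn_G1", human_gene = "G1")
  s2 <- summarize_external(ext, om)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$median_ac50, median(c(1, 10, 100, 4)))
})

test_that("delta dataset applies qualifier and support filters", {
  set.seed(77)
  n <- 1000
  panel <- data.frame(drug_id = sprintf("d%04d", 1:n), target_gene = "G1",
                    qualifier = sample(c("=", ">"), n, TRUE, c(0.9, 0.1)),
                    ac50 = 10^runif(n, -2, 1),
                    cov_mode = sample(c("common", "rare"), n, TRUE,
                                      c(0.95, 0.05)),
                    stringsAsFactors = FALSE)
  ext <- data.frame(drug_id = panel$drug_id, gene = "G1",
                    qualifier = sample(c("=", ">"), n, TRUE, c(0.9, 0.1)),
                    ac50 = 10^runif(n, -2, 1), stringsAsFactors = FALSE)
  d <- build_delta_dataset(panel, ext, min_support = 100)
  both_meas <- panel$qualifier == "=" & ext$qualifier == "="
  lv <- table(panel$cov_mode[both_meas])
  expected <- sum(both_meas & panel$cov_mode %in% names(lv)[lv >= 100])
  expect_equal(nrow(d), expected)
  expect_true(all(d$abs_delta >= 0))
  # pAC50 conversion: 1 uM -> 6
  one <- which(abs(panel$ac50 - 1) == min(abs(panel$ac50 - 1)))[1]
  expect_equal(pac50(1), 6)
  # abs_delta is symmetric in which source is 'external'
  panel2 <- panel; names(panel2)[names(panel2) == "target_gene"] <- "target_gene"
  d_swap <- build_delta_dataset(
    data.frame(drug_id = ext$drug_id, target_gene = ext$gene,
               qualifier = ext$qualifier, ac50 = ext$ac50,
               cov_mode = panel$cov_mode, stringsAsFactors = FALSE),
    data.frame(drug_id = panel$drug_id, gene = panel$target_gene,
               qualifier = panel$qualifier, ac50 = panel$ac50,
               stringsAsFactors = FALSE),
    min_support = 100)
  expect_equal(sort(d$abs_delta), sort(d_swap$abs_delta))
})

test_that("difference model recovers a planted covariate effect", {
  set.seed(123)
  n <- 5000
  cov_f <- sample(c("funcA", "bindB"), n, TRUE)
  panel_p <- runif(n, 4, 8); ext_p <- panel_p + rnorm(n, 0, 0.3)
  delta <- abs(panel_p - ext_p) + 0.5 * (cov_f == "funcA") + rnorm(n, 0, 0.2)
  deltas <- data.frame(drug_id = as.character(1:n), target_gene = "G",
                       panel_pac50 = panel_p, ext_pac50 = ext_p,
                       abs_delta = delta, same_species = 1,
                       cov_format = cov_f, stringsAsFactors = FALSE)
  expect_warning(m <- model_activity_differences(deltas, n_trials = 25),
                 "constant")
  # with every level dummy-encoded the +0.5 shift on funcA can equally be
  # attributed to funcA (+0.5) or to bindB (-0.5); accept either
  got <- names(m$retained)[grepl("^cov_format", names(m$retained))]
  expect_length(got, 1)
  expect_lt(abs(abs(unname(m$retained[got])) - 0.5), 0.1)
})

test_that("a pure-noise covariate is rarely retained", {
  retained <- logical(20)
  set.seed(321)
  for (s in 1:20) {
    n <- 5000
    panel_p <- runif(n, 4, 8); ext_p <- panel_p + rnorm(n, 0, 0.3)
    delta <- abs(panel_p - ext_p) + rnorm(n, 0, 0.2)
    deltas <- data.frame(drug_id = as.character(1:n), target_gene = "G",
                         panel_pac50 = panel_p, ext_pac50 = ext_p,
                         abs_delta = delta, same_species = 1,
                         cov_noise = sample(c("u", "v"), n, TRUE),
                         stringsAsFactors = FALSE)
    m <- suppressWarnings(
      model_activity_differences(deltas, n_trials = 20, seed = s))
    retained[s] <- any(grepl("cov_noise", names(m$retained)))
  }
  expect_lte(mean(retained), 0.05)
})
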
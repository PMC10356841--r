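make_results <- function(ids, qualifier, ac50) {
  data.frame(drug_id = ids, qualifier = qualifier, ac50 = ac50,
             stringsAsFactors = FALSE)
}

test_that("an assay duplicated against itself is concordant", {
  set.seed(10)
  ids <- sprintf("d%02d", 1:12)
  r <- make_results(ids, rep(c("=", ">"), each = 6),
                    c(10^runif(6, -1, 0.9), rep(30, 6)))
  cc <- assess_concordance(r, r)
  expect_true(cc$evaluable)
  expect_equal(cc$sens_a, 1)
  expect_equal(cc$pearson_r, 1)
  expect_false(cc$concordant)  # only 6 measured pairs, below the minimum
  r2 <- make_results(ids, rep("=", 12), 10^runif(12, -1, 0.9))
  expect_true(assess_concordance(r2, r2)$concordant)
})

test_that("pairs with insufficient overlap are never merged", {
  ids <- sprintf("d%02d", 1:9)
  r <- make_results(ids, rep("=", 9), rep(1, 9))
  cc <- assess_concordance(r, r)
  expect_false(cc$evaluable)
  expect_false(cc$concordant)
})

test_that("low shared-active sensitivity blocks concordance", {
  # 20 shared compounds; assay A calls 10 active, assay B calls the same 4
  # of them active plus none else: sens_a = 4/10, sens_b = 4/4
  ids <- sprintf("d%02d", 1:20)
  va <- c(rep(1, 10), rep(30, 10))
  qa <- rep(c("=", ">"), each = 10)
  vb <- c(rep(1, 4), rep(30, 16))
  qb <- rep(c("=", ">"), c(4, 16))
  cc <- assess_concordance(make_results(ids, qa, va),
                           make_results(ids, qb, vb))
  expect_equal(cc$sens_a, 0.4)
  expect_equal(cc$sens_b, 1)
  expect_false(cc$concordant)
})

test_that("groups are connected components with chain merging", {
  assays <- data.frame(
    assay_id = c("A", "B", "C", "D"),
    target_gene = "T1", mode = "binding", species = "human",
    protein_class = "GPCR", event = "e", format = "f", readout = "r",
    max_conc = 10, stringsAsFactors = FALSE)
  conc <- data.frame(assay_a = c("A", "B", "A"), assay_b = c("B", "C", "C"),
                     concordant = c(TRUE, TRUE, FALSE))
  summ <- data.frame(assay_id = c("A", "A", "B", "C", "D"))
  g <- build_assay_groups(assays, conc, summ)
  expect_equal(length(unique(g$group_id[g$assay_id %in% c("A", "B", "C")])), 1)
  expect_false(g$group_id[g$assay_id == "D"] %in%
                 g$group_id[g$assay_id != "D"])
  # preferred assay = most results (A has 2)
  expect_true(g$is_preferred[g$assay_id == "A"])
  expect_true(g$is_preferred[g$assay_id == "D"])  # singleton group
  # tie on result count resolves to the smallest assay id
  conc0 <- conc[0, ]
  summ_tie <- data.frame(assay_id = c("A", "B", "C", "D"))
  g2 <- build_assay_groups(assays, conc0, summ_tie)
  expect_true(all(g2$is_preferred))  # all singletons
  conc_ab <- data.frame(assay_a = "A", assay_b = "B", concordant = TRUE)
  g3 <- build_assay_groups(assays, conc_ab, summ_tie)
  expect_true(g3$is_preferred[g3$assay_id == "A"])
  expect_false(g3$is_preferred[g3$assay_id == "B"])
})

test_that("group assignment is invariant to edge order", {
  assays <- data.frame(
    assay_id = sprintf("a%d", 1:5), target_gene = "T", mode = "binding",
    species = "human", protein_class = "Enzyme", event = "e", format = "f",
    readout = "r", max_conc = 30, stringsAsFactors = FALSE)
  conc <- data.frame(assay_a = c("a1", "a2", "a4"),
                     assay_b = c("a2", "a3", "a5"),
                     concordant = TRUE)
  summ <- data.frame(assay_id = sprintf("a%d", 1:5))
  g1 <- build_assay_groups(assays, conc, summ)
  g2 <- build_assay_groups(assays, conc[c(3, 1, 2), ], summ)
  expect_equal(g1, g2)
})

test_that("representative selection honors the precedence rules", {
  base <- data.frame(
    qualifier = "=", ac50 = c(1, 2, 3),
    is_metabolite = c(FALSE, TRUE, FALSE),
    match_level = c(1L, 2L, 1L),
    assay_is_preferred = c(TRUE, FALSE, FALSE),
    substance_key = c("k1", "k2", "k3"),
    assay_id = c("a1", "a2", "a3"), stringsAsFactors = FALSE)
  # active metabolite beats parent regardless of anything else
  expect_equal(select_representative(base)$substance_key, "k2")
  # without a metabolite: better match level, then preferred assay
  b2 <- base[c(1, 3), ]; b2$match_level <- c(2L, 1L)
  expect_equal(select_representative(b2)$substance_key, "k3")
  b3 <- base[c(1, 3), ]
  expect_equal(select_representative(b3)$substance_key, "k1")
  expect_equal(select_representative(base[1, ])$substance_key, "k1")
})

test_that("active-metabolite results represent the parent drug", {
  summ <- data.frame(
    drug_id = c("ena", "ena_m"), substance_key = c("kp", "km"),
    assay_id = "a1", qualifier = "=", ac50 = c(5, 0.1),
    n_summarized = 1L, n_total = 1L, stringsAsFactors = FALSE)
  drugs <- data.frame(
    drug_id = c("ena", "ena_m"), parent_id = c("ena", "ena"),
    structure_key = c("kp", "km"), names = "", moa = "",
    is_active_metabolite = c(FALSE, TRUE), stringsAsFactors = FALSE)
  assays <- data.frame(assay_id = "a1", target_gene = "T1",
                       group_id = "g1", is_preferred = TRUE,
                       stringsAsFactors = FALSE)
  rep <- representative_activities(summ, drugs, assays)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$drug_id, "ena")
  expect_equal(rep$substance_key, "km")
  expect_equal(rep$ac50, 0.1)
})

test_that("promiscuity equals the brute-force active fraction", {
  r <- data.frame(drug_id = "nef", qualifier = rep(c("=", ">"), c(40, 48)),
                  ac50 = c(10^runif(31, -2, 0.99), runif(9, 10, 30),
                           rep(30, 48)))
  p <- compute_promiscuity(r)
  expect_equal(p$n_active, 31L)
  expect_equal(p$n_tested, 88L)
  expect_equal(p$promiscuity, 31 / 88, tolerance = 1e-12)
  # all censored: zero promiscuity
  r0 <- data.frame(drug_id = "d", qualifier = ">", ac50 = 30)
  expect_equal(compute_promiscuity(r0)$promiscuity, 0)
  # random fixture vs direct count
  set.seed(12)
  rr <- data.frame(drug_id = sample(c("x", "y"), 60, TRUE),
                   qualifier = sample(c("=", ">"), 60, TRUE),
                   ac50 = 10^runif(60, -2, 1.5))
  pp <- compute_promiscuity(rr)
  for (d in c("x", "y")) {
    sub <- rr[rr$drug_id == d, ]
    expect_equal(pp$promiscuity[pp$drug_id == d],
                 mean(sub$qualifier == "=" & sub$ac50 < 10))
  }
})

test_that("vectorized summarization matches the single-cell rule", {
  set.seed(5)
  n <- 400
  act <- data.frame(drug_id = sample(sprintf("d%02d", 1:15), n, TRUE),
                    substance_key = "k",
                    assay_id = sample(c("a1", "a2", "a3"), n, TRUE),
                    qualifier = sample(c("=", ">"), n, TRUE),
                    ac50 = round(10^runif(n, -2, 1.6), 5))
  fast <- summarize_activities(act)
  key <- paste(act$drug_id, act$assay_id)
  for (i in sample(nrow(fast), 25)) {
    cell <- act[act$drug_id == fast$drug_id[i] &
                  act$assay_id == fast$assay_id[i], ]
    s <- summarize_ac50(cell$qualifier, cell$ac50)
    expect_equal(fast$qualifier[i], s$qualifier)
    expect_equal(fast$ac50[i], s$value)
    expect_equal(fast$n_summarized[i], s$n_summarized)
    expect_equal(fast$n_total[i], s$n_total)
  }
})
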
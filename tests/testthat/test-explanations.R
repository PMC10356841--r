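# Fixture in the spirit of the sedative-hypnotic case: a GABA-agonist drug
# with an unpublished potent muscarinic binding activity, where the
# muscarinic target is significantly associated with an ocular ADR.
explain_fixture <- function() {
  rep_results <- data.frame(
    drug_id = c("hypnotic", "hypnotic", "anticholinergic", "comparator"),
    assay_group_id = c("gGABA", "gCHRM", "gCHRM", "gCHRM"),
    qualifier = "=", ac50 = c(0.046, 0.21, 0.05, 1.4),
    activity_class = c("on_target", "unpublished_off_target",
                       "known_off_target", "unpublished_off_target"),
    stringsAsFactors = FALSE)
  assays <- data.frame(assay_id = c("aGABA", "aCHRM"),
                       target_gene = c("GABA1", "CHRM"),
                       group_id = c("gGABA", "gCHRM"),
                       stringsAsFactors = FALSE)
  measures <- data.frame(
    drug_id = c("hypnotic", "anticholinergic", "comparator", "bystander"),
    assay_group_id = "gCHRM", measure = "ac50", qualifier = "=",
    value = c(0.21, 0.05, 1.4, 5), stringsAsFactors = FALSE)
  labels <- data.frame(
    source = "FAERS", term_code = "accom",
    drug_id = c("hypnotic", "anticholinergic", "comparator", "bystander"),
    label = "pos", stringsAsFactors = FALSE)
  sig <- data.frame(assay_group_id = "gCHRM", measure = "ac50", cutoff = 30,
                    term_code = "accom", source = "FAERS", kw_p = 1e-8,
                    roc_auc = 0.8, stringsAsFactors = FALSE)
  moa <- data.frame(drug_id = "hypnotic", target_gene = "GABA1",
                    action_type = "agonist", stringsAsFactors = FALSE)
  list(rep = rep_results, assays = assays, measures = measures,
       labels = labels, sig = sig, moa = moa)
}

test_that("an unpublished potent off-target activity is flagged", {
  f <- explain_fixture()
  ex <- flag_explanations(f$rep, f$measures, f$labels, f$sig, f$assays, f$moa)
  hit <- ex[ex$drug_id == "hypnotic" & ex$term_code == "accom", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$flagged)
  expect_true(all(unlist(hit[grep("^c[1-6]", names(hit))])))
})

test_that("published activity or missing annotation breaks the chain", {
  f <- explain_fixture()
  # the same activity marked known (published below 10 uM) is not a candidate
  f2 <- f; f2$rep$activity_class[2] <- "known_off_target"
  ex2 <- flag_explanations(f2$rep, f2$measures, f2$labels, f2$sig, f2$assays,
                           f2$moa)
  expect_false(any(ex2$drug_id == "hypnotic"))
  # drug not positive for the term: criterion 2 fails
  f3 <- f; f3$labels <- f3$labels[f3$labels$drug_id != "hypnotic", ]
  ex3 <- flag_explanations(f3$rep, f3$measures, f3$labels, f3$sig, f3$assays,
                           f3$moa)
  hit <- ex3[ex3$drug_id == "hypnotic", ]
  expect_false(hit$c2_drug_positive)
  expect_false(hit$flagged)
  # a known off-target activity for the same term only 5-fold weaker:
  # criterion 6 fails
  f4 <- f
  f4$rep <- rbind(f4$rep, data.frame(
    drug_id = "hypnotic", assay_group_id = "gCHRM2", qualifier = "=",
    ac50 = 0.21 * 5, activity_class = "known_off_target"))
  f4$assays <- rbind(f4$assays, data.frame(
    assay_id = "aCHRM2", target_gene = "CHRM2", group_id = "gCHRM2"))
  f4$sig <- rbind(f4$sig, data.frame(
    assay_group_id = "gCHRM2", measure = "ac50", cutoff = 30,
    term_code = "accom", source = "FAERS", kw_p = 1e-4, roc_auc = 0.7))
  ex4 <- flag_explanations(f4$rep, f4$measures, f4$labels, f4$sig, f4$assays,
                           f4$moa)
  hit4 <- ex4[ex4$drug_id == "hypnotic" & ex4$assay_group_id == "gCHRM", ]
  expect_false(hit4$c6_known_weaker)
  expect_false(hit4$flagged)
  # 10-fold or weaker is acceptable
  f4$rep$ac50[nrow(f4$rep)] <- 0.21 * 10
  ex5 <- flag_explanations(f4$rep, f4$measures, f4$labels, f4$sig, f4$assays,
                           f4$moa)
  expect_true(ex5[ex5$drug_id == "hypnotic" &
                    ex5$assay_group_id == "gCHRM", "c6_known_weaker"])
})

test_that("on-target significance for the same term blocks the flag", {
  f <- explain_fixture()
  f$sig <- rbind(f$sig, data.frame(
    assay_group_id = "gGABA", measure = "ac50", cutoff = 30,
    term_code = "accom", source = "FAERS", kw_p = 1e-5, roc_auc = 0.75))
  ex <- flag_explanations(f$rep, f$measures, f$labels, f$sig, f$assays, f$moa)
  hit <- ex[ex$drug_id == "hypnotic" & ex$assay_group_id == "gCHRM", ]
  expect_false(hit$c5_not_on_target)
  expect_false(hit$flagged)
})

test_that("flagging equals brute-force evaluation and is monotone in the
           ceiling", {
  set.seed(71)
  n_drugs <- 50
  drugs <- sprintf("d%02d", 1:n_drugs)
  rep <- data.frame(
    drug_id = rep(drugs, each = 2),
    assay_group_id = rep(c("g1", "g2"), n_drugs),
    qualifier = sample(c("=", ">"), 2 * n_drugs, TRUE, c(0.7, 0.3)),
    ac50 = round(10^runif(2 * n_drugs, -2, 1.5), 4),
    activity_class = sample(c("unpublished_off_target", "known_off_target",
                              "on_target"), 2 * n_drugs, TRUE,
                            c(0.6, 0.3, 0.1)), stringsAsFactors = FALSE)
  assays <- data.frame(assay_id = c("a1", "a2"), target_gene = c("T1", "T2"),
                       group_id = c("g1", "g2"), stringsAsFactors = FALSE)
  measures <- data.frame(drug_id = rep$drug_id,
                         assay_group_id = rep$assay_group_id,
                         measure = "ac50", qualifier = rep$qualifier,
                         value = rep$ac50, stringsAsFactors = FALSE)
  labels <- data.frame(source = "SIDER",
                       term_code = sample(c("t1", "t2"), 60, TRUE),
                       drug_id = sample(drugs, 60, TRUE), label = "pos",
                       stringsAsFactors = FALSE)
  labels <- unique(labels)
  sig <- data.frame(assay_group_id = c("g1", "g2"), measure = "ac50",
                    cutoff = 30, term_code = c("t1", "t2"),
                    source = "SIDER", kw_p = c(1e-7, 1e-5),
                    roc_auc = c(0.8, 0.72), stringsAsFactors = FALSE)
  moa <- data.frame(drug_id = drugs[1:10], target_gene = "T1",
                    action_type = "antagonist", stringsAsFactors = FALSE)
  ex <- flag_explanations(rep, measures, labels, sig, assays, moa)
  # brute force over all candidate triples
  for (i in seq_len(nrow(ex))) {
    r <- ex[i, ]
    expect_true(r$c1_unpublished_potent)
    expect_equal(r$c2_drug_positive,
                 any(labels$drug_id == r$drug_id &
                       labels$term_code == r$term_code))
    if (r$c2_drug_positive && r$c3_assoc_significant) {
      pos_drugs <- labels$drug_id[labels$term_code == r$term_code]
      act <- measures[measures$assay_group_id == r$assay_group_id &
                        measures$qualifier == "=" &
                        measures$value < 10 &
                        measures$drug_id %in% pos_drugs, ]
      dv <- act$value[act$drug_id == r$drug_id]
      expect_equal(r$c4_top_quartiles,
                   length(dv) > 0 && dv[1] <= quantile(act$value, 0.75),
                   info = paste(r$drug_id, r$term_code))
    }
    expect_equal(r$flagged, all(unlist(r[grep("^c[1-6]", names(r))])))
  }
  # lowering the ceiling never adds flags
  ex2 <- flag_explanations(rep, measures, labels, sig, assays, moa,
                           ac50_ceiling = 1)
  flagged1 <- paste(ex$drug_id, ex$assay_group_id,
                    ex$term_code)[ex$flagged]
  flagged2 <- paste(ex2$drug_id, ex2$assay_group_id,
                    ex2$term_code)[ex2$flagged]
  expect_true(all(flagged2 %in% flagged1))
  # referential integrity: every flagged term is in the significant table
  expect_true(all(ex$term_code[ex$flagged] %in% sig$term_code))
})
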
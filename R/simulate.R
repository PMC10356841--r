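# Synthetic input bundles with the statistical structure the analysis
# assumes and a planted causal target-ADR map for recovery testing.

#' Simulation configuration
#'
#' Defaults describe a mid-sized secondary pharmacology campaign: ~800
#' marketed drugs profiled on a 40-protocol panel (a few targets carry two
#' protocols, exercising assay grouping), latent log10 AC50 centred at 100
#' micromolar with unit spread so ~16% of drug-target pairs are active
#' below 10 micromolar, targets correlated in polypharmacology blocks, a
#' log-normal exposure distribution, and a balanced four-level ADR
#' ontology. ADR labels are drawn per source from a logistic model on the
#' potency at the planted causal targets (baseline log-odds -3.5, i.e.
#' ~3-7% label prevalence; effect 4.5 per 10-fold potency gain, the
#' strength of a well-validated pharmacological ADR driver), with
#' independent per-source label flips.
#'
#' @param n_drugs number of parent drugs.
#' @param n_assays number of assay protocols.
#' @param duplicate_assay_targets targets carrying two protocols.
#' @param n_pt,n_ht,n_hg,n_soc ontology sizes per level.
#' @param multi_parent_frac fraction of PTs with a second HT parent.
#' @param p_max_conc_30 probability an assay tops out at 30 (vs 10)
#'   micromolar.
#' @param potency_mean,potency_sd latent log10 AC50 (micromolar)
#'   distribution.
#' @param replicate_sd replicate noise, log10 units.
#' @param replicate_probs probabilities of 1, 2, 3 replicate runs.
#' @param test_prob probability a drug is tested in an assay.
#' @param block_size,block_r polypharmacology block size and latent
#'   correlation.
#' @param moa_frac fraction of drugs with a mechanism-of-action target.
#' @param moa_potency_mean,moa_potency_sd latent log10 AC50 at the MOA
#'   target.
#' @param metabolite_frac fraction of drugs with an active-metabolite
#'   form.
#' @param exposure_missing fraction of drugs without exposure data.
#' @param cmax_mean,cmax_sd log10 total Cmax (micromolar) distribution.
#' @param cmax_noise_sd between-measurement noise, log10 units.
#' @param ppb_shape1,ppb_shape2 Beta parameters of the bound fraction.
#' @param n_causal number of planted causal (target, PT) pairs.
#' @param causal_effect log-odds increase per 10-fold potency gain.
#' @param baseline_logodds ADR baseline log-odds.
#' @param flip_prob per-source label flip probability.
#' @param lrt_multiplier FAERS positivity multiplier encoded in the
#'   generated scores.
#' @param published_frac probability a true off-target activity appears in
#'   the external tables.
#' @param seed master seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_drugs = 800, n_assays = 40,
                       duplicate_assay_targets = 4,
                       n_pt = 60, n_ht = 20, n_hg = 8, n_soc = 4,
                       multi_parent_frac = 0.05, p_max_conc_30 = 0.5,
                       potency_mean = 2, potency_sd = 1,
                       replicate_sd = 0.2,
                       replicate_probs = c(0.7, 0.2, 0.1),
                       test_prob = 0.85, block_size = 2, block_r = 0.6,
                       moa_frac = 0.7, moa_potency_mean = -0.5,
                       moa_potency_sd = 0.5, metabolite_frac = 0.05,
                       exposure_missing = 0.1, cmax_mean = -0.5,
                       cmax_sd = 0.8, cmax_noise_sd = 0.2,
                       ppb_shape1 = 8, ppb_shape2 = 2,
                       n_causal = 8, causal_effect = 4.5,
                       baseline_logodds = -3.5, flip_prob = 0.02,
                       lrt_multiplier = 5, published_frac = 0.3,
                       seed = 1) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_max_conc_30, cfg$multi_parent_frac, cfg$test_prob,
             cfg$block_r, cfg$moa_frac, cfg$metabolite_frac,
             cfg$exposure_missing, cfg$flip_prob, cfg$published_frac,
             cfg$replicate_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.finite(cfg$causal_effect)) stop("causal_effect must be finite")
  if (cfg$n_causal > 0 && cfg$test_prob == 0)
    stop("infeasible: causal effects planted but no drug is ever tested")
  n_targets <- cfg$n_assays - cfg$duplicate_assay_targets
  if (cfg$n_causal > floor(n_targets / max(1, cfg$block_size)))
    stop("n_causal exceeds the number of polypharmacology blocks")
  if (cfg$n_causal > cfg$n_pt) stop("n_causal exceeds n_pt")
  structure(cfg, class = "sim_config")
}

random_keys <- function(n) {
  blk <- function(len) vapply(seq_len(n), function(i)
    paste(sample(LETTERS, len, replace = TRUE), collapse = ""), "")
  paste(blk(14), blk(10), blk(1), sep = "-")
}

generate_hierarchy_edges <- function(cfg) {
  pt <- sprintf("PT%03d", seq_len(cfg$n_pt))
  ht <- sprintf("HT%03d", seq_len(cfg$n_ht))
  hg <- sprintf("HG%02d", seq_len(cfg$n_hg))
  soc <- sprintf("SOC%d", seq_len(cfg$n_soc))
  e <- rbind(
    data.frame(child_code = pt,
               parent_code = ht[(seq_len(cfg$n_pt) - 1L) %% cfg$n_ht + 1L],
               child_level = "PT", parent_level = "HT"),
    data.frame(child_code = ht,
               parent_code = hg[(seq_len(cfg$n_ht) - 1L) %% cfg$n_hg + 1L],
               child_level = "HT", parent_level = "HG"),
    data.frame(child_code = hg,
               parent_code = soc[(seq_len(cfg$n_hg) - 1L) %% cfg$n_soc + 1L],
               child_level = "HG", parent_level = "SOC"))
  n_multi <- floor(cfg$multi_parent_frac * cfg$n_pt)
  if (n_multi > 0 && cfg$n_ht >= 2) {
    picks <- sample(cfg$n_pt, n_multi)
    first <- (picks - 1L) %% cfg$n_ht + 1L
    second <- first %% cfg$n_ht + 1L
    e <- rbind(e, data.frame(child_code = pt[picks], parent_code = ht[second],
                             child_level = "PT", parent_level = "HT"))
  }
  e
}

#' Generate a complete synthetic input bundle
#'
#' Draws assay metadata, block-correlated latent drug-target potencies,
#' censored replicate activities, drug metadata with MOA annotations and
#' active-metabolite forms, exposure measurements, external
#' (literature-style) activity records, a reference structure table, a
#' toy PT/HT/HG/SOC ontology, and per-source ADR annotations from a
#' logistic model on the planted causal potencies. The bundle is
#' byte-identical for identical config and seed.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return named list of data.frames (see [write_bundle()]) plus
#'   `hierarchy`, `decoy_map`, and the latent potency matrix as attribute
#'   `latent`.
#' @export
generate_bundle <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- seed
  set.seed(cfg$seed)
  n_targets <- cfg$n_assays - cfg$duplicate_assay_targets
  targets <- sprintf("T%03d", seq_len(n_targets))
  assay_target_idx <- c(seq_len(cfg$duplicate_assay_targets),
                        seq_len(n_targets))
  assay_target_idx <- sort(assay_target_idx)
  modes_by_target <- sample(c("binding", "inhibition", "agonist",
                              "antagonist"), n_targets, replace = TRUE,
                            prob = c(0.4, 0.2, 0.2, 0.2))
  class_by_target <- sample(c("GPCR", "Ion channel", "Transporter",
                              "Nuclear receptor", "Enzyme", "Kinase"),
                            n_targets, replace = TRUE,
                            prob = c(0.35, 0.15, 0.15, 0.1, 0.15, 0.1))
  assays <- data.frame(
    assay_id = sprintf("assay_%03d", seq_len(cfg$n_assays)),
    target_gene = targets[assay_target_idx],
    mode = modes_by_target[assay_target_idx],
    species = sample(c("human", "rat"), cfg$n_assays, replace = TRUE,
                     prob = c(0.9, 0.1)),
    protein_class = class_by_target[assay_target_idx],
    event = sample(c("protein binding", "second messenger", "enzyme activity"),
                   cfg$n_assays, replace = TRUE),
    format = sample(c("biochemical", "cellular"), cfg$n_assays,
                    replace = TRUE),
    readout = sample(c("radioactivity", "fluorescence", "luminescence"),
                     cfg$n_assays, replace = TRUE),
    max_conc = sample(c(30, 10), cfg$n_assays, replace = TRUE,
                      prob = c(cfg$p_max_conc_30, 1 - cfg$p_max_conc_30)),
    stringsAsFactors = FALSE)

  # drugs: parents then active-metabolite forms
  parent_ids <- sprintf("drug_%04d", seq_len(cfg$n_drugs))
  has_moa <- runif(cfg$n_drugs) < cfg$moa_frac
  moa_target <- ifelse(has_moa, targets[sample(n_targets, cfg$n_drugs,
                                               replace = TRUE)], NA)
  moa_action <- ifelse(has_moa,
                       sample(c("agonist", "antagonist", "inhibition"),
                              cfg$n_drugs, replace = TRUE,
                              prob = c(0.3, 0.5, 0.2)), NA)
  n_met <- floor(cfg$metabolite_frac * cfg$n_drugs)
  met_parent <- if (n_met > 0) sort(sample(cfg$n_drugs, n_met)) else integer()
  met_ids <- sprintf("%s_m", parent_ids[met_parent])
  form_ids <- c(parent_ids, met_ids)
  n_forms <- length(form_ids)
  keys <- random_keys(n_forms)
  drugs <- data.frame(
    drug_id = form_ids,
    parent_id = c(parent_ids, parent_ids[met_parent]),
    structure_key = keys,
    names = paste0("name ", form_ids, "|syn ", seq_len(n_forms)),
    moa = c(ifelse(has_moa, paste0(moa_target, ":", moa_action), ""),
            rep("", n_met)),
    is_active_metabolite = c(rep(FALSE, cfg$n_drugs), rep(TRUE, n_met)),
    stringsAsFactors = FALSE)

  # latent log10 AC50 per form x target, block-correlated
  n_blocks <- ceiling(n_targets / cfg$block_size)
  block_of <- rep(seq_len(n_blocks), each = cfg$block_size)[seq_len(n_targets)]
  zb <- matrix(rnorm(cfg$n_drugs * n_blocks), cfg$n_drugs, n_blocks)
  ze <- matrix(rnorm(cfg$n_drugs * n_targets), cfg$n_drugs, n_targets)
  z <- sqrt(cfg$block_r) * zb[, block_of, drop = FALSE] +
    sqrt(1 - cfg$block_r) * ze
  latent <- cfg$potency_mean + cfg$potency_sd * z
  moa_idx <- which(has_moa)
  latent[cbind(moa_idx, match(moa_target[moa_idx], targets))] <-
    rnorm(length(moa_idx), cfg$moa_potency_mean, cfg$moa_potency_sd)
  if (n_met > 0)
    latent <- rbind(latent,
                    latent[met_parent, , drop = FALSE] +
                      matrix(rnorm(n_met * n_targets, 0, 0.3), n_met))
  dimnames(latent) <- list(form_ids, targets)

  # replicate-level activities, censored at the assay's top concentration
  tested <- matrix(runif(n_forms * cfg$n_assays) < cfg$test_prob,
                   n_forms, cfg$n_assays)
  cell <- which(tested, arr.ind = TRUE)
  n_rep <- sample(seq_along(cfg$replicate_probs), nrow(cell),
                  replace = TRUE, prob = cfg$replicate_probs)
  ri <- rep(seq_len(nrow(cell)), n_rep)
  true_l10 <- latent[cbind(cell[ri, 1], assay_target_idx[cell[ri, 2]])]
  obs_l10 <- true_l10 + rnorm(length(ri), 0, cfg$replicate_sd)
  maxc <- assays$max_conc[cell[ri, 2]]
  censored <- obs_l10 >= log10(maxc)
  activities <- data.frame(
    drug_id = form_ids[cell[ri, 1]],
    substance_key = keys[cell[ri, 1]],
    assay_id = assays$assay_id[cell[ri, 2]],
    qualifier = ifelse(censored, ">", "="),
    ac50 = signif(ifelse(censored, maxc, 10^obs_l10), 6),
    stringsAsFactors = FALSE)

  # exposure measurements (parents only)
  has_exp <- runif(cfg$n_drugs) >= cfg$exposure_missing
  exp_rows <- list()
  cmax_base <- rnorm(cfg$n_drugs, cfg$cmax_mean, cfg$cmax_sd)
  ppb_base <- 100 * rbeta(cfg$n_drugs, cfg$ppb_shape1, cfg$ppb_shape2)
  for (i in which(has_exp)) {
    nc <- sample(1:4, 1)
    np <- sample(1:3, 1)
    rows <- data.frame(
      drug_id = parent_ids[i],
      quantity = rep(c("cmax_tot", "ppb_pct"), c(nc, np)),
      value = signif(c(10^(cmax_base[i] + rnorm(nc, 0, cfg$cmax_noise_sd)),
                       pmin(99.9, pmax(0, ppb_base[i] + rnorm(np, 0, 2)))), 6),
      binding_label = "", stringsAsFactors = FALSE)
    if (runif(1) < 0.1)
      rows <- rbind(rows, data.frame(
        drug_id = parent_ids[i], quantity = "ppb_pct",
        value = signif(pmin(99.9, ppb_base[i] + 10), 6),
        binding_label = "albumin", stringsAsFactors = FALSE))
    exp_rows[[length(exp_rows) + 1L]] <- rows
  }
  exposure <- do.call(rbind, exp_rows)

  # hierarchy and planted causal map
  meddra_edges <- generate_hierarchy_edges(cfg)
  hierarchy <- meddra_hierarchy(meddra_edges)
  block_leader <- match(unique(block_of), block_of)
  causal_t_idx <- block_leader[seq_len(cfg$n_causal)]
  causal_assay <- assays$assay_id[match(causal_t_idx, assay_target_idx)]
  causal_term <- sprintf("PT%03d", seq_len(cfg$n_causal))
  decoy_t_idx <- vapply(causal_t_idx, function(ti) {
    others <- setdiff(which(block_of == block_of[ti]), ti)
    if (length(others)) others[1] else NA_integer_
  }, 0L)
  decoy_assay <- ifelse(is.na(decoy_t_idx), NA,
                        assays$assay_id[match(decoy_t_idx, assay_target_idx)])
  ground_truth <- data.frame(
    assay_id = causal_assay, target_gene = targets[causal_t_idx],
    term_code = causal_term,
    effect = rep(cfg$causal_effect, length(causal_assay)),
    decoy_assay_id = decoy_assay,
    decoy_target = ifelse(is.na(decoy_t_idx), NA, targets[decoy_t_idx]),
    stringsAsFactors = FALSE)

  # per-source ADR labels from a logistic model on the measured causal
  # potency: the summarized panel AC50 of the causal assay (censored
  # results score 0), falling back to the latent potency for untested
  # drugs. Planting the effect on the measured value keeps correlated
  # decoy targets conditionally uninformative, which is what the
  # sparse-model stage is asked to detect.
  pt_codes <- sprintf("PT%03d", seq_len(cfg$n_pt))
  maxc_of_causal <- assays$max_conc[match(causal_assay, assays$assay_id)]
  causal_score <- function(ci) {
    maxc_l10 <- log10(maxc_of_causal[ci])
    s <- rep(0, cfg$n_drugs)  # untested or censored: baseline risk only
    rows <- activities$assay_id == causal_assay[ci] &
      activities$drug_id %in% parent_ids
    if (any(rows)) {
      sm <- summarize_activities(activities[rows, ])
      di <- match(sm$drug_id, parent_ids)
      s[di] <- pmax(0, maxc_l10 - log10(pmin(sm$ac50, maxc_of_causal[ci])))
    }
    s
  }
  causal_scores <- lapply(seq_len(cfg$n_causal), causal_score)
  ann <- list()
  for (src in c("SIDER", "FAERS")) {
    for (ti in seq_len(cfg$n_pt)) {
      eta <- rep(cfg$baseline_logodds, cfg$n_drugs)
      ci <- which(causal_term == pt_codes[ti])
      if (length(ci)) eta <- eta + cfg$causal_effect * causal_scores[[ci]]
      y <- rbinom(cfg$n_drugs, 1, plogis(eta))
      flip <- runif(cfg$n_drugs) < cfg$flip_prob
      y <- ifelse(flip, 1L - y, y)
      if (src == "SIDER") {
        pos <- which(y == 1)
        if (length(pos))
          ann[[length(ann) + 1L]] <- data.frame(
            drug_id = parent_ids[pos], term_code = pt_codes[ti],
            source = "SIDER", positive = TRUE, lrt = NA_real_,
            lrt_threshold = NA_real_, stringsAsFactors = FALSE)
      } else {
        thr <- signif(2 * exp(rnorm(cfg$n_drugs, 0, 0.2)), 6)
        lrt <- signif(ifelse(
          y == 1,
          cfg$lrt_multiplier * thr * (1 + rexp(cfg$n_drugs, 2)),
          cfg$lrt_multiplier * thr * runif(cfg$n_drugs, 0.05, 0.95)), 6)
        keep <- y == 1 | lrt > thr  # weak signals below threshold reported too
        ann[[length(ann) + 1L]] <- data.frame(
          drug_id = parent_ids[keep], term_code = pt_codes[ti],
          source = "FAERS", positive = NA, lrt = lrt[keep],
          lrt_threshold = thr[keep], stringsAsFactors = FALSE)
      }
    }
  }
  adr_annotations <- do.call(rbind, ann)

  # external activity records: published subset of true activities
  act_pairs <- which(latent[seq_len(cfg$n_drugs), , drop = FALSE] < 1,
                     arr.ind = TRUE)
  is_moa_pair <- !is.na(moa_target[act_pairs[, 1]]) &
    moa_target[act_pairs[, 1]] == targets[act_pairs[, 2]]
  published <- is_moa_pair | runif(nrow(act_pairs)) < cfg$published_frac
  pub <- act_pairs[published, , drop = FALSE]
  n_ext <- sample(1:3, nrow(pub), replace = TRUE)
  pi <- rep(seq_len(nrow(pub)), n_ext)
  external_activities <- data.frame(
    drug_id = parent_ids[pub[pi, 1]],
    gene = targets[pub[pi, 2]],
    value = signif(10^(latent[cbind(pub[pi, 1], pub[pi, 2])] +
                         rnorm(length(pi), 0, 0.3)), 6),
    type = "ac50", qualifier = "=",
    source = sample(c("chembl", "drugcentral"), length(pi), replace = TRUE),
    stringsAsFactors = FALSE)

  # reference structure table for crossref
  ref_kind <- sample(c("exact", "protonation", "name_only"), cfg$n_drugs,
                     replace = TRUE, prob = c(0.8, 0.15, 0.05))
  ref_key <- keys[seq_len(cfg$n_drugs)]
  prot <- ref_kind == "protonation"
  ref_key[prot] <- paste0(substr(ref_key[prot], 1, 26),
                          sample(letters, sum(prot), replace = TRUE))
  ref_key[ref_kind == "name_only"] <- random_keys(sum(ref_kind == "name_only"))
  reference_structures <- data.frame(
    reference_id = sprintf("REF%05d", seq_len(cfg$n_drugs)),
    key = ref_key,
    names = paste0("name ", parent_ids),
    stringsAsFactors = FALSE)

  structure(list(
    activities = activities, assays = assays, drugs = drugs,
    exposure = exposure, adr_annotations = adr_annotations,
    meddra_edges = meddra_edges, external_activities = external_activities,
    reference_structures = reference_structures, ground_truth = ground_truth,
    hierarchy = hierarchy,
    decoy_map = ground_truth[!is.na(ground_truth$decoy_assay_id),
                             c("assay_id", "decoy_assay_id", "term_code")],
    config = cfg), latent = latent)
}

#' Generate a decoy-confound scenario
#'
#' A bundle in which every planted causal assay is paired with a decoy
#' assay whose latent activity correlates with the causal one at `r`,
#' while ADR labels depend only on the causal assay -- the
#' polypharmacology confound the sparse-model stage must undo.
#'
#' @param config a [sim_config()]; block structure is overridden to pairs.
#' @param r latent causal-decoy correlation.
#' @param seed optional seed override.
#' @return a bundle (see [generate_bundle()]) whose `decoy_map` pairs each
#'   causal assay with its decoy.
#' @export
generate_decoy_scenario <- function(config = sim_config(n_drugs = 600),
                                    r = 0.8, seed = NULL) {
  cfg <- config
  cfg$block_size <- 2
  cfg$block_r <- r
  cfg <- do.call(sim_config, cfg[setdiff(names(cfg), character())])
  generate_bundle(cfg, seed = seed)
}
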
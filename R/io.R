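# Delimited-text readers and writers for the pipeline's input tables.
# All tables are UTF-8, tab-separated with a header row; missing values are
# empty strings. Concentrations are micromolar throughout.

read_tsv_raw <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", na.strings = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  df
}

as_num <- function(x) suppressWarnings(as.numeric(x))
as_lgl <- function(x) {
  out <- toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")
  out[is.na(x)] <- NA
  out
}

#' Write a table as tab-separated text
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an activity table
#'
#' One row per substance x assay result (replicate-level or summarized).
#' Required columns: `drug_id`, `substance_key`, `assay_id`, `qualifier`,
#' `ac50`. Optional: `n_summarized`, `n_total`, `is_representative`.
#' An unknown qualifier anywhere rejects the whole file; rows with a
#' non-positive or non-numeric AC50 (or inconsistent replicate counts) are
#' dropped with a warning naming the offending file lines.
#'
#' @param path path to a tab-separated file.
#' @return data.frame of validated activity records.
#' @export
read_activity_table <- function(path) {
  df <- read_tsv_raw(path, c("drug_id", "substance_key", "assay_id",
                             "qualifier", "ac50"))
  bad_q <- !df$qualifier %in% c("=", ">")
  if (any(bad_q))
    stop("unknown qualifier(s) in ", basename(path), " at line(s) ",
         paste(which(bad_q) + 1L, collapse = ", "),
         " (allowed: '=', '>')")
  df$ac50 <- as_num(df$ac50)
  has_counts <- all(c("n_summarized", "n_total") %in% names(df))
  if (has_counts) {
    df$n_summarized <- as_num(df$n_summarized)
    df$n_total <- as_num(df$n_total)
  }
  if ("is_representative" %in% names(df))
    df$is_representative <- as_lgl(df$is_representative)
  bad <- !is.finite(df$ac50) | df$ac50 <= 0
  if (has_counts) {
    bad <- bad | !(df$n_summarized >= 1 & df$n_summarized <= df$n_total) |
      (df$qualifier == ">" & df$n_summarized != df$n_total)
  }
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    warning("dropping ", sum(bad), " malformed row(s) in ", basename(path),
            " at line(s) ", paste(which(bad) + 1L, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read assay metadata
#'
#' Required columns: `assay_id`, `target_gene`, `mode`, `species`,
#' `protein_class`, `event`, `format`, `readout`, `max_conc`. Optional:
#' `group_id`, `is_preferred`. `mode` must be one of binding, inhibition,
#' agonist, antagonist; `max_conc` one of 10 or 30 (micromolar).
#'
#' @inheritParams read_activity_table
#' @return data.frame of assay records.
#' @export
read_assay_table <- function(path) {
  df <- read_tsv_raw(path, c("assay_id", "target_gene", "mode", "species",
                             "protein_class", "event", "format", "readout",
                             "max_conc"))
  bad_mode <- !df$mode %in% c("binding", "inhibition", "agonist", "antagonist")
  if (any(bad_mode))
    stop("unknown assay mode(s): ", paste(unique(df$mode[bad_mode]), collapse = ", "))
  df$max_conc <- as_num(df$max_conc)
  if (!all(df$max_conc %in% c(10, 30)))
    stop("max_conc must be 10 or 30 micromolar")
  if ("is_preferred" %in% names(df)) {
    df$is_preferred <- as_lgl(df$is_preferred)
    if ("group_id" %in% names(df)) {
      n_pref <- tapply(df$is_preferred, df$group_id, sum)
      if (any(n_pref != 1))
        stop("each assay group must have exactly one preferred assay")
    }
  }
  df
}

#' Read drug metadata
#'
#' Required columns: `drug_id`, `parent_id` (empty for parent drugs),
#' `structure_key` (27-character three-block hashed key, see
#' [parse_structure_key()]), `names` (pipe-separated synonyms), `moa`
#' (pipe-separated `GENE:action` pairs, may be empty),
#' `is_active_metabolite`.
#'
#' @inheritParams read_activity_table
#' @return data.frame of drug records; `parent_id` filled with `drug_id`
#'   where empty.
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_raw(path, c("drug_id", "parent_id", "structure_key",
                             "names", "moa", "is_active_metabolite"))
  df$parent_id[is.na(df$parent_id)] <- df$drug_id[is.na(df$parent_id)]
  df$is_active_metabolite <- as_lgl(df$is_active_metabolite)
  df
}

#' Expand the pipe-separated mechanism-of-action column to long form
#' @param drugs data.frame from [read_drug_table()] (or with the same
#'   `drug_id`/`moa` columns).
#' @return data.frame with `drug_id`, `target_gene`, `action_type`.
#' @export
parse_moa <- function(drugs) {
  keep <- !is.na(drugs$moa) & nzchar(drugs$moa)
  if (!any(keep))
    return(data.frame(drug_id = character(), target_gene = character(),
                      action_type = character(), stringsAsFactors = FALSE))
  parts <- strsplit(drugs$moa[keep], "|", fixed = TRUE)
  out <- data.frame(
    drug_id = rep(drugs$drug_id[keep], lengths(parts)),
    entry = unlist(parts), stringsAsFactors = FALSE)
  split2 <- strsplit(out$entry, ":", fixed = TRUE)
  data.frame(drug_id = out$drug_id,
             target_gene = vapply(split2, `[`, "", 1L),
             action_type = vapply(split2, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Read an exposure table
#'
#' Long-format measurements: `drug_id`, `quantity` (one of `cmax_tot`
#' \[micromolar\] or `ppb_pct` \[percent bound\]), `value`; optional
#' `binding_label` (e.g. albumin/glycoprotein rows, excluded from protein
#' binding summaries) and `source`.
#'
#' @inheritParams read_activity_table
#' @return data.frame of exposure measurements.
#' @export
read_exposure_table <- function(path) {
  df <- read_tsv_raw(path, c("drug_id", "quantity", "value"))
  if (!all(df$quantity %in% c("cmax_tot", "ppb_pct")))
    stop("quantity must be cmax_tot or ppb_pct")
  df$value <- as_num(df$value)
  if (anyNA(df$value) || any(df$value < 0))
    stop("exposure values must be non-negative numbers")
  if (!"binding_label" %in% names(df)) df$binding_label <- NA_character_
  df
}

#' Read ADR annotations
#'
#' One row per drug x MedDRA preferred term x source. Required: `drug_id`,
#' `term_code`, `source` (SIDER or FAERS). Optional: `positive` (boolean;
#' SIDER rows default to positive), `lrt` and `lrt_threshold`
#' (FAERS disproportionality score and its drug-specific threshold).
#'
#' @inheritParams read_activity_table
#' @return data.frame of annotations.
#' @export
read_adr_annotations <- function(path) {
  df <- read_tsv_raw(path, c("drug_id", "term_code", "source"))
  if (!all(df$source %in% c("SIDER", "FAERS")))
    stop("source must be SIDER or FAERS")
  df$positive <- if ("positive" %in% names(df)) as_lgl(df$positive) else NA
  df$positive[is.na(df$positive) & df$source == "SIDER"] <- TRUE
  for (col in c("lrt", "lrt_threshold"))
    df[[col]] <- if (col %in% names(df)) as_num(df[[col]]) else NA_real_
  df
}

#' Read a MedDRA-like hierarchy from an edge list
#'
#' Expects columns `child_code`, `parent_code`, `child_level`,
#' `parent_level` and returns a queryable [meddra_hierarchy()] object.
#'
#' @inheritParams read_activity_table
#' @return a `meddra_hierarchy` object.
#' @export
read_meddra_hierarchy <- function(path) {
  df <- read_tsv_raw(path, c("child_code", "parent_code",
                             "child_level", "parent_level"))
  meddra_hierarchy(df)
}

#' Read a full input bundle from a directory
#'
#' Reads the standard table set written by [write_bundle()]:
#' `activities.tsv`, `assays.tsv`, `drugs.tsv`, `exposure.tsv`,
#' `adr_annotations.tsv`, `meddra_edges.tsv`, and, when present,
#' `external_activities.tsv`, `reference_structures.tsv`,
#' `ground_truth.tsv`.
#'
#' @param dir directory containing the tables.
#' @return named list of data.frames plus the parsed `hierarchy`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(
    activities = read_activity_table(p("activities.tsv")),
    assays = read_assay_table(p("assays.tsv")),
    drugs = read_drug_table(p("drugs.tsv")),
    exposure = read_exposure_table(p("exposure.tsv")),
    adr_annotations = read_adr_annotations(p("adr_annotations.tsv")),
    meddra_edges = read_tsv_raw(p("meddra_edges.tsv"),
                                c("child_code", "parent_code",
                                  "child_level", "parent_level")))
  out$hierarchy <- meddra_hierarchy(out$meddra_edges)
  for (opt in c("external_activities", "reference_structures", "ground_truth")) {
    f <- p(paste0(opt, ".tsv"))
    if (file.exists(f)) {
      tab <- read_tsv_raw(f, character())
      for (col in intersect(c("ac50", "value", "effect", "true_log10_ac50"),
                            names(tab)))
        tab[[col]] <- as_num(tab[[col]])
      out[[opt]] <- tab
    }
  }
  out
}

#' Write a bundle of input tables to a directory
#' @param bundle named list of data.frames (as from [generate_bundle()]).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    if (!is.data.frame(bundle[[nm]])) next
    write_tsv(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}
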
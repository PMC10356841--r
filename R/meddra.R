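#' A queryable MedDRA-like hierarchy
#'
#' The hierarchy links preferred terms (PT) upward through high-level terms
#' (HT) and high-level group terms (HG) to system organ classes (SOC). It is
#' a directed acyclic graph, not a tree: a term may have several parents
#' (e.g. a PT mapping to two SOCs). Construction rejects edges whose levels
#' are not strictly increasing (PT < HT < HG < SOC) and codes assigned
#' inconsistent levels, which together also rule out cycles.
#'
#' @param edges data.frame with columns `child_code`, `parent_code`,
#'   `child_level`, `parent_level`.
#' @return An object of class `meddra_hierarchy`.
#' @export
meddra_hierarchy <- function(edges) {
  req <- c("child_code", "parent_code", "child_level", "parent_level")
  if (!all(req %in% names(edges))) stop("edges needs columns: ",
                                        paste(req, collapse = ", "))
  rank <- c(PT = 1L, HT = 2L, HG = 3L, SOC = 4L)
  if (!all(edges$child_level %in% names(rank)) ||
      !all(edges$parent_level %in% names(rank)))
    stop("levels must be PT, HT, HG or SOC")
  if (!all(rank[edges$parent_level] > rank[edges$child_level]))
    stop("level inversion: every edge must go strictly upward (PT<HT<HG<SOC)")
  lv <- c(stats::setNames(edges$child_level, edges$child_code),
          stats::setNames(edges$parent_level, edges$parent_code))
  lv <- lv[!duplicated(names(lv))]
  chk <- unique(data.frame(code = c(edges$child_code, edges$parent_code),
                           level = c(edges$child_level, edges$parent_level)))
  if (anyDuplicated(chk$code))
    stop("code(s) assigned more than one level: ",
         paste(unique(chk$code[duplicated(chk$code)]), collapse = ", "))
  h <- structure(list(
    edges = edges,
    level = lv,
    parents = split(edges$parent_code, edges$child_code),
    children = split(edges$child_code, edges$parent_code)),
    class = "meddra_hierarchy")
  pts <- meddra_terms(h, "PT")
  no_soc <- pts[vapply(pts, function(p) length(socs_of(h, p)) == 0L, TRUE)]
  if (length(no_soc))
    stop("PT(s) with no SOC ancestor: ", paste(no_soc, collapse = ", "))
  h
}

#' @export
print.meddra_hierarchy <- function(x, ...) {
  tab <- table(factor(x$level, levels = c("PT", "HT", "HG", "SOC")))
  cat("MedDRA-like hierarchy:", paste(tab, names(tab), collapse = ", "),
      "/", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Hierarchy queries
#'
#' `meddra_level` returns the level of a code; `meddra_parents` /
#' `meddra_children` the immediate neighbours; `meddra_ancestors` /
#' `meddra_descendants` every code reachable at a given level;
#' `socs_of` the SOC ancestors of any term; `pts_under` the PT leaves below
#' a term; `siblings_under_ht` the other PTs sharing at least one parent HT
#' with a PT; `sisters_of` the other same-level terms sharing at least one
#' parent with a term. For multi-parent terms the sibling/sister sets are
#' unions over all parents.
#'
#' @param h a [meddra_hierarchy()].
#' @param code a term code.
#' @param level target level for ancestor/descendant queries.
#' @return character vector of term codes (or a level string).
#' @name meddra-queries
NULL

#' @rdname meddra-queries
#' @export
meddra_level <- function(h, code) {
  out <- unname(h$level[code])
  if (anyNA(out)) stop("unknown term code(s): ",
                       paste(code[is.na(out)], collapse = ", "))
  out
}

#' @rdname meddra-queries
#' @export
meddra_terms <- function(h, level) names(h$level)[h$level == level]

#' @rdname meddra-queries
#' @export
meddra_parents <- function(h, code) unique(unlist(h$parents[code], use.names = FALSE))

#' @rdname meddra-queries
#' @export
meddra_children <- function(h, code) unique(unlist(h$children[code], use.names = FALSE))

walk <- function(h, code, level, dir = c("up", "down")) {
  dir <- match.arg(dir)
  step <- if (dir == "up") h$parents else h$children
  seen <- character()
  frontier <- code
  while (length(frontier)) {
    frontier <- unique(unlist(step[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
  }
  seen[h$level[seen] == level & !is.na(h$level[seen])]
}

#' @rdname meddra-queries
#' @export
meddra_ancestors <- function(h, code, level) walk(h, code, level, "up")

#' @rdname meddra-queries
#' @export
meddra_descendants <- function(h, code, level) walk(h, code, level, "down")

#' @rdname meddra-queries
#' @export
socs_of <- function(h, code) meddra_ancestors(h, code, "SOC")

#' @rdname meddra-queries
#' @export
pts_under <- function(h, code) {
  if (meddra_level(h, code) == "PT") return(code)
  meddra_descendants(h, code, "PT")
}

#' @rdname meddra-queries
#' @export
siblings_under_ht <- function(h, pt) {
  stopifnot(meddra_level(h, pt) == "PT")
  hts <- intersect(meddra_parents(h, pt), meddra_terms(h, "HT"))
  setdiff(unique(unlist(h$children[hts], use.names = FALSE)), pt)
}

#' @rdname meddra-queries
#' @export
sisters_of <- function(h, code) {
  lvl <- meddra_level(h, code)
  up <- meddra_parents(h, code)
  sibs <- unique(unlist(h$children[up], use.names = FALSE))
  setdiff(sibs[h$level[sibs] == lvl], code)
}
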
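#' Qualified concentration values
#'
#' Panel results are reported as an AC50 in micromolar with a qualifier:
#' `"="` for a measured value, `">"` for a right-censored result where no
#' activity was detected up to the highest tested concentration (the stored
#' value). The same pair represents safety margins, which inherit the
#' qualifier of the AC50 they derive from.
#'
#' @param qualifier character vector of `"="`/`">"` codes.
#' @param value positive numeric vector, same length as `qualifier`.
#' @return Invisibly `TRUE`; called for its validation side effect.
#' @export
assert_qualified <- function(qualifier, value) {
  if (length(qualifier) != length(value))
    stop("qualifier and value must have the same length")
  bad_q <- !qualifier %in% c("=", ">")
  if (any(bad_q))
    stop("unknown qualifier(s): ", paste(unique(qualifier[bad_q]), collapse = ", "))
  bad_v <- !is.finite(value) | value <= 0
  if (any(bad_v))
    stop("values must be finite and positive; offending positions: ",
         paste(which(bad_v), collapse = ", "))
  invisible(TRUE)
}

geometric_mean <- function(x) {
  if (length(x) == 1L) return(x)  # exact on singletons
  exp(mean(log(x)))
}

#' Summarize replicate qualified AC50 values
#'
#' Replicate runs of one substance in one assay are collapsed to a single
#' qualified AC50. If any replicate was measured (`"="`), the summary is the
#' geometric mean of the measured values with qualifier `"="`, and
#' `n_summarized` counts the measured replicates. If every replicate is
#' censored (`">"`), the summary keeps qualifier `">"` with the largest
#' censoring level, and all replicates count as summarized.
#'
#' @inheritParams assert_qualified
#' @return List with `qualifier`, `value`, `n_summarized`, `n_total`.
#' @examples
#' summarize_ac50(c(">", ">"), c(1, 30))   # ">" 30, 2 of 2
#' summarize_ac50(c("=", "="), c(1, 100))  # "=" 10
#' @export
summarize_ac50 <- function(qualifier, value) {
  if (length(value) == 0L) stop("cannot summarize an empty replicate set")
  assert_qualified(qualifier, value)
  measured <- qualifier == "="
  if (any(measured)) {
    list(qualifier = "=", value = geometric_mean(value[measured]),
         n_summarized = sum(measured), n_total = length(value))
  } else {
    list(qualifier = ">", value = max(value),
         n_summarized = length(value), n_total = length(value))
  }
}
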
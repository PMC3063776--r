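#' Consensus of per-method risk calls
#'
#' Combines the calls of two or more classifiers for each individual into a
#' single call: high-risk only when at least `min_high` methods (default 2)
#' call the individual high-risk, low-risk otherwise.  Under the default
#' rule a `"cnc"` (could-not-classify) entry simply counts as a non-high
#' vote and the consensus itself never emits `"cnc"`; the alternative
#' `cnc = "propagate"` mode instead returns `"cnc"` for any individual with
#' at least one `"cnc"` vote.
#'
#' @param calls a character matrix or data frame with one column per method
#'   and one row per individual, entries in `{"high", "low", "cnc"}`; a
#'   single individual may also be given as a character vector of length
#'   >= 2.
#' @param min_high number of high votes required for a consensus high call.
#' @param cnc `"low"` (default: CNC is a non-high vote) or `"propagate"`.
#' @return Character vector of consensus calls, one per individual.
#' @export
consensus_call <- function(calls, min_high = 2L, cnc = c("low", "propagate")) {
  cnc <- match.arg(cnc)
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  if (is.vector(calls) && is.character(calls)) {
    calls <- matrix(calls, nrow = 1L)
  }
  if (!is.matrix(calls) || ncol(calls) < 2L) {
    stop("a consensus needs calls from at least 2 methods", call. = FALSE)
  }
  if (!all(calls %in% c("high", "low", "cnc"))) {
    stop("calls must be 'high', 'low' or 'cnc'", call. = FALSE)
  }
  out <- ifelse(rowSums(calls == "high") >= min_high, "high", "low")
  if (cnc == "propagate") {
    out[rowSums(calls == "cnc") > 0L] <- "cnc"
  }
  out
}
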
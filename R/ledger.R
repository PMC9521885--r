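#' Create a filter ledger
#'
#' A filter ledger is the audit trail of a pipeline run: one row per filtering
#' rule applied, recording how many rows went in, came out, and were dropped.
#' Every ingestion and scoring step that can discard rows writes to the ledger
#' instead of dropping them silently, so the closure invariant
#' `rows_in - rows_dropped = rows_out` can be checked at every stage.
#'
#' The ledger is a mutable environment so that a single ledger can be threaded
#' through all pipeline stages without copying.
#'
#' @return An object of class `filter_ledger`.
#' @seealso [ledger_add()], [as.data.frame.filter_ledger()]
#' @export
#' @examples
#' led <- new_ledger()
#' ledger_add(led, "drop_negative_visits", rows_in = 100, rows_out = 98)
#' as.data.frame(led)
new_ledger <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  class(env) <- "filter_ledger"
  env
}

#' Record a filtering rule in a ledger
#'
#' @param ledger a [new_ledger()] object.
#' @param rule character name of the rule.
#' @param rows_in,rows_out row counts before and after the rule.
#' @param detail optional free-text note (e.g. which units were affected).
#' @return The ledger, invisibly.
#' @export
ledger_add <- function(ledger, rule, rows_in, rows_out, detail = NA_character_) {
  stopifnot(inherits(ledger, "filter_ledger"), rows_out <= rows_in, rows_out >= 0)
  ledger$entries[[length(ledger$entries) + 1L]] <- list(
    rule = rule, rows_in = as.integer(rows_in), rows_out = as.integer(rows_out),
    rows_dropped = as.integer(rows_in - rows_out), detail = detail
  )
  invisible(ledger)
}

#' @export
as.data.frame.filter_ledger <- function(x, ...) {
  if (length(x$entries) == 0L) {
    return(data.frame(rule = character(), rows_in = integer(), rows_out = integer(),
                      rows_dropped = integer(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$entries, function(e) {
    data.frame(rule = e$rule, rows_in = e$rows_in, rows_out = e$rows_out,
               rows_dropped = e$rows_dropped, detail = e$detail,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.filter_ledger <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Filter ledger:", nrow(df), "rule(s),",
      sum(df$rows_dropped), "row(s) dropped in total\n")
  if (nrow(df) > 0L) print(df, row.names = FALSE)
  invisible(x)
}
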
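# Classed conditions so callers can distinguish validation failures from
# computation failures (tryCatch on the subclass).

rw_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "restwatch_error"), call = call))
}

#' Test whether a condition is a restwatch error of a given subclass
#'
#' @param cond a condition object
#' @param class subclass name, e.g. "rw_malformed_epoch"
#' @return logical
#' @export
is_rw_error <- function(cond, class = "restwatch_error") {
  inherits(cond, class)
}
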
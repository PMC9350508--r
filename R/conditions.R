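# Classed error conditions.
#
# Every user-facing failure mode maps onto one of a small set of condition
# classes so callers (and the CLI) can react programmatically:
#   cg_not_found    - a body id, connection, type, or archive that does not exist
#   cg_input_error  - invalid arguments (bad regex, unknown ROI, bad event)
#   cg_ingest_error - raw bundle fails schema or referential-integrity checks
#   cg_format_error - malformed SWC text
#   cg_undefined    - a metric whose denominator is empty (never reported as 0/0)
#   cg_budget_error - path search exceeded its node-expansion budget
#   cg_log_error    - an edit log failed mid-application (carries partial state)
# All inherit from "cg_error".

cg_stop <- function(class, fmt, ..., data = NULL) {
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "cg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L), data = data)
  ))
}

# Validate a user-supplied regular expression and apply the full-match rule:
# patterns are matched against the whole type/instance string unless the
# caller anchors them explicitly with ^ or $.
cg_regex <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    cg_stop("cg_input_error", "pattern must be a single character string")
  ok <- tryCatch({grepl(pattern, "x", perl = TRUE); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    cg_stop("cg_input_error", "invalid regular expression: %s", pattern)
  if (startsWith(pattern, "^") || endsWith(pattern, "$")) pattern
  else paste0("^(?:", pattern, ")$")
}

cg_regex_match <- function(pattern, x) {
  pat <- cg_regex(pattern)
  !is.na(x) & grepl(pat, x, perl = TRUE)
}
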
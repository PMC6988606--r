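# Condition classes used across the package. Every user-facing failure is a
# classed condition so the CLI can map it to a distinct exit code and tests
# can assert on the failure kind rather than on message text.
#
# Class hierarchy (all inherit from "refassets_error"):
#   refassets_parse_error     - malformed registry path
#   refassets_schema_error    - malformed or version-incompatible config file
#   refassets_missing_error   - lookup failed; carries `level` (genome/asset/tag/seek_key)
#   refassets_exists_error    - refusing to overwrite without `force`
#   refassets_build_error     - asset build failed
#   refassets_usage_error     - bad command-line usage
#   refassets_network_error   - no server reachable
#   refassets_integrity_error - digest verification failed

refassets_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "refassets_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_parse <- function(message) refassets_abort(message, "refassets_parse_error")

abort_schema <- function(message) refassets_abort(message, "refassets_schema_error")

#' @noRd
#' @param level which namespace level failed: "genome", "asset", "tag" or
#'   "seek_key" -- callers (and the server's not-found responses) rely on it.
abort_missing <- function(message, level) {
  refassets_abort(message, "refassets_missing_error", level = level)
}

abort_exists <- function(message) refassets_abort(message, "refassets_exists_error")

abort_build <- function(message) refassets_abort(message, "refassets_build_error")

abort_usage <- function(message) refassets_abort(message, "refassets_usage_error")

abort_network <- function(message) refassets_abort(message, "refassets_network_error")

abort_integrity <- function(message) refassets_abort(message, "refassets_integrity_error")
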
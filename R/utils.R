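# Classed conditions used across the package: schema (missing columns),
# validation (bad values, with row numbers), integrity (key violations), io.

abort_schema <- function(msg) {
  rlang::abort(msg, class = c("ctpa_schema_error", "ctpa_error"))
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = c("ctpa_validation_error", "ctpa_error"))
}

abort_integrity <- function(msg) {
  rlang::abort(msg, class = c("ctpa_integrity_error", "ctpa_error"))
}

abort_io <- function(msg) {
  rlang::abort(msg, class = c("ctpa_io_error", "ctpa_error"))
}

# Parse ISO-8601-ish timestamps as site-local wall-clock time. All
# comparisons in the package are same-site, so timestamps are held in UTC
# purely to avoid DST arithmetic; no timezone conversion is ever applied.
parse_wallclock <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

format_wallclock <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}
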
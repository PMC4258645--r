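# Condition helpers. Three broad families map onto the CLI exit codes:
# config (2), analysis (3), io (4). Specific subclasses come first so
# callers can catch e.g. "swf_centre_not_found" without string matching.

swf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "swf_error"), call = call))
}

swf_config_error <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s [field: %s]", msg, field)
  swf_stop(msg, "swf_config_error")
}

swf_analysis_error <- function(msg, subclass = NULL) {
  swf_stop(msg, c(subclass, "swf_analysis_error"))
}

swf_io_error <- function(msg) {
  swf_stop(msg, "swf_io_error")
}

#' @keywords internal
stopifnot_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    swf_config_error(sprintf("'%s' must be a finite numeric scalar", name),
                     field = name)
  if (strict_min && x <= min)
    swf_config_error(sprintf("'%s' must be > %g", name, min), field = name)
  if (!strict_min && x < min)
    swf_config_error(sprintf("'%s' must be >= %g", name, min), field = name)
  invisible(x)
}
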
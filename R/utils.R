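#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor density dist hclust cutree pt sd var setNames
#' @importFrom utils head tail
NULL

.datatable.aware <- TRUE

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0)
    stopf("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

# Stage-boundary log line with parameter echo; silenced via
# options(evomics.verbose = FALSE).
log_stage <- function(stage, ...) {
  if (!isTRUE(getOption("evomics.verbose", TRUE))) return(invisible(NULL))
  params <- list(...)
  msg <- if (length(params))
    paste0(names(params), "=", vapply(params, function(p)
      paste(format(p, digits = 6), collapse = ","), character(1)),
      collapse = " ")
  else ""
  message(sprintf("[evomics:%s] %s", stage, msg))
  invisible(NULL)
}
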
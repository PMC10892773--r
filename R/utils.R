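#' @useDynLib pdmil, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats kmeans median rnorm runif sd var fft quantile
#' @importFrom utils head tail
NULL

# classed conditions so callers/tests can match on error class
pd_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pdmil_error")))
}

pd_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "pdmil_warning")))
}

# Derive a child seed from a parent seed and one or more integer tags.
# Kept inside 32-bit range; multiplicative hashing keeps streams for
# neighbouring tags uncorrelated.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483629
  for (t in tags) h <- (h * 48271 + as.double(t) + 1) %% 2147483629
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shallow-merge user options over defaults (one level of nesting)
merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}
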
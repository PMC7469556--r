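#' @keywords internal
"_PACKAGE"

#' @useDynLib adipolink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree dist hclust prcomp pt phyper p.adjust
#'   quantile rnorm rbinom runif sd var setNames as.dist IQR median
#' @importFrom utils read.delim write.table head
NULL

# Internal messaging helper: all progress/attrition notes flow through here so
# callers can silence them with suppressMessages().
log_note <- function(...) {
  message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Deterministic alphabetical sort regardless of user locale.
sort_c <- function(x) sort(x, method = "radix")
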
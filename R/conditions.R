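#' @useDynLib segeval, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile qt pt approx rnorm rlnorm runif sd setNames
#' @importFrom utils write.csv
NULL

# Classed error conditions so callers (and tests) can discriminate failure
# modes: segeval_<class> plus the generic segeval_error.
seg_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("segeval_", class), "segeval_error")))
}

seg_warn <- function(msg, class = "warning") {
  warning(warningCondition(msg, class = c(paste0("segeval_", class), "segeval_warning")))
}
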
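#' @keywords internal
#' @aliases slitmicelle-package
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% .data abort warn
#' @useDynLib slitmicelle, .registration = TRUE
"_PACKAGE"

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# centered moving average with odd window; ends use shrunken windows
moving_average <- function(x, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1 || length(x) < 3) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
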
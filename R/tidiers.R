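#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname run_grid
#' @param x An `experiment_summary`.
#' @param ... Unused.
#' @export
tidy.experiment_summary <- function(x, ...) x$runs

#' @rdname run_grid
#' @export
glance.experiment_summary <- function(x, ...) x$conditions
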
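#' Lambda schedules for alchemical transformations
#'
#' A lambda schedule is the ordered set of mixing parameters defining the
#' intermediate states V(lambda) = (1 - lambda) V0 + lambda V1 between the
#' two end-state ligands. It must start at 0, end at 1 and be strictly
#' increasing. The default production schedule uses 13 values, denser near
#' the endpoints where the potential changes fastest.
#'
#' @param values Numeric vector of mixing parameters in `[0, 1]`.
#' @return A numeric vector with class `"lambda_schedule"`.
#' @examples
#' lambda_schedule()           # the 13-window default
#' lambda_schedule(c(0, 0.5, 1))
#' @export
lambda_schedule <- function(values = lambda_default()) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("a lambda schedule needs at least two numeric values", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("lambda values must be finite", call. = FALSE)
  if (values[1L] != 0 || values[length(values)] != 1)
    stop("lambda schedule must start at 0 and end at 1", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("lambda schedule must be strictly increasing", call. = FALSE)
  structure(as.numeric(values), class = "lambda_schedule")
}

#' @rdname lambda_schedule
#' @export
lambda_default <- function() {
  c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 1)
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat("lambda schedule with", length(x), "states:\n")
  print(unclass(x), ...)
  invisible(x)
}
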
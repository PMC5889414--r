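#' Reduced-potential sample matrix
#'
#' The sole input of the multistate estimators: every sample drawn in any of
#' the K lambda states, evaluated in *all* K states, in reduced (kT) units.
#' Row k holds u_k(x_n) for all N samples; `origin` records which state
#' generated each sample and `n_k` the per-state sample counts.
#'
#' @param u Numeric K x N matrix of reduced potentials (dimensionless).
#' @param origin Integer vector of length N giving the generating state of
#'   each column (1-based). Columns must be grouped so that all samples of
#'   state 1 come first, then state 2, and so on; `n_k` is derived from it.
#' @param temperature Temperature in kelvin at which the potentials were
#'   reduced (default 300).
#' @param schedule Optional [lambda_schedule()] with one value per row.
#' @return An object of class `"reduced_potential"`.
#' @export
reduced_potential <- function(u, origin, temperature = 300, schedule = NULL) {
  u <- as.matrix(u)
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("reduced potentials must all be finite numbers", call. = FALSE)
  K <- nrow(u)
  N <- ncol(u)
  origin <- as.integer(origin)
  if (length(origin) != N)
    stop("'origin' must attribute every sample (column) to one state",
         call. = FALSE)
  if (anyNA(origin) || any(origin < 1L) || any(origin > K))
    stop("'origin' entries must index rows of 'u'", call. = FALSE)
  if (is.unsorted(origin))
    stop("samples must be ordered by generating state", call. = FALSE)
  n_k <- tabulate(origin, nbins = K)
  if (sum(n_k) != N)
    stop("sample counts n_k must sum to the number of columns", call. = FALSE)
  if (!is.null(schedule)) {
    schedule <- lambda_schedule(schedule)
    if (length(schedule) != K)
      stop("schedule length (", length(schedule),
           ") does not match the number of states (", K, ")", call. = FALSE)
  }
  structure(
    list(u = u, n_k = n_k, origin = origin,
         temperature = temperature, schedule = schedule),
    class = "reduced_potential")
}

#' @export
print.reduced_potential <- function(x, ...) {
  cat("reduced-potential matrix:", nrow(x$u), "states x", ncol(x$u),
      "samples at", x$temperature, "K\n")
  cat("samples per state:", paste(x$n_k, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.reduced_potential <- function(x) dim(x$u)

#' Reverse the state order of a reduced-potential matrix
#'
#' Used to check estimator antisymmetry: the end-to-end free energy of the
#' reversed matrix is the negation of the original.
#'
#' @param x A [reduced_potential()] object.
#' @return A [reduced_potential()] with rows (and sample blocks) reversed.
#' @export
reverse_states <- function(x) {
  stopifnot(inherits(x, "reduced_potential"))
  K <- nrow(x$u)
  ord <- order(K + 1L - x$origin)  # regroup columns so new state 1 first
  reduced_potential(x$u[K:1, ord, drop = FALSE],
                    origin = (K + 1L - x$origin)[ord],
                    temperature = x$temperature,
                    schedule = if (!is.null(x$schedule))
                      lambda_schedule(rev(1 - as.numeric(x$schedule))))
}
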
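#' Exponential-averaging free-energy estimate
#'
#' The single-direction (Zwanzig) estimator
#' \eqn{\Delta G = -\log \langle e^{-w} \rangle} from work values in kT
#' units, computed with a log-sum-exp so that large works cannot overflow.
#' Biased when phase-space overlap is poor; use the diagnostics in
#' [assess_windows()] to judge reliability.
#'
#' @param w Numeric vector of work values (kT).
#' @return Free-energy difference in kT.
#' @export
exponential_average <- function(w) {
  if (length(w) == 0L) stop("no work values supplied", call. = FALSE)
  if (any(!is.finite(w))) stop("work values must be finite", call. = FALSE)
  -(logsumexp(-w) - log(length(w)))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Bennett acceptance ratio (two-state) estimate
#'
#' Solves the Bennett self-consistency equation for the free-energy
#' difference between two states from forward works (sampled in the initial
#' state) and reverse works (sampled in the final state), both in kT.
#' Implemented independently of [mbar()] as a root find on the Fermi-function
#' balance, so the two can cross-validate each other: at K = 2 they agree to
#' numerical precision.
#'
#' @param w_fwd Forward work values w = u_1 - u_0 on samples from state 0
#'   (kT).
#' @param w_rev Reverse work values w = u_0 - u_1 on samples from state 1
#'   (kT).
#' @param tol Root-finding tolerance (kT).
#' @return Free-energy difference state 0 -> state 1, in kT.
#' @export
bar <- function(w_fwd, w_rev, tol = 1e-12) {
  if (length(w_fwd) == 0L || length(w_rev) == 0L)
    stop("both work directions are required", call. = FALSE)
  stopifnot(all(is.finite(w_fwd)), all(is.finite(w_rev)))
  M <- log(length(w_fwd) / length(w_rev))
  fermi <- function(x) 1 / (1 + exp(x))
  # increasing in dG: root is unique
  g <- function(dG) sum(fermi(M + w_fwd - dG)) - sum(fermi(-M + w_rev + dG))
  lo <- -(max(abs(w_fwd)) + max(abs(w_rev)) + abs(M) + 10)
  hi <- -lo
  while (g(lo) > 0) lo <- 2 * lo
  while (g(hi) < 0) hi <- 2 * hi
  stats::uniroot(g, c(lo, hi), tol = tol)$root
}

#' Free-energy estimates with provenance
#'
#' A value/standard-error pair in kJ/mol tagged with the leg it came from:
#' `"protein"` or `"water"` for single transformation legs, `"binding"` only
#' for cycle-combined relative binding free energies.
#'
#' @param value Free-energy difference, kJ/mol.
#' @param se Standard error, kJ/mol (nonnegative).
#' @param phase One of `"protein"`, `"water"`, `"binding"`.
#' @param transformation Transformation label (e.g. `"OMe->OH"`).
#' @return An object of class `"fep_estimate"`.
#' @export
free_energy_estimate <- function(value, se, phase = c("protein", "water",
                                                      "binding"),
                                 transformation = NA_character_) {
  phase <- match.arg(phase)
  stopifnot(is.finite(value), is.finite(se), se >= 0)
  structure(list(value = value, se = se, phase = phase,
                 transformation = transformation),
            class = "fep_estimate")
}

#' @export
print.fep_estimate <- function(x, ...) {
  cat(sprintf("%s%s: %.3f +/- %.3f kJ/mol\n",
              if (is.na(x$transformation)) "" else paste0(x$transformation,
                                                          " "),
              switch(x$phase, binding = "ddG_bind", paste0("dG_", x$phase)),
              x$value, x$se))
  invisible(x)
}

#' End-to-end free energy of a transformation leg
#'
#' Fits [mbar()] over the full lambda schedule of one leg and returns the
#' end-to-end free-energy difference in kJ/mol, with a stratified-bootstrap
#' standard error.
#'
#' @param u A [reduced_potential()] for the leg.
#' @param phase `"protein"` or `"water"`.
#' @param transformation Transformation label.
#' @param n_boot Bootstrap resamples (default 100).
#' @param seed Optional seed for the bootstrap.
#' @param ... Passed to [mbar()].
#' @return A [free_energy_estimate()].
#' @export
leg_free_energy <- function(u, phase = c("protein", "water"),
                            transformation = NA_character_, n_boot = 100L,
                            seed = NULL, ...) {
  phase <- match.arg(phase)
  fit <- mbar(u, n_boot = n_boot, seed = seed, ...)
  K <- length(fit$f)
  kT <- kT_kJmol(fit$temperature)
  se_kT <- if (n_boot > 0L)
    stats::sd(fit$boot_f[, K] - fit$boot_f[, 1L]) else 0
  free_energy_estimate((fit$f[K] - fit$f[1L]) * kT, se_kT * kT,
                       phase = phase, transformation = transformation)
}

#' Combine leg standard errors in quadrature
#'
#' Independent window or leg uncertainties propagate as
#' \eqn{SE = \sqrt{\sum_i SE_i^2}}.
#'
#' @param se Numeric vector of standard errors.
#' @return Combined standard error.
#' @export
se_quadrature <- function(se) {
  stopifnot(all(is.finite(se)), all(se >= 0))
  sqrt(sum(se^2))
}

#' Thermodynamic-cycle combination of two legs
#'
#' The relative binding free energy of a ligand transformation is the
#' difference of the same alchemical transformation carried out in the
#' protein binding site and free in solution:
#' \eqn{\Delta\Delta G_{bind} = \Delta G_{protein} - \Delta G_{water}},
#' with the standard errors combined in quadrature.
#'
#' @param protein,water [free_energy_estimate()] objects for the two legs of
#'   the same transformation.
#' @return A [free_energy_estimate()] with `phase = "binding"`.
#' @export
combine_cycle <- function(protein, water) {
  stopifnot(inherits(protein, "fep_estimate"), inherits(water,
                                                        "fep_estimate"))
  if (protein$phase != "protein" || water$phase != "water")
    stop("combine_cycle() expects a protein leg and a water leg",
         call. = FALSE)
  if (!identical(protein$transformation, water$transformation))
    stop("legs belong to different transformations: ",
         protein$transformation, " vs ", water$transformation,
         call. = FALSE)
  free_energy_estimate(protein$value - water$value,
                       se_quadrature(c(protein$se, water$se)),
                       phase = "binding",
                       transformation = protein$transformation)
}
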
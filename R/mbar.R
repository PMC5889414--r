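#' Fit the multistate Bennett acceptance ratio estimator
#'
#' `mbar()` is the central fitting function of the package. Given reduced
#' potentials of every sample evaluated in every lambda state it solves the
#' MBAR self-consistency equations
#' \deqn{f_i = -\log \sum_n \frac{\exp(-u_{in})}{\sum_k N_k \exp(f_k - u_{kn})}}
#' for the dimensionless state free energies, anchored at `f[1] = 0`. The
#' solver runs damped self-consistent iteration with log-sum-exp
#' stabilisation and switches to BFGS minimisation of the equivalent convex
#' objective when the fixed-point iteration stalls; both paths are
#' overflow-safe. Uncertainties come from a stratified bootstrap: samples
#' are redrawn with replacement *within* each sampling state, preserving the
#' per-state sample counts.
#'
#' Samples are treated as uncorrelated (as after subsampling a trajectory at
#' an interval beyond its correlation time); no statistical-inefficiency
#' correction is applied.
#'
#' @param u A [reduced_potential()] object, or a K x N numeric matrix of
#'   reduced potentials (then `origin` is required).
#' @param origin Integer vector attributing each column to its generating
#'   state (ignored when `u` is a [reduced_potential()]).
#' @param temperature Temperature in kelvin, used by methods that convert
#'   to kJ/mol.
#' @param tol Relative convergence tolerance on the free energies.
#' @param max_iter Maximum number of solver iterations.
#' @param n_boot Number of stratified bootstrap resamples for standard
#'   errors; 0 skips the bootstrap (then `se` is `NA` except `se[1] = 0`).
#' @param seed Optional integer seed for the bootstrap, applied locally
#'   (the caller's random-number state is restored on exit).
#' @return An object of class `"mbar"` with components `f` (anchored state
#'   free energies, kT), `se` (bootstrap standard errors, kT), `n_k`,
#'   `n_iterations`, `temperature`, `schedule` and, when bootstrapped,
#'   `boot_f` (the n_boot x K matrix of anchored resample solutions).
#' @seealso [bar()] for the two-state special case, [leg_free_energy()] for
#'   the kJ/mol end-to-end estimate of a transformation leg.
#' @examples
#' leg <- generate_harmonic_leg(harmonic_leg_spec(n_per_state = 100), seed = 1)
#' fit <- mbar(leg$u, n_boot = 20, seed = 1)
#' fit
#' coef(fit)[13] - leg$exact_df  # estimation error in kT
#' @export
mbar <- function(u, origin = NULL, temperature = 300, tol = 1e-10,
                 max_iter = 10000L, n_boot = 0L, seed = NULL) {
  if (!inherits(u, "reduced_potential")) {
    if (is.null(origin))
      stop("'origin' is required when 'u' is a plain matrix", call. = FALSE)
    u <- reduced_potential(u, origin = origin, temperature = temperature)
  }
  if (sum(u$n_k > 0L) < 2L)
    stop("MBAR needs at least two states with samples", call. = FALSE)
  sol <- mbar_solve(u$u, u$n_k, tol = tol, max_iter = max_iter)
  se <- rep(NA_real_, length(sol$f))
  se[1L] <- 0
  boot_f <- NULL
  if (n_boot > 0L) {
    if (n_boot < 2L) stop("n_boot must be at least 2", call. = FALSE)
    boot_f <- mbar_bootstrap(u, n_boot = n_boot, seed = seed,
                             f_init = sol$f, tol = tol, max_iter = max_iter)
    se <- apply(boot_f, 2L, stats::sd)
    se[1L] <- 0
  }
  structure(
    list(f = sol$f, se = se, n_k = u$n_k, n_iterations = sol$n_iterations,
         converged = TRUE, temperature = u$temperature,
         schedule = u$schedule, n_boot = n_boot, boot_f = boot_f,
         u = u),
    class = "mbar")
}

# Damped self-consistent iteration (compiled, log-sum-exp stabilised) with
# a quasi-Newton rescue on the equivalent convex objective when the fixed
# point stalls. u: K x N, n_k: counts (zeros allowed). Returns anchored f.
mbar_solve <- function(u, n_k, tol = 1e-10, max_iter = 10000L,
                       f_init = NULL) {
  K <- nrow(u)
  f <- if (is.null(f_init)) numeric(K) else f_init - f_init[1L]
  phase1 <- min(200L, max_iter)
  res <- .mbar_scf_fast(u, as.integer(n_k), f, tol, phase1)
  if (!res$stable)  # extreme potentials: rerun fully in the log domain
    res <- .mbar_scf(u, as.integer(n_k), f, tol, phase1)
  if (!res$converged && phase1 < max_iter) {
    # stalled: quasi-Newton refinement, then resume the fixed point
    sampled <- which(n_k > 0L)
    f <- mbar_bfgs(u, n_k, sampled, log(n_k[sampled]), res$f)
    res2 <- .mbar_scf(u, as.integer(n_k), f, tol, max_iter - phase1)
    res2$n_iterations <- res2$n_iterations + res$n_iterations
    res <- res2
  }
  if (!res$converged)
    stop("MBAR failed to converge in ", max_iter,
         " iterations (residual ", signif(res$residual, 3), ")",
         call. = FALSE)
  list(f = res$f, n_iterations = res$n_iterations)
}

# convex objective: sum_n log sum_k n_k exp(f_k - u_kn) - sum_k n_k f_k,
# minimised over f[-1] with f[1] = 0 (gradient is the self-consistency gap)
mbar_bfgs <- function(u, n_k, sampled, log_nk, f) {
  K <- nrow(u)
  obj <- function(ff) {
    f_full <- c(0, ff)
    a <- (log_nk + f_full[sampled]) - u[sampled, , drop = FALSE]
    amax <- colmax(a)
    sum(amax + log(colSums(exp(a - rep(amax, each = nrow(a)))))) -
      sum(n_k * f_full)
  }
  grad <- function(ff) {
    f_full <- c(0, ff)
    a <- (log_nk + f_full[sampled]) - u[sampled, , drop = FALSE]
    amax <- colmax(a)
    log_denom <- amax + log(colSums(exp(a - rep(amax, each = nrow(a)))))
    # expected sample counts under current f
    w <- exp((log_nk + f_full[sampled]) - u[sampled, , drop = FALSE] -
               rep(log_denom, each = length(sampled)))
    exp_counts <- numeric(K)
    exp_counts[sampled] <- rowSums(w)
    (exp_counts - n_k)[-1L]
  }
  fit <- stats::optim(f[-1L], obj, grad, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  c(0, fit$par)
}

mbar_bootstrap <- function(u, n_boot, seed, f_init, tol, max_iter) {
  K <- nrow(u$u)
  groups <- split(seq_len(ncol(u$u)), u$origin)
  with_local_seed(seed, {
    boot_f <- matrix(NA_real_, n_boot, K)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]),
        use.names = FALSE)
      sol <- tryCatch(
        mbar_solve(u$u[, idx, drop = FALSE], u$n_k, tol = tol,
                   max_iter = max_iter, f_init = f_init),
        error = function(e)
          stop("bootstrap resample ", b, ": ", conditionMessage(e),
               call. = FALSE))
      boot_f[b, ] <- sol$f
    }
    boot_f
  })
}

# column maxima via a running elementwise max over rows: O(K) vectorised
# ops, not O(N) function calls (N can be thousands of samples)
colmax <- function(m) {
  out <- m[1L, ]
  for (i in seq_len(nrow(m))[-1L]) {
    v <- m[i, ]
    gt <- v > out
    if (any(gt)) out[gt] <- v[gt]
  }
  out
}
rowmax <- function(m) {
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) out[i] <- max(m[i, ])
  out
}

# run code with a locally-set RNG seed, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' @export
print.mbar <- function(x, ...) {
  K <- length(x$f)
  cat("MBAR fit:", K, "states,", sum(x$n_k), "samples,",
      x$n_iterations, "iterations\n")
  kT <- kT_kJmol(x$temperature)
  cat(sprintf("end-to-end delta f = %.4f kT (%.3f kJ/mol)",
              x$f[K] - x$f[1L], (x$f[K] - x$f[1L]) * kT))
  if (x$n_boot > 0L)
    cat(sprintf(" +/- %.4f kT [%d bootstrap resamples]",
                sqrt(x$se[K]^2 + x$se[1L]^2), x$n_boot))
  cat("\n")
  invisible(x)
}

#' @export
coef.mbar <- function(object, ...) object$f

#' @export
summary.mbar <- function(object, ...) {
  K <- length(object$f)
  df <- data.frame(
    state = seq_len(K) - 1L,
    lambda = if (!is.null(object$schedule)) as.numeric(object$schedule)
             else NA_real_,
    n = object$n_k,
    f_kT = object$f,
    se_kT = object$se)
  structure(list(states = df, temperature = object$temperature,
                 n_boot = object$n_boot,
                 delta_f = object$f[K] - object$f[1L]),
            class = "summary.mbar")
}

#' @export
print.summary.mbar <- function(x, ...) {
  cat("MBAR state free energies (kT, anchored at state 0) at",
      x$temperature, "K\n")
  print(x$states, row.names = FALSE, digits = 4)
  cat(sprintf("end-to-end delta f: %.4f kT = %.3f kJ/mol\n", x$delta_f,
              x$delta_f * kT_kJmol(x$temperature)))
  invisible(x)
}

#' @export
plot.mbar <- function(x, ...) {
  lam <- if (!is.null(x$schedule)) as.numeric(x$schedule)
         else seq_along(x$f) - 1L
  graphics::plot(lam, x$f, type = "b", xlab = expression(lambda),
                 ylab = "f (kT)", ...)
  if (x$n_boot > 0L)
    graphics::arrows(lam, x$f - x$se, lam, x$f + x$se, angle = 90,
                     code = 3, length = 0.03)
  invisible(x)
}
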
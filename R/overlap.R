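#' Phase-space overlap measures for adjacent lambda windows
#'
#' Free-energy estimates are only trustworthy when the perturbation-energy
#' distributions of adjacent lambda states overlap. Five measures are
#' monitored per window: the Bhattacharyya coefficient
#' (\code{bhattacharyya()}), the Wu-Kofke distribution overlap
#' (\code{kab_overlap()}) and bias metric (\code{bias_metric_pi()}), the
#' weight of the largest term in the exponential average
#' (\code{max_weight()}), and the forward/backward exponential-average
#' hysteresis (\code{ea_hysteresis()}). The first two are evaluated under a
#' Gaussian approximation of the two distributions, validated in the test
#' suite against dense numerical integration.
#'
#' @param mu_a,sd_a,mu_b,sd_b Mean and standard deviation (kT) of the
#'   perturbation-energy distribution sampled in each of the two states;
#'   standard deviations must be positive.
#' @return `bhattacharyya()` and `kab_overlap()`: a number in `[0, 1]`,
#'   1 for identical distributions.
#' @name overlap_measures
NULL

#' @rdname overlap_measures
#' @details For Gaussians the Bhattacharyya coefficient
#'   \eqn{\Omega = \int \sqrt{p_A p_B}} has the closed form
#'   \eqn{\sqrt{2\sigma_A\sigma_B/(\sigma_A^2+\sigma_B^2)}\,
#'   \exp(-(\mu_A-\mu_B)^2 / (4(\sigma_A^2+\sigma_B^2)))}.
#' @export
bhattacharyya <- function(mu_a, sd_a, mu_b, sd_b) {
  check_dist(sd_a, sd_b)
  sqrt(2 * sd_a * sd_b / (sd_a^2 + sd_b^2)) *
    exp(-(mu_a - mu_b)^2 / (4 * (sd_a^2 + sd_b^2)))
}

#' @rdname overlap_measures
#' @details The Wu-Kofke overlap
#'   \eqn{K_{AB} = \int 2 p_A p_B / (p_A + p_B)} (twice the harmonic mean of
#'   the densities) has no closed form and is evaluated by adaptive
#'   quadrature.
#' @export
kab_overlap <- function(mu_a, sd_a, mu_b, sd_b) {
  check_dist(sd_a, sd_b)
  integrand <- function(x) {
    pa <- stats::dnorm(x, mu_a, sd_a)
    pb <- stats::dnorm(x, mu_b, sd_b)
    num <- 2 * pa * pb
    ifelse(num > 0, num / (pa + pb), 0)
  }
  q <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-9,
                        stop.on.error = FALSE)
  if (!q$message %in% "OK")
    stop("overlap quadrature failed: ", q$message, call. = FALSE)
  min(q$value, 1)
}

check_dist <- function(sd_a, sd_b) {
  if (!is.finite(sd_a) || !is.finite(sd_b) || sd_a <= 0 || sd_b <= 0)
    stop("distribution standard deviations must be positive",
         call. = FALSE)
}

#' @rdname overlap_measures
#' @param sigma_w Standard deviation of the work distribution (kT).
#' @param n Number of work samples (at least 2).
#' @details The bias metric \eqn{\Pi = \sqrt{2 \ln n} - \sigma_w} compares
#'   the reach of n samples into the tail of a Gaussian work distribution
#'   with its width; the accepted safety criterion is \eqn{\Pi > 0.4}. It is
#'   computed per direction and the window value is the minimum of the two.
#' @export
bias_metric_pi <- function(sigma_w, n) {
  if (!is.numeric(n) || n < 2) stop("n must be at least 2", call. = FALSE)
  stopifnot(is.finite(sigma_w), sigma_w >= 0)
  sqrt(2 * log(n)) - sigma_w
}

#' @rdname overlap_measures
#' @param w Work samples in kT.
#' @details \eqn{w_{max}} is the largest normalised weight
#'   \eqn{e^{-w_n} / \sum_m e^{-w_m}} entering the exponential average;
#'   values approaching 1 mean a single sample dominates the estimate.
#'   Always in `[1/N, 1]`.
#' @export
max_weight <- function(w) {
  if (length(w) == 0L) stop("no work values supplied", call. = FALSE)
  stopifnot(all(is.finite(w)))
  lw <- -w - logsumexp(-w)
  exp(max(lw))
}

#' @rdname overlap_measures
#' @param w_fwd,w_rev Forward and reverse work samples of the same window
#'   (kT).
#' @param temperature Kelvin, for the kJ/mol conversion.
#' @details The hysteresis
#'   \eqn{\Delta\Delta G_{EA} = \Delta G_{EA}(fwd) - (-\Delta G_{EA}(rev))}
#'   is the disagreement of the two single-direction estimates of the same
#'   window free energy; it vanishes in expectation for converged sampling.
#'   Returned in kJ/mol.
#' @export
ea_hysteresis <- function(w_fwd, w_rev, temperature = 300) {
  dg_f <- exponential_average(w_fwd)
  dg_r <- exponential_average(w_rev)
  (dg_f - (-dg_r)) * kT_kJmol(temperature)
}

#' Default warning thresholds for the overlap report
#'
#' A window is flagged when \eqn{\Pi \le 0.4} (the accepted safety
#' criterion), \eqn{w_{max} \ge 0.5} (a single sample carries half the
#' average), \eqn{\Omega \le 0.1}, \eqn{K_{AB} \le 0.1}, or
#' \eqn{|\Delta\Delta G_{EA}| \ge 4} kJ/mol. All configurable.
#'
#' @param pi_min,w_max_max,omega_min,kab_min,ddg_ea_max Threshold values.
#' @return A named list of thresholds.
#' @export
overlap_thresholds <- function(pi_min = 0.4, w_max_max = 0.5,
                               omega_min = 0.1, kab_min = 0.1,
                               ddg_ea_max = 4) {
  list(pi_min = pi_min, w_max_max = w_max_max, omega_min = omega_min,
       kab_min = kab_min, ddg_ea_max = ddg_ea_max)
}

#' Per-window overlap report
#'
#' Computes all five overlap measures for every adjacent lambda window of a
#' reduced-potential matrix. Forward works of window (k, k+1) are
#' \eqn{u_{k+1,n} - u_{k,n}} over the samples generated in state k; reverse
#' works are \eqn{u_{k,n} - u_{k+1,n}} over the samples of state k+1.
#'
#' @param u A [reduced_potential()] object.
#' @param thresholds A list as returned by [overlap_thresholds()].
#' @return A data frame of class `"fep_overlap"`, one row per window, with
#'   columns `window`, `omega`, `k_ab`, `pi_fwd`, `pi_rev`, `pi`
#'   (the minimum of the two directions), `w_max_fwd`, `w_max_rev`,
#'   `ddg_ea` (kJ/mol) and `flags` (comma-separated violated thresholds,
#'   empty when all pass). The thresholds are attached as an attribute.
#' @export
assess_windows <- function(u, thresholds = overlap_thresholds()) {
  stopifnot(inherits(u, "reduced_potential"))
  K <- nrow(u$u)
  if (K < 2L) stop("need at least two states", call. = FALSE)
  rows <- lapply(seq_len(K - 1L), function(k) {
    w_f <- u$u[k + 1L, u$origin == k] - u$u[k, u$origin == k]
    w_r <- u$u[k, u$origin == k + 1L] - u$u[k + 1L, u$origin == k + 1L]
    if (length(w_f) < 2L || length(w_r) < 2L)
      stop("window ", k, ": need at least two samples in each direction",
           call. = FALSE)
    # perturbation-energy distributions: Delta u in state k and state k+1
    mu_a <- mean(w_f); sd_a <- stats::sd(w_f)
    mu_b <- mean(-w_r); sd_b <- stats::sd(w_r)
    pi_f <- bias_metric_pi(stats::sd(w_f), length(w_f))
    pi_r <- bias_metric_pi(stats::sd(w_r), length(w_r))
    data.frame(
      window = k,
      omega = bhattacharyya(mu_a, sd_a, mu_b, sd_b),
      k_ab = kab_overlap(mu_a, sd_a, mu_b, sd_b),
      pi_fwd = pi_f, pi_rev = pi_r, pi = min(pi_f, pi_r),
      w_max_fwd = max_weight(w_f), w_max_rev = max_weight(w_r),
      ddg_ea = ea_hysteresis(w_f, w_r, u$temperature))
  })
  rep <- do.call(rbind, rows)
  th <- thresholds
  flag <- function(cond, lab) ifelse(cond, lab, NA_character_)
  fl <- cbind(flag(rep$pi <= th$pi_min, "PI"),
              flag(pmax(rep$w_max_fwd, rep$w_max_rev) >= th$w_max_max,
                   "W_MAX"),
              flag(rep$omega <= th$omega_min, "OMEGA"),
              flag(rep$k_ab <= th$kab_min, "K_AB"),
              flag(abs(rep$ddg_ea) >= th$ddg_ea_max, "DDG_EA"))
  rep$flags <- apply(fl, 1L, function(r)
    paste(r[!is.na(r)], collapse = ","))
  attr(rep, "thresholds") <- th
  class(rep) <- c("fep_overlap", "data.frame")
  rep
}

#' @export
print.fep_overlap <- function(x, digits = 3, ...) {
  cat("overlap diagnostics for", nrow(x), "lambda windows\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) signif(col, digits) else col)
  print(df, row.names = FALSE)
  nbad <- sum(nzchar(x$flags))
  if (nbad) cat(nbad, "window(s) flagged\n") else
    cat("all windows within thresholds\n")
  invisible(x)
}
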
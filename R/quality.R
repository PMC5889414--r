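#' Deviation statistics between calculated and experimental affinities
#'
#' With deviations \eqn{d_i = calc_i - exp_i}: MAD is the mean absolute
#' deviation, MSD the mean signed deviation (positive when calculations
#' overestimate), RMSD the root-mean-square deviation and Max the largest
#' absolute deviation. All in kJ/mol. On any input MAD <= RMSD <= Max and
#' |MSD| <= MAD.
#'
#' @param calc,exp Paired numeric vectors (same transformations, same
#'   order), kJ/mol.
#' @return Named vector `c(mad, msd, rmsd, max)`.
#' @export
deviation_stats <- function(calc, exp) {
  check_paired(calc, exp, n_min = 1L)
  d <- calc - exp
  c(mad = mean(abs(d)), msd = mean(d), rmsd = sqrt(mean(d^2)),
    max = max(abs(d)))
}

#' Direction-symmetric squared correlation
#'
#' The Pearson R^2 between calculated and experimental relative free
#' energies depends on the (arbitrary) direction chosen for each
#' transformation. This estimator removes that dependence by scoring every
#' pair in both directions: the point set \{(x_i, y_i)\} \{(-x_i, -y_i)\}
#' has zero means, so the statistic reduces to
#' \eqn{R^2 = (\sum x_i y_i)^2 / (\sum x_i^2 \sum y_i^2)} and is invariant
#' under flipping the sign of any single transformation on both axes.
#'
#' @inheritParams deviation_stats
#' @return R^2 in `[0, 1]`.
#' @export
bidirectional_r2 <- function(calc, exp) {
  check_paired(calc, exp, n_min = 2L)
  sx2 <- sum(calc^2)
  sy2 <- sum(exp^2)
  if (sx2 == 0 || sy2 == 0)
    stop("correlation undefined: one axis is identically zero",
         call. = FALSE)
  sum(calc * exp)^2 / (sx2 * sy2)
}

#' Sign-concordance rank correlation over studied transformations
#'
#' A restricted Kendall statistic evaluated only over the transformations
#' actually studied (never over all pairwise combinations): a
#' transformation is concordant when calculated and experimental values
#' have the same sign, discordant when they differ, and excluded as a tie
#' when either side is exactly zero. \eqn{\tau_r = (C - D) / (C + D)}.
#'
#' `tau_r90()` additionally admits a transformation only when both the
#' calculated and the experimental value are statistically nonzero at the
#' two-sided 90% level (|value| >= z90 * se); an absent experimental
#' standard error means the measurement is taken at face value and always
#' passes the filter.
#'
#' @inheritParams deviation_stats
#' @return The correlation in `[-1, 1]`, with attributes `n_used`,
#'   `concordant` and `discordant`.
#' @export
tau_r <- function(calc, exp) {
  check_paired(calc, exp, n_min = 1L)
  s <- sign(calc) * sign(exp)
  C <- sum(s > 0)
  D <- sum(s < 0)
  if (C + D == 0L)
    stop("all transformations are ties; tau_r undefined", call. = FALSE)
  structure((C - D) / (C + D), n_used = C + D, concordant = C,
            discordant = D)
}

#' @rdname tau_r
#' @param calc_se,exp_se Standard errors paired with `calc` and `exp`;
#'   `exp_se` may contain `NA` for unreported experimental uncertainties.
#' @param z90 Two-sided significance threshold (default 1.645, the 90%
#'   normal quantile).
#' @export
tau_r90 <- function(calc, calc_se, exp, exp_se, z90 = 1.645) {
  check_paired(calc, exp, n_min = 1L)
  stopifnot(length(calc_se) == length(calc), length(exp_se) == length(exp))
  keep <- abs(calc) >= z90 * calc_se &
    (is.na(exp_se) | abs(exp) >= z90 * exp_se)
  if (!any(keep))
    stop("no transformation is significant on both axes; tau_r90 undefined",
         call. = FALSE)
  tau_r(calc[keep], exp[keep])
}

check_paired <- function(calc, exp, n_min) {
  if (length(calc) != length(exp))
    stop("calculated and experimental vectors differ in length",
         call. = FALSE)
  if (length(calc) < n_min)
    stop("need at least ", n_min, " paired values", call. = FALSE)
  stopifnot(all(is.finite(calc)), all(is.finite(exp)))
}

#' Parametric-simulation uncertainty of a quality measure
#'
#' Draws `n_rep` synthetic data sets in which every calculated and
#' experimental value is resampled from a Gaussian centred on its reported
#' value with its reported standard error (zero where no error is
#' reported), recomputes the quality measure on each, and returns the
#' standard deviation of the measure over the replicates. A replicate in
#' which the measure is undefined (e.g. a sign correlation with no
#' surviving transformations) is recorded as missing; more than 10% missing
#' replicates is an error.
#'
#' @param calc,calc_se,exp,exp_se Paired values and standard errors
#'   (kJ/mol); `exp_se` may contain `NA`.
#' @param metric A function `(calc, calc_se, exp, exp_se) -> number`, or
#'   one of `"mad"`, `"msd"`, `"rmsd"`, `"max"`, `"r2"`, `"tau_r"`,
#'   `"tau_r90"`.
#' @param n_rep Number of replicates (default 1000).
#' @param seed Optional integer seed (applied locally).
#' @return The standard deviation of the measure across replicates.
#' @export
metric_uncertainty <- function(calc, calc_se, exp, exp_se, metric,
                               n_rep = 1000L, seed = NULL) {
  if (n_rep < 2L) stop("n_rep must be at least 2", call. = FALSE)
  fn <- if (is.function(metric)) metric else metric_by_name(metric)
  exp_sd <- ifelse(is.na(exp_se), 0, exp_se)
  n <- length(calc)
  vals <- with_local_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      cs <- stats::rnorm(n, calc, calc_se)
      es <- stats::rnorm(n, exp, exp_sd)
      tryCatch(as.numeric(fn(cs, calc_se, es, exp_se)),
               error = function(e) NA_real_)
    }, numeric(1L))
  })
  if (mean(is.na(vals)) > 0.1)
    stop("metric undefined in more than 10% of replicates", call. = FALSE)
  stats::sd(vals, na.rm = TRUE)
}

metric_by_name <- function(name) {
  switch(match.arg(name, c("mad", "msd", "rmsd", "max", "r2", "tau_r",
                           "tau_r90")),
    mad = function(c_, cse, e_, ese) deviation_stats(c_, e_)[["mad"]],
    msd = function(c_, cse, e_, ese) deviation_stats(c_, e_)[["msd"]],
    rmsd = function(c_, cse, e_, ese) deviation_stats(c_, e_)[["rmsd"]],
    max = function(c_, cse, e_, ese) deviation_stats(c_, e_)[["max"]],
    r2 = function(c_, cse, e_, ese) bidirectional_r2(c_, e_),
    tau_r = function(c_, cse, e_, ese) tau_r(c_, e_),
    tau_r90 = function(c_, cse, e_, ese) tau_r90(c_, cse, e_, ese))
}

#' Consensus over method variants
#'
#' The consensus estimate of each transformation is the mean of its
#' relative binding free energy over the method variants, with a standard
#' error from the variation between the variants: SE = sd / sqrt(M) with
#' the sample standard deviation over the M variants. Because the variants
#' differ in deliberate methodological choices, this spread measures the
#' sensitivity of the result to the method, complementing the per-variant
#' statistical errors.
#'
#' @param results A rectangular `"fep_results"` table with at least two
#'   variants per transformation.
#' @return A data frame of class `"fep_consensus"` with columns
#'   `transformation`, `ddG`, `se`.
#' @export
consensus <- function(results) {
  assert_rectangular(results)
  variants <- unique(results$variant)
  if (length(variants) < 2L)
    stop("consensus needs at least two method variants", call. = FALSE)
  trans <- unique(results$transformation)
  out <- do.call(rbind, lapply(trans, function(tr) {
    v <- results$ddG[results$transformation == tr]
    data.frame(transformation = tr, ddG = mean(v),
               se = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("fep_consensus", "data.frame")
  out
}

#' z-test for a difference between two method variants
#'
#' Tests whether two estimates of the same quantity differ significantly,
#' given their standard errors: z = |a - b| / sqrt(se_a^2 + se_b^2),
#' compared with the two-sided normal quantile of the chosen confidence
#' level (1.96 at 95%, 1.645 at 90%).
#'
#' @param a,b Estimates (kJ/mol).
#' @param se_a,se_b Standard errors; not both zero.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A list with `z`, `significant`, `z_crit` and `level`.
#' @export
variant_difference_test <- function(a, se_a, b, se_b, level = 0.95) {
  stopifnot(se_a >= 0, se_b >= 0, level > 0, level < 1)
  if (se_a == 0 && se_b == 0)
    stop("both standard errors are zero; test undefined", call. = FALSE)
  z <- abs(a - b) / sqrt(se_a^2 + se_b^2)
  z_crit <- stats::qnorm(1 - (1 - level) / 2)
  list(z = z, significant = z > z_crit, z_crit = z_crit, level = level)
}

#' Evaluate calculated affinities against experiment
#'
#' Computes the full quality-measure suite (MAD, MSD, RMSD, Max,
#' direction-symmetric R^2, tau_r, tau_r90) for every method variant of a
#' result table against an experimental table, each measure paired with its
#' parametric-simulation uncertainty, plus the same report for the
#' consensus of the variants. Transformations named in `exclude` are
#' dropped from every report (sensitivity analysis).
#'
#' @param results A rectangular `"fep_results"` table.
#' @param experimental An `"fep_experimental"` table covering the same
#'   transformations.
#' @param exclude Character vector of transformation labels to drop.
#' @param include_consensus Also evaluate the across-variant consensus
#'   (default TRUE).
#' @param n_rep Replicates for [metric_uncertainty()] (default 1000).
#' @param seed Optional integer seed for the uncertainty simulation.
#' @param z90 Significance threshold for [tau_r90()].
#' @return An object of class `"fep_quality"`: a long data frame with
#'   columns `variant`, `metric`, `value`, `sd`, `n_used`, carrying the
#'   evaluation settings as attributes.
#' @export
evaluate_affinities <- function(results, experimental, exclude = NULL,
                                include_consensus = TRUE, n_rep = 1000L,
                                seed = NULL, z90 = 1.645) {
  assert_rectangular(results)
  stopifnot(inherits(experimental, "fep_experimental"))
  exclude <- as.character(exclude)
  trans <- unique(results$transformation)
  unmatched <- c(setdiff(trans, experimental$transformation),
                 setdiff(experimental$transformation, trans))
  if (length(unmatched))
    stop("transformations not shared by both tables: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  bad_excl <- setdiff(exclude, trans)
  if (length(bad_excl))
    stop("unknown transformation(s) in 'exclude': ",
         paste(bad_excl, collapse = ", "), call. = FALSE)
  keep <- setdiff(trans, exclude)
  if (length(keep) < 2L)
    stop("fewer than two transformations left after exclusion",
         call. = FALSE)
  exp_row <- experimental[match(keep, experimental$transformation), ]
  variants <- unique(results$variant)
  blocks <- lapply(variants, function(v) {
    rows <- results[results$variant == v, ]
    rows <- rows[match(keep, rows$transformation), ]
    quality_block(v, rows$ddG, rows$se, exp_row$ddG, exp_row$se,
                  n_rep = n_rep, seed = seed, z90 = z90)
  })
  if (include_consensus) {
    cons <- consensus(results)
    cons <- cons[match(keep, cons$transformation), ]
    blocks <- c(blocks, list(
      quality_block("Consensus", cons$ddG, cons$se, exp_row$ddG,
                    exp_row$se, n_rep = n_rep, seed = seed, z90 = z90)))
  }
  out <- do.call(rbind, blocks)
  attr(out, "transformations") <- keep
  attr(out, "exclude") <- exclude
  attr(out, "n_rep") <- n_rep
  attr(out, "seed") <- seed
  attr(out, "z90") <- z90
  class(out) <- c("fep_quality", "data.frame")
  out
}

quality_block <- function(variant, calc, calc_se, exp, exp_se, n_rep, seed,
                          z90) {
  dev <- deviation_stats(calc, exp)
  r2 <- bidirectional_r2(calc, exp)
  tr <- tau_r(calc, exp)
  tr90 <- tau_r90(calc, calc_se, exp, exp_se, z90 = z90)
  metrics <- c("mad", "msd", "rmsd", "max", "r2", "tau_r", "tau_r90")
  values <- c(dev, r2 = unname(r2), tau_r = as.numeric(tr),
              tau_r90 = as.numeric(tr90))
  sds <- vapply(metrics, function(m) {
    fn <- if (m == "tau_r90")
      function(c_, cse, e_, ese) tau_r90(c_, cse, e_, ese, z90 = z90)
    else metric_by_name(m)
    metric_uncertainty(calc, calc_se, exp, exp_se, fn, n_rep = n_rep,
                       seed = seed)
  }, numeric(1L))
  data.frame(variant = variant, metric = metrics, value = unname(values),
             sd = unname(sds),
             n_used = c(rep(NA_integer_, 5L), attr(tr, "n_used"),
                        attr(tr90, "n_used")),
             stringsAsFactors = FALSE)
}

#' @export
print.fep_quality <- function(x, digits = 2, ...) {
  cat("quality measures over",
      length(attr(x, "transformations")), "transformations")
  if (length(attr(x, "exclude")))
    cat(" (excluding ", paste(attr(x, "exclude"), collapse = ", "), ")",
        sep = "")
  cat("; uncertainties from", attr(x, "n_rep"), "simulated replicates\n")
  wide <- stats::reshape(
    as.data.frame(x)[, c("variant", "metric", "value")],
    idvar = "metric", timevar = "variant", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide[-1L] <- lapply(wide[-1L], round, digits)
  print(wide, row.names = FALSE)
  invisible(x)
}
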
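#' Harmonic-oscillator lambda leg with analytic free energy
#'
#' A one-dimensional harmonic oscillator is the standard exactly solvable
#' stand-in for an alchemical leg: mixing two harmonic endpoint potentials
#' \eqn{V_i(x) = k_i (x - c_i)^2 / 2 + a_i} with
#' \eqn{V(\lambda) = (1-\lambda) V_0 + \lambda V_1} yields another harmonic
#' potential with force constant \eqn{K(\lambda) = (1-\lambda)k_0 +
#' \lambda k_1}, so every state can be sampled exactly (a Gaussian with
#' variance 1/K) and the free energy of each state is known in closed form:
#' the end-to-end difference is \eqn{\ln(k_1/k_0)/2 + (a_1 - a_0)} in kT,
#' independent of the centres.
#'
#' @param k0,k1 Endpoint force constants (reduced units, > 0).
#' @param c0,c1 Endpoint centres.
#' @param a0,a1 Constant endpoint offsets (kT); used to dial in an
#'   arbitrary target free energy without touching the overlap structure.
#' @param schedule A [lambda_schedule()] (default the 13-window schedule).
#' @param n_per_state Samples drawn in every lambda state (default 500,
#'   matching a 5 ns production run sampled every 10 ps).
#' @param temperature Kelvin (default 300).
#' @return `harmonic_leg_spec()`: a specification list.
#' @export
harmonic_leg_spec <- function(k0 = 1, k1 = 4, c0 = 0, c1 = 0, a0 = 0,
                              a1 = 0, schedule = lambda_schedule(),
                              n_per_state = 500L, temperature = 300) {
  stopifnot(k0 > 0, k1 > 0, n_per_state >= 1L)
  list(k0 = k0, k1 = k1, c0 = c0, c1 = c1, a0 = a0, a1 = a1,
       schedule = lambda_schedule(schedule),
       n_per_state = as.integer(n_per_state), temperature = temperature)
}

#' @rdname harmonic_leg_spec
#' @param spec A specification from `harmonic_leg_spec()`.
#' @param seed Integer seed; the same spec and seed give a bit-identical
#'   matrix.
#' @return `generate_harmonic_leg()`: a list with `u` (a
#'   [reduced_potential()]), `exact_df` (the analytic end-to-end free
#'   energy, kT) and `exact_f` (analytic per-state free energies anchored
#'   at state 1).
#' @export
generate_harmonic_leg <- function(spec, seed = NULL) {
  lam <- as.numeric(spec$schedule)
  K_lam <- (1 - lam) * spec$k0 + lam * spec$k1
  c_lam <- ((1 - lam) * spec$k0 * spec$c0 + lam * spec$k1 * spec$c1) / K_lam
  # constant term of the mixed potential after completing the square
  off <- (1 - lam) * spec$a0 + lam * spec$a1 +
    0.5 * ((1 - lam) * spec$k0 * spec$c0^2 + lam * spec$k1 * spec$c1^2 -
             K_lam * c_lam^2)
  f_exact <- 0.5 * log(K_lam / (2 * pi)) + off
  f_exact <- f_exact - f_exact[1L]
  K <- length(lam)
  n <- spec$n_per_state
  x <- with_local_seed(seed,
    unlist(lapply(seq_len(K), function(k)
      stats::rnorm(n, c_lam[k], 1 / sqrt(K_lam[k]))), use.names = FALSE))
  u <- vapply(seq_len(K), function(k)
    0.5 * K_lam[k] * (x - c_lam[k])^2 + off[k], numeric(length(x)))
  rp <- reduced_potential(t(u), origin = rep(seq_len(K), each = n),
                          temperature = spec$temperature,
                          schedule = spec$schedule)
  list(u = rp, exact_df = 0.5 * log(spec$k1 / spec$k0) +
         (spec$a1 - spec$a0), exact_f = f_exact)
}

#' Fluctuation-consistent Gaussian work samples
#'
#' Draws forward and reverse work values for a window with true free-energy
#' difference `dg_true`, both Gaussian with standard deviation `sigma`
#' (kT). The means are placed at \eqn{\Delta G + \sigma^2/2} (forward) and
#' \eqn{-\Delta G + \sigma^2/2} (reverse), the unique Gaussian pair
#' consistent with the Crooks fluctuation relation, so
#' \eqn{\langle w_f \rangle + \langle w_r \rangle = \sigma^2} and both
#' exponential averages converge to the same free energy.
#'
#' @param dg_true True free-energy difference (kT).
#' @param sigma Work standard deviation (kT, >= 0).
#' @param n Samples per direction.
#' @param seed Optional integer seed.
#' @return A list with numeric vectors `w_fwd` and `w_rev`.
#' @export
generate_gaussian_work <- function(dg_true, sigma, n, seed = NULL) {
  stopifnot(sigma >= 0, n >= 1)
  with_local_seed(seed, {
    list(w_fwd = stats::rnorm(n, dg_true + sigma^2 / 2, sigma),
         w_rev = stats::rnorm(n, -dg_true + sigma^2 / 2, sigma))
  })
}

#' Specification of an emulated multi-variant binding study
#'
#' Defines a synthetic counterpart of a seven-transformation, six-variant
#' relative binding affinity study with known ground truth. Per
#' (transformation, variant) cell the generated table value is
#' truth + bias + noise, where the bias (sd `bias_sd`) is drawn once per
#' cell - emulating systematic differences of 1-2 kJ/mol between method
#' variants - and the noise (sd `noise_sd`, which is also the declared
#' standard error) emulates the statistical error of one calculation.
#'
#' @param transformations Transformation labels (default the seven
#'   galectin-3 transformations).
#' @param truth_ddG True relative binding free energies, kJ/mol (default
#'   the experimental galectin-3 affinities, giving realistic magnitudes).
#' @param exp_se Standard errors attached to the emulated experimental
#'   table (`NA` allowed; default the galectin-3 experimental errors).
#' @param variants Method-variant labels (default the six standard ones).
#' @param bias_sd,noise_sd Per-cell systematic and statistical spread,
#'   kJ/mol.
#' @param water_dG True water-leg free energy per transformation, kJ/mol
#'   (the protein leg is then `water_dG + truth_ddG`).
#' @param n_per_lambda Samples per lambda state for generated energy files.
#' @param schedule A [lambda_schedule()].
#' @param temperature Kelvin.
#' @return A specification list of class `"study_spec"`.
#' @export
study_spec <- function(transformations = galectin3_transformations(),
                       truth_ddG = galectin3_experimental()$ddG,
                       exp_se = galectin3_experimental()$se,
                       variants = method_variants(),
                       bias_sd = 1.5, noise_sd = 0.5,
                       water_dG = rep(0, length(transformations)),
                       n_per_lambda = 500L,
                       schedule = lambda_schedule(), temperature = 300) {
  stopifnot(length(truth_ddG) == length(transformations),
            length(water_dG) == length(transformations),
            bias_sd >= 0, noise_sd >= 0)
  structure(list(transformations = transformations, truth_ddG = truth_ddG,
                 exp_se = rep_len(exp_se, length(transformations)),
                 variants = variants, bias_sd = bias_sd,
                 noise_sd = noise_sd, water_dG = water_dG,
                 n_per_lambda = as.integer(n_per_lambda),
                 schedule = lambda_schedule(schedule),
                 temperature = temperature),
            class = "study_spec")
}

#' Emulate a full relative binding affinity study
#'
#' Generates, under a single seed, (a) a rectangular result table of
#' emulated calculated affinities with declared standard errors, (b) the
#' emulated experimental table, (c) the ground-truth record per cell and,
#' optionally, (d) per-leg harmonic energy-sample files whose analytic
#' protein-minus-water free-energy difference equals the cell's true
#' affinity - so the full estimate-combine-evaluate chain can be exercised
#' against known truth.
#'
#' Sample files realise each leg as the standard harmonic pair (force
#' constants 1 and 4) plus a constant endpoint offset dialled to the target
#' free energy, which changes the free energy without degrading window
#' overlap.
#'
#' @param spec A [study_spec()].
#' @param seed Integer seed; all draws (biases, noise, samples) derive from
#'   it.
#' @param dir Directory for energy-sample files; required when
#'   `write_samples = TRUE`.
#' @param write_samples Generate per-leg energy-sample files (default
#'   `FALSE`: tables only).
#' @return A list with `results` (`"fep_results"`), `experimental`
#'   (`"fep_experimental"`), `truth` (data frame `transformation`,
#'   `variant`, `ddG_true`), and `files` (data frame `transformation`,
#'   `variant`, `phase`, `path`, `dG_true` or `NULL`).
#' @export
emulate_study <- function(spec, seed = 1L, dir = NULL,
                          write_samples = FALSE) {
  stopifnot(inherits(spec, "study_spec"))
  nt <- length(spec$transformations)
  nv <- length(spec$variants)
  cells <- expand.grid(transformation = spec$transformations,
                       variant = spec$variants, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  truth_map <- stats::setNames(spec$truth_ddG, spec$transformations)
  water_map <- stats::setNames(spec$water_dG, spec$transformations)
  draws <- with_local_seed(seed, {
    list(bias = stats::rnorm(nt * nv, 0, spec$bias_sd),
         noise = stats::rnorm(nt * nv, 0, spec$noise_sd))
  })
  cells$ddG_true <- truth_map[cells$transformation] + draws$bias
  cells$ddG_obs <- cells$ddG_true + draws$noise
  results <- fep_results(cells$transformation, cells$variant,
                         cells$ddG_obs, rep(spec$noise_sd, nrow(cells)))
  experimental <- fep_experimental(spec$transformations, spec$truth_ddG,
                                   spec$exp_se)
  files <- NULL
  if (write_samples) {
    if (is.null(dir)) stop("'dir' is required to write sample files",
                           call. = FALSE)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    kT <- kT_kJmol(spec$temperature)
    rows <- vector("list", 2L * nrow(cells))
    for (i in seq_len(nrow(cells))) {
      dg_w <- water_map[[cells$transformation[i]]]
      dg_p <- dg_w + cells$ddG_true[i]
      for (phase in c("protein", "water")) {
        target_kT <- (if (phase == "protein") dg_p else dg_w) / kT
        leg_spec <- harmonic_leg_spec(
          k0 = 1, k1 = 4, a1 = target_kT - 0.5 * log(4),
          schedule = spec$schedule, n_per_state = spec$n_per_lambda,
          temperature = spec$temperature)
        leg_seed <- derive_seed(seed, 1000L + 2L * i +
                                  (phase == "water"))
        leg <- generate_harmonic_leg(leg_spec, seed = leg_seed)
        path <- file.path(dir, paste0(
          sanitize_label(cells$transformation[i]), "_",
          sanitize_label(cells$variant[i]), "_", phase, ".tsv"))
        write_energy_samples(leg$u, path)
        rows[[2L * i - (phase == "protein")]] <- data.frame(
          transformation = cells$transformation[i],
          variant = cells$variant[i], phase = phase, path = path,
          dG_true = if (phase == "protein") dg_p else dg_w,
          stringsAsFactors = FALSE)
      }
    }
    files <- do.call(rbind, rows)
    utils::write.table(files, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(results = results, experimental = experimental,
       truth = cells[, c("transformation", "variant", "ddG_true")],
       files = files, spec = spec, seed = seed)
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9]+", "-", x)
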
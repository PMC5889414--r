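#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with defaults matching the
#' standard study conditions: 300 K, the 13-window lambda schedule, 100
#' bootstrap resamples, 1000 uncertainty-simulation replicates, a 90%
#' significance threshold of 1.645 for tau_r90 and the default overlap
#' thresholds. Configurations round-trip through a YAML file.
#'
#' @param temperature Kelvin.
#' @param schedule Lambda schedule values.
#' @param n_boot Bootstrap resamples per leg.
#' @param n_rep Replicates for metric uncertainties.
#' @param z90 Significance threshold for [tau_r90()].
#' @param thresholds Overlap thresholds, see [overlap_thresholds()].
#' @param seed Global integer seed; per-stage seeds are derived from it.
#' @param exclude Transformations to exclude from evaluation.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(temperature = 300,
                            schedule = lambda_default(), n_boot = 100L,
                            n_rep = 1000L, z90 = 1.645,
                            thresholds = overlap_thresholds(), seed = 1L,
                            exclude = character()) {
  schedule <- as.numeric(unlist(schedule))  # YAML may deliver a list
  structure(list(temperature = temperature,
                 schedule = as.numeric(lambda_schedule(schedule)),
                 n_boot = as.integer(n_boot), n_rep = as.integer(n_rep),
                 z90 = z90, thresholds = thresholds,
                 seed = as.integer(seed),
                 exclude = as.character(unlist(exclude))),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  merged <- utils::modifyList(unclass(defaults), raw)
  do.call(pipeline_config, merged)
}

#' @rdname pipeline_config
#' @param config A `"pipeline_config"`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive a per-stage child seed from the global seed
#'
#' Counter-based derivation (a Lehmer step plus the stage counter, kept
#' below 2^31) so that every stage and every generated file gets a
#' distinct, reproducible stream and stages can be rerun independently.
#'
#' @param seed Global integer seed.
#' @param index Stage or item counter.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 44488 * 48271 + as.numeric(index)) %%
               2147483647)
}

#' Estimate a result table from per-leg energy-sample files
#'
#' Runs [mbar()] with bootstrap errors on the protein and water leg of
#' every (transformation, variant) cell listed in the manifest and combines
#' them through the thermodynamic cycle.
#'
#' @param files Data frame with columns `transformation`, `variant`,
#'   `phase` (`"protein"`/`"water"`) and `path`, or the path of a manifest
#'   TSV with those columns (as written by [emulate_study()]).
#' @param config A [pipeline_config()].
#' @return An `"fep_results"` table of relative binding free energies.
#' @export
estimate_study <- function(files, config = pipeline_config()) {
  if (is.character(files))
    files <- utils::read.delim(files, stringsAsFactors = FALSE)
  need <- c("transformation", "variant", "phase", "path")
  if (!all(need %in% names(files)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- unique(files[, c("transformation", "variant")])
  rows <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    legs <- lapply(c("protein", "water"), function(ph) {
      sel <- files$transformation == key$transformation[i] &
        files$variant == key$variant[i] & files$phase == ph
      if (sum(sel) != 1L)
        stop("expected exactly one ", ph, " leg for ",
             key$transformation[i], " x ", key$variant[i], call. = FALSE)
      u <- read_energy_samples(files$path[sel],
                               temperature = config$temperature)
      leg_free_energy(u, phase = ph,
                      transformation = key$transformation[i],
                      n_boot = config$n_boot,
                      seed = derive_seed(config$seed,
                                         2L * i + (ph == "water")))
    })
    est <- combine_cycle(legs[[1L]], legs[[2L]])
    rows[[i]] <- data.frame(transformation = key$transformation[i],
                            variant = key$variant[i], ddG = est$value,
                            se = est$se, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  fep_results(out$transformation, out$variant, out$ddG, out$se)
}

#' Run the full analysis chain
#'
#' Executes estimate -> diagnose -> evaluate on a directory of energy
#' sample files and an experimental table, writing `results.tsv`,
#' `overlap.tsv` and `quality.tsv` into `out_dir`. Every report embeds the
#' full effective configuration as commented header lines, and identical
#' configuration plus seed yields byte-identical reports.
#'
#' @param manifest Manifest TSV path or data frame (see
#'   [estimate_study()]).
#' @param experimental Path of an experimental table TSV, or an
#'   `"fep_experimental"`.
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the three reports.
#' @export
run_pipeline <- function(manifest, experimental, out_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(experimental)) {
    if (!file.exists(experimental))
      stop("evaluate stage: experimental table not found: ", experimental,
           call. = FALSE)
    experimental <- read_experimental_table(experimental)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("[estimate] fitting MBAR per leg (n_boot = ", config$n_boot,
          ", seed = ", config$seed, ")")
  results <- estimate_study(manifest, config)
  write_report(results_interface(results),
               file.path(out_dir, "results.tsv"), config)
  message("[diagnose] overlap measures per window")
  files <- if (is.character(manifest))
    utils::read.delim(manifest, stringsAsFactors = FALSE) else manifest
  th <- do.call(overlap_thresholds, config$thresholds)
  diag <- do.call(rbind, lapply(seq_len(nrow(files)), function(i) {
    u <- read_energy_samples(files$path[i],
                             temperature = config$temperature)
    rep <- as.data.frame(assess_windows(u, th))
    cbind(files[i, c("transformation", "variant", "phase")], rep,
          row.names = NULL)
  }))
  write_report(diag, file.path(out_dir, "overlap.tsv"), config)
  message("[evaluate] quality measures vs experiment (n_rep = ",
          config$n_rep, ")")
  quality <- evaluate_affinities(results, experimental,
                                 exclude = config$exclude,
                                 n_rep = config$n_rep,
                                 seed = derive_seed(config$seed, 999L),
                                 z90 = config$z90)
  write_report(as.data.frame(quality), file.path(out_dir, "quality.tsv"),
               config)
  invisible(list(results = results, overlap = diag, quality = quality))
}

#' Write a report TSV with the effective configuration as header
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config A [pipeline_config()] echoed into `#`-prefixed header
#'   lines for auditability.
#' @export
write_report <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    flat <- unlist(unclass(config))
    writeLines(paste0("# ", names(flat), ": ",
                      vapply(flat, format, character(1L))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# result table with the on-disk column names, so reports re-read as tables
results_interface <- function(results) {
  data.frame(transformation = results$transformation,
             variant = results$variant, ddG_kJmol = results$ddG,
             se_kJmol = results$se, stringsAsFactors = FALSE)
}
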
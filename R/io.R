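#' Read per-lambda energy samples
#'
#' Energy-sample files are TSV with a header line
#' `# lambda_schedule: <comma-separated lambda values>` followed by a column
#' header `origin_state  u_0  ...  u_{K-1}` and one row per sample: the
#' 0-based index of the state that generated the sample and its reduced
#' potential evaluated in every state. One file per transformation leg.
#'
#' @param path Path to an energy-sample file.
#' @param schedule Optional [lambda_schedule()] the file must match.
#' @param temperature Temperature in kelvin (default 300).
#' @return A [reduced_potential()] object.
#' @export
read_energy_samples <- function(path, schedule = NULL, temperature = 300) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("energy-sample file ", path, " is too short to contain samples",
         call. = FALSE)
  m <- regmatches(lines[1L],
                  regexec("^#\\s*lambda_schedule:\\s*(.+)$", lines[1L]))[[1L]]
  if (length(m) != 2L)
    stop("line 1: missing '# lambda_schedule:' header in ", path,
         call. = FALSE)
  sched <- lambda_schedule(parse_signed(strsplit(m[2L], ",")[[1L]]))
  if (!is.null(schedule)) {
    schedule <- lambda_schedule(schedule)
    if (length(schedule) != length(sched) ||
        any(abs(as.numeric(schedule) - as.numeric(sched)) > 1e-12))
      stop("lambda schedule in ", path,
           " does not match the expected schedule", call. = FALSE)
  }
  K <- length(sched)
  header <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != K + 1L || header[1L] != "origin_state")
    stop("line 2: expected columns origin_state, u_0 ... u_", K - 1L,
         " in ", path, call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    stop("no sample rows in ", path, call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != K + 1L)
  if (length(bad))
    stop("line ", bad[1L] + 2L, ": expected ", K + 1L, " fields in ", path,
         call. = FALSE)
  dat <- matrix(parse_signed(unlist(fields)), ncol = K + 1L, byrow = TRUE)
  if (any(!is.finite(dat))) {
    bad <- which(rowSums(!is.finite(dat)) > 0L)[1L]
    stop("line ", bad + 2L, ": non-finite value in ", path, call. = FALSE)
  }
  origin <- dat[, 1L] + 1L
  if (any(origin != round(origin)) || any(origin < 1L) || any(origin > K))
    stop("origin_state entries must be integers in 0..", K - 1L, " in ",
         path, call. = FALSE)
  reduced_potential(t(dat[, -1L, drop = FALSE]), origin = as.integer(origin),
                    temperature = temperature, schedule = sched)
}

#' @rdname read_energy_samples
#' @param x A [reduced_potential()] object (must carry a schedule).
#' @export
write_energy_samples <- function(x, path) {
  stopifnot(inherits(x, "reduced_potential"))
  if (is.null(x$schedule))
    stop("cannot write energy samples without a lambda schedule",
         call. = FALSE)
  K <- nrow(x$u)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# lambda_schedule: ",
                    paste(format(as.numeric(x$schedule), trim = TRUE),
                          collapse = ",")), con)
  writeLines(paste(c("origin_state", paste0("u_", seq_len(K) - 1L)),
                   collapse = "\t"), con)
  body <- cbind(x$origin - 1L, t(x$u))
  writeLines(apply(format(body, trim = TRUE, digits = 17), 1L, paste,
                   collapse = "\t"), con)
  invisible(path)
}

#' Parse numbers accepting typographic minus signs
#'
#' Published tables often use the typographic minus (U+2212) with a space
#' before the digits; this helper normalises both to ASCII before parsing.
#'
#' @param x Character vector of numbers.
#' @return Numeric vector; an unparseable entry is an error.
#' @export
parse_signed <- function(x) {
  x <- gsub("\u2212", "-", x)
  x <- gsub("^(\\s*-)\\s+", "\\1", trimws(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.nan(out) & !is.na(x) &
    !(trimws(x) %in% c("NA", ""))
  if (any(bad))
    stop("cannot parse number: '", x[which(bad)[1L]], "'", call. = FALSE)
  out
}

#' Read and write relative binding free-energy tables
#'
#' Result tables are TSV with columns `transformation`, `variant`,
#' `ddG_kJmol`, `se_kJmol`: one row per transformation x method-variant
#' cell. Experimental tables have columns `transformation`, `ddG_kJmol` and
#' an optional `se_kJmol`; a missing or empty standard error is preserved as
#' `NA` (meaning: not reported, treated as always significant downstream,
#' never as zero).
#'
#' @param path File path.
#' @return `read_result_table()`: a data frame of class `"fep_results"`;
#'   `read_experimental_table()`: a data frame of class
#'   `"fep_experimental"`.
#' @export
read_result_table <- function(path) {
  df <- read_tsv_checked(path, c("transformation", "variant", "ddG_kJmol",
                                 "se_kJmol"))
  key <- paste(df$transformation, df$variant)
  if (anyDuplicated(key))
    stop("duplicate (transformation, variant) entry: ",
         key[anyDuplicated(key)], call. = FALSE)
  fep_results(df$transformation, df$variant,
              parse_signed(df$ddG_kJmol), parse_signed(df$se_kJmol))
}

#' @rdname read_result_table
#' @export
read_experimental_table <- function(path) {
  df <- read_tsv_checked(path, c("transformation", "ddG_kJmol"))
  if (anyDuplicated(df$transformation))
    stop("duplicate transformation: ",
         df$transformation[anyDuplicated(df$transformation)], call. = FALSE)
  se <- if ("se_kJmol" %in% names(df)) parse_signed(df$se_kJmol)
        else rep(NA_real_, nrow(df))
  fep_experimental(df$transformation, parse_signed(df$ddG_kJmol), se)
}

#' @rdname read_result_table
#' @param x Table to write.
#' @export
write_result_table <- function(x, path) {
  stopifnot(inherits(x, "fep_results"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("transformation",
                     "variant", "ddG_kJmol", "se_kJmol"))
  invisible(path)
}

#' @rdname read_result_table
#' @export
write_experimental_table <- function(x, path) {
  stopifnot(inherits(x, "fep_experimental"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("transformation", "ddG_kJmol", "se_kJmol"))
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  if (nrow(df) == 0L) stop("no rows in ", path, call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Construct result and experimental tables in memory
#'
#' @param transformation,variant,ddG,se Parallel vectors (recycled where
#'   scalar); `se` may contain `NA` only in experimental tables.
#' @return Classed data frames as for [read_result_table()].
#' @export
fep_results <- function(transformation, variant, ddG, se) {
  df <- data.frame(transformation = as.character(transformation),
                   variant = as.character(variant),
                   ddG = as.numeric(ddG), se = as.numeric(se),
                   stringsAsFactors = FALSE)
  if (anyNA(df$ddG) || anyNA(df$se) || any(df$se < 0))
    stop("result table requires finite ddG and nonnegative se",
         call. = FALSE)
  class(df) <- c("fep_results", "data.frame")
  df
}

#' @rdname fep_results
#' @export
fep_experimental <- function(transformation, ddG, se = NA_real_) {
  df <- data.frame(transformation = as.character(transformation),
                   ddG = as.numeric(ddG),
                   se = rep_len(as.numeric(se), length(ddG)),
                   stringsAsFactors = FALSE)
  if (anyNA(df$ddG) || any(!is.na(df$se) & df$se < 0))
    stop("experimental table requires finite ddG and nonnegative se",
         call. = FALSE)
  class(df) <- c("fep_experimental", "data.frame")
  df
}

#' Check that a result table is rectangular
#'
#' Every listed transformation must have an entry for every listed variant.
#'
#' @param x A `"fep_results"` table.
#' @return Invisibly `x`; error if cells are missing.
#' @export
assert_rectangular <- function(x) {
  stopifnot(inherits(x, "fep_results"))
  tab <- table(x$transformation, x$variant)
  if (any(tab != 1L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)
    stop("result table is not rectangular; missing e.g. ",
         rownames(tab)[bad[1L, 1L]], " x ", colnames(tab)[bad[1L, 2L]],
         call. = FALSE)
  }
  invisible(x)
}
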
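# CSV readers/writers for the pipeline's exchange formats. Dialect:
# comma-separated, '.' decimal, UTF-8, '#'-prefixed metadata lines,
# densities in scientific notation with 9 significant digits so every
# writer/reader pair round-trips losslessly.

fmt9 <- function(x) formatC(x, format = "e", digits = 8)

write_lines_utf8 <- function(lines, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
}

read_csv_skip_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[trimws(m[2])]] <- if (is.na(val)) m[3] else val
    }
  }
  attr(df, "metadata") <- meta
  df
}

#' Write a decay trace to CSV
#'
#' Two columns `time_s,signal`; scalar ground-truth metadata is emitted as
#' `# key: value` header lines.
#'
#' @param trace A [decay_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  meta <- c(list(species = trace$species_label),
            if (!is.na(trace$depth_mm)) list(depth_mm = trace$depth_mm),
            trace$metadata$ground_truth)
  hdr <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k,
            if (is.numeric(v)) fmt9(v) else as.character(v))
  }, character(1))
  body <- c("time_s,signal",
            paste(fmt9(trace$times), fmt9(trace$signal), sep = ","))
  write_lines_utf8(c(hdr, body), path)
  invisible(path)
}

#' Read a decay trace from CSV
#'
#' @param path Path to a `time_s,signal` CSV, optionally with `# key: value`
#'   metadata lines.
#' @return A [decay_trace()]; parsed metadata in `metadata`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- read_csv_skip_meta(path)
  if (!all(c("time_s", "signal") %in% names(df)))
    stop("trace CSV must have columns time_s,signal", call. = FALSE)
  meta <- attr(df, "metadata")
  decay_trace(df$time_s, df$signal,
              species_label = meta$species %||% "OH",
              depth_mm = meta$depth_mm %||% NA_real_,
              metadata = meta)
}

#' Write a depth profile to CSV (`depth_mm,density_cm3,solution`)
#' @param profile A [depth_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  body <- c("depth_mm,density_cm3,solution",
            paste(profile$depth_mm, fmt9(profile$density_cm3),
                  profile$solution, sep = ","))
  write_lines_utf8(body, path)
  invisible(path)
}

#' Read a depth profile from CSV
#' @param path Path to a `depth_mm,density_cm3,solution` CSV.
#' @return A [depth_profile()].
#' @export
read_profile_csv <- function(path) {
  if (!file.exists(path))
    stop("profile file not found: ", path, call. = FALSE)
  df <- read_csv_skip_meta(path)
  need <- c("depth_mm", "density_cm3")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns depth_mm,density_cm3",
         call. = FALSE)
  sol <- if ("solution" %in% names(df)) df$solution[1] else "other"
  if (!sol %in% c("DI", "PBS", "other")) sol <- "other"
  depth_profile(df$depth_mm, df$density_cm3, sol)
}

#' Read a batch of absorption measurements
#'
#' Expected columns: `wavelength_nm,I0,IV,path_cm,sigma_cm2`; an optional
#' `depth_mm` column is carried through.
#'
#' @param path CSV path.
#' @return data.frame of the raw rows (not yet validated; see
#'   [density_from_absorption()]).
#' @export
read_absorption_csv <- function(path) {
  if (!file.exists(path))
    stop("absorption file not found: ", path, call. = FALSE)
  df <- read_csv_skip_meta(path)
  need <- c("I0", "IV", "path_cm", "sigma_cm2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("absorption CSV missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Write a simulated trajectory to CSV (`time_s,<species>...`)
#' @param traj An `ohkin_trajectory` from [simulate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  hdr <- paste(names(traj), collapse = ",")
  rows <- apply(traj, 1, function(r) paste(fmt9(r), collapse = ","))
  write_lines_utf8(c(hdr, rows), path)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path CSV path.
#' @return data.frame with `time_s` and one column per species.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path, call. = FALSE)
  read_csv_skip_meta(path)
}

#' Write a theory-vs-experiment lifetime comparison CSV
#'
#' Columns `n0_1e16_cm3,experimental_us,theory_us`, lifetimes in
#' microseconds.
#'
#' @param cmp data.frame from [compare_theory_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(cmp, path) {
  body <- c("n0_1e16_cm3,experimental_us,theory_us",
            if (nrow(cmp) > 0)
              paste(signif(cmp$n0_cm3 / 1e16, 6),
                    signif(cmp$tau_experimental_s * 1e6, 6),
                    signif(cmp$tau_theory_s * 1e6, 6), sep = ","))
  write_lines_utf8(body, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records inputs, effective configuration, seed, package version and
#' wall-clock time so a run can be reproduced.
#'
#' @param path Output path.
#' @param command Subcommand name.
#' @param config Effective configuration (list).
#' @param seed Master seed used (or `NA`).
#' @param extra Additional fields to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config = list(), seed = NA,
                           extra = list()) {
  manifest <- c(
    list(command = command,
         package = "ohkin",
         version = as.character(utils::packageVersion("ohkin")),
         seed = seed,
         config = config,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
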
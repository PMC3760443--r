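# File I/O binding the pipeline stages: mass-list TSV, assignment TSV,
# truth tables, JSON run summaries, and packaged reference mass lists.

#' Read an observed mass list from TSV
#'
#' Expects a tab-separated file with header columns `sample_id`,
#' `group_label`, `mz` (extra columns are kept); blank lines and lines
#' starting with `#` are skipped. File order is preserved.
#'
#' @param path TSV path.
#' @return Data frame with at least `sample_id`, `group_label` and
#'   numeric `mz`.
#' @export
read_masslist <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  if (!length(lineno)) stop("no data lines in ", path, call. = FALSE)
  df <- utils::read.delim(text = lines[keep], header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group_label", "mz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mass list ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  mz <- suppressWarnings(as.numeric(df$mz))
  bad <- which(is.na(mz))
  if (length(bad))
    stop(sprintf("non-numeric mz '%s' at line %d of %s",
                 df$mz[bad[1]], lineno[bad[1] + 1L], path),
         call. = FALSE)
  df$mz <- mz
  df
}

#' Write an observed mass list as TSV
#'
#' Inverse of [read_masslist()]; masses are written at full precision so
#' that a read-back reproduces the input.
#'
#' @param masses data frame with `sample_id`, `group_label`, `mz`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_masslist <- function(masses, path) {
  masses <- .as_masslist(masses)
  out <- masses[, c("sample_id", "group_label", "mz")]
  out$mz <- format(out$mz, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write assignments as TSV
#'
#' Report dialect: columns `mz`, `assigned_form`, `theoretical_mz`,
#' `delta_mda`, `rank`, `n_ties`. Masses carry four decimals (Da), the
#' delta one decimal in mDa; unassigned rows have an empty form field
#' and rank 0. Output is byte-stable for a fixed input.
#'
#' @param assignments data frame from [assign_all()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_assignments <- function(assignments, path) {
  stopifnot(is.data.frame(assignments))
  unas <- is.na(assignments$assigned_form)
  out <- data.frame(
    mz = sprintf("%.4f", assignments$mz),
    assigned_form = ifelse(unas, "", assignments$assigned_form),
    theoretical_mz = ifelse(unas, "",
                            sprintf("%.4f", assignments$theoretical_mz)),
    delta_mda = ifelse(unas, "",
                       sprintf("%.1f", 1000 * assignments$delta)),
    rank = assignments$rank,
    n_ties = assignments$n_ties,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Echoes the run configuration with package version, seed, counts and
#' (when available) the calibration estimate; keys are sorted so the
#' output is byte-stable.
#'
#' @param path output path.
#' @param ... named summary fields (e.g. config echo, counts).
#' @param assignments optional [assign_all()] result; its tolerance and
#'   calibration attributes are included.
#' @return Invisibly, `path`.
#' @export
write_run_summary <- function(path, ..., assignments = NULL) {
  fields <- list(package = "acylforms",
                 version = as.character(utils::packageVersion("acylforms")),
                 ...)
  if (!is.null(assignments)) {
    fields$n_masses <- nrow(assignments)
    fields$n_assigned <- sum(!is.na(assignments$assigned_form))
    fields$tolerance <- attr(assignments, "tolerance")
    cal <- attr(assignments, "calibration")
    if (!is.null(cal)) fields$calibration <- cal
  }
  fields <- fields[order(names(fields))]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Packaged reference mass lists (flounder stomach extracts)
#'
#' Observed [M+H]+ mass lists of ghrelin species purified from barfin
#' flounder stomach extracts, one file per feeding group (normal feed
#' plus C7-, C8- and C9-enriched feed), transcribed with their published
#' form labels. The `expected_form` column carries the published label
#' and the `note` column flags rows excluded from strict reproduction:
#' `adduct` (the +24/+17/+1 satellite species), `anomalous` (a mass
#' ~1.8 Da from its label's theoretical value, a probable misprint) and
#' `label_conflict` (a published label inconsistent with the
#' glycine-donor rule).
#'
#' @param group one of `"cont"`, `"C7"`, `"C8"`, `"C9"`.
#' @return Data frame as from [read_masslist()], with `expected_form`
#'   and `note` columns.
#' @export
table1_masses <- function(group = c("cont", "C7", "C8", "C9")) {
  group <- match.arg(group)
  file <- sprintf("table1_%s.tsv", tolower(group))
  path <- system.file("extdata", file, package = "acylforms",
                      mustWork = TRUE)
  read_masslist(path)
}
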
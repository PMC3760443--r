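# Matching observed [M+H]+ masses to candidate molecular forms, global
# calibration-offset estimation, and Edman-read consistency checks.

#' Match one observed mass against a candidate set
#'
#' The best candidate minimizes |observed - theoretical| and is reported
#' only when that minimum is within `tolerance`. All candidates whose
#' |delta| is within `tie_window` of the best |delta| are reported as
#' ties (the best form included), ordered by |delta| then label.
#'
#' @param mz observed [M+H]+ in Da.
#' @param candidates a `candidate_set` from [enumerate_forms()].
#' @param tolerance maximum |observed - theoretical| in Da for an
#'   assignment (default 0.25, the absolute MALDI-TOF scale the flounder
#'   data support).
#' @param tie_window ties are candidates within this margin (Da) of the
#'   best |delta| (default 0.05).
#' @return List with `label` (NA if no match), `theoretical` (Da),
#'   `delta` (observed - theoretical, Da), and `ties` (data frame of
#'   tied candidates).
#' @examples
#' cands <- enumerate_forms(flounder_ghrelin_context(), enum_config())
#' match_one(2172.06, cands)$label  # "19-(C10:0)"
#' @export
match_one <- function(mz, candidates, tolerance = 0.25,
                      tie_window = 0.05) {
  stopifnot(inherits(candidates, "candidate_set"), nrow(candidates) > 0L)
  if (!is.numeric(mz) || length(mz) != 1L || !is.finite(mz) || mz <= 0)
    stop("mz must be a single positive finite number", call. = FALSE)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  th <- candidates$mz  # sorted ascending by construction
  i <- findInterval(mz, th)
  near <- unique(pmin(pmax(c(i, i + 1L), 1L), length(th)))
  best_i <- near[which.min(abs(mz - th[near]))]
  best_delta <- mz - th[best_i]
  if (abs(best_delta) > tolerance)
    return(list(label = NA_character_, theoretical = NA_real_,
                delta = NA_real_,
                ties = candidates[0L, c("label", "mz")]))
  win <- abs(best_delta) + tie_window
  tied <- candidates[abs(mz - th) <= win, c("label", "mz")]
  tied <- tied[order(abs(mz - tied$mz), tied$label), ]
  rownames(tied) <- NULL
  list(label = candidates$label[best_i], theoretical = th[best_i],
       delta = best_delta, ties = tied)
}

.as_masslist <- function(masses) {
  if (is.numeric(masses))
    masses <- data.frame(sample_id = as.character(seq_along(masses)),
                         group_label = character(length(masses)),
                         mz = as.numeric(masses),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(masses),
            all(c("sample_id", "group_label", "mz") %in% names(masses)))
  masses
}

.match_frame <- function(masses, candidates, tolerance, tie_window) {
  res <- lapply(masses$mz, match_one, candidates = candidates,
                tolerance = tolerance, tie_window = tie_window)
  data.frame(
    sample_id = as.character(masses$sample_id),
    group_label = as.character(masses$group_label),
    mz = masses$mz,
    assigned_form = vapply(res, `[[`, "", "label"),
    theoretical_mz = vapply(res, `[[`, 0, "theoretical"),
    delta = vapply(res, `[[`, 0, "delta"),
    rank = ifelse(is.na(vapply(res, `[[`, "", "label")), 0L, 1L),
    n_ties = vapply(res, function(r) nrow(r$ties), 0L),
    stringsAsFactors = FALSE
  )
}

#' Assign a list of observed masses to molecular forms
#'
#' Each observed mass is matched independently (duplicates included).
#' With `offset_correction = TRUE` a two-pass scheme is used: provisional
#' matching, robust estimation of the global calibration offset
#' ([estimate_offset()]) over the confidently assigned masses, then
#' re-matching after subtracting the offset from every observed mass.
#' Output order follows input order.
#'
#' @param masses numeric vector of [M+H]+ values, or a data frame with
#'   columns `sample_id`, `group_label`, `mz` (as from
#'   [read_masslist()]).
#' @inheritParams match_one
#' @param offset_correction estimate and remove a global calibration
#'   offset before the final matching pass.
#' @return Data frame with one row per observed mass: `sample_id`,
#'   `group_label`, `mz`, `assigned_form` (NA for no match),
#'   `theoretical_mz`, `delta` (offset-corrected observed minus
#'   theoretical), `rank` (1 if assigned, 0 otherwise), `n_ties`, and
#'   `offset_applied`. When correction is on, the
#'   [estimate_offset()] result is attached as attribute
#'   `"calibration"`.
#' @export
assign_all <- function(masses, candidates, tolerance = 0.25,
                       offset_correction = FALSE, tie_window = 0.05) {
  masses <- .as_masslist(masses)
  if (!nrow(masses)) {
    out <- .match_frame(masses, candidates, tolerance, tie_window)
    out$offset_applied <- numeric(0)
    return(out)
  }
  out <- .match_frame(masses, candidates, tolerance, tie_window)
  offset <- 0
  calibration <- NULL
  if (offset_correction && any(!is.na(out$assigned_form))) {
    calibration <- estimate_offset(out)
    offset <- calibration$offset
    corrected <- masses
    corrected$mz <- masses$mz - offset
    out <- .match_frame(corrected, candidates, tolerance, tie_window)
    out$mz <- masses$mz  # report the as-measured mass
  }
  out$offset_applied <- offset
  attr(out, "calibration") <- calibration
  attr(out, "tolerance") <- tolerance
  out
}

#' Estimate the global calibration offset
#'
#' Median of observed-minus-theoretical deltas over the assigned masses;
#' the median is robust to the occasional aberrant row. Dispersion is the
#' raw median absolute deviation (no consistency constant).
#'
#' @param assignments data frame from [assign_all()] (or any frame with
#'   `assigned_form` and `delta` columns).
#' @return List with `offset` (Da), `n_used`, `dispersion` (Da).
#' @export
estimate_offset <- function(assignments) {
  stopifnot(is.data.frame(assignments),
            all(c("assigned_form", "delta") %in% names(assignments)))
  d <- assignments$delta[!is.na(assignments$assigned_form)]
  if (!length(d))
    stop("no confident assignments to estimate an offset from",
         call. = FALSE)
  off <- stats::median(d)
  list(offset = off, n_used = length(d),
       dispersion = stats::median(abs(d - off)))
}

#' Check an Edman sequencing read against a molecular form
#'
#' Edman degradation reports one residue per cycle; a residue blocked by
#' a covalent modification gives no signal, conventionally written `X`.
#' Non-`X` cycles must equal the context residue at that position. In
#' strict mode (the default, appropriate for modification-site
#' inference) every `X` cycle must be explained by a modified site of
#' the form, and every modified site within the read span must appear as
#' `X`; lenient mode lets `X` match anything.
#'
#' @param read string over the 20 one-letter codes plus `X`.
#' @param form either a one-row slice of a `candidate_set` or a list
#'   with elements `length` and `acyl_n` (NA or `NULL` meaning
#'   des-acyl).
#' @param context the [processing_context()] the form was enumerated
#'   from.
#' @param strict logical (default TRUE).
#' @return TRUE if the read is consistent with the form.
#' @examples
#' ctx <- flounder_ghrelin_context()
#' cands <- enumerate_forms(ctx, enum_config())
#' edman_consistent("GSXFLSPSHKPPNKGKP",
#'                  cands[cands$label == "19-(C10:0)", ], ctx)  # TRUE
#' @export
edman_consistent <- function(read, form, context, strict = TRUE) {
  stopifnot(inherits(context, "processing_context"))
  if (!is.character(read) || length(read) != 1L || !nzchar(read))
    stop("read must be a non-empty string", call. = FALSE)
  cyc <- strsplit(toupper(read), "")[[1]]
  bad <- which(!cyc %in% c(.AA_ALPHABET, "X"))
  if (length(bad))
    stop(sprintf("invalid Edman cycle character '%s' at cycle %d",
                 cyc[bad[1]], bad[1]), call. = FALSE)
  if (is.data.frame(form)) {
    stopifnot(nrow(form) == 1L)
    form <- list(length = form$length, acyl_n = form$acyl_n)
  }
  L <- as.integer(form$length)
  acylated <- !is.null(form$acyl_n) && !is.na(form$acyl_n)
  if (length(cyc) > L)
    stop("read is longer than the molecular form", call. = FALSE)
  total <- paste0(context$core, context$extension)
  site <- context$acyl_site
  for (i in seq_along(cyc)) {
    expected <- substr(total, i, i)
    modified <- acylated && i == site
    if (cyc[i] == "X") {
      if (strict && !modified) return(FALSE)
    } else {
      if (cyc[i] != expected) return(FALSE)
      if (strict && modified) return(FALSE)
    }
  }
  TRUE
}
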
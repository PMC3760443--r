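# Synthetic mass-list generator emulating the feeding experiment's
# statistical structure: mixtures of molecular forms, Gaussian
# measurement noise, a global calibration offset, optional adducts.

.SCENARIOS <- c("control", "C7", "C8", "C9")

# Qualitative mixture weights per feeding scenario, keyed by form label.
# The study reports yield ranks per group (highest / second / third), not
# proportions; these weights encode that rank order plus the remaining
# forms detected in each group and are configuration, not measured
# values. The C7 scenario shares the control support (no C7-acylated form
# is ever produced) at reduced total abundance.
.SCENARIO_WEIGHTS <- list(
  control = c("19-(C10:0)" = 0.50, "20-(C10:0)-amide" = 0.20,
              "19-(C8:0)" = 0.08,
              "21-(C8:0)" = 0.0244, "19-(C9:0)" = 0.0244,
              "19-(C10:1)" = 0.0244, "21-(C9:0)" = 0.0244,
              "21-(C10:1)" = 0.0244, "20-(C8:0)-amide" = 0.0244,
              "20-(C10:2)-amide" = 0.0244, "20-(C9:0)-amide" = 0.0244,
              "20-(C10:1)-amide" = 0.0248),
  C7 = c("19-(C10:0)" = 0.50, "20-(C10:0)-amide" = 0.15,
         "19-(C10:1)" = 0.10, "21-(C10:0)" = 0.10,
         "21-(C10:1)" = 0.05, "20-(C10:1)-amide" = 0.05,
         "19-(C8:0)" = 0.05),
  C8 = c("19-(C8:0)" = 0.45, "20-(C8:0)-amide" = 0.15,
         "19-(C10:0)" = 0.15, "20-(C10:0)-amide" = 0.10,
         "21-(C8:0)" = 0.05, "19-(C9:0)" = 0.04, "19-(C10:1)" = 0.06),
  C9 = c("19-(C9:0)" = 0.45, "19-(C10:0)" = 0.15,
         "20-(C9:0)-amide" = 0.15, "21-(C9:0)" = 0.10,
         "18-(C9:0)" = 0.05, "19-(C8:0)" = 0.05, "19-(C10:2)" = 0.05)
)

#' Mixture weights for a feeding scenario
#'
#' Maps a feeding-group scenario onto mixture weights over the candidate
#' forms: the control and C7 groups are dominated by the 19-residue
#' decanoylated (C10:0) peptide, the C8 and C9 groups by the 19-residue
#' C8:0 and C9:0 peptides respectively, and no C7-acylated form ever
#' receives positive weight. Weights encode the published yield ranks,
#' not measured proportions.
#'
#' @param scenario one of `"control"`, `"C7"`, `"C8"`, `"C9"`.
#' @param candidates a `candidate_set`; every weighted form must be
#'   present in it.
#' @return Named numeric vector over `candidates$label`, summing to 1,
#'   with attribute `abundance_scale` (relative total abundance of the
#'   group; < 1 for C7, whose total ghrelin activity is reduced).
#' @export
scenario_weights <- function(scenario, candidates) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% .SCENARIOS)
    stop("unknown scenario '", paste(scenario, collapse = ","),
         "'; use one of ", paste(.SCENARIOS, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(candidates, "candidate_set"))
  base <- .SCENARIO_WEIGHTS[[scenario]]
  missing <- setdiff(names(base), candidates$label)
  if (length(missing))
    stop("candidate set lacks weighted forms: ",
         paste(missing, collapse = ", "), call. = FALSE)
  w <- stats::setNames(numeric(nrow(candidates)), candidates$label)
  w[names(base)] <- base
  w <- w / sum(w)
  attr(w, "abundance_scale") <- if (scenario == "C7") 0.5 else 1
  w
}

#' Simulation configuration
#'
#' @param scenario `"control"`, `"C7"`, `"C8"`, `"C9"` or `"custom"`
#'   (which requires `weights`).
#' @param n_masses number of observed masses to draw (>= 1).
#' @param sigma Gaussian mass-noise SD in Da (default 0.05, the
#'   MALDI-TOF scale of the flounder data).
#' @param offset global calibration shift in Da added to every mass.
#' @param adduct_prob probability that a drawn form is replaced by its
#'   adduct variant.
#' @param seed integer seed; the generator never touches the global RNG
#'   state.
#' @param weights named numeric vector over candidate labels (custom
#'   scenario only); non-negative, normalized internally.
#' @param adduct [adduct_spec()] used for adduct replacement (default
#'   the "+24" registry entry).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scenario = "control", n_masses = 100L,
                       sigma = 0.05, offset = 0, adduct_prob = 0,
                       seed = 1L, weights = NULL,
                       adduct = adduct_registry()[["+24"]]) {
  n_masses <- as.integer(n_masses)
  if (is.na(n_masses) || n_masses < 1L)
    stop("n_masses must be >= 1", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("sigma must be >= 0", call. = FALSE)
  if (!is.numeric(adduct_prob) || adduct_prob < 0 || adduct_prob > 1)
    stop("adduct_prob must be in [0, 1]", call. = FALSE)
  if (!scenario %in% c(.SCENARIOS, "custom"))
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  if (scenario == "custom") {
    if (is.null(weights) || is.null(names(weights)) ||
        any(weights < 0) || sum(weights) <= 0)
      stop("custom scenario needs named non-negative weights",
           call. = FALSE)
    weights <- weights / sum(weights)
  }
  structure(list(scenario = scenario, n_masses = n_masses, sigma = sigma,
                 offset = offset, adduct_prob = adduct_prob,
                 seed = as.integer(seed), weights = weights,
                 adduct = adduct),
            class = "sim_config")
}

#' Simulate a synthetic mass list with ground truth
#'
#' Draws `n_masses` molecular forms i.i.d. from the scenario's mixture
#' weights, computes their exact theoretical [M+H]+, optionally replaces
#' a form by its adduct variant with probability `adduct_prob`, and adds
#' the global calibration offset plus Gaussian noise. Fully reproducible
#' from the seed; the global RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @param context a [processing_context()] (default the flounder
#'   ghrelin context).
#' @param enum an [enum_config()] defining the form space.
#' @return List with `truth` (data frame: `id`, `true_form`,
#'   `theoretical_mz`, `observed_mz`) and `observed` (mass-list data
#'   frame with columns `sample_id`, `group_label`, `mz`, the assigner's
#'   input dialect).
#' @export
simulate_dataset <- function(config,
                             context = flounder_ghrelin_context(),
                             enum = enum_config()) {
  stopifnot(inherits(config, "sim_config"))
  candidates <- enumerate_forms(context, enum)
  w <- if (config$scenario == "custom") {
    missing <- setdiff(names(config$weights), candidates$label)
    if (length(missing))
      stop("weights name forms absent from the candidate set: ",
           paste(missing, collapse = ", "), call. = FALSE)
    full <- stats::setNames(numeric(nrow(candidates)), candidates$label)
    full[names(config$weights)] <- config$weights
    full
  } else {
    scenario_weights(config$scenario, candidates)
  }
  n <- config$n_masses
  draws <- withr::with_seed(config$seed, {
    idx <- sample.int(nrow(candidates), n, replace = TRUE, prob = w)
    list(idx = idx,
         adduct_flip = stats::runif(n) < config$adduct_prob,
         noise = stats::rnorm(n, 0, config$sigma))
  })
  label <- candidates$label[draws$idx]
  theo <- candidates$mz[draws$idx]
  flip <- draws$adduct_flip
  if (any(flip)) {
    label[flip] <- paste(label[flip], config$adduct$label)
    theo[flip] <- theo[flip] + config$adduct$delta
  }
  observed <- theo + config$offset + draws$noise
  id <- sprintf("sim%04d", seq_len(n))
  truth <- data.frame(id = id, true_form = label, theoretical_mz = theo,
                      observed_mz = observed, stringsAsFactors = FALSE)
  masses <- data.frame(sample_id = id, group_label = config$scenario,
                       mz = observed, stringsAsFactors = FALSE)
  list(truth = truth, observed = masses)
}

#' Top-1 recovery of true forms
#'
#' Fraction of simulated observations whose assigned best form equals
#' the generating form; unassigned masses count as failures.
#'
#' @param truth the `truth` data frame from [simulate_dataset()].
#' @param assignments result of [assign_all()] on the matching
#'   `observed` table.
#' @return Fraction in [0, 1].
#' @export
recovery <- function(truth, assignments) {
  stopifnot(is.data.frame(truth), is.data.frame(assignments))
  if (nrow(truth) != nrow(assignments) ||
      !identical(as.character(truth$id),
                 as.character(assignments$sample_id)))
    stop("truth and assignments are not id-aligned", call. = FALSE)
  hit <- !is.na(assignments$assigned_form) &
    assignments$assigned_form == truth$true_form
  mean(hit)
}
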
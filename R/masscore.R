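# Peptide and modification mass calculus: residue masses, C-terminal
# states, fatty-acyl deltas, adducts, and [M+H]+ assembly.

.water_mass <- function(mode) {
  em <- .element_masses(mode)
  2 * em[["H"]] + em[["O"]]
}

# Amidation replaces the C-terminal hydroxyl with an amine: -OH +NH2,
# i.e. -O +N +H (monoisotopic: -0.98402 Da).
.amide_delta <- function(mode) {
  em <- .element_masses(mode)
  em[["N"]] + em[["H"]] - em[["O"]]
}

.check_cterm <- function(cterm) {
  match.arg(cterm, c("free_acid", "amide"))
}

.check_residues <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("peptide sequence must be a non-empty string", call. = FALSE)
  aa <- strsplit(seq, "")[[1]]
  bad <- which(!aa %in% .AA_ALPHABET)
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]),
         call. = FALSE)
  aa
}

#' Residue (water-loss) mass of a standard amino acid
#'
#' @param aa one-letter code of one of the 20 standard amino acids.
#' @param mode `"monoisotopic"` (default) or `"average"`.
#' @return Residue mass in Da.
#' @examples
#' residue_mass("G")  # 57.02146
#' @export
residue_mass <- function(aa, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (!is.character(aa) || length(aa) != 1L || nchar(aa) != 1L ||
      !aa %in% .AA_ALPHABET)
    stop(sprintf("unknown residue '%s'", as.character(aa)[1]), call. = FALSE)
  formula_mass(.RESIDUE_FORMULA[aa, ], mode)
}

#' Mass of an elemental formula
#'
#' @param counts named integer vector of element counts (names among
#'   C, H, N, O, S, Na).
#' @param mode mass mode.
#' @return Mass in Da.
#' @export
formula_mass <- function(counts, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  em <- .element_masses(mode)
  if (is.null(names(counts)) || !all(names(counts) %in% names(em)))
    stop("formula counts must be named with elements among ",
         paste(names(em), collapse = ", "), call. = FALSE)
  sum(counts * em[names(counts)])
}

#' Elemental formula of a peptide
#'
#' Assembles the full elemental composition of a peptide with the given
#' C-terminal state. This is an independent route to the peptide mass
#' (compare [peptide_mass()], which sums per-residue masses).
#'
#' @inheritParams peptide_mass
#' @return Named integer vector of element counts.
#' @export
peptide_formula <- function(seq, cterm = "free_acid") {
  cterm <- .check_cterm(cterm)
  aa <- .check_residues(seq)
  counts <- colSums(.RESIDUE_FORMULA[aa, , drop = FALSE])
  counts[["H"]] <- counts[["H"]] + 2L  # + H2O
  counts[["O"]] <- counts[["O"]] + 1L
  if (cterm == "amide") {
    counts[["O"]] <- counts[["O"]] - 1L
    counts[["N"]] <- counts[["N"]] + 1L
    counts[["H"]] <- counts[["H"]] + 1L
  }
  counts
}

#' Neutral mass of a peptide
#'
#' Sum of residue masses plus water (free acid); the amide state applies
#' the -OH -> -NH2 replacement (-0.98402 Da monoisotopic).
#'
#' @param seq amino-acid string over the 20 standard one-letter codes.
#' @param cterm `"free_acid"` (default) or `"amide"`.
#' @param mode `"monoisotopic"` (default) or `"average"`.
#' @return Neutral mass in Da.
#' @examples
#' peptide_mass("GSSFLSPSHKPPNKGKPPR")  # 2017.0857
#' @export
peptide_mass <- function(seq, cterm = "free_acid",
                         mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  cterm <- .check_cterm(cterm)
  aa <- .check_residues(seq)
  m <- sum(vapply(aa, residue_mass, 0, mode = mode)) + .water_mass(mode)
  if (cterm == "amide") m <- m + .amide_delta(mode)
  m
}

#' Fatty-acyl specification
#'
#' A fatty-acyl group Cn:m with `n` carbons and `m` double bonds. Its mass
#' contribution is the fatty acid minus water, i.e. the esterified acyl
#' moiety CnH(2n-2-2m)O.
#'
#' @param n chain length in carbons (>= 2).
#' @param m number of double bonds (>= 0); must satisfy 2n - 2 - 2m >= 0.
#' @return An object of class `fatty_acyl`.
#' @examples
#' fatty_acyl(10)      # decanoyl, C10:0
#' fatty_acyl(10, 1)   # C10:1
#' @export
fatty_acyl <- function(n, m = 0L) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 2L) stop("chain length n must be >= 2", call. = FALSE)
  if (is.na(m) || m < 0L) stop("unsaturation m must be >= 0", call. = FALSE)
  if (2L * n - 2L - 2L * m < 0L)
    stop(sprintf("C%d:%d has a negative hydrogen count", n, m),
         call. = FALSE)
  structure(list(n = n, m = m), class = "fatty_acyl")
}

#' @export
format.fatty_acyl <- function(x, ...) sprintf("C%d:%d", x$n, x$m)

#' @export
print.fatty_acyl <- function(x, ...) {
  cat("<fatty_acyl>", format(x), "\n")
  invisible(x)
}

#' Mass delta of a fatty-acyl modification
#'
#' @param acyl a [fatty_acyl()] object (or `NULL`, giving 0).
#' @param mode mass mode.
#' @return Delta in Da (mass of CnH(2n-2-2m)O).
#' @examples
#' acyl_delta(fatty_acyl(8))   # 126.10447 (octanoyl)
#' acyl_delta(fatty_acyl(10))  # 154.13577 (decanoyl)
#' @export
acyl_delta <- function(acyl, mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  if (is.null(acyl)) return(0)
  if (!inherits(acyl, "fatty_acyl"))
    stop("acyl must be a fatty_acyl object or NULL", call. = FALSE)
  formula_mass(c(C = acyl$n, H = 2L * acyl$n - 2L - 2L * acyl$m, O = 1L),
               mode)
}

#' Adduct specification
#'
#' @param label non-empty adduct label.
#' @param delta signed mass shift in Da.
#' @return An object of class `adduct_spec`.
#' @export
adduct_spec <- function(label, delta) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("adduct label must be a non-empty string", call. = FALSE)
  delta <- as.numeric(delta)
  if (!is.finite(delta)) stop("adduct delta must be finite", call. = FALSE)
  structure(list(label = label, delta = delta), class = "adduct_spec")
}

#' Built-in adduct registry
#'
#' Adducts recurring in MALDI-TOF peptide spectra: the Na-for-H
#' replacement (+21.98194 Da), an empirical "+24" sodium-like species
#' (+23.98 Da, matching the printed mass differences of the
#' sodium-associated peaks in the flounder ghrelin data; chemically
#' ambiguous and therefore configurable), and a "+1" satellite
#' (+0.98402 Da, the free-acid/amide spacing). All values are
#' user-overridable by constructing [adduct_spec()] objects directly.
#'
#' @return Named list of [adduct_spec()] objects.
#' @export
adduct_registry <- function() {
  list(
    `Na-H` = adduct_spec("Na-H", 21.981944),
    `+24`  = adduct_spec("+24", 23.98),
    `+1`   = adduct_spec("+1", 0.98402)
  )
}

#' Theoretical [M+H]+ of a molecular form
#'
#' Neutral peptide mass plus the acyl delta (if any), the adduct delta
#' (if any), and one proton (1.007276 Da).
#'
#' @inheritParams peptide_mass
#' @param acyl a [fatty_acyl()] or `NULL` for the des-acyl form.
#' @param adduct an [adduct_spec()] or `NULL`.
#' @return [M+H]+ in Da.
#' @examples
#' # decanoylated 19-residue flounder ghrelin, measured at 2172.06
#' form_mh("GSSFLSPSHKPPNKGKPPR", acyl = fatty_acyl(10))  # 2172.229
#' @export
form_mh <- function(seq, cterm = "free_acid", acyl = NULL, adduct = NULL,
                    mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  m <- peptide_mass(seq, cterm, mode) + acyl_delta(acyl, mode)
  if (!is.null(adduct)) {
    if (!inherits(adduct, "adduct_spec"))
      stop("adduct must be an adduct_spec object or NULL", call. = FALSE)
    m <- m + adduct$delta
  }
  m + .PROTON_MASS
}
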
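# Physical and chemical constants used throughout the mass calculus.
# Monoisotopic element masses follow CODATA/AME values; average masses are
# IUPAC standard atomic weights (abridged). All masses in Da.

.ELEMENTS <- c("C", "H", "N", "O", "S", "Na")

.ELEMENT_MASS <- list(
  monoisotopic = c(C = 12.0,      H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100, Na = 22.9897692809),
  average      = c(C = 12.011,    H = 1.008,          N = 14.007,
                   O = 15.999,    S = 32.06,          Na = 22.98977)
)

# Mass of a bare proton (not the hydrogen atom): used for [M+H]+ in both
# mass modes.
.PROTON_MASS <- 1.007276

# Residue (water-loss) elemental compositions of the 20 standard amino
# acids, rows ordered C, H, N, O, S.
.RESIDUE_FORMULA <- matrix(
  c(3,  5, 1, 1, 0,  # A
    3,  5, 1, 1, 1,  # C
    4,  5, 1, 3, 0,  # D
    5,  7, 1, 3, 0,  # E
    9,  9, 1, 1, 0,  # F
    2,  3, 1, 1, 0,  # G
    6,  7, 3, 1, 0,  # H
    6, 11, 1, 1, 0,  # I
    6, 12, 2, 1, 0,  # K
    6, 11, 1, 1, 0,  # L
    5,  9, 1, 1, 1,  # M
    4,  6, 2, 2, 0,  # N
    5,  7, 1, 1, 0,  # P
    5,  8, 2, 2, 0,  # Q
    6, 12, 4, 1, 0,  # R
    3,  5, 1, 2, 0,  # S
    4,  7, 1, 2, 0,  # T
    5,  9, 1, 1, 0,  # V
   11, 10, 2, 1, 0,  # W
    9,  9, 1, 2, 0), # Y
  ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("C", "H", "N", "O", "S"))
)

.AA_ALPHABET <- rownames(.RESIDUE_FORMULA)

# IUPAC nucleotide ambiguity codes, embedded (not read from a file or
# borrowed at run time) so that degeneracy arithmetic is stable.
.IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.element_masses <- function(mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  .ELEMENT_MASS[[mode]]
}

#' Export mass constants as a machine-readable table
#'
#' Writes every constant entering the mass calculus (element masses in both
#' modes, residue elemental formulas and residue masses, water, proton and
#' amidation deltas) to a tab-separated file for external audit.
#'
#' @param path output file path.
#' @return Invisibly, the data frame that was written.
#' @export
write_mass_constants <- function(path) {
  mono <- .element_masses("monoisotopic")
  avg <- .element_masses("average")
  el <- data.frame(
    kind = "element", name = names(mono),
    formula = names(mono),
    monoisotopic = unname(mono), average = unname(avg),
    stringsAsFactors = FALSE
  )
  fml <- apply(.RESIDUE_FORMULA, 1L, function(r) {
    nz <- r[r > 0]
    paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = "")
  })
  res <- data.frame(
    kind = "residue", name = .AA_ALPHABET, formula = unname(fml),
    monoisotopic = vapply(.AA_ALPHABET, residue_mass, 0,
                          mode = "monoisotopic"),
    average = vapply(.AA_ALPHABET, residue_mass, 0, mode = "average"),
    stringsAsFactors = FALSE
  )
  spc <- data.frame(
    kind = "special",
    name = c("water", "proton", "amide_delta"),
    formula = c("H2O", "H+", "NH2-for-OH"),
    monoisotopic = c(.water_mass("monoisotopic"), .PROTON_MASS,
                     .amide_delta("monoisotopic")),
    average = c(.water_mass("average"), .PROTON_MASS,
                .amide_delta("average")),
    stringsAsFactors = FALSE
  )
  out <- rbind(el, res, spc)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
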
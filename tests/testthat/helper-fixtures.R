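# Shared fixtures: the flounder ghrelin context, default candidate set,
# and reference masses frozen from an independent elemental-composition
# oracle (computed once with pyteomics at 1e-5 Da agreement).

fl_ctx <- flounder_ghrelin_context()
fl_cands <- enumerate_forms(fl_ctx, enum_config())

# Independent oracle values (Da)
ORACLE <- list(
  res_G = 57.02146372,
  res_S = 87.03202840,
  water = 18.01056468,
  gg_free = 132.05349212,
  gg_amide = 131.06947654,
  core19_free = 2017.08574224,      # GSSFLSPSHKPPNKGKPPR
  acyl_c8 = 126.10446507,
  acyl_c9 = 140.12011513,
  acyl_c10 = 154.13576520,
  mh_19_c8 = 2144.19748331,
  mh_19_c9 = 2158.21313337,
  mh_19_c10 = 2172.22878344,
  mh_19_desacyl = 2018.09301924,    # core19 + proton
  mh_20_c8_amide = 2214.25058151,
  mh_20_c9_amide = 2228.26623158,
  mh_20_c10_amide = 2242.28188164,
  mh_18_c9 = 2002.11202235,
  mh_21_c8 = 2272.25606082
)

CORE20 <- "GSSFLSPSHKPPNKGKPPRA"
CORE19 <- "GSSFLSPSHKPPNKGKPPR"
PRIMER <- "TNGGNMGNCARACNATGGARG"
EDMAN_READ <- "GSXFLSPSHKPPNKGKP"

# random peptide over the 20 standard residues
random_peptide <- function(n) {
  paste0(sample(rownames(acylforms:::.RESIDUE_FORMULA), n,
                replace = TRUE), collapse = "")
}

unambiguous <- function(masses) is.na(masses$note) | masses$note == ""
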
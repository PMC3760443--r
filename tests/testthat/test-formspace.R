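test_that("candidate counts follow the closed-form product", {
  # default config: 5 backbones (18,19,20,21 acid + 20 amide) x
  # (6 chains x 3 unsaturation levels + des-acyl)
  expect_equal(nrow(fl_cands), 5 * (6 * 3 + 1))
  # widened chain range 6..12: 5 x (7 x 3 + 1) = 110
  wide <- enumerate_forms(fl_ctx, enum_config(chain_range = 6:12))
  expect_equal(nrow(wide), 110)
  # brute-force product for a handful of small configs
  for (cfg in list(enum_config(lengths = 19, chain_range = 8:10,
                               max_unsat = 1, include_desacyl = FALSE),
                   enum_config(lengths = 19:20, chain_range = 8:9,
                               max_unsat = 0),
                   enum_config(lengths = 18:20, chain_range = 10,
                               max_unsat = 2,
                               adducts = adduct_registry()["+24"]))) {
    cs <- enumerate_forms(fl_ctx, cfg)
    n_bb <- length(cfg$lengths) +
      length(glycine_donor_positions(fl_ctx, cfg$lengths))
    n_mod <- length(cfg$chain_range) * (cfg$max_unsat + 1) +
      cfg$include_desacyl
    n_add <- 1 + length(cfg$adducts)
    expect_equal(nrow(cs), n_bb * n_mod * n_add)
  }
})

test_that("single-point enumeration reproduces the principal form", {
  one <- enumerate_forms(fl_ctx,
                         enum_config(lengths = 19, chain_range = 10,
                                     max_unsat = 0,
                                     include_desacyl = FALSE))
  expect_equal(nrow(one), 1L)
  expect_equal(one$label, "19-(C10:0)")
  expect_equal(one$mz, ORACLE$mh_19_c10, tolerance = 1e-4)
})

test_that("amidation requires a downstream glycine donor", {
  expect_equal(glycine_donor_positions(fl_ctx, 18:21), 20L)
  ctx_gg <- processing_context(CORE20, "GG")
  expect_equal(glycine_donor_positions(ctx_gg, 20:21), c(20L, 21L))
  expect_equal(glycine_donor_positions(fl_ctx, 18L), integer(0))
  # extension without glycine: no amide form at any length
  ctx_a <- processing_context(CORE20, "A")
  cs <- enumerate_forms(ctx_a, enum_config())
  expect_false(any(cs$cterm == "amide"))
  expect_false(any(grepl("amide", cs$label)))
})

test_that("enumeration is deterministic, sorted and cache-free", {
  again <- enumerate_forms(fl_ctx, enum_config())
  expect_identical(fl_cands, again)
  expect_false(is.unsorted(fl_cands$mz))
  expect_false(anyDuplicated(fl_cands$label) > 0)
  # every stored mass equals an independent recomputation
  total <- paste0(fl_ctx$core, fl_ctx$extension)
  for (i in seq_len(nrow(fl_cands))) {
    row <- fl_cands[i, ]
    acyl <- if (is.na(row$acyl_n)) NULL else
      fatty_acyl(row$acyl_n, row$acyl_m)
    expect_equal(row$mz,
                 form_mh(substr(total, 1, row$length), row$cterm, acyl),
                 tolerance = 1e-12)
  }
})

test_that("mass-gap structure: global near-isobars, separated observed forms", {
  # the amide-Cn / free-acid-Cn+5 family caps the global gap near
  # 0.025 Da for any chain range spanning >= 5 carbons
  expect_equal(min_mass_gap(fl_cands), 0.02515, tolerance = 1e-3)
  wide <- enumerate_forms(fl_ctx, enum_config(chain_range = 6:12))
  expect_equal(min_mass_gap(wide), 0.02515, tolerance = 1e-3)
  # but every form observed in the stomach extracts is well separated
  # from every other default candidate: matching at 0.25 Da is sound
  observed <- c("19-(C8:0)", "19-(C9:0)", "19-(C10:0)", "19-(C10:1)",
                "19-(C10:2)", "18-(C9:0)", "21-(C8:0)", "21-(C9:0)",
                "21-(C10:0)", "21-(C10:1)", "20-(C8:0)-amide",
                "20-(C9:0)-amide", "20-(C10:0)-amide",
                "20-(C10:1)-amide", "20-(C10:2)-amide")
  expect_true(all(observed %in% fl_cands$label))
  for (f in observed) {
    gap <- min(abs(fl_cands$mz[fl_cands$label != f] -
                     fl_cands$mz[fl_cands$label == f]))
    expect_gt(gap, 0.9)
  }
})

test_that("chains of C6 and below collide with C10 amide forms", {
  # documents why the default chain range starts at C7: the 21-residue
  # C6-acylated free acids sit 0.073 Da below the 20-residue C10-amide
  # forms, inside any realistic MALDI-TOF tolerance
  wide <- enumerate_forms(fl_ctx, enum_config(chain_range = 6:12))
  mz <- function(l) wide$mz[wide$label == l]
  expect_equal(mz("20-(C10:1)-amide") - mz("21-(C6:2)"), 0.0728,
               tolerance = 1e-3)
  expect_equal(mz("20-(C10:0)-amide") - mz("21-(C6:1)"), 0.0728,
               tolerance = 1e-3)
})

test_that("enumeration rejects unrealizable configurations", {
  expect_error(enumerate_forms(fl_ctx, enum_config(lengths = 18:25)),
               "exceeds core\\+extension")
  expect_error(enumerate_forms(processing_context(CORE20, "G",
                                                  acyl_site = 8),
                               enum_config(lengths = 5:6)),
               "acyl site")
})

test_that("candidate sets export in published notation", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(fl_cands, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), nrow(fl_cands))
  expect_true("19-(C10:0)" %in% back$form)
  expect_equal(back$theoretical_mz[back$form == "19-(C10:0)"],
               2172.2288, tolerance = 1e-4)
})
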
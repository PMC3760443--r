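test_that("match_one finds the principal decanoylated form", {
  m <- match_one(2172.06, fl_cands, tolerance = 0.25)
  expect_equal(m$label, "19-(C10:0)")
  expect_equal(m$delta, -0.169, tolerance = 1e-2)
  # a 0.05 Da tolerance is tighter than the instrument offset: no match
  expect_true(is.na(match_one(2172.06, fl_cands, tolerance = 0.05)$label))
  # exact theoretical mass matches itself with zero delta
  i <- which(fl_cands$label == "20-(C9:0)-amide")
  m2 <- match_one(fl_cands$mz[i], fl_cands)
  expect_equal(m2$label, "20-(C9:0)-amide")
  expect_equal(m2$delta, 0)
})

test_that("match_one agrees with an exhaustive linear scan", {
  scan_oracle <- function(mz, cands, tol) {
    d <- abs(mz - cands$mz)
    i <- which.min(d)
    if (d[i] <= tol) cands$label[i] else NA_character_
  }
  set.seed(31)
  mzs <- runif(1000, min(fl_cands$mz) - 1, max(fl_cands$mz) + 1)
  for (mz in mzs)
    expect_identical(match_one(mz, fl_cands, 0.25)$label,
                     scan_oracle(mz, fl_cands, 0.25))
})

test_that("control-group masses assign uniquely to the principal form", {
  a <- assign_all(table1_masses("cont"), fl_cands, tolerance = 0.25)
  hits <- a$mz[!is.na(a$assigned_form) & a$assigned_form == "19-(C10:0)"]
  expect_equal(hits, 2172.06)
})

test_that("offset correction leaves well-separated assignments invariant", {
  masses <- table1_masses("cont")
  base <- assign_all(masses, fl_cands, tolerance = 0.25)
  shifted <- masses
  shifted$mz <- masses$mz + 0.10
  corr <- assign_all(shifted, fl_cands, tolerance = 0.25,
                     offset_correction = TRUE)
  expect_equal(corr$assigned_form, base$assigned_form)
  cal <- attr(corr, "calibration")
  expect_equal(cal$offset, estimate_offset(base)$offset + 0.10,
               tolerance = 1e-9)
  expect_equal(corr$offset_applied, rep(cal$offset, nrow(masses)))
})

test_that("no-match and empty inputs are valid results", {
  a <- assign_all(10.0, fl_cands)
  expect_equal(nrow(a), 1L)
  expect_true(is.na(a$assigned_form))
  expect_equal(a$rank, 0L)
  empty <- assign_all(numeric(0), fl_cands)
  expect_equal(nrow(empty), 0L)
})

test_that("offset estimation is the median with MAD dispersion", {
  fake <- data.frame(assigned_form = c("a", "b", "c"),
                     delta = c(-0.17, -0.16, -0.06))
  est <- estimate_offset(fake)
  expect_equal(est$offset, -0.16)
  expect_equal(est$n_used, 3L)
  zero <- data.frame(assigned_form = "a", delta = c(0, 0))
  expect_equal(estimate_offset(zero)$offset, 0)
  expect_equal(estimate_offset(zero)$dispersion, 0)
  none <- data.frame(assigned_form = NA_character_, delta = NA_real_)
  expect_error(estimate_offset(none), "no confident")
})

test_that("enlarging the tolerance never changes or drops an assignment", {
  masses <- c(table1_masses("cont")$mz, 2150.0, 2190.0)
  tols <- c(0.05, 0.1, 0.25, 0.5)
  prev <- assign_all(masses, fl_cands, tolerance = tols[1])
  for (tol in tols[-1]) {
    cur <- assign_all(masses, fl_cands, tolerance = tol)
    was <- !is.na(prev$assigned_form)
    expect_true(all(!is.na(cur$assigned_form[was])))
    expect_equal(cur$assigned_form[was], prev$assigned_form[was])
    prev <- cur
  }
})

test_that("assigning exact theoretical masses recovers every form", {
  a <- assign_all(fl_cands$mz, fl_cands, tolerance = 0.25)
  expect_equal(a$assigned_form, fl_cands$label)
  expect_true(all(a$delta == 0))
  expect_true(all(a$rank == 1L))
  # the near-isobaric amide/free-acid pairs surface as reported ties
  expect_true(any(a$n_ties > 1))
})

test_that("Edman reads discriminate acylated from des-acyl forms", {
  c10 <- fl_cands[fl_cands$label == "19-(C10:0)", ]
  desacyl <- fl_cands[fl_cands$label == "19-desacyl", ]
  # the published read: cycle 3 blank, consistent with acyl-Ser3
  expect_true(edman_consistent(EDMAN_READ, c10, fl_ctx))
  expect_false(edman_consistent(EDMAN_READ, desacyl, fl_ctx))
  # lenient mode lets the blank cycle match anything
  expect_true(edman_consistent(EDMAN_READ, desacyl, fl_ctx,
                               strict = FALSE))
  # a detected Ser3 contradicts the modified site in strict mode
  expect_false(edman_consistent("GSS", c10, fl_ctx))
  expect_true(edman_consistent("GSS", c10, fl_ctx, strict = FALSE))
  # sequence mismatches fail in any mode
  expect_false(edman_consistent("GSXW", c10, fl_ctx, strict = FALSE))
  expect_error(edman_consistent(strrep("G", 25), c10, fl_ctx), "longer")
  expect_error(edman_consistent("GS?", c10, fl_ctx), "cycle 3")
})
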
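# Spectral preprocessing operators: exact small-case oracles, the
# scatter-invariance properties SNV/MSC exist for, Savitzky-Golay
# correctness on polynomials, and chain parsing/composition.

test_that("SNV standardizes rows and is idempotent and affine-invariant", {
  s <- tiny_spectra(rbind(c(1, 2, 3)))
  expect_equal(unname(snv(s)$absorbance[1, ]), c(-1, 0, 1))

  set.seed(1)
  ref <- rnorm(20)
  s2 <- tiny_spectra(rbind(ref, 3 * ref + 5))
  out <- snv(s2)$absorbance
  expect_equal(unname(out[1, ]), unname(out[2, ]), tolerance = 1e-12)
  expect_equal(snv(snv(s2))$absorbance, snv(s2)$absorbance, tolerance = 1e-12)
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_equal(unname(apply(out, 1, sd)), c(1, 1))

  expect_error(snv(tiny_spectra(rbind(c(1, 1, 1), c(1, 2, 3)))), "S1")
})

test_that("MSC inverts affine scatter against a reference", {
  set.seed(2)
  ref <- rnorm(30) + 2
  s <- tiny_spectra(rbind(2 * ref + 1))
  expect_equal(unname(msc(s, reference = ref)$absorbance[1, ]), ref,
               tolerance = 1e-10)
  # reference = the row itself: identity
  expect_equal(unname(msc(s, reference = 2 * ref + 1)$absorbance[1, ]),
               2 * ref + 1, tolerance = 1e-10)

  # a_i + b_i * common shape -> all corrected rows agree
  shape <- sin(seq(0, 3, length.out = 40)) + 2
  rows <- t(sapply(1:6, function(i) runif(1, -1, 1) + runif(1, 0.5, 2) * shape))
  out <- msc(tiny_spectra(rows))$absorbance
  expect_lt(max(apply(out, 2, function(col) diff(range(col)))), 1e-8)

  # spectrum orthogonal to reference
  expect_error(msc(tiny_spectra(rbind(c(1, -1, 0, 0))),
                   reference = c(0, 0, 1, -1)), "orthogonal")
})

test_that("Savitzky-Golay reproduces analytic derivatives of polynomials", {
  wl <- seq(1000, 1100, by = 1)
  lin <- tiny_spectra(rbind(3 * wl + 7), wl)
  d1 <- savitzky_golay(lin, 15, 2, deriv_order = 1)
  expect_equal(unname(d1$absorbance[1, ]), rep(3, ncol(d1$absorbance)),
               tolerance = 1e-8)
  # axis shrinks by half a window per side
  expect_equal(d1$wavelengths_nm, wl[8:94])

  # derivative kills constant offsets
  s <- tiny_spectra(rbind(sin(wl / 10)), wl)
  s_off <- tiny_spectra(rbind(sin(wl / 10) + 100), wl)
  expect_equal(savitzky_golay(s, 15, 2, 1)$absorbance,
               savitzky_golay(s_off, 15, 2, 1)$absorbance, tolerance = 1e-8)

  # second derivative of a quadratic equals twice its leading coefficient
  quad <- tiny_spectra(rbind(0.5 * wl^2 - 3 * wl + 2), wl)
  d2 <- savitzky_golay(quad, 15, 2, deriv_order = 2)
  expect_equal(unname(d2$absorbance[1, ]), rep(1, ncol(d2$absorbance)),
               tolerance = 1e-6)

  # smoothing (deriv 0) reproduces a polynomial of the fitted degree exactly
  sm <- savitzky_golay(quad, 15, 2, deriv_order = 0)
  expect_equal(unname(sm$absorbance[1, ]),
               unname(quad$absorbance[1, 8:94]), tolerance = 1e-6)

  expect_error(savitzky_golay(lin, 14, 2, 1), "odd")
  expect_error(savitzky_golay(lin, 201, 2, 0), "larger than spectrum")
  expect_error(savitzky_golay(lin, 15, 2, 3), "deriv_order")
})

test_that("normalization maps rows to the unit interval or unit norm", {
  expect_equal(unname(normalize_spectra(tiny_spectra(rbind(c(2, 4, 6))),
                                        "minmax")$absorbance[1, ]),
               c(0, 0.5, 1))
  expect_equal(unname(normalize_spectra(tiny_spectra(rbind(c(3, 4))),
                                        "vector")$absorbance[1, ]),
               c(0.6, 0.8))
  s <- tiny_spectra(rbind(c(2, 4, 6), c(-1, 0, 3)))
  once <- normalize_spectra(s, "minmax")
  expect_equal(normalize_spectra(once, "minmax")$absorbance, once$absorbance)
  expect_error(normalize_spectra(tiny_spectra(rbind(c(5, 5, 5)))), "constant")
})

test_that("baseline correction removes exactly the fitted line", {
  wl <- 1:50
  s <- tiny_spectra(rbind(2 * wl + 3, sin(wl / 5) + 0.1 * wl), wl)
  out <- baseline_correct(s)
  expect_equal(unname(out$absorbance[1, ]), rep(0, 50), tolerance = 1e-10)
  slopes <- apply(out$absorbance, 1, function(r) coef(lm(r ~ wl))[2])
  expect_lt(max(abs(slopes)), 1e-10)
  expect_equal(baseline_correct(out)$absorbance, out$absorbance,
               tolerance = 1e-12)
})

test_that("chain labels parse, round-trip and compose left to right", {
  ch <- parse_chain("1Der+SNV")
  expect_equal(ch$label, "1Der+SNV")
  expect_equal(vapply(ch$steps, `[[`, "", "op"), c("1Der", "SNV"))
  expect_equal(parse_chain(chain_label(ch$steps))$steps, ch$steps)

  chp <- parse_chain("SG(window=11,poly=3)+SNV")
  expect_equal(chp$steps[[1]]$params$window_points, 11)
  expect_equal(chp$steps[[1]]$params$polyorder, 3)
  expect_equal(chp$label, "SG(window=11,poly=3)+SNV")

  expect_equal(chain_label(list()), "Original")
  expect_error(parse_chain("Bogus+SNV"), "unknown preprocessing operator")

  ds <- simulate_nir_dataset(quick_cfg(seed = 3))
  expect_identical(apply_chain("Original", ds$spectra)$absorbance,
                   ds$spectra$absorbance)
  manual <- snv(savitzky_golay(ds$spectra, 15, 2, 1))
  chained <- apply_chain("1Der+SNV", ds$spectra)
  expect_equal(chained$absorbance, manual$absorbance, tolerance = 1e-12)
  expect_equal(attr(chained, "chain"), "1Der+SNV")

  # operator failures carry the step index
  const <- tiny_spectra(matrix(1, 2, 30))
  expect_error(apply_chain("SNV", const), "step 1")
})
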
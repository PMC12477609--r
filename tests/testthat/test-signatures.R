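test_that("difference signatures subtract pointwise with unit checks", {
  wl <- 220:350
  a <- spectrum_tbl(wl, runif(131, 1e5, 3e5), unit = "molar_extinction")
  b <- spectrum_tbl(wl, runif(131, 1e5, 3e5), unit = "molar_extinction")
  expect_true(all(difference_signature(a, a)$value == 0))
  d1 <- difference_signature(a, b)
  d2 <- difference_signature(b, a)
  expect_equal(d1$value, -d2$value)
  expect_identical(spec_unit(d1), "molar_ellipticity")
  # grid mismatch requires explicit resampling
  b2 <- spectrum_tbl(seq(220, 350, by = 0.5), 1:261, unit = "molar_extinction")
  expect_error(difference_signature(a, b2), "resample")
  # unit mismatch
  expect_error(difference_signature(a, spectrum_tbl(wl, 1:131,
                                                    unit = "absorbance")),
               "unit")
})

test_that("eps2fold recovers injected signatures from synthetic folded spectra", {
  tab <- default_nn_table()
  s <- "TGAGGGTGGGTAGGGTGGGTAA"
  tpl <- default_templates(noise_sd = 0)$parallel
  folded <- generate_folded_uv(s, tpl, tab, seed = 1)
  sig <- eps2fold(s, folded, tab)
  expect_equal(range(sig$wavelength), c(220, 310))
  expect_equal(sig$value, eval_template(tpl, sig$wavelength))
  # folded equal to the calculated unfolded spectrum gives a zero signature
  unf <- unfolded_spectrum(s, tab)
  expect_true(all(eps2fold(s, unf, tab)$value == 0))
  # absorbance input is auto-converted via its metadata
  abs_folded <- molar_to_absorbance(folded, l = 1, C = 4e-6)
  expect_equal(eps2fold(s, abs_folded, tab)$value, sig$value)
})

test_that("signature band structure matches the topology classes", {
  tab <- default_nn_table()
  s <- "TGAGGGTGGGTAGGGTGGGTAA"
  tpls <- default_templates(noise_sd = 0)
  sig_at <- function(sig, nm) sig$value[sig$wavelength == nm]
  for (cls in names(tpls)) {
    sig <- eps2fold(s, generate_folded_uv(s, tpls[[cls]], tab, 1), tab)
    expect_gt(sig_at(sig, 245), 0)
    expect_lt(sig_at(sig, 295), 0)
  }
  sig_par <- eps2fold(s, generate_folded_uv(s, tpls$parallel, tab, 1), tab)
  sig_anti <- eps2fold(s, generate_folded_uv(s, tpls$antiparallel, tab, 1), tab)
  expect_lt(sig_at(sig_par, 265), 0)
  # near zero at 265 for antiparallel, relative to its extrema
  expect_lt(abs(sig_at(sig_anti, 265)), 0.1 * max(abs(sig_anti$value)))
})

test_that("IDS equals the signature when the references agree, and a
           partially folded reference attenuates it linearly", {
  tab <- default_nn_table()
  s <- "GGGTTAGGGTTAGGGTTTGGG"
  tpl <- default_templates(noise_sd = 0)$antiparallel
  folded <- generate_folded_uv(s, tpl, tab, 1)
  unf <- unfolded_spectrum(s, tab)
  expect_equal(ids(folded, unf)$value, eps2fold(s, folded, tab)$value)
  # mixture reference: alpha folded + (1 - alpha) unfolded
  alpha <- 0.3
  mix <- spectrum_tbl(unf$wavelength,
                      alpha * folded$value + (1 - alpha) * unf$value,
                      unit = "molar_extinction")
  expect_equal(ids(folded, mix)$value,
               (1 - alpha) * ids(folded, unf)$value)
  zero <- spectrum_tbl(unf$wavelength, rep(0, nrow(unf)),
                       unit = "molar_extinction")
  expect_true(all(ids(zero, zero)$value == 0))
})

test_that("signatures are linear in the folded spectrum (conformer mixtures)", {
  tab <- default_nn_table()
  s <- "TTGGGTTAGGGTTAGGGTTAGGGA"
  tpls <- default_templates(noise_sd = 0)
  f1 <- generate_folded_uv(s, tpls$parallel, tab, 1)
  f2 <- generate_folded_uv(s, tpls$hybrid, tab, 1)
  w <- 0.25
  fm <- spectrum_tbl(f1$wavelength, w * f1$value + (1 - w) * f2$value,
                     unit = "molar_extinction")
  expect_equal(eps2fold(s, fm, tab)$value,
               w * eps2fold(s, f1, tab)$value +
                 (1 - w) * eps2fold(s, f2, tab)$value)
})

test_that("group summaries give pointwise mean and sample sd per label", {
  wl <- 240:242
  sps <- list(
    a1 = spectrum_tbl(wl, c(1, 1, 1)),
    a2 = spectrum_tbl(wl, c(-1, 1, 3)),
    b1 = spectrum_tbl(wl, c(2, 2, 2)),
    b2 = spectrum_tbl(wl, c(2, 2, 2))
  )
  gs <- group_summary(sps, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(gs$mean[gs$label == "A"], c(0, 1, 2))
  expect_equal(gs$sd[gs$label == "A"], c(sqrt(2), 0, sqrt(2)))
  expect_true(all(gs$sd[gs$label == "B"] == 0))

  # brute-force oracle on a 5-spectrum toy set
  set.seed(5)
  vals <- matrix(rnorm(5 * 3), 5, 3)
  sps5 <- lapply(1:5, function(i) spectrum_tbl(wl, vals[i, ]))
  names(sps5) <- paste0("s", 1:5)
  labs <- c(s1 = "x", s2 = "x", s3 = "x", s4 = "y", s5 = "y")
  gs5 <- group_summary(sps5, labs)
  for (lab in c("x", "y")) {
    rows <- which(labs == lab)
    for (j in seq_along(wl)) {
      got <- gs5[gs5$label == lab & gs5$wavelength == wl[j], ]
      expect_equal(got$mean, mean(vals[rows, j]))
      expect_equal(got$sd, stats::sd(vals[rows, j]))
    }
  }
})

test_that("singleton groups warn and report sd 0", {
  sps <- list(a = spectrum_tbl(240:241, c(1, 2)),
              b = spectrum_tbl(240:241, c(3, 4)),
              b2 = spectrum_tbl(240:241, c(5, 6)))
  expect_warning(gs <- group_summary(sps, c(a = "A", b = "B", b2 = "B")),
                 "singleton")
  expect_true(all(gs$sd[gs$label == "A"] == 0))
})

test_that("optional normalizations rescale as documented", {
  sp <- spectrum_tbl(220:222, c(-4, 2, 1))
  expect_equal(normalize_signature(sp, "minmax")$value, c(-1, 0.5, 0.25))
  expect_equal(stats::sd(normalize_signature(sp, "unit_variance")$value), 1)
})
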
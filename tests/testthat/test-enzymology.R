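test_that("activity normalisation pins controls to 100 and background to 0", {
  wells <- data.frame(
    dataset = "d1",
    cpm = c(5000, 5200, 150, 170, 2660, 4000),
    role = c("no_compound_control", "no_compound_control",
             "no_enzyme_background", "no_enzyme_background",
             "sample", "sample")
  )
  norm <- normalize_activity(wells)
  m_ctrl <- mean(c(5000, 5200))
  m_bg <- mean(c(150, 170))
  expect_equal(norm$percent_activity[1:2],
               100 * (c(5000, 5200) - m_bg) / (m_ctrl - m_bg))
  expect_equal(mean(norm$percent_activity[1:2]), 100)
  expect_equal(mean(norm$percent_activity[3:4]), 0)
  # a sample at the control mean is exactly 100%, at background exactly 0%,
  # halfway is 50%
  wells2 <- rbind(wells, data.frame(dataset = "d1",
                                    cpm = c(m_ctrl, m_bg, (m_ctrl + m_bg) / 2),
                                    role = "sample"))
  norm2 <- normalize_activity(wells2)
  expect_equal(norm2$percent_activity[7:9], c(100, 0, 50))
})

test_that("normalisation is invariant under joint affine rescaling of CPM", {
  wells <- data.frame(
    dataset = "d",
    cpm = c(4000, 100, 2050, 900),
    role = c("no_compound_control", "no_enzyme_background", "sample", "sample")
  )
  base <- normalize_activity(wells)$percent_activity
  wells$cpm <- 3.7 * wells$cpm + 250
  expect_equal(normalize_activity(wells)$percent_activity, base,
               tolerance = 1e-12)
  # degenerate window
  bad <- data.frame(dataset = "d", cpm = c(100, 200),
                    role = c("no_compound_control", "no_enzyme_background"))
  expect_error(normalize_activity(bad), "degenerate")
  expect_error(normalize_activity(data.frame(dataset = "d", cpm = 1,
                                             role = "sample")),
               "lacks")
})

test_that("CPM-to-product conversion is exact unit arithmetic", {
  expect_equal(cpm_to_product(0, 100, 10), 0)
  expect_equal(cpm_to_product(1000, 100, 10), 1000)  # 10 pmol in 10 uL = 1 uM
  expect_error(cpm_to_product(10, 0, 10), "positive")
  # inverse pair with the generator's conversion
  sc <- assay_scenario(noise_cv = 0, seed = 1)
  tc <- simulate_assay(sc, "timecourse")
  s <- tc[tc$role == "sample", ]
  bg <- mean(tc$cpm[tc$role == "no_enzyme_background"])
  product <- cpm_to_product(s$cpm - bg, sc$counts_per_pmol, sc$volume_ul)
  expect_equal(product, sc$kcat_true * sc$enzyme_nM * s$time,
               tolerance = 1e-9)
})

test_that("kcat fitting matches closed-form slopes and scaling laws", {
  # single endpoint, zero intercept: 120 nM in 1 h from 20 nM enzyme
  k <- fit_kcat(120, 1, enzyme_nM = 20)
  expect_equal(k$kcat, 6)
  expect_equal(fit_kcat(c(0, 0, 0), c(0.5, 1, 2), 20)$kcat, 0)
  # noiseless multi-point slope 480 nM/h
  tt <- seq(0.25, 2, by = 0.25)
  k24 <- fit_kcat(480 * tt, tt, enzyme_nM = 20)
  expect_equal(k24$kcat, 24, tolerance = 1e-9)
  # linearity: doubling product doubles kcat; doubling enzyme halves it
  expect_equal(fit_kcat(960 * tt, tt, 20)$kcat, 48, tolerance = 1e-9)
  expect_equal(fit_kcat(480 * tt, tt, 40)$kcat, 12, tolerance = 1e-9)
  # negative slope clips to zero with a flag
  kneg <- fit_kcat(c(100, 50, 10), c(0.5, 1, 1.5), 20)
  expect_equal(kneg$kcat, 0)
  expect_true(kneg$clipped)
})

test_that("fold change reproduces the published activation ratios", {
  mk <- function(kcat, sd = 1, substrate = "peptide", complex = "I363M") {
    fit_kcat(kcat * 20, 1, 20, substrate = substrate, complex_id = complex)
  }
  # vehicle-normalised activation of the mutant complex (peptide substrate)
  expect_equal(fold_change(mk(20), mk(9))$ratio, 20 / 9, tolerance = 1e-12)
  expect_equal(fold_change(mk(21), mk(9))$ratio, 21 / 9, tolerance = 1e-12)
  # identity and error propagation
  same <- mk(9)
  expect_equal(fold_change(same, same)$ratio, 1)
  expect_error(fold_change(mk(20, substrate = "nucleosome"), mk(9)),
               "mismatch")
  zero <- fit_kcat(0, 1, 20, substrate = "peptide", complex_id = "I363M")
  expect_error(fold_change(mk(20), zero), "positive")
})

test_that("4PL fit recovers a noiseless dose-response exactly", {
  conc <- c(0.03, 0.1, 0.3, 1, 3, 10, 30, 100)
  truth <- list(bottom = 100, top = 230, ec50 = 2.3, hill = 1)
  percent <- truth$bottom + (truth$top - truth$bottom) /
    (1 + (truth$ec50 / conc)^truth$hill)
  fit <- fit_dose_response(rep(conc, 3), rep(percent, 3))
  expect_equal(fit$ec50, 2.3, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$direction, "activation")
  # midpoint identity: the fitted curve at conc = EC50 is (top + bottom)/2
  mid <- fit$bottom + (fit$top - fit$bottom) / (1 + (fit$ec50 / fit$ec50))
  expect_equal(mid, (fit$top + fit$bottom) / 2)
  expect_error(fit_dose_response(c(1, 2, 3, 4), c(1, 2, 3, 4)), ">= 5")
})

test_that("4PL fit agrees with a coarse grid-search oracle on noisy data", {
  sc <- assay_scenario(noise_cv = 0.03, seed = 23)
  dr <- simulate_assay(sc, "dose_response")
  norm <- normalize_activity(dr)
  s <- norm[norm$role == "sample", ]
  fit <- fit_dose_response(s$compound_conc, s$percent_activity)

  # oracle: exhaustive search over (ec50, hill); bottom/top solved linearly
  conc <- s$compound_conc
  y <- s$percent_activity
  best <- list(rss = Inf)
  for (ec in exp(seq(log(0.2), log(30), length.out = 300))) {
    for (h in seq(0.5, 2, by = 0.05)) {
      w <- 1 / (1 + (ec / conc)^h)
      ls <- lm(y ~ w)
      rss <- sum(residuals(ls)^2)
      if (rss < best$rss) best <- list(rss = rss, ec50 = ec)
    }
  }
  expect_equal(fit$ec50, best$ec50, tolerance = 0.05)
})

test_that("quadratic bound fraction matches mass-action root finding", {
  quad <- bound_fraction(100, 40, 50)
  oracle <- uniroot(function(pl) (100 - pl) * (40 - pl) / pl - 50,
                    c(1e-9, 40 - 1e-9), tol = 1e-12)$root / 40
  expect_equal(quad, oracle, tolerance = 1e-9)
  # hyperbolic limit: negligible depletion at tracer = kd/100
  p <- c(25, 50, 100, 200, 400)
  fb <- bound_fraction(p, tracer = 1, kd = 100)
  expect_equal(fb, p / (p + 100), tolerance = 0.01)
  expect_equal(bound_fraction(100, 1e-6, 100), 0.5, tolerance = 1e-3)
})

test_that("FP fit recovers a noiseless quadratic-depletion titration", {
  sc <- assay_scenario(noise_cv = 0, kd_true = 156, seed = 2)
  fp <- simulate_assay(sc, "fp_titration")
  fit <- fit_fp_binding(fp$protein_conc, fp$fp, tracer_nM = 40)
  expect_equal(fit$kd, 156, tolerance = 1e-3)
  expect_equal(fit$fp_min, 60, tolerance = 1e-4)
  expect_equal(fit$fp_max, 240, tolerance = 1e-4)
  expect_false(fit$wide_interval)
  # fitted curve is non-decreasing in protein concentration
  pgrid <- seq(1, 2000, length.out = 200)
  curve <- fit$fp_min + (fit$fp_max - fit$fp_min) *
    bound_fraction(pgrid, 40, fit$kd)
  expect_true(all(diff(curve) >= 0))
  # noisy titrations that stop far from saturation carry a wide-interval
  # warning (a noiseless truncated titration is fit exactly by a shallow
  # curve, so the diagnostic needs realistic noise to engage)
  scn <- assay_scenario(noise_cv = 0.02, kd_true = 156, seed = 2)
  fpn <- simulate_assay(scn, "fp_titration")
  low <- fpn[fpn$protein_conc < 60, ]
  expect_warning(fit_fp_binding(low$protein_conc, low$fp, 40), "wide")
})

test_that("dose-response parameter recovery matches the replicate design", {
  # simulated triplicate 8-point datasets at 3% noise: the median fitted
  # EC50 tracks the truth and the spread is on the reported-uncertainty
  # scale (fewer datasets than a full calibration study, same conditions)
  fits <- vapply(1:60, function(i) {
    sc <- assay_scenario(noise_cv = 0.03, seed = 1000 + i)
    dr <- simulate_assay(sc, "dose_response")
    norm <- normalize_activity(dr)
    s <- norm[norm$role == "sample", ]
    fit_dose_response(s$compound_conc, s$percent_activity)$ec50
  }, numeric(1))
  expect_lt(abs(median(fits) - 2.3) / 2.3, 0.10)
  expect_lt(sd(fits), 0.4)
})
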
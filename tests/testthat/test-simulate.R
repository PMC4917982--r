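# presets with the soil and contact elements made electrically negligible,
# so the network collapses to the plant's single parallel RC
.bareSim <- function(...) {
  SimulationConfig(
    soilPresets = data.frame(soil = c("silt_loam", "loam", "sandy_loam"),
                             r_ohm = 1e-6, c_f = 1e-18),
    contactR = 1e-6, contactC = 1e-18, ...)
}

test_that("root dry mass sampling respects the truncated normal", {
  sim <- SimulationConfig()
  expect_identical(sampleRdm(sim, 0), numeric(0))
  set.seed(61); a <- sampleRdm(sim, 100)
  set.seed(61); b <- sampleRdm(sim, 100)
  expect_identical(a, b)
  set.seed(62)
  big <- sampleRdm(sim, 5000)
  expect_true(all(big >= 0.02 & big <= 0.72))
  # rejection-sampling oracle for the truncated mean
  set.seed(63)
  raw <- rnorm(2e5, 0.2, 0.19)
  oracle <- mean(raw[raw >= 0.02 & raw <= 0.72])
  expect_lt(abs(mean(big) - oracle), 0.02)
})

test_that("a bare plant is an ideal parallel RC with the configured line", {
  sim <- .bareSim()
  for (rdm in c(0.05, 0.3, 0.7)) {
    sp <- plantSoilSpectrum(rdm, "loam", "4T", "clamp", sim, noise = FALSE)
    cp <- computeVariable(sp$z_ohm, sp$theta_deg, sp$frequency_hz, "Cp")
    rp <- computeVariable(sp$z_ohm, sp$theta_deg, sp$frequency_hz, "Rp")
    cTrue <- (4.2 * rdm + 0.37) * 1e-9
    # constant across the whole spectrum, at the configured values
    expect_equal(cp, rep(cTrue, 26), tolerance = 1e-6)
    expect_equal(rp, rep(2e5 / (rdm + 0.05), 26), tolerance = 1e-6)
  }
  # the zero-root-mass limit leaves exactly the intercept capacitance
  sp0 <- plantSoilSpectrum(0, "loam", "4T", "clamp", sim, noise = FALSE)
  cp0 <- computeVariable(sp0$z_ohm, sp0$theta_deg, sp0$frequency_hz, "Cp")
  expect_equal(cp0[1], 0.37e-9, tolerance = 1e-6)
})

test_that("2T and 4T noiseless spectra differ by exactly two contacts", {
  sim <- SimulationConfig()
  z2 <- with(plantSoilSpectrum(0.3, "loam", "2T", "clamp", sim,
                               noise = FALSE),
             toComplex(z_ohm, theta_deg))
  z4 <- with(plantSoilSpectrum(0.3, "loam", "4T", "clamp", sim,
                               noise = FALSE),
             toComplex(z_ohm, theta_deg))
  f <- defaultGrid()
  contact <- 1000 / (1 + 1i * 2 * pi * f * 1000 * 1e-9)  # oracle element
  expect_lt(max(Mod(z2 - z4 - 2 * contact) / Mod(contact)), 1e-9)
  # 3T sits exactly one contact above 4T
  z3 <- with(plantSoilSpectrum(0.3, "loam", "3T", "clamp", sim,
                               noise = FALSE),
             toComplex(z_ohm, theta_deg))
  expect_lt(max(Mod(z3 - z4 - contact) / Mod(contact)), 1e-9)
})

test_that("simulateStudy produces the full design, reproducibly", {
  sim <- SimulationConfig(seed = 9)
  st <- simulateStudy(sim)
  expect_equal(ncol(st$spectra), 180L)  # 30 plants x 3 configs x 2 electrodes
  expect_equal(nrow(st$plants), 30L)
  expect_equal(unname(table(st$plants$soil)[c("silt_loam", "loam",
                                              "sandy_loam")]),
               c(14L, 8L, 8L), ignore_attr = TRUE)
  st2 <- simulateStudy(sim)
  expect_identical(SummarizedExperiment::assay(st$spectra, "Z"),
                   SummarizedExperiment::assay(st2$spectra, "Z"))
  st3 <- simulateStudy(SimulationConfig(seed = 10))
  expect_false(identical(SummarizedExperiment::assay(st$spectra, "Z"),
                         SummarizedExperiment::assay(st3$spectra, "Z")))
  expect_identical(st$plants$rdm_g == st3$plants$rdm_g,
                   rep(FALSE, 30))  # new noise, same structure
})

test_that("simulated files round-trip through the readers", {
  sim <- SimulationConfig(nPlants = 4, seed = 12)
  st <- simulateStudy(sim, configs = "3T", electrodes = "clamp")
  dir <- withr::local_tempdir()
  writeSimulation(st, dir)
  ie <- readSpectra(file.path(dir, "spectra.csv"))
  pl <- readPlants(file.path(dir, "plants.csv"))
  ie <- attachPlants(ie, pl)
  expect_equal(unname(SummarizedExperiment::assay(ie, "Z")),
               unname(SummarizedExperiment::assay(st$spectra, "Z")),
               tolerance = 1e-12)
  expect_equal(pl$rdm_g, st$plants$rdm_g, tolerance = 1e-12)
})

test_that("rising contact resistance degrades 2T screening, never 4T", {
  r2at <- function(contactR) {
    sim <- SimulationConfig(seed = 7, contactR = contactR)
    st <- simulateStudy(sim, electrodes = "clamp")
    ve <- electricalVariables(st$spectra, "Cp")
    c(r2_2T = r2Max(screenVariable(ve, "Cp", "2T")),
      z4 = sum(SummarizedExperiment::assay(
        st$spectra, "Z")[, SummarizedExperiment::colData(
          st$spectra)$config == "4T"]))
  }
  lv <- sapply(c(1e3, 5e4, 5e5), r2at)
  expect_true(all(diff(lv["r2_2T", ]) < 0))
  # 4T spectra are byte-identical: no contact element, same noise draws
  expect_equal(lv["z4", 1], lv["z4", 2], tolerance = 1e-12)
  expect_equal(lv["z4", 1], lv["z4", 3], tolerance = 1e-12)
})

test_that("needle distortion grows with frequency in the comparison", {
  st <- simulateStudy(SimulationConfig(seed = 42))
  ve <- electricalVariables(st$spectra, "Cp")
  cmp <- compareElectrodes(ve)
  # in 2T/3T the log-frequency distortion dominates the hookup floor
  for (cfg in c("2T", "3T")) {
    cc <- cmp[cmp$config == cfg, ]
    expect_gt(cor(cc$frequency_hz, cc$mean_delta, method = "spearman"),
              0.9)
  }
  # 4T sits on its stem-base position-noise floor, above the others
  expect_gt(min(cmp$mean_delta[cmp$config == "4T"]),
            max(cmp$mean_delta[cmp$config == "2T"]))
  expect_true(any(cmp$significant))  # the default distortion is detectable
})

test_that("4T screening is degraded relative to 2T and 3T", {
  st <- simulateStudy(SimulationConfig(seed = 42), electrodes = "clamp")
  ve <- electricalVariables(st$spectra, "Cp")
  r2 <- vapply(c("2T", "3T", "4T"), function(cfg)
    r2Max(screenVariable(ve, "Cp", cfg)), numeric(1))
  expect_lt(r2[["4T"]], r2[["2T"]])
  expect_lt(r2[["4T"]], r2[["3T"]])
})

test_that("without electrode distortion the comparison stays null", {
  st <- simulateStudy(SimulationConfig(seed = 1, electrodeDistortion = 0))
  cmp <- compareElectrodes(electricalVariables(st$spectra, "Cp"))
  expect_false(any(cmp$significant))
  # hookup/position noise floors only: ~8% in 2T/3T, ~25% in 4T
  expect_lt(max(cmp$mean_delta[cmp$config != "4T"]), 0.2)
  expect_lt(max(cmp$mean_delta), 0.4)
})

test_that("the optimum frequency is an interior, soil-robust grid point", {
  sim <- SimulationConfig()
  fopt <- optimumFrequency(sim)
  expect_true(fopt %in% defaultGrid())
  expect_gt(fopt, 10)
  expect_lt(fopt, 10000)
  # deterministic: no RNG involved
  expect_identical(fopt, optimumFrequency(sim))
})
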
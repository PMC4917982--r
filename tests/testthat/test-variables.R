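test_that("toComplex converts polar samples to cartesian impedance", {
  expect_equal(toComplex(100, 0), 100 + 0i)
  expect_equal(toComplex(100, -90), 0 - 100i)
  expect_equal(toComplex(141.42, -45), 100 - 100i, tolerance = 1e-4)
})

test_that("limiting cases: pure capacitor and pure resistor", {
  # pure capacitor at 1 kHz: Cp = 1/(w Z)
  expect_equal(computeVariable(1000, -90, 1000, "Cp"),
               1 / (2 * pi * 1000 * 1000), tolerance = 1e-12)
  expect_equal(computeVariable(1000, -90, 1000, "Cp"), 1.5915e-7,
               tolerance = 1e-4)
  # resistive limit
  expect_equal(computeVariable(1000, 0, 1000, "G"), 1e-3)
  expect_equal(computeVariable(1000, 0, 1000, "Rp"), 1000)
  expect_equal(computeVariable(1000, 0, 1000, "Rs"), 1000)
  expect_equal(computeVariable(1000, 0, 1000, "R"), 1000)
  expect_equal(computeVariable(1000, 0, 1000, "X"), 0)
  expect_equal(computeVariable(1000, 0, 1000, "Cp"), 0)
  expect_equal(computeVariable(1000, 0, 1000, "B"), 0)
})

test_that("an ideal parallel RC is inverted exactly", {
  R <- 1e4; C <- 1e-8; f <- 116.0933
  s <- asPolar(oracleParallelRC(R, C, f))
  expect_equal(computeVariable(s$z_ohm, s$theta_deg, f, "Cp"), C,
               tolerance = 1e-9)
  expect_equal(computeVariable(s$z_ohm, s$theta_deg, f, "Rp"), R,
               tolerance = 1e-9)
})

test_that("singular phases raise domain errors; inductive phases do not", {
  expect_error(computeVariable(100, 0, 100, "Cs"), "Cs.*theta = 0")
  expect_error(computeVariable(100, -90, 100, "Rp"), "Rp")
  # positive phase gives a negative capacitance, not an error
  expect_lt(computeVariable(100, 5, 100, "Cp"), 0)
})

test_that("every variable matches the complex-admittance oracle", {
  set.seed(21)
  n <- 500
  z <- exp(runif(n, 0, log(1e6)))
  th <- runif(n, -89.9, -0.1)
  f <- sample(defaultGrid(), n, replace = TRUE)
  ora <- oracleVariables(z, th, f)
  for (v in screeningVariables())
    expect_equal(computeVariable(z, th, f, v), ora[[v]], tolerance = 1e-9,
                 info = v)
})

test_that("redundant variables obey their algebraic identities", {
  set.seed(22)
  z <- exp(runif(50, 1, 10)); th <- runif(50, -89, -1)
  f <- sample(defaultGrid(), 50, replace = TRUE)
  # R equals Rs; B is proportional to Cp (B = -w Cp)
  expect_equal(computeVariable(z, th, f, "R"),
               computeVariable(z, th, f, "Rs"))
  expect_equal(computeVariable(z, th, f, "B"),
               -2 * pi * f * computeVariable(z, th, f, "Cp"),
               tolerance = 1e-12)
})

test_that("serial and parallel representations describe the same impedance", {
  set.seed(23)
  z <- exp(runif(200, 0, 12)); th <- runif(200, -89.9, -0.1)
  f <- sample(defaultGrid(), 200, replace = TRUE)
  w <- 2 * pi * f
  rs <- computeVariable(z, th, f, "Rs")
  cs <- computeVariable(z, th, f, "Cs")
  rp <- computeVariable(z, th, f, "Rp")
  cp <- computeVariable(z, th, f, "Cp")
  target <- toComplex(z, th)
  serial <- rs + 1 / (1i * w * cs)
  parallel <- 1 / (1 / rp + 1i * w * cp)
  expect_lt(max(Mod(serial - target) / Mod(target)), 1e-9)
  expect_lt(max(Mod(parallel - target) / Mod(target)), 1e-9)
})

test_that("ideal RC circuits give frequency-constant equivalent elements", {
  f <- defaultGrid()
  # parallel RC: Cp and Rp constant over the whole spectrum
  sp <- asPolar(oracleParallelRC(1e4, 1e-8, f))
  cp <- computeVariable(sp$z_ohm, sp$theta_deg, f, "Cp")
  rp <- computeVariable(sp$z_ohm, sp$theta_deg, f, "Rp")
  expect_equal(cp, rep(1e-8, 26), tolerance = 1e-9)
  expect_equal(rp, rep(1e4, 26), tolerance = 1e-9)
  # serial RC: Cs and Rs constant
  ss <- asPolar(oracleSerialRC(500, 1e-7, f))
  cs <- computeVariable(ss$z_ohm, ss$theta_deg, f, "Cs")
  rs <- computeVariable(ss$z_ohm, ss$theta_deg, f, "Rs")
  expect_equal(cs, rep(1e-7, 26), tolerance = 1e-9)
  expect_equal(rs, rep(500, 26), tolerance = 1e-9)
})

test_that("electricalVariables preserves structure and counts", {
  set.seed(24)
  f <- defaultGrid()
  n <- 30
  zstar <- sapply(seq_len(n), function(i)
    oracleParallelRC(1e4 + 100 * i, 1e-9 * i, f))
  ie <- makeExperiment(zstar, f, plant_id = sprintf("p%02d", 1:n))
  ve <- electricalVariables(ie)
  expect_equal(SummarizedExperiment::assayNames(ve), screeningVariables())
  expect_equal(dim(ve), c(26L, 30L))
  tab <- variablesTable(ve)
  expect_equal(nrow(tab), 26L * 30L * 8L)
  expect_setequal(unique(tab$unit[tab$variable == "Cp"]), "F")
  tabNf <- variablesTable(ve, capacitanceUnit = "nF")
  expect_equal(tabNf$value[tabNf$variable == "Cp"],
               1e9 * tab$value[tab$variable == "Cp"])
  expect_setequal(unique(tabNf$unit[tabNf$variable == "Cs"]), "nF")
})
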
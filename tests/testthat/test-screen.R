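test_that("fitLinear reproduces exact lines and the closed-form oracle", {
  exact <- fitLinear(c(1, 2, 3), c(2, 4, 6))
  expect_equal(exact$slope_a, 2)
  expect_equal(exact$intercept_b, 0)
  expect_equal(exact$r2, 1)

  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  y <- c(1, 2, 1, 2, 1.5)
  got <- fitLinear(x, y)
  ora <- oracleOls(x, y)
  expect_equal(got$slope_a, ora$a, tolerance = 1e-9)
  expect_equal(got$intercept_b, ora$b, tolerance = 1e-9)
  expect_equal(got$r2, ora$r2, tolerance = 1e-9)
  expect_equal(got$p_value, ora$p, tolerance = 1e-9)
})

test_that("r2 equals the squared Pearson correlation", {
  set.seed(31)
  for (i in 1:20) {
    x <- runif(15, 0.02, 0.72)
    y <- 4 * x + rnorm(15)
    expect_equal(fitLinear(x, y)$r2, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("degenerate designs are rejected or flattened", {
  expect_error(fitLinear(c(1, 2), c(1, 2)), "insufficient")
  expect_error(fitLinear(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  flat <- fitLinear(c(1, 2, 3), c(5, 5, 5))
  expect_equal(flat$r2, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$slope_a, 0)
})

test_that("significance stars follow the 0.01/0.05 levels", {
  expect_equal(significanceStars(c(0.004, 0.01, 0.049, 0.05, 0.5)),
               c("***", "**", "**", "", ""))
})

.lineExperiment <- function(signalRow, a = 4.2e-9, b = 0.37e-9) {
  # 30 plants, 3 soils; the Cp-RDM line lives at exactly one grid
  # frequency, all other frequencies carry a pure per-soil constant
  f <- defaultGrid()
  soils <- rep(c("silt_loam", "loam", "sandy_loam"), times = c(14, 8, 8))
  rdm <- seq(0.02, 0.72, length.out = 30)
  soilLevel <- c(silt_loam = 1e-9, loam = 2e-9, sandy_loam = 3e-9)
  vals <- matrix(rep(soilLevel[soils], each = 26), 26, 30)
  vals[signalRow, ] <- a * rdm + b
  cd <- S4Vectors::DataFrame(plant_id = sprintf("p%02d", 1:30),
                             config = "3T", electrode = "clamp",
                             soil = soils, rdm_g = rdm)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(Cp = vals),
    rowData = S4Vectors::DataFrame(frequency_hz = f), colData = cd)
  se
}

test_that("screen finds the single signal-bearing frequency exactly", {
  ve <- .lineExperiment(signalRow = 14)
  for (mode in c("pooled", "soil_averaged")) {
    sc <- screenVariable(ve, "Cp", "3T", mode = mode)
    expect_equal(fMax(sc), defaultGrid()[14])
    expect_equal(r2Max(sc), 1, tolerance = 1e-12)
    i <- which(screenTable(sc)$frequency_hz == fMax(sc))
    expect_equal(screenTable(sc)$slope_a[i], 4.2e-9, tolerance = 1e-9)
    expect_equal(screenTable(sc)$intercept_b[i], 0.37e-9,
                 tolerance = 1e-9)
  }
})

test_that("a response independent of RDM ties at r2 = 0, broken low", {
  ve <- .lineExperiment(signalRow = 14)
  # overwrite the signal row too: no frequency carries information
  SummarizedExperiment::assays(ve)$Cp[14, ] <-
    SummarizedExperiment::assays(ve)$Cp[13, ]
  sc <- screenVariable(ve, "Cp", "3T", mode = "pooled")
  expect_true(all(screenTable(sc)$r2 < 0.999))
  expect_equal(max(screenTable(sc)$r2), r2Max(sc))
  flat <- .lineExperiment(signalRow = 14)
  SummarizedExperiment::assays(flat)$Cp[] <- 1e-9  # same value everywhere
  sc0 <- screenVariable(flat, "Cp", "3T", mode = "pooled")
  expect_true(all(screenTable(sc0)$r2 == 0))
  expect_equal(fMax(sc0), 0.5)  # tie-break toward the lowest frequency
})

test_that("soil-averaged curve is the arithmetic mean of per-soil r2", {
  set.seed(32)
  ve <- .lineExperiment(signalRow = 14)
  noisy <- SummarizedExperiment::assays(ve)$Cp
  noisy <- noisy * exp(matrix(rnorm(length(noisy), sd = 0.2), nrow(noisy)))
  SummarizedExperiment::assays(ve)$Cp <- noisy
  sc <- screenVariable(ve, "Cp", "3T", mode = "soil_averaged")
  cd <- SummarizedExperiment::colData(ve)
  i <- 14
  perSoil <- vapply(unique(cd$soil), function(s) {
    j <- cd$soil == s
    fitLinear(cd$rdm_g[j], noisy[i, j])$r2
  }, numeric(1))
  expect_equal(screenTable(sc)$r2[i], mean(perSoil), tolerance = 1e-12)
  # pooled slope/intercept are reported alongside the averaged curve
  pooled <- fitLinear(cd$rdm_g, noisy[i, ])
  expect_equal(screenTable(sc)$slope_a[i], pooled$slope_a)
  expect_equal(screenTable(sc)$r2_pooled[i], pooled$r2)
})

test_that("screening is invariant under plant order permutation", {
  set.seed(33)
  ve <- .lineExperiment(signalRow = 10)
  perm <- sample(30)
  sc1 <- screenVariable(ve, "Cp", "3T")
  sc2 <- screenVariable(ve[, perm], "Cp", "3T")
  expect_equal(screenTable(sc1), screenTable(sc2), tolerance = 1e-12)
})

test_that("fitted coefficients converge to truth as noise shrinks", {
  set.seed(34)
  rdm <- seq(0.02, 0.72, length.out = 30)
  eps <- rnorm(30)  # one noise shape, scaled down
  bias <- vapply(c(0.3, 0.1, 0.01), function(sd) {
    fit <- fitLinear(rdm, 4.2 * rdm + 0.37 + sd * eps)
    abs(fit$slope_a - 4.2) + abs(fit$intercept_b - 0.37)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("a spectrum without a plant record fails with its id", {
  ve <- .lineExperiment(signalRow = 14)
  cd <- SummarizedExperiment::colData(ve)
  cd$rdm_g[3] <- NA
  SummarizedExperiment::colData(ve) <- cd
  expect_error(screenVariable(ve, "Cp", "3T"), "p03")
})
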
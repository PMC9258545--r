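test_that("the colonisation model carries the published parameterisation", {
  m <- colonizationModel()
  ep <- epochs(m)
  expect_true(any(ep$years_ago == 50000 & ep$ne == 2000))
  expect_true(any(ep$years_ago == 5000 & ep$ne == 10000))
  expect_true(any(ep$years_ago == 500 & ep$ne == 100))
  expect_true(any(ep$years_ago == 90 & ep$ne == 10000))
  expect_equal(m@admixture$fraction, 0.70)
  expect_equal(m@inbreeding$prob, 0.70)
  expect_equal(m@inbreeding$window, c(500, 90))
  expect_equal(m@mu, 1.5e-8)
  expect_equal(m@rec, 1e-8)
  expect_equal(m@chromLenBp, 1e7)
  expect_equal(m@genYears, 30)
})

test_that("rescaling preserves theta and rho and event probabilities", {
  m <- colonizationModel()
  expect_equal(rescaleModel(m, 1)@epochs, m@epochs)
  r <- rescaleModel(m, 10)
  expect_equal(epochs(r)$ne[1], 1000)
  expect_equal(r@mu, 1.5e-7)
  expect_equal(4 * epochs(r)$ne * r@mu, 4 * epochs(m)$ne * m@mu)
  expect_equal(4 * epochs(r)$ne * r@rec, 4 * epochs(m)$ne * m@rec)
  expect_equal(r@admixture$fraction, 0.70)
  expect_equal(r@inbreeding$prob, 0.70)
  expect_error(rescaleModel(m, 0.5), ">= 1")
})

test_that("the generation plan keeps every epoch alive for >= 1 generation", {
  r <- rescaleModel(colonizationModel(), 20)
  gp <- hapscan:::generationPlan(r)
  # bottleneck epoch squeezed to one scaled generation, not zero
  expect_true(any(gp$plan$neB == 5))
  expect_true(any(gp$plan$selfing == 0.7))
  expect_equal(sum(gp$plan$admix > 0), 1L)
  # pulse parents come from the source deme at its pre-pulse size
  pulse <- which(gp$plan$admix > 0)
  expect_equal(gp$plan$neA[pulse], 500L)
  expect_equal(gp$burnGens, 10L * gp$burnNe)
})

test_that("no mutation means no markers", {
  m <- tinyModel(ne = 10, mu = 0)
  s <- simulatePanel(m, 5, seed = 1)
  expect_equal(nMarkers(samplePanel(s)), 0L)
})

test_that("simulation is deterministic given (model, n, seed)", {
  m <- tinyModel(ne = 15)
  s1 <- simulatePanel(m, 8, seed = 42)
  s2 <- simulatePanel(m, 8, seed = 42)
  expect_identical(alleles(samplePanel(s1)), alleles(samplePanel(s2)))
  expect_identical(positions(samplePanel(s1)), positions(samplePanel(s2)))
  s3 <- simulatePanel(m, 8, seed = 43)
  expect_false(identical(alleles(samplePanel(s1)),
                         alleles(samplePanel(s3))))
})

test_that("sampling more individuals than the population errors", {
  m <- tinyModel(ne = 10)
  expect_error(simulatePanel(m, 11, seed = 1), "sample larger")
})

test_that("simulated panels respect the frequency retention rule", {
  m <- tinyModel(ne = 25)
  p <- samplePanel(simulatePanel(m, 12, seed = 5))
  f <- derivedFreq(p)
  expect_true(all(f > 0.05 & f < 1))
  expect_true(all(diff(positions(p)) > 0))
  p0 <- samplePanel(simulatePanel(m, 12, seed = 5, minFreq = 0))
  expect_gte(nMarkers(p0), nMarkers(p))
})

test_that("group partitioning is disjoint, seeded, and MAF-refiltered", {
  m <- tinyModel(ne = 40)
  s <- simulatePanel(m, 40, seed = 9)
  g1 <- partitionGroups(s, groupSize = 10, nGroups = 3, seed = 1)
  g2 <- partitionGroups(s, groupSize = 10, nGroups = 3, seed = 1)
  expect_length(g1, 3L)
  expect_true(all(vapply(g1, nIndividuals, integer(1)) == 10L))
  ids <- unlist(lapply(g1, individualIds))
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(lapply(g1, individualIds), lapply(g2, individualIds))
  for (g in g1) {
    f <- derivedFreq(g)
    expect_true(all(f >= 0.05 & f <= 0.95))
  }
  expect_error(partitionGroups(s, groupSize = 35, nGroups = 2, seed = 1),
               "insufficient individuals")
})

test_that("a shared burn-in forks into distinct but exchangeable runs", {
  m <- tinyModel(ne = 20)
  b <- burninPopulation(m, seed = 3)
  runs <- simulateRuns(m, nRuns = 2, nSample = 10, seed = 3, burnState = b)
  expect_length(runs, 2L)
  expect_false(identical(positions(samplePanel(runs[[1]])),
                         positions(samplePanel(runs[[2]]))))
})

test_that("the admixture pulse pulls the target towards the source lineage", {
  # matched bottleneck runs from one burn-in, with and without the pulse;
  # frequency divergence to the source must shrink when the pulse is on
  mOn <- tinyModel(ne = 40, bottleneck = TRUE)
  mOff <- mOn
  mOff@admixture$fraction <- 0
  b <- burninPopulation(mOn, seed = 21)
  divergence <- function(model) {
    ts <- simulateWithSource(model, 20, 20, seed = 22, burnState = b,
                             minFreq = 0)
    mean(abs(derivedFreq(ts$target) - derivedFreq(ts$source)))
  }
  dOn <- divergence(mOn)
  dOff <- divergence(mOff)
  expect_lt(dOn, dOff)
  expect_gt(dOn, 0)  # admixed, not replaced: still diverged from the source
})
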
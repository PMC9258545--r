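# Shared simulation fixtures for the calibration suites. The q = 20 desk
# preset of the published demography is expensive to burn in, so one
# equilibrium population is computed lazily and reused; replicate runs are
# forked from it with their own seeds (the batch design the demography is
# meant to be run with). Everything is deterministic under the fixed seeds.
simCache <- local({
  env <- new.env(parent = emptyenv())
  function(name, fn) {
    if (!exists(name, envir = env)) assign(name, fn(), envir = env)
    get(name, envir = env)
  }
})

deskModels <- function() list(
  bneck = rescaleModel(colonizationModel(), 20),
  ctrl = rescaleModel(constantModel(), 20))

deskBurnin <- function() simCache("burn", function() {
  burninPopulation(deskModels()$bneck, seed = 1)
})

# ten seeded replicate pairs (constant-Ne control vs colonisation model),
# 50 diploids each, forked from the shared equilibrium state
calibrationPairs <- function() simCache("pairs", function() {
  md <- deskModels()
  b <- deskBurnin()
  lapply(1:10, function(k) list(
    ctrl = samplePanel(simulatePanel(md$ctrl, 50, seed = 100 + k,
                                     burnState = b)),
    bneck = samplePanel(simulatePanel(md$bneck, 50, seed = 200 + k,
                                      burnState = b))))
})

# standardised iHS per 80-individual group: 5 pooled groups from one run,
# one test group from an independent run
nullScanData <- function() simCache("nullscan", function() {
  md <- deskModels()
  b <- deskBurnin()
  gm <- uniformMap(1e7, 1)
  run1 <- simulatePanel(md$bneck, 400, seed = 301, burnState = b)
  run2 <- simulatePanel(md$bneck, 400, seed = 302, burnState = b)
  poolGroups <- partitionGroups(run1, 80, 5, seed = 303)
  testGroup <- partitionGroups(run2, 80, 1, seed = 304)[[1]]
  scan <- function(p) suppressWarnings(
    standardizeIHS(ihsScan(p, gm)))
  list(pool = lapply(poolGroups, scan), test = scan(testGroup))
})
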
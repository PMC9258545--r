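test_that("EHH is 1 at the core and matches direct enumeration outward", {
  # 4 derived carriers split into two classes of 2 at the next marker
  a <- rbind(
    c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L),
    c(0L, 0L), c(0L, 0L))
  p <- HaplotypePanel(a, positions = c(100, 200),
                      individualIds = sprintf("i%d", 1:3))
  gm <- uniformMap(1000, 1)
  e <- computeEHH(p, gm, 1, "derived")
  expect_equal(e$right$ehh[1], 1)             # the core itself
  expect_equal(e$right$ehh[2], 1 / 3)         # (1 + 1) / C(4,2)
  expect_equal(oracleEHH(a, 1, 1L, 2), 1 / 3)

  # identical carriers: EHH stays 1 across the window
  a2 <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L))
  p2 <- HaplotypePanel(a2, positions = c(10, 20, 30))
  e2 <- computeEHH(p2, uniformMap(100, 1), 1, "derived")
  expect_equal(e2$right$ehh, c(1, 1, 1))
})

test_that("EHH agrees with the enumeration oracle on random panels", {
  for (seed in 1:5) {
    p <- randomPanel(12, 30, seed = seed)
    gm <- uniformMap(40000, 1)
    core <- 15L
    for (al in c("derived", "ancestral")) {
      e <- computeEHH(p, gm, core, al)
      if (e$skipped) next
      alNum <- if (al == "derived") 1L else 0L
      for (k in seq_len(nrow(e$right))[-1]) {
        expect_equal(e$right$ehh[k],
                     oracleEHH(alleles(p), core, alNum, e$right$idx[k]))
      }
      for (k in seq_len(nrow(e$left))[-1]) {
        expect_equal(e$left$ehh[k],
                     oracleEHH(alleles(p), core, alNum, e$left$idx[k]))
      }
    }
  }
})

test_that("EHH curves are non-increasing outward", {
  for (seed in 6:9) {
    p <- randomPanel(16, 40, seed = seed)
    gm <- uniformMap(50000, 1)
    e <- computeEHH(p, gm, 20, "derived")
    if (e$skipped) next
    expect_true(all(diff(e$right$ehh) <= 1e-12))
    expect_true(all(diff(e$left$ehh) <= 1e-12))
  }
})

test_that("the one-sided EHH integral matches the hand trapezoid", {
  # worked example: points (0, 1.0), (0.02, 0.5), (0.04, 0.05) at cutoff
  # 0.05 integrate to 0.02*(1+0.5)/2 + 0.02*(0.5+0.05)/2 = 0.0205 cM
  expect_equal(oracleTrapezoid(c(0, 0.02, 0.04), c(1, 0.5, 0.05), 0.05),
               0.0205)
})

test_that("iHS integrals match an independent EHH + trapezoid oracle", {
  set.seed(101)
  for (seed in 11:14) {
    p <- randomPanel(20, 60, seed = seed)
    gm <- uniformMap(80000, 2)
    cm <- interpolateCM(gm, positions(p))
    res <- ihsScan(p, gm)
    ok <- which(!res$skipped)
    for (core in head(ok, 3)) {
      sideInt <- function(allele, dir) {
        idx <- if (dir > 0) core:nMarkers(p) else core:1
        e <- vapply(idx, function(j)
          if (j == core) 1 else oracleEHH(alleles(p), core, allele, j),
          numeric(1))
        oracleTrapezoid(cm[idx], e, 0.05)
      }
      ihhA <- sideInt(0L, -1) + sideInt(0L, +1)
      ihhD <- sideInt(1L, -1) + sideInt(1L, +1)
      expect_equal(res$ihh_a[core], ihhA, tolerance = 1e-10)
      expect_equal(res$ihh_d[core], ihhD, tolerance = 1e-10)
      expect_equal(res$uihs[core], log(ihhD / ihhA), tolerance = 1e-10)
    }
  }
})

test_that("swapping ancestral/derived labels negates uihs exactly", {
  p <- randomPanel(20, 60, seed = 31)
  gm <- uniformMap(80000, 2)
  res <- ihsScan(p, gm)
  flipped <- HaplotypePanel(1L - alleles(p), positions = positions(p))
  resF <- ihsScan(flipped, gm)
  ok <- !res$skipped & !resF$skipped
  expect_true(any(ok))
  expect_equal(res$uihs[ok], -resF$uihs[ok], tolerance = 1e-12)
})

test_that("cores are skipped for MAF and for curves that never reach the cutoff", {
  # rare derived allele -> maf skip
  a <- matrix(0L, 40, 3)
  a[1, 2] <- 1L
  a[, 1] <- rep(c(0L, 1L), 20)
  a[, 3] <- rep(c(1L, 0L), 20)
  p <- HaplotypePanel(a, positions = c(10, 20, 30))
  r <- computeIHS(p, uniformMap(100, 1), 2)
  expect_true(r$skipped)
  expect_equal(r$reason, "maf")

  # carriers identical to the chromosome end -> EHH stuck at 1
  a2 <- cbind(rep(c(0L, 1L), 10), rep(c(0L, 1L), 10), rep(c(0L, 1L), 10))
  p2 <- HaplotypePanel(a2, positions = c(10, 20, 30))
  r2 <- computeIHS(p2, uniformMap(100, 1), 2)
  expect_true(r2$skipped)
  expect_equal(r2$reason, "no_cutoff_crossing")
})

test_that("standardisation centres and scales every DAF bin", {
  mk <- function(daf, uihs) data.frame(
    marker_id = sprintf("m%d", seq_along(daf)), core = seq_along(daf),
    daf = daf, ihh_a = 1, ihh_d = exp(uihs), uihs = uihs,
    skipped = FALSE, reason = "", stringsAsFactors = FALSE)

  r1 <- standardizeIHS(mk(c(0.3, 0.3), c(-1, 1)))
  expect_equal(r1$sihs, c(-1, 1))

  r2 <- standardizeIHS(mk(c(0.5, 0.5, 0.5), c(0, 1, 2)))
  expect_equal(r2$sihs, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r2$sihs[1], -1.2247, tolerance = 1e-4)

  set.seed(99)
  big <- mk(runif(600, 0.05, 0.95), rnorm(600))
  rb <- standardizeIHS(big)
  for (b in unique(floor(rb$daf / 0.02))) {
    s <- rb$sihs[floor(rb$daf / 0.02) == b]
    s <- s[!is.na(s)]
    if (length(s) < 2) next
    expect_lt(abs(mean(s)), 1e-9)
    expect_lt(abs(mean((s - mean(s))^2) - 1), 1e-9)
  }

  expect_warning(standardizeIHS(mk(c(0.1, 0.5, 0.5), c(1, 0, 1))),
                 "< 2 records")
  expect_error(standardizeIHS(mk(c(0.5, 0.5), c(0, 1))[0, ]),
               "no iHS records")
})

test_that("r-squared matches direct Pearson computation", {
  g <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 2))
  ld <- ldDecay(g, pos = c(100, 600), windowKb = 100)
  expect_equal(sum(ld$n_pairs), 1L)
  expect_equal(ld$mean_r2[1], cor(g[, 1], g[, 2])^2)
  expect_equal(ld$mean_r2[1], 0.2066, tolerance = 1e-4)

  # duplicated marker: r2 = 1
  g2 <- cbind(c(0, 1, 2, 1), c(0, 1, 2, 1))
  ld2 <- ldDecay(g2, pos = c(100, 1600))
  expect_equal(ld2$mean_r2[ld2$n_pairs > 0], 1)

  # zero-variance markers are excluded, not scored 0
  g3 <- cbind(c(1, 1, 1, 1), c(0, 1, 2, 1))
  ld3 <- ldDecay(g3, pos = c(100, 600))
  expect_equal(sum(ld3$n_pairs), 0L)
})

test_that("bins, windows and pair counts follow the 100 kb / 1 kb layout", {
  p <- randomPanel(10, 50, seed = 55, spanBp = 150000)
  ld <- ldDecay(p)
  expect_equal(nrow(ld), 100L)
  expect_equal(ld$lo_kb, 0:99)
  expect_equal(ld$hi_kb, 1:100)
  pos <- positions(p)
  ok <- apply(genotypeMatrix(p), 2, sd) > 0
  d <- outer(pos, pos, "-")
  use <- upper.tri(d) & abs(d) <= 1e5 & outer(ok, ok, "&")
  expect_equal(sum(ld$n_pairs), sum(use))
  expect_true(all(ld$mean_r2 >= 0 & ld$mean_r2 <= 1, na.rm = TRUE))
})

test_that("mean r2 between independent markers is near its null expectation", {
  # free recombination: E[r2] ~ 1/(n-1) for n diploid dosage vectors
  set.seed(77)
  n <- 60
  m <- 160
  g <- sapply(runif(m, 0.2, 0.8), function(p)
    rbinom(n, 1, p) + rbinom(n, 1, p))
  pos <- seq(10000, by = 10000, length.out = m)
  ld <- ldDecay(g, pos = pos, windowKb = 100)
  r2s <- ld$mean_r2[ld$n_pairs > 0]
  w <- ld$n_pairs[ld$n_pairs > 0]
  mu <- sum(r2s * w) / sum(w)
  se <- sqrt(2) / (n - 1) / sqrt(sum(w))   # var(r2) ~ 2/(n-1)^2 under null
  expect_lt(abs(mu - 1 / (n - 1)), 3 * se + 0.002)
})

test_that("Nei haplotype diversity follows the closed form", {
  # all identical -> 0
  a <- matrix(1L, 4, 10)
  p <- HaplotypePanel(a, positions = 1:10 * 10)
  expect_equal(haplotypeDiversity(p)$mean_hap_div, 0)

  # 4 all-distinct haplotypes -> (4/3) * (1 - 4/16) = 1
  a2 <- rbind(rep(0L, 10), rep(1L, 10),
              rep(c(0L, 1L), 5), rep(c(1L, 0L), 5))
  p2 <- HaplotypePanel(a2, positions = 1:10 * 10)
  expect_equal(haplotypeDiversity(p2)$mean_hap_div, 1)

  # n = 2 distinct -> 2 * (1 - 1/2) = 1
  a3 <- rbind(rep(0L, 10), rep(1L, 10))
  p3 <- HaplotypePanel(a3, positions = 1:10 * 10, individualIds = "x")
  expect_equal(haplotypeDiversity(p3)$mean_hap_div, 1)

  # windows are non-overlapping 10-marker blocks; remainder dropped
  p4 <- randomPanel(8, 25, seed = 3)
  hd <- haplotypeDiversity(p4)
  expect_equal(nrow(hd$windows), 2L)
  expect_error(haplotypeDiversity(randomPanel(8, 5, seed = 1)),
               "fewer markers")
})

test_that("expected heterozygosity is 2p(1-p) averaged over sites", {
  a <- cbind(rep(c(0L, 1L), 5), c(1L, rep(0L, 9)))
  p <- HaplotypePanel(a, positions = c(10, 20))
  eh <- expectedHeterozygosity(p)
  expect_equal(eh$per_site, c(0.5, 2 * 0.1 * 0.9))
  expect_equal(eh$mean_exp_het, mean(c(0.5, 0.18)))

  a2 <- matrix(0L, 4, 1)
  expect_equal(expectedHeterozygosity(
    HaplotypePanel(a2, positions = 1))$mean_exp_het, 0)
})
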
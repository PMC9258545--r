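# panels here use a uniform 1 cM / 100 kb map scale unless stated, so
# genetic lengths are easy to plant by position
test_that("two identical haplotypes yield one segment spanning the panel", {
  set.seed(1)
  m <- 200
  a <- matrix(rbinom(6 * m, 1, 0.5), nrow = 6)
  a[2, ] <- a[1, ]                      # haplotypes 1 and 2 identical
  pos <- sort(sample.int(3e6, m))
  p <- HaplotypePanel(a, positions = pos)
  gm <- uniformMap(3e6, 10)             # 10 cM/Mb: panel spans ~30 cM
  segs <- detectIBD(p, gm, minCm = 2)
  s12 <- segs[segs$hap_i == 1 & segs$hap_j == 2, ]
  expect_equal(nrow(s12), 1L)
  expect_equal(s12$start_bp, pos[1])
  expect_equal(s12$end_bp, pos[m])
  expect_equal(s12$n_markers, m)
})

test_that("mutually random haplotypes produce no long segments", {
  set.seed(2)
  m <- 800
  a <- matrix(rbinom(10 * m, 1, 0.5), nrow = 10)
  p <- HaplotypePanel(a, positions = sort(sample.int(8e6, m)))
  segs <- detectIBD(p, uniformMap(8e6, 1), minCm = 2)
  expect_equal(nrow(segs), 0L)
})

test_that("a planted tract is recovered with slice-level endpoint accuracy", {
  set.seed(3)
  m <- 1000
  nHap <- 12
  a <- matrix(rbinom(nHap * m, 1, 0.5), nrow = nHap)
  pos <- sort(sample.int(1e7, m))
  gm <- uniformMap(1e7, 1)
  cm <- interpolateCM(gm, pos)
  # plant a 5 cM identical tract between haplotypes 3 and 7
  inTract <- which(cm >= 3 & cm <= 8)
  a[7, inTract] <- a[3, inTract]
  p <- HaplotypePanel(a, positions = pos)
  segs <- detectIBD(p, gm, minCm = 2)
  hit <- segs[segs$hap_i == 3 & segs$hap_j == 7, ]
  expect_equal(nrow(hit), 1L)
  # endpoints within one 64-marker slice of the planted boundaries
  sliceCm <- 64 * mean(diff(cm))
  expect_lt(abs(hit$start_bp - pos[min(inTract)]), 1e7)
  expect_lt(abs(cm[match(hit$start_bp, pos)] - 3), sliceCm + 0.5)
  expect_lt(abs(cm[match(hit$end_bp, pos)] - 8), sliceCm + 0.5)
  # and the exhaustive all-pairs oracle agrees it is the only pair
  orc <- oracleIBDExact(p, gm, minCm = 2)
  expect_equal(nrow(orc), 1L)
  expect_equal(c(orc$hap_i, orc$hap_j), c(3L, 7L))
})

test_that("with no mismatch allowance the detector matches the exhaustive scan", {
  for (seed in 1:20) {
    set.seed(seed)
    nHap <- sample(c(6, 8, 10, 12, 14), 1)
    m <- sample(300:900, 1)
    a <- matrix(rbinom(nHap * m, 1, 0.5), nrow = nHap)
    # plant 0-2 long shared tracts
    for (k in seq_len(sample(0:2, 1))) {
      ij <- sample(nHap, 2)
      lo <- sample(m - 200, 1)
      a[ij[2], lo:(lo + 199)] <- a[ij[1], lo:(lo + 199)]
    }
    pos <- sort(sample.int(m * 1000L, m))
    p <- HaplotypePanel(a, positions = pos)
    gm <- uniformMap(m * 1000L, 10)
    cm <- interpolateCM(gm, pos)
    sliceCm <- 64 * max(diff(cm))
    det <- detectIBD(p, gm, maxHomMismatch = 0, maxHetMismatch = 0,
                     minCm = 2)
    orc <- oracleIBDExact(p, gm, minCm = 2)
    # every oracle segment comfortably above one slice length is detected
    long <- orc[orc$length_cM >= 2 + 2 * sliceCm, , drop = FALSE]
    if (nrow(long)) {
      for (r in seq_len(nrow(long))) {
        expect_true(any(det$hap_i == long$hap_i[r] &
                        det$hap_j == long$hap_j[r]))
      }
    }
    # every detected segment corresponds to an oracle segment within one
    # slice of tolerance (no spurious detections)
    if (nrow(det)) {
      for (r in seq_len(nrow(det))) {
        cand <- orc[orc$hap_i == det$hap_i[r] & orc$hap_j == det$hap_j[r], ,
                    drop = FALSE]
        expect_true(nrow(cand) > 0)
        best <- cand[which.max(cand$length_cM), ]
        expect_lt(abs(det$length_cM[r] - best$length_cM),
                  2 * sliceCm + 1e-9)
      }
    }
  }
})

test_that("mismatch allowances are consumed by genotype context when merging", {
  # haplotypes 1 (ind 1) and 3 (ind 2) identical except isolated mismatches
  m <- 64 * 5
  a <- matrix(0L, 4, m)
  base <- rep(c(0L, 1L), length.out = m)
  a[1, ] <- base
  a[3, ] <- base
  a[2, ] <- base                    # ind 1 homozygous everywhere
  a[4, ] <- base                    # ind 2 homozygous everywhere
  # one hom-context mismatch inside slice 2, one inside slice 4
  a[3, 100] <- 1L - a[3, 100]; a[4, 100] <- a[3, 100]
  a[3, 230] <- 1L - a[3, 230]; a[4, 230] <- a[3, 230]
  pos <- seq(1000, by = 3000, length.out = m)
  p <- HaplotypePanel(a, positions = pos)
  gm <- uniformMap(1e6, 10)
  # one hom mismatch allowed: the two clean outer regions cannot bridge
  # both mismatches, so the best segment absorbs exactly one of them
  segs <- detectIBD(p, gm, maxHomMismatch = 1, maxHetMismatch = 0,
                    minCm = 0.5)
  s13 <- segs[segs$hap_i == 1 & segs$hap_j == 3, ]
  expect_gte(nrow(s13), 2L)
  # with two hom mismatches allowed the pair merges into one segment
  segs2 <- detectIBD(p, gm, maxHomMismatch = 2, maxHetMismatch = 0,
                     minCm = 0.5)
  s13b <- segs2[segs2$hap_i == 1 & segs2$hap_j == 3, ]
  expect_equal(nrow(s13b), 1L)
  expect_equal(s13b$n_markers, m)
})

test_that("the IBD score applies the 3-20 cM band and pair normalisation", {
  seg <- function(len) data.frame(hap_i = 1L, hap_j = 3L, start_bp = 1,
                                  end_bp = 2, length_cM = len,
                                  n_markers = 10L)
  # n = 2: norm constant C(4,2) - 2 = 4; one 10 cM segment -> 2.5
  s <- ibdScore(seg(10), nIndividuals = 2)
  expect_equal(s$norm_constant, 4)
  expect_equal(s$score, 2.5)
  # out-of-band segments are excluded entirely
  expect_equal(ibdScore(seg(25), 2)$score, 0)
  expect_equal(ibdScore(seg(2.5), 2)$score, 0)
  expect_equal(ibdScore(seg(10)[0, ], 2)$score, 0)
  expect_error(ibdScore(seg(10), 1), "at least 2")
  # adding an in-band segment strictly increases the score
  two <- rbind(seg(10), seg(5))
  expect_gt(ibdScore(two, 2)$score, s$score)
  # duplicating every individual changes only the norm constant
  s4 <- ibdScore(two, 4)
  expect_equal(s4$score * (choose(8, 2) - 4),
               ibdScore(two, 2)$score * 4)
})

test_that("the weighted block jackknife matches the two-block closed form", {
  seg <- function(mid, len) data.frame(hap_i = 1L, hap_j = 3L,
                                       start_bp = mid - 5e5,
                                       end_bp = mid + 5e5,
                                       length_cM = len, n_markers = 50L)
  segs <- rbind(seg(5e6, 10), seg(15e6, 4))
  jk <- ibdJackknife(segs, nIndividuals = 2, extent = c(1, 2e7))
  expect_equal(jk$n_blocks, 2L)
  loo1 <- ibdScore(segs[2, ], 2)$score
  loo2 <- ibdScore(segs[1, ], 2)$score
  expect_equal(jk$se, abs(loo1 - loo2) / 2)
  expect_true(jk$ci[1] <= jk$score && jk$score <= jk$ci[2])

  # identical per-block mass -> zero variance
  segs2 <- rbind(seg(5e6, 10), seg(15e6, 10))
  expect_equal(ibdJackknife(segs2, 2, extent = c(1, 2e7))$se, 0)

  expect_error(ibdJackknife(segs, 2, extent = c(1, 9e6)),
               "insufficient blocks")
})
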
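# Fixtures and independent oracle implementations used across the suite.
# Oracles are deliberately naive (direct enumeration) and never share code
# with the package internals they check.

# random panel with positions spread over spanBp
randomPanel <- function(nHap, m, seed, spanBp = m * 1000) {
  set.seed(seed)
  a <- matrix(rbinom(nHap * m, 1L, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                          each = nHap)]),
              nrow = nHap, ncol = m)
  pos <- sort(sample.int(spanBp, m))
  HaplotypePanel(a, positions = pos)
}

# EHH by direct enumeration: probability that two random carriers are
# identical over the interval core..j (inclusive of j, exclusive of core)
oracleEHH <- function(a, core, allele, j) {
  car <- which(a[, core] == allele)
  n <- length(car)
  if (n < 2) return(NA_real_)
  rng <- if (j >= core) seq(core, j) else seq(j, core)
  key <- apply(a[car, rng, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(key)
  sum(choose(cnt, 2)) / choose(n, 2)
}

# trapezoid integral of a one-sided EHH curve out to the interpolated
# crossing of `cutoff`; points = data.frame(cm, ehh) starting at the core
oracleTrapezoid <- function(cm, ehh, cutoff) {
  total <- 0
  for (k in 2:length(cm)) {
    w <- abs(cm[k] - cm[k - 1])
    if (ehh[k] <= cutoff) {
      frac <- if (ehh[k - 1] > ehh[k])
        (ehh[k - 1] - cutoff) / (ehh[k - 1] - ehh[k]) else 1
      return(total + w * frac * (ehh[k - 1] + cutoff) / 2)
    }
    total <- total + w * (ehh[k - 1] + ehh[k]) / 2
  }
  NA_real_  # never crossed
}

# exhaustive IBD oracle: maximal exact-match runs per haplotype pair
# (no mismatch allowance), reported when >= minCm on the map
oracleIBDExact <- function(panel, gmap, minCm) {
  a <- alleles(panel)
  cm <- interpolateCM(gmap, positions(panel))
  n <- nrow(a)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same <- a[i, ] == a[j, ]
      r <- rle(same)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        len <- cm[ends[k]] - cm[starts[k]]
        if (len >= minCm)
          out[[length(out) + 1L]] <- data.frame(
            hap_i = i, hap_j = j, start = starts[k], end = ends[k],
            length_cM = len)
      }
    }
  }
  if (!length(out)) return(data.frame(hap_i = integer(), hap_j = integer(),
                                      start = integer(), end = integer(),
                                      length_cM = numeric()))
  do.call(rbind, out)
}

# brute-force ROH oracle: enumerates every window explicitly
oracleROH <- function(g, pos, p) {
  m <- length(g)
  W <- m - p$windowSnp + 1L
  if (W < 1L) return(NULL)
  homWin <- logical(W)
  for (w in seq_len(W)) {
    win <- g[w:(w + p$windowSnp - 1L)]
    homWin[w] <- sum(win == 1L, na.rm = TRUE) <= p$windowHet &&
      sum(is.na(win)) <= p$windowMissing
  }
  qual <- logical(m)
  for (i in seq_len(m)) {
    ws <- intersect(seq_len(W), (i - p$windowSnp + 1L):i)
    if (length(ws))
      qual[i] <- mean(homWin[ws]) >= p$windowThreshold
  }
  segs <- list()
  cur <- integer()
  flush <- function(cur, segs) {
    if (!length(cur)) return(segs)
    nSnp <- length(cur)
    lenKb <- (pos[cur[nSnp]] - pos[cur[1]] + 1) / 1000
    if (nSnp >= p$minSnp && lenKb >= p$minKb &&
        lenKb / nSnp <= p$maxKbPerSnp)
      segs[[length(segs) + 1L]] <- data.frame(
        start_bp = pos[cur[1]], end_bp = pos[cur[nSnp]],
        n_snp = nSnp, length_kb = lenKb)
    segs
  }
  for (i in seq_len(m)) {
    if (qual[i]) {
      if (length(cur) &&
          (pos[i] - pos[cur[length(cur)]] > p$maxGapKb * 1000 ||
           i - cur[length(cur)] > 1L)) {
        segs <- flush(cur, segs)
        cur <- integer()
      }
      cur <- c(cur, i)
    } else {
      segs <- flush(cur, segs)
      cur <- integer()
    }
  }
  segs <- flush(cur, segs)
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

# small fast demographic model for unit tests (not the study conditions)
tinyModel <- function(ne = 25, mu = 1e-6, rec = 1e-7, L = 1e6,
                      bottleneck = FALSE) {
  ep <- if (bottleneck)
    data.frame(years_ago = c(1e5, 600, 90), ne = c(ne, 4, ne))
  else
    data.frame(years_ago = c(1e5, 600), ne = c(ne, ne))
  methods::new("DemographyModel",
    epochs = ep,
    admixture = list(years_ago = if (bottleneck) 600 else NA_real_,
                     fraction = if (bottleneck) 0.7 else 0,
                     source = if (bottleneck) "src" else "none"),
    inbreeding = list(prob = if (bottleneck) 0.7 else 0,
                      window = if (bottleneck) c(600, 90)
                               else c(NA_real_, NA_real_)),
    mu = mu, rec = rec, chromLenBp = L, genYears = 30, scaleQ = 1)
}

# panel whose favored-allele EHH crosses 0.25 at a chosen cM on each side:
# carriers stay identical out to +/- nearCm and split completely at the
# next marker, so the interpolated crossing sits 3/4 of the way between
tmrcaPanel <- function(nearCm, farCm, span = 10) {
  cmPos <- c(-farCm, -nearCm, 0, nearCm, farCm) + span / 2
  bp <- round(cmPos * 1e5) + 1          # 1 cM = 100 kb
  a <- rbind(
    c(0L, 1L, 1L, 1L, 0L),
    c(1L, 1L, 1L, 1L, 1L),
    c(0L, 0L, 0L, 0L, 1L),
    c(1L, 0L, 0L, 0L, 0L))
  list(panel = HaplotypePanel(a, positions = bp),
       gmap = uniformMap(span * 1e5, 10))
}
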
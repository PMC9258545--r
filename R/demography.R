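#' The colonisation-bottleneck demographic model
#'
#' Builds the neutral demographic null model used to calibrate the selection
#' scan: a 10 Mb chromosome evolving at mutation rate 1.5e-8 and uniform
#' recombination rate 1e-8 per bp per generation in a diploid population of
#' effective size 10,000 that (i) contracts to 2,000 at 50 kya (out-of-Africa
#' bottleneck), (ii) recovers to 10,000 at 5 kya, (iii) undergoes a
#' colonisation bottleneck to 100 individuals from 500 to 90 years ago --
#' opened by a single-generation admixture pulse in which a European-like
#' lineage contributes 70% of parents, and accompanied by a 70% inbreeding
#' (selfing) probability throughout the bottleneck window -- and (iv)
#' recovers to 10,000 at 90 years ago. Generations last 30 years.
#'
#' The European-like source lineage is maintained as a second deme that
#' follows the same size trajectory from the out-of-Africa split until the
#' pulse.
#'
#' @return A \code{\linkS4class{DemographyModel}} with \code{scaleQ = 1}.
#' @seealso \code{\link{rescaleModel}} to run the model at desk scale,
#'   \code{\link{simulatePanel}} to draw samples from it.
#' @export
colonizationModel <- function() {
  new("DemographyModel",
      epochs = data.frame(
        years_ago = c(2.15e6, 50000, 5000, 500, 90),
        ne = c(10000, 2000, 10000, 100, 10000)),
      admixture = list(years_ago = 500, fraction = 0.70,
                       source = "European-like"),
      inbreeding = list(prob = 0.70, window = c(500, 90)),
      mu = 1.5e-8, rec = 1e-8, chromLenBp = 1e7,
      genYears = 30, scaleQ = 1)
}

#' Constant-size control model
#'
#' A no-event control matched to \code{\link{colonizationModel}}: the same
#' chromosome, rates and schedule length (a size-preserving epoch boundary
#' at 50 kya keeps the post-burn-in run length identical), but constant
#' effective size, no admixture and no inbreeding.
#'
#' @param ne constant diploid effective size (default 10,000).
#' @return A \code{\linkS4class{DemographyModel}}.
#' @export
constantModel <- function(ne = 10000) {
  new("DemographyModel",
      epochs = data.frame(years_ago = c(2.15e6, 50000), ne = c(ne, ne)),
      admixture = list(years_ago = NA_real_, fraction = 0,
                       source = "none"),
      inbreeding = list(prob = 0, window = c(NA_real_, NA_real_)),
      mu = 1.5e-8, rec = 1e-8, chromLenBp = 1e7,
      genYears = 30, scaleQ = 1)
}

#' @rdname DemographyModel-accessors
#' @param x a \code{\linkS4class{DemographyModel}}.
#' @export
setMethod("epochs", "DemographyModel", function(x) x@epochs)

setMethod("show", "DemographyModel", function(object) {
  cat("DemographyModel:", nrow(object@epochs), "epochs,",
      sprintf("chrom %.3g bp, mu %.3g, rec %.3g, g %g y, q %g\n",
              object@chromLenBp, object@mu, object@rec,
              object@genYears, object@scaleQ))
  print(object@epochs, row.names = FALSE)
  if (object@admixture$fraction > 0)
    cat(sprintf("  admixture: %.0f%% from %s at %g ya\n",
                100 * object@admixture$fraction, object@admixture$source,
                object@admixture$years_ago))
  if (object@inbreeding$prob > 0)
    cat(sprintf("  inbreeding: prob %.2f during (%g, %g) ya\n",
                object@inbreeding$prob, object@inbreeding$window[1],
                object@inbreeding$window[2]))
})

#' Rescale a demographic model for desk-scale simulation
#'
#' Standard population rescaling by a factor \code{q}: all effective sizes
#' are divided by \code{q} (floored, minimum 2), all times measured in
#' generations are divided by \code{q}, and the per-generation mutation and
#' recombination rates are multiplied by \code{q}. The population-scaled
#' parameters theta = 4 Ne mu and rho = 4 Ne rec -- and therefore the
#' sample statistics they govern -- are preserved, at a fraction of the
#' computing cost. Event probabilities (admixture fraction, inbreeding
#' probability) are untouched.
#'
#' @param model a \code{\linkS4class{DemographyModel}}.
#' @param q rescaling factor, >= 1.
#' @return The rescaled \code{\linkS4class{DemographyModel}} (its
#'   \code{scaleQ} slot multiplied by \code{q}).
#' @name rescaleModel
#' @export
setMethod("rescaleModel", "DemographyModel", function(model, q) {
  if (q < 1) stop("rescaling factor q must be >= 1")
  ep <- model@epochs
  ep$ne <- pmax(2, floor(ep$ne / q))
  new("DemographyModel",
      epochs = ep,
      admixture = model@admixture,
      inbreeding = model@inbreeding,
      mu = model@mu * q, rec = model@rec * q,
      chromLenBp = model@chromLenBp,
      genYears = model@genYears,
      scaleQ = model@scaleQ * q)
})

# Per-generation simulation plan for the post-burn-in phase.
# Times in years are converted to scaled generations (years / (g * q)) and
# rounded; epoch boundaries are nudged so that every epoch younger than the
# burn-in occupies at least one generation. Returns a data.frame ordered
# oldest generation first, with the colonised deme's size (neB), the
# source deme's size (neA), and the per-generation selfing probability and
# admixture fraction applying to offspring born that generation.
generationPlan <- function(model) {
  g <- model@genYears * model@scaleQ
  ep <- model@epochs
  bounds <- round(ep$years_ago / g)
  # enforce strictly decreasing boundaries, youngest upwards
  n <- length(bounds)
  bounds[n] <- max(bounds[n], 0)
  if (n > 1)
    for (i in (n - 1):1) bounds[i] <- max(bounds[i], bounds[i + 1] + 1)
  if (n == 1) {
    return(list(plan = data.frame(gens_ago = integer(), neB = integer(),
                                  neA = integer(), selfing = numeric(),
                                  admix = numeric()),
                burnNe = ep$ne[1],
                burnGens = 10L * as.integer(ep$ne[1])))
  }
  postGens <- bounds[2]                    # split happens this many gens ago
  tt <- seq(postGens, 0)                   # simulated generations, oldest first
  neB <- vapply(tt, function(t) {
    i <- max(which(bounds >= t))
    as.integer(ep$ne[i])
  }, integer(1))

  selfing <- rep(0, length(tt))
  inb <- model@inbreeding
  if (!is.null(inb$prob) && inb$prob > 0 && !anyNA(inb$window)) {
    wStart <- max(round(inb$window[1] / g), 1)
    wEnd <- max(round(inb$window[2] / g), 0)
    if (wStart <= wEnd) wStart <- wEnd + 1
    selfing[tt <= wStart & tt > wEnd] <- inb$prob
  }

  admix <- rep(0, length(tt))
  adm <- model@admixture
  pulseGen <- NA_integer_
  if (!is.null(adm$fraction) && adm$fraction > 0 && !is.na(adm$years_ago)) {
    pulseGen <- max(round(adm$years_ago / g), 1)
    admix[tt == pulseGen] <- adm$fraction
  }

  # source deme: mirrors the colonised deme's trajectory until the pulse,
  # then holds the size the lineage had just before the pulse (the size of
  # the epoch the pulse generation + 1 falls in; the burn-in size when the
  # pulse opens the very first post-split generation)
  neA <- neB
  if (!is.na(pulseGen)) {
    i <- which(bounds >= pulseGen + 1)
    pre <- as.integer(if (length(i)) ep$ne[max(i)] else ep$ne[1])
    neA[tt <= pulseGen] <- pre
  }

  list(plan = data.frame(gens_ago = tt, neB = neB, neA = neA,
                         selfing = selfing, admix = admix),
       burnNe = as.integer(ep$ne[1]),
       burnGens = 10L * as.integer(ep$ne[1]))
}
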
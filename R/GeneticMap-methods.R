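setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@bp), "anchors,",
      sprintf("%.4g-%.4g bp, %.4g-%.4g cM\n",
              min(object@bp), max(object@bp),
              min(object@cM), max(object@cM)))
})

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between map anchors; positions beyond the first or
#' last anchor take the boundary value (constant extrapolation).
#'
#' @param map a \code{\linkS4class{GeneticMap}}.
#' @param bp numeric vector of physical positions.
#' @return Numeric vector of genetic positions in cM.
#' @name interpolateCM
#' @export
setMethod("interpolateCM", "GeneticMap", function(map, bp) {
  if (length(map@bp) == 1L)
    return(rep(map@cM, length(bp)))
  approx(map@bp, map@cM, xout = bp, method = "linear", rule = 2)$y
})
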
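#' Accessors for spinsym S4 containers
#'
#' @param x a spinsym object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trajFrames", function(x) standardGeneric("trajFrames"))

#' @rdname accessors
#' @export
setGeneric("trajParams", function(x) standardGeneric("trajParams"))

#' @rdname accessors
#' @export
setGeneric("trajOutcome", function(x) standardGeneric("trajOutcome"))

#' @rdname accessors
#' @export
setGeneric("inCluster", function(x) standardGeneric("inCluster"))

#' @rdname accessors
#' @export
setGeneric("stackData", function(x) standardGeneric("stackData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("trackFrames", function(x) standardGeneric("trackFrames"))

#' @rdname accessors
#' @export
setGeneric("onsetTime", function(x) standardGeneric("onsetTime"))

setMethod("trajFrames", "Trajectory", function(x) x@frames)
setMethod("trajParams", "Trajectory", function(x) x@params)
setMethod("trajOutcome", "Trajectory", function(x) x@outcome)
setMethod("inCluster", "Trajectory", function(x) x@inIndex)
setMethod("inCluster", "ClusterTrack", function(x) x@inIndex)
setMethod("stackData", "ImageStack", function(x) x@data)
setMethod("voxelSize", "ImageStack",
          function(x) c(dz = x@dz, dxy = x@dxy))
setMethod("trackFrames", "ClusterTrack", function(x) x@frames)
setMethod("onsetTime", "RotationFit", function(x) x@ti)

setMethod("show", "Trajectory", function(object) {
  fr <- object@frames
  cat("Trajectory:", nrow(fr), "frames, t in [",
      signif(fr$t[1], 4), ",", signif(fr$t[nrow(fr)], 4), "]\n")
  cat("  outcome:", object@outcome,
      if (object@outcome == "broken")
        sprintf("(cluster %d internalized)", object@inIndex) else "", "\n")
  cat("  stop:", object@stopReason,
      " max |r1-r2|:", signif(object@maxAsym, 4), "\n")
  cat("  sigma:", object@params$sigma, " dt:", object@params$dt,
      " seed:", object@seed, "\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: T=%d Z=%d Y=%d X=%d, dz=%g um, dxy=%g um (%s)\n",
              d[1], d[2], d[3], d[4], object@dz, object@dxy,
              object@channel))
})

setMethod("show", "ClusterTrack", function(object) {
  fr <- object@frames
  n2 <- sum(!is.na(fr$c2x))
  cat(sprintf("ClusterTrack: %d frames (%d with two clusters), dz=%g dxy=%g um\n",
              nrow(fr), n2, object@dz, object@dxy))
})

setMethod("show", "FlowField", function(object) {
  d <- dim(object@u)
  cat(sprintf("FlowField: %d frame pairs, %dx%d grid, %.0f%% valid\n",
              d[1], d[2], d[3], 100 * mean(object@valid)))
})

setMethod("show", "RotationFit", function(object) {
  cat("RotationFit: y = D + (A-D)/(1+(t/C)^B)^E\n")
  print(signif(object@coef, 5))
  cat("  rmse:", signif(object@rmse, 4), " t_i:", signif(object@ti, 5),
      if (object@degenerate) "(degenerate)" else "",
      if (object@extrapolated) "(extrapolated)" else "", "\n")
})

setMethod("show", "CortexProfile", function(object) {
  cat(sprintf("CortexProfile: %d band pixels, peak at %.1f px\n",
              nrow(object@band), object@peakDist))
})
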
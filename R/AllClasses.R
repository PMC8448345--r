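#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib spinsym, .registration = TRUE
NULL

#' Trajectory of a simulated anaphase II spindle
#'
#' Container for one run of the overdamped two-cluster mechanical model:
#' the resolved parameter set, the recorded per-frame state, the fixed
#' cortical anchor points, and the outcome of the symmetry-breaking
#' process.
#'
#' @slot params named list, the resolved [modelParams()] set.
#' @slot frames data.frame with one row per recorded frame and columns
#'   `t`, `x1x`, `x1y`, `x2x`, `x2y`, `cx`, `cy`, `r1`, `r2` (cluster to
#'   anchor distances), `d1`, `d2` (cluster to cortex distances),
#'   `alpha` (retrospective rotation angle, degrees) and `depth`
#'   (ingression depth, units of the oocyte radius).
#' @slot anchors 2x2 numeric matrix, fixed cortical attraction points
#'   (rows = clusters).
#' @slot outcome `"broken"` or `"symmetric"`.
#' @slot inIndex integer, which cluster (1 or 2) internalized; `NA` for
#'   symmetric runs.
#' @slot maxAsym maximum over the run of |r1 - r2|.
#' @slot stopReason `"tmax"`, `"rotation_complete"` or `"escape"`.
#' @slot seed integer seed the run was started from (NA if unseeded).
#'
#' @seealso [simulateSpindle()], [trajFrames()], [trajOutcome()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(params = "list", frames = "data.frame",
                 anchors = "matrix", outcome = "character",
                 inIndex = "integer", maxAsym = "numeric",
                 stopReason = "character", seed = "integer"))

setValidity("Trajectory", function(object) {
  need <- c("t", "x1x", "x1y", "x2x", "x2y", "cx", "cy",
            "r1", "r2", "d1", "d2", "alpha", "depth")
  if (!all(need %in% names(object@frames)))
    return(paste("frames lacks columns:",
                 paste(setdiff(need, names(object@frames)), collapse = ", ")))
  if (nrow(object@frames) > 1 && any(diff(object@frames$t) <= 0))
    return("frame times must be strictly increasing")
  if (!object@outcome %in% c("broken", "symmetric"))
    return("outcome must be 'broken' or 'symmetric'")
  TRUE
})

#' 4D fluorescence image stack
#'
#' A T x Z x Y x X intensity array with physical voxel sizes, the common
#' currency of the imaging pipeline. Single time points and single
#' planes are stored with the degenerate dimensions kept.
#'
#' @slot data 4D numeric array, dimension order (T, Z, Y, X).
#' @slot dz z-spacing in micrometres.
#' @slot dxy in-plane pixel size in micrometres.
#' @slot channel free-text channel label.
#'
#' @seealso [imageStack()], [renderStack()], [readImageStack()]
#' @exportClass ImageStack
setClass("ImageStack",
  representation(data = "array", dz = "numeric", dxy = "numeric",
                 channel = "character"))

setValidity("ImageStack", function(object) {
  if (length(dim(object@data)) != 4L)
    return("data must be a 4D (T,Z,Y,X) array")
  if (object@dz <= 0 || object@dxy <= 0)
    return("voxel sizes must be positive")
  if (any(object@data < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  TRUE
})

#' Tracked DNA clusters
#'
#' Per-frame 3D centroids of up to two DNA clusters plus the cell
#' centroid and per-cluster cortex distances, in physical micrometres.
#' Produced by [trackClusters()] on segmented stacks, or synthesised
#' from a [Trajectory] for round-trip validation.
#'
#' @slot frames data.frame with columns `frame`, `t`, `c1x..c1z`,
#'   `c2x..c2z` (NA where a cluster is missing), `cellx..cellz`,
#'   `d1`, `d2` (cortex distances) and `qc` (character flags).
#' @slot dz,dxy voxel sizes used for the physical scaling.
#' @slot inIndex which track internalized (1, 2 or NA when unknown).
#'
#' @seealso [trackClusters()], [clusterDistance()], [rotationAngle()]
#' @exportClass ClusterTrack
setClass("ClusterTrack",
  representation(frames = "data.frame", dz = "numeric", dxy = "numeric",
                 inIndex = "integer"))

setValidity("ClusterTrack", function(object) {
  need <- c("frame", "t", "c1x", "c1y", "c1z", "c2x", "c2y", "c2z",
            "cellx", "celly", "cellz", "d1", "d2", "qc")
  if (!all(need %in% names(object@frames)))
    return(paste("frames lacks columns:",
                 paste(setdiff(need, names(object@frames)), collapse = ", ")))
  TRUE
})

#' Per-frame grid of PIV velocity vectors
#'
#' @slot u,v numeric arrays (frame pair, grid row, grid col) of velocity
#'   components in pixels per frame along image x (columns) and y (rows).
#' @slot gx,gy grid-point image coordinates (pixels).
#' @slot valid logical array matching `u`, FALSE where the vector was
#'   masked out or failed correlation quality checks.
#' @slot dtMin frame interval in minutes (for unit conversion).
#' @slot dxy pixel size in micrometres.
#'
#' @seealso [pivTwoPass()], [smoothField()], [axialVelocity()]
#' @exportClass FlowField
setClass("FlowField",
  representation(u = "array", v = "array", gx = "numeric", gy = "numeric",
                 valid = "array", dtMin = "numeric", dxy = "numeric"))

setValidity("FlowField", function(object) {
  if (!identical(dim(object@u), dim(object@v)) ||
      !identical(dim(object@u), dim(object@valid)))
    return("u, v and valid must have identical dimensions")
  if (length(dim(object@u)) != 3L)
    return("u must be (frame, grid row, grid col)")
  TRUE
})

#' Five-parameter logistic fit of a rotation curve
#'
#' Parameterisation `y(t) = D + (A - D) / (1 + (t/C)^B)^E` with `A` the
#' early asymptote, `D` the late asymptote, `C` the inflection scale,
#' `B` the slope and `E` the asymmetry.
#'
#' @slot coef named numeric (A, B, C, D, E).
#' @slot window numeric length-2 fit window on the time axis.
#' @slot rmse residual root-mean-square error.
#' @slot ti onset time (5% of fitted span), NA when undefined.
#' @slot degenerate TRUE when the fitted span was below threshold.
#' @slot extrapolated TRUE when `ti` lies outside the data span.
#'
#' @seealso [fitRotationLogistic()], [rotationOnset()]
#' @exportClass RotationFit
setClass("RotationFit",
  representation(coef = "numeric", window = "numeric", rmse = "numeric",
                 ti = "numeric", degenerate = "logical",
                 extrapolated = "logical"))

#' Cortical intensity profile
#'
#' Band pixels along the cell outline with arclength parameter,
#' per-pixel normalized intensity, per-pixel Euclidean distance to each
#' DNA cluster, the binned intensity-versus-distance curve and the
#' extracted peak distance.
#'
#' @slot band data.frame with columns `x`, `y` (pixel coordinates),
#'   `arclength` (pixels along the outline, origin at the point
#'   equidistant from the clusters), `intensity` (normalized to the
#'   profile mean), `dist1`, `dist2` (distance to each cluster).
#' @slot curve data.frame `dist`, `intensity`, `n` (binned means).
#' @slot peakDist argmax distance of the smoothed binned curve.
#'
#' @seealso [corticalBand()], [intensityVsDistance()]
#' @exportClass CortexProfile
setClass("CortexProfile",
  representation(band = "data.frame", curve = "data.frame",
                 peakDist = "numeric"))

setValidity("CortexProfile", function(object) {
  if (nrow(object@band) &&
      abs(mean(object@band$intensity) - 1) > 1e-9)
    return("band intensity must be normalized to mean 1")
  TRUE
})
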
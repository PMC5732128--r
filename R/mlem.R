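## Dual-matrix ML-EM: Monte Carlo forward projections (a_ij, realized
## operationally by simulation) combined with ray-tracing back-projections
## (b_ij). The source estimate is kept as a float activity map plus an
## integer history map; re-apportioning the histories from the activity
## after every update is what maintains the absolute counts-to-activity
## relationship across iterations.

#' Apportion the history budget over voxels
#'
#' Integer history counts proportional to the voxel activities, computed by
#' largest-remainder apportionment so the counts sum exactly to the budget.
#' Deterministic; remainder ties break toward the lower voxel index.
#'
#' @param activity an [ActivityMap-class] (or bare non-negative array)
#' @param budget total number of histories
#' @return integer array of the same shape summing to \code{budget}
#' @export
allocateHistories <- function(activity, budget) {
  f <- if (is(activity, "ActivityMap")) values(activity) else activity
  tot <- sum(f)
  if (tot <= 0) stop("total activity must be > 0")
  q <- as.numeric(budget) * as.numeric(f) / tot
  base <- floor(q)
  rem <- round(budget - sum(base))
  out <- base
  if (rem > 0) {
    frac <- q - base
    idx <- order(-frac, seq_along(frac))[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  out <- array(as.integer(out), dim = dim(f) %||% length(f))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One dual-matrix ML-EM update
#'
#' Performs a single iteration: (1) Monte Carlo forward projection of the
#' current history map, scaled to the current total activity and the
#' acquisition time of the measured data; (2) pixel ratios
#' \code{p / max(q, eps * mean(q > 0))}; (3) ray-tracing back-projection of
#' the ratios; (4) multiplicative voxel update
#' \code{f * backprojected / sensitivity} (zero-sensitivity voxels stay
#' zero); (5) largest-remainder re-apportionment of the history map.
#'
#' @param state a [ReconstructionState-class]
#' @param measured a [ProjectionSet-class]
#' @param geometry a [CameraGeometry-class]
#' @param density a [DensityMap-class] or NULL (non-attenuating)
#' @param tables a [PhysicsTables-class]
#' @param config a [ReconstructionConfig-class]
#' @param simConfig a [SimulationConfig-class] template for the forward
#'   step (its seed is replaced by \code{iterationSeed})
#' @param sensitivity precomputed [sensitivityMap] (computed when NULL)
#' @param iterationSeed RNG seed for this iteration's forward projection
#' @return the updated [ReconstructionState-class]
#' @export
emUpdate <- function(state, measured, geometry, density = NULL,
                     tables = physicsTables(),
                     config = reconstructionConfig(),
                     simConfig = simulationConfig(),
                     sensitivity = NULL,
                     iterationSeed = config@seed) {
  grid <- grid3d(state)
  if (is.null(sensitivity)) sensitivity <- sensitivityMap(geometry, grid)
  p <- counts(measured)
  nPix <- geometry@units[[1]]@nPix
  if (!identical(dim(p), c(nPix, nPix, length(geometry@units))))
    stop("measured projection shape does not match the geometry")
  fwdCfg <- simConfig
  fwdCfg@seed <- as.integer(iterationSeed %% .Machine$integer.max)
  fwdCfg@nHistories <- sum(as.numeric(state@historyMap))
  fwdCfg@poissonSampling <- FALSE
  q <- counts(forwardProject(state@historyMap, totalActivity(state),
                             acquisitionTime(measured), geometry, density,
                             grid, tables, fwdCfg,
                             energyWindow(measured)))
  if (all(q == 0)) stop("all-zero simulated projections")
  eps <- config@ratioEpsilon * mean(q[q > 0])
  ratio <- p / pmax(q, eps)
  bp <- bpVolume(backproject(ratio, geometry, grid))
  f <- values(state@activity)
  fNew <- array(0, dim = dim(f))
  ok <- sensitivity > 0
  fNew[ok] <- f[ok] * bp[ok] / sensitivity[ok]
  act <- activityMap(grid, fNew)
  out <- reconstructionState(act,
                             allocateHistories(act, config@historiesPerIteration),
                             iteration = state@iteration + 1L)
  # Poisson log-likelihood proxy of the measured data under the simulated
  # projections; recorded for observation, not optimized monotonically
  attr(out, "logLik") <- sum(p[q > 0] * log(q[q > 0])) - sum(q)
  out
}

#' Dual-matrix ML-EM reconstruction
#'
#' Starts from a uniform positive estimate spread over the in-FOV,
#' nonzero-sensitivity voxels and runs \code{nIterations} updates, with the
#' forward projection of iteration i seeded with \code{seed + i} so runs
#' are reproducible and iterations independent. No calibration factor
#' enters anywhere: the reconstructed voxel values are in MBq because the
#' forward model relates histories to activity. Per-iteration total
#' activity and a Poisson log-likelihood proxy are logged (the likelihood
#' is recorded for observation only: a dual-matrix update does not inherit
#' the monotone-likelihood guarantee of classical ML-EM).
#'
#' @param measured a [ProjectionSet-class]
#' @param geometry a [CameraGeometry-class]
#' @param density a [DensityMap-class] or NULL
#' @param grid a [VoxelGrid-class]; required when \code{density} is NULL
#' @param tables a [PhysicsTables-class]
#' @param config a [ReconstructionConfig-class]
#' @param simConfig a [SimulationConfig-class] template for forward steps
#' @param trackMasks optional named list of voxel masks; the summed
#'   activity inside each mask is logged per iteration
#' @return list with \code{state} (final [ReconstructionState-class]),
#'   \code{log} (per-iteration data.frame), and \code{filtered} (a
#'   post-filtered copy of the activity map, or NULL when
#'   \code{postFilter = "none"})
#' @export
reconstruct <- function(measured, geometry, density = NULL, grid = NULL,
                        tables = physicsTables(),
                        config = reconstructionConfig(),
                        simConfig = simulationConfig(),
                        trackMasks = NULL) {
  if (is.null(grid)) {
    if (is.null(density)) stop("need a grid or a density map")
    grid <- grid3d(density)
  }
  sens <- sensitivityMap(geometry, grid)
  co <- .coordArrays(grid)
  inFov <- (co$x^2 + co$y^2 + co$z^2) <= (fovDiameter(geometry) / 2)^2
  support <- inFov & (sens > 0)
  if (!any(support)) stop("no voxel is inside the FOV with nonzero sensitivity")
  f0 <- array(0, dim = rep(grid@N, 3L))
  f0[support] <- config@initialTotalActivity / sum(support)
  act <- activityMap(grid, f0)
  state <- reconstructionState(
    act, allocateHistories(act, config@historiesPerIteration), 0L)

  logRows <- vector("list", config@nIterations)
  p <- counts(measured)
  for (it in seq_len(config@nIterations)) {
    state <- emUpdate(state, measured, geometry, density, tables, config,
                      simConfig, sensitivity = sens,
                      iterationSeed = config@seed + it)
    row <- data.frame(iteration = it, totalActivity = totalActivity(state),
                      logLik = attr(state, "logLik"))
    if (!is.null(trackMasks)) {
      v <- values(state@activity)
      for (nm in names(trackMasks))
        row[[nm]] <- sum(v[trackMasks[[nm]]])
    }
    logRows[[it]] <- row
  }
  log <- if (config@nIterations > 0) do.call(rbind, logRows) else
    data.frame(iteration = integer(), totalActivity = numeric(),
               logLik = numeric())

  filtered <- switch(config@postFilter,
    none = NULL,
    gaussian = activityMap(grid, gaussianFilter3d(values(state@activity))),
    butterworth = activityMap(grid, butterworthFilter(values(state@activity),
                                                      voxel = grid@m)))
  list(state = state, log = log, filtered = filtered)
}
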
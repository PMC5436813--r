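# Spatial smoothness estimation, Monte-Carlo null distribution of the
# maximal cluster extent, connected-component labeling and conjunction.

# 1D Gaussian kernel with rows renormalized at the edges
.gaussBand <- function(n, sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- w[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

#' Smooth a 3D (or 4D) array with a separable Gaussian kernel
#'
#' Per-axis FWHM in mm; axes whose FWHM does not exceed the voxel size
#' are left unsmoothed. Edge rows of the kernel are renormalized.
#'
#' @param x numeric 3D or 4D array (4D: each volume smoothed alike).
#' @param fwhm numeric length 1 or 3, mm.
#' @param voxelSize numeric length 1 or 3, mm.
#' @return array of the same shape.
#' @export
smoothVolume <- function(x, fwhm, voxelSize) {
  d <- dim(x)
  stopifnot(length(d) %in% c(3L, 4L))
  fwhm <- rep(fwhm, length.out = 3)
  voxelSize <- rep(voxelSize, length.out = 3)
  sigmaVox <- fwhm / (2 * sqrt(2 * log(2))) / voxelSize
  out <- x
  for (ax in 1:3) {
    if (fwhm[ax] <= voxelSize[ax]) next
    K <- .gaussBand(d[ax], sigmaVox[ax])
    perm <- c(ax, setdiff(seq_along(d), ax))
    m <- matrix(aperm(out, perm), d[ax])
    m <- K %*% m
    out <- aperm(array(m, d[perm]), order(perm))
  }
  out
}

#' Estimate spatial smoothness from residuals
#'
#' Per-voxel residual time series are standardized to unit variance; for
#' each axis the variance of first differences between adjacent in-mask
#' voxels estimates the lag-1 spatial autocorrelation
#' \code{rho = 1 - var_diff / 2}, from which the FWHM of the equivalent
#' Gaussian smoothing kernel is
#' \code{voxel * sqrt(-2 log(2) / log(rho))}. Axes rougher than white
#' noise (\code{rho <= 0}) are flagged and set to the voxel size.
#'
#' @param resid X x Y x Z x T residual array (e.g.
#'   \code{\link{residualSeries}}) or a \linkS4class{VolumeSeries}.
#' @param mask logical 3D array; default: voxels with finite, nonzero
#'   variance.
#' @param voxelSize numeric length 1 or 3, mm.
#' @return list of class \code{SmoothnessEstimate} with \code{fwhm}
#'   (length 3, mm), \code{voxelSize}, and \code{rho} per axis.
#' @export
estimateSmoothness <- function(resid, mask = NULL, voxelSize = 3.5) {
  if (is(resid, "VolumeSeries")) {
    if (is.null(mask)) mask <- resid@mask
    voxelSize <- voxelSize(resid@affine)
    resid <- resid@data
  }
  d <- dim(resid)
  stopifnot(length(d) == 4L, d[4] >= 2L)
  voxelSize <- rep(voxelSize, length.out = 3)
  flat <- matrix(resid, prod(d[1:3]), d[4])
  sds <- apply(flat, 1L, sd)
  if (is.null(mask)) {
    mask <- array(is.finite(sds) & sds > 0, d[1:3])
  }
  usable <- as.vector(mask) & is.finite(sds) & sds > 0
  if (!any(usable))
    stop("residuals have no variance inside the mask; ",
         "smoothness undefined", call. = FALSE)
  z <- flat
  z[usable, ] <- flat[usable, ] / sds[usable]
  uArr <- array(usable, d[1:3])

  fwhm <- numeric(3)
  rho <- numeric(3)
  offsets <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) { rho[ax] <- NA_real_; fwhm[ax] <- voxelSize[ax]; next }
    # adjacent voxel pairs along this axis with both members usable
    notLast <- as.vector(slice.index(uArr, ax)) < n
    pairIdx <- which(usable & notLast)
    pairIdx <- pairIdx[usable[pairIdx + offsets[ax]]]
    if (length(pairIdx) == 0L) {
      rho[ax] <- NA_real_; fwhm[ax] <- voxelSize[ax]; next
    }
    diffs <- z[pairIdx + offsets[ax], , drop = FALSE] -
      z[pairIdx, , drop = FALSE]
    varDiff <- mean(diffs^2)
    rho[ax] <- 1 - varDiff / 2
    if (!is.finite(rho[ax]) || rho[ax] <= 0) {
      warning("axis ", ax, ": residuals rougher than white noise ",
              "(var_diff >= 2); FWHM set to voxel size")
      fwhm[ax] <- voxelSize[ax]
    } else if (rho[ax] >= 1) {
      warning("axis ", ax, ": residuals spatially constant; ",
              "smoothness not estimable, FWHM set to voxel size")
      fwhm[ax] <- voxelSize[ax]
    } else {
      fwhm[ax] <- voxelSize[ax] * sqrt(-2 * log(2) / log(rho[ax]))
    }
  }
  structure(list(fwhm = fwhm, voxelSize = voxelSize, rho = rho),
            class = "SmoothnessEstimate")
}

.NEIGHBOR_OFFSETS <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[ord == 1, , drop = FALSE],
         "18" = g[ord <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26", call. = FALSE))
}

#' Label suprathreshold clusters
#'
#' Connected components of a binary 3D map under 6-, 18- or
#' 26-connectivity (components found with igraph), reported as a table
#' sorted by size, largest first.
#'
#' @param bin logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param statMap optional numeric 3D array (e.g. the t map) used to
#'   locate and report each cluster's peak.
#' @param affine optional 4x4 voxel-to-world transform for peak
#'   coordinates in mm; default identity (voxel units).
#' @return list with \code{labels} (integer 3D array, 0 = background) and
#'   \code{table} (data.frame: label, size, peak_x/y/z in world mm,
#'   peak_stat).
#' @export
labelClusters <- function(bin, connectivity = 26L, statMap = NULL,
                          affine = diag(4)) {
  d <- dim(bin)
  stopifnot(length(d) == 3L)
  labels <- array(0L, d)
  empty <- data.frame(label = integer(), size = integer(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), peak_stat = numeric())
  idx <- which(bin)
  if (length(idx) == 0L)
    return(list(labels = labels, table = empty))
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  offs <- .NEIGHBOR_OFFSETS(connectivity)
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2L, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbIdx <- (nb[ok, 3] - 1L) * d[1] * d[2] +
      (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    nbRank <- rank[nbIdx]
    hit <- nbRank > 0L
    if (any(hit))
      edges <- rbind(edges,
                     cbind(seq_along(idx)[ok][hit], nbRank[hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel by decreasing size, ties by first occurrence
  sizes <- tabulate(comp)
  ord <- order(-sizes, seq_along(sizes))
  newLab <- integer(length(sizes))
  newLab[ord] <- seq_along(ord)
  lab <- newLab[comp]
  labels[idx] <- lab

  nClust <- max(lab)
  tab <- empty[rep(1L, 0L), ]
  stat <- if (is.null(statMap)) NULL else statMap[idx]
  for (cl in seq_len(nClust)) {
    members <- which(lab == cl)
    if (is.null(stat)) {
      peakMember <- members[1L]
      peakStat <- NA_real_
    } else {
      peakMember <- members[which.max(stat[members])]
      peakStat <- stat[peakMember]
    }
    vox <- coords[peakMember, ]
    world <- (affine %*% c(vox - 1L, 1))[1:3]
    tab <- rbind(tab, data.frame(
      label = cl, size = length(members),
      peak_x = world[1], peak_y = world[2], peak_z = world[3],
      peak_stat = peakStat))
  }
  list(labels = labels, table = tab)
}

#' Simulate the null distribution of the maximal cluster extent
#'
#' Each iteration draws Gaussian white noise over the volume, smooths it
#' to the target FWHM, standardizes it within the mask, thresholds at the
#' upper voxel-p Gaussian quantile, and records the largest cluster. The
#' extent threshold k is the smallest cluster size whose familywise
#' exceedance proportion is at most \code{alpha}; clusters of size
#' exactly k survive.
#'
#' @param dim integer length-3 volume shape.
#' @param mask logical 3D array (default: whole volume).
#' @param smoothness a \code{SmoothnessEstimate} (or list with
#'   \code{fwhm} and \code{voxelSize}).
#' @param voxelP voxel-level threshold p.
#' @param nIter number of Monte-Carlo simulations (>= 100; default 1000).
#' @param seed integer seed; the simulation is fully reproducible.
#' @param connectivity 6, 18 or 26; must match the one used when applying
#'   the threshold (enforced by \code{\link{applyClusterThreshold}}).
#' @param alpha familywise level (default 0.05).
#' @param covariate name recorded in the result.
#' @return an \linkS4class{ExtentThreshold}.
#' @export
simulateExtentThreshold <- function(dim, mask = NULL, smoothness,
                                    voxelP = 0.005, nIter = 1000L,
                                    seed = 1L, connectivity = 26L,
                                    alpha = 0.05,
                                    covariate = "covariate") {
  stopifnot(length(dim) == 3L)
  if (nIter < 100L)
    stop("need at least 100 simulations for a stable null",
         call. = FALSE)
  if (is.null(mask)) mask <- array(TRUE, dim)
  if (sum(mask) < 100L)
    warning("mask smaller than 100 voxels: extent null is unstable")
  zCrit <- qnorm(1 - voxelP)
  maskIdx <- which(mask)
  nullMax <- integer(nIter)
  oldSeed <- .saveSeed()
  on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  for (it in seq_len(nIter)) {
    x <- array(rnorm(prod(dim)), dim)
    x <- smoothVolume(x, smoothness$fwhm, smoothness$voxelSize)
    v <- x[maskIdx]
    v <- (v - mean(v)) / sd(v)
    bin <- array(FALSE, dim)
    bin[maskIdx] <- v > zCrit
    if (!any(bin)) { nullMax[it] <- 0L; next }
    lc <- labelClusters(bin, connectivity)
    nullMax[it] <- max(lc$table$size)
  }
  k <- 1L
  while (mean(nullMax >= k) > alpha) k <- k + 1L
  new("ExtentThreshold", covariate = covariate, voxelP = voxelP,
      nullMax = nullMax, k = k, alpha = alpha, seed = as.integer(seed),
      connectivity = as.integer(connectivity))
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restoreSeed <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' Apply the combined voxel + cluster-extent threshold
#'
#' Thresholds the group t map at the voxel level, labels clusters, and
#' retains those of size at least k (inclusive).
#'
#' @param map a \linkS4class{GroupStatMap}.
#' @param extent an \linkS4class{ExtentThreshold} simulated for this
#'   covariate's contrast.
#' @param voxelP voxel threshold; default the one the extent was
#'   simulated at.
#' @param connectivity default the extent's; a mismatch is an error.
#' @param tail passed to \code{\link{thresholdVoxelwise}}.
#' @return list with \code{map} (logical 3D array of significant voxels)
#'   and \code{clusters} (surviving-cluster table).
#' @export
applyClusterThreshold <- function(map, extent, voxelP = extent@voxelP,
                                  connectivity = extent@connectivity,
                                  tail = "one") {
  stopifnot(is(map, "GroupStatMap"), is(extent, "ExtentThreshold"))
  if (connectivity != extent@connectivity)
    stop("connectivity must match the extent simulation (",
         extent@connectivity, ")", call. = FALSE)
  bin <- thresholdVoxelwise(map, voxelP, tail)
  lc <- labelClusters(bin, connectivity, statMap = map@t,
                      affine = map@affine)
  keep <- lc$table$size >= extent@k
  sigLabels <- lc$table$label[keep]
  sig <- array(lc$labels %in% sigLabels, dim(bin))
  list(map = sig, clusters = lc$table[keep, , drop = FALSE])
}

#' Conjunction of significant maps
#'
#' Voxelwise logical AND: the conjunction-null test marks a voxel only if
#' it is significant in every contributing map.
#'
#' @param maps list of logical 3D arrays of identical shape.
#' @return logical 3D array.
#' @export
conjunction <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  d <- dim(maps[[1L]])
  same <- vapply(maps, function(m) identical(dim(m), d), logical(1))
  if (!all(same)) stop("all maps must share the same shape", call. = FALSE)
  Reduce(`&`, maps)
}

#' Write a cluster table as TSV
#' @param table cluster data.frame.
#' @param path output path.
#' @export
writeClusterTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
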
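# Voxelwise subject-level OLS, real-minus-reversed contrasts, and
# group-level one-sample t statistics with voxel thresholding.

#' Construct a BOLD volume series
#'
#' @param data numeric X x Y x Z x T array.
#' @param affine 4x4 voxel-to-world transform; default scales by
#'   \code{voxelSize}.
#' @param tr repetition time, seconds.
#' @param mask logical 3D array; default all TRUE.
#' @param voxelSize voxel edge length(s) in mm used for the default
#'   affine.
#' @return a \linkS4class{VolumeSeries}.
#' @export
volumeSeries <- function(data, tr, mask = NULL, affine = NULL,
                         voxelSize = 3.5) {
  d <- dim(data)
  stopifnot(length(d) == 4L)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (is.null(affine)) {
    vs <- rep(voxelSize, length.out = 3)
    affine <- diag(c(vs, 1))
  }
  new("VolumeSeries", data = data, affine = affine, tr = tr,
      mask = array(as.logical(mask), d[1:3]))
}

#' Voxel size from an affine
#' @param affine 4x4 matrix.
#' @return numeric length-3 voxel edge lengths (mm).
#' @export
voxelSize <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Fit the GLM in every voxel
#'
#' Ordinary least squares of each in-mask voxel's time course on the
#' design matrix. The design must have full column rank; a rank-deficient
#' design is rejected with the offending columns named.
#'
#' @param vol a \linkS4class{VolumeSeries}.
#' @param design a \linkS4class{DesignMatrix} whose rows match the
#'   volume count.
#' @return list of class \code{VoxelFit}: \code{beta} (K x V matrix of
#'   coefficients over in-mask voxels), \code{resid} (T x V residuals),
#'   \code{maskIdx} (linear voxel indices), \code{dim}, \code{mask},
#'   \code{affine}, \code{tr}, \code{design} (the DesignMatrix).
#' @export
fitVoxelwise <- function(vol, design) {
  stopifnot(is(vol, "VolumeSeries"), is(design, "DesignMatrix"))
  X <- design@values
  d <- dim(vol@data)
  if (nrow(X) != d[4])
    stop("design has ", nrow(X), " rows but volume series has ", d[4],
         " volumes", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  maskIdx <- which(vol@mask)
  Y <- t(matrix(vol@data, prod(d[1:3]), d[4])[maskIdx, , drop = FALSE])
  beta <- qr.coef(qrX, Y)
  resid <- Y - X %*% beta
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, resid = resid, maskIdx = maskIdx,
                 dim = d[1:3], mask = vol@mask, affine = vol@affine,
                 tr = vol@tr, design = design),
            class = "VoxelFit")
}

#' Beta map of one regressor as a 3D array
#' @param fit a \code{VoxelFit}.
#' @param column design column name.
#' @return 3D array, NA outside the mask.
#' @export
betaMap <- function(fit, column) {
  stopifnot(inherits(fit, "VoxelFit"))
  if (!column %in% rownames(fit$beta))
    stop("no design column '", column, "'", call. = FALSE)
  out <- array(NA_real_, fit$dim)
  out[fit$maskIdx] <- fit$beta[column, ]
  out
}

#' Residual time series as a 4D array
#' @param fit a \code{VoxelFit}.
#' @return X x Y x Z x T array, NA outside the mask.
#' @export
residualSeries <- function(fit) {
  stopifnot(inherits(fit, "VoxelFit"))
  T <- nrow(fit$resid)
  out <- array(NA_real_, c(fit$dim, T))
  flat <- matrix(out, prod(fit$dim), T)
  flat[fit$maskIdx, ] <- t(fit$resid)
  array(flat, c(fit$dim, T))
}

#' Real-minus-reversed contrast for one covariate
#'
#' For every story with both a real and a reversed run in the design, the
#' voxelwise difference beta(real) - beta(reversed) of the covariate's
#' column is formed; with several stories the per-story differences are
#' averaged.
#'
#' @param fit a \code{VoxelFit}.
#' @param covariate regressor role, e.g. \code{"ppl_lex"},
#'   \code{"ppl_pos"}, \code{"ppl_pho"}.
#' @param subject subject identifier carried into the result.
#' @return list of class \code{SubjectContrast}: \code{map} (3D array, NA
#'   outside the mask), \code{covariate}, \code{subject}, \code{affine}.
#' @export
contrastRealVsReversed <- function(fit, covariate, subject = "subj") {
  stopifnot(inherits(fit, "VoxelFit"))
  info <- fit$design@runInfo
  stories <- unique(info$pair)
  diffs <- NULL
  nPairs <- 0L
  for (st in stories) {
    realRun <- info$name[info$pair == st & !info$reversed]
    revRun <- info$name[info$pair == st & info$reversed]
    if (length(realRun) != 1L || length(revRun) != 1L)
      stop("story '", st, "' lacks a real/reversed run pair",
           call. = FALSE)
    colReal <- paste(realRun, covariate, sep = "_")
    colRev <- paste(revRun, covariate, sep = "_")
    if (!all(c(colReal, colRev) %in% rownames(fit$beta)))
      stop("covariate '", covariate, "' has no paired columns for ",
           "story '", st, "'", call. = FALSE)
    d <- fit$beta[colReal, ] - fit$beta[colRev, ]
    diffs <- if (is.null(diffs)) d else diffs + d
    nPairs <- nPairs + 1L
  }
  map <- array(NA_real_, fit$dim)
  map[fit$maskIdx] <- diffs / nPairs
  structure(list(map = map, covariate = covariate, subject = subject,
                 affine = fit$affine),
            class = "SubjectContrast")
}

#' Group one-sample t map over subject contrasts
#'
#' One-sample t statistic against zero at every voxel of the common mask,
#' with \code{df = n - 1}. Voxels with zero between-subject variance are
#' set to NA (flagged, not infinite).
#'
#' @param contrasts list of \code{SubjectContrast} objects for the same
#'   covariate.
#' @return a \linkS4class{GroupStatMap}.
#' @export
groupTTest <- function(contrasts) {
  n <- length(contrasts)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  covName <- contrasts[[1L]]$covariate
  ok <- vapply(contrasts, function(x)
    inherits(x, "SubjectContrast") && identical(x$covariate, covName),
    logical(1))
  if (!all(ok))
    stop("all contrasts must be SubjectContrast of the same covariate",
         call. = FALSE)
  dims <- dim(contrasts[[1L]]$map)
  M <- vapply(contrasts, function(x) as.vector(x$map),
              numeric(prod(dims)))
  mu <- rowMeans(M)
  s <- apply(M, 1L, sd)
  t <- mu / (s / sqrt(n))
  t[!is.finite(t)] <- NA_real_
  affine <- contrasts[[1L]]$affine
  new("GroupStatMap", t = array(t, dims), df = n - 1L,
      covariate = covName, affine = affine,
      voxelSize = voxelSize(affine))
}

#' Voxelwise threshold of a group t map
#'
#' One-tailed (positive) by default: a voxel passes if its t exceeds the
#' upper-p quantile of the t distribution with the map's df. Two-tailed
#' compares |t| against the upper-p/2 quantile.
#'
#' @param map a \linkS4class{GroupStatMap}.
#' @param p voxel-level probability threshold in (0, 1).
#' @param tail \code{"one"} (default) or \code{"two"}.
#' @return logical 3D array; NA voxels never pass.
#' @export
thresholdVoxelwise <- function(map, p = 0.005, tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(is(map, "GroupStatMap"), p > 0, p < 1)
  if (tail == "one") {
    crit <- qt(1 - p, df = map@df)
    out <- map@t > crit
  } else {
    crit <- qt(1 - p / 2, df = map@df)
    out <- abs(map@t) > crit
  }
  out[is.na(out)] <- FALSE
  out
}

# ---- NIfTI I/O ----

#' Write a 3D/4D array or stat map as NIfTI-1
#'
#' @param x numeric array, logical array, \linkS4class{VolumeSeries} or
#'   \linkS4class{GroupStatMap}. Stat maps get a JSON sidecar recording
#'   df and covariate.
#' @param path output path (.nii or .nii.gz).
#' @export
writeNIfTI <- function(x, path) {
  if (is(x, "VolumeSeries")) {
    img <- RNifti::asNifti(x@data)
    img <- RNifti::`sform<-`(img, structure(x@affine, code = 2L))
    img$pixdim[5] <- x@tr   # time step lives in pixdim slot 5 (dim 4)
    RNifti::writeNifti(img, path)
  } else if (is(x, "GroupStatMap")) {
    tt <- x@t
    tt[is.na(tt)] <- 0
    img <- RNifti::asNifti(tt)
    img <- RNifti::`sform<-`(img, structure(x@affine, code = 2L))
    RNifti::writeNifti(img, path)
    jsonlite::write_json(list(df = x@df, covariate = x@covariate),
                         sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE)
  } else {
    RNifti::writeNifti(RNifti::asNifti(x * 1), path)
  }
  invisible(path)
}

#' Read a NIfTI volume series
#' @param path NIfTI file.
#' @param tr repetition time override; default taken from the header.
#' @param mask optional logical array or NIfTI path (nonzero = in mask).
#' @return a \linkS4class{VolumeSeries} (4D input) or plain array.
#' @export
readNIfTIVolumes <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L) return(arr)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  if (is.character(mask))
    mask <- as.array(RNifti::readNifti(mask)) != 0
  affine <- structure(RNifti::xform(img), class = "matrix")
  volumeSeries(arr, tr = tr, mask = mask,
               affine = matrix(as.numeric(affine), 4, 4))
}
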
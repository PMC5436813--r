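# First-level design construction: double-gamma HRF, boxcar event
# regressors with parametric amplitude modulation, and per-run assembly of
# word-duration, perplexity, frequency, motion and constant columns.

#' Hemodynamic response function specification
#'
#' Canonical double-gamma difference kernel. The positive lobe peaks at
#' \code{peakDelay} seconds and the (downweighted) undershoot at
#' \code{undershootDelay} seconds; each gamma is parameterized so its mode
#' sits exactly at the stated delay.
#'
#' @param peakDelay seconds to the response peak (default 6).
#' @param undershootDelay seconds to the undershoot trough (default 16).
#' @param peakDispersion,undershootDispersion gamma dispersions, seconds.
#' @param ratio peak-to-undershoot amplitude ratio denominator: the
#'   undershoot is subtracted scaled by \code{1/ratio} (default 6).
#' @param length kernel support, seconds (default 32).
#' @return an object of class \code{HRFSpec}.
#' @export
hrfSpec <- function(peakDelay = 6, undershootDelay = 16,
                    peakDispersion = 1, undershootDispersion = 1,
                    ratio = 6, length = 32) {
  stopifnot(peakDelay > 0, undershootDelay > 0, peakDispersion > 0,
            undershootDispersion > 0, ratio > 0, length > 0)
  structure(list(peakDelay = peakDelay, undershootDelay = undershootDelay,
                 peakDispersion = peakDispersion,
                 undershootDispersion = undershootDispersion,
                 ratio = ratio, length = length),
            class = "HRFSpec")
}

#' Sample the canonical HRF kernel
#'
#' Difference of two gamma densities, peak-normalized to 1. With the
#' default specification the kernel rises from 0 at the origin to its
#' maximum near 6 s and shows a shallow undershoot near 16 s.
#'
#' @param spec an \code{\link{hrfSpec}}.
#' @param dt sampling interval, seconds (> 0).
#' @return numeric vector of kernel values at 0, dt, 2 dt, ...
#' @export
canonicalHRF <- function(spec = hrfSpec(), dt = 0.1) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  t <- seq(0, spec$length, by = dt)
  shape1 <- spec$peakDelay / spec$peakDispersion + 1
  shape2 <- spec$undershootDelay / spec$undershootDispersion + 1
  h <- dgamma(t, shape = shape1, scale = spec$peakDispersion) -
    dgamma(t, shape = shape2, scale = spec$undershootDispersion) /
      spec$ratio
  h / max(h)
}

#' Build an HRF-convolved (modulated) event regressor
#'
#' Events are laid down as boxcars from onset to onset + duration at
#' microtime resolution, scaled by their amplitudes, convolved with the
#' HRF kernel, and downsampled to the TR grid. For parametric modulators
#' the amplitudes are mean-centered first, so the column carries only the
#' variance of the covariate around its mean.
#'
#' @param onsets,durations numeric vectors, seconds; intervals are
#'   half-open \code{[onset, onset + duration)}.
#' @param amplitudes per-event amplitudes (default all 1).
#' @param hrf HRF kernel sampled at \code{tr / microtime} (see
#'   \code{\link{canonicalHRF}}).
#' @param nVolumes number of volumes T in the run.
#' @param tr repetition time, seconds.
#' @param microtime microtime bins per TR (default 16).
#' @param meanCenter centre amplitudes before scaling (TRUE for
#'   parametric modulators, FALSE for the word-duration regressor).
#' @return numeric vector of length \code{nVolumes}.
#' @export
modulatedRegressor <- function(onsets, durations, amplitudes = NULL,
                               hrf, nVolumes, tr, microtime = 16L,
                               meanCenter = TRUE) {
  stopifnot(length(onsets) == length(durations), tr > 0, nVolumes >= 1)
  runEnd <- nVolumes * tr
  bad <- which(onsets + durations > runEnd + 1e-9 | onsets < 0)
  if (length(bad))
    stop("event(s) outside run [0, ", runEnd, ") at index: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(amplitudes)) amplitudes <- rep(1, length(onsets))
  stopifnot(length(amplitudes) == length(onsets))
  if (meanCenter && length(amplitudes))
    amplitudes <- amplitudes - mean(amplitudes)

  dt <- tr / microtime
  n <- nVolumes * microtime
  x <- numeric(n)
  for (i in seq_along(onsets)) {
    from <- floor(onsets[i] / dt) + 1L
    to <- ceiling((onsets[i] + durations[i]) / dt)
    to <- min(to, n)
    x[from:to] <- x[from:to] + amplitudes[i]
  }
  if (length(onsets) == 0L) return(numeric(nVolumes))
  # direct linear convolution, truncated to the run
  conv <- convolve(x, rev(hrf), type = "open")[seq_len(n)]
  conv[seq(1L, by = microtime, length.out = nVolumes)]
}

.RUN_ROLES <- c("duration", "ppl_lex", "ppl_pos", "ppl_pho",
                "freq_lex", "freq_pos", "freq_pho",
                paste0("motion", 1:6), "constant")
.INTEREST_ROLES <- c("ppl_lex", "ppl_pos", "ppl_pho")

#' Assemble the multi-run first-level design matrix
#'
#' Per run: one word-duration regressor, three perplexity modulators
#' (regressors of interest), three log2-frequency modulators (nuisance),
#' six motion parameters (nuisance) and one constant. Runs are stacked
#' block-diagonally in time with run-local columns, so real and reversed
#' runs get separate coefficients for identical story-derived regressors:
#' a reversed run is built from its paired real story's covariate table.
#'
#' @param runs list of run descriptions; each a list with elements
#'   \code{name} (unique run id), \code{pair} (story id; the same for a
#'   real run and its reversed partner), \code{reversed} (logical),
#'   \code{covariates} (covariate table of the paired story, from
#'   \code{\link{buildCovariates}}), \code{motion} (T x 6 numeric matrix)
#'   and \code{nVolumes}.
#' @param tr repetition time, seconds.
#' @param hrf an \code{\link{hrfSpec}}.
#' @param microtime microtime bins per TR.
#' @return a \linkS4class{DesignMatrix}.
#' @export
assembleDesign <- function(runs, tr, hrf = hrfSpec(), microtime = 16L) {
  stopifnot(length(runs) >= 1L)
  kernel <- canonicalHRF(hrf, dt = tr / microtime)
  blocks <- vector("list", length(runs))
  info <- data.frame(name = character(), reversed = logical(),
                     pair = character(), nVolumes = integer())
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    stopifnot(!is.null(r$name), !is.null(r$covariates),
              !is.null(r$motion), !is.null(r$nVolumes))
    cov <- r$covariates
    T <- as.integer(r$nVolumes)
    motion <- as.matrix(r$motion)
    if (nrow(motion) != T || ncol(motion) != 6L)
      stop("run '", r$name, "': motion must be a ", T,
           " x 6 matrix, got ", nrow(motion), " x ", ncol(motion),
           call. = FALSE)
    mk <- function(amp, center) modulatedRegressor(
      cov$onset, cov$duration, amp, kernel, T, tr,
      microtime = microtime, meanCenter = center)
    X <- cbind(
      duration = mk(NULL, FALSE),
      ppl_lex = mk(cov$lex_ppl, TRUE),
      ppl_pos = mk(cov$pos_ppl, TRUE),
      ppl_pho = mk(cov$pho_ppl, TRUE),
      freq_lex = mk(cov$lex_freq, TRUE),
      freq_pos = mk(cov$pos_freq, TRUE),
      freq_pho = mk(cov$pho_freq, TRUE),
      motion, constant = rep(1, T))
    colnames(X) <- paste(r$name, .RUN_ROLES, sep = "_")
    blocks[[i]] <- X
    info <- rbind(info, data.frame(
      name = r$name, reversed = isTRUE(r$reversed),
      pair = if (is.null(r$pair)) r$name else r$pair, nVolumes = T))
  }
  totalT <- sum(info$nVolumes)
  K <- sum(vapply(blocks, ncol, integer(1)))
  values <- matrix(0, totalT, K)
  cn <- character(K)
  runLabels <- character(totalT)
  columnRun <- character(K)
  interest <- logical(K)
  row0 <- 0L; col0 <- 0L
  for (i in seq_along(blocks)) {
    B <- blocks[[i]]
    values[row0 + seq_len(nrow(B)), col0 + seq_len(ncol(B))] <- B
    cn[col0 + seq_len(ncol(B))] <- colnames(B)
    runLabels[row0 + seq_len(nrow(B))] <- info$name[i]
    columnRun[col0 + seq_len(ncol(B))] <- info$name[i]
    interest[col0 + seq_len(ncol(B))] <- .RUN_ROLES %in% .INTEREST_ROLES
    row0 <- row0 + nrow(B); col0 <- col0 + ncol(B)
  }
  colnames(values) <- cn
  new("DesignMatrix", values = values, tr = tr, runLabels = runLabels,
      interest = interest, columnRun = columnRun, runInfo = info)
}

#' Write a design matrix as TSV with a JSON sidecar
#'
#' The TSV holds the T x K values with column names; the sidecar records
#' TR, run labels, the interest mask and the run table.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param path TSV path; the sidecar is written alongside with extension
#'   \code{.json}.
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "DesignMatrix"))
  utils::write.table(design@values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(tr = design@tr, runLabels = design@runLabels,
         interest = design@interest, columnRun = design@columnRun,
         runInfo = design@runInfo),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a design matrix written by \code{\link{writeDesign}}
#' @param path TSV path (sidecar expected alongside).
#' @return a \linkS4class{DesignMatrix}.
#' @export
readDesign <- function(path) {
  values <- as.matrix(utils::read.delim(path, check.names = FALSE))
  side <- jsonlite::read_json(sub("\\.[^.]*$", ".json", path),
                              simplifyVector = TRUE)
  new("DesignMatrix", values = values, tr = side$tr,
      runLabels = side$runLabels, interest = side$interest,
      columnRun = side$columnRun,
      runInfo = as.data.frame(side$runInfo))
}

#' Read motion parameters
#'
#' Six columns (three translations, three rotations), whitespace- or
#' tab-separated, one row per volume.
#'
#' @param path file path.
#' @return T x 6 numeric matrix.
#' @export
readMotion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L)
    stop("motion file must have 6 columns", call. = FALSE)
  unname(m)
}
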
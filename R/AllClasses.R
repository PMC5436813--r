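#' @import methods
#' @importFrom stats convolve cor dgamma pt qnorm qt quantile rnorm runif
#'   rexp rpois sd var setNames
NULL

# separator used to join symbols into n-gram keys; never occurs in tokens
.SEP <- "\x1f"

#' Trigram (second-order Markov) language model
#'
#' Holds n-gram count tables up to \code{order}, the predicted vocabulary
#' (including the end-of-sentence and unknown markers), and the smoothing
#' configuration: Jelinek-Mercer interpolation weights across orders plus an
#' add-k constant at the unigram level.
#'
#' @slot order integer model order (3 for a trigram model).
#' @slot vocab character, the predicted vocabulary: every symbol that can
#'   appear in target position, including the end and unknown markers.
#' @slot counts list of named numeric vectors, one per order 1..order;
#'   element n maps an n-gram key to its count.
#' @slot contextCounts list of named numeric vectors for orders 2..order;
#'   element n maps an (n-1)-symbol history to the number of n-grams
#'   observed with that history.
#' @slot total numeric, total target tokens (unigram mass).
#' @slot lambda numeric interpolation weights, one per order, summing to 1;
#'   lambda[n] weighs the order-n maximum-likelihood estimate.
#' @slot addK numeric >= 0, add-k smoothing applied to the unigram estimate.
#' @slot minCount integer, symbols rarer than this in training map to the
#'   unknown marker before counting.
#' @slot markers named character of length 3: begin, end, unknown symbols.
#' @exportClass NGramModel
setClass("NGramModel",
  representation(
    order = "integer",
    vocab = "character",
    counts = "list",
    contextCounts = "list",
    total = "numeric",
    lambda = "numeric",
    addK = "numeric",
    minCount = "integer",
    markers = "character"
  )
)

setValidity("NGramModel", function(object) {
  msg <- character()
  if (length(object@order) != 1L || object@order < 1L)
    msg <- c(msg, "order must be a single integer >= 1")
  if (length(object@lambda) != object@order)
    msg <- c(msg, "lambda must have one weight per order")
  if (abs(sum(object@lambda) - 1) > 1e-9)
    msg <- c(msg, "lambda weights must sum to 1")
  if (any(object@lambda < 0))
    msg <- c(msg, "lambda weights must be non-negative")
  if (object@addK < 0)
    msg <- c(msg, "addK must be non-negative")
  if (length(object@counts) != object@order)
    msg <- c(msg, "counts must have one table per order")
  if (any(unlist(object@counts, use.names = FALSE) < 0))
    msg <- c(msg, "all counts must be non-negative")
  if (!all(c("begin", "end", "unk") %in% names(object@markers)))
    msg <- c(msg, "markers must name begin, end and unk symbols")
  if (length(msg)) msg else TRUE
})

#' Word-timed stimulus transcript with three annotation streams
#'
#' An ordered sequence of word events, each carrying its surface form, a
#' fine-grained part-of-speech tag, its phonemic transcription, and its
#' timing (onset and duration in seconds from run start).
#'
#' @slot storyId single character identifier.
#' @slot word character vector of word forms.
#' @slot pos character vector of fine-grained PoS tags (base tag plus
#'   optional parenthesised subcategory features).
#' @slot phonemes list of character vectors, the phoneme sequence per word.
#' @slot onset numeric, seconds, non-decreasing.
#' @slot duration numeric, seconds, strictly positive.
#' @exportClass StimulusTranscript
setClass("StimulusTranscript",
  representation(
    storyId = "character",
    word = "character",
    pos = "character",
    phonemes = "list",
    onset = "numeric",
    duration = "numeric"
  )
)

setValidity("StimulusTranscript", function(object) {
  n <- length(object@word)
  msg <- character()
  if (n == 0L) msg <- c(msg, "transcript must contain at least one token")
  if (length(object@pos) != n || length(object@phonemes) != n ||
      length(object@onset) != n || length(object@duration) != n)
    msg <- c(msg, "word, pos, phonemes, onset and duration must align")
  if (any(lengths(object@phonemes) == 0L))
    msg <- c(msg, "every token must have at least one phoneme")
  if (n > 1L && any(diff(object@onset) < 0))
    msg <- c(msg, "onsets must be non-decreasing")
  if (any(object@onset < 0)) msg <- c(msg, "onsets must be >= 0")
  if (any(object@duration <= 0)) msg <- c(msg, "durations must be > 0")
  if (length(msg)) msg else TRUE
})

#' Part-of-speech tagset with subcategory counts
#'
#' A set of base grammatical categories, each with the number of
#' fine-grained morpho-syntactic subcategories it expands into.
#'
#' @slot baseTag character vector of base tags.
#' @slot nSubcategories integer vector, positive, aligned with baseTag.
#' @exportClass Tagset
setClass("Tagset",
  representation(baseTag = "character", nSubcategories = "integer")
)

setValidity("Tagset", function(object) {
  msg <- character()
  if (length(object@baseTag) != length(object@nSubcategories))
    msg <- c(msg, "baseTag and nSubcategories must align")
  if (anyDuplicated(object@baseTag))
    msg <- c(msg, "base tags must be unique")
  if (any(object@nSubcategories < 1L))
    msg <- c(msg, "subcategory counts must be positive integers")
  if (length(msg)) msg else TRUE
})

#' First-level design matrix
#'
#' A time-by-regressor matrix sampled at the repetition time, with run
#' structure: per-run word-duration regressor, perplexity modulators
#' (regressors of interest), frequency and motion nuisance regressors, and
#' one constant per run.
#'
#' @slot values numeric T x K matrix with column names.
#' @slot tr numeric, sampling interval in seconds.
#' @slot runLabels character of length T, run membership per row.
#' @slot interest logical of length K, TRUE for regressors of interest.
#' @slot columnRun character of length K, owning run per column.
#' @slot runInfo data.frame with one row per run: name, reversed flag,
#'   story pairing, and volume count.
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(
    values = "matrix",
    tr = "numeric",
    runLabels = "character",
    interest = "logical",
    columnRun = "character",
    runInfo = "data.frame"
  )
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  X <- object@values
  if (length(object@runLabels) != nrow(X))
    msg <- c(msg, "runLabels must have one entry per row")
  if (length(object@interest) != ncol(X) ||
      length(object@columnRun) != ncol(X))
    msg <- c(msg, "interest and columnRun must have one entry per column")
  if (object@tr <= 0) msg <- c(msg, "tr must be positive")
  if (any(object@interest & colSums(abs(X)) == 0))
    msg <- c(msg, "regressors of interest must not be all-zero")
  const <- grep("constant$", colnames(X))
  if (length(const) > 1L) {
    G <- crossprod(X[, const, drop = FALSE])
    if (any(abs(G[upper.tri(G)]) > 1e-12))
      msg <- c(msg, "per-run constants must be orthogonal across runs")
  }
  if (length(msg)) msg else TRUE
})

#' 4D BOLD volume series
#'
#' @slot data numeric X x Y x Z x T array.
#' @slot affine numeric 4x4 voxel-to-world transform (mm).
#' @slot tr numeric repetition time, seconds.
#' @slot mask logical X x Y x Z array, TRUE inside the brain.
#' @exportClass VolumeSeries
setClass("VolumeSeries",
  representation(
    data = "array", affine = "matrix", tr = "numeric", mask = "array"
  )
)

setValidity("VolumeSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array")
  if (!identical(dim(object@mask), dim(object@data)[1:3]))
    msg <- c(msg, "mask must match the spatial dimensions of data")
  if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  if (length(msg)) msg else TRUE
})

#' Group-level t-statistic map
#'
#' @slot t numeric 3D array of one-sample t statistics (NA outside the
#'   group mask or at zero-variance voxels).
#' @slot df integer degrees of freedom (subjects - 1).
#' @slot covariate character, name of the contrasted covariate.
#' @slot affine numeric 4x4 voxel-to-world transform.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @exportClass GroupStatMap
setClass("GroupStatMap",
  representation(
    t = "array", df = "integer", covariate = "character",
    affine = "matrix", voxelSize = "numeric"
  )
)

setValidity("GroupStatMap", function(object) {
  msg <- character()
  if (length(dim(object@t)) != 3L) msg <- c(msg, "t must be a 3D array")
  if (object@df < 1L) msg <- c(msg, "df must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Monte-Carlo cluster-extent threshold
#'
#' The null distribution of the maximal suprathreshold cluster extent under
#' smoothness-matched Gaussian noise, and the smallest cluster size whose
#' familywise exceedance probability is at most alpha.
#'
#' @slot covariate character.
#' @slot voxelP numeric, voxel-level threshold p.
#' @slot nullMax integer vector, max cluster size per simulation.
#' @slot k integer, extent threshold (clusters of size >= k survive).
#' @slot alpha numeric, familywise level (0.05).
#' @slot seed integer seed used for the simulations.
#' @slot connectivity integer, 6, 18 or 26.
#' @exportClass ExtentThreshold
setClass("ExtentThreshold",
  representation(
    covariate = "character", voxelP = "numeric", nullMax = "integer",
    k = "integer", alpha = "numeric", seed = "integer",
    connectivity = "integer"
  )
)

setValidity("ExtentThreshold", function(object) {
  msg <- character()
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (object@voxelP <= 0 || object@voxelP >= 1)
    msg <- c(msg, "voxelP must be in (0, 1)")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  # k is the smallest integer with empirical P(max >= k) <= alpha
  exceed <- function(k) mean(object@nullMax >= k)
  if (exceed(object@k) > object@alpha)
    msg <- c(msg, "k does not control the familywise exceedance at alpha")
  if (object@k > 1L && exceed(object@k - 1L) <= object@alpha)
    msg <- c(msg, "k is not the smallest size controlling alpha")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NGramModel", function(object) {
  cat(sprintf(
    "NGramModel of order %d: %d vocabulary symbols, %.0f training tokens\n",
    object@order, length(object@vocab), object@total))
  cat(sprintf("  lambda = (%s), add-k = %g, min count = %d\n",
    paste(format(object@lambda), collapse = ", "),
    object@addK, object@minCount))
})

setMethod("show", "StimulusTranscript", function(object) {
  cat(sprintf(
    "StimulusTranscript '%s': %d tokens, %.1f s, %d phonemes\n",
    object@storyId, length(object@word),
    max(object@onset + object@duration), sum(lengths(object@phonemes))))
})

setMethod("show", "Tagset", function(object) {
  cat(sprintf("Tagset: %d base tags, %d fine-grained tags\n",
    length(object@baseTag), sum(object@nSubcategories)))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf(
    "DesignMatrix: %d volumes x %d regressors (%d of interest), TR %.2f s, %d run(s)\n",
    nrow(object@values), ncol(object@values), sum(object@interest),
    object@tr, length(unique(object@runLabels))))
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "VolumeSeries: %d x %d x %d voxels x %d volumes, TR %.2f s, %d in mask\n",
    d[1], d[2], d[3], d[4], object@tr, sum(object@mask)))
})

setMethod("show", "GroupStatMap", function(object) {
  cat(sprintf("GroupStatMap '%s': df = %d, %d finite voxels\n",
    object@covariate, object@df, sum(is.finite(object@t))))
})

setMethod("show", "ExtentThreshold", function(object) {
  cat(sprintf(
    "ExtentThreshold '%s': voxel p = %g, k = %d voxels (alpha %.2f, %d simulations, %d-connectivity)\n",
    object@covariate, object@voxelP, object@k, object@alpha,
    length(object@nullMax), object@connectivity))
})

# ---- accessors ----

#' Number of tokens in a transcript
#' @param x a StimulusTranscript
#' @return integer token count
#' @export
nTokens <- function(x) {
  stopifnot(is(x, "StimulusTranscript"))
  length(x@word)
}

#' Design matrix values
#' @param x a DesignMatrix
#' @return the numeric T x K matrix
#' @export
designValues <- function(x) {
  stopifnot(is(x, "DesignMatrix"))
  x@values
}

#' Regressor-of-interest mask of a design matrix
#' @param x a DesignMatrix
#' @return named logical vector, one entry per column
#' @export
interestMask <- function(x) {
  stopifnot(is(x, "DesignMatrix"))
  setNames(x@interest, colnames(x@values))
}

#' t-statistic array of a group map
#' @param x a GroupStatMap
#' @return numeric 3D array
#' @export
statValues <- function(x) {
  stopifnot(is(x, "GroupStatMap"))
  x@t
}

#' Cluster-extent threshold in voxels
#' @param x an ExtentThreshold
#' @return integer minimum surviving cluster size
#' @export
extentK <- function(x) {
  stopifnot(is(x, "ExtentThreshold"))
  x@k
}

#' Model vocabulary
#' @param x an NGramModel
#' @return character vector of predicted symbols
#' @export
vocabulary <- function(x) {
  stopifnot(is(x, "NGramModel"))
  x@vocab
}
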
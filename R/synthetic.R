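# Seeded synthetic inputs: a Zipfian lexicon with PoS tags and phoneme
# transcriptions, tag-chain corpora at the three annotation levels,
# word-timed stimulus transcripts, and BOLD volumes with planted,
# recoverable covariate effects.

#' Default synthetic tagset
#'
#' Three base grammatical categories with a handful of fine-grained
#' subcategories each. The category frequency masses are the stationary
#' distribution of \code{\link{defaultTagTransitions}}, so token-level
#' tag frequencies in generated text match the masses used when tags are
#' assigned to lexicon words — which keeps the marginal word-frequency
#' law Zipfian.
#'
#' @return list with \code{tagset} (a \linkS4class{Tagset}) and
#'   \code{mass} (named numeric, category frequency shares).
#' @export
syntheticTagset <- function() {
  list(tagset = new("Tagset",
                    baseTag = c("N", "WW", "LID"),
                    nSubcategories = c(4L, 3L, 2L)),
       mass = stationaryDistribution(defaultTagTransitions()))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P row-stochastic transition matrix.
#' @return named numeric vector summing to 1.
#' @export
stationaryDistribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  setNames(v / sum(v), rownames(P))
}

#' Generate a synthetic lexicon
#'
#' Word frequencies follow a Zipf law (weight proportional to
#' rank^-exponent); each word receives a fixed fine-grained PoS tag (base
#' category sampled by category mass, subcategory uniform) and a fixed
#' phoneme sequence drawn from the inventory, so the grapheme-to-phoneme
#' mapping is a reusable lookup table.
#'
#' @param vocabSize number of word types (>= 10; default 500).
#' @param zipfExponent Zipf exponent (default 1).
#' @param tagsetSpec as returned by \code{\link{syntheticTagset}}.
#' @param phonemeInventory character vector of phoneme symbols (default
#'   30 ASCII symbols).
#' @param seed integer seed; the lexicon is a pure function of the
#'   arguments.
#' @return list of class \code{SyntheticLexicon}: \code{entries}
#'   (data.frame word, tag, baseTag, rank, weight, with phoneme
#'   sequences in \code{phonemes}), \code{tagset}, \code{mass},
#'   \code{phonemeInventory}, \code{seed}.
#' @export
generateLexicon <- function(vocabSize = 500L, zipfExponent = 1,
                            tagsetSpec = syntheticTagset(),
                            phonemeInventory = .defaultPhonemes(),
                            seed = 1L) {
  if (vocabSize < 10L) stop("vocabSize must be >= 10", call. = FALSE)
  ts <- tagsetSpec$tagset
  if (length(ts@baseTag) == 0L) stop("empty tagset", call. = FALSE)
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  rank <- seq_len(vocabSize)
  weight <- rank^(-zipfExponent)
  weight <- weight / sum(weight)
  # mass-balanced tag assignment: words (largest weight first) go to the
  # category with the largest remaining frequency deficit, so each
  # category's realized Zipf mass matches its target mass and the
  # token-level word distribution stays globally Zipfian
  mass <- tagsetSpec$mass[ts@baseTag]
  got <- setNames(numeric(length(ts@baseTag)), ts@baseTag)
  base <- character(vocabSize)
  for (i in rank) {
    deficit <- mass - got
    pick <- ts@baseTag[which.max(deficit)]
    base[i] <- pick
    got[pick] <- got[pick] + weight[i]
  }
  sub <- vapply(base, function(b)
    sample.int(ts@nSubcategories[ts@baseTag == b], 1L), integer(1))
  tag <- sprintf("%s(sub%d)", base, sub)
  nPho <- pmin(7L, 2L + rpois(vocabSize, 1.5))
  phonemes <- lapply(nPho, function(k)
    .samplePhonotactic(k, phonemeInventory))
  entries <- data.frame(word = sprintf("w%04d", rank), tag = tag,
                        baseTag = base, rank = rank, weight = weight,
                        stringsAsFactors = FALSE)
  entries$phonemes <- phonemes
  structure(list(entries = entries, tagset = ts, mass = tagsetSpec$mass,
                 phonemeInventory = phonemeInventory, seed = seed),
            class = "SyntheticLexicon")
}

.defaultPhonemes <- function() {
  # 20 consonants and 10 vowels (long-vowel notation with ":")
  c(letters[1:20], paste0(letters[1:10], ":"))
}

# shared phonotactics: consonant-vowel alternation with Zipf-weighted
# symbol choice within each class, so phoneme trigrams are reused across
# words instead of identifying them
.samplePhonotactic <- function(k, inventory) {
  vowels <- inventory[grepl(":$", inventory)]
  cons <- setdiff(inventory, vowels)
  if (!length(vowels) || !length(cons)) {
    wts <- seq_along(inventory)^-1
    return(sample(inventory, k, replace = TRUE, prob = wts))
  }
  wC <- seq_along(cons)^-1
  wV <- seq_along(vowels)^-1
  isC <- logical(k)
  isC[1] <- runif(1) < 0.7
  if (k > 1)
    for (j in 2:k) isC[j] <- if (isC[j - 1]) runif(1) < 0.1 else
      runif(1) < 0.85
  out <- character(k)
  out[isC] <- sample(cons, sum(isC), replace = TRUE, prob = wC)
  out[!isC] <- sample(vowels, sum(!isC), replace = TRUE, prob = wV)
  out
}

#' Default base-tag transition matrix
#'
#' A row-stochastic matrix over the synthetic base tags with mild
#' category-dependent structure (articles prefer nouns next, nouns prefer
#' verbs), emulating shallow combinatorial constraints.
#'
#' @param tags base tag names (default the synthetic tagset's).
#' @return row-stochastic matrix with tag dimnames.
#' @export
defaultTagTransitions <- function(tags = c("N", "WW", "LID")) {
  P <- matrix(1 / length(tags), length(tags), length(tags),
              dimnames = list(tags, tags))
  if (all(c("N", "WW", "LID") %in% tags)) {
    P["LID", ] <- c(N = 0.8, WW = 0.1, LID = 0.1)[tags]
    P["N", ] <- c(N = 0.2, WW = 0.6, LID = 0.2)[tags]
    P["WW", ] <- c(N = 0.3, WW = 0.2, LID = 0.5)[tags]
  }
  P
}

# vectorized categorical sampling: one draw per row index in `state`
.sampleNext <- function(P, state, u) {
  cum <- t(apply(P, 1L, cumsum))
  1L + rowSums(u > cum[state, , drop = FALSE])
}

# sample `n` tokens' base tags and words; returns data.frame
.sampleTokens <- function(lexicon, P, lengths) {
  tags <- rownames(P)
  byTag <- split(seq_len(nrow(lexicon$entries)),
                 lexicon$entries$baseTag)
  nTot <- sum(lengths)
  sid <- rep.int(seq_along(lengths), lengths)
  posInSent <- sequence(lengths)
  tagIdx <- integer(nTot)
  # initial tags from the category mass, then the Markov chain
  first <- posInSent == 1L
  tagIdx[first] <- sample.int(length(tags), sum(first), replace = TRUE,
                              prob = lexicon$mass[tags])
  maxLen <- max(lengths)
  for (j in 2:max(2L, maxLen)) {
    cur <- which(posInSent == j)
    if (!length(cur)) break
    prev <- tagIdx[cur - 1L]
    tagIdx[cur] <- .sampleNext(P, prev, runif(length(cur)))
  }
  tokTag <- tags[tagIdx]
  wordIdx <- integer(nTot)
  for (tg in tags) {
    at <- which(tokTag == tg)
    if (!length(at)) next
    pool <- byTag[[tg]]
    w <- lexicon$entries$weight[pool]
    wordIdx[at] <- pool[sample.int(length(pool), length(at),
                                   replace = TRUE, prob = w)]
  }
  data.frame(sentence = sid, baseTag = tokTag, wordIdx = wordIdx)
}

#' Generate token-aligned training corpora
#'
#' Sentences are generated by sampling a base-tag chain from the
#' transition matrix and then a word per tag by within-category Zipf
#' weights. Returns three parallel corpora: word forms, fine-grained PoS
#' tags (the sampled word's lexicon tag), and per-word phoneme sequences
#' (one phoneme "sentence" per word token, matching within-word phoneme
#' context).
#'
#' @param lexicon a \code{SyntheticLexicon}.
#' @param tagTransitions row-stochastic base-tag transition matrix.
#' @param nSentences number of sentences (default 50000).
#' @param meanLength mean sentence length in words (default 8).
#' @param seed integer seed.
#' @return list of class \code{SyntheticCorpus} with \code{words},
#'   \code{pos}, \code{phonemes} (each a corpus: list of character
#'   vectors) and the generation parameters.
#' @export
generateCorpus <- function(lexicon, tagTransitions = defaultTagTransitions(),
                           nSentences = 50000L, meanLength = 8,
                           seed = 1L) {
  if (any(abs(rowSums(tagTransitions) - 1) > 1e-9))
    stop("tag transition rows must sum to 1", call. = FALSE)
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  lens <- pmax(1L, rpois(nSentences, meanLength))
  tok <- .sampleTokens(lexicon, tagTransitions, lens)
  words <- split(lexicon$entries$word[tok$wordIdx], tok$sentence)
  pos <- split(lexicon$entries$tag[tok$wordIdx], tok$sentence)
  phon <- lexicon$entries$phonemes[tok$wordIdx]
  structure(list(words = unname(words), pos = unname(pos),
                 phonemes = phon, tokens = tok,
                 nSentences = nSentences, meanLength = meanLength,
                 seed = seed),
            class = "SyntheticCorpus")
}

#' Generate a word-timed stimulus transcript
#'
#' Words are sampled with the same tag-chain process as the training
#' corpora; onsets accumulate exponentially jittered inter-word
#' intervals with mean \code{1 / rate}; durations are proportional to
#' phoneme count with a floor.
#'
#' @param lexicon a \code{SyntheticLexicon}.
#' @param tagTransitions row-stochastic base-tag transition matrix.
#' @param totalDuration run length, seconds.
#' @param rate speech rate, words per second (default 2).
#' @param perPhoneme seconds of duration per phoneme (default 0.06).
#' @param minDuration duration floor, seconds (default 0.12).
#' @param storyId identifier.
#' @param seed integer seed.
#' @return a \linkS4class{StimulusTranscript}.
#' @export
generateTranscript <- function(lexicon,
                               tagTransitions = defaultTagTransitions(),
                               totalDuration = 150, rate = 2,
                               perPhoneme = 0.06, minDuration = 0.12,
                               storyId = "story", seed = 1L) {
  stopifnot(rate > 0, totalDuration > 0)
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  # draw more gaps than needed, then truncate to the run
  nDraw <- ceiling(totalDuration * rate + 10 * sqrt(totalDuration * rate))
  gaps <- rexp(nDraw, rate = rate)
  onsets <- cumsum(gaps)
  onsets <- onsets[onsets < totalDuration - minDuration]
  n <- length(onsets)
  if (n < 1L) stop("run too short for any word", call. = FALSE)
  tok <- .sampleTokens(lexicon, tagTransitions, n)
  words <- lexicon$entries$word[tok$wordIdx]
  tags <- lexicon$entries$tag[tok$wordIdx]
  phon <- lexicon$entries$phonemes[tok$wordIdx]
  dur <- pmax(minDuration, perPhoneme * lengths(phon))
  dur <- pmin(dur, totalDuration - onsets)
  stimulusTranscript(words, tags, phon, onsets, dur, storyId = storyId)
}

#' Ground truth for planted covariate effects
#'
#' Three rectangular ROIs, one per perplexity covariate, arranged so
#' that ROIs overlap pairwise (lexical with PoS, PoS with phonological)
#' but the three-way intersection is empty. Planted amplitudes are in
#' design-column units; \code{effectSD} expresses them as the standard
#' deviation of the stimulus-locked BOLD signal, so effect size is
#' stated in noise units regardless of covariate scale.
#'
#' @param design a \linkS4class{DesignMatrix} whose covariate columns
#'   set the amplitude scale.
#' @param dim volume shape (default \code{c(20, 20, 20)}).
#' @param effectSD standard deviation of the planted signal time course
#'   in BOLD units (default 1, i.e. equal to the default noise sd).
#' @param sigma white/AR(1) innovation noise sd (default 1).
#' @param ar1 temporal AR(1) coefficient of the noise (default 0.3).
#' @param fwhm spatial smoothness of the noise, mm (default 7).
#' @param voxelSize mm (default 3.5).
#' @param subjectSD between-subject amplitude jitter as a fraction of
#'   the amplitude (default 0.1).
#' @return list of class \code{GroundTruth}: \code{rois} (named list of
#'   logical arrays), \code{amplitude} (named, design-column units),
#'   \code{sigma}, \code{ar1}, \code{fwhm}, \code{voxelSize},
#'   \code{subjectSD}.
#' @export
groundTruth <- function(design, dim = c(20L, 20L, 20L), effectSD = 1,
                        sigma = 1, ar1 = 0.3, fwhm = 7,
                        voxelSize = 3.5, subjectSD = 0.1) {
  stopifnot(is(design, "DesignMatrix"), length(dim) == 3L)
  # fractional extents scale with the volume: lexical and phonological
  # cores sit at opposite ends with the PoS ROI bridging both. The
  # lex/pho gap (6 voxels, 21 mm at default scale) is about three times
  # the noise FWHM: cluster-extent inference carries no voxel-level
  # localization guarantee, so exclusive zones must be separated by
  # well more than the noise correlation length to stay resolvable.
  fr <- function(ax, lo, hi)
    max(1L, round(lo * dim[ax])):min(dim[ax], round(hi * dim[ax]))
  box <- function(xr) {
    m <- array(FALSE, dim)
    m[xr, fr(2, 0.25, 0.70), fr(3, 0.30, 0.65)] <- TRUE
    m
  }
  rois <- list(
    ppl_lex = box(fr(1, 0.05, 0.35)),
    ppl_pos = box(fr(1, 0.30, 0.75)),
    ppl_pho = box(fr(1, 0.70, 0.95)))
  if (any(rois$ppl_lex & rois$ppl_pos & rois$ppl_pho))
    stop("three-way ROI intersection must be empty", call. = FALSE)
  info <- design@runInfo
  amp <- vapply(names(rois), function(cov) {
    vals <- unlist(lapply(info$name[!info$reversed], function(rn)
      design@values[design@runLabels == rn, paste(rn, cov, sep = "_")]))
    effectSD / sd(vals)
  }, numeric(1))
  structure(list(rois = rois, amplitude = amp, sigma = sigma, ar1 = ar1,
                 fwhm = fwhm, voxelSize = voxelSize,
                 subjectSD = subjectSD, effectSD = effectSD),
            class = "GroundTruth")
}

#' Generate per-subject motion parameter series
#'
#' Slow random-walk drifts: three translations (mm) and three rotations
#' (radians).
#'
#' @param nVolumes volumes in the run.
#' @param sdStep innovation sd per volume (default 0.02).
#' @return nVolumes x 6 matrix.
#' @export
generateMotion <- function(nVolumes, sdStep = 0.02) {
  apply(matrix(rnorm(nVolumes * 6L, sd = sdStep), nVolumes, 6L), 2L,
        cumsum)
}

#' Simulate BOLD volume series with planted effects
#'
#' For each subject: the covariate regressors of interest of the real
#' runs, scaled by the planted (subject-jittered) amplitudes, are added
#' inside their ROIs; reversed runs carry no stimulus-locked signal.
#' Noise is voxelwise AR(1) with white innovations, spatially smoothed
#' to the target FWHM and restandardized to sd \code{sigma}. Motion
#' regressors are regenerated per subject and substituted into the
#' subject's copy of the design.
#'
#' @param design a \linkS4class{DesignMatrix} (template; motion columns
#'   are replaced per subject).
#' @param truth a \code{\link{groundTruth}} object.
#' @param nSubjects number of subjects (default 12).
#' @param tr repetition time, seconds.
#' @param seed integer seed.
#' @return list of subjects, each with \code{vol} (a
#'   \linkS4class{VolumeSeries} spanning all runs), \code{design} (the
#'   subject's DesignMatrix), \code{amplitudes} (realized planted
#'   amplitudes), \code{subject} (id).
#' @export
generateBold <- function(design, truth, nSubjects = 12L, tr = 0.88,
                         seed = 1L) {
  stopifnot(is(design, "DesignMatrix"), inherits(truth, "GroundTruth"))
  dims <- dim(truth$rois[[1L]])
  for (r in truth$rois)
    if (!identical(dim(r), dims))
      stop("all ROIs must share the volume shape", call. = FALSE)
  info <- design@runInfo
  T <- nrow(design@values)
  nVox <- prod(dims)
  affine <- diag(c(rep(truth$voxelSize, 3), 1))
  oldSeed <- .saveSeed(); on.exit(.restoreSeed(oldSeed))
  set.seed(seed)
  subjects <- vector("list", nSubjects)
  for (s in seq_len(nSubjects)) {
    X <- design@values
    # per-subject motion replaces the template's motion columns
    for (rn in info$name) {
      rows <- which(design@runLabels == rn)
      mcols <- paste(rn, paste0("motion", 1:6), sep = "_")
      X[rows, mcols] <- generateMotion(length(rows))
    }
    subjDesign <- design
    subjDesign@values <- X

    amp <- truth$amplitude * (1 + rnorm(length(truth$amplitude),
                                        sd = truth$subjectSD))
    names(amp) <- names(truth$amplitude)
    signalFlat <- matrix(0, nVox, T)
    for (cov in names(truth$rois)) {
      roiIdx <- which(truth$rois[[cov]])
      course <- numeric(T)
      for (rn in info$name[!info$reversed]) {
        rows <- which(design@runLabels == rn)
        course[rows] <- X[rows, paste(rn, cov, sep = "_")]
      }
      signalFlat[roiIdx, ] <- signalFlat[roiIdx, ] +
        rep(amp[[cov]], length(roiIdx)) %o% course
    }
    # AR(1) noise with white innovations, then spatial smoothing
    if (truth$sigma > 0) {
      innov <- matrix(rnorm(T * nVox, sd = truth$sigma), T, nVox)
      noise <- stats::filter(innov, truth$ar1, method = "recursive")
      noise <- array(t(noise), c(dims, T))
      if (truth$fwhm > truth$voxelSize) {
        noise <- smoothVolume(noise, truth$fwhm, truth$voxelSize)
        # restandardize so sigma keeps its meaning after smoothing
        noise <- noise * (truth$sigma / sd(noise))
      }
      dat <- array(signalFlat, c(dims, T)) + noise
    } else {
      dat <- array(signalFlat, c(dims, T))
    }
    subjects[[s]] <- list(
      vol = volumeSeries(dat, tr = tr, affine = affine),
      design = subjDesign, amplitudes = amp,
      subject = sprintf("sub-%02d", s))
  }
  subjects
}
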
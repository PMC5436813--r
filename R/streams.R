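# The three parallel annotation streams of a stimulus transcript and the
# six per-word covariates derived from them: trigram perplexity and unigram
# log2 frequency at the lexical, part-of-speech and phonological levels.

#' Construct a stimulus transcript
#'
#' @param word character vector of word forms.
#' @param pos character vector of fine-grained PoS tags; subcategory
#'   features, if any, follow the base tag in parentheses
#'   (e.g. \code{"N(soort,ev)"}).
#' @param phonemes list of character vectors, one phoneme sequence per word.
#' @param onset,duration numeric vectors, seconds.
#' @param storyId identifier.
#' @return a \linkS4class{StimulusTranscript}.
#' @export
stimulusTranscript <- function(word, pos, phonemes, onset, duration,
                               storyId = "story") {
  new("StimulusTranscript", storyId = storyId, word = word, pos = pos,
      phonemes = phonemes, onset = as.numeric(onset),
      duration = as.numeric(duration))
}

#' Base tag of a fine-grained PoS tag
#'
#' Strips the parenthesised morpho-syntactic subcategory features, leaving
#' the base grammatical category.
#'
#' @param tag character vector of fine-grained tags.
#' @return character vector of base tags.
#' @export
baseTag <- function(tag) sub("\\(.*$", "", tag)

#' Extract the three annotation streams
#'
#' @param transcript a \linkS4class{StimulusTranscript}.
#' @return list with components \code{words}, \code{pos} (each one symbol
#'   per token), \code{phonemes} (the flattened phoneme sequence) and
#'   \code{phonemeToken} (integer index mapping each phoneme back to its
#'   token).
#' @export
extractStreams <- function(transcript) {
  stopifnot(is(transcript, "StimulusTranscript"))
  list(
    words = transcript@word,
    pos = transcript@pos,
    phonemes = unlist(transcript@phonemes, use.names = FALSE),
    phonemeToken = rep.int(seq_along(transcript@word),
                           lengths(transcript@phonemes))
  )
}

#' Count units per stream
#'
#' @param transcript a \linkS4class{StimulusTranscript}.
#' @return named integer vector: \code{words} (token count),
#'   \code{baseTags} (distinct base grammatical categories) and
#'   \code{phonemes} (total phoneme count).
#' @export
countStreamUnits <- function(transcript) {
  s <- extractStreams(transcript)
  c(words = length(s$words),
    baseTags = length(unique(baseTag(s$pos))),
    phonemes = length(s$phonemes))
}

#' Mean phoneme perplexity of one word
#'
#' The phonological perplexity of a word is the arithmetic mean of the
#' per-phoneme trigram perplexities over that word's phonemes. By default
#' phoneme histories are confined to the word (begin-padded per word);
#' \code{context = "continuous"} lets histories run across word boundaries
#' through the whole transcript.
#'
#' @param model phoneme-level \linkS4class{NGramModel}.
#' @param transcript a \linkS4class{StimulusTranscript}.
#' @param index token index.
#' @param context \code{"within_word"} (default) or \code{"continuous"}.
#' @return mean per-phoneme perplexity (dimensionless).
#' @export
wordPhonemePerplexity <- function(model, transcript, index,
                                  context = c("within_word", "continuous")) {
  context <- match.arg(context)
  stopifnot(is(transcript, "StimulusTranscript"))
  if (context == "within_word") {
    mean(scoreSequence(model, transcript@phonemes[[index]])$perplexity)
  } else {
    s <- extractStreams(transcript)
    ppl <- scoreSequence(model, s$phonemes)$perplexity
    mean(ppl[s$phonemeToken == index])
  }
}

#' Build the six-covariate table for a transcript
#'
#' Computes, per token: trigram perplexity of the word and PoS streams
#' (each scored as one padded sequence over the transcript), the mean
#' per-phoneme trigram perplexity, and unigram log2 relative frequencies
#' at all three levels (phoneme frequency averaged over the word's
#' phonemes). Out-of-vocabulary symbols are mapped to the unknown marker,
#' never dropped.
#'
#' @param transcript a \linkS4class{StimulusTranscript}.
#' @param lexModel,posModel,phoModel trained \linkS4class{NGramModel}s for
#'   the word, PoS and phoneme streams.
#' @param phonemeContext passed to \code{\link{wordPhonemePerplexity}}.
#' @return data.frame with one row per token: token metadata (word, onset,
#'   duration) and columns \code{lex_ppl}, \code{pos_ppl}, \code{pho_ppl},
#'   \code{lex_freq}, \code{pos_freq}, \code{pho_freq}.
#' @export
buildCovariates <- function(transcript, lexModel, posModel, phoModel,
                            phonemeContext = c("within_word",
                                               "continuous")) {
  phonemeContext <- match.arg(phonemeContext)
  s <- extractStreams(transcript)
  n <- length(s$words)

  lexPpl <- scoreSequence(lexModel, s$words)$perplexity
  posPpl <- scoreSequence(posModel, s$pos)$perplexity

  if (phonemeContext == "within_word") {
    phoScores <- lapply(transcript@phonemes, function(ph)
      scoreSequence(phoModel, ph)$perplexity)
    phoPpl <- vapply(phoScores, mean, numeric(1))
  } else {
    allPpl <- scoreSequence(phoModel, s$phonemes)$perplexity
    phoPpl <- as.numeric(tapply(allPpl, s$phonemeToken, mean))
  }

  phoFreqAll <- unigramLog2Freq(phoModel, s$phonemes)
  phoFreq <- as.numeric(tapply(phoFreqAll, s$phonemeToken, mean))

  data.frame(
    word = s$words, onset = transcript@onset,
    duration = transcript@duration,
    lex_ppl = lexPpl, pos_ppl = posPpl, pho_ppl = phoPpl,
    lex_freq = unigramLog2Freq(lexModel, s$words),
    pos_freq = unigramLog2Freq(posModel, s$pos),
    pho_freq = phoFreq
  )
}

.COVARIATE_COLS <- c("lex_ppl", "pos_ppl", "pho_ppl",
                     "lex_freq", "pos_freq", "pho_freq")

#' Pairwise Pearson correlations among the six covariates
#'
#' @param table a covariate table from \code{\link{buildCovariates}}.
#' @return symmetric 6x6 correlation matrix with unit diagonal.
#'   Zero-variance columns yield NA in their row and column, with a
#'   warning, rather than a silent zero.
#' @export
covariateCorrelations <- function(table) {
  cols <- .COVARIATE_COLS
  if (!all(cols %in% names(table)))
    stop("table must contain the six covariate columns", call. = FALSE)
  if (nrow(table) < 3L)
    stop("need at least 3 rows to estimate correlations", call. = FALSE)
  X <- as.matrix(table[, cols])
  sds <- apply(X, 2, sd)
  R <- suppressWarnings(cor(X))
  diag(R) <- 1
  if (any(sds == 0)) {
    warning("zero-variance column(s): ",
            paste(cols[sds == 0], collapse = ", "),
            "; correlations undefined")
    R[sds == 0, ] <- NA_real_
    R[, sds == 0] <- NA_real_
    diag(R)[sds == 0] <- NA_real_
  }
  R
}

# ---- transcript I/O and packaged fixtures ----

#' Read a transcript from an events TSV
#'
#' Tab-separated UTF-8 with columns \code{onset}, \code{duration},
#' \code{word}, \code{pos}, \code{phonemes} (phoneme symbols
#' space-separated within the cell).
#'
#' @param path file path.
#' @param storyId identifier for the resulting transcript.
#' @return a \linkS4class{StimulusTranscript}.
#' @export
readTranscript <- function(path, storyId = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         encoding = "UTF-8", check.names = FALSE)
  need <- c("onset", "duration", "word", "pos", "phonemes")
  if (!all(need %in% names(d)))
    stop("events TSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  stimulusTranscript(
    word = as.character(d$word), pos = as.character(d$pos),
    phonemes = strsplit(trimws(as.character(d$phonemes)), "[[:space:]]+"),
    onset = d$onset, duration = d$duration, storyId = storyId)
}

#' Write a transcript as an events TSV
#' @param transcript a \linkS4class{StimulusTranscript}.
#' @param path output path.
#' @export
writeTranscript <- function(transcript, path) {
  stopifnot(is(transcript, "StimulusTranscript"))
  d <- data.frame(
    onset = transcript@onset, duration = transcript@duration,
    word = transcript@word, pos = transcript@pos,
    phonemes = vapply(transcript@phonemes, paste, character(1),
                      collapse = " "))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a covariate table as TSV
#' @param table data.frame from \code{\link{buildCovariates}}.
#' @param path output path.
#' @export
writeCovariates <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged example sentence
#'
#' A 13-word Dutch sentence annotated at all three levels: word forms,
#' fine-grained PoS tags over 7 distinct base categories, and a 40-phoneme
#' transcription (diphthongs are single symbols).
#'
#' @return a \linkS4class{StimulusTranscript}.
#' @export
exampleTranscript <- function() {
  readTranscript(system.file("extdata", "example_sentence.tsv",
                             package = "perplexityBOLD", mustWork = TRUE),
                 storyId = "example")
}

#' Packaged part-of-speech tagset
#'
#' A CGN-style Dutch tagset summary: 12 base grammatical categories whose
#' fine-grained subcategory counts sum to 320 tags.
#'
#' @return a \linkS4class{Tagset}.
#' @export
cgnTagset <- function() {
  d <- utils::read.delim(
    system.file("extdata", "cgn_tagset.tsv",
                package = "perplexityBOLD", mustWork = TRUE),
    stringsAsFactors = FALSE)
  new("Tagset", baseTag = d$base_tag,
      nSubcategories = as.integer(d$n_subcategories))
}

#' Total number of fine-grained tags in a tagset
#' @param tagset a \linkS4class{Tagset}.
#' @return integer sum of subcategory counts.
#' @export
tagsetTotal <- function(tagset) {
  stopifnot(is(tagset, "Tagset"))
  sum(tagset@nSubcategories)
}
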
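# N-gram language models over symbol streams.
#
# A trigram (second-order Markov) model predicts each symbol from the
# preceding two. Conditional probabilities are Jelinek-Mercer interpolations
# of the maximum-likelihood estimates at each available order, with add-k
# smoothing at the unigram level, so that every conditional distribution is
# proper: for any history the probabilities sum to 1 over the predicted
# vocabulary.

.DEFAULT_MARKERS <- c(begin = "<s>", end = "</s>", unk = "<unk>")

.checkCorpus <- function(corpus) {
  if (!is.list(corpus) || length(corpus) == 0L)
    stop("corpus must be a non-empty list of sentences", call. = FALSE)
  ok <- vapply(corpus, function(s)
    is.character(s) && length(s) > 0L && all(nzchar(s)), logical(1))
  if (!all(ok))
    stop("every sentence must be a non-empty character vector of ",
         "non-empty symbols (offending sentence ", which(!ok)[1], ")",
         call. = FALSE)
  invisible(corpus)
}

#' Train an n-gram language model
#'
#' Counts all n-grams up to \code{order} over the corpus, with each sentence
#' padded by \code{order - 1} begin markers and one end marker; histories
#' never cross sentence boundaries. Symbols occurring fewer than
#' \code{minCount} times are mapped to the unknown marker before counting.
#'
#' @param corpus list of character vectors, one pre-tokenized sentence each.
#' @param order model order; 3 gives the trigram model.
#' @param lambda interpolation weights, one per order from unigram upward;
#'   normalized to sum to 1. Default puts most mass on the highest order.
#' @param addK add-k smoothing constant applied to the unigram estimate.
#' @param minCount minimum training count for a symbol to enter the
#'   vocabulary; rarer symbols become the unknown marker. Default 1 keeps
#'   every attested symbol.
#' @param markers named character vector with begin, end and unk symbols.
#' @return an \linkS4class{NGramModel}.
#' @examples
#' m <- trainNGram(list(c("a", "b", "a", "b")), order = 3)
#' condProb(m, c("a", "b"), "a")
#' @export
trainNGram <- function(corpus, order = 3L,
                       lambda = c(0.1, 0.2, 0.7)[seq_len(order)],
                       addK = 1, minCount = 1L,
                       markers = .DEFAULT_MARKERS) {
  .checkCorpus(corpus)
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 1L)
    stop("order must be a single integer >= 1", call. = FALSE)
  if (length(lambda) != order)
    stop("lambda must supply one weight per order", call. = FALSE)
  lambda <- lambda / sum(lambda)

  raw <- unlist(corpus, use.names = FALSE)
  if (any(raw %in% markers))
    stop("corpus symbols must not collide with the reserved markers",
         call. = FALSE)
  if (minCount > 1L) {
    rawCounts <- table(raw)
    rare <- names(rawCounts)[rawCounts < minCount]
    corpus <- lapply(corpus, function(s) {
      s[s %in% rare] <- markers[["unk"]]
      s
    })
  }

  padded <- lapply(corpus, function(s)
    c(rep(markers[["begin"]], order - 1L), s, markers[["end"]]))
  toks <- unlist(padded, use.names = FALSE)
  sid <- rep.int(seq_along(padded), lengths(padded))
  L <- length(toks)

  counts <- vector("list", order)
  contextCounts <- vector("list", order)
  for (n in seq_len(order)) {
    if (n > L) {
      counts[[n]] <- numeric(0)
      next
    }
    idx <- seq_len(L - n + 1L)
    within <- sid[idx] == sid[idx + n - 1L]
    if (n == 1L) {
      # unigram targets exclude begin padding
      keep <- toks != markers[["begin"]]
      tab <- table(toks[keep])
    } else {
      cols <- lapply(seq_len(n) - 1L, function(o) toks[idx + o])
      # windows predicting a begin pad are not events: drop them so
      # conditional distributions normalize over real targets
      keep <- within & cols[[n]] != markers[["begin"]]
      keys <- do.call(paste, c(cols, sep = .SEP))[keep]
      tab <- table(keys)
      ctxCols <- cols[seq_len(n - 1L)]
      ctxKeys <- if (n == 2L) ctxCols[[1L]][keep] else
        do.call(paste, c(ctxCols, sep = .SEP))[keep]
      ctab <- table(ctxKeys)
      contextCounts[[n]] <- setNames(as.numeric(ctab), names(ctab))
    }
    counts[[n]] <- setNames(as.numeric(tab), names(tab))
  }

  vocab <- sort(unique(c(names(counts[[1L]]), markers[["unk"]])))
  new("NGramModel",
      order = order, vocab = vocab, counts = counts,
      contextCounts = contextCounts,
      total = sum(counts[[1L]]), lambda = lambda,
      addK = as.numeric(addK), minCount = as.integer(minCount),
      markers = markers)
}

# map symbols outside the vocabulary to the unknown marker; the begin
# marker is legal in history position
.mapUnk <- function(model, x) {
  known <- x %in% model@vocab | x == model@markers[["begin"]]
  x[!known] <- model@markers[["unk"]]
  x
}

.lookup <- function(tab, keys) {
  v <- tab[keys]
  v[is.na(v)] <- 0
  unname(v)
}

# vectorized interpolated conditional probability; h1/h2/w recycled
.condProbVec <- function(model, h1, h2, w) {
  w <- .mapUnk(model, w)
  n <- max(length(h1), length(h2), length(w))
  w <- rep_len(w, n)
  V <- length(model@vocab)
  k <- model@addK
  p1 <- (.lookup(model@counts[[1L]], w) + k) / (model@total + k * V)
  p <- model@lambda[1L] * p1
  if (model@order >= 2L) {
    h2 <- rep_len(.mapUnk(model, h2), n)
    ctx1 <- .lookup(model@contextCounts[[2L]], h2)
    c2 <- .lookup(model@counts[[2L]], paste(h2, w, sep = .SEP))
    p2 <- p1
    p2[ctx1 > 0] <- (c2 / ctx1)[ctx1 > 0]
    p <- p + model@lambda[2L] * p2
  }
  if (model@order >= 3L) {
    h1 <- rep_len(.mapUnk(model, h1), n)
    ctx2 <- .lookup(model@contextCounts[[3L]],
                    paste(h1, h2, sep = .SEP))
    c3 <- .lookup(model@counts[[3L]], paste(h1, h2, w, sep = .SEP))
    p3 <- p2
    p3[ctx2 > 0] <- (c3 / ctx2)[ctx2 > 0]
    p <- p + model@lambda[3L] * p3
  }
  p
}

.checkHistory <- function(model, history) {
  need <- model@order - 1L
  if (length(history) != need)
    stop("history must supply ", need, " symbol(s) for an order-",
         model@order, " model", call. = FALSE)
  history
}

#' Conditional probability of a token given its history
#'
#' Interpolated estimate: lambda-weighted combination of the trigram,
#' bigram and add-k unigram maximum-likelihood estimates. When a history
#' is unattested, its term falls back to the next lower-order estimate, so
#' the distribution over the vocabulary always sums to 1. Out-of-vocabulary
#' symbols (in history or target position) are mapped to the unknown marker.
#'
#' @param model an \linkS4class{NGramModel}.
#' @param history character vector of \code{order - 1} preceding symbols
#'   (begin markers for sentence-initial positions).
#' @param token the predicted symbol.
#' @return probability in [0, 1]; 0 only when smoothing is disabled.
#' @export
condProb <- function(model, history, token) {
  stopifnot(is(model, "NGramModel"))
  .checkHistory(model, history)
  h1 <- if (model@order >= 3L) history[length(history) - 1L] else ""
  h2 <- if (model@order >= 2L) history[length(history)] else ""
  .condProbVec(model, h1, h2, token)
}

#' Surprisal of a token in context
#'
#' The negative base-2 logarithm of the conditional probability, in bits.
#' A fully predictable token (probability 1) has surprisal 0; with
#' smoothing disabled a zero-probability token yields \code{Inf} with a
#' warning.
#'
#' @inheritParams condProb
#' @return surprisal in bits (non-negative).
#' @export
surprisal <- function(model, history, token) {
  p <- condProb(model, history, token)
  if (any(p == 0))
    warning("zero probability under unsmoothed model: infinite surprisal")
  -log2(p)
}

#' Per-token perplexity
#'
#' Two raised to the surprisal, i.e. the reciprocal of the conditional
#' probability under base-2 logs: the effective branching factor of the
#' predictive distribution at this token.
#'
#' @inheritParams condProb
#' @return perplexity (>= 1 whenever the probability is at most 1).
#' @export
perplexity <- function(model, history, token) {
  2^surprisal(model, history, token)
}

#' Score every token of a sentence
#'
#' Pads the sentence with begin markers, then computes the conditional
#' probability, surprisal and perplexity of each symbol given its
#' within-sentence history. Padding restarts at each call, so scoring a
#' concatenation of two sentences differs from concatenating their scores.
#'
#' @param model an \linkS4class{NGramModel}.
#' @param sentence character vector of symbols; may be empty.
#' @return data.frame with columns token, probability, surprisal,
#'   perplexity; one row per input symbol.
#' @export
scoreSequence <- function(model, sentence) {
  stopifnot(is(model, "NGramModel"))
  if (length(sentence) == 0L)
    return(data.frame(token = character(), probability = numeric(),
                      surprisal = numeric(), perplexity = numeric()))
  pad <- rep(model@markers[["begin"]], model@order - 1L)
  seqd <- c(pad, sentence)
  n <- length(sentence)
  off <- model@order - 1L
  h1 <- if (model@order >= 3L) seqd[seq_len(n) + off - 2L] else rep("", n)
  h2 <- if (model@order >= 2L) seqd[seq_len(n) + off - 1L] else rep("", n)
  p <- .condProbVec(model, h1, h2, sentence)
  s <- -log2(p)
  data.frame(token = sentence, probability = p, surprisal = s,
             perplexity = 2^s)
}

#' Unigram log2 relative frequency
#'
#' \code{log2(count / total)} over the training unigrams, with
#' out-of-vocabulary symbols mapped to the unknown marker. A zero-count
#' symbol (an unknown marker never attested in training) receives the
#' add-k smoothed estimate so the value stays finite when \code{addK > 0}.
#'
#' @inheritParams condProb
#' @param token symbol whose relative frequency is requested.
#' @return log2 relative frequency in bits (<= 0).
#' @export
unigramLog2Freq <- function(model, token) {
  stopifnot(is(model, "NGramModel"))
  w <- .mapUnk(model, token)
  cnt <- .lookup(model@counts[[1L]], w)
  V <- length(model@vocab)
  k <- model@addK
  ifelse(cnt > 0, log2(cnt / model@total),
         log2((cnt + k) / (model@total + k * V)))
}

# ---- corpus and model I/O ----

#' Read a tokenized corpus
#'
#' One sentence per line, whitespace-separated symbols, UTF-8. The same
#' format serves word, PoS-tag and phoneme corpora.
#'
#' @param path file path.
#' @return list of character vectors.
#' @export
readCorpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("corpus file is empty", call. = FALSE)
  strsplit(trimws(lines), "[[:space:]]+")
}

#' Write a tokenized corpus
#' @param corpus list of character vectors.
#' @param path file path.
#' @export
writeCorpus <- function(corpus, path) {
  .checkCorpus(corpus)
  writeLines(vapply(corpus, paste, character(1), collapse = " "), path,
             useBytes = FALSE)
  invisible(path)
}

#' Serialize a model to versioned JSON
#'
#' The container holds counts, vocabulary and the smoothing configuration
#' and round-trips bit-exactly through \code{\link{readNGramModel}}.
#'
#' @param model an \linkS4class{NGramModel}.
#' @param path output file path.
#' @export
writeNGramModel <- function(model, path) {
  stopifnot(is(model, "NGramModel"))
  obj <- list(
    format = "ngram-model", version = 1L,
    order = model@order, vocab = model@vocab,
    counts = lapply(model@counts, as.list),
    contextCounts = lapply(model@contextCounts, function(x)
      if (is.null(x)) NULL else as.list(x)),
    total = model@total, lambda = model@lambda, addK = model@addK,
    minCount = model@minCount, markers = as.list(model@markers))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model serialized by \code{\link{writeNGramModel}}
#' @param path JSON file path.
#' @return an \linkS4class{NGramModel}.
#' @export
readNGramModel <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "ngram-model"))
    stop("not an n-gram model container", call. = FALSE)
  asNamed <- function(x) {
    if (is.null(x) || length(x) == 0L) return(numeric(0))
    setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  ctx <- lapply(obj$contextCounts, function(x)
    if (is.null(x)) NULL else asNamed(x))
  # pad context list to model order (unigram slot is empty)
  length(ctx) <- as.integer(obj$order)
  new("NGramModel",
      order = as.integer(obj$order),
      vocab = vapply(obj$vocab, as.character, character(1),
                     USE.NAMES = FALSE),
      counts = lapply(obj$counts, asNamed),
      contextCounts = ctx,
      total = as.numeric(obj$total),
      lambda = vapply(obj$lambda, as.numeric, numeric(1),
                      USE.NAMES = FALSE),
      addK = as.numeric(obj$addK),
      minCount = as.integer(obj$minCount),
      markers = setNames(vapply(obj$markers, as.character, character(1),
                                USE.NAMES = FALSE),
                         names(obj$markers)))
}
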
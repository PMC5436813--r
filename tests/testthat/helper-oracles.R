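# Independent brute-force oracles used to validate the package
# implementations on small inputs. These are written with explicit loops
# and plain dictionaries, sharing no code with the package internals.

# -- n-gram oracle ---------------------------------------------------------

# count every n-gram of the padded corpus into a nested list keyed by the
# space-joined n-gram
oracleNGramCounts <- function(corpus, order,
                              begin = "<s>", end = "</s>") {
  tabs <- lapply(seq_len(order), function(i) new.env(parent = emptyenv()))
  bump <- function(env, key) {
    cur <- if (is.null(env[[key]])) 0 else env[[key]]
    env[[key]] <- cur + 1
  }
  for (sent in corpus) {
    padded <- c(rep(begin, order - 1), sent, end)
    for (n in seq_len(order)) {
      for (i in seq_len(length(padded) - n + 1)) {
        gram <- padded[i:(i + n - 1)]
        # a begin pad is never a predicted event
        if (gram[n] == begin) next
        bump(tabs[[n]], paste(gram, collapse = " "))
      }
    }
  }
  lapply(tabs, as.list)
}

# interpolated conditional probability computed by explicit summation:
# lambda-weighted MLEs with lower-order fallback for unattested histories
# and add-k smoothing on the unigram
oracleCondProb <- function(corpus, history, token, order = 3,
                           lambda = c(0.1, 0.2, 0.7), addK = 1,
                           begin = "<s>", end = "</s>", unk = "<unk>") {
  lambda <- lambda / sum(lambda)
  tabs <- oracleNGramCounts(corpus, order, begin, end)
  vocab <- sort(unique(c(unlist(strsplit(names(tabs[[1]]), " ")), unk)))
  getc <- function(n, gram) {
    v <- tabs[[n]][[paste(gram, collapse = " ")]]
    if (is.null(v)) 0 else v
  }
  mapu <- function(x) if (x %in% c(vocab, begin)) x else unk
  token <- mapu(token)
  history <- vapply(history, mapu, character(1))
  total <- sum(unlist(tabs[[1]]))
  V <- length(vocab)
  p1 <- (getc(1, token) + addK) / (total + addK * V)
  p <- lambda[1] * p1
  if (order >= 2) {
    h2 <- history[length(history)]
    ctx1 <- 0
    for (w in c(vocab, begin))
      ctx1 <- ctx1 + getc(2, c(h2, w))
    p2 <- if (ctx1 > 0) getc(2, c(h2, token)) / ctx1 else p1
    p <- p + lambda[2] * p2
  }
  if (order >= 3) {
    h1 <- history[length(history) - 1]
    ctx2 <- 0
    for (w in c(vocab, begin))
      ctx2 <- ctx2 + getc(3, c(h1, h2, w))
    p3 <- if (ctx2 > 0) getc(3, c(h1, h2, token)) / ctx2 else p2
    p <- p + lambda[3] * p3
  }
  p
}

oracleScoreSentence <- function(corpus, sentence, order = 3,
                                lambda = c(0.1, 0.2, 0.7), addK = 1) {
  padded <- c(rep("<s>", order - 1), sentence)
  sapply(seq_along(sentence), function(t) {
    hist <- padded[(t + order - 2 - (order - 2)):(t + order - 2)]
    oracleCondProb(corpus, hist, sentence[t], order, lambda, addK)
  })
}

# -- flood-fill cluster oracle --------------------------------------------

# recursive flood fill over a logical 3D array; returns sizes of all
# connected components under the given connectivity
oracleClusterSizes <- function(bin, connectivity = 26) {
  d <- dim(bin)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(offs)) == 1,
                 "18" = rowSums(abs(offs)) <= 2,
                 "26" = rep(TRUE, nrow(offs)))
  offs <- offs[keep, , drop = FALSE]
  seen <- array(FALSE, d)
  sizes <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!bin[x, y, z] || seen[x, y, z]) next
    # iterative stack-based flood fill
    stack <- matrix(c(x, y, z), ncol = 3)
    seen[x, y, z] <- TRUE
    size <- 0L
    while (nrow(stack) > 0) {
      v <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      size <- size + 1L
      for (k in seq_len(nrow(offs))) {
        nb <- v + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (bin[nb[1], nb[2], nb[3]] && !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          stack <- rbind(stack, nb)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# -- shared tiny fixtures --------------------------------------------------

toyCorpus <- function() {
  list(c("the", "cat", "sat"),
       c("the", "dog", "sat", "down"),
       c("a", "cat", "ran"))
}

# a quick transcript with arbitrary but valid annotations
tinyTranscript <- function(words, storyId = "tiny") {
  n <- length(words)
  stimulusTranscript(
    word = words,
    pos = rep(c("N(a)", "WW(b)"), length.out = n),
    phonemes = lapply(words, function(w) strsplit(w, "")[[1]]),
    onset = seq(0, by = 0.5, length.out = n),
    duration = rep(0.4, n),
    storyId = storyId)
}
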
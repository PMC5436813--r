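# trigram model training, conditional probabilities, surprisal,
# perplexity, frequencies, and serialization

test_that("training produces brute-force sliding-window counts", {
  m <- trainNGram(list(c("a", "b", "a", "b")), order = 3)
  sep <- "\x1f"
  expect_equal(unname(m@counts[[3]][paste("<s>", "<s>", "a", sep = sep)]),
               1)
  expect_equal(unname(m@counts[[3]][paste("a", "b", "a", sep = sep)]), 1)
  expect_equal(unname(m@counts[[1]]["a"]), 2)
  expect_equal(unname(m@counts[[1]]["</s>"]), 1)

  m1 <- trainNGram(list("a"), order = 1)
  expect_equal(unname(m1@counts[[1]]["a"]), 1)
  expect_equal(unname(m1@counts[[1]]["</s>"]), 1)

  # oracle agreement on every attested trigram of a larger toy corpus
  oc <- oracleNGramCounts(toyCorpus(), 3)
  m2 <- trainNGram(toyCorpus(), order = 3)
  for (key in names(oc[[3]])) {
    parts <- strsplit(key, " ")[[1]]
    expect_equal(unname(m2@counts[[3]][paste(parts, collapse = sep)]),
                 oc[[3]][[key]], info = key)
  }
})

test_that("training is deterministic and rejects invalid input", {
  m1 <- trainNGram(toyCorpus(), order = 3)
  m2 <- trainNGram(toyCorpus(), order = 3)
  expect_identical(m1@counts, m2@counts)
  expect_error(trainNGram(list(), order = 3), "non-empty")
  expect_error(trainNGram(toyCorpus(), order = 0), "order")
  expect_error(trainNGram(list(c("a", "")), order = 2), "non-empty")
})

test_that("conditional probabilities normalize over the vocabulary", {
  m <- trainNGram(toyCorpus(), order = 3)
  v <- vocabulary(m)
  # attested, partially attested and unattested histories
  for (h in list(c("the", "cat"), c("<s>", "the"), c("cat", "never"),
                 c("zz", "qq"))) {
    expect_equal(sum(condProb(m, h, v)), 1, tolerance = 1e-9)
  }
})

test_that("random-history normalization holds on a random corpus", {
  set.seed(42)
  syms <- paste0("s", 1:12)
  corpus <- replicate(15, sample(syms, sample(3:8, 1), replace = TRUE),
                      simplify = FALSE)
  m <- trainNGram(corpus, order = 3, lambda = c(0.25, 0.35, 0.4),
                  addK = 0.5)
  v <- vocabulary(m)
  for (i in 1:100) {
    h <- sample(c(syms, "<s>", "unseen"), 2, replace = TRUE)
    expect_equal(sum(condProb(m, h, v)), 1, tolerance = 1e-9)
  }
})

test_that("cond_prob, surprisal, perplexity match the brute-force oracle", {
  corpus <- toyCorpus()
  lambda <- c(0.1, 0.3, 0.6)
  m <- trainNGram(corpus, order = 3, lambda = lambda, addK = 1)
  cases <- list(
    list(h = c("the", "cat"), w = "sat"),
    list(h = c("<s>", "<s>"), w = "the"),
    list(h = c("<s>", "the"), w = "dog"),
    list(h = c("dog", "sat"), w = "down"),
    list(h = c("cat", "sat"), w = "unknown-word"),
    list(h = c("never", "seen"), w = "cat"))
  for (cs in cases) {
    po <- oracleCondProb(corpus, cs$h, cs$w, order = 3,
                         lambda = lambda, addK = 1)
    p <- condProb(m, cs$h, cs$w)
    expect_equal(p, po, tolerance = 1e-12)
    expect_equal(surprisal(m, cs$h, cs$w), -log2(po),
                 tolerance = 1e-12)
    expect_equal(perplexity(m, cs$h, cs$w), 1 / po,
                 tolerance = 1e-12)
  }
})

test_that("deterministic continuation yields probability one", {
  # "b" always follows ("a","a"); pure trigram weight, no smoothing
  corpus <- list(c("a", "a", "b", "a", "a", "b"))
  m <- trainNGram(corpus, order = 3, lambda = c(0, 0, 1), addK = 0)
  expect_equal(condProb(m, c("a", "a"), "b"), 1)
  expect_equal(surprisal(m, c("a", "a"), "b"), 0)
  expect_equal(perplexity(m, c("a", "a"), "b"), 1)
})

test_that("surprisal and perplexity identities hold", {
  m <- trainNGram(toyCorpus(), order = 3)
  # analytic anchors: p = 1 -> 0 bits -> ppl 1; p = 0.5 -> 1 bit;
  # p = 0.25 -> 2 bits -> ppl 4
  expect_equal(-log2(1), 0)
  expect_equal(-log2(0.5), 1)
  expect_equal(-log2(0.25), 2)
  sc <- scoreSequence(m, c("the", "cat", "sat"))
  expect_equal(sc$surprisal, -log2(sc$probability))
  expect_identical(sc$perplexity, 2^sc$surprisal)
  # monotonicity: perplexity strictly decreasing in probability
  ord <- order(sc$probability)
  expect_true(all(diff(sc$perplexity[ord]) < 0 |
                    diff(sc$probability[ord]) == 0))
})

test_that("unsmoothed zero probability warns and returns Inf", {
  m <- trainNGram(list(c("a", "b")), order = 2, lambda = c(0, 1),
                  addK = 0)
  expect_warning(s <- surprisal(m, "a", "<unk>"), "zero probability")
  expect_identical(s, Inf)
})

test_that("scoreSequence respects padding and matches the oracle", {
  corpus <- toyCorpus()
  m <- trainNGram(corpus, order = 3)
  one <- scoreSequence(m, "the")
  expect_equal(nrow(one), 1L)
  expect_equal(one$probability,
               condProb(m, c("<s>", "<s>"), "the"))
  expect_equal(nrow(scoreSequence(m, character(0))), 0L)

  s1 <- c("the", "cat")
  s2 <- c("sat", "down")
  joint <- scoreSequence(m, c(s1, s2))
  parts <- rbind(scoreSequence(m, s1), scoreSequence(m, s2))
  expect_false(isTRUE(all.equal(joint$probability, parts$probability)))

  sent <- c("a", "cat", "sat", "down")
  expect_equal(scoreSequence(m, sent)$probability,
               oracleScoreSentence(corpus, sent), tolerance = 1e-12)
})

test_that("unigram log2 frequency matches hand counts", {
  m1 <- trainNGram(list("only"), order = 1)
  # "only" is 1 of 2 unigram tokens (word + end marker)
  expect_equal(unigramLog2Freq(m1, "only"), -1)
  m <- trainNGram(list(c("a", "b", "b")), order = 2)
  # tokens: a, b, b, </s>: a has relative frequency 1/4
  expect_equal(unigramLog2Freq(m, "a"), -2)
  expect_equal(unigramLog2Freq(m, "b"), log2(2 / 4))
  # unknown symbol: finite smoothed estimate
  expect_true(is.finite(unigramLog2Freq(m, "zzz")))
})

test_that("rare symbols map to the unknown marker under minCount", {
  corpus <- list(c("a", "a", "a", "rare"), c("a", "a"))
  m <- trainNGram(corpus, order = 2, minCount = 2L)
  expect_false("rare" %in% vocabulary(m))
  expect_equal(unname(m@counts[[1]]["<unk>"]), 1)
})

test_that("model JSON serialization round-trips bit-exactly", {
  m <- trainNGram(toyCorpus(), order = 3, lambda = c(0.2, 0.3, 0.5),
                  addK = 0.25)
  path <- withr::local_tempfile(fileext = ".json")
  writeNGramModel(m, path)
  m2 <- readNGramModel(path)
  expect_identical(m@counts, m2@counts)
  expect_identical(m@contextCounts, m2@contextCounts)
  expect_identical(m@vocab, m2@vocab)
  expect_identical(m@lambda, m2@lambda)
  expect_identical(condProb(m, c("the", "cat"), "sat"),
                   condProb(m2, c("the", "cat"), "sat"))
})

test_that("corpus text round-trips through one-sentence-per-line files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeCorpus(toyCorpus(), path)
  expect_identical(readCorpus(path), toyCorpus())
})
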
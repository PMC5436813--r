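# annotation streams, covariate construction and correlation diagnostics

test_that("the example sentence fixture has 13 words, 7 base tags, 40 phonemes", {
  tr <- exampleTranscript()
  s <- extractStreams(tr)
  expect_length(s$words, 13L)
  expect_length(s$pos, 13L)
  expect_length(s$phonemes, 40L)
  expect_identical(unname(countStreamUnits(tr)), c(13L, 7L, 40L))
})

test_that("the packaged tagset's subcategory counts sum to 320", {
  ts <- cgnTagset()
  expect_identical(tagsetTotal(ts), 320L)
  expect_true(all(ts@nSubcategories >= 1L))
})

test_that("stream extraction preserves lengths, alignment and order", {
  tr <- tinyTranscript(c("ab", "cde", "f"))
  s <- extractStreams(tr)
  expect_length(s$words, 3L)
  expect_length(s$phonemes, 6L)
  expect_identical(s$phonemeToken, c(1L, 1L, 2L, 2L, 2L, 3L))

  one <- tinyTranscript("xy")
  s1 <- extractStreams(one)
  expect_identical(c(length(s1$words), length(s1$pos),
                     length(s1$phonemes)), c(1L, 1L, 2L))

  # concatenating transcripts concatenates all three streams
  a <- tinyTranscript(c("ab", "cd"))
  b <- tinyTranscript(c("ef", "gh"))
  both <- stimulusTranscript(
    c(a@word, b@word), c(a@pos, b@pos), c(a@phonemes, b@phonemes),
    c(a@onset, max(a@onset) + 1 + b@onset),
    c(a@duration, b@duration))
  sa <- extractStreams(a); sb <- extractStreams(b)
  sBoth <- extractStreams(both)
  expect_identical(sBoth$words, c(sa$words, sb$words))
  expect_identical(sBoth$phonemes, c(sa$phonemes, sb$phonemes))
})

test_that("unit counting respects base-tag identity", {
  tr <- tinyTranscript(c("ab", "cd"))
  # duplicating tokens doubles words and phonemes, not distinct tags
  dup <- stimulusTranscript(
    rep(tr@word, 2), rep(tr@pos, 2), rep(tr@phonemes, 2),
    seq(0, by = 0.5, length.out = 4), rep(0.4, 4))
  c1 <- countStreamUnits(tr); c2 <- countStreamUnits(dup)
  expect_identical(unname(c2["words"]), unname(2L * c1["words"]))
  expect_identical(unname(c2["phonemes"]), unname(2L * c1["phonemes"]))
  expect_identical(unname(c2["baseTags"]), unname(c1["baseTags"]))
  # a token with one word and two phonemes counts (1, 1, 2)
  single <- stimulusTranscript("ab", "N", list(c("a", "b")), 0, 0.3)
  expect_identical(unname(countStreamUnits(single)), c(1L, 1L, 2L))
})

test_that("invalid transcripts are rejected", {
  expect_error(stimulusTranscript("a", "N", list(character(0)), 0, 0.3),
               "phoneme")
  expect_error(stimulusTranscript(c("a", "b"), c("N", "N"),
                                  list("a", "b"), c(1, 0), c(0.3, 0.3)),
               "non-decreasing")
  expect_error(stimulusTranscript(character(0), character(0), list(),
                                  numeric(0), numeric(0)),
               "at least one token")
})

test_that("word phoneme perplexity is the mean over the word's phonemes", {
  # model in which every phoneme continuation is deterministic
  det <- trainNGram(list(c("p", "q", "r")), order = 3,
                    lambda = c(0, 0, 1), addK = 0)
  tr <- stimulusTranscript("pqr", "N", list(c("p", "q", "r")), 0, 0.3)
  expect_equal(wordPhonemePerplexity(det, tr, 1), 1)

  # mean of per-phoneme perplexities equals the oracle mean
  corpus <- list(c("p", "q"), c("p", "r"), c("q", "p"))
  m <- trainNGram(corpus, order = 3)
  tr2 <- stimulusTranscript("pq", "N", list(c("p", "q")), 0, 0.3)
  oracle <- mean(1 / oracleScoreSentence(corpus, c("p", "q")))
  expect_equal(wordPhonemePerplexity(m, tr2, 1), oracle,
               tolerance = 1e-12)
})

.covCols <- function() c("lex_ppl", "pos_ppl", "pho_ppl",
                         "lex_freq", "pos_freq", "pho_freq")

test_that("covariate tables align with tokens and match oracle recomputation", {
  wordCorpus <- toyCorpus()
  posCorpus <- list(c("N(a)", "WW(b)", "N(a)"), c("WW(b)", "N(a)"))
  phoCorpus <- list(c("t", "h", "e"), c("c", "a", "t"), c("s", "a", "t"))
  lexM <- trainNGram(wordCorpus, order = 3)
  posM <- trainNGram(posCorpus, order = 3)
  phoM <- trainNGram(phoCorpus, order = 3)

  tr <- stimulusTranscript(
    word = c("the", "cat"), pos = c("N(a)", "WW(b)"),
    phonemes = list(c("t", "h", "e"), c("c", "a", "t")),
    onset = c(0, 0.5), duration = c(0.4, 0.4))
  tab <- buildCovariates(tr, lexM, posM, phoM)
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.finite(as.matrix(tab[, .covCols()]))))
  expect_identical(tab$word, tr@word)

  # oracle recomputation of all six columns
  expect_equal(tab$lex_ppl,
               1 / oracleScoreSentence(wordCorpus, c("the", "cat")),
               tolerance = 1e-12)
  expect_equal(tab$pos_ppl,
               1 / oracleScoreSentence(posCorpus, c("N(a)", "WW(b)")),
               tolerance = 1e-12)
  expect_equal(tab$pho_ppl[1],
               mean(1 / oracleScoreSentence(phoCorpus, c("t", "h", "e"))),
               tolerance = 1e-12)
  expect_equal(tab$lex_freq, unigramLog2Freq(lexM, c("the", "cat")))
  expect_equal(tab$pho_freq[2],
               mean(unigramLog2Freq(phoM, c("c", "a", "t"))))

  # single-token transcript: one row, all finite
  tr1 <- stimulusTranscript("the", "N(a)", list(c("t", "h", "e")), 0, 0.3)
  tab1 <- buildCovariates(tr1, lexM, posM, phoM)
  expect_equal(nrow(tab1), 1L)
  expect_true(all(is.finite(as.matrix(tab1[, .covCols()]))))

  # pure function: identical inputs give identical tables
  expect_identical(tab, buildCovariates(tr, lexM, posM, phoM))
})

test_that("covariate correlations have unit diagonal and flag zero variance", {
  set.seed(1)
  tab <- data.frame(lex_ppl = rnorm(10), pos_ppl = rnorm(10),
                    pho_ppl = rnorm(10), lex_freq = rnorm(10),
                    pos_freq = rnorm(10), pho_freq = rnorm(10))
  R <- covariateCorrelations(tab)
  expect_equal(unname(diag(R)), rep(1, 6))
  expect_equal(R, t(R))
  # a column against its own copy correlates exactly 1
  tab2 <- tab; tab2$pos_ppl <- tab2$lex_ppl
  expect_equal(covariateCorrelations(tab2)["lex_ppl", "pos_ppl"], 1)
  # hand-computed 3-row Pearson r
  tab3 <- tab[1:3, ]
  tab3$lex_ppl <- c(1, 2, 4); tab3$lex_freq <- c(3, 1, 0)
  handR <- sum((tab3$lex_ppl - mean(tab3$lex_ppl)) *
                 (tab3$lex_freq - mean(tab3$lex_freq))) /
    sqrt(sum((tab3$lex_ppl - mean(tab3$lex_ppl))^2) *
           sum((tab3$lex_freq - mean(tab3$lex_freq))^2))
  expect_equal(covariateCorrelations(tab3)["lex_ppl", "lex_freq"], handR)
  # zero-variance columns are flagged NA, not silently zero
  tabz <- tab; tabz$pho_freq <- 1
  expect_warning(Rz <- covariateCorrelations(tabz), "zero-variance")
  expect_true(all(is.na(Rz["pho_freq", ])))
  expect_false(anyNA(Rz[.covCols()[1:5], .covCols()[1:5]]))
})

test_that("transcripts round-trip through events TSV", {
  tr <- exampleTranscript()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTranscript(tr, path)
  tr2 <- readTranscript(path, storyId = "example")
  expect_identical(tr@word, tr2@word)
  expect_identical(tr@phonemes, tr2@phonemes)
  expect_equal(tr@onset, tr2@onset)
})
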
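test_that("inventory respects consistency proportions and typicality structure", {
  inv <- generate_inventory(n_chars = 300, prop_consistent = 1 / 3, seed = 7)
  # about one third single-pronunciation
  expect_equal(sum(inv$consistent), 100)
  pt <- inv$pron_table
  for (pos in 1:2) {
    per_char <- table(pt$char[pt$position == pos])
    expect_true(all(per_char[inv$consistent] == 1))
    expect_true(all(per_char[!inv$consistent] >= 2))
  }
  # type frequencies distinct within every (char, position): strictly one
  # modal pronunciation
  by_cp <- split(pt, paste(pt$char, pt$position))
  expect_true(all(vapply(by_cp, function(d) {
    !anyDuplicated(d$type_freq) && sum(d$modal) == 1 && all(d$type_freq >= 1)
  }, logical(1))))
})

test_that("inventory generation is deterministic and validates input", {
  a <- generate_inventory(n_chars = 40, seed = 3)
  b <- generate_inventory(n_chars = 40, seed = 3)
  expect_identical(a, b)
  expect_error(generate_inventory(n_chars = 4), "n_chars")
  expect_error(generate_inventory(n_chars = 40, max_pronunciations = 1),
               "max_pronunciations")
  # degenerate limit: everything consistent, flagged
  expect_warning(inv1 <- generate_inventory(n_chars = 40,
                                            prop_consistent = 1, seed = 1),
                 "consistent")
  expect_true(all(inv1$consistent))
})

test_that("semantic prototypes and exemplars have the required bit counts", {
  inv <- generate_inventory(n_chars = 50, seed = 11)
  expect_true(all(rowSums(inv$prototypes) == 30))
  sem <- generate_semantics(c(3, 17), inv, seed = 5)
  expect_length(sem, 100)
  expect_equal(sum(sem), 40)                    # two 20-bit exemplars
  expect_equal(sum(sem[1:50]), 20)
  # exemplar on-bits are a subset of the prototype's
  expect_true(all(which(sem[1:50] == 1) %in% which(inv$prototypes[3, ] == 1)))
  expect_true(all(which(sem[51:100] == 1) %in% which(inv$prototypes[17, ] == 1)))
  expect_error(generate_semantics(c(1, 999), inv), "outside")
})

test_that("same-prototype exemplars overlap by at least 10 on-bits", {
  # pigeonhole: each exemplar removes 10 of the 30 prototype on-bits, so two
  # exemplars share >= 30 - 10 - 10 = 10; checked by explicit counting
  inv <- generate_inventory(n_chars = 20, seed = 2)
  for (i in 1:50) {
    ch <- (i %% 20) + 1
    e1 <- generate_semantics(c(ch, 1), inv, seed = i)[1:50]
    e2 <- generate_semantics(c(ch, 1), inv, seed = i + 1000)[1:50]
    expect_gte(sum(e1 * e2), 10)
  }
})

test_that("within-character semantic overlap exceeds between-character overlap", {
  lex <- tiny_lexicon()
  w <- lex$words
  set.seed(1)
  same <- c(); diff <- c()
  for (i in 1:150) {
    pair <- sample(nrow(w), 2)
    ov1 <- sum(lex$semantics[pair[1], 1:50] * lex$semantics[pair[2], 1:50])
    if (w$char1[pair[1]] == w$char1[pair[2]]) same <- c(same, ov1) else
      diff <- c(diff, ov1)
  }
  # guarantee some same-character pairs exist
  sc <- which(duplicated(w$char1) | duplicated(w$char1, fromLast = TRUE))
  for (ch in unique(w$char1[sc])[1:10]) {
    ix <- which(w$char1 == ch)[1:2]
    same <- c(same, sum(lex$semantics[ix[1], 1:50] * lex$semantics[ix[2], 1:50]))
  }
  expect_gt(mean(same), mean(diff))
})

test_that("build_words constructs aligned patterns and derivable conditions", {
  lex <- tiny_lexicon()
  inv <- lex$inventory
  n <- nrow(lex$words)
  expect_equal(dim(lex$orthography), c(n, 2 * inv$visual_bits))
  expect_equal(dim(lex$phonology),
               c(n, inv$mora_slots * inv$mora_feature_bits))
  expect_equal(dim(lex$semantics), c(n, 100))
  expect_true(all(rowSums(lex$semantics) == 40))
  # orthography is the concatenation of the two characters' visual codes
  i <- 5
  expect_equal(lex$orthography[i, ],
               c(inv$visual[lex$words$char1[i], ],
                 inv$visual[lex$words$char2[i], ]))
  # a relabeling pass reproduces the stored conditions exactly
  expect_identical(derive_conditions(lex), lex$words$condition)
  # conditions partition as specified
  pt <- inv$pron_table
  key <- paste(pt$char, pt$position, pt$pron)
  w <- lex$words
  at <- w[w$condition == "atypical", ]
  expect_true(all(!pt$modal[match(paste(at$char1, 1, at$pron1), key)]))
  expect_true(all(!pt$modal[match(paste(at$char2, 2, at$pron2), key)]))
  co <- w[w$condition == "consistent", ]
  expect_true(all(inv$consistent[co$char1] & inv$consistent[co$char2]))
  expect_error(build_words(lex$inventory, n_words = 0), "positive")
})

test_that("friends_ratio matches a brute-force toy computation", {
  lex <- tiny_lexicon()
  w <- lex$words
  # brute-force re-computation for a handful of words
  for (i in c(1, 10, 25, 60)) {
    r <- tryCatch(friends_ratio(i, lex), error = function(e) NA_real_)
    nb1 <- setdiff(which(w$char1 == w$char1[i]), i)
    nb2 <- setdiff(which(w$char2 == w$char2[i]), i)
    if (length(nb1) == 0 || length(nb2) == 0) {
      expect_true(is.na(r))
    } else {
      manual <- mean(c(mean(w$pron1[nb1] == w$pron1[i]),
                       mean(w$pron2[nb2] == w$pron2[i])))
      expect_equal(r, manual)
    }
  }
  # words in the consistent condition always score exactly 1
  cons <- which(w$condition == "consistent")
  for (i in cons) {
    r <- tryCatch(friends_ratio(i, lex), error = function(e) NA_real_)
    if (!is.na(r)) expect_identical(r, 1)
  }
  expect_error(friends_ratio("nope", lex), "unknown word")
})

test_that("friends_ratio signals an empty neighborhood explicitly", {
  inv <- generate_inventory(n_chars = 30, seed = 1)
  lex <- suppressWarnings(build_words(inv, n_words = 30, seed = 1))
  w <- lex$words
  lonely <- which(!(w$char1 %in% w$char1[duplicated(w$char1)]))
  if (length(lonely) > 0) {
    expect_error(friends_ratio(lonely[1], lex), "neighborhood")
  } else {
    succeed("no lonely word in this draw")
  }
})

test_that("test-set selection hits the configured bands and constraints", {
  lex <- tiny_lexicon()
  st <- test_set_stats(lex)
  expect_equal(nrow(st), 3)
  expect_equal(st$n, rep(4, 3))
  expect_equal(st$mean_ratio[st$condition == "consistent"], 1.0)
  expect_lt(abs(st$mean_ratio[st$condition == "typical"] - 0.71), 0.05 + 1e-9)
  expect_lt(abs(st$mean_ratio[st$condition == "atypical"] - 0.33), 0.05 + 1e-9)
  # every test word's characters occur in at least 2 other words
  idx <- match(lex$test_ids, lex$words$word_id)
  nbs <- kanjinet:::neighborhood_sizes(lex)
  expect_true(all(nbs[idx, ] >= 2))
  # atypical test words are non-modal at both positions, re-derived from the
  # inventory's type frequencies
  expect_true(all(lex$words$condition[idx] %in%
                    c("consistent", "typical", "atypical")))
  expect_error(select_test_set(lex, n_per_condition = 0), "positive")
})

test_that("lexicon generation is seed-reproducible end to end", {
  a <- generate_lexicon(n_chars = 30, n_words = 150, n_per_condition = 4,
                        seed = 42, max_retries = 20)
  b <- tiny_lexicon()
  expect_identical(a$words, b$words)
  expect_identical(a$test_ids, b$test_ids)
  expect_identical(a$phonology, b$phonology)
})

test_that("lexicon round-trips through TSV + JSON", {
  lex <- tiny_lexicon()
  tmp <- file.path(tempdir(), "lexrt")
  write_lexicon(lex, tmp)
  back <- read_lexicon(tmp)
  expect_equal(back$words$word_id, lex$words$word_id)
  expect_equal(back$words$frequency, lex$words$frequency)
  expect_identical(back$test_ids, lex$test_ids)
  expect_equal(back$orthography, lex$orthography,
               ignore_attr = TRUE)
  expect_equal(back$phonology, lex$phonology, ignore_attr = TRUE)
  expect_identical(derive_conditions(back), back$words$condition)
  # friends ratios identical after the round trip
  idx <- match(lex$test_ids, lex$words$word_id)
  expect_equal(vapply(idx, friends_ratio, numeric(1), lexicon = back),
               vapply(idx, friends_ratio, numeric(1), lexicon = lex))
})
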
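## Synthetic quasiregular lexicon: characters with position-dependent
## pronunciations, two-character words, semantic prototype/exemplar vectors,
## friends/neighbors ratios and condition-balanced test-set selection.

#' Generate a synthetic character inventory
#'
#' Creates a set of abstract characters, each with a binary visual feature
#' vector, a 50-bit semantic prototype (exactly 30 on-bits), and one or more
#' legitimate pronunciations per word position. A configurable fraction of
#' characters is *consistent* (a single pronunciation per position); the rest
#' are *inconsistent* with 2..`max_pronunciations` pronunciations whose type
#' frequencies are distinct, so exactly one pronunciation is strictly most
#' typical at each position.
#'
#' Pronunciations are mora sequences of length 1-2 drawn from a synthetic mora
#' inventory; each mora carries a binary distinctive-feature vector. Identical
#' mora sequences across characters share a sequence id (homophony), but the
#' pronunciations of one character at one position are always distinct.
#'
#' @param n_chars Number of characters (>= 6).
#' @param n_positions Word positions (the package models 2-character words).
#' @param prop_consistent Fraction of characters with a single pronunciation.
#' @param max_pronunciations Upper bound on pronunciations per position for
#'   inconsistent characters (>= 2).
#' @param n_morae Size of the mora inventory.
#' @param mora_features Binary distinctive features per mora.
#' @param visual_bits Bits in each character's visual feature vector.
#' @param seed Integer seed; the same seed reproduces the inventory exactly.
#' @return An object of class `knet_inventory`.
#' @export
generate_inventory <- function(n_chars = 300L, n_positions = 2L,
                               prop_consistent = 1 / 3,
                               max_pronunciations = 3L,
                               n_morae = 40L, mora_features = 10L,
                               visual_bits = 30L, seed = 1L) {
  if (n_chars < 6L) stop("n_chars must be at least 6")
  if (prop_consistent <= 0 || prop_consistent >= 1) {
    if (prop_consistent != 1) stop("prop_consistent must be in (0, 1]")
  }
  if (max_pronunciations < 2L) stop("max_pronunciations must be >= 2")
  if (prop_consistent == 1) {
    warning("all characters consistent: typical/atypical conditions cannot be constructed")
  }

  with_seed(seed, {
    ## mora feature vectors: distinct, non-zero (all-zero row = padding)
    mora_mat <- matrix(0L, n_morae, mora_features)
    seen <- character(0)
    for (m in seq_len(n_morae)) {
      repeat {
        v <- stats::rbinom(mora_features, 1L, 0.5)
        key <- paste(v, collapse = "")
        if (sum(v) > 0L && !(key %in% seen)) break
      }
      seen <- c(seen, key)
      mora_mat[m, ] <- v
    }

    ## visual features, distinct per character
    visual <- matrix(0L, n_chars, visual_bits)
    seen <- character(0)
    for (ch in seq_len(n_chars)) {
      repeat {
        v <- stats::rbinom(visual_bits, 1L, 0.5)
        key <- paste(v, collapse = "")
        if (!(key %in% seen)) break
      }
      seen <- c(seen, key)
      visual[ch, ] <- v
    }

    ## 50-bit semantic prototypes with exactly 30 on-bits
    prototypes <- t(vapply(seq_len(n_chars), function(ch) {
      v <- integer(50)
      v[sample.int(50, 30)] <- 1L
      v
    }, integer(50)))

    consistent <- rep(FALSE, n_chars)
    consistent[sample.int(n_chars, round(prop_consistent * n_chars))] <- TRUE
    if (prop_consistent == 1) consistent[] <- TRUE

    ## global registry of mora sequences (content-deduplicated)
    seq_key <- character(0)
    pron_seqs <- list()
    register_seq <- function(morae) {
      key <- paste(morae, collapse = "-")
      hit <- match(key, seq_key)
      if (!is.na(hit)) return(hit)
      seq_key[[length(seq_key) + 1L]] <<- key
      pron_seqs[[length(pron_seqs) + 1L]] <<- morae
      length(pron_seqs)
    }
    draw_seq <- function() {
      len <- sample(1:2, 1L)
      sample.int(n_morae, len, replace = TRUE)
    }

    rows <- vector("list", n_chars * n_positions)
    ri <- 0L
    for (ch in seq_len(n_chars)) {
      for (pos in seq_len(n_positions)) {
        k <- if (consistent[ch]) 1L else {
          if (max_pronunciations == 2L) 2L else {
            sample(2:max_pronunciations, 1L,
                   prob = c(0.8, rep(0.2 / (max_pronunciations - 2L),
                                     max_pronunciations - 2L)))
          }
        }
        sids <- integer(0)
        while (length(sids) < k) {
          sid <- register_seq(draw_seq())
          if (!(sid %in% sids)) sids <- c(sids, sid)
        }
        ## type frequencies: modal share in (0.5, 0.85); distinct integer
        ## counts out of 1000 so one pronunciation is strictly most typical
        if (k == 1L) {
          tf <- 1000L
        } else {
          u <- stats::runif(1, 0.5, 0.85)
          rest <- stats::runif(k - 1L)
          shares <- c(u, (1 - u) * rest / sum(rest))
          tf <- round(shares * 1000)
          tf[tf < 1] <- 1
          while (anyDuplicated(tf)) {
            d <- which(duplicated(tf))
            tf[d] <- tf[d] + seq_along(d)
          }
        }
        ri <- ri + 1L
        rows[[ri]] <- data.frame(char = ch, position = pos, pron = sids,
                                 type_freq = as.integer(tf),
                                 modal = tf == max(tf))
      }
    }
    pron_table <- do.call(rbind, rows)

    structure(list(
      n_chars = n_chars, n_positions = n_positions,
      visual_bits = visual_bits, n_morae = n_morae,
      mora_feature_bits = mora_features, mora_slots = 3L * n_positions,
      mora_features = mora_mat, visual = visual, prototypes = prototypes,
      pron_seqs = pron_seqs, pron_table = pron_table,
      consistent = consistent, prop_consistent = prop_consistent,
      seed = as.integer(seed)
    ), class = "knet_inventory")
  })
}

#' @export
print.knet_inventory <- function(x, ...) {
  cat("<knet_inventory>", x$n_chars, "characters,",
      sum(x$consistent), "consistent;",
      length(x$pron_seqs), "distinct pronunciations\n")
  invisible(x)
}

pronunciations_of <- function(inventory, char, position) {
  pt <- inventory$pron_table
  pt[pt$char == char & pt$position == position, , drop = FALSE]
}

#' Generate a word's semantic vector from its characters' prototypes
#'
#' Each character contributes a 50-bit exemplar obtained by switching off 10 of
#' the 30 on-bits of its fixed prototype; the word's 100-bit semantic vector is
#' the concatenation of the two exemplars. Exemplars of the same character
#' therefore always share at least 10 on-bits, making semantics partially
#' correlated with orthography while remaining arbitrary with respect to
#' phonology.
#'
#' @param char_pair Integer vector of length 2 (character ids).
#' @param inventory A `knet_inventory` holding the prototypes.
#' @param seed Integer seed for the exemplar sampling.
#' @return Integer 0/1 vector of length 100 with exactly 40 on-bits.
#' @export
generate_semantics <- function(char_pair, inventory, seed = 1L) {
  stopifnot(length(char_pair) == 2L)
  if (any(char_pair < 1L | char_pair > inventory$n_chars)) {
    stop("character id outside the inventory")
  }
  with_seed(seed, {
    unlist(lapply(char_pair, function(ch) {
      proto <- inventory$prototypes[ch, ]
      on <- which(proto == 1L)
      ex <- proto
      ex[sample(on, 10L)] <- 0L
      ex
    }), use.names = FALSE)
  })
}

## phonology target: concatenated mora feature rows, zero-padded to the slot
## count (position-1 morae first)
phonology_vector <- function(inventory, pron1, pron2) {
  morae <- c(inventory$pron_seqs[[pron1]], inventory$pron_seqs[[pron2]])
  fb <- inventory$mora_feature_bits
  out <- numeric(inventory$mora_slots * fb)
  for (i in seq_along(morae)) {
    out[((i - 1L) * fb + 1L):(i * fb)] <- inventory$mora_features[morae[i], ]
  }
  out
}

#' Build a synthetic lexicon of two-character words
#'
#' Samples unique character pairs (so orthography identifies a word),
#' per-position pronunciation choices with probability proportional to type
#' frequency, word frequencies from a log-normal family, and constructs the
#' orthographic, phonological and semantic pattern matrices. Condition labels
#' (consistent / typical / atypical / filler) are derived from the inventory.
#'
#' @param inventory A `knet_inventory`.
#' @param n_words Number of words (> 0).
#' @param frequency_params List with `mean_log10` and `sd_log10` of the
#'   log10 occurrences-per-million distribution, plus `test_log10_target` and
#'   `test_log10_window` defining the low-frequency band test items are drawn
#'   from.
#' @param seed Integer seed.
#' @return An object of class `knet_lexicon`.
#' @export
build_words <- function(inventory, n_words = 1200L,
                        frequency_params = list(), seed = 1L) {
  if (n_words < 1L) stop("n_words must be positive")
  fp <- utils::modifyList(list(mean_log10 = 1.0, sd_log10 = 0.6,
                               test_log10_target = 0.77,
                               test_log10_window = 0.45), frequency_params)
  nc <- inventory$n_chars
  if (n_words < 3L * nc / 2L) {
    warning("few words per character; orthographic neighborhoods may be empty")
  }
  with_seed(seed, {
    ## unique (char1, char2) pairs
    pair_code <- integer(0)
    char1 <- integer(n_words); char2 <- integer(n_words)
    n_have <- 0L
    while (n_have < n_words) {
      c1 <- sample.int(nc, 1L); c2 <- sample.int(nc, 1L)
      code <- (c1 - 1L) * nc + c2
      if (code %in% pair_code) next
      n_have <- n_have + 1L
      pair_code <- c(pair_code, code)
      char1[n_have] <- c1; char2[n_have] <- c2
    }

    pick_pron <- function(ch, pos) {
      pr <- pronunciations_of(inventory, ch, pos)
      if (nrow(pr) == 1L) return(pr$pron)
      sample(pr$pron, 1L, prob = pr$type_freq)
    }
    pron1 <- vapply(char1, pick_pron, integer(1), pos = 1L)
    pron2 <- vapply(char2, pick_pron, integer(1), pos = 2L)

    frequency <- 10^stats::rnorm(n_words, fp$mean_log10, fp$sd_log10)

    orth <- cbind(inventory$visual[char1, , drop = FALSE],
                  inventory$visual[char2, , drop = FALSE])
    phon <- t(vapply(seq_len(n_words), function(i) {
      phonology_vector(inventory, pron1[i], pron2[i])
    }, numeric(inventory$mora_slots * inventory$mora_feature_bits)))
    sem <- t(vapply(seq_len(n_words), function(i) {
      generate_semantics(c(char1[i], char2[i]), inventory,
                         seed = sample.int(2^30, 1L))
    }, integer(100)))

    words <- data.frame(
      word_id = sprintf("w%05d", seq_len(n_words)),
      char1 = char1, char2 = char2, pron1 = pron1, pron2 = pron2,
      frequency = frequency, condition = NA_character_,
      stringsAsFactors = FALSE
    )
    lex <- structure(list(inventory = inventory, words = words,
                          orthography = orth, phonology = phon,
                          semantics = sem, frequency_params = fp,
                          test_ids = character(0), seed = as.integer(seed)),
                     class = "knet_lexicon")
    lex$words$condition <- derive_conditions(lex)
    lex
  })
}

#' @export
print.knet_lexicon <- function(x, ...) {
  cat("<knet_lexicon>", nrow(x$words), "words over",
      x$inventory$n_chars, "characters;",
      length(x$test_ids), "test items\n")
  print(table(x$words$condition))
  invisible(x)
}

#' Re-derive condition labels from the inventory
#'
#' A word is *consistent* when both of its characters have a single
#' pronunciation at their position; *typical* when both characters are
#' inconsistent and both chosen pronunciations are the (strictly) most
#' frequent; *atypical* when both characters are inconsistent and both chosen
#' pronunciations are non-modal; *filler* otherwise (mixed cases).
#'
#' @param lexicon A `knet_lexicon`.
#' @return Character vector of labels, one per word.
#' @export
derive_conditions <- function(lexicon) {
  inv <- lexicon$inventory
  w <- lexicon$words
  pt <- inv$pron_table
  key <- paste(pt$char, pt$position, pt$pron)
  modal <- pt$modal[match(paste(w$char1, 1L, w$pron1), key)]
  modal2 <- pt$modal[match(paste(w$char2, 2L, w$pron2), key)]
  cons1 <- inv$consistent[w$char1]
  cons2 <- inv$consistent[w$char2]
  out <- rep("filler", nrow(w))
  out[cons1 & cons2] <- "consistent"
  out[!cons1 & !cons2 & modal & modal2] <- "typical"
  out[!cons1 & !cons2 & !modal & !modal2] <- "atypical"
  out
}

#' Friends/neighbors ratio of a word
#'
#' For each of the word's two positions, the orthographic neighborhood is the
#' set of *other* lexicon words carrying the same character in the same
#' position; the friends ratio at that position is the fraction of the
#' neighborhood pronouncing the character as the target word does. The
#' word-level value is the mean over the two positions.
#'
#' @param word_id A word id present in the lexicon (or an integer row index).
#' @param lexicon A `knet_lexicon`.
#' @return A single number in \[0, 1\].
#' @export
friends_ratio <- function(word_id, lexicon) {
  w <- lexicon$words
  i <- if (is.numeric(word_id)) as.integer(word_id) else match(word_id, w$word_id)
  if (is.na(i) || i < 1L || i > nrow(w)) stop("unknown word id")
  r <- numeric(2)
  for (pos in 1:2) {
    ch <- if (pos == 1L) w$char1[i] else w$char2[i]
    pr <- if (pos == 1L) w$pron1[i] else w$pron2[i]
    nb <- if (pos == 1L) which(w$char1 == ch) else which(w$char2 == ch)
    nb <- setdiff(nb, i)
    if (length(nb) == 0L) {
      stop("word ", w$word_id[i], " has an empty neighborhood at position ",
           pos, "; friends ratio is undefined")
    }
    nb_pron <- if (pos == 1L) w$pron1[nb] else w$pron2[nb]
    r[pos] <- mean(nb_pron == pr)
  }
  mean(r)
}

## vectorized internal version; NA where a neighborhood is empty
friends_ratio_all <- function(lexicon) {
  w <- lexicon$words
  out <- rep(NA_real_, nrow(w))
  for (i in seq_len(nrow(w))) {
    out[i] <- tryCatch(friends_ratio(i, lexicon), error = function(e) NA_real_)
  }
  out
}

neighborhood_sizes <- function(lexicon) {
  w <- lexicon$words
  n1 <- table(w$char1)[as.character(w$char1)] - 1L
  n2 <- table(w$char2)[as.character(w$char2)] - 1L
  cbind(pos1 = as.integer(n1), pos2 = as.integer(n2))
}

## greedy subset selection: choose n items whose mean (ratio, logf) is close
## to the targets; deterministic given the candidate order
greedy_select <- function(ratio, logf, n, ratio_target, logf_target,
                          ratio_weight = 1, logf_weight = 1) {
  stopifnot(length(ratio) >= n)
  obj <- function(sel) {
    ratio_weight * abs(mean(ratio[sel]) - ratio_target) +
      logf_weight * abs(mean(logf[sel]) - logf_target)
  }
  score <- ratio_weight * abs(ratio - ratio_target) +
    logf_weight * abs(logf - logf_target)
  sel <- order(score)[seq_len(n)]
  rest <- setdiff(seq_along(ratio), sel)
  repeat {
    best <- obj(sel); swap <- NULL
    for (a in seq_along(sel)) {
      for (b in seq_along(rest)) {
        cand <- sel; cand[a] <- rest[b]
        v <- obj(cand)
        if (v < best - 1e-12) { best <- v; swap <- c(a, b) }
      }
    }
    if (is.null(swap)) break
    tmp <- sel[swap[1]]
    sel[swap[1]] <- rest[swap[2]]
    rest[swap[2]] <- tmp
  }
  sel
}

#' Select a condition-balanced low-frequency test set
#'
#' Picks `n_per_condition` words for each of the consistent, typical and
#' atypical conditions from the low-frequency band configured in the lexicon's
#' frequency parameters, requiring every test word's characters to occur in at
#' least two other words (so a neighborhood exists), and targeting the
#' condition-mean friends ratios given by `ratio_targets` within `band`.
#'
#' @param lexicon A `knet_lexicon`.
#' @param n_per_condition Test words per condition (> 0).
#' @param ratio_targets Named targets for the condition-mean friends ratio.
#' @param band Half-width of the acceptable window around each target mean.
#' @param seed Integer seed (selection is deterministic given the lexicon; the
#'   seed only breaks ties in candidate ordering).
#' @return The lexicon with `test_ids` filled in.
#' @export
select_test_set <- function(lexicon, n_per_condition = 20L,
                            ratio_targets = c(consistent = 1.0,
                                              typical = 0.71,
                                              atypical = 0.33),
                            band = 0.05, seed = 1L) {
  if (n_per_condition < 1L) stop("n_per_condition must be positive")
  w <- lexicon$words
  fp <- lexicon$frequency_params
  logf <- log10(w$frequency)
  in_band <- abs(logf - fp$test_log10_target) <= fp$test_log10_window
  nbs <- neighborhood_sizes(lexicon)
  has_nbhd <- nbs[, 1] >= 2L & nbs[, 2] >= 2L
  ratio <- friends_ratio_all(lexicon)

  picked <- character(0)
  for (cond in c("consistent", "typical", "atypical")) {
    cand <- which(w$condition == cond & in_band & has_nbhd & !is.na(ratio))
    if (length(cand) < n_per_condition) {
      stop(sprintf(
        "only %d eligible %s-condition candidates (need %d); regenerate the lexicon with a new seed",
        length(cand), cond, n_per_condition), call. = FALSE)
    }
    sel <- with_seed(derive_seed(seed, paste0("select_", cond)), {
      cand <- sample(cand)  # tie-break order
      cand[greedy_select(ratio[cand], logf[cand], n_per_condition,
                         ratio_targets[[cond]], fp$test_log10_target,
                         ratio_weight = 4, logf_weight = 1)]
    })
    got <- mean(ratio[sel])
    ## enforce a bar tighter than `band` so realized means track the targets
    ## closely; a draw that cannot reach it is regenerated from a new seed
    if (abs(got - ratio_targets[[cond]]) > min(band, 0.035)) {
      stop(sprintf(
        "%s-condition mean friends ratio %.3f outside %.2f +/- %.2f; regenerate the lexicon with a new seed",
        cond, got, ratio_targets[[cond]], band), call. = FALSE)
    }
    picked <- c(picked, w$word_id[sel])
  }
  overall_f <- mean(logf[match(picked, w$word_id)])
  if (abs(overall_f - fp$test_log10_target) > 0.04) {
    stop(sprintf(
      "test-set mean log10 frequency %.3f misses target %.2f; regenerate the lexicon with a new seed",
      overall_f, fp$test_log10_target), call. = FALSE)
  }
  lexicon$test_ids <- picked
  lexicon
}

#' Generate a complete lexicon (inventory, words, test set) with retries
#'
#' Convenience wrapper chaining [generate_inventory()], [build_words()] and
#' [select_test_set()]. If the sampled lexicon cannot satisfy the test-set
#' constraints, generation is retried with derived seeds (up to `max_retries`)
#' before failing; retries are deterministic functions of `seed`.
#'
#' @param n_chars,n_words,n_per_condition Scale parameters.
#' @param prop_consistent Fraction of single-pronunciation characters.
#' @param frequency_params See [build_words()].
#' @param seed Master seed.
#' @param max_retries Attempts before giving up.
#' @param ... Passed to [generate_inventory()].
#' @return A `knet_lexicon` with `test_ids` populated.
#' @export
generate_lexicon <- function(n_chars = 300L, n_words = 1200L,
                             n_per_condition = 20L, prop_consistent = 1 / 3,
                             frequency_params = list(), seed = 1L,
                             max_retries = 5L, ...) {
  last_err <- NULL
  for (attempt in seq_len(max_retries)) {
    s <- derive_seed(seed, "lexicon", attempt)
    lex <- tryCatch({
      inv <- generate_inventory(n_chars = n_chars,
                                prop_consistent = prop_consistent,
                                seed = s, ...)
      lex <- build_words(inv, n_words = n_words,
                         frequency_params = frequency_params,
                         seed = derive_seed(s, "words"))
      select_test_set(lex, n_per_condition = n_per_condition,
                      seed = derive_seed(s, "testset"))
    }, error = function(e) e)
    if (!inherits(lex, "error")) return(lex)
    last_err <- lex
  }
  stop("lexicon generation failed after ", max_retries, " attempts: ",
       conditionMessage(last_err), call. = FALSE)
}

#' Summary statistics of the test set
#'
#' @param lexicon A `knet_lexicon` with a selected test set.
#' @return Data frame with per-condition mean friends ratio and mean log10
#'   frequency.
#' @export
test_set_stats <- function(lexicon) {
  if (length(lexicon$test_ids) == 0L) stop("no test set selected")
  w <- lexicon$words
  idx <- match(lexicon$test_ids, w$word_id)
  ratio <- vapply(idx, friends_ratio, numeric(1), lexicon = lexicon)
  df <- data.frame(condition = w$condition[idx], ratio = ratio,
                   log10_freq = log10(w$frequency[idx]))
  out <- do.call(rbind, lapply(split(df, df$condition), function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               mean_ratio = mean(d$ratio), sd_ratio = stats::sd(d$ratio),
               mean_log10_freq = mean(d$log10_freq))
  }))
  rownames(out) <- NULL
  out[order(match(out$condition, c("consistent", "typical", "atypical"))), ]
}
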
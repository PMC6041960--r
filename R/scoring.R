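## Output decoding, error taxonomy (surface / semantic / other), condition
## summaries.

#' Decode a phonological output by nearest neighbor
#'
#' Returns the lexicon word whose phonological target is closest (Euclidean
#' distance) to the settled output vector; ties are broken by the lowest word
#' row index (lowest word id), deterministically.
#'
#' @param output Numeric vector (one output) or matrix (one output per row)
#'   matching the phonology dimension.
#' @param lexicon A `knet_lexicon`.
#' @return Integer word row index (or vector of them).
#' @export
decode_output <- function(output, lexicon) {
  P <- lexicon$phonology
  if (is.null(dim(output))) output <- matrix(output, nrow = 1L)
  if (ncol(output) != ncol(P)) {
    stop("output dimension ", ncol(output), " != phonology dimension ",
         ncol(P))
  }
  ## squared distances via the expansion |o - p|^2 = |o|^2 - 2 o.p + |p|^2
  cross <- tcrossprod(output, P)              # n_out x n_words
  p2 <- rowSums(P^2)
  d2 <- sweep(-2 * cross, 2L, p2, `+`)        # |o|^2 constant per row
  ## round to kill floating-point ties before argmin (max.col breaks ties
  ## randomly; apply/which.min takes the first = lowest id)
  apply(round(d2, 9), 1L, which.min)
}

#' Read words with the model and decode the outputs
#'
#' Runs the reading task (visual clamped) for each word and decodes the final
#' time step of the phonetic output layer against the whole lexicon.
#'
#' @param net A `knet_network` (any lesion mask is honored).
#' @param lexicon A `knet_lexicon`.
#' @param word_idx Word row indices to read.
#' @return Integer vector of decoded word row indices.
#' @export
read_words <- function(net, lexicon, word_idx) {
  out <- forward_batch(net, "reading",
                       lexicon$orthography[word_idx, , drop = FALSE])
  decode_output(out, lexicon)
}

#' 95th percentile of random-pair semantic overlap
#'
#' Null threshold used by [classify_error()] to decide whether a decoded word
#' is semantically related to the target: overlap is the number of shared
#' on-bits between the two words' 100-bit semantic vectors.
#'
#' @param lexicon A `knet_lexicon`.
#' @param n_pairs Random pairs to sample.
#' @param seed Integer seed.
#' @return Scalar threshold.
#' @export
semantic_null_threshold <- function(lexicon, n_pairs = 2000L, seed = 1L) {
  n <- nrow(lexicon$words)
  with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    keep <- i != j
    ov <- rowSums(lexicon$semantics[i[keep], , drop = FALSE] *
                    lexicon$semantics[j[keep], , drop = FALSE])
    stats::quantile(ov, 0.95, names = FALSE, type = 1)
  })
}

## pronunciation rows of a word: (seq id at position 1, seq id at position 2)
word_prons <- function(lexicon, idx) {
  cbind(lexicon$words$pron1[idx], lexicon$words$pron2[idx])
}

#' Classify a reading response
#'
#' *correct*: decoded word equals the target. *surface*: at one or both
#' positions the decoded word's pronunciation is a different legitimate
#' pronunciation of the target's character there (the `regularization` flag
#' additionally records whether some substituted pronunciation has a higher
#' type frequency than the target's, i.e. the response is more regular).
#' *semantic*: the decoded word shares a character with the target in the same
#' position and their semantic overlap exceeds the lexicon-wide null
#' threshold. Otherwise *other*. Classes are mutually exclusive with this
#' precedence: correct, surface, semantic, other.
#'
#' @param target_idx,decoded_idx Word row indices.
#' @param lexicon A `knet_lexicon`.
#' @param null_threshold From [semantic_null_threshold()]; computed on the
#'   fly when NULL.
#' @return List with `class` and `regularization` (logical).
#' @export
classify_error <- function(target_idx, decoded_idx, lexicon,
                           null_threshold = NULL) {
  if (decoded_idx == target_idx) {
    return(list(class = "correct", regularization = FALSE))
  }
  inv <- lexicon$inventory
  w <- lexicon$words
  tchars <- c(w$char1[target_idx], w$char2[target_idx])
  tpron <- word_prons(lexicon, target_idx)[1, ]
  dpron <- word_prons(lexicon, decoded_idx)[1, ]

  surface <- FALSE; regular <- FALSE
  for (pos in 1:2) {
    pr <- pronunciations_of(inv, tchars[pos], pos)
    if (dpron[pos] %in% pr$pron && dpron[pos] != tpron[pos]) {
      surface <- TRUE
      tf_sub <- pr$type_freq[match(dpron[pos], pr$pron)]
      tf_tgt <- pr$type_freq[match(tpron[pos], pr$pron)]
      if (tf_sub > tf_tgt) regular <- TRUE
    }
  }
  if (surface) return(list(class = "surface", regularization = regular))

  shares_char <- (w$char1[decoded_idx] == w$char1[target_idx]) ||
    (w$char2[decoded_idx] == w$char2[target_idx])
  if (shares_char) {
    if (is.null(null_threshold)) {
      null_threshold <- semantic_null_threshold(lexicon)
    }
    ov <- sum(lexicon$semantics[target_idx, ] * lexicon$semantics[decoded_idx, ])
    if (ov > null_threshold) {
      return(list(class = "semantic", regularization = FALSE))
    }
  }
  list(class = "other", regularization = FALSE)
}

#' Evaluate reading on a set of words
#'
#' @param net A `knet_network` (lesion mask honored).
#' @param lexicon A `knet_lexicon`.
#' @param word_idx Word row indices to test.
#' @param null_threshold Semantic-null threshold (precompute for speed).
#' @return Data frame: one row per word with the decoded id, correctness,
#'   error class and regularization flag.
#' @export
evaluate_reading <- function(net, lexicon, word_idx, null_threshold = NULL) {
  if (is.null(null_threshold)) {
    null_threshold <- semantic_null_threshold(lexicon)
  }
  decoded <- read_words(net, lexicon, word_idx)
  cls <- vector("character", length(word_idx))
  reg <- logical(length(word_idx))
  for (i in seq_along(word_idx)) {
    r <- classify_error(word_idx[i], decoded[i], lexicon, null_threshold)
    cls[i] <- r$class; reg[i] <- r$regularization
  }
  data.frame(word_id = lexicon$words$word_id[word_idx],
             condition = lexicon$words$condition[word_idx],
             decoded_word_id = lexicon$words$word_id[decoded],
             correct = decoded == word_idx, error_class = cls,
             regularization = reg, stringsAsFactors = FALSE)
}

## per-condition accuracy and error-class rates from an evaluate_reading()
## table
condition_rates <- function(trials) {
  do.call(rbind, lapply(split(trials, trials$condition), function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               accuracy = mean(d$error_class == "correct"),
               surface_rate = mean(d$error_class == "surface"),
               semantic_rate = mean(d$error_class == "semantic"),
               other_rate = mean(d$error_class == "other"),
               regularization_rate = mean(d$regularization),
               stringsAsFactors = FALSE)
  }))
}

#' Summarize a lesion battery into condition summaries
#'
#' Repetition-level rows are averaged within each (simulation, condition,
#' lesion status) cell first, matching the averaging of repeated lesion
#' samples within a simulation.
#'
#' @param battery Battery table from [run_battery()].
#' @return One row per (simulation_seed, condition, lesion_status).
#' @export
summarize_battery <- function(battery) {
  need <- c("simulation_seed", "condition", "lesion_status", "accuracy",
            "surface_rate", "semantic_rate", "other_rate")
  if (!all(need %in% names(battery))) {
    stop("battery table lacks columns: ",
         paste(setdiff(need, names(battery)), collapse = ", "))
  }
  f <- interaction(battery$simulation_seed, battery$condition,
                   battery$lesion_status, drop = TRUE)
  out <- do.call(rbind, lapply(split(battery, f), function(d) {
    data.frame(simulation_seed = d$simulation_seed[1],
               condition = d$condition[1],
               lesion_status = d$lesion_status[1],
               accuracy = mean(d$accuracy),
               surface_rate = mean(d$surface_rate),
               semantic_rate = mean(d$semantic_rate),
               other_rate = mean(d$other_rate),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  ## completeness check: every simulation must contribute every cell
  tab <- table(out$simulation_seed, out$condition, out$lesion_status)
  if (any(tab != 1L)) stop("incomplete battery design: missing cells")
  out
}
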
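## Serialization: lexicon TSV + JSON sidecar, training checkpoints, tables.

#' Write a lexicon to disk
#'
#' The word table goes to `<path>.tsv` (one word per row: id, characters,
#' pronunciation ids, frequency, condition, test-set flag); the inventory and
#' the dense pattern matrices go to a JSON sidecar `<path>.json`. Writing and
#' re-reading restores the lexicon exactly.
#'
#' @param lexicon A `knet_lexicon`.
#' @param path Base path (without extension).
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  w <- lexicon$words
  w$is_test <- w$word_id %in% lexicon$test_ids
  utils::write.table(w, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  inv <- lexicon$inventory
  sidecar <- list(
    inventory = list(
      n_chars = inv$n_chars, n_positions = inv$n_positions,
      visual_bits = inv$visual_bits, n_morae = inv$n_morae,
      mora_feature_bits = inv$mora_feature_bits, mora_slots = inv$mora_slots,
      mora_features = inv$mora_features, visual = inv$visual,
      prototypes = inv$prototypes, pron_seqs = inv$pron_seqs,
      pron_table = inv$pron_table, consistent = inv$consistent,
      prop_consistent = inv$prop_consistent, seed = inv$seed
    ),
    frequency_params = lexicon$frequency_params,
    test_ids = lexicon$test_ids,
    seed = lexicon$seed,
    orthography = lexicon$orthography,
    phonology = lexicon$phonology,
    semantics = lexicon$semantics
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a lexicon written by [write_lexicon()]
#'
#' @param path Base path (without extension).
#' @return A `knet_lexicon`.
#' @export
read_lexicon <- function(path) {
  w <- utils::read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ii <- sc$inventory
  inv <- structure(list(
    n_chars = ii$n_chars, n_positions = ii$n_positions,
    visual_bits = ii$visual_bits, n_morae = ii$n_morae,
    mora_feature_bits = ii$mora_feature_bits, mora_slots = ii$mora_slots,
    mora_features = as.matrix(ii$mora_features),
    visual = as.matrix(ii$visual),
    prototypes = as.matrix(ii$prototypes),
    pron_seqs = lapply(ii$pron_seqs, as.integer),
    pron_table = as.data.frame(ii$pron_table),
    consistent = as.logical(ii$consistent),
    prop_consistent = ii$prop_consistent, seed = ii$seed
  ), class = "knet_inventory")
  test_ids <- as.character(sc$test_ids %||% w$word_id[w$is_test])
  w$is_test <- NULL
  structure(list(inventory = inv, words = w,
                 orthography = as.matrix(sc$orthography),
                 phonology = as.matrix(sc$phonology),
                 semantics = as.matrix(sc$semantics),
                 frequency_params = sc$frequency_params,
                 test_ids = test_ids, seed = sc$seed),
            class = "knet_lexicon")
}

#' Save a trained network checkpoint
#'
#' Weights, biases, frozen mask and the architecture spec are stored with a
#' content hash of the spec so a checkpoint cannot silently be reloaded
#' against a different architecture.
#'
#' @param fit A `knet_fit` or `knet_network`.
#' @param path File path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(fit, path) {
  net <- if (inherits(fit, "knet_fit")) fit$net else fit
  obj <- list(net = net,
              spec_hash = spec_hash(net$spec),
              seed = if (inherits(fit, "knet_fit")) fit$seed else NA_integer_,
              log = if (inherits(fit, "knet_fit")) fit$log else NULL,
              drill_log = if (inherits(fit, "knet_fit")) fit$drill_log else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint written by [write_checkpoint()]
#'
#' @param path File path.
#' @return A `knet_fit`.
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$spec_hash, spec_hash(obj$net$spec))) {
    stop("checkpoint spec hash mismatch")
  }
  structure(list(net = obj$net, log = obj$log, drill_log = obj$drill_log,
                 seed = obj$seed),
            class = "knet_fit")
}

## cheap deterministic hash of the architecture description
spec_hash <- function(spec) {
  s <- paste(c(spec$layers$name, spec$layers$size, spec$connections$name,
               spec$n_timesteps, spec$integration_rate, spec$gain,
               spec$error_window), collapse = "|")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
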
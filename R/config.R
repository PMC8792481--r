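# YAML configuration: overrides for the clade vocabulary, the range-state
# list, and the trade-adjustment switches, so a full analysis can be pinned
# in one reviewable file.

#' Read a pipeline configuration file
#'
#' YAML with any subset of the keys: `mtdna_labels`, `nudna_labels`,
#' `subspecies_of` (map nuDNA label to subspecies; all three must be given
#' together to override the vocabulary), `range_states` (ISO codes or
#' aliases), `mid1990s_cutoff` (integer year), `fr_w2_all_exporters`
#' (logical), `quantity_rule` (`"max"` or `"exporter"`),
#' `assume_country_clade_for_captive` (logical). Missing keys fall back to
#' the packaged defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return list with elements `vocabulary`, `range_states` (`NULL` when not
#'   overridden), `mid1990s_cutoff`, `fr_w2_all_exporters`, `quantity_rule`,
#'   `assume_country_clade_for_captive`.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  vocab_keys <- c("mtdna_labels", "nudna_labels", "subspecies_of")
  have <- vocab_keys %in% names(cfg)
  if (any(have) && !all(have)) {
    stop("configuration error: vocabulary overrides need all of ",
         paste(vocab_keys, collapse = ", "), call. = FALSE)
  }
  vocabulary <- if (all(have)) {
    clade_vocabulary(unlist(cfg$mtdna_labels), unlist(cfg$nudna_labels),
                     unlist(cfg$subspecies_of))
  } else {
    default_vocabulary()
  }
  list(
    vocabulary = vocabulary,
    range_states = if (!is.null(cfg$range_states))
      normalize_country(unlist(cfg$range_states)) else NULL,
    mid1990s_cutoff = if (!is.null(cfg$mid1990s_cutoff))
      as.integer(cfg$mid1990s_cutoff) else 1995L,
    fr_w2_all_exporters = if (!is.null(cfg$fr_w2_all_exporters))
      isTRUE(cfg$fr_w2_all_exporters) else TRUE,
    quantity_rule = if (!is.null(cfg$quantity_rule))
      match.arg(cfg$quantity_rule, c("max", "exporter")) else "max",
    assume_country_clade_for_captive =
      isTRUE(cfg$assume_country_clade_for_captive)
  )
}
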
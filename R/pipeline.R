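# Joining adjusted trade records to registry clade profiles, scoring each
# record's translocation suitability, propagating multi-clade ambiguity as
# best/worst bounds, and emitting quantity-weighted summaries and flow
# tables.

.summary_classes <- c("FIRST", "SECOND", "THIRD", "W2", "NO_OPTION")

#' Score adjusted trade records against the registry
#'
#' Each record's source genetic profile is the country profile of its
#' genetic-attribution country (origin when present, else exporter); the
#' target profile is the importer's. Best- and worst-case suitability are
#' the maximum and minimum over the cartesian product of candidate LCU pairs
#' on both sides, so multi-clade countries yield a best/worst bound rather
#' than a point. Captive (`C`) and unknown (`U`) individuals are `NO_OPTION`
#' outright — their genetic background is unknown — unless
#' `assume_country_clade_for_captive` is set, in which case they are scored
#' by their attribution country's profile (the scenario analysis). `W2`
#' records are flagged as managed-metapopulation (a hybrid source) and
#' reported as their own class.
#'
#' @param records an `adjusted_records` data frame from [adjust_source()].
#' @param registry a `lion_registry`; every importer must be a range state
#'   with at least one record.
#' @param assume_country_clade_for_captive scenario flag (default `FALSE`).
#' @return data frame of class `scored_records`: the input plus columns
#'   `best, worst` (level tokens), `suitability_class` (one of `FIRST,
#'   SECOND, THIRD, W2, NO_OPTION`), `hybrid_source`, `w2_source`,
#'   `scoring_note`.
#' @export
score_records <- function(records, registry,
                          assume_country_clade_for_captive = FALSE) {
  stopifnot(inherits(registry, "lion_registry"))
  n <- nrow(records)
  unresolvable <- setdiff(unique(records$importer), registry$range_states)
  if (length(unresolvable)) {
    bad <- which(records$importer %in% unresolvable)
    stop("unresolvable target country for record(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         ": importer(s) not in the registry range states: ",
         paste(unresolvable, collapse = ", "), call. = FALSE)
  }
  registry_countries <- unique(unlist(lapply(
    Filter(function(r) r$extant, registry$records), `[[`, "countries")))

  best <- character(n); worst <- character(n)
  hybrid <- logical(n); note <- character(n)
  for (i in seq_len(n)) {
    cls <- records$source_class[i]
    src_country <- records$genetic_source[i]
    captive_like <- cls %in% c("C", "U")
    if (captive_like && !assume_country_clade_for_captive) {
      best[i] <- worst[i] <- "NO_OPTION"
      note[i] <- "captive/unknown genetic origin"
      next
    }
    if (!src_country %in% registry_countries) {
      best[i] <- worst[i] <- "NO_OPTION"
      note[i] <- paste0("source country ", src_country,
                        " has no profiled lion population")
      next
    }
    src_cp <- country_profile(registry, src_country)
    tgt_cp <- country_profile(registry, records$importer[i])
    lv <- character(0)
    for (s in src_cp$records) for (t in tgt_cp$records) {
      lv <- c(lv, score_pair_full(s, t, registry$vocabulary)$level)
    }
    best[i] <- best_level(lv)
    worst[i] <- worst_level(lv)
    hybrid[i] <- src_cp$any_hybrid
    note[i] <- sprintf("%d candidate LCU pair(s) %s->%s%s",
                       length(lv), src_country, records$importer[i],
                       if (captive_like)
                         "; captive scored by country clade (scenario)" else "")
  }
  w2 <- records$source_class == "W2"
  hybrid[w2] <- TRUE  # managed-metapopulation stock is a hybrid source
  out <- records
  out$best <- best
  out$worst <- worst
  out$suitability_class <- ifelse(
    w2, "W2",
    ifelse(records$source_class %in% c("C", "U") &
             !assume_country_clade_for_captive, "NO_OPTION", best))
  out$hybrid_source <- hybrid
  out$w2_source <- w2
  out$scoring_note <- note
  class(out) <- c("scored_records", class(records))
  attr(out, "exclusions") <- attr(records, "exclusions")
  attr(out, "scenario") <- assume_country_clade_for_captive
  out
}

#' Quantity-weighted suitability summary
#'
#' Tallies individuals (not permits) per suitability class — `W2` counted as
#' its own, fifth class — per exporter, per importer, and per consolidated
#' trade category. Country tables are ordered count-descending, ties
#' alphabetical. Percentages are rounded to whole percent for report parity;
#' raw fractions are kept alongside.
#'
#' @param scored a `scored_records` data frame.
#' @return an object of class `suitability_summary`.
#' @export
summarize_suitability <- function(scored) {
  total <- sum(scored$quantity)
  tally_by <- function(key) {
    if (!nrow(scored)) {
      return(data.frame(key = character(0), count = numeric(0),
                        percent = numeric(0), fraction = numeric(0),
                        stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(scored$quantity, by = list(key = key), FUN = sum)
    names(agg) <- c("key", "count")
    agg <- agg[order(-agg$count, agg$key), , drop = FALSE]
    rownames(agg) <- NULL
    agg$percent <- if (total > 0) round(100 * agg$count / total) else 0
    agg$fraction <- if (total > 0) agg$count / total else 0
    agg
  }
  by_class_raw <- tally_by(scored$suitability_class)
  by_class <- data.frame(class = .summary_classes,
                         count = 0, percent = 0, fraction = 0,
                         stringsAsFactors = FALSE)
  m <- match(by_class$class, by_class_raw$key)
  hit <- !is.na(m)
  by_class$count[hit] <- by_class_raw$count[m[hit]]
  by_class$percent[hit] <- by_class_raw$percent[m[hit]]
  by_class$fraction[hit] <- by_class_raw$fraction[m[hit]]

  class_breakdown <- function(key) {
    if (!nrow(scored)) return(list())
    split_q <- split(seq_len(nrow(scored)), key)
    lapply(split_q, function(idx) {
      v <- vapply(.summary_classes, function(cl)
        sum(scored$quantity[idx][scored$suitability_class[idx] == cl]),
        numeric(1))
      names(v) <- .summary_classes
      v
    })
  }
  structure(
    list(individuals_total = total,
         by_class = by_class,
         by_exporter = tally_by(scored$exporter),
         by_importer = tally_by(scored$importer),
         exporter_class_breakdown = class_breakdown(scored$exporter),
         importer_class_breakdown = class_breakdown(scored$importer),
         by_trade_category = tally_by(scored$category)),
    class = "suitability_summary"
  )
}

#' @export
print.suitability_summary <- function(x, ...) {
  cat(sprintf("Suitability summary: %d individuals\n", x$individuals_total))
  for (i in seq_len(nrow(x$by_class))) {
    cat(sprintf("  %-10s %5d (%d%%)\n", x$by_class$class[i],
                x$by_class$count[i], x$by_class$percent[i]))
  }
  if (nrow(x$by_exporter)) {
    cat(sprintf("  top exporter: %s %d (%d%%); top importer: %s %d (%d%%)\n",
                x$by_exporter$key[1], x$by_exporter$count[1],
                x$by_exporter$percent[1],
                x$by_importer$key[1], x$by_importer$count[1],
                x$by_importer$percent[1]))
  }
  invisible(x)
}

#' No-option range under the country-clade scenario
#'
#' With captive individuals scored by their attribution country's clades,
#' the number of `NO_OPTION` individuals becomes a range: the lower bound
#' counts individuals whose best-case score is `NO_OPTION`, the upper bound
#' those whose worst-case score is (multi-clade release countries, e.g. a
#' DRC import, make the two differ).
#'
#' @param scored a `scored_records` data frame computed with
#'   `assume_country_clade_for_captive = TRUE`.
#' @return named numeric vector `c(min = ..., max = ...)` of individuals.
#' @export
scenario_no_option_range <- function(scored) {
  if (!isTRUE(attr(scored, "scenario"))) {
    warning("records were not scored under assume_country_clade_for_captive = TRUE",
            call. = FALSE)
  }
  c(min = sum(scored$quantity[scored$best == "NO_OPTION"]),
    max = sum(scored$quantity[scored$worst == "NO_OPTION"]))
}

#' Aggregate scored records to flow edges
#'
#' One edge per (exporter, importer, trade category, suitability class),
#' with the summed number of individuals; the tabular twin of a flow map.
#'
#' @param scored a `scored_records` data frame.
#' @return data frame with columns `exporter, importer, category,
#'   suitability_class, individuals`, deterministically ordered.
#' @export
flow_edges <- function(scored) {
  if (!nrow(scored)) {
    return(data.frame(exporter = character(0), importer = character(0),
                      category = character(0),
                      suitability_class = character(0),
                      individuals = numeric(0), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(
    scored$quantity,
    by = list(exporter = scored$exporter, importer = scored$importer,
              category = scored$category,
              suitability_class = scored$suitability_class),
    FUN = sum)
  names(agg)[names(agg) == "x"] <- "individuals"
  agg <- agg[order(agg$exporter, agg$importer, agg$category,
                   agg$suitability_class), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Export summary, country and flow tables
#'
#' Writes `summary.json` (class counts with keys exactly `FIRST, SECOND,
#' THIRD, W2, NO_OPTION`), `by_country.csv`, `flow_edges.csv`, and
#' `run_log.txt` recording configuration and input digests. Output is
#' deterministic for fixed input.
#'
#' @param summary a [summarize_suitability()] result.
#' @param edges a [flow_edges()] result.
#' @param out_dir output directory, created if needed.
#' @param config named list recorded in the run log.
#' @param input_files paths whose md5 digests go into the run log.
#' @return character vector of written paths, invisibly.
#' @export
export_reports <- function(summary, edges, out_dir, config = list(),
                           input_files = character(0)) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("summary.json", "by_country.csv",
                                "flow_edges.csv", "run_log.txt"))
  by_class <- as.list(stats::setNames(summary$by_class$count,
                                      summary$by_class$class))
  jsonlite::write_json(
    list(individuals_total = summary$individuals_total,
         by_class = by_class,
         by_class_percent = as.list(stats::setNames(
           summary$by_class$percent, summary$by_class$class)),
         by_trade_category = as.list(stats::setNames(
           summary$by_trade_category$count, summary$by_trade_category$key))),
    paths[1], auto_unbox = TRUE, pretty = TRUE, digits = NA)

  exp_df <- summary$by_exporter; exp_df$role <- "exporter"
  imp_df <- summary$by_importer; imp_df$role <- "importer"
  cc <- rbind(exp_df, imp_df)
  names(cc)[names(cc) == "key"] <- "country"
  utils::write.csv(cc[, c("role", "country", "count", "percent", "fraction")],
                   paths[2], row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(edges, paths[3], row.names = FALSE, fileEncoding = "UTF-8")

  log_lines <- c(
    "liontrax run log",
    sprintf("individuals_total: %s", summary$individuals_total),
    if (length(config))
      sprintf("config %s: %s", names(config),
              vapply(config, function(v) paste(format(v), collapse = ","),
                     character(1))),
    if (length(input_files))
      sprintf("input %s md5 %s", input_files,
              unname(tools::md5sum(input_files)))
  )
  writeLines(log_lines, paths[4])
  invisible(paths)
}
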
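# CITES Trade Database comparative-tabulation handling: parsing, inclusion
# filters, quantity reconciliation, the four consolidated trade categories,
# and the W1/W2/C/U source-class adjustment.
#
# Source codes: W wild, F born in captivity (F1), R ranched, C bred in
# captivity. Purpose codes kept: N (re)introduction into the wild,
# T commercial, B captive breeding, H hunting trophy.

.cites_column_map <- c(
  "year" = "year", "taxon" = "taxon", "importer" = "importer",
  "exporter" = "exporter", "origin" = "origin", "term" = "term",
  "unit" = "unit", "purpose" = "purpose", "source" = "source",
  "importer reported quantity" = "qty_importer",
  "importer.reported.quantity" = "qty_importer",
  "importer_reported_quantity" = "qty_importer",
  "qty_importer" = "qty_importer",
  "exporter reported quantity" = "qty_exporter",
  "exporter.reported.quantity" = "qty_exporter",
  "exporter_reported_quantity" = "qty_exporter",
  "qty_exporter" = "qty_exporter"
)

.kept_purposes <- c("N", "T", "B", "H")
.kept_sources <- c("W", "F", "R", "C", "")

#' Read a CITES comparative-tabulation CSV
#'
#' Accepts the column dialect exported by the CITES Trade Database
#' (`Year, Taxon, Importer, Exporter, Origin, Importer reported quantity,
#' Exporter reported quantity, Term, Unit, Purpose, Source`),
#' case-insensitively. Rows with an unparseable year or negative quantities
#' are dropped and reported, line-numbered, in the `"diagnostics"`
#' attribute — never silently.
#'
#' @param path CSV path.
#' @return a data frame of class `cites_records` with columns `year, taxon,
#'   importer, exporter, origin, qty_importer, qty_exporter, term, unit,
#'   purpose, source`, and attribute `diagnostics` (character vector).
#' @export
read_cites_csv <- function(path) {
  if (!file.exists(path)) stop("CITES file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = ",", quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", encoding = "UTF-8",
                          na.strings = character(0))
  nm <- tolower(trimws(names(df)))
  mapped <- unname(.cites_column_map[nm])
  keep <- !is.na(mapped)
  df <- df[, keep, drop = FALSE]
  names(df) <- mapped[keep]
  required <- c("year", "taxon", "importer", "exporter", "term", "purpose",
                "source")
  missing_cols <- setdiff(required, names(df))
  has_qty <- any(c("qty_importer", "qty_exporter") %in% names(df))
  if (length(missing_cols) || !has_qty) {
    stop("CITES schema error: found columns [",
         paste(names(df), collapse = ", "), "]; expected at least [",
         paste(required, collapse = ", "),
         "] plus one reported-quantity column", call. = FALSE)
  }
  for (col in c("origin", "unit", "qty_importer", "qty_exporter")) {
    if (!col %in% names(df)) df[[col]] <- ""
  }

  diagnostics <- character(0)
  year <- suppressWarnings(as.integer(df$year))
  bad_year <- is.na(year)
  if (any(bad_year)) {
    diagnostics <- c(diagnostics,
      sprintf("line %d: unparseable Year '%s'",
              which(bad_year) + 1L, df$year[bad_year]))
  }
  qi <- suppressWarnings(as.numeric(df$qty_importer))
  qe <- suppressWarnings(as.numeric(df$qty_exporter))
  qi[!nzchar(trimws(df$qty_importer))] <- NA_real_
  qe[!nzchar(trimws(df$qty_exporter))] <- NA_real_
  bad_qty <- (!is.na(qi) & qi < 0) | (!is.na(qe) & qe < 0) |
    (is.na(qi) & nzchar(trimws(df$qty_importer))) |
    (is.na(qe) & nzchar(trimws(df$qty_exporter)))
  if (any(bad_qty)) {
    diagnostics <- c(diagnostics,
      sprintf("line %d: invalid quantity ('%s'/'%s')",
              which(bad_qty) + 1L, df$qty_importer[bad_qty],
              df$qty_exporter[bad_qty]))
  }
  ok <- !bad_year & !bad_qty
  out <- data.frame(
    year = year[ok],
    taxon = trimws(df$taxon[ok]),
    importer = toupper(trimws(df$importer[ok])),
    exporter = toupper(trimws(df$exporter[ok])),
    origin = toupper(trimws(df$origin[ok])),
    qty_importer = qi[ok],
    qty_exporter = qe[ok],
    term = tolower(trimws(df$term[ok])),
    unit = trimws(df$unit[ok]),
    purpose = toupper(trimws(df$purpose[ok])),
    source = toupper(trimws(df$source[ok])),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cites_records", "data.frame")
  attr(out, "diagnostics") <- diagnostics
  out
}

is_lion_taxon <- function(taxon) {
  grepl("^panthera[ .]+leo", tolower(trimws(taxon)))
}

#' Reconcile importer- and exporter-reported quantities
#'
#' Permit counts reflect the maximum number of individuals intended to move,
#' so the reconciled quantity is the maximum of the two reported quantities
#' (missing treated as zero), rounded to integer. Records reconciling to
#' zero carry no individuals and are excluded by [filter_records()].
#'
#' @param records a `cites_records` data frame (or any data frame with
#'   `qty_importer` / `qty_exporter` columns).
#' @param rule `"max"` (default) or `"exporter"` (exporter-preferred, fall
#'   back to importer).
#' @return integer vector of reconciled quantities.
#' @export
reconcile_quantity <- function(records, rule = c("max", "exporter")) {
  rule <- match.arg(rule)
  qi <- ifelse(is.na(records$qty_importer), 0, records$qty_importer)
  qe <- ifelse(is.na(records$qty_exporter), 0, records$qty_exporter)
  q <- if (rule == "max") pmax(qi, qe) else ifelse(qe > 0, qe, qi)
  as.integer(round(q))
}

#' Apply the inclusion filters for the live-lion trade audit
#'
#' Keeps live-term lion records imported into lion range states in the study
#' window, with purpose in `{N, T, B, H}` and source in `{W, F, R, C}` or
#' blank. Each record failing a filter is tallied (records and individuals)
#' under the first filter that rejects it; exclusions are data, not errors.
#'
#' @param records a `cites_records` data frame.
#' @param range_states ISO alpha-2 codes of lion range states.
#' @param year_min,year_max inclusive study window (default 1983-2019).
#' @return the kept records (class `cites_records`) with attribute
#'   `exclusions`: a data frame of per-filter record and individual tallies.
#' @export
filter_records <- function(records, range_states, year_min = 1983,
                           year_max = 2019) {
  range_states <- normalize_country(range_states)
  q <- reconcile_quantity(records)
  reasons <- rep(NA_character_, nrow(records))
  fail <- function(cond, label) {
    hit <- is.na(reasons) & cond
    reasons[hit] <<- label
  }
  fail(records$term != "live", "term-not-live")
  fail(!is_lion_taxon(records$taxon), "taxon-not-lion")
  fail(records$year < year_min | records$year > year_max, "year-out-of-range")
  fail(!(records$importer %in% range_states), "importer-not-range-state")
  fail(!(records$purpose %in% .kept_purposes), "purpose-excluded")
  fail(!(records$source %in% .kept_sources), "source-excluded")
  fail(q < 1L, "zero-quantity")

  labels <- c("term-not-live", "taxon-not-lion", "year-out-of-range",
              "importer-not-range-state", "purpose-excluded",
              "source-excluded", "zero-quantity")
  excl <- data.frame(
    filter = labels,
    records = vapply(labels, function(l) sum(reasons %in% l, na.rm = TRUE),
                     integer(1)),
    individuals = vapply(labels, function(l) sum(q[reasons %in% l]),
                         numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  kept <- records[is.na(reasons), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("cites_records", "data.frame")
  attr(kept, "exclusions") <- excl
  attr(kept, "individuals_in") <- sum(q)
  attr(kept, "individuals_kept") <- sum(q[is.na(reasons)])
  kept
}

#' Consolidated trade category from source class and purpose
#'
#' The four analysis categories: wild-sourced (`W`, `F`, `R`, or adjusted
#' `W1`/`W2`) vs captive (`C`; unknown `U` is grouped with captive), crossed
#' with (re)introduction purpose (`N`) vs commercial/breeding/trophy
#' purposes (`T`, `B`, `H`).
#'
#' @param source_class raw source code (`W`/`F`/`R`/`C`) or adjusted class
#'   (`W1`/`W2`/`C`/`U`); vectorized.
#' @param purpose purpose code in `{N, T, B, H}`; vectorized.
#' @return character vector over `WILD_REINTRO`, `CAPTIVE_REINTRO`,
#'   `WILD_COMMERCIAL`, `CAPTIVE_COMMERCIAL`.
#' @export
categorize_trade <- function(source_class, purpose) {
  source_class <- toupper(source_class)
  purpose <- toupper(purpose)
  wild <- source_class %in% c("W", "F", "R", "W1", "W2")
  captive <- source_class %in% c("C", "U")
  if (any(!wild & !captive)) {
    stop("classification error: source class out of domain: ",
         paste(unique(source_class[!wild & !captive]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!purpose %in% .kept_purposes)) {
    stop("classification error: purpose out of domain: ",
         paste(unique(purpose[!purpose %in% .kept_purposes]), collapse = ", "),
         call. = FALSE)
  }
  reintro <- purpose == "N"
  ifelse(wild,
         ifelse(reintro, "WILD_REINTRO", "WILD_COMMERCIAL"),
         ifelse(reintro, "CAPTIVE_REINTRO", "CAPTIVE_COMMERCIAL"))
}

#' The packaged source-class override table
#'
#' Explicit, citable reclassifications that cannot be derived from permit
#' codes alone. Ships with the Rwanda (Akagera) restocking, whose lions are
#' documented in grey literature as sourced from the South African managed
#' metapopulation despite captive-coded permits.
#'
#' @return data frame with columns `exporter, importer, year_min, year_max,
#'   class, citation`.
#' @export
default_overrides <- function() {
  path <- system.file("extdata", "default_overrides.csv",
                      package = "liontrax", mustWork = TRUE)
  read_overrides(path)
}

#' Read a source-class override table
#'
#' @param path CSV with columns `exporter, importer, year_min, year_max,
#'   class, citation`.
#' @return the override data frame, countries normalized.
#' @export
read_overrides <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character",
                        na.strings = character(0))
  needed <- c("exporter", "importer", "year_min", "year_max", "class")
  missing_cols <- setdiff(needed, tolower(names(df)))
  if (length(missing_cols)) {
    stop("override schema error: missing ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  names(df) <- tolower(names(df))
  if (!"citation" %in% names(df)) df$citation <- ""
  df$exporter <- normalize_country(df$exporter)
  df$importer <- normalize_country(df$importer)
  df$year_min <- as.integer(df$year_min)
  df$year_max <- as.integer(df$year_max)
  df$class <- toupper(df$class)
  stopifnot(all(df$class %in% c("W1", "W2", "C", "U")))
  df
}

#' Adjust raw source codes to W1/W2/C/U classes
#'
#' Applies the re-classification heuristics for the South African managed
#' metapopulation, in fixed precedence: (1) an explicit override row;
#' (2) source `F` or `R` is managed-metapopulation stock, `W2`; (3) South
#' African exports coded `W` after 2005 are `W2` (Kruger and Kgalagadi had
#' ceased to supply translocations); (4) South African exports with a blank
#' source before the mid-1990s cutoff are wild, `W1` (the metapopulation
#' reserves date from 1991 and captive facilities were rare pre-1994);
#' (5) blank-source South African exports at or after the cutoff are `W2`;
#' (6) remaining `W` is `W1`; (7) `C` stays `C`; (8) anything else is `U`
#' (unknown). The clause that fired is recorded per record.
#'
#' Also computes the reconciled `quantity`, the consolidated trade
#' `category`, and the genetic attribution country (`origin` when present
#' and different from the exporter — re-exports — else the exporter).
#'
#' @param records filtered `cites_records`.
#' @param overrides override table from [read_overrides()] /
#'   [default_overrides()], or `NULL` for none.
#' @param mid1990s_cutoff first year no longer treated as pre-mid-1990s
#'   (default 1995).
#' @param fr_w2_all_exporters apply clause (2) to every exporter (default)
#'   or only to South Africa.
#' @param quantity_rule passed to [reconcile_quantity()].
#' @return data frame of class `adjusted_records`: the input columns plus
#'   `quantity, source_class, category, adjustment_rule, genetic_source`.
#' @export
adjust_source <- function(records, overrides = NULL, mid1990s_cutoff = 1995,
                          fr_w2_all_exporters = TRUE,
                          quantity_rule = c("max", "exporter")) {
  n <- nrow(records)
  quantity <- reconcile_quantity(records, match.arg(quantity_rule))
  source_class <- character(n)
  rule <- character(n)
  for (i in seq_len(n)) {
    src <- records$source[i]; exp <- records$exporter[i]
    yr <- records$year[i]
    ov_class <- NA_character_
    if (!is.null(overrides) && nrow(overrides)) {
      hit <- overrides$exporter == exp &
        overrides$importer == records$importer[i] &
        overrides$year_min <= yr & yr <= overrides$year_max
      if (any(hit)) ov_class <- overrides$class[which(hit)[1]]
    }
    if (!is.na(ov_class)) {
      source_class[i] <- ov_class
      rule[i] <- "override-table"
    } else if (src %in% c("F", "R") && (fr_w2_all_exporters || exp == "ZA")) {
      source_class[i] <- "W2"; rule[i] <- "F/R-to-W2"
    } else if (exp == "ZA" && src == "W" && yr > 2005) {
      source_class[i] <- "W2"; rule[i] <- "ZA-W-post-2005-to-W2"
    } else if (exp == "ZA" && src == "" && yr < mid1990s_cutoff) {
      source_class[i] <- "W1"; rule[i] <- "ZA-blank-pre-mid1990s-to-W1"
    } else if (exp == "ZA" && src == "") {
      source_class[i] <- "W2"; rule[i] <- "ZA-blank-post-mid1990s-to-W2"
    } else if (src == "W") {
      source_class[i] <- "W1"; rule[i] <- "W-to-W1"
    } else if (src == "C") {
      source_class[i] <- "C"; rule[i] <- "C-unchanged"
    } else {
      source_class[i] <- "U"; rule[i] <- "unknown-source"
    }
  }
  out <- records
  out$quantity <- quantity
  out$source_class <- source_class
  out$category <- if (n) categorize_trade(source_class, records$purpose)
                  else character(0)
  out$adjustment_rule <- rule
  out$genetic_source <- ifelse(nzchar(records$origin) &
                                 records$origin != records$exporter,
                               records$origin, records$exporter)
  class(out) <- c("adjusted_records", "cites_records", "data.frame")
  attr(out, "exclusions") <- attr(records, "exclusions")
  out
}

#' Write adjusted records to CSV
#'
#' The emitted file is itself parseable by [read_cites_csv()] (the original
#' columns are preserved), so re-running the pipeline on its own output is
#' idempotent.
#'
#' @param records an `adjusted_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjusted <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}
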
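# The population registry: one row per lion conservation unit (LCU), carrying
# the unit's clade profile, assignment certainty, suture-zone membership and
# management flags. This is the machine-readable form of the LCU tables that
# back the country suitability matrix.

.suture_zone_countries <- list(
  SZ1 = c("SD", "SS", "ET"),
  SZ2 = c("ZM", "MW", "MZ")
)

.certainty_levels <- c("high", "fairly_high", "medium")

#' Construct one LCU record
#'
#' @param id stable identifier, unique within a registry.
#' @param name free-text population name.
#' @param countries character vector of ISO-3166 alpha-2 codes (aliases such
#'   as "RSA" are accepted); transboundary units carry all member countries.
#' @param mtdna,nudna clade labels (see [genetic_profile()]).
#' @param certainty one of `"high"`, `"fairly_high"`, `"medium"`.
#' @param suture_zone `"none"`, `"SZ1"` (Sudan/South Sudan/Ethiopia) or
#'   `"SZ2"` (Zambia/Malawi/Mozambique).
#' @param hybrid_origin `TRUE` for populations carrying human-mediated
#'   cross-clade admixture; such records keep their nominal clade labels plus
#'   the introgressed mtDNA labels.
#' @param managed_metapopulation `TRUE` for the South African managed
#'   metapopulation ("W2") stock.
#' @param extant `FALSE` marks historic populations, which are retained in the
#'   registry but excluded from [country_profile()].
#' @param notes free text.
#' @param vocabulary the active [clade_vocabulary()].
#' @return an object of class `lcu_record`.
#' @export
lcu_record <- function(id, name, countries, mtdna, nudna,
                       certainty = "medium", suture_zone = "none",
                       hybrid_origin = FALSE, managed_metapopulation = FALSE,
                       extant = TRUE, notes = "",
                       vocabulary = default_vocabulary()) {
  id <- as.character(id)
  if (!nzchar(id)) stop("LCU id must be non-empty", call. = FALSE)
  countries <- unique(normalize_country(countries))
  certainty <- match.arg(tolower(gsub("[ -]", "_", certainty)), .certainty_levels)
  suture_zone <- toupper(as.character(suture_zone))
  if (suture_zone %in% c("", "NONE")) suture_zone <- "none"
  if (!suture_zone %in% c("none", "SZ1", "SZ2")) {
    stop("suture_zone must be one of none, SZ1, SZ2", call. = FALSE)
  }
  profile <- genetic_profile(mtdna, nudna, vocabulary)
  rec <- structure(
    list(id = id, name = as.character(name), countries = countries,
         profile = profile, certainty = certainty, suture_zone = suture_zone,
         hybrid_origin = isTRUE(as.logical(hybrid_origin)),
         managed_metapopulation = isTRUE(as.logical(managed_metapopulation)),
         extant = isTRUE(as.logical(extant)), notes = as.character(notes)),
    class = "lcu_record"
  )
  if (suture_zone != "none" &&
      length(profile$nudna) < 2L &&
      !any(countries %in% .suture_zone_countries[[suture_zone]])) {
    stop("record '", id, "': suture-zone membership requires >=2 nuDNA labels ",
         "or a country inside the ", suture_zone, " country set", call. = FALSE)
  }
  rec
}

#' @export
print.lcu_record <- function(x, ...) {
  cat(sprintf("<LCU %s> %s [%s]\n", x$id, x$name,
              paste(x$countries, collapse = ",")))
  print(x$profile)
  flags <- c(if (x$suture_zone != "none") x$suture_zone,
             if (x$hybrid_origin) "hybrid",
             if (x$managed_metapopulation) "W2",
             if (!x$extant) "historic")
  cat("  certainty:", x$certainty,
      if (length(flags)) paste0(" flags: ", paste(flags, collapse = ",")), "\n")
  invisible(x)
}

#' Assemble a validated registry
#'
#' @param records list of [lcu_record()] objects.
#' @param vocabulary the shared [clade_vocabulary()].
#' @param range_states ISO alpha-2 codes of countries with current wild lion
#'   presence; defaults to the union of record countries. A range state with
#'   no record triggers a warning (not an error).
#' @return an object of class `lion_registry`.
#' @export
lion_registry <- function(records, vocabulary = default_vocabulary(),
                          range_states = NULL) {
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate LCU id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  all_countries <- unique(unlist(lapply(records, function(r) r$countries)))
  if (is.null(range_states)) {
    range_states <- sort(all_countries)
  } else {
    range_states <- sort(unique(normalize_country(range_states)))
    uncovered <- setdiff(range_states, all_countries)
    if (length(uncovered)) {
      warning("range state(s) with no registry record: ",
              paste(uncovered, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(vocabulary = vocabulary, records = records,
         range_states = range_states),
    class = "lion_registry"
  )
}

#' @export
print.lion_registry <- function(x, ...) {
  cat(sprintf("Lion registry: %d LCUs across %d countries (%d range states)\n",
              length(x$records),
              length(unique(unlist(lapply(x$records, `[[`, "countries")))),
              length(x$range_states)))
  invisible(x)
}

#' @export
length.lion_registry <- function(x) length(x$records)

registry_ids <- function(registry) {
  vapply(registry$records, `[[`, character(1), "id")
}

.registry_columns <- c("id", "name", "countries", "mtdna", "nudna",
                       "certainty", "suture_zone", "hybrid_origin",
                       "managed_metapopulation", "extant", "notes")

#' Read a registry from a delimited text file
#'
#' The file is UTF-8 delimited text (comma by default; tab accepted and
#' auto-detected) with header columns `id, name, countries, mtdna, nudna,
#' certainty, suture_zone, hybrid_origin, managed_metapopulation, extant,
#' notes` (case-insensitive). Multi-valued cells (`countries`, `mtdna`,
#' `nudna`) use `|` as the inner separator. Invalid rows are rejected
#' together, with row-numbered diagnostics.
#'
#' @param path file path.
#' @param vocabulary the [clade_vocabulary()] labels are validated against.
#' @param range_states optional explicit range-state list (ISO alpha-2 or
#'   aliases).
#' @return a `lion_registry`.
#' @export
load_registry <- function(path, vocabulary = default_vocabulary(),
                          range_states = NULL) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  # na.strings is empty so Namibia's ISO code "NA" survives as text
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0))
  names(df) <- tolower(trimws(names(df)))
  missing_cols <- setdiff(setdiff(.registry_columns, "notes"), names(df))
  if (length(missing_cols)) {
    stop("registry schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"notes" %in% names(df)) df$notes <- ""
  if (nrow(df) == 0L) stop("empty registry: file has no data rows", call. = FALSE)

  problems <- character(0)
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      lcu_record(
        id = df$id[i], name = df$name[i],
        countries = split_multi(df$countries[i]),
        mtdna = split_multi(df$mtdna[i]),
        nudna = split_multi(df$nudna[i]),
        certainty = df$certainty[i], suture_zone = df$suture_zone[i],
        hybrid_origin = parse_flag(df$hybrid_origin[i]),
        managed_metapopulation = parse_flag(df$managed_metapopulation[i]),
        extant = parse_flag(df$extant[i], default = TRUE),
        notes = df$notes[i], vocabulary = vocabulary
      ),
      error = function(e) conditionMessage(e)
    )
    if (is.character(rec)) {
      problems <- c(problems, sprintf("row %d: %s", i, rec))
      records[i] <- list(NULL)
    } else {
      records[[i]] <- rec
    }
  }
  if (length(problems)) {
    stop("registry validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  lion_registry(records, vocabulary, range_states)
}

#' Write a registry to a delimited text file
#'
#' Inverse of [load_registry()]: `load_registry(write_registry(r, f))` equals
#' `r` field for field.
#'
#' @param registry a `lion_registry`.
#' @param path output path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path, sep = ",") {
  stopifnot(inherits(registry, "lion_registry"))
  rows <- lapply(registry$records, function(r) {
    data.frame(
      id = r$id, name = r$name,
      countries = paste(r$countries, collapse = "|"),
      mtdna = paste(r$profile$mtdna, collapse = "|"),
      nudna = paste(r$profile$nudna, collapse = "|"),
      certainty = r$certainty, suture_zone = r$suture_zone,
      hybrid_origin = r$hybrid_origin,
      managed_metapopulation = r$managed_metapopulation,
      extant = r$extant, notes = r$notes,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double",
                     fileEncoding = "UTF-8")
  invisible(path)
}

split_multi <- function(x) {
  parts <- trimws(strsplit(as.character(x), "|", fixed = TRUE)[[1]])
  parts[nzchar(parts)]
}

parse_flag <- function(x, default = FALSE) {
  x <- tolower(trimws(as.character(x)))
  if (!length(x) || is.na(x) || !nzchar(x)) return(default)
  if (x %in% c("true", "t", "1", "yes", "y")) return(TRUE)
  if (x %in% c("false", "f", "0", "no", "n")) return(FALSE)
  stop("unparseable logical flag: '", x, "'", call. = FALSE)
}

#' Aggregate the genetic profile of a country
#'
#' Unions the profiles of all extant LCUs listing the country, and reports
#' aggregate flags: whether any contributing unit is hybrid-origin, any sits
#' in a suture zone, any is managed-metapopulation stock, and whether the
#' union spans more than one nuclear clade (`multi_clade`). Historic
#' (`extant = FALSE`) records are excluded.
#'
#' @param registry a `lion_registry`.
#' @param country ISO alpha-2 code or alias.
#' @return an object of class `country_profile`: the union `profile`, the
#'   contributing `records`, and logical flags.
#' @export
country_profile <- function(registry, country) {
  stopifnot(inherits(registry, "lion_registry"))
  country <- normalize_country(country)
  recs <- Filter(function(r) r$extant && country %in% r$countries,
                 registry$records)
  if (!length(recs)) {
    stop("no extant lion population on record for country ", country,
         call. = FALSE)
  }
  mt <- sort(unique(unlist(lapply(recs, function(r) r$profile$mtdna))))
  nu <- sort(unique(unlist(lapply(recs, function(r) r$profile$nudna))))
  structure(
    list(country = country,
         profile = genetic_profile(mt, nu, registry$vocabulary),
         records = recs,
         lcu_ids = vapply(recs, `[[`, character(1), "id"),
         any_hybrid = any(vapply(recs, `[[`, logical(1), "hybrid_origin")),
         any_suture = any(vapply(recs, function(r) r$suture_zone != "none",
                                 logical(1))),
         any_w2 = any(vapply(recs, `[[`, logical(1),
                             "managed_metapopulation")),
         multi_clade = length(nu) > 1L),
    class = "country_profile"
  )
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("Country %s (%d LCU%s): ", x$country, length(x$records),
              if (length(x$records) > 1) "s" else ""))
  print(x$profile)
  flags <- c(if (x$any_hybrid) "hybrid", if (x$any_suture) "suture",
             if (x$any_w2) "W2", if (x$multi_clade) "multi-clade")
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' The packaged country-level lion registry
#'
#' A country-level approximation of the full LCU table, encoding the facts
#' the continental synthesis states directly: suture zone 1
#' (Sudan/South Sudan/Ethiopia, nuclear Central x East overlap across the two
#' subspecies), suture zone 2 (Zambia/Malawi/Mozambique, East x Southern),
#' the Kavango-Zambezi mtDNA haplogroup overlap (South West with
#' East/Southern, all Southern nuclear clade, hence not a suture zone),
#' hybrid-origin flags for the Kruger-area and managed-metapopulation stock
#' in South Africa and for Zimbabwe, Eswatini, Rwanda, Malawi and Lake
#' Nakuru-Soysambu in Kenya, and the Indian population nested in
#' *P. l. leo*. It is an approximation at country scale, not the full
#' 132-unit table; load the full table with [load_registry()] when available.
#'
#' @return a `lion_registry`.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "default_registry.csv", package = "liontrax",
                      mustWork = TRUE)
  load_registry(path, default_vocabulary())
}
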
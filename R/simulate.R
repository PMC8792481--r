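# Seed-controlled synthetic registries and CITES-style trade-record sets
# with ground-truth sidecars. The generators are first-class: every pipeline
# stage is testable record-by-record against the generator's bookkeeping,
# with no download.

#' Parameters for registry simulation
#'
#' @param n_lcus number of simulated conservation units.
#' @param n_mt_clades,n_nu_clades sizes of the simulated clade vocabularies.
#' @param subspecies_split fraction of nuclear clades assigned to
#'   *melanochaita* (the rest are *leo*).
#' @param p_suture probability an LCU sits in a suture zone (such units get
#'   two nuclear labels).
#' @param p_hybrid probability of hybrid origin (an extra introgressed mtDNA
#'   label).
#' @param countries_per_lcu countries listed per unit.
#' @param seed RNG seed; identical parameters and seed give an identical
#'   registry.
#' @return a list of class `registry_sim_params`.
#' @export
registry_sim_params <- function(n_lcus = 20, n_mt_clades = 4, n_nu_clades = 3,
                                subspecies_split = 0.5, p_suture = 0.1,
                                p_hybrid = 0.1, countries_per_lcu = 1,
                                seed = 1) {
  stopifnot(n_lcus >= 1, n_mt_clades >= 1, n_nu_clades >= 1,
            subspecies_split >= 0, subspecies_split <= 1,
            p_suture >= 0, p_suture <= 1, p_hybrid >= 0, p_hybrid <= 1,
            countries_per_lcu >= 1)
  structure(as.list(environment()), class = "registry_sim_params")
}

#' Simulate a registry with known composition
#'
#' Builds a synthetic clade vocabulary (`mt1..mtK`, `nu1..nuK`; the last
#' `subspecies_split` fraction of nuclear clades are *melanochaita*), draws
#' each unit's clades, suture and hybrid flags, and assigns real ISO country
#' codes from a reserved pool. The returned ground-truth table records every
#' unit's intended labels and flags so recovery can be checked without
#' consulting the registry code.
#'
#' @param params a [registry_sim_params()].
#' @return list with elements `registry` (a `lion_registry`), `vocabulary`,
#'   and `ground_truth` (data frame).
#' @export
simulate_registry <- function(params = registry_sim_params()) {
  stopifnot(inherits(params, "registry_sim_params"))
  set.seed(params$seed)
  mt_labels <- paste0("mt", seq_len(params$n_mt_clades))
  nu_labels <- paste0("nu", seq_len(params$n_nu_clades))
  n_mel <- round(params$subspecies_split * params$n_nu_clades)
  ssp <- stats::setNames(
    c(rep("leo", params$n_nu_clades - n_mel), rep("melanochaita", n_mel)),
    nu_labels)
  vocab <- clade_vocabulary(mt_labels, nu_labels, ssp)

  country_pool <- setdiff(.iso_alpha2,
                          c("XX", "ZR", "CS", "SU", "YU", "DD", "AN"))
  need <- params$n_lcus * params$countries_per_lcu
  if (need > length(country_pool)) {
    country_pool <- rep(country_pool, length.out = need)  # reuse -> transboundary
  }
  countries <- sample(country_pool, need, replace = need > length(country_pool))

  records <- vector("list", params$n_lcus)
  gt <- vector("list", params$n_lcus)
  for (i in seq_len(params$n_lcus)) {
    nu <- sample(nu_labels, 1)
    suture <- stats::runif(1) < params$p_suture && params$n_nu_clades >= 2
    if (suture) nu <- c(nu, sample(setdiff(nu_labels, nu), 1))
    mt <- sample(mt_labels, 1)
    hybrid <- stats::runif(1) < params$p_hybrid && params$n_mt_clades >= 2
    if (hybrid) mt <- c(mt, sample(setdiff(mt_labels, mt), 1))
    cc <- countries[((i - 1) * params$countries_per_lcu + 1):
                      (i * params$countries_per_lcu)]
    records[[i]] <- lcu_record(
      id = sprintf("SIM%03d", i), name = sprintf("Simulated unit %d", i),
      countries = cc, mtdna = mt, nudna = nu,
      certainty = sample(c("high", "fairly_high", "medium"), 1),
      suture_zone = if (suture) sample(c("SZ1", "SZ2"), 1) else "none",
      hybrid_origin = hybrid, vocabulary = vocab)
    gt[[i]] <- data.frame(
      id = sprintf("SIM%03d", i),
      mtdna = paste(sort(unique(mt)), collapse = "|"),
      nudna = paste(sort(unique(nu)), collapse = "|"),
      countries = paste(cc, collapse = "|"),
      suture = suture, hybrid = hybrid, stringsAsFactors = FALSE)
  }
  list(registry = lion_registry(records, vocab),
       vocabulary = vocab,
       ground_truth = do.call(rbind, gt))
}

#' Parameters for trade-record simulation
#'
#' @param n_records number of in-scope permit rows to generate.
#' @param class_weights named weights over intended adjusted classes
#'   `W1, W2, C, U, OVERRIDE` (`OVERRIDE` rows are captive-coded permits
#'   covered by the packaged override table, i.e. the Rwanda restocking
#'   pattern); normalized internally.
#' @param category_weights named weights over the four trade categories;
#'   since the wild/captive side of the category is fixed by the class, only
#'   the conditional reintroduction-vs-commercial split is used.
#' @param year_range inclusive years, default `c(1983, 2019)`.
#' @param quantity_mean mean of the truncated-geometric permit quantity law
#'   (small permit sizes are typical of live-animal trade).
#' @param exporter_pools named list of per-class exporter probability
#'   vectors (named by ISO code); `NULL` for built-in pools.
#' @param importer_pool named probability vector over importing range
#'   states; `NULL` for a built-in pool.
#' @param p_malformed fraction of injected malformed rows (unparseable
#'   year); opt-in, default 0.
#' @param p_out_of_scope fraction of injected out-of-scope rows (non-live
#'   terms, non-range importers, excluded purposes); opt-in, default 0.
#' @param seed RNG seed.
#' @return a list of class `trade_sim_params`.
#' @export
trade_sim_params <- function(n_records = 500,
                             class_weights = c(W1 = 0.25, W2 = 0.25,
                                               C = 0.25, U = 0.15,
                                               OVERRIDE = 0.10),
                             category_weights = c(WILD_REINTRO = 0.25,
                                                  CAPTIVE_REINTRO = 0.25,
                                                  WILD_COMMERCIAL = 0.25,
                                                  CAPTIVE_COMMERCIAL = 0.25),
                             year_range = c(1983, 2019),
                             quantity_mean = 2,
                             exporter_pools = NULL, importer_pool = NULL,
                             p_malformed = 0, p_out_of_scope = 0, seed = 1) {
  stopifnot(n_records >= 0, quantity_mean >= 1,
            all(class_weights >= 0), sum(class_weights) > 0,
            all(category_weights >= 0), sum(category_weights) > 0,
            p_malformed >= 0, p_malformed <= 1,
            p_out_of_scope >= 0, p_out_of_scope <= 1,
            year_range[1] <= year_range[2])
  stopifnot(setequal(names(class_weights),
                     c("W1", "W2", "C", "U", "OVERRIDE")))
  class_weights <- class_weights / sum(class_weights)
  category_weights <- category_weights / sum(category_weights)
  structure(as.list(environment()), class = "trade_sim_params")
}

.default_exporter_pools <- list(
  W1 = c(ZW = 0.25, ZA = 0.20, BW = 0.15, NA. = 0.13, TZ = 0.08, ZM = 0.07,
         KE = 0.05, MZ = 0.04, UG = 0.03),
  W2 = c(ZA = 1),
  C = c(ZA = 0.25, ZW = 0.14, US = 0.12, FR = 0.08, DE = 0.08, GB = 0.05,
        ES = 0.03, BW = 0.08, NA. = 0.07, TZ = 0.05, ZM = 0.05),
  U = c(ZW = 0.3, BW = 0.25, TZ = 0.2, KE = 0.15, ZM = 0.1),
  OVERRIDE = c(ZA = 1)
)

.default_importer_pool <- c(ZA = 0.60, ZM = 0.07, MZ = 0.05, ZW = 0.05,
                            BW = 0.04, NA. = 0.04, TZ = 0.04, KE = 0.03,
                            MW = 0.02, UG = 0.02, SN = 0.02, BJ = 0.02)

# "NA." is used as a list name for Namibia to survive R name mangling
fix_na_name <- function(x) { names(x)[names(x) == "NA."] <- "NA"; x }

#' Simulate a CITES-dialect trade-record file with ground truth
#'
#' Writes (or returns) a table in the comparative-tabulation dialect read by
#' [read_cites_csv()]. Permit codes are constructed so that
#' [adjust_source()] with the packaged override table deterministically
#' recovers each record's intended class: `W1` rows are coded `W` (South
#' African ones dated 2005 or earlier), `W2` rows are coded `F`/`R`, `C`
#' rows are captive-coded away from the override pattern, `U` rows have a
#' blank source outside South Africa, and `OVERRIDE` rows replicate the
#' captive-coded Rwanda restocking covered by [default_overrides()].
#'
#' The ground-truth sidecar has one row per emitted CSV data row, in file
#' order, recording the intended class, category, quantity and flags, plus
#' whether the row was deliberately malformed or out of scope; kept pipeline
#' rows therefore align with `ground_truth[!malformed & !out_of_scope, ]`
#' row for row.
#'
#' @param params a [trade_sim_params()].
#' @param registry a `lion_registry` supplying the importer pool (its range
#'   states) when `importer_pool` is `NULL`.
#' @param path optional CSV output path; when `NULL` no file is written.
#' @return list with `table` (data frame in CITES dialect), `ground_truth`
#'   (data frame), and `path`.
#' @export
simulate_trade <- function(params = trade_sim_params(),
                           registry = default_registry(), path = NULL) {
  stopifnot(inherits(params, "trade_sim_params"))
  set.seed(params$seed)
  pools <- if (is.null(params$exporter_pools)) .default_exporter_pools
           else params$exporter_pools
  pools <- lapply(pools, fix_na_name)
  imp_pool <- fix_na_name(
    if (is.null(params$importer_pool)) .default_importer_pool
    else params$importer_pool)
  imp_pool <- imp_pool[names(imp_pool) %in% registry$range_states]
  if (!length(imp_pool)) {
    imp_pool <- stats::setNames(rep(1, length(registry$range_states)),
                                registry$range_states)
  }
  cw <- params$class_weights
  catw <- params$category_weights
  p_reintro_wild <- catw["WILD_REINTRO"] /
    max(catw["WILD_REINTRO"] + catw["WILD_COMMERCIAL"], 1e-12)
  p_reintro_capt <- catw["CAPTIVE_REINTRO"] /
    max(catw["CAPTIVE_REINTRO"] + catw["CAPTIVE_COMMERCIAL"], 1e-12)

  n <- params$n_records
  rows <- vector("list", n)
  gt <- vector("list", n)
  rgeom_trunc <- function(mean) {
    as.integer(min(1L + stats::rgeom(1, prob = 1 / mean), 25L))
  }
  for (i in seq_len(n)) {
    cls <- sample(names(cw), 1, prob = cw)
    year <- sample(params$year_range[1]:params$year_range[2], 1)
    q <- rgeom_trunc(params$quantity_mean)
    importer <- sample(names(imp_pool), 1, prob = imp_pool)
    exporter <- sample(names(pools[[cls]]), 1, prob = pools[[cls]])
    src <- switch(cls,
      W1 = "W",
      W2 = sample(c("F", "R"), 1),
      C = "C",
      U = "",
      OVERRIDE = "C")
    if (cls == "W1" && exporter == "ZA" && year > 2005) {
      year <- sample(params$year_range[1]:2005, 1)
    }
    if (cls == "U" && exporter == "ZA") exporter <- "ZW"
    if (cls == "OVERRIDE") {
      importer <- "RW"
      year <- sample(2015:2017, 1)
    }
    if (cls == "C" && exporter == "ZA" && importer == "RW" &&
        year >= 2015 && year <= 2017) {
      importer <- "ZA"  # keep plain captive rows off the override pattern
    }
    wild_side <- cls %in% c("W1", "W2", "OVERRIDE")
    p_reintro <- if (wild_side) p_reintro_wild else p_reintro_capt
    purpose <- if (stats::runif(1) < p_reintro) "N"
               else sample(c("T", "B", "H"), 1)
    adj_class <- if (cls == "OVERRIDE") "W2" else cls
    category <- categorize_trade(adj_class, purpose)
    # both parties usually report; the importer sometimes under-reports
    qi <- if (stats::runif(1) < 0.3) "" else as.character(max(q - sample(0:1, 1), 0))
    rows[[i]] <- data.frame(
      Year = as.character(year), Taxon = "Panthera leo",
      Importer = importer, Exporter = exporter, Origin = "",
      `Importer reported quantity` = qi,
      `Exporter reported quantity` = as.character(q),
      Term = "live", Unit = "", Purpose = purpose, Source = src,
      check.names = FALSE, stringsAsFactors = FALSE)
    gt[[i]] <- data.frame(
      row = i, intended_class = adj_class, raw_source = src,
      category = category, purpose = purpose, exporter = exporter,
      importer = importer, year = year, quantity = q,
      expected_suitability = switch(adj_class, C = "NO_OPTION",
                                    U = "NO_OPTION", W2 = "W2",
                                    NA_character_),
      malformed = FALSE, out_of_scope = FALSE, reason = "",
      stringsAsFactors = FALSE)
  }
  tab <- if (n) do.call(rbind, rows) else empty_cites_table()
  gt <- if (n) do.call(rbind, gt) else empty_trade_gt()

  if (n && params$p_out_of_scope > 0) {
    k <- stats::rbinom(1, n, params$p_out_of_scope)
    for (j in seq_len(k)) {
      kind <- sample(c("term", "importer", "purpose", "year"), 1)
      row <- tab[sample(n, 1), , drop = FALSE]
      reason <- switch(kind,
        term = { row$Term <- "trophies"; "term-not-live" },
        importer = { row$Importer <- "US"; "importer-not-range-state" },
        purpose = { row$Purpose <- "Z"; "purpose-excluded" },
        year = { row$Year <- "1975"; "year-out-of-range" })
      tab <- rbind(tab, row)
      gt <- rbind(gt, data.frame(
        row = nrow(tab), intended_class = NA_character_,
        raw_source = row$Source, category = NA_character_,
        purpose = row$Purpose, exporter = row$Exporter,
        importer = row$Importer, year = suppressWarnings(as.integer(row$Year)),
        quantity = max(as.integer(row$`Exporter reported quantity`),
                       suppressWarnings(as.integer(row$`Importer reported quantity`)),
                       0, na.rm = TRUE),
        expected_suitability = NA_character_, malformed = FALSE,
        out_of_scope = TRUE, reason = reason, stringsAsFactors = FALSE))
    }
  }
  if (n && params$p_malformed > 0) {
    k <- stats::rbinom(1, n, params$p_malformed)
    for (j in seq_len(k)) {
      row <- tab[sample(n, 1), , drop = FALSE]
      row$Year <- "199O"  # letter O: unparseable
      tab <- rbind(tab, row)
      gt <- rbind(gt, data.frame(
        row = nrow(tab), intended_class = NA_character_,
        raw_source = row$Source, category = NA_character_,
        purpose = row$Purpose, exporter = row$Exporter,
        importer = row$Importer, year = NA_integer_,
        quantity = NA_integer_, expected_suitability = NA_character_,
        malformed = TRUE, out_of_scope = FALSE, reason = "unparseable-year",
        stringsAsFactors = FALSE))
    }
  }
  rownames(tab) <- NULL
  rownames(gt) <- NULL
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(table = tab, ground_truth = gt, path = path)
}

empty_cites_table <- function() {
  data.frame(Year = character(0), Taxon = character(0),
             Importer = character(0), Exporter = character(0),
             Origin = character(0),
             `Importer reported quantity` = character(0),
             `Exporter reported quantity` = character(0),
             Term = character(0), Unit = character(0),
             Purpose = character(0), Source = character(0),
             check.names = FALSE, stringsAsFactors = FALSE)
}

empty_trade_gt <- function() {
  data.frame(row = integer(0), intended_class = character(0),
             raw_source = character(0), category = character(0),
             purpose = character(0), exporter = character(0),
             importer = character(0), year = integer(0),
             quantity = integer(0), expected_suitability = character(0),
             malformed = logical(0), out_of_scope = logical(0),
             reason = character(0), stringsAsFactors = FALSE)
}

#' Replication-profile trade parameters
#'
#' A parameter set whose expected composition mirrors the headline audit
#' proportions: roughly 81% of individuals captive-coded on the raw permits,
#' about 7% of those reclassified to `W2` by the override pattern (so about
#' 73% remain captive after adjustment and about 10% end up `W2`), South
#' Africa dominant on both the exporter and importer side, and permit
#' quantities following the small truncated-geometric law. Intended for
#' demonstration and composition checks, not as a reconstruction of the
#' underlying permit table.
#'
#' @param n number of permit rows (default 1056, the audited record count).
#' @param seed RNG seed.
#' @return a `trade_sim_params` object.
#' @export
replication_profile <- function(n = 1056, seed = 1) {
  trade_sim_params(
    n_records = n,
    class_weights = c(W1 = 0.167, W2 = 0.028, C = 0.729, U = 0.002,
                      OVERRIDE = 0.074),
    category_weights = c(WILD_REINTRO = 0.12, CAPTIVE_REINTRO = 0.18,
                         WILD_COMMERCIAL = 0.14, CAPTIVE_COMMERCIAL = 0.56),
    year_range = c(1983, 2019),
    quantity_mean = 2,
    importer_pool = c(ZA = 0.60, ZM = 0.07, MZ = 0.05, ZW = 0.05,
                      BW = 0.04, NA. = 0.04, TZ = 0.04, KE = 0.03,
                      MW = 0.02, UG = 0.02),
    seed = seed)
}
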
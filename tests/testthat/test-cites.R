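test_that("comparative-tabulation files parse, including subspecies spellings", {
  f <- write_cites_fixture(list(
    cites_row(source = "C", purpose = "T"),
    cites_row(taxon = "Panthera leo persica", importer = "IN", exporter = "IN"),
    cites_row(term = "trophies")
  ))
  recs <- read_cites_csv(f)
  expect_equal(nrow(recs), 3)
  expect_true(all(liontrax:::is_lion_taxon(recs$taxon)))
  expect_identical(recs$term[3], "trophies")  # parsed; excluded later by filter
  expect_length(attr(recs, "diagnostics"), 0)
})

test_that("malformed rows are reported with line numbers, not dropped silently", {
  rows <- list(cites_row(), cites_row(year = "199O"), cites_row(qe = "-3"))
  f <- write_cites_fixture(rows)
  recs <- read_cites_csv(f)
  expect_equal(nrow(recs), 1)
  d <- attr(recs, "diagnostics")
  expect_length(d, 2)
  expect_match(d[1], "line 3: unparseable Year '199O'")
  expect_match(d[2], "line 4")
})

test_that("unrecognized headers raise a schema error listing the columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Annum,Species,To,From", "2000,Panthera leo,ZA,ZW"), f)
  expect_error(read_cites_csv(f), "schema error")
})

test_that("quantity reconciliation takes the permit maximum", {
  df <- data.frame(qty_importer = c(4, NA, 0), qty_exporter = c(6, 2, 0))
  expect_identical(reconcile_quantity(df), c(6L, 2L, 0L))
  expect_identical(reconcile_quantity(df, rule = "exporter"), c(6L, 2L, 0L))
  df2 <- data.frame(qty_importer = c(5, 3), qty_exporter = c(2, NA))
  expect_identical(reconcile_quantity(df2), c(5L, 3L))
  expect_identical(reconcile_quantity(df2, rule = "exporter"), c(2L, 3L))
})

test_that("inclusion filters keep the audit scope and tally every exclusion", {
  rs <- c("ZA", "ZM", "MW")
  f <- write_cites_fixture(list(
    cites_row(importer = "ZA"),                        # kept
    cites_row(importer = "US", qe = "5"),              # not a range state
    cites_row(purpose = "Z", qe = "3"),                # zoo purpose
    cites_row(term = "trophies", qe = "7"),
    cites_row(year = 1960, qe = "2"),
    cites_row(taxon = "Acinonyx jubatus", qe = "4"),
    cites_row(source = "I", qe = "1"),                 # seized/confiscated
    cites_row(qi = "0", qe = "0")                      # zero quantity
  ))
  recs <- read_cites_csv(f)
  kept <- filter_records(recs, rs)
  expect_equal(nrow(kept), 1)
  excl <- attr(kept, "exclusions")
  get <- function(fl, col) excl[excl$filter == fl, col]
  expect_equal(get("importer-not-range-state", "individuals"), 5)
  expect_equal(get("purpose-excluded", "records"), 1)
  expect_equal(get("term-not-live", "individuals"), 7)
  expect_equal(get("year-out-of-range", "records"), 1)
  expect_equal(get("taxon-not-lion", "records"), 1)
  expect_equal(get("source-excluded", "records"), 1)
  expect_equal(get("zero-quantity", "records"), 1)
  # conservation: individuals in = kept + excluded
  expect_equal(attr(kept, "individuals_in"),
               attr(kept, "individuals_kept") + sum(excl$individuals))
  # empty input
  empty <- filter_records(recs[0, ], rs)
  expect_equal(nrow(empty), 0)
  expect_true(all(attr(empty, "exclusions")$records == 0))
})

test_that("trade categorization is total and exact over its code domain", {
  for (src in c("W", "F", "R")) {
    expect_identical(categorize_trade(src, "N"), "WILD_REINTRO")
    for (p in c("T", "B", "H")) {
      expect_identical(categorize_trade(src, p), "WILD_COMMERCIAL")
    }
  }
  expect_identical(categorize_trade("C", "N"), "CAPTIVE_REINTRO")
  for (p in c("T", "B", "H")) {
    expect_identical(categorize_trade("C", p), "CAPTIVE_COMMERCIAL")
  }
  expect_error(categorize_trade("X", "N"), "classification error")
  expect_error(categorize_trade("W", "Z"), "classification error")
})

test_that("source-class adjustment clauses fire in precedence order", {
  rows <- list(
    cites_row(exporter = "ZA", year = 2010, source = "W"),   # W2: post-2005
    cites_row(exporter = "ZA", year = 1990, source = ""),    # W1: pre-cutoff
    cites_row(exporter = "ZA", year = 1996, source = ""),    # W2: post-cutoff
    cites_row(exporter = "ZM", year = 2001, source = "F"),   # W2: F/R anywhere
    cites_row(exporter = "KE", year = 2000, source = "C"),   # C unchanged
    cites_row(exporter = "ZA", importer = "RW", year = 2015,
              source = "C"),                                 # override row
    cites_row(exporter = "BW", year = 1999, source = "W"),   # W1
    cites_row(exporter = "TZ", year = 1999, source = "")     # U
  )
  recs <- read_cites_csv(write_cites_fixture(rows))
  adj <- adjust_source(recs, default_overrides())
  expect_identical(adj$source_class,
                   c("W2", "W1", "W2", "W2", "C", "W2", "W1", "U"))
  expect_identical(adj$adjustment_rule[6], "override-table")
  expect_identical(adj$adjustment_rule[1], "ZA-W-post-2005-to-W2")
  # scoping the F/R clause to South Africa is a config switch
  adj2 <- adjust_source(recs, default_overrides(), fr_w2_all_exporters = FALSE)
  expect_identical(adj2$source_class[4], "U")
  # configurable mid-1990s cutoff
  adj3 <- adjust_source(recs, mid1990s_cutoff = 1997)
  expect_identical(adj3$source_class[3], "W1")
})

test_that("adjustment is order-stable under record permutation", {
  sim <- simulate_trade(trade_sim_params(n_records = 60, seed = 3))
  recs <- read_cites_csv(write_cites_fixture(list(sim$table)))
  adj <- adjust_source(recs, default_overrides())
  perm <- sample(nrow(recs))
  adj_p <- adjust_source(recs[perm, ], default_overrides())
  expect_identical(adj_p$source_class, adj$source_class[perm])
})

test_that("origin wins over exporter for genetic attribution on re-exports", {
  recs <- read_cites_csv(write_cites_fixture(list(
    cites_row(exporter = "US", origin = "TZ", source = "W"),
    cites_row(exporter = "ZW", origin = "", source = "W")
  )))
  adj <- adjust_source(recs)
  expect_identical(adj$genetic_source, c("TZ", "ZW"))
})

test_that("re-running the pipeline on its own emitted file is idempotent", {
  reg <- default_registry()
  sim <- simulate_trade(trade_sim_params(n_records = 80, seed = 9), reg)
  f1 <- write_cites_fixture(list(sim$table))
  adj <- adjust_source(filter_records(read_cites_csv(f1), reg$range_states),
                       default_overrides())
  f2 <- tempfile(fileext = ".csv")
  write_adjusted(adj, f2)
  adj2 <- adjust_source(filter_records(read_cites_csv(f2), reg$range_states),
                        default_overrides())
  expect_identical(adj2$source_class, adj$source_class)
  expect_identical(adj2$quantity, adj$quantity)
  expect_identical(adj2$category, adj$category)
})
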
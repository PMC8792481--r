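test_that("vocabulary enforces a complete nuclear-clade to subspecies map", {
  expect_error(
    clade_vocabulary("m1", c("n1", "n2"), c(n1 = "leo")),
    "subspecies"
  )
  v <- clade_vocabulary(c("M1", " m2 "), c("N1", "n2"),
                        c(N1 = "Leo", n2 = "melanochaita"))
  expect_setequal(v$mtdna_labels, c("m1", "m2"))
  expect_identical(unname(v$subspecies_of["n1"]), "leo")
})

test_that("genetic profiles reject empty or out-of-vocabulary label sets", {
  v <- default_vocabulary()
  expect_error(genetic_profile(character(0), "west", v), "at least one")
  expect_error(genetic_profile("west", "souther", v), "souther")
  p <- genetic_profile(c("West", "CENTRAL"), "west", v)
  expect_setequal(p$mtdna, c("west", "central"))
})

test_that("registry files round-trip field for field, csv and tsv", {
  reg <- default_registry()
  for (sep in c(",", "\t")) {
    f <- tempfile(fileext = ".csv")
    write_registry(reg, f, sep = sep)
    back <- load_registry(f)
    expect_identical(length(back), length(reg))
    for (i in seq_along(reg$records)) {
      expect_identical(back$records[[i]], reg$records[[i]])
    }
    expect_identical(back$range_states, reg$range_states)
  }
})

test_that("unicode LCU names survive a write/load round trip", {
  v <- default_vocabulary()
  rec <- lcu_record("u1", "Réserve de Niokolo–Koba", "SN",
                    "west", "west", vocabulary = v)
  f <- tempfile(fileext = ".csv")
  write_registry(lion_registry(list(rec), v), f)
  expect_identical(load_registry(f)$records[[1]]$name,
                   "Réserve de Niokolo–Koba")
})

test_that("invalid rows are rejected with row-numbered diagnostics", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,name,countries,mtdna,nudna,certainty,suture_zone,hybrid_origin,managed_metapopulation,extant,notes",
    "a,Good,TZ,east/southern,east,high,none,FALSE,FALSE,TRUE,",
    "b,BadClade,TZ,east/southern,Souther,high,none,FALSE,FALSE,TRUE,",
    "c,BadCountry,QQ,east/southern,east,high,none,FALSE,FALSE,TRUE,"
  ), f)
  err <- tryCatch(load_registry(f), error = conditionMessage)
  expect_match(err, "row 2: .*souther")
  expect_match(err, "row 3: .*QQ")
})

test_that("schema errors name the missing column and empty files are refused", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,name,countries,mtdna,certainty,suture_zone,hybrid_origin,managed_metapopulation,extant",
               "a,A,TZ,west,high,none,FALSE,FALSE,TRUE"), f)
  expect_error(load_registry(f), "nudna")
  f2 <- tempfile(fileext = ".csv")
  writeLines("id,name,countries,mtdna,nudna,certainty,suture_zone,hybrid_origin,managed_metapopulation,extant,notes",
             f2)
  expect_error(load_registry(f2), "empty registry")
})

test_that("duplicate ids are rejected", {
  v <- default_vocabulary()
  r <- lcu_record("x", "X", "TZ", "east/southern", "east", vocabulary = v)
  expect_error(lion_registry(list(r, r), v), "duplicate")
})

test_that("country aliases resolve and unknown codes error", {
  expect_identical(normalize_country(c("RSA", "drc", "na")), c("ZA", "CD", "NA"))
  expect_error(normalize_country("Atlantis"), "ATLANTIS")
  expect_identical(normalize_country("Atlantis", strict = FALSE), NA_character_)
})

test_that("country_profile unions profiles and is order-independent", {
  v <- default_vocabulary()
  recs <- list(
    lcu_record("k1", "north", "KE", "north east", "east", vocabulary = v),
    lcu_record("k2", "south", "KE", "east/southern", "east", vocabulary = v),
    lcu_record("d1", "drc-c", "CD", "central", "central", vocabulary = v),
    lcu_record("d2", "drc-e", "CD", "north east", "east", vocabulary = v),
    lcu_record("t1", "tz", "TZ", "east/southern", "east", vocabulary = v)
  )
  reg <- lion_registry(recs, v)
  ke <- country_profile(reg, "KE")
  expect_setequal(ke$profile$mtdna, c("north east", "east/southern"))
  expect_false(ke$multi_clade)
  cd <- country_profile(reg, "CD")
  expect_true(cd$multi_clade)
  tz <- country_profile(reg, "TZ")
  expect_identical(tz$profile, recs[[5]]$profile)

  reg_perm <- lion_registry(recs[c(4, 2, 5, 1, 3)], v)
  ke2 <- country_profile(reg_perm, "KE")
  expect_identical(ke2$profile, ke$profile)
  expect_identical(country_profile(reg, "KE")$profile, ke$profile)  # idempotent
  expect_error(country_profile(reg, "GH"), "no extant lion population")
})

test_that("historic records are kept in the registry but excluded from profiles", {
  v <- default_vocabulary()
  recs <- list(
    lcu_record("h", "historic", "ET", "central", "central", extant = FALSE,
               vocabulary = v),
    lcu_record("e", "extant", "ET", "north east", "east", vocabulary = v)
  )
  reg <- lion_registry(recs, v)
  expect_identical(country_profile(reg, "ET")$lcu_ids, "e")
  f <- tempfile(); write_registry(reg, f)
  expect_false(load_registry(f)$records[[1]]$extant)
})

test_that("the packaged registry satisfies every record invariant", {
  reg <- default_registry()
  expect_gt(length(reg), 20)
  for (r in reg$records) {
    expect_true(all(is_iso_alpha2(r$countries)))
    expect_true(r$certainty %in% c("high", "fairly_high", "medium"))
    if (r$suture_zone != "none") {
      expect_true(length(r$profile$nudna) >= 2 ||
                    any(r$countries %in%
                          liontrax:::.suture_zone_countries[[r$suture_zone]]))
    }
  }
  # facts stated by the continental synthesis
  sz1 <- Filter(function(r) r$suture_zone == "SZ1", reg$records)
  expect_setequal(unlist(lapply(sz1, `[[`, "countries")), c("SD", "SS", "ET"))
  sz2 <- Filter(function(r) r$suture_zone == "SZ2", reg$records)
  expect_setequal(unlist(lapply(sz2, `[[`, "countries")), c("ZM", "MW", "MZ"))
  for (cc in c("ZA", "ZW", "SZ", "RW", "MW", "KE")) {
    expect_true(country_profile(reg, cc)$any_hybrid, label = cc)
  }
  expect_true(country_profile(reg, "ZA")$any_w2)
  # KAZA: mtDNA haplogroups overlap but the nuclear clade is Southern only
  bw <- country_profile(reg, "BW")
  expect_setequal(bw$profile$mtdna, c("south west", "east/southern"))
  expect_identical(bw$profile$nudna, "southern")
  expect_false(bw$any_suture)
  # the Gir record maps to P. l. leo through its nuclear clade
  gir <- Filter(function(r) "IN" %in% r$countries, reg$records)[[1]]
  expect_identical(subspecies_of(gir$profile$nudna, reg$vocabulary), "leo")
})
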
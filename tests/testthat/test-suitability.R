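v <- default_vocabulary()

test_that("pairwise levels follow the hierarchical rules", {
  a <- make_rec("a", "southern", "east/southern", v)
  b <- make_rec("b", "southern", "east/southern", v)
  expect_identical(score_pair(a, b, v)$level, "FIRST")

  c1 <- make_rec("c1", "southern", "south west", v)
  expect_identical(score_pair(c1, b, v)$level, "SECOND")

  d <- make_rec("d", "east", "east/southern", v)
  e <- make_rec("e", "southern", "south west", v)
  expect_identical(score_pair(d, e, v)$level, "THIRD")

  w <- make_rec("w", "west", "west", v)
  i <- make_rec("i", "india", "india", v)
  expect_identical(score_pair(w, i, v)$level, "NO_OPTION")
  expect_identical(score_pair(i, w, v)$level, "NO_OPTION")

  # third choice is unavailable within P. l. leo
  cen <- make_rec("cen", "central", "central", v)
  expect_identical(score_pair(w, cen, v)$level, "NO_OPTION")
})

test_that("multi-haplogroup units score FIRST against either parent clade", {
  kaza <- make_rec("kaza", "southern", c("south west", "east/southern"), v)
  sw <- make_rec("sw", "southern", "south west", v)
  es <- make_rec("es", "southern", "east/southern", v)
  expect_identical(score_pair(kaza, sw, v)$level, "FIRST")
  expect_identical(score_pair(kaza, es, v)$level, "FIRST")
})

test_that("self-pairs are FIRST and hybrid/W2 sources carry flags, not demotion", {
  h <- make_rec("h", "southern", c("east/southern", "south west"), v,
                hybrid = TRUE, w2 = TRUE)
  s <- score_pair(h, h, v)
  expect_identical(s$level, "FIRST")
  expect_true(s$hybrid_source)
  expect_true(s$w2_source)
  plain <- make_rec("p", "east", "east/southern", v)
  expect_false(score_pair(plain, plain, v)$hybrid_source)
})

test_that("vocabulary mismatch is a configuration error", {
  small <- clade_vocabulary("m1", "n1", c(n1 = "leo"))
  a <- make_rec("a", "n1", "m1", small)
  expect_error(score_pair(a, a, v), "configuration")
})

test_that("suture directionality: into is best-case, out is worst-case, within is FIRST", {
  sz1 <- lcu_record("sz1", "suture", "ET", c("central", "north east"),
                    c("central", "east"), suture_zone = "SZ1", vocabulary = v)
  central <- make_rec("cen", "central", "central", v, country = "CM")
  southern <- make_rec("sou", "southern", "east/southern", v, country = "ZA")

  into <- apply_suture_direction(score_pair(central, sz1, v), central, sz1, v)
  expect_true(into$suture_into)
  expect_identical(into$level, "FIRST")  # best case over zone components

  out <- apply_suture_direction(score_pair(sz1, southern, v), sz1, southern, v)
  expect_true(out$suture_from)
  # worst case: the leo-side component scores NO_OPTION against Southern
  expect_identical(out$level, "NO_OPTION")
  expect_false(out$suture_into)

  sz2a <- lcu_record("sz2a", "z", "ZM", "east/southern", c("east", "southern"),
                     suture_zone = "SZ2", vocabulary = v)
  sz2b <- lcu_record("sz2b", "m", "MW", "east/southern", c("east", "southern"),
                     suture_zone = "SZ2", vocabulary = v)
  within <- apply_suture_direction(score_pair(sz2a, sz2b, v), sz2a, sz2b, v)
  expect_identical(within$level, "FIRST")

  # a non-overlapping source is not upgraded on entry
  w <- make_rec("w", "west", "west", v, country = "SN")
  noin <- apply_suture_direction(score_pair(w, sz1, v), w, sz1, v)
  expect_false(noin$suture_into)
})

test_that("matrix is complete, FIRST on the diagonal, symmetric away from modifiers", {
  sim <- simulate_registry(registry_sim_params(n_lcus = 12, p_suture = 0.25,
                                               p_hybrid = 0.25, seed = 11))
  m <- build_matrix(sim$registry, axis = "lcu")
  lv <- matrix_levels(m)
  expect_identical(dim(lv), c(12L, 12L))
  expect_true(all(diag(lv) == "FIRST"))
  gt <- sim$ground_truth
  for (i in 1:12) for (j in 1:12) {
    if (!gt$suture[i] && !gt$suture[j] && !gt$hybrid[i] && !gt$hybrid[j]) {
      expect_identical(lv[i, j], lv[j, i])
    }
  }
})

test_that("a suture-zone record makes the matrix asymmetric exactly at its rows", {
  recs <- list(
    lcu_record("sz", "suture", "ZM", "east/southern", c("east", "southern"),
               suture_zone = "SZ2", vocabulary = v),
    make_rec("p1", "southern", "east/southern", v, country = "ZA"),
    make_rec("p2", "east", "east/southern", v, country = "TZ")
  )
  m <- matrix_levels(build_matrix(lion_registry(recs, v), axis = "lcu"))
  expect_identical(m["p1", "p2"], m["p2", "p1"])       # away from the zone
  expect_identical(m["sz", "p1"], "THIRD")             # worst over components
  expect_identical(m["p1", "sz"], "FIRST")             # best into the zone
})

test_that("matrix cells equal brute-force recomputation on a synthetic registry", {
  sim <- simulate_registry(registry_sim_params(n_lcus = 10, n_mt_clades = 3,
                                               n_nu_clades = 3, p_suture = 0.3,
                                               p_hybrid = 0.2, seed = 5))
  reg <- sim$registry
  ssp <- reg$vocabulary$subspecies_of
  m <- build_matrix(reg, axis = "lcu")
  for (i in seq_along(reg$records)) for (j in seq_along(reg$records)) {
    s <- reg$records[[i]]; t <- reg$records[[j]]
    base <- oracle_level(s$profile$nudna, s$profile$mtdna,
                         t$profile$nudna, t$profile$mtdna, ssp)
    want <- oracle_suture_level(base, s$profile$nudna, s$profile$mtdna,
                                s$suture_zone, t$profile$nudna,
                                t$profile$mtdna, t$suture_zone, ssp)
    expect_identical(m$cells[[i, j]]$level, want,
                     label = sprintf("cell %d,%d", i, j))
  }
})

test_that("country matrices carry best-case levels with multi-clade flags", {
  recs <- list(
    make_rec("d1", "central", "central", v, country = "CD"),
    make_rec("d2", "east", "north east", v, country = "CD"),
    make_rec("t", "east", "east/southern", v, country = "TZ")
  )
  m <- build_matrix(lion_registry(recs, v), axis = "country")
  expect_identical(m$axis, c("CD", "TZ"))
  cell <- m$cells[["TZ", "CD"]]
  expect_identical(cell$level, "SECOND")   # best case: into the East-clade site
  expect_true(cell$multi_clade)
  expect_match(cell$rationale, "worst case NO_OPTION")
})

test_that("matrices round-trip through csv and json", {
  recs <- list(
    make_rec("h", "southern", c("east/southern", "south west"), v,
             country = "ZA", hybrid = TRUE, w2 = TRUE),
    make_rec("p", "southern", "east/southern", v, country = "MZ")
  )
  m <- build_matrix(lion_registry(recs, v), axis = "lcu")
  fc <- tempfile(fileext = ".csv")
  write_matrix(m, fc, "csv")
  tok <- utils::read.csv(fc, check.names = FALSE, colClasses = "character")
  expect_identical(tok[tok$source == "h", "p"], "FIRST;hybrid;w2")
  back <- read_matrix(fc)
  expect_identical(matrix_levels(back), matrix_levels(m))

  fj <- tempfile(fileext = ".json")
  write_matrix(m, fj, "json")
  backj <- read_matrix(fj)
  for (i in 1:2) for (j in 1:2) {
    expect_identical(backj$cells[[i, j]], m$cells[[i, j]])
  }

  single <- build_matrix(lion_registry(recs[2], v), axis = "lcu")
  f1 <- tempfile(fileext = ".csv")
  write_matrix(single, f1)
  expect_identical(matrix_levels(read_matrix(f1))[1, 1], "FIRST")
})

test_that("country matrix of the packaged registry lists range states alphabetically", {
  m <- build_matrix(default_registry(), axis = "country")
  expect_identical(m$axis, sort(m$axis))
  expect_true(all(c("ZA", "IN", "KE") %in% m$axis))
  expect_identical(m$cells[["ZA", "IN"]]$level, "NO_OPTION")
})
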
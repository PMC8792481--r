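# Independent brute-force oracle for the pairwise decision rules, kept
# deliberately separate from the package implementation: the level is looked
# up in a hand-written truth table over the four booleans that define the
# decision tree, not recomputed through rule precedence.

# truth table: india-xor, shared nuclear label, shared mtDNA label,
# melanochaita in the shared-subspecies set -> level
.oracle_table <- local({
  tb <- expand.grid(india_xor = c(FALSE, TRUE), shared_nu = c(FALSE, TRUE),
                    shared_mt = c(FALSE, TRUE), shared_mela = c(FALSE, TRUE))
  lvl <- character(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    r <- tb[i, ]
    lvl[i] <-
      if (r$india_xor) "NO_OPTION"
      else if (r$shared_nu && r$shared_mt) "FIRST"
      else if (r$shared_nu) "SECOND"
      else if (r$shared_mela) "THIRD"
      else "NO_OPTION"
  }
  tb$level <- lvl
  tb
})

oracle_level <- function(s_nu, s_mt, t_nu, t_mt, ssp_map) {
  key <- list(
    india_xor = xor("india" %in% s_nu, "india" %in% t_nu),
    shared_nu = length(intersect(s_nu, t_nu)) > 0,
    shared_mt = length(intersect(s_mt, t_mt)) > 0,
    shared_mela = "melanochaita" %in%
      intersect(unique(ssp_map[s_nu]), unique(ssp_map[t_nu]))
  )
  hit <- .oracle_table$india_xor == key$india_xor &
    .oracle_table$shared_nu == key$shared_nu &
    .oracle_table$shared_mt == key$shared_mt &
    .oracle_table$shared_mela == key$shared_mela
  .oracle_table$level[hit]
}

# suture directionality, restated independently on top of oracle_level
oracle_suture_level <- function(base, s_nu, s_mt, s_sz, t_nu, t_mt, t_sz,
                                ssp_map) {
  rank <- c(FIRST = 3, SECOND = 2, THIRD = 1, NO_OPTION = 0)
  if (s_sz != "none" && t_sz != "none") {
    if (s_sz == t_sz) return("FIRST")
    return(base)
  }
  if (t_sz != "none" && s_sz == "none") {
    if (length(intersect(s_nu, t_nu)) == 0) return(base)
    lv <- sapply(t_nu, function(u) oracle_level(s_nu, s_mt, u, t_mt, ssp_map))
    return(names(which.max(rank[lv])))
  }
  if (s_sz != "none" && t_sz == "none") {
    lv <- sapply(s_nu, function(u) oracle_level(u, s_mt, t_nu, t_mt, ssp_map))
    return(names(which.min(rank[lv])))
  }
  base
}

# a compact vocabulary with an India analogue, used for exhaustive
# enumeration: two African nuclear clades (one per subspecies) plus india
oracle_vocab <- function() {
  clade_vocabulary(
    mtdna_labels = c("m1", "m2", "india"),
    nudna_labels = c("n1", "n2", "india"),
    subspecies_of = c(n1 = "leo", n2 = "melanochaita", india = "leo")
  )
}

# all non-empty label subsets
label_subsets <- function(labels) {
  idx <- seq_along(labels)
  out <- list()
  for (k in idx) {
    cmb <- utils::combn(idx, k)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1]] <- labels[cmb[, j]]
  }
  out
}

make_rec <- function(id, nu, mt, vocab, country = "TZ", suture = "none",
                     hybrid = FALSE, w2 = FALSE) {
  lcu_record(id, id, country, mtdna = mt, nudna = nu,
             suture_zone = suture, hybrid_origin = hybrid,
             managed_metapopulation = w2, vocabulary = vocab)
}

# minimal in-memory CITES table in the comparative-tabulation dialect
cites_row <- function(year = 2000, taxon = "Panthera leo", importer = "ZA",
                      exporter = "ZW", origin = "", qi = "", qe = "2",
                      term = "live", unit = "", purpose = "N", source = "W") {
  data.frame(Year = as.character(year), Taxon = taxon, Importer = importer,
             Exporter = exporter, Origin = origin,
             `Importer reported quantity` = as.character(qi),
             `Exporter reported quantity` = as.character(qe),
             Term = term, Unit = unit, Purpose = purpose, Source = source,
             check.names = FALSE, stringsAsFactors = FALSE)
}

write_cites_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  path
}
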
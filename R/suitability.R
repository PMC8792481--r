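# Hierarchical source/target suitability classification.
#
# Levels, best first: FIRST (shared nuclear clade and shared mtDNA
# haplogroup), SECOND (shared nuclear clade, differentiated mtDNA), THIRD
# (different nuclear clades within P. l. melanochaita), NO_OPTION (cross-
# subspecies moves, any move between India and Africa, unknown genetic
# origin). Suture-zone directionality and hybrid-source fading are modifier
# flags applied on top of the level.

#' Suitability levels, best to worst
#' @export
suitability_levels <- c("FIRST", "SECOND", "THIRD", "NO_OPTION")

.level_order <- c(FIRST = 3L, SECOND = 2L, THIRD = 1L, NO_OPTION = 0L)

#' Rank of a suitability level (higher is better)
#' @param level character vector of level tokens.
#' @return integer ranks, `FIRST = 3` down to `NO_OPTION = 0`.
#' @export
level_rank <- function(level) {
  r <- .level_order[toupper(level)]
  if (anyNA(r)) stop("unknown suitability level: ",
                     paste(level[is.na(r)], collapse = ", "), call. = FALSE)
  unname(r)
}

best_level <- function(levels) names(.level_order)[match(max(level_rank(levels)), .level_order)]
worst_level <- function(levels) names(.level_order)[match(min(level_rank(levels)), .level_order)]

#' Construct a suitability score
#'
#' @param level one of `"FIRST"`, `"SECOND"`, `"THIRD"`, `"NO_OPTION"`.
#' @param hybrid_source source population carries human-mediated admixture
#'   (the "faded" marking: usable only after per-individual genetic testing).
#' @param w2_source source is managed-metapopulation (W2) stock.
#' @param suture_into,suture_from directionality flags for moves into / out
#'   of a suture zone; mutually exclusive.
#' @param multi_clade the cell aggregates units spanning more than one
#'   nuclear clade (best-case level shown, worst case in the rationale).
#' @param rationale non-empty text naming the rule that fired.
#' @return an object of class `suitability_score`.
#' @export
suitability_score <- function(level, hybrid_source = FALSE, w2_source = FALSE,
                              suture_into = FALSE, suture_from = FALSE,
                              multi_clade = FALSE, rationale) {
  level <- toupper(level)
  if (!level %in% suitability_levels) stop("unknown level: ", level, call. = FALSE)
  if (isTRUE(suture_into) && isTRUE(suture_from)) {
    stop("suture_into and suture_from are mutually exclusive", call. = FALSE)
  }
  if (missing(rationale) || !nzchar(rationale)) {
    stop("rationale must be non-empty", call. = FALSE)
  }
  structure(
    list(level = level, hybrid_source = isTRUE(hybrid_source),
         w2_source = isTRUE(w2_source), suture_into = isTRUE(suture_into),
         suture_from = isTRUE(suture_from), multi_clade = isTRUE(multi_clade),
         rationale = rationale),
    class = "suitability_score"
  )
}

#' @export
print.suitability_score <- function(x, ...) {
  cat(score_token(x), "-", x$rationale, "\n")
  invisible(x)
}

score_token <- function(score) {
  flags <- c(if (score$hybrid_source) "hybrid", if (score$w2_source) "w2",
             if (score$suture_into) "suture_into",
             if (score$suture_from) "suture_from",
             if (score$multi_clade) "multi")
  paste(c(score$level, flags), collapse = ";")
}

parse_score_token <- function(token, rationale = "parsed from matrix file") {
  parts <- strsplit(token, ";", fixed = TRUE)[[1]]
  suitability_score(parts[1],
                    hybrid_source = "hybrid" %in% parts,
                    w2_source = "w2" %in% parts,
                    suture_into = "suture_into" %in% parts,
                    suture_from = "suture_from" %in% parts,
                    multi_clade = "multi" %in% parts,
                    rationale = rationale)
}

# Core decision rules on a pair of genetic profiles. "Shared" means a
# non-empty label intersection, so multi-haplogroup units (KAZA) score FIRST
# against either parent clade. Returns level + rationale only; flags are the
# caller's concern.
score_profiles <- function(source, target, vocabulary = default_vocabulary()) {
  s_nu <- source$nudna; t_nu <- target$nudna
  s_india <- "india" %in% s_nu; t_india <- "india" %in% t_nu
  if (xor(s_india, t_india)) {
    return(list(level = "NO_OPTION",
                rationale = "India rule: moves between the Indian and any African population are excluded despite shared subspecies"))
  }
  shared_nu <- length(intersect(s_nu, t_nu)) > 0L
  shared_mt <- length(intersect(source$mtdna, target$mtdna)) > 0L
  if (shared_nu && shared_mt) {
    return(list(level = "FIRST",
                rationale = "same nuDNA clade and same mtDNA haplogroup"))
  }
  if (shared_nu) {
    return(list(level = "SECOND",
                rationale = "same nuDNA clade, differentiated mtDNA haplogroups"))
  }
  shared_ssp <- intersect(subspecies_of(s_nu, vocabulary),
                          subspecies_of(t_nu, vocabulary))
  if ("melanochaita" %in% shared_ssp) {
    return(list(level = "THIRD",
                rationale = "different nuDNA clades within P. l. melanochaita"))
  }
  list(level = "NO_OPTION",
       rationale = if (length(shared_ssp))
         "different nuDNA clades; third choice is unavailable within P. l. leo"
       else "different subspecies")
}

#' Score one source/target LCU pair
#'
#' Applies the hierarchical decision rules in precedence order: the India
#' exclusion first, then shared nuclear + shared mtDNA (`FIRST`), shared
#' nuclear only (`SECOND`), cross-nuclear within *P. l. melanochaita*
#' (`THIRD`), otherwise `NO_OPTION`. Label sharing is non-empty set
#' intersection. Hybrid-origin and managed-metapopulation status of the
#' source set the `hybrid_source` / `w2_source` flags without changing the
#' level. Suture-zone directionality is applied separately by
#' [apply_suture_direction()].
#'
#' @param source,target [lcu_record()] objects sharing `vocabulary`.
#' @param vocabulary the active [clade_vocabulary()].
#' @return a [suitability_score()].
#' @export
score_pair <- function(source, target, vocabulary = default_vocabulary()) {
  stopifnot(inherits(source, "lcu_record"), inherits(target, "lcu_record"))
  all_labels <- c(source$profile$nudna, target$profile$nudna)
  if (!all(all_labels %in% vocabulary$nudna_labels) ||
      !all(c(source$profile$mtdna, target$profile$mtdna) %in%
           vocabulary$mtdna_labels)) {
    stop("configuration error: record labels are not drawn from the supplied vocabulary",
         call. = FALSE)
  }
  base <- score_profiles(source$profile, target$profile, vocabulary)
  suitability_score(base$level,
                    hybrid_source = source$hybrid_origin,
                    w2_source = source$managed_metapopulation,
                    rationale = base$rationale)
}

# per-nuclear-clade component profiles of a record; each component keeps the
# record's full mtDNA set (the country-scale data do not pair haplogroups
# with nuclear clades)
component_profiles <- function(record, vocabulary) {
  lapply(record$profile$nudna, function(u)
    genetic_profile(record$profile$mtdna, u, vocabulary))
}

#' Apply suture-zone directionality to a pairwise score
#'
#' Movement into a suture zone (by a source sharing a nuclear clade with the
#' zone's overlap set) is scored best-case over the zone's component clades;
#' movement out of a suture zone is scored worst-case, because the zone may
#' hold naturally hybrid individuals. Two units in the same suture zone score
#' `FIRST` (source from within the zone itself). Levels are never pushed
#' above `FIRST` or below `NO_OPTION`.
#'
#' @param score the [suitability_score()] from [score_pair()].
#' @param source,target the scored [lcu_record()]s.
#' @param vocabulary the active [clade_vocabulary()].
#' @return a [suitability_score()], possibly with `suture_into` or
#'   `suture_from` set and the level revised.
#' @export
apply_suture_direction <- function(score, source, target,
                                   vocabulary = default_vocabulary()) {
  s_sz <- source$suture_zone; t_sz <- target$suture_zone
  if (s_sz == "none" && t_sz == "none") return(score)
  if (s_sz != "none" && t_sz != "none") {
    if (s_sz == t_sz) {
      return(suitability_score("FIRST",
        hybrid_source = score$hybrid_source, w2_source = score$w2_source,
        rationale = paste0("both units in suture zone ", s_sz,
                           ": source from within the same suture zone")))
    }
    return(score)  # moves between distinct suture zones keep the base level
  }
  if (t_sz != "none") {
    # into a suture zone: only for sources overlapping the zone's clade set
    if (length(intersect(source$profile$nudna, target$profile$nudna)) == 0L) {
      return(score)
    }
    lv <- vapply(component_profiles(target, vocabulary), function(p)
      score_profiles(source$profile, p, vocabulary)$level, character(1))
    return(suitability_score(best_level(lv),
      hybrid_source = score$hybrid_source, w2_source = score$w2_source,
      suture_into = TRUE,
      rationale = paste0("movement into suture zone ", t_sz,
                         " from an overlapping clade: best case over zone components")))
  }
  # from a suture zone outwards: worst case over the zone's components
  lv <- vapply(component_profiles(source, vocabulary), function(p)
    score_profiles(p, target$profile, vocabulary)$level, character(1))
  note <- if (s_sz == "SZ1" &&
              "leo" %in% subspecies_of(target$profile$nudna, vocabulary))
    "; advisory: prioritize P. l. leo individuals for the northern subspecies" else ""
  suitability_score(worst_level(lv),
    hybrid_source = score$hybrid_source, w2_source = score$w2_source,
    suture_from = TRUE,
    rationale = paste0("movement out of suture zone ", s_sz,
                       ": worst case over zone components (possible hybrid individuals)",
                       note))
}

score_pair_full <- function(source, target, vocabulary) {
  apply_suture_direction(score_pair(source, target, vocabulary),
                         source, target, vocabulary)
}

#' Build the full source-by-target suitability matrix
#'
#' Every ordered (source, target) combination is scored, including the
#' diagonal. On the `"lcu"` axis each cell is one [score_pair()] +
#' [apply_suture_direction()] evaluation. On the `"country"` axis each cell
#' aggregates all extant LCU pairs between the two countries: the cell shows
#' the best-case level, flags aggregate from the best-scoring pair, a
#' `multi_clade` flag marks unions spanning more than one nuclear clade, and
#' the worst-case level is retained in the rationale. The matrix is
#' asymmetric exactly where suture zones or hybrid populations are involved.
#'
#' @param registry a `lion_registry`.
#' @param axis `"lcu"` (default) or `"country"`.
#' @return an object of class `suitability_matrix` with fields `axis`
#'   (ordered labels), `axis_type`, and `cells` (a list-matrix of
#'   [suitability_score()]s).
#' @export
build_matrix <- function(registry, axis = c("lcu", "country")) {
  stopifnot(inherits(registry, "lion_registry"))
  axis <- match.arg(axis)
  if (length(registry$records) == 0L) stop("empty registry", call. = FALSE)
  vocab <- registry$vocabulary
  if (axis == "lcu") {
    labels <- registry_ids(registry)
    recs <- registry$records
    cells <- matrix(vector("list", length(labels)^2),
                    nrow = length(labels), dimnames = list(labels, labels))
    for (i in seq_along(recs)) for (j in seq_along(recs)) {
      cells[[i, j]] <- score_pair_full(recs[[i]], recs[[j]], vocab)
    }
  } else {
    labels <- sort(unique(unlist(lapply(
      Filter(function(r) r$extant, registry$records), `[[`, "countries"))))
    cells <- matrix(vector("list", length(labels)^2),
                    nrow = length(labels), dimnames = list(labels, labels))
    profs <- lapply(labels, function(cc) country_profile(registry, cc))
    names(profs) <- labels
    for (src in labels) for (tgt in labels) {
      cells[[src, tgt]] <- score_country_cell(profs[[src]], profs[[tgt]], vocab)
    }
  }
  structure(list(axis = labels, axis_type = axis, cells = cells),
            class = "suitability_matrix")
}

score_country_cell <- function(src_cp, tgt_cp, vocabulary) {
  pair_scores <- list()
  for (s in src_cp$records) for (t in tgt_cp$records) {
    pair_scores[[length(pair_scores) + 1L]] <- score_pair_full(s, t, vocabulary)
  }
  lv <- vapply(pair_scores, `[[`, character(1), "level")
  best <- best_level(lv); worst <- worst_level(lv)
  best_sc <- pair_scores[[which.max(level_rank(lv))]]
  multi <- src_cp$multi_clade || tgt_cp$multi_clade
  rationale <- sprintf("best of %d LCU pair(s): %s%s", length(pair_scores),
                       best_sc$rationale,
                       if (multi || worst != best)
                         sprintf("; worst case %s", worst) else "")
  suitability_score(best,
                    hybrid_source = src_cp$any_hybrid,
                    w2_source = src_cp$any_w2,
                    suture_into = best_sc$suture_into,
                    suture_from = best_sc$suture_from,
                    multi_clade = multi,
                    rationale = rationale)
}

#' Extract the level tokens of a suitability matrix
#' @param matrix a `suitability_matrix`.
#' @return character matrix of level tokens.
#' @export
matrix_levels <- function(matrix) {
  stopifnot(inherits(matrix, "suitability_matrix"))
  apply(matrix$cells, c(1, 2), function(cell) cell[[1]]$level)
}

#' @export
print.suitability_matrix <- function(x, ...) {
  cat(sprintf("Suitability matrix (%s axis, %d x %d)\n", x$axis_type,
              length(x$axis), length(x$axis)))
  lv <- matrix_levels(x)
  tab <- table(factor(lv, levels = suitability_levels))
  cat("  cell levels:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Write a suitability matrix to CSV or JSON
#'
#' The CSV form stores one level token per cell with `;`-separated flag
#' suffixes (e.g. `"SECOND;hybrid"`), source units as rows, in axis order.
#' The JSON form stores full score objects including rationales.
#'
#' @param matrix a `suitability_matrix`.
#' @param path output path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("csv", "json")) {
  stopifnot(inherits(matrix, "suitability_matrix"))
  format <- match.arg(format)
  if (format == "csv") {
    tok <- apply(matrix$cells, c(1, 2), function(cell) score_token(cell[[1]]))
    df <- data.frame(source = matrix$axis, tok, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("source", matrix$axis)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       qmethod = "double", fileEncoding = "UTF-8")
  } else {
    cells <- list()
    for (src in matrix$axis) for (tgt in matrix$axis) {
      sc <- matrix$cells[[src, tgt]]
      cells[[length(cells) + 1L]] <- c(list(source = src, target = tgt),
                                       unclass(sc))
    }
    jsonlite::write_json(
      list(axis_type = matrix$axis_type, axis = matrix$axis, cells = cells),
      path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a suitability matrix written by [write_matrix()]
#'
#' @param path input path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @return a `suitability_matrix`. CSV files carry levels and flags only, so
#'   rationales are placeholders; JSON round-trips the full scores.
#' @export
read_matrix <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.table(path, header = TRUE, sep = ",", quote = "\"",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character",
                            na.strings = character(0))
    labels <- df$source
    cells <- matrix(vector("list", length(labels)^2), nrow = length(labels),
                    dimnames = list(labels, labels))
    for (i in seq_along(labels)) for (j in seq_along(labels)) {
      cells[[i, j]] <- parse_score_token(df[i, labels[j]])
    }
    axis_type <- if (all(nchar(labels) == 2L)) "country" else "lcu"
    structure(list(axis = labels, axis_type = axis_type, cells = cells),
              class = "suitability_matrix")
  } else {
    obj <- jsonlite::read_json(path)
    labels <- unlist(obj$axis)
    cells <- matrix(vector("list", length(labels)^2), nrow = length(labels),
                    dimnames = list(labels, labels))
    for (cell in obj$cells) {
      cells[[cell$source, cell$target]] <- suitability_score(
        cell$level, hybrid_source = isTRUE(cell$hybrid_source),
        w2_source = isTRUE(cell$w2_source),
        suture_into = isTRUE(cell$suture_into),
        suture_from = isTRUE(cell$suture_from),
        multi_clade = isTRUE(cell$multi_clade),
        rationale = cell$rationale)
    }
    structure(list(axis = labels, axis_type = obj$axis_type, cells = cells),
              class = "suitability_matrix")
  }
}
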
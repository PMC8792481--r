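# Clade vocabulary: the label sets for mtDNA haplogroups and nuclear clades,
# and the nuclear-clade -> subspecies map. All label handling is
# case-normalised so registry files written by hand survive round trips.

#' Construct a clade vocabulary
#'
#' A vocabulary defines the admissible mtDNA haplogroup labels, nuclear
#' (nuDNA) clade labels, and the mapping from each nuclear clade to a
#' subspecies. Every registry and every suitability computation is carried
#' out relative to one vocabulary.
#'
#' @param mtdna_labels character vector of mtDNA clade names.
#' @param nudna_labels character vector of nuDNA clade names.
#' @param subspecies_of named character vector mapping every nuDNA label to a
#'   subspecies name; names must cover `nudna_labels` exactly.
#' @return an object of class `clade_vocabulary`.
#' @seealso [default_vocabulary()] for the lion vocabulary shipped with the
#'   package.
#' @examples
#' clade_vocabulary(c("A", "B"), c("A", "B"), c(A = "leo", B = "melanochaita"))
#' @export
clade_vocabulary <- function(mtdna_labels, nudna_labels, subspecies_of) {
  mtdna_labels <- normalize_label(mtdna_labels)
  nudna_labels <- normalize_label(nudna_labels)
  names(subspecies_of) <- normalize_label(names(subspecies_of))
  subspecies_of <- vapply(subspecies_of, function(s) tolower(trimws(s)), character(1))
  if (anyDuplicated(mtdna_labels)) stop("duplicate mtDNA labels", call. = FALSE)
  if (anyDuplicated(nudna_labels)) stop("duplicate nuDNA labels", call. = FALSE)
  if (!setequal(names(subspecies_of), nudna_labels)) {
    stop("subspecies_of must map every nuDNA label to exactly one subspecies; ",
         "missing: ", paste(setdiff(nudna_labels, names(subspecies_of)), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(mtdna_labels = mtdna_labels,
         nudna_labels = nudna_labels,
         subspecies_of = subspecies_of[nudna_labels]),
    class = "clade_vocabulary"
  )
}

#' The default lion clade vocabulary
#'
#' Six mtDNA haplogroups (West, Central, North East, East/Southern,
#' South West, India) and five nuclear clades (West, Central, East,
#' Southern, India). Nuclear clades West, Central and India belong to
#' *P. l. leo*; East and Southern belong to *P. l. melanochaita*. The
#' treatment of West and Central Africa as distinct nuclear clades follows
#' the continental phylogeographic pattern; the India clade is nested within
#' the northern subspecies despite its strong differentiation.
#'
#' @return a `clade_vocabulary`.
#' @export
default_vocabulary <- function() {
  clade_vocabulary(
    mtdna_labels = c("west", "central", "north east", "east/southern",
                     "south west", "india"),
    nudna_labels = c("west", "central", "east", "southern", "india"),
    subspecies_of = c(west = "leo", central = "leo", india = "leo",
                      east = "melanochaita", southern = "melanochaita")
  )
}

# lower-case, trimmed, internal whitespace collapsed
normalize_label <- function(x) {
  gsub("[[:space:]]+", " ", tolower(trimws(as.character(x))))
}

#' @export
print.clade_vocabulary <- function(x, ...) {
  cat("Clade vocabulary\n")
  cat("  mtDNA :", paste(x$mtdna_labels, collapse = ", "), "\n")
  cat("  nuDNA :", paste(x$nudna_labels, collapse = ", "), "\n")
  cat("  subspecies:",
      paste(sprintf("%s->%s", names(x$subspecies_of), x$subspecies_of),
            collapse = ", "), "\n")
  invisible(x)
}

#' Construct a genetic profile
#'
#' The clade assignment of one population: a non-empty set of mtDNA
#' haplogroup labels and a non-empty set of nuDNA clade labels. Multiple
#' mtDNA labels encode natural haplogroup overlap (as in the
#' Kavango-Zambezi area); multiple nuDNA labels encode suture zones where
#' nuclear clades co-occur.
#'
#' @param mtdna,nudna character vectors of clade labels.
#' @param vocabulary the active [clade_vocabulary()]; labels are checked
#'   against it.
#' @return an object of class `genetic_profile`.
#' @export
genetic_profile <- function(mtdna, nudna, vocabulary = default_vocabulary()) {
  mtdna <- unique(normalize_label(mtdna))
  nudna <- unique(normalize_label(nudna))
  if (length(mtdna) == 0L || length(nudna) == 0L) {
    stop("a genetic profile needs at least one mtDNA and one nuDNA label",
         call. = FALSE)
  }
  bad_mt <- setdiff(mtdna, vocabulary$mtdna_labels)
  bad_nu <- setdiff(nudna, vocabulary$nudna_labels)
  if (length(bad_mt) || length(bad_nu)) {
    stop("unknown clade label(s): ",
         paste(c(bad_mt, bad_nu), collapse = ", "), call. = FALSE)
  }
  structure(list(mtdna = sort(mtdna), nudna = sort(nudna)),
            class = "genetic_profile")
}

#' Subspecies implied by a set of nuclear clade labels
#'
#' @param nudna character vector of nuDNA labels.
#' @param vocabulary the active vocabulary.
#' @return character vector of subspecies names (unique).
#' @export
subspecies_of <- function(nudna, vocabulary = default_vocabulary()) {
  unique(unname(vocabulary$subspecies_of[normalize_label(nudna)]))
}

#' @export
print.genetic_profile <- function(x, ...) {
  cat("mtDNA {", paste(x$mtdna, collapse = ", "), "}  nuDNA {",
      paste(x$nudna, collapse = ", "), "}\n")
  invisible(x)
}
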
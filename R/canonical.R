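#' Canonical display form of a tandem repeat unit
#'
#' Tandem units recovered from reads are arbitrary rotations of either strand
#' of the underlying repeat. This maps any such unit to a single display
#' form so counts can be merged: pick the G-rich strand (more G than C; on a
#' tie, the strand whose minimal rotation sorts first), then among its
#' rotations place the longest G-run as the suffix (ties broken by the
#' longest leading T-run, then lexicographically). TTTAGGG, its rotations,
#' and its reverse-complement rotations all map to TTTAGGG.
#'
#' @param unit A repeat unit over A/C/G/T.
#' @return The display form, a single string.
#' @examples
#' canonical_form("TAGGGTT") # TTTAGGG
#' canonical_form("CCCTAAA") # TTTAGGG (C-strand)
#' @export
canonical_form <- function(unit) {
  unit <- assert_dna(unit, "unit")
  rc <- revcomp_chr(unit)
  ng <- nchar(gsub("[^G]", "", unit))
  nc <- nchar(gsub("[^C]", "", unit)) # = G count of the reverse complement
  strand <- if (ng > nc) unit
  else if (nc > ng) rc
  else if (min(rotations_chr(unit)) <= min(rotations_chr(rc))) unit else rc

  rots <- rotations_chr(strand)
  gsuf <- nchar(rots) - nchar(sub("G*$", "", rots))
  cand <- rots[gsuf == max(gsuf)]
  tlead <- nchar(cand) - nchar(sub("^T*", "", cand))
  cand <- cand[tlead == max(tlead)]
  min(cand)
}

#' Strand- and rotation-invariant key of a repeat unit
#'
#' The lexicographically minimal rotation over both strands; two units have
#' equal keys iff one is a rotation of the other or of its reverse
#' complement.
#'
#' @inheritParams canonical_form
#' @return A single string.
#' @export
canonical_key <- function(unit) {
  unit <- assert_dna(unit, "unit")
  min(c(rotations_chr(unit), rotations_chr(revcomp_chr(unit))))
}

#' Circular edit distance between repeat units
#'
#' Minimum Levenshtein distance from any rotation of `unit` (either strand)
#' to `motif`. This is the similarity measure used to admit novel telomere
#' candidates: TTCAGGG sits at circular distance 1 from TTTAGGG.
#'
#' @param unit,motif Repeat units over A/C/G/T.
#' @return A non-negative integer.
#' @export
circular_edit_distance <- function(unit, motif) {
  unit <- assert_dna(unit, "unit")
  motif <- assert_dna(motif, "motif")
  forms <- unique(c(rotations_chr(unit), rotations_chr(revcomp_chr(unit))))
  as.integer(min(utils::adist(forms, motif)))
}

# Longest G-run of the display form, counted circularly.
max_g_run <- function(display_form) {
  runs <- regmatches(display_form, gregexpr("G+", display_form))[[1]]
  if (length(runs) == 0L) return(0L)
  n <- nchar(display_form)
  if (!grepl("[^G]", display_form)) return(n)
  suf <- n - nchar(sub("G*$", "", display_form)) # trailing Gs
  pre <- n - nchar(sub("^G*", "", display_form)) # leading Gs
  max(max(nchar(runs)), suf + pre)
}

#' Classify a repeat unit against the telomere catalog
#'
#' Exact match first: a unit whose canonical key equals a catalog key is that
#' catalog motif. Otherwise a unit within `max_circular_edit` circular edit
#' distance of any catalog motif, and carrying a G-run of at least 2 on its
#' G-rich strand, is reported as a novel telomere candidate. Anything else
#' (generic microsatellites such as AC repeats) is rejected.
#'
#' @param display_form A unit in display form (see [canonical_form()]).
#' @param catalog A catalog data.frame, normally [telomere_catalog()].
#' @param max_circular_edit Maximum circular edit distance admitting a novel
#'   candidate (default 1).
#' @return A one-row data.frame (`display_form`, `family_name`, `source`
#'   where `source` is `"catalog"` or `"novel_candidate"`), or `NULL` when
#'   the unit is not telomere-like.
#' @examples
#' classify_unit("TTTAGGG")$family_name # Arabidopsis-type
#' classify_unit("ACACAC")              # NULL
#' @export
classify_unit <- function(display_form, catalog = telomere_catalog(),
                          max_circular_edit = 1L) {
  stopifnot(nrow(catalog) > 0L)
  key <- canonical_key(display_form)
  hit <- match(key, catalog$canonical_key)
  if (!is.na(hit)) {
    return(data.frame(display_form = catalog$display_form[hit],
                      family_name = catalog$family_name[hit],
                      source = "catalog", stringsAsFactors = FALSE))
  }
  d <- vapply(catalog$display_form, circular_edit_distance,
              integer(1), unit = display_form)
  if (min(d) <= max_circular_edit && max_g_run(display_form) >= 2L) {
    near <- catalog$family_name[which.min(d)]
    return(data.frame(display_form = display_form,
                      family_name = paste0("novel (near ", near, ")"),
                      source = "novel_candidate", stringsAsFactors = FALSE))
  }
  NULL
}
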
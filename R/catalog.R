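#' Catalog of plant and animal telomeric repeat motifs
#'
#' The eight telomere repeat families screened by the motif classifier. Seven
#' are long-established telomere motifs across plants, algae and vertebrates;
#' the eighth, TTCAGGG, is the noncanonical unit carried by the Svalbard
#' poppy (*Papaver dahlianum*). Motifs are stored in display form (G-rich
#' strand, rotated so the G-run is terminal) together with a strand- and
#' rotation-invariant canonical key used for exact matching.
#'
#' @param include_novel Keep the TTCAGGG entry (default `TRUE`). Dropping it
#'   reproduces a de-novo discovery scenario in which TTCAGGG must surface as
#'   a novel candidate rather than a catalog hit.
#' @return A data.frame with columns `display_form`, `canonical_key`,
#'   `family_name` and `source` (all `"catalog"`).
#' @examples
#' telomere_catalog()
#' @export
telomere_catalog <- function(include_novel = TRUE) {
  motifs <- c(
    "TTTAGGG"    = "Arabidopsis-type",
    "TTAGGG"     = "vertebrate-type",
    "TTTTAGGG"   = "Chlamydomonas-type",
    "TTCAGG"     = "Genlisea-type",
    "TTTCAGG"    = "Genlisea-type",
    "TTTTAGG"    = "Klebsormidium-type",
    "TTTTTTAGGG" = "Cestrum-type",
    "TTCAGGG"    = "Papaver-type"
  )
  if (!include_novel) motifs <- motifs[names(motifs) != "TTCAGGG"]
  data.frame(
    display_form = names(motifs),
    canonical_key = vapply(names(motifs), canonical_key, character(1)),
    family_name = unname(motifs),
    source = "catalog",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
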
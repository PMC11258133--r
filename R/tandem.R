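#' Detect a tandem repeat unit in a sequence window
#'
#' A window is telomere-like when it is (near-)fully periodic: the smallest
#' period `u` with at most `max_mismatch` violations of
#' `window[i] == window[i + u]` must fall inside `unit_len_range`, the unit
#' must be primitive (not itself periodic), and the window must hold at
#' least `min_copies` complete copies. Periods are scanned from 1, so
#' homopolymer and dinucleotide windows — whose smallest period lies below
#' the range — are rejected rather than reported at an inflated multiple.
#' `N` bases violate every period.
#'
#' @param windows Character vector of windows (typically 60 bp, see
#'   [trim_to_window()]).
#' @param unit_len_range Length-2 integer vector, smallest and largest unit
#'   length considered (default `c(6, 10)`, spanning all catalog motifs).
#' @param max_mismatch Allowed periodicity violations per window (default 0:
#'   fully periodic windows only).
#' @param min_copies Minimum complete unit copies per window (default 4).
#' @return A data.frame with one row per window: `unit` (NA when no hit) and
#'   `copies`.
#' @examples
#' find_tandem_unit(strrep("TTTAGGG", 9))       # unit TTTAGGG, 9 copies
#' find_tandem_unit(strrep("A", 60))            # no hit: period 1
#' @export
find_tandem_unit <- function(windows, unit_len_range = c(6L, 10L),
                             max_mismatch = 0L, min_copies = 4L) {
  stopifnot(length(unit_len_range) == 2L,
            unit_len_range[1] >= 1L,
            unit_len_range[1] <= unit_len_range[2],
            max_mismatch >= 0L, min_copies >= 1L)
  windows <- toupper(as.character(windows))
  res <- find_tandem_units_cpp(windows,
                               as.integer(unit_len_range[1]),
                               as.integer(unit_len_range[2]),
                               as.integer(max_mismatch),
                               as.integer(min_copies))
  data.frame(unit = res$unit, copies = res$copies, stringsAsFactors = FALSE)
}
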
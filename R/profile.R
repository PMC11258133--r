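#' Profile telomeric repeat content of a window set
#'
#' Runs the full per-window chain — tandem-unit detection
#' ([find_tandem_unit()]), strand/rotation merging ([canonical_form()]) and
#' catalog classification ([classify_unit()]) — and aggregates window and
#' copy counts per motif. Relative abundance is normalised over
#' telomere-like hits only (catalog motifs plus novel candidates), so the
#' abundances sum to 1 whenever any hit exists; raw counts are always kept
#' alongside.
#'
#' @param windows Character vector of trimmed read windows.
#' @param catalog Motif catalog (default [telomere_catalog()]).
#' @param sample_id Label carried into the output table.
#' @param unit_len_range,max_mismatch,min_copies Passed to
#'   [find_tandem_unit()].
#' @param max_circular_edit Passed to [classify_unit()].
#' @return A `motif_count_table`: data.frame with columns `sample`, `motif`,
#'   `family`, `source`, `windows`, `copies`, `relative_abundance`, sorted by
#'   decreasing window count. Attribute `n_windows` records the input size.
#' @export
profile_sample <- function(windows, catalog = telomere_catalog(),
                           sample_id = "sample",
                           unit_len_range = c(6L, 10L), max_mismatch = 0L,
                           min_copies = 4L, max_circular_edit = 1L) {
  hits <- find_tandem_unit(windows, unit_len_range, max_mismatch, min_copies)
  keep <- !is.na(hits$unit)
  out <- data.frame(sample = character(0), motif = character(0),
                    family = character(0), source = character(0),
                    windows = integer(0), copies = integer(0),
                    relative_abundance = numeric(0), stringsAsFactors = FALSE)
  if (any(keep)) {
    units <- hits$unit[keep]
    copies <- hits$copies[keep]
    uniq <- unique(units)
    disp <- vapply(uniq, canonical_form, character(1))
    cls <- lapply(unique(disp), classify_unit, catalog = catalog,
                  max_circular_edit = max_circular_edit)
    names(cls) <- unique(disp)
    motif_of <- setNames(disp[match(units, uniq)], NULL)
    rows <- list()
    for (d in names(cls)) {
      c1 <- cls[[d]]
      if (is.null(c1)) next # generic microsatellite
      sel <- motif_of == d
      key <- c1$display_form
      if (!is.null(rows[[key]])) {
        rows[[key]]$windows <- rows[[key]]$windows + sum(sel)
        rows[[key]]$copies <- rows[[key]]$copies + sum(copies[sel])
      } else {
        rows[[key]] <- data.frame(sample = sample_id, motif = key,
                                  family = c1$family_name, source = c1$source,
                                  windows = sum(sel),
                                  copies = sum(copies[sel]),
                                  stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      out <- do.call(rbind, unname(rows))
      out$relative_abundance <- out$windows / sum(out$windows)
      out <- out[order(-out$windows, out$motif), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out, n_windows = length(windows),
            class = c("motif_count_table", "data.frame"))
}

#' @export
print.motif_count_table <- function(x, ...) {
  cat(sprintf("Telomere motif profile (%d windows scanned, %d telomere-like)\n",
              attr(x, "n_windows"), sum(x$windows)))
  if (nrow(x) == 0L) cat("  no telomere-like tandem hits\n")
  else print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Call the telomeric repeat of a sample
#'
#' The motif with maximal relative abundance is called when it clears both
#' evidence thresholds; ties or sub-threshold tables yield an undetermined
#' call with all candidates listed.
#'
#' @param table A `motif_count_table` from [profile_sample()].
#' @param min_windows Minimum supporting windows for a call (default 50).
#' @param min_fraction Minimum relative abundance for a call (default 0.5).
#' @return A `telomere_call` list: `motif` (string or `NA`), `determined`,
#'   `family`, `source`, `windows`, `relative_abundance`, `candidates`
#'   (the full table).
#' @export
call_sample_telomere <- function(table, min_windows = 50L,
                                 min_fraction = 0.5) {
  res <- list(motif = NA_character_, determined = FALSE,
              family = NA_character_, source = NA_character_,
              windows = 0L, relative_abundance = NA_real_,
              candidates = table)
  if (nrow(table) > 0L) {
    top <- which(table$windows == max(table$windows))
    if (length(top) == 1L &&
        table$windows[top] >= min_windows &&
        table$relative_abundance[top] >= min_fraction) {
      res$motif <- table$motif[top]
      res$determined <- TRUE
      res$family <- table$family[top]
      res$source <- table$source[top]
      res$windows <- table$windows[top]
      res$relative_abundance <- table$relative_abundance[top]
    }
  }
  structure(res, class = "telomere_call")
}

#' @export
print.telomere_call <- function(x, ...) {
  if (x$determined) {
    cat(sprintf("Telomeric repeat call: %s (%s, %s; %d windows, %.1f%% of hits)\n",
                x$motif, x$family, x$source, x$windows,
                100 * x$relative_abundance))
  } else {
    cat("Telomeric repeat call: undetermined\n")
    if (nrow(x$candidates)) print(x$candidates)
  }
  invisible(x)
}
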
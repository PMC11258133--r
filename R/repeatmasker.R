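#' Parse a RepeatMasker .out annotation table
#'
#' Reads the standard 15-column RepeatMasker alignment table (three header
#' lines, whitespace-separated body, query coordinates 1-based inclusive)
#' into 0-based half-open repeat intervals, and aggregates masked bases per
#' summary category: Retroelement, DNA transposon, Rolling-circle, Small
#' RNA, Satellite, Simple repeat, Low complexity, plus Unclassified.
#' Per-class totals sum alignment lengths without deduplicating overlaps;
#' overlap-aware masking fractions are computed downstream per bin.
#'
#' @param path Path to the `.out` file.
#' @return List with `intervals` (data.frame `contig`, `start`, `end`,
#'   `family`, `class`, `category`) and `class_totals` (named numeric,
#'   bases per category).
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body <- if (length(lines) > 3L) lines[-(1:3)] else character(0)
  body <- body[nzchar(trimws(body))]
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), family = character(0),
                      class = character(0), category = character(0),
                      stringsAsFactors = FALSE)
  cats <- c("Retroelement", "DNA transposon", "Rolling-circle", "Small RNA",
            "Satellite", "Simple repeat", "Low complexity", "Unclassified")
  totals <- setNames(numeric(length(cats)), cats)
  if (length(body) == 0L)
    return(list(intervals = empty, class_totals = totals))
  parts <- strsplit(trimws(body), "\\s+")
  nf <- vapply(parts, length, integer(1))
  bad <- which(nf < 14L)
  if (length(bad))
    stop(sprintf("malformed RepeatMasker line %d: %s",
                 bad[1] + 3L, body[bad[1]]), call. = FALSE)
  get <- function(i) vapply(parts, `[`, character(1), i)
  qbegin <- suppressWarnings(as.integer(get(6L)))
  qend <- suppressWarnings(as.integer(get(7L)))
  if (anyNA(qbegin) || anyNA(qend) || any(qbegin < 1L) || any(qend < qbegin))
    stop(sprintf("malformed RepeatMasker coordinates at line %d",
                 which(is.na(qbegin) | is.na(qend) | qbegin < 1 | qend < qbegin)[1] + 3L),
         call. = FALSE)
  intervals <- data.frame(
    contig = get(5L),
    start = qbegin - 1L, # to 0-based half-open
    end = qend,
    family = get(10L),
    class = get(11L),
    stringsAsFactors = FALSE)
  intervals$category <- repeat_category(intervals$class)
  width <- intervals$end - intervals$start
  agg <- tapply(width, intervals$category, sum)
  totals[names(agg)] <- agg
  list(intervals = intervals, class_totals = totals)
}

# Map RepeatMasker class/family strings onto the seven summary categories.
repeat_category <- function(class) {
  top <- sub("/.*$", "", class)
  out <- rep("Unclassified", length(class))
  out[top %in% c("LTR", "LINE", "SINE", "Retroposon")] <- "Retroelement"
  out[top == "DNA"] <- "DNA transposon"
  out[top == "RC"] <- "Rolling-circle"
  out[top %in% c("snRNA", "tRNA", "rRNA", "srpRNA", "scRNA", "ncRNA")] <- "Small RNA"
  out[top == "Satellite"] <- "Satellite"
  out[top == "Simple_repeat"] <- "Simple repeat"
  out[top == "Low_complexity"] <- "Low complexity"
  out
}
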
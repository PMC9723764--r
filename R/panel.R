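#' Define the region layout of a lectin barcode
#'
#' A lectin barcode is partitioned into flanking regions and a middle
#' region; the read matcher applies a separate mismatch allowance to
#' each (see [match_tolerance()]). Coordinates are 0-based half-open
#' intervals, as in BED, and must tile the barcode exactly.
#'
#' @param barcode_length Integer, barcode length in bases.
#' @param flank_spans List of length-2 integer vectors `c(start, end)`,
#'   the flanking intervals. The default places one flank at each end
#'   of a 22-base barcode.
#' @param middle_span Length-2 integer vector, the middle interval.
#' @return An object of class `region_layout`.
#' @examples
#' region_layout(12, flank_spans = list(c(0, 4), c(8, 12)),
#'               middle_span = c(4, 8))
#' @export
region_layout <- function(barcode_length = 22L,
                          flank_spans = list(c(0L, 7L), c(15L, 22L)),
                          middle_span = c(7L, 15L)) {
  barcode_length <- as.integer(barcode_length)
  if (length(barcode_length) != 1L || is.na(barcode_length) ||
      barcode_length < 1L) {
    stop("'barcode_length' must be a single positive integer")
  }
  flank_spans <- lapply(flank_spans, as.integer)
  middle_span <- as.integer(middle_span)
  spans <- c(flank_spans, list(middle_span))
  for (sp in spans) {
    if (length(sp) != 2L || anyNA(sp)) {
      stop("malformed interval: each span must be c(start, end)")
    }
    if (sp[1] < 0L || sp[2] > barcode_length || sp[1] >= sp[2]) {
      stop(sprintf("malformed interval [%d,%d): spans must be non-empty and lie within [0,%d)",
                   sp[1], sp[2], barcode_length))
    }
  }
  covered <- integer(0)
  for (sp in spans) covered <- c(covered, seq.int(sp[1], sp[2] - 1L))
  if (anyDuplicated(covered)) {
    stop("flank and middle spans overlap")
  }
  if (!identical(sort(covered), seq.int(0L, barcode_length - 1L))) {
    stop("flank and middle spans must together cover exactly [0, barcode_length)")
  }
  structure(
    list(barcode_length = barcode_length,
         flank_spans = flank_spans,
         middle_span = middle_span),
    class = "region_layout"
  )
}

# 1-based positions of the flank / middle regions within the barcode
flank_positions <- function(layout) {
  sort(unlist(lapply(layout$flank_spans,
                     function(sp) seq.int(sp[1] + 1L, sp[2]))))
}

middle_positions <- function(layout) {
  sp <- layout$middle_span
  seq.int(sp[1] + 1L, sp[2])
}

#' Construct a DNA-barcoded lectin panel
#'
#' The panel is the barcode whitelist used by the counter: one DNA
#' barcode per lectin, a shared [region_layout()], and the number of
#' uninformative bases trimmed from the start of every read before
#' matching (three in the assay's read structure).
#'
#' @param lectin_name Character vector of unique lectin names.
#' @param barcode_seq Character vector of DNA barcodes over A/C/G/T,
#'   all of the layout's `barcode_length`; must be distinct.
#' @param specificity Character vector of free-text glycan-specificity
#'   annotations (never interpreted computationally).
#' @param layout A [region_layout()].
#' @param prefix_trim Integer, bases removed from the read start before
#'   matching (default 3).
#' @return An object of class `lectin_panel`.
#' @seealso [load_panel()], [write_panel()], [validate_separability()]
#' @export
lectin_panel <- function(lectin_name, barcode_seq,
                         specificity = rep("", length(lectin_name)),
                         layout = region_layout(),
                         prefix_trim = 3L) {
  stopifnot(inherits(layout, "region_layout"))
  lectin_name <- as.character(lectin_name)
  barcode_seq <- toupper(as.character(barcode_seq))
  specificity <- as.character(specificity)
  n <- length(lectin_name)
  if (n < 2L) {
    stop("a panel needs at least 2 lectins (log-ratio analysis requires a reference partner)")
  }
  if (length(barcode_seq) != n || length(specificity) != n) {
    stop("'lectin_name', 'barcode_seq' and 'specificity' must have equal length")
  }
  dup <- unique(lectin_name[duplicated(lectin_name)])
  if (length(dup)) {
    stop("duplicate lectin names: ", paste(dup, collapse = ", "))
  }
  dup <- unique(barcode_seq[duplicated(barcode_seq)])
  if (length(dup)) {
    stop("duplicate barcode sequences: ", paste(dup, collapse = ", "))
  }
  bad <- grepl("[^ACGT]", barcode_seq)
  if (any(bad)) {
    stop("barcodes must be over {A,C,G,T}; offending: ",
         paste(lectin_name[bad], collapse = ", "))
  }
  wrong <- nchar(barcode_seq) != layout$barcode_length
  if (any(wrong)) {
    stop(sprintf("barcode length must equal layout barcode_length (%d); offending: %s",
                 layout$barcode_length,
                 paste(lectin_name[wrong], collapse = ", ")))
  }
  prefix_trim <- as.integer(prefix_trim)
  if (length(prefix_trim) != 1L || is.na(prefix_trim) || prefix_trim < 0L) {
    stop("'prefix_trim' must be a single non-negative integer")
  }
  structure(
    list(layout = layout,
         lectin_name = lectin_name,
         barcode_seq = barcode_seq,
         specificity = specificity,
         prefix_trim = prefix_trim),
    class = "lectin_panel"
  )
}

#' @export
print.lectin_panel <- function(x, ...) {
  lay <- x$layout
  flanks <- paste(vapply(lay$flank_spans,
                         function(sp) sprintf("[%d,%d)", sp[1], sp[2]), ""),
                  collapse = " ")
  cat(sprintf("lectin_panel: %d lectins, %d-base barcodes\n",
              length(x$lectin_name), lay$barcode_length))
  cat(sprintf("  flanks %s, middle [%d,%d), prefix_trim %d\n",
              flanks, lay$middle_span[1], lay$middle_span[2], x$prefix_trim))
  invisible(x)
}

#' @export
length.lectin_panel <- function(x) length(x$lectin_name)

format_spans <- function(spans) {
  paste(vapply(spans, function(sp) sprintf("%d-%d", sp[1], sp[2]), ""),
        collapse = ",")
}

parse_spans <- function(txt) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    se <- suppressWarnings(as.integer(strsplit(p, "-", fixed = TRUE)[[1]]))
    if (length(se) != 2L || anyNA(se)) {
      stop("malformed interval spec: ", p)
    }
    se
  })
}

#' Read a lectin panel file
#'
#' The on-disk format is tab-separated with columns
#' `lectin_name`, `barcode_seq`, `specificity`, preceded by a
#' `#layout:` comment line holding `key=value;` pairs for
#' `barcode_length`, `flanks`, `middle` and `prefix_trim`
#' (0-based half-open intervals, e.g.
#' `#layout: barcode_length=22;flanks=0-7,15-22;middle=7-15;prefix_trim=3`).
#'
#' @param path Path to a panel file.
#' @return A validated [lectin_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#layout:")) {
    stop("panel file must start with a '#layout:' line: ", path)
  }
  spec <- sub("^#layout:\\s*", "", lines[1])
  kv <- strsplit(spec, ";", fixed = TRUE)[[1]]
  kv <- kv[nzchar(trimws(kv))]
  pairs <- strsplit(trimws(kv), "=", fixed = TRUE)
  keys <- vapply(pairs, `[`, "", 1L)
  vals <- vapply(pairs, `[`, "", 2L)
  names(vals) <- keys
  need <- c("barcode_length", "flanks", "middle", "prefix_trim")
  miss <- setdiff(need, keys)
  if (length(miss)) {
    stop("#layout: line missing key(s): ", paste(miss, collapse = ", "))
  }
  layout <- region_layout(
    barcode_length = as.integer(vals[["barcode_length"]]),
    flank_spans = parse_spans(vals[["flanks"]]),
    middle_span = parse_spans(vals[["middle"]])[[1]]
  )
  tab <- utils::read.delim(text = lines[-1], header = TRUE,
                           colClasses = "character", comment.char = "")
  need_cols <- c("lectin_name", "barcode_seq", "specificity")
  if (!all(need_cols %in% names(tab))) {
    stop("panel table must have columns: ", paste(need_cols, collapse = ", "))
  }
  lectin_panel(tab$lectin_name, tab$barcode_seq, tab$specificity,
               layout = layout,
               prefix_trim = as.integer(vals[["prefix_trim"]]))
}

#' Write a lectin panel file
#'
#' @param panel A [lectin_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "lectin_panel"))
  lay <- panel$layout
  header <- sprintf("#layout: barcode_length=%d;flanks=%s;middle=%s;prefix_trim=%d",
                    lay$barcode_length,
                    format_spans(lay$flank_spans),
                    format_spans(list(lay$middle_span)),
                    panel$prefix_trim)
  body <- paste(panel$lectin_name, panel$barcode_seq, panel$specificity,
                sep = "\t")
  writeLines(c(header,
               paste("lectin_name", "barcode_seq", "specificity", sep = "\t"),
               body),
             path)
  invisible(path)
}

#' Export panel barcodes as FASTA
#'
#' Record ids are the lectin names; useful for interoperability with
#' alignment-based tooling.
#'
#' @param panel A [lectin_panel()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
panel_to_fasta <- function(panel, path) {
  stopifnot(inherits(panel, "lectin_panel"))
  seqs <- Biostrings::DNAStringSet(panel$barcode_seq)
  names(seqs) <- panel$lectin_name
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Check that a panel is unambiguous under a mismatch tolerance
#'
#' Two barcodes collide when some read sequence lies within the
#' mismatch budgets of both. With per-region Hamming budgets this is
#' decidable exactly from pairwise distances: a read within tolerance
#' of both A and B exists if and only if, in every region, the
#' inter-barcode mismatch count is at most twice that region's
#' allowance (split the differing positions between the two barcodes).
#'
#' @param panel A [lectin_panel()].
#' @param tol A [match_tolerance()].
#' @return A list of class `separability_report` with elements
#'   `ambiguous` (logical, any collision) and `collisions` (data frame
#'   of colliding pairs with their per-region distances).
#' @export
validate_separability <- function(panel, tol = match_tolerance()) {
  stopifnot(inherits(panel, "lectin_panel"), inherits(tol, "match_tolerance"))
  m <- length(panel)
  chars <- do.call(rbind, strsplit(panel$barcode_seq, "", fixed = TRUE))
  fpos <- flank_positions(panel$layout)
  mpos <- middle_positions(panel$layout)
  out <- list(a = character(0), b = character(0),
              df = integer(0), dm = integer(0))
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      diffs <- chars[i, ] != chars[j, ]
      df <- sum(diffs[fpos])
      dm <- sum(diffs[mpos])
      if (df <= 2L * tol$max_flank_mismatches &&
          dm <= 2L * tol$max_middle_mismatches) {
        out$a <- c(out$a, panel$lectin_name[i])
        out$b <- c(out$b, panel$lectin_name[j])
        out$df <- c(out$df, df)
        out$dm <- c(out$dm, dm)
      }
    }
  }
  collisions <- data.frame(lectin_a = out$a, lectin_b = out$b,
                           flank_distance = out$df,
                           middle_distance = out$dm,
                           stringsAsFactors = FALSE)
  structure(list(ambiguous = nrow(collisions) > 0L,
                 collisions = collisions,
                 tolerance = tol),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  if (x$ambiguous) {
    cat(sprintf("panel AMBIGUOUS: %d colliding pair(s)\n", nrow(x$collisions)))
    print(x$collisions)
  } else {
    cat("panel separable: no barcode pair collides under the tolerance\n")
  }
  invisible(x)
}
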
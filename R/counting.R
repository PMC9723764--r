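#' Mismatch tolerance for barcode matching
#'
#' The assay's matching rule allows up to two mismatches summed over
#' the flanking regions and one mismatch in the middle region, after
#' removing the first three (uninformative) bases of each read; those
#' are the defaults here.
#'
#' @param max_flank_mismatches Integer >= 0, mismatch budget summed
#'   over all flanking spans.
#' @param max_middle_mismatches Integer >= 0, mismatch budget for the
#'   middle span.
#' @param prefix_trim Integer >= 0 or `NULL`; bases dropped from the
#'   read start before matching. `NULL` (default) inherits the panel's
#'   `prefix_trim`.
#' @return An object of class `match_tolerance`.
#' @export
match_tolerance <- function(max_flank_mismatches = 2L,
                            max_middle_mismatches = 1L,
                            prefix_trim = NULL) {
  max_flank_mismatches <- as.integer(max_flank_mismatches)
  max_middle_mismatches <- as.integer(max_middle_mismatches)
  if (is.na(max_flank_mismatches) || max_flank_mismatches < 0L ||
      is.na(max_middle_mismatches) || max_middle_mismatches < 0L) {
    stop("mismatch budgets must be non-negative integers")
  }
  if (!is.null(prefix_trim)) {
    prefix_trim <- as.integer(prefix_trim)
    if (is.na(prefix_trim) || prefix_trim < 0L) {
      stop("'prefix_trim' must be a non-negative integer or NULL")
    }
  }
  structure(list(max_flank_mismatches = max_flank_mismatches,
                 max_middle_mismatches = max_middle_mismatches,
                 prefix_trim = prefix_trim),
            class = "match_tolerance")
}

effective_prefix_trim <- function(panel, tol) {
  if (is.null(tol$prefix_trim)) panel$prefix_trim else tol$prefix_trim
}

#' Match reads against a lectin panel
#'
#' Drops the read prefix, then compares the next `barcode_length`
#' bases against every panel barcode, counting mismatches separately
#' over the flanking spans and the middle span. Candidates are
#' barcodes within both budgets; a read is `assigned` to the unique
#' candidate of minimal total mismatch, `ambiguous` on a tie,
#' `unassigned` when no candidate exists, and `too_short` when the
#' trimmed read cannot cover the barcode. `N` (or any non-ACGT
#' character) counts as a mismatch at its position.
#'
#' @param read_seq Character vector of read sequences over A/C/G/T/N.
#' @param panel A [lectin_panel()].
#' @param tol A [match_tolerance()].
#' @return A data frame with one row per read and columns `status`
#'   (factor: assigned/ambiguous/unassigned/too_short), `lectin_name`
#'   (NA unless assigned), `flank_mismatches`, `middle_mismatches`.
#' @examples
#' pan <- generate_panel(4, seed = 1)
#' match_read(paste0("ACG", pan$barcode_seq[2]), pan)
#' @export
match_read <- function(read_seq, panel, tol = match_tolerance()) {
  stopifnot(inherits(panel, "lectin_panel"), inherits(tol, "match_tolerance"))
  lay <- panel$layout
  res <- match_reads_cpp(toupper(as.character(read_seq)),
                         panel$barcode_seq,
                         flank_positions(lay) - 1L,
                         middle_positions(lay) - 1L,
                         tol$max_flank_mismatches,
                         tol$max_middle_mismatches,
                         effective_prefix_trim(panel, tol),
                         lay$barcode_length)
  status_levels <- c("assigned", "ambiguous", "unassigned", "too_short")
  data.frame(
    status = factor(status_levels[res$status + 1L], levels = status_levels),
    lectin_name = ifelse(is.na(res$index), NA_character_,
                         panel$lectin_name[res$index]),
    flank_mismatches = res$flank_mm,
    middle_mismatches = res$middle_mm,
    stringsAsFactors = FALSE
  )
}

tally_names <- c("n_reads_total", "n_assigned", "n_ambiguous",
                 "n_unassigned", "n_too_short")

#' Count barcode reads for one sample
#'
#' Streams a FASTQ file (plain or gzip) in chunks, applies
#' [match_read()] to every record, and tabulates per-lectin counts
#' plus status tallies. Memory use is independent of file size.
#'
#' @param fastq_path Path to a FASTQ file.
#' @param panel A [lectin_panel()].
#' @param tol A [match_tolerance()].
#' @param chunk_size Records per chunk (default 20000).
#' @return A list with `counts` (named integer vector, one entry per
#'   panel lectin) and `tallies` (named integer vector:
#'   n_reads_total, n_assigned, n_ambiguous, n_unassigned,
#'   n_too_short).
#' @export
count_sample <- function(fastq_path, panel, tol = match_tolerance(),
                         chunk_size = 20000L) {
  stopifnot(inherits(panel, "lectin_panel"))
  if (!file.exists(fastq_path)) stop("FASTQ file not found: ", fastq_path)
  counts <- stats::setNames(integer(length(panel)), panel$lectin_name)
  tallies <- stats::setNames(integer(5L), tally_names)
  con <- gzfile(fastq_path, open = "rt")
  on.exit(close(con), add = TRUE)
  rec_offset <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L) {
      stop(sprintf("malformed FASTQ record %d in %s: truncated record",
                   rec_offset + length(lines) %/% 4L + 1L, fastq_path))
    }
    nrec <- length(lines) %/% 4L
    hdr <- lines[seq.int(1L, length(lines), by = 4L)]
    sep <- lines[seq.int(3L, length(lines), by = 4L)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
    if (length(bad)) {
      stop(sprintf("malformed FASTQ record %d in %s",
                   rec_offset + bad[1], fastq_path))
    }
    seqs <- lines[seq.int(2L, length(lines), by = 4L)]
    res <- match_read(seqs, panel, tol)
    tallies["n_reads_total"] <- tallies["n_reads_total"] + nrec
    st <- table(res$status)
    tallies["n_assigned"] <- tallies["n_assigned"] + st[["assigned"]]
    tallies["n_ambiguous"] <- tallies["n_ambiguous"] + st[["ambiguous"]]
    tallies["n_unassigned"] <- tallies["n_unassigned"] + st[["unassigned"]]
    tallies["n_too_short"] <- tallies["n_too_short"] + st[["too_short"]]
    hit <- res$lectin_name[res$status == "assigned"]
    if (length(hit)) {
      tab <- table(factor(hit, levels = panel$lectin_name))
      counts <- counts + as.integer(tab)
    }
    rec_offset <- rec_offset + nrec
  }
  if (rec_offset == 0L) {
    warning("empty FASTQ file: ", fastq_path)
  }
  list(counts = counts, tallies = tallies)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample_id`, `group`, `fastq_path`.
#' Relative FASTQ paths are resolved against the sheet's directory.
#'
#' @param path Path to the sample sheet TSV.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.delim(path, colClasses = "character")
  need <- c("sample_id", "group", "fastq_path")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup)) {
    stop("duplicate sample_id in sample sheet: ", paste(dup, collapse = ", "))
  }
  rel <- !file.exists(sheet$fastq_path)
  sheet$fastq_path[rel] <- file.path(dirname(path), sheet$fastq_path[rel])
  sheet
}

#' Count barcode reads for a whole experiment
#'
#' Runs [count_sample()] over every row of a sample sheet (in sheet
#' order) and assembles the count matrix. All FASTQ paths are checked
#' before any counting starts.
#'
#' @param sample_sheet Path to a sample sheet TSV, or a data frame
#'   with columns `sample_id`, `group`, `fastq_path`.
#' @param panel A [lectin_panel()].
#' @param tol A [match_tolerance()].
#' @return An object of class `lectin_counts`: list with `counts`
#'   (samples x lectins integer matrix), `tallies` (data frame of
#'   per-sample status tallies) and `groups` (named character vector).
#' @export
count_experiment <- function(sample_sheet, panel, tol = match_tolerance()) {
  sheet <- if (is.character(sample_sheet)) {
    read_sample_sheet(sample_sheet)
  } else {
    sample_sheet
  }
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup)) {
    stop("duplicate sample_id in sample sheet: ", paste(dup, collapse = ", "))
  }
  missing <- sheet$fastq_path[!file.exists(sheet$fastq_path)]
  if (length(missing)) {
    stop("FASTQ file(s) not found: ", paste(missing, collapse = ", "))
  }
  n <- nrow(sheet)
  counts <- matrix(0L, n, length(panel),
                   dimnames = list(sheet$sample_id, panel$lectin_name))
  tallies <- matrix(0L, n, 5L, dimnames = list(sheet$sample_id, tally_names))
  for (i in seq_len(n)) {
    row <- count_sample(sheet$fastq_path[i], panel, tol)
    counts[i, ] <- row$counts
    tallies[i, ] <- row$tallies
  }
  structure(
    list(counts = counts,
         tallies = cbind(data.frame(sample_id = sheet$sample_id,
                                    stringsAsFactors = FALSE),
                         as.data.frame(tallies, row.names = sheet$sample_id)),
         groups = stats::setNames(sheet$group, sheet$sample_id)),
    class = "lectin_counts"
  )
}

#' @export
print.lectin_counts <- function(x, ...) {
  cat(sprintf("lectin_counts: %d samples x %d lectins\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  assigned %s of %s reads\n",
              format(sum(x$tallies$n_assigned), big.mark = ","),
              format(sum(x$tallies$n_reads_total), big.mark = ",")))
  invisible(x)
}

#' Write a count matrix and QC tallies to disk
#'
#' @param x A `lectin_counts` object from [count_experiment()].
#' @param counts_path Output TSV path (`sample_id` + one column per
#'   lectin).
#' @param qc_path Optional output path for the QC JSON of per-sample
#'   status tallies; skipped when `NULL`.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(x, counts_path, qc_path = NULL) {
  stopifnot(inherits(x, "lectin_counts"))
  df <- cbind(data.frame(sample_id = rownames(x$counts),
                         stringsAsFactors = FALSE),
              as.data.frame(x$counts))
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(qc_path)) {
    jsonlite::write_json(x$tallies, qc_path, dataframe = "rows",
                         pretty = TRUE)
  }
  invisible(counts_path)
}
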
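# Independent brute-force read matcher: enumerates every barcode and
# applies the per-region budgets literally, one read at a time.
# Deliberately shares no code with the package's matcher.
oracle_match <- function(read, panel, tol = match_tolerance()) {
  pt <- if (is.null(tol$prefix_trim)) panel$prefix_trim else tol$prefix_trim
  bl <- panel$layout$barcode_length
  if (nchar(read) < pt + bl) {
    return(list(status = "too_short", lectin_name = NA_character_,
                flank_mismatches = NA_integer_,
                middle_mismatches = NA_integer_))
  }
  rb <- strsplit(toupper(substr(read, pt + 1L, pt + bl)), "")[[1]]
  fpos <- unlist(lapply(panel$layout$flank_spans,
                        function(sp) (sp[1] + 1L):sp[2]))
  mpos <- (panel$layout$middle_span[1] + 1L):panel$layout$middle_span[2]
  cand <- data.frame(i = integer(0), f = integer(0), m = integer(0))
  for (i in seq_along(panel$barcode_seq)) {
    bb <- strsplit(panel$barcode_seq[i], "")[[1]]
    f <- sum(rb[fpos] != bb[fpos])
    m <- sum(rb[mpos] != bb[mpos])
    if (f <= tol$max_flank_mismatches && m <= tol$max_middle_mismatches) {
      cand <- rbind(cand, data.frame(i = i, f = f, m = m))
    }
  }
  if (nrow(cand) == 0L) {
    return(list(status = "unassigned", lectin_name = NA_character_,
                flank_mismatches = NA_integer_,
                middle_mismatches = NA_integer_))
  }
  tot <- cand$f + cand$m
  best <- which(tot == min(tot))
  if (length(best) > 1L) {
    return(list(status = "ambiguous", lectin_name = NA_character_,
                flank_mismatches = NA_integer_,
                middle_mismatches = NA_integer_))
  }
  list(status = "assigned",
       lectin_name = panel$lectin_name[cand$i[best]],
       flank_mismatches = cand$f[best],
       middle_mismatches = cand$m[best])
}

random_dna <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                           collapse = ""),
         "")
}

# Mutate a barcode at exactly the given flank / middle positions
# (each substitution changes the base, so mismatch counts are exact).
mutate_barcode <- function(barcode, layout, n_flank = 0L, n_middle = 0L) {
  ch <- strsplit(barcode, "")[[1]]
  fpos <- unlist(lapply(layout$flank_spans, function(sp) (sp[1] + 1L):sp[2]))
  mpos <- (layout$middle_span[1] + 1L):layout$middle_span[2]
  flip <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  for (p in sample(fpos, n_flank)) ch[p] <- flip(ch[p])
  for (p in sample(mpos, n_middle)) ch[p] <- flip(ch[p])
  paste(ch, collapse = "")
}

# A read carrying the given barcode body plus the uninformative prefix
with_prefix <- function(barcode, prefix_trim = 3L) {
  paste0(paste(sample(c("A", "C", "G", "T"), prefix_trim, TRUE),
               collapse = ""),
         barcode)
}

write_fastq_records <- function(path, seqs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))),
             path)
  path
}

# Profiles object built straight from a percentage matrix
profiles_from_matrix <- function(mat, groups) {
  normalize_profiles(mat, groups = stats::setNames(groups, rownames(mat)))
}
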
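#' Default lectin names for simulated panels
#'
#' The first eight names are lectins from the assay's panel that carry
#' well-characterized specificities (GlcNAc-, mannose- and
#' alpha2-6-sialic-acid binders); the remainder are generic
#' placeholders. Used by [generate_panel()].
#'
#' @param n Number of lectins.
#' @return Character vector of length `n`.
#' @export
default_lectin_names <- function(n) {
  known <- c("rABA", "rSRL", "rPVL", "rGRFT", "rBanana", "SSA", "TJAI", "SNA")
  if (n <= length(known)) return(known[seq_len(n)])
  c(known, sprintf("LEC%02d", seq.int(length(known) + 1L, n)))
}

default_specificities <- function(names) {
  spec <- c(rABA = "GlcNAc/Galb1-3GalNAc", rSRL = "GlcNAc/Galb1-3GalNAc",
            rPVL = "GlcNAc", rGRFT = "Man", rBanana = "Man",
            SSA = "a2-6Sia", TJAI = "a2-6Sia", SNA = "a2-6Sia")
  out <- unname(spec[names])
  out[is.na(out)] <- "unspecified"
  out
}

#' Generate a random, well-separated lectin panel
#'
#' Draws random barcodes sequentially, accepting each only if its
#' Hamming distance to every accepted barcode is at least
#' `min_separation`. The default separation of 7 guarantees zero
#' collisions under the default tolerance (a collision needs at most
#' 2x2 flank plus 2x1 middle = 6 differing positions).
#'
#' @param n_lectins Number of lectins (>= 2).
#' @param layout A [region_layout()].
#' @param min_separation Minimum pairwise Hamming distance.
#' @param seed Integer seed; the result is deterministic given it.
#' @param prefix_trim Prefix bases recorded in the panel (default 3).
#' @param max_attempts Rejection-sampling budget.
#' @return A [lectin_panel()] that passes [validate_separability()]
#'   under the default tolerance.
#' @export
generate_panel <- function(n_lectins, layout = region_layout(),
                           min_separation = 7L, seed = 1L,
                           prefix_trim = 3L,
                           max_attempts = 1000L * n_lectins) {
  stopifnot(inherits(layout, "region_layout"))
  if (n_lectins < 2L) stop("'n_lectins' must be at least 2")
  if (min_separation > layout$barcode_length) {
    stop(sprintf("min_separation (%d) exceeds barcode_length (%d); use longer barcodes",
                 min_separation, layout$barcode_length))
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  len <- layout$barcode_length
  accepted <- character(0)
  accepted_mat <- NULL
  attempts <- 0L
  while (length(accepted) < n_lectins) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("could not place %d barcodes at min_separation %d within %d attempts; use longer barcodes",
                   n_lectins, min_separation, max_attempts))
    }
    cand <- sample(bases, len, replace = TRUE)
    if (is.null(accepted_mat) ||
        all(rowSums(accepted_mat != matrix(cand, nrow(accepted_mat), len,
                                           byrow = TRUE)) >= min_separation)) {
      accepted <- c(accepted, paste(cand, collapse = ""))
      accepted_mat <- rbind(accepted_mat, cand)
    }
  }
  nm <- default_lectin_names(n_lectins)
  lectin_panel(nm, accepted, default_specificities(nm),
               layout = layout, prefix_trim = prefix_trim)
}

#' Default per-lectin baseline composition
#'
#' A smooth, uneven abundance profile (geometric decay with ratio
#' 0.85, renormalized): a few dominant lectin signals plus a long tail
#' of minor ones, which is the typical shape of a lectin percentage
#' profile. At the default 39 lectins the largest share is about 15%
#' and the smallest about 0.03%.
#'
#' @param n_lectins Number of lectins.
#' @param ratio Geometric decay ratio in (0, 1].
#' @return Numeric vector summing to 1.
#' @export
default_composition <- function(n_lectins, ratio = 0.85) {
  w <- ratio^(seq_len(n_lectins) - 1)
  w / sum(w)
}

#' Describe a two-group experimental design
#'
#' Captures group labels, replicate numbers, a shared baseline
#' composition, and planted fold-changes applied to chosen lectins in
#' chosen groups (then renormalized) — e.g. the elevated
#' alpha2-6-sialic-acid binders (SSA, TJAI, SNA) that distinguish the
#' preweaned-pup microbiota from the adult one.
#'
#' @param panel A [lectin_panel()]; compositions are indexed by its
#'   lectin names.
#' @param groups Named integer vector: samples per group (default
#'   `c(pups = 3, adult = 3)`).
#' @param baseline Numeric vector of per-lectin proportions summing to
#'   1 (default [default_composition()]).
#' @param effects Named list, one element per affected group, each a
#'   named numeric vector of fold-changes keyed by lectin name, e.g.
#'   `list(pups = c(SSA = 5, TJAI = 5, SNA = 5))`.
#' @return An object of class `group_design` with the per-group
#'   renormalized compositions.
#' @export
group_design <- function(panel,
                         groups = c(pups = 3L, adult = 3L),
                         baseline = default_composition(length(panel)),
                         effects = list()) {
  stopifnot(inherits(panel, "lectin_panel"))
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("'groups' must be a named vector of samples per group")
  }
  groups <- stats::setNames(as.integer(groups), names(groups))
  if (any(groups < 1L)) stop("each group needs at least 1 sample")
  if (length(baseline) != length(panel)) {
    stop("'baseline' must have one proportion per panel lectin")
  }
  if (any(baseline < 0) || abs(sum(baseline) - 1) > 1e-9) {
    stop("'baseline' must be non-negative and sum to 1")
  }
  unknown_g <- setdiff(names(effects), names(groups))
  if (length(unknown_g)) {
    stop("effects refer to unknown group(s): ", paste(unknown_g, collapse = ", "))
  }
  comps <- matrix(rep(baseline, each = length(groups)),
                  nrow = length(groups),
                  dimnames = list(names(groups), panel$lectin_name))
  for (g in names(effects)) {
    fc <- effects[[g]]
    unknown_l <- setdiff(names(fc), panel$lectin_name)
    if (length(unknown_l)) {
      stop("effects refer to unknown lectin(s): ",
           paste(unknown_l, collapse = ", "))
    }
    if (any(fc <= 0)) stop("fold-changes must be positive")
    comps[g, names(fc)] <- comps[g, names(fc)] * fc
    comps[g, ] <- comps[g, ] / sum(comps[g, ])
  }
  structure(list(groups = groups, compositions = comps, effects = effects),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat(sprintf("group_design: %s\n",
              paste(sprintf("%s (n=%d)", names(x$groups), x$groups),
                    collapse = " vs ")))
  for (g in names(x$effects)) {
    fc <- x$effects[[g]]
    cat(sprintf("  effect in %s: %s\n", g,
                paste(sprintf("%s x%g", names(fc), fc), collapse = ", ")))
  }
  invisible(x)
}

design_sample_ids <- function(design) {
  unlist(lapply(names(design$groups), function(g) {
    sprintf("%s_%d", g, seq_len(design$groups[[g]]))
  }), use.names = FALSE)
}

design_sample_groups <- function(design) {
  rep(names(design$groups), design$groups)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate per-sample lectin read counts
#'
#' Draws each sample's lectin counts from a multinomial over its
#' group's composition. With `overdispersion > 0` the composition is
#' first jittered per sample from a Dirichlet with concentration
#' `composition / overdispersion`, adding between-replicate
#' variability beyond counting noise (off by default).
#'
#' @param panel A [lectin_panel()].
#' @param design A [group_design()].
#' @param depth Reads per sample.
#' @param overdispersion Dirichlet overdispersion (0 = pure
#'   multinomial).
#' @param seed Integer seed.
#' @return A list with `counts` (samples x lectins integer matrix),
#'   `compositions` (per-sample realized compositions), `groups`
#'   (named character vector) and `seed`.
#' @export
simulate_counts <- function(panel, design, depth = 1e5,
                            overdispersion = 0, seed = 1L) {
  stopifnot(inherits(panel, "lectin_panel"), inherits(design, "group_design"))
  set.seed(seed)
  ids <- design_sample_ids(design)
  grp <- design_sample_groups(design)
  m <- length(panel)
  counts <- matrix(0L, length(ids), m,
                   dimnames = list(ids, panel$lectin_name))
  comps <- matrix(0, length(ids), m, dimnames = dimnames(counts))
  for (i in seq_along(ids)) {
    p <- design$compositions[grp[i], ]
    if (overdispersion > 0) p <- rdirichlet1(p / overdispersion)
    comps[i, ] <- p
    counts[i, ] <- as.integer(stats::rmultinom(1, depth, p))
  }
  list(counts = counts, compositions = comps,
       groups = stats::setNames(grp, ids), seed = seed)
}

apply_substitutions <- function(char_mat, error_rate) {
  if (error_rate <= 0) return(char_mat)
  hit <- which(stats::runif(length(char_mat)) < error_rate)
  if (!length(hit)) return(char_mat)
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, length(hit), replace = TRUE)
  char_mat[hit] <- others[cbind(match(char_mat[hit], rownames(others)), pick)]
  char_mat
}

collapse_rows <- function(char_mat) {
  do.call(paste0, as.data.frame(char_mat, stringsAsFactors = FALSE))
}

#' Simulate a Glycan-seq sequencing run
#'
#' The in-silico mirror of barcode release and sequencing: per sample,
#' lectin read counts are drawn multinomially from the group
#' composition over `(1 - contaminant_fraction) * depth` reads;
#' contaminant reads are fully random sequence. Each lectin read is
#' three random prefix bases followed by the lectin's barcode with
#' i.i.d. substitution errors. Reads are shuffled, written as 4-line
#' FASTQ (Phred+33, constant quality), and every record's true label
#' is recorded in a truth table aligned one-to-one with the FASTQ.
#'
#' @param panel A [lectin_panel()].
#' @param design A [group_design()].
#' @param out_dir Output directory (created if needed).
#' @param depth Reads per sample (truth labels per sample sum to this).
#' @param error_rate Per-base substitution probability in `[0, 0.5)`.
#' @param contaminant_fraction Proportion of unassignable reads in
#'   `[0, 1)`.
#' @param seed Integer master seed; outputs are byte-identical given
#'   identical arguments.
#' @param paired Also write a filler mate-2 FASTQ per sample (the
#'   matching rule only uses read 1).
#' @return An object of class `glycanseq_sim`: list with
#'   `sample_sheet` (path), `fastq` (named paths), `truth` (list:
#'   `counts` samples x lectins true-label matrix,
#'   `n_contaminant` per sample, `compositions`, `table_path`),
#'   `manifest` (path) and the simulation parameters.
#' @export
simulate_reads <- function(panel, design, out_dir,
                           depth = 1e5, error_rate = 0.005,
                           contaminant_fraction = 0.01, seed = 1L,
                           paired = FALSE) {
  stopifnot(inherits(panel, "lectin_panel"), inherits(design, "group_design"))
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("'error_rate' must be in [0, 0.5)")
  }
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("'contaminant_fraction' must be in [0, 1)")
  }
  if (!length(design$groups)) stop("empty design")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ids <- design_sample_ids(design)
  grp <- design_sample_groups(design)
  lay <- panel$layout
  bl <- lay$barcode_length
  width <- panel$prefix_trim + bl
  bases <- c("A", "C", "G", "T")
  bc_mat <- do.call(rbind, strsplit(panel$barcode_seq, "", fixed = TRUE))
  qual <- strrep("I", width)
  n_cont <- as.integer(round(contaminant_fraction * depth))
  n_lect <- as.integer(depth) - n_cont

  truth_counts <- matrix(0L, length(ids), length(panel),
                         dimnames = list(ids, panel$lectin_name))
  comps <- matrix(0, length(ids), length(panel), dimnames = dimnames(truth_counts))
  fastq <- stats::setNames(file.path(out_dir, paste0(ids, "_R1.fastq")), ids)
  truth_path <- file.path(out_dir, "truth.tsv")
  tcon <- file(truth_path, open = "wt")
  on.exit(close(tcon), add = TRUE)
  writeLines(paste("sample_id", "read_id", "true_label", sep = "\t"), tcon)

  for (i in seq_along(ids)) {
    p <- design$compositions[grp[i], ]
    comps[i, ] <- p
    cnt <- as.integer(stats::rmultinom(1, n_lect, p))
    truth_counts[i, ] <- cnt
    labels <- c(rep(panel$lectin_name, cnt), rep("contaminant", n_cont))
    ord <- sample.int(length(labels))
    labels <- labels[ord]
    is_lect <- labels != "contaminant"
    seq_mat <- matrix("", length(labels), width)
    seq_mat[, seq_len(panel$prefix_trim)] <-
      sample(bases, length(labels) * panel$prefix_trim, replace = TRUE)
    bc_idx <- match(labels[is_lect], panel$lectin_name)
    body <- bc_mat[bc_idx, , drop = FALSE]
    body <- apply_substitutions(body, error_rate)
    seq_mat[is_lect, panel$prefix_trim + seq_len(bl)] <- body
    if (any(!is_lect)) {
      seq_mat[!is_lect, panel$prefix_trim + seq_len(bl)] <-
        sample(bases, sum(!is_lect) * bl, replace = TRUE)
    }
    seqs <- collapse_rows(seq_mat)
    read_ids <- sprintf("%s.%06d", ids[i], seq_along(labels))
    recs <- as.vector(rbind(paste0("@", read_ids), seqs, "+",
                            rep(qual, length(seqs))))
    writeLines(recs, fastq[[i]])
    if (paired) {
      r2 <- sub("_R1\\.fastq$", "_R2.fastq", fastq[[i]])
      filler <- strrep("A", width)
      writeLines(as.vector(rbind(paste0("@", read_ids), filler, "+", qual)), r2)
    }
    writeLines(paste(ids[i], read_ids, labels, sep = "\t"), tcon)
  }

  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  writeLines(c(paste("sample_id", "group", "fastq_path", sep = "\t"),
               paste(ids, grp, basename(fastq), sep = "\t")),
             sheet_path)
  manifest_path <- file.path(out_dir, "sim_manifest.json")
  jsonlite::write_json(
    list(seed = seed, depth = depth, error_rate = error_rate,
         contaminant_fraction = contaminant_fraction,
         n_lectins = length(panel), groups = as.list(design$groups),
         effects = design$effects,
         fastq = as.list(basename(fastq)),
         sample_sheet = basename(sheet_path),
         truth_table = basename(truth_path)),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(
    list(sample_sheet = sheet_path, fastq = fastq,
         truth = list(counts = truth_counts,
                      n_contaminant = stats::setNames(rep(n_cont, length(ids)), ids),
                      compositions = comps, table_path = truth_path),
         manifest = manifest_path, depth = depth, error_rate = error_rate,
         contaminant_fraction = contaminant_fraction, seed = seed),
    class = "glycanseq_sim"
  )
}

#' @export
print.glycanseq_sim <- function(x, ...) {
  cat(sprintf("glycanseq_sim: %d samples, depth %g, error_rate %g, contaminants %g, seed %d\n",
              length(x$fastq), x$depth, x$error_rate,
              x$contaminant_fraction, x$seed))
  invisible(x)
}
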
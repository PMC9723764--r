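utc_timestamp <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

file_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full Glycan-seq analysis pipeline
#'
#' Executes count -> normalize -> cluster -> differential in order on
#' a panel and sample sheet, writing every stage's output plus a run
#' manifest to `out_dir`. The manifest records the package version,
#' timestamps, all configuration values, input checksums and output
#' paths; it is written even when a stage fails (with the failing
#' stage named in its `status`). When the sample sheet contains a
#' single group the differential stage is skipped with a notice.
#'
#' @param panel_path Path to a panel file (see [load_panel()]).
#' @param sample_sheet_path Path to a sample sheet TSV.
#' @param out_dir Output directory (created if needed).
#' @param tol A [match_tolerance()].
#' @param cfg A [differential_config()].
#' @param metric,linkage Clustering options (see [cluster_samples()]).
#' @param log10_offset Optional log-transform offset for clustering.
#' @param positive_threshold Percentage threshold for positive-signal
#'   flags (strict `>`; default 15).
#' @param quiet Suppress progress messages.
#' @return An object of class `glycanseq_run`: list with `counts`,
#'   `profiles`, `clustering`, `differential` (NULL when skipped),
#'   `positive` (per-group flagged lectins), `manifest` (path) and
#'   `outputs` (named paths).
#' @export
run_full <- function(panel_path, sample_sheet_path, out_dir,
                     tol = match_tolerance(),
                     cfg = differential_config(),
                     metric = "euclidean", linkage = "average",
                     log10_offset = NULL, positive_threshold = 15,
                     quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest_path <- file.path(out_dir, "manifest.json")
  outputs <- list(
    counts = file.path(out_dir, "counts.tsv"),
    qc = file.path(out_dir, "qc.json"),
    profiles = file.path(out_dir, "profiles.tsv"),
    dendrogram = file.path(out_dir, "dendrogram.nwk"),
    heatmap_matrix = file.path(out_dir, "heatmap_matrix.tsv"),
    differential = file.path(out_dir, "differential.tsv")
  )
  manifest <- list(
    tool = "glycanseq",
    version = as.character(utils::packageVersion("glycanseq")),
    started = utc_timestamp(),
    config = list(
      max_flank_mismatches = tol$max_flank_mismatches,
      max_middle_mismatches = tol$max_middle_mismatches,
      prefix_trim = tol$prefix_trim,
      pseudocount = cfg$pseudocount, test = cfg$test,
      alpha = cfg$alpha, w_fraction = cfg$w_fraction,
      metric = metric, linkage = linkage,
      log10_offset = log10_offset,
      positive_threshold = positive_threshold
    ),
    inputs = list(panel = panel_path, sample_sheet = sample_sheet_path),
    input_checksums = file_checksums(c(panel_path, sample_sheet_path)),
    outputs = lapply(outputs, identity),
    status = "running", failed_stage = NULL, finished = NULL
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  write_manifest()
  stage <- "load"
  result <- tryCatch({
    panel <- load_panel(panel_path)
    sheet <- read_sample_sheet(sample_sheet_path)

    stage <- "count"
    say("stage count: ", nrow(sheet), " samples")
    counts <- count_experiment(sheet, panel, tol)
    write_counts(counts, outputs$counts, outputs$qc)

    stage <- "normalize"
    profiles <- normalize_profiles(counts)
    write_profiles(profiles, outputs$profiles)

    stage <- "cluster"
    clustering <- cluster_samples(profiles, metric = metric,
                                  linkage = linkage,
                                  log10_offset = log10_offset)
    writeLines(clustering$newick, outputs$dendrogram)
    hm <- clustering$ordered_percent
    utils::write.table(
      cbind(data.frame(sample_id = rownames(hm), stringsAsFactors = FALSE),
            as.data.frame(formatC(hm, format = "f", digits = 4))),
      outputs$heatmap_matrix, sep = "\t", quote = FALSE, row.names = FALSE)

    positive <- lapply(stats::setNames(nm = unique(sheet$group)),
                       function(g) flag_positive(profiles, g,
                                                 positive_threshold))

    stage <- "differential"
    differential <- NULL
    if (length(unique(sheet$group)) == 2L) {
      differential <- ancom_adapted(profiles, cfg = cfg)
      report_differential(differential, outputs$differential)
    } else {
      say("stage differential: skipped (need exactly two groups, found ",
          length(unique(sheet$group)), ")")
      manifest$outputs$differential <- NULL
    }
    list(counts = counts, profiles = profiles, clustering = clustering,
         differential = differential, positive = positive)
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    manifest$finished <<- utc_timestamp()
    write_manifest()
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  manifest$status <- "ok"
  manifest$finished <- utc_timestamp()
  write_manifest()
  structure(c(result, list(manifest = manifest_path, outputs = outputs)),
            class = "glycanseq_run")
}

#' @export
print.glycanseq_run <- function(x, ...) {
  cat("glycanseq_run:\n")
  print(x$counts)
  if (!is.null(x$differential)) {
    sig <- significant_lectins(x$differential)
    cat(sprintf("  significant lectins (%d): %s\n", length(sig),
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}
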
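#' Convert lectin counts to percentage profiles
#'
#' Each lectin's count is divided by the sample's total number of
#' assigned lectin barcodes and expressed as a percentage, so every
#' sample row sums to 100. Ambiguous and unassigned reads are excluded
#' from the denominator.
#'
#' @param counts A `lectin_counts` object from [count_experiment()],
#'   or a samples x lectins count matrix.
#' @param groups Optional named character vector of group labels
#'   (taken from `counts` when it is a `lectin_counts` object).
#' @return An object of class `lectin_profiles`: list with `percent`
#'   (samples x lectins numeric matrix, rows summing to 100) and
#'   `groups`.
#' @export
normalize_profiles <- function(counts, groups = NULL) {
  if (inherits(counts, "lectin_counts")) {
    if (is.null(groups)) groups <- counts$groups
    mat <- counts$counts
  } else {
    mat <- as.matrix(counts)
  }
  totals <- rowSums(mat)
  zero <- rownames(mat)[totals == 0]
  if (length(zero)) {
    stop("sample(s) with no assigned lectin reads: ",
         paste(zero, collapse = ", "))
  }
  pct <- 100 * mat / totals
  if (is.null(groups)) {
    groups <- stats::setNames(rep(NA_character_, nrow(mat)), rownames(mat))
  }
  structure(list(percent = pct, groups = groups),
            class = "lectin_profiles")
}

#' @export
print.lectin_profiles <- function(x, ...) {
  cat(sprintf("lectin_profiles: %d samples x %d lectins (%%, rows sum to 100)\n",
              nrow(x$percent), ncol(x$percent)))
  if (!all(is.na(x$groups))) {
    cat("  groups:", paste(unique(x$groups), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag positive lectin signals in a group
#'
#' A lectin is positive when its mean percentage within the group
#' strictly exceeds the threshold (default 15, the screening cutoff
#' used to pick lectins for orthogonal validation).
#'
#' @param profiles A `lectin_profiles` object.
#' @param group Group label to average over.
#' @param threshold Percentage threshold (strict `>`).
#' @return Character vector of flagged lectin names (possibly empty).
#' @export
flag_positive <- function(profiles, group, threshold = 15) {
  stopifnot(inherits(profiles, "lectin_profiles"))
  if (threshold < 0) stop("'threshold' must be >= 0")
  in_group <- profiles$groups == group
  if (!any(in_group, na.rm = TRUE)) {
    stop("unknown group label: ", group)
  }
  means <- colMeans(profiles$percent[which(in_group), , drop = FALSE])
  names(means)[means > threshold]
}

#' Hierarchically cluster sample profiles
#'
#' Agglomerative clustering of the sample rows of a percentage profile
#' matrix, the view used to ask whether two conditions separate into
#' two clusters. Deterministic given its inputs.
#'
#' @param profiles A `lectin_profiles` object.
#' @param metric Distance metric, one of `stats::dist`'s methods
#'   (default `"euclidean"`).
#' @param linkage Agglomeration method, one of `stats::hclust`'s
#'   (default `"average"`).
#' @param log10_offset Optional positive offset; when given, profiles
#'   are transformed to `log10(percent + offset)` before clustering.
#' @return An object of class `lectin_clustering`: list with `hclust`,
#'   `leaf_order` (sample ids in dendrogram order), `cophenetic`
#'   (symmetric matrix), `newick` (dendrogram as Newick text),
#'   `ordered_percent` (heatmap-ready reordered matrix), `metric`,
#'   `linkage`.
#' @export
cluster_samples <- function(profiles, metric = "euclidean",
                            linkage = "average", log10_offset = NULL) {
  stopifnot(inherits(profiles, "lectin_profiles"))
  metrics <- c("euclidean", "maximum", "manhattan", "canberra",
               "binary", "minkowski")
  linkages <- c("ward.D", "ward.D2", "single", "complete", "average",
                "mcquitty", "median", "centroid")
  if (!metric %in% metrics) {
    stop("unknown metric '", metric, "'; options: ",
         paste(metrics, collapse = ", "))
  }
  if (!linkage %in% linkages) {
    stop("unknown linkage '", linkage, "'; options: ",
         paste(linkages, collapse = ", "))
  }
  mat <- profiles$percent
  if (nrow(mat) < 2L) stop("clustering needs at least 2 samples")
  if (!is.null(log10_offset)) {
    if (log10_offset <= 0) stop("'log10_offset' must be positive")
    mat <- log10(mat + log10_offset)
  }
  d <- stats::dist(mat, method = metric)
  hc <- stats::hclust(d, method = linkage)
  coph <- as.matrix(stats::cophenetic(hc))
  structure(
    list(hclust = hc,
         leaf_order = rownames(mat)[hc$order],
         cophenetic = coph,
         newick = ape::write.tree(ape::as.phylo(hc)),
         ordered_percent = profiles$percent[hc$order, , drop = FALSE],
         metric = metric, linkage = linkage),
    class = "lectin_clustering"
  )
}

#' @export
print.lectin_clustering <- function(x, ...) {
  cat(sprintf("lectin_clustering: %d samples, %s distance, %s linkage\n",
              length(x$leaf_order), x$metric, x$linkage))
  cat("  leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' Cut a sample dendrogram into k clusters
#'
#' @param clustering A `lectin_clustering` object.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(clustering, k = 2L) {
  stopifnot(inherits(clustering, "lectin_clustering"))
  stats::cutree(clustering$hclust, k = k)
}

#' Write percentage profiles to TSV
#'
#' Values are written with four decimals.
#'
#' @param profiles A `lectin_profiles` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "lectin_profiles"))
  mat <- profiles$percent
  fmt <- matrix(formatC(mat, format = "f", digits = 4),
                nrow(mat), dimnames = dimnames(mat))
  df <- cbind(data.frame(sample_id = rownames(mat),
                         group = unname(profiles$groups[rownames(mat)]),
                         stringsAsFactors = FALSE),
              as.data.frame(fmt))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read percentage profiles from TSV
#'
#' @param path A TSV written by [write_profiles()].
#' @return A `lectin_profiles` object.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")),
                      drop = FALSE])
  rownames(mat) <- df$sample_id
  grp <- stats::setNames(as.character(df$group), df$sample_id)
  # re-close rows to compensate for 4-decimal rounding on disk
  mat <- 100 * mat / rowSums(mat)
  structure(list(percent = mat, groups = grp), class = "lectin_profiles")
}
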
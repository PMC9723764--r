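#' Configuration for the ANCOM-style differential test
#'
#' @param pseudocount Positive value added to percentages before
#'   taking logs, guarding exact zeros. The default, 0.001, is the
#'   percentage contributed by a single read at a typical per-sample
#'   depth of 1e5, so it is negligible against any observable nonzero
#'   percentage; a pseudocount comparable to the smallest real
#'   percentages would distort null log-ratios between groups whenever
#'   a strong effect rescales the rest of the composition.
#' @param test Per-pair two-group test: `"welch"` (default, two-sided
#'   Welch t-test on log-ratios) or `"mann-whitney"`.
#' @param alpha Significance level (default 0.05).
#' @param w_fraction Fraction of a lectin's partner tests that must
#'   reject for the lectin to be called (default 0.7).
#' @return An object of class `differential_config`.
#' @export
differential_config <- function(pseudocount = 0.001,
                                test = c("welch", "mann-whitney"),
                                alpha = 0.05, w_fraction = 0.7) {
  test <- match.arg(test)
  if (pseudocount <= 0) stop("'pseudocount' must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (w_fraction <= 0 || w_fraction > 1) stop("'w_fraction' must be in (0, 1]")
  structure(list(pseudocount = pseudocount, test = test,
                 alpha = alpha, w_fraction = w_fraction),
            class = "differential_config")
}

#' Holm-Bonferroni step-down adjustment
#'
#' Orders the m p-values increasingly, multiplies the i-th smallest by
#' (m - i + 1), enforces monotonicity by a running maximum, caps at 1,
#' and returns the adjusted values in the input order. Controls the
#' family-wise error rate without independence assumptions.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03)) # 0.03 0.06 0.06
#' @export
holm_bonferroni <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  adj <- cummax((m - seq_len(m) + 1) * pvals[o])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# All-pairs Welch t-tests on log-ratio differences, computed from the
# per-group covariance matrices of the log-transformed profiles: for
# d = L[,i] - L[,j], var_g(d) = S_g[i,i] + S_g[j,j] - 2 S_g[i,j].
# Returns the m x m matrix of two-sided p-values (diagonal NA).
welch_logratio_pmat <- function(L1, L2) {
  n1 <- nrow(L1); n2 <- nrow(L2)
  mu1 <- colMeans(L1); mu2 <- colMeans(L2)
  S1 <- stats::cov(L1); S2 <- stats::cov(L2)
  v1 <- outer(diag(S1), diag(S1), "+") - 2 * S1
  v2 <- outer(diag(S2), diag(S2), "+") - 2 * S2
  v1[v1 < 0] <- 0  # numerical noise on near-constant ratios
  v2[v2 < 0] <- 0
  delta <- outer(mu1, mu1, "-") - outer(mu2, mu2, "-")
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tstat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero-variance pairs: identical ratios -> no evidence (p = 1);
  # separated constants -> certain difference (p = 0)
  degen <- se2 == 0
  p[degen] <- ifelse(delta[degen] == 0, 1, 0)
  diag(p) <- NA_real_
  p
}

mann_whitney_pmat <- function(L1, L2) {
  m <- ncol(L1)
  p <- matrix(NA_real_, m, m, dimnames = list(colnames(L1), colnames(L1)))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      d1 <- L1[, i] - L1[, j]
      d2 <- L2[, i] - L2[, j]
      if (all(d1 == d1[1]) && all(d2 == d2[1]) && d1[1] == d2[1]) {
        p[i, j] <- 1
      } else {
        p[i, j] <- suppressWarnings(
          stats::wilcox.test(d1, d2, exact = TRUE)$p.value)
      }
    }
  }
  p
}

#' ANCOM-style differential lectin analysis
#'
#' Compositional two-group test adapted from the Analysis of
#' Compositions of Microbiomes: for each lectin i, the per-sample
#' log-ratio `log((x_i + c) / (x_j + c))` is formed against every
#' partner lectin j and compared between the groups with a two-group
#' test; the (n_lectins - 1) partner p-values are Holm-adjusted within
#' lectin i; `W_i` counts adjusted rejections at `alpha`. A lectin is
#' called significant when `W_i >= ceiling(w_fraction * W_max)` and
#' its smallest Holm-adjusted partner p-value (`summary_p`) is below
#' `alpha`.
#'
#' @param profiles A `lectin_profiles` object (percent scale).
#' @param groups Character vector of the two group labels to compare;
#'   `NULL` uses the two labels present in the profiles.
#' @param cfg A [differential_config()].
#' @return An object of class `lectin_differential`: data frame with
#'   columns `lectin`, `W`, `W_max`, `summary_p`, `significant`, plus
#'   attributes `raw_p` and `adjusted_p` (lectin x partner matrices)
#'   and `config`.
#' @export
ancom_adapted <- function(profiles, groups = NULL,
                          cfg = differential_config()) {
  stopifnot(inherits(profiles, "lectin_profiles"),
            inherits(cfg, "differential_config"))
  labels <- profiles$groups
  if (is.null(groups)) {
    groups <- unique(labels)
  }
  if (length(groups) != 2L) {
    stop("exactly two group labels are required, got: ",
         paste(groups, collapse = ", "))
  }
  idx1 <- which(labels == groups[1])
  idx2 <- which(labels == groups[2])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("each group needs at least 2 samples (",
         groups[1], ": ", length(idx1), ", ",
         groups[2], ": ", length(idx2), ")")
  }
  mat <- profiles$percent
  m <- ncol(mat)
  if (m < 3L) stop("differential analysis needs at least 3 lectins")
  L <- log(mat + cfg$pseudocount)
  L1 <- L[idx1, , drop = FALSE]
  L2 <- L[idx2, , drop = FALSE]
  raw_p <- switch(cfg$test,
                  welch = welch_logratio_pmat(L1, L2),
                  `mann-whitney` = mann_whitney_pmat(L1, L2))
  adj_p <- raw_p
  for (i in seq_len(m)) {
    partners <- setdiff(seq_len(m), i)
    adj_p[i, partners] <- holm_bonferroni(raw_p[i, partners])
  }
  W <- rowSums(adj_p < cfg$alpha, na.rm = TRUE)
  W_max <- m - 1L
  summary_p <- apply(adj_p, 1, min, na.rm = TRUE)
  significant <- (W >= ceiling(cfg$w_fraction * W_max)) &
    (summary_p < cfg$alpha)
  res <- data.frame(lectin = colnames(mat),
                    W = as.integer(W),
                    W_max = W_max,
                    summary_p = summary_p,
                    significant = significant,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(res, class = c("lectin_differential", "data.frame"),
            raw_p = raw_p, adjusted_p = adj_p, config = cfg,
            groups = groups)
}

#' Write a differential report
#'
#' Rows are sorted by (significant desc, W desc, summary_p asc), with
#' remaining ties broken lexicographically by lectin name.
#'
#' @param result A `lectin_differential` from [ancom_adapted()].
#' @param path Output TSV path.
#' @return The sorted data frame, invisibly.
#' @export
report_differential <- function(result, path) {
  stopifnot(inherits(result, "lectin_differential"))
  ord <- order(-result$significant, -result$W, result$summary_p,
               result$lectin)
  out <- result[ord, c("lectin", "W", "W_max", "summary_p", "significant")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Significant lectins from a differential result
#'
#' @param result A `lectin_differential`.
#' @return Character vector of significant lectin names.
#' @export
significant_lectins <- function(result) {
  stopifnot(inherits(result, "lectin_differential"))
  sort(result$lectin[result$significant])
}
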
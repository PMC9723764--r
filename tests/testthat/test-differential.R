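test_that("Holm step-down adjustment matches hand-computed values", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.5), 0.5)
  p <- rep(0.02, 6)
  expect_equal(holm_bonferroni(p), rep(min(1, 6 * 0.02), 6))
  expect_equal(holm_bonferroni(rep(0.4, 4)), rep(1, 4))
  expect_error(holm_bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_bonferroni(c(0.1, -0.1)), "\\[0, 1\\]")
  expect_identical(holm_bonferroni(numeric(0)), numeric(0))
})

test_that("Holm adjustment agrees with stats::p.adjust on random vectors", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(holm_bonferroni(p), stats::p.adjust(p, method = "holm"))
  }
})

test_that("adjusted p-values dominate raw p-values elementwise", {
  set.seed(42)
  p <- runif(25)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
})

test_that("the all-pairs Welch computation matches stats::t.test", {
  set.seed(55)
  m <- 6
  mat <- matrix(rlnorm(10 * m, 3, 0.5), 10, m,
                dimnames = list(paste0("s", 1:10), paste0("L", 1:m)))
  prof <- profiles_from_matrix(mat, rep(c("a", "b"), each = 5))
  cfg <- differential_config()
  res <- ancom_adapted(prof, c("a", "b"), cfg)
  raw <- attr(res, "raw_p")
  L <- log(prof$percent + cfg$pseudocount)
  for (i in 1:m) for (j in 1:m) {
    if (i == j) next
    d <- L[, i] - L[, j]
    want <- stats::t.test(d[1:5], d[6:10])$p.value
    expect_equal(raw[i, j], want, tolerance = 1e-10)
  }
})

test_that("a strong planted effect attains maximal W and is called", {
  pan <- generate_panel(10, seed = 60)
  target <- pan$lectin_name[4]
  des <- group_design(pan, effects =
                        stats::setNames(list(stats::setNames(8, target)),
                                        "pups"))
  sim <- simulate_counts(pan, des, depth = 1e5, seed = 61)
  prof <- normalize_profiles(sim$counts, groups = sim$groups)
  res <- ancom_adapted(prof)
  expect_equal(res$lectin[which.max(res$W)], target)
  expect_true(res$significant[res$lectin == target])
  expect_identical(significant_lectins(res), target)
})

test_that("sample-identical groups produce p = 1 and no calls", {
  mat <- rbind(a1 = c(10, 30, 60), a2 = c(20, 30, 50),
               b1 = c(10, 30, 60), b2 = c(20, 30, 50))
  colnames(mat) <- paste0("L", 1:3)
  prof <- profiles_from_matrix(mat, c("a", "a", "b", "b"))
  res <- ancom_adapted(prof, c("a", "b"))
  raw <- attr(res, "raw_p")
  expect_true(all(raw[!is.na(raw)] == 1))
  expect_false(any(res$significant))
  expect_true(all(res$W == 0))
})

test_that("results are equivariant under lectin permutation", {
  pan <- generate_panel(8, seed = 70)
  des <- group_design(pan, effects = list(pups = c(SSA = 4)))
  sim <- simulate_counts(pan, des, depth = 5e4, seed = 71)
  prof <- normalize_profiles(sim$counts, groups = sim$groups)
  res <- ancom_adapted(prof)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  prof_perm <- normalize_profiles(sim$counts[, perm], groups = sim$groups)
  res_perm <- ancom_adapted(prof_perm)
  ord <- match(res$lectin, res_perm$lectin)
  expect_equal(res_perm$W[ord], res$W)
  expect_equal(res_perm$summary_p[ord], res$summary_p)
  expect_equal(res_perm$significant[ord], res$significant)
})

test_that("the planted lectin's W is monotone in fold-change", {
  pan <- generate_panel(12, seed = 80)
  W_at <- vapply(c(2, 5, 10), function(fold) {
    des <- group_design(pan, effects = list(pups = c(SSA = fold)))
    sim <- simulate_counts(pan, des, depth = 1e5, seed = 81)
    prof <- normalize_profiles(sim$counts, groups = sim$groups)
    res <- ancom_adapted(prof)
    res$W[res$lectin == "SSA"]
  }, 0L)
  expect_true(all(diff(W_at) >= 0))
  expect_equal(W_at[3], 11L)
})

test_that("the Mann-Whitney per-pair option runs and stays conservative", {
  pan <- generate_panel(6, seed = 90)
  des <- group_design(pan, effects = list(pups = c(SSA = 8)))
  sim <- simulate_counts(pan, des, depth = 1e5, seed = 91)
  prof <- normalize_profiles(sim$counts, groups = sim$groups)
  res <- ancom_adapted(prof, cfg = differential_config(test = "mann-whitney"))
  # with n = 3 per group the smallest exact two-sided p is 0.1, so
  # nothing can clear alpha after Holm - the rank test cannot call at
  # this replication level, which is why Welch is the default
  expect_true(all(res$summary_p >= 0.1))
  expect_false(any(res$significant))
})

test_that("group and dimension preconditions are enforced", {
  mat <- rbind(a1 = c(10, 90), a2 = c(20, 80),
               b1 = c(30, 70), b2 = c(40, 60))
  colnames(mat) <- c("L1", "L2")
  prof2 <- profiles_from_matrix(mat, c("a", "a", "b", "b"))
  expect_error(ancom_adapted(prof2), "at least 3 lectins")
  mat3 <- cbind(mat, L3 = c(5, 5, 5, 5))
  prof3 <- profiles_from_matrix(mat3, c("a", "a", "b", "b"))
  expect_error(ancom_adapted(prof3, c("a", "zz")), "at least 2 samples")
  prof_one <- profiles_from_matrix(mat3, c("a", "a", "a", "b"))
  expect_error(ancom_adapted(prof_one, c("a", "b")), "at least 2 samples")
  expect_error(ancom_adapted(prof3, c("a", "b", "c")), "exactly two")
})

test_that("differential reports are sorted with declared tie-breaks", {
  res <- structure(
    data.frame(lectin = c("zeta", "alpha", "mid", "top"),
               W = c(5L, 5L, 2L, 9L),
               W_max = 9L,
               summary_p = c(0.2, 0.2, 0.01, 0.001),
               significant = c(FALSE, FALSE, FALSE, TRUE),
               stringsAsFactors = FALSE),
    class = c("lectin_differential", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- report_differential(res, f)
  expect_equal(out$lectin, c("top", "alpha", "zeta", "mid"))
  ondisk <- utils::read.delim(f)
  expect_equal(ondisk$lectin, c("top", "alpha", "zeta", "mid"))
  expect_equal(names(ondisk),
               c("lectin", "W", "W_max", "summary_p", "significant"))
})

test_that("differential_config validates its fields", {
  expect_error(differential_config(pseudocount = 0), "pseudocount")
  expect_error(differential_config(alpha = 1), "alpha")
  expect_error(differential_config(w_fraction = 0), "w_fraction")
  expect_error(differential_config(test = "anova"), "arg")
})
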
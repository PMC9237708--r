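# build a distances data.frame of the shape scoreSubjects() returns
mkDistances <- function(total, ids = sprintf("s%03d", seq_along(total))) {
  data.frame(subject_id = ids,
             fc_euclidean = total / 4, fc_mahalanobis = total / 4,
             sc_euclidean = total / 4, sc_mahalanobis = total / 4,
             fc_distance = total / 2, sc_distance = total / 2,
             total = total, stringsAsFactors = FALSE)
}

mkManifest <- function(engel, ids, exclude = FALSE) {
  data.frame(subject_id = ids, group = "left_out",
             age = 40, seizure_side = "left", engel_1yr = engel,
             exclude_from_group_stats = exclude, stringsAsFactors = FALSE)
}

test_that("an extreme group separation is detected in every pairwise test", {
  set.seed(61)
  engel <- rep(c("Ia", "Ib-d", "II", "III-IV"), each = 8)
  tot <- rnorm(32, 10, 1) + ifelse(engel == "III-IV", 10, 0)
  d <- mkDistances(tot)
  oc <- compareOutcomes(d, mkManifest(engel, d$subject_id))
  expect_lt(oc$total$kw_p, 0.01)
  pw <- oc$total$pairwise
  hitsUnfav <- pw$group_a == "III-IV" | pw$group_b == "III-IV"
  expect_true(all(pw$significant_at_0.05[hitsUnfav]))
  expect_true(all(pw$p_bonferroni >= pw$rank_sum_p_raw))
  expect_true(all(pw$p_bonferroni <= 1))
  expect_named(oc, c("total", "fc", "sc", "euclidean", "mahalanobis"))
})

test_that("excluded subjects are dropped and emptied groups are an error", {
  set.seed(62)
  engel <- rep(c("Ia", "Ib-d", "II", "III-IV"), each = 5)
  d <- mkDistances(rnorm(20, 10))
  mf <- mkManifest(engel, d$subject_id)
  mf$exclude_from_group_stats[mf$engel_1yr == "II"][1] <- TRUE
  oc <- compareOutcomes(d, mf)
  # manual check: statistic computed without the excluded subject
  keep <- !mf$exclude_from_group_stats
  kw <- kruskal.test(d$total[keep], factor(engel[keep]))
  expect_equal(oc$total$kw_statistic, unname(kw$statistic))
  mfAll <- mkManifest(engel, d$subject_id)
  mfAll$exclude_from_group_stats[mfAll$engel_1yr == "II"] <- TRUE
  expect_error(compareOutcomes(d, mfAll), "emptied")
})

test_that("null Kruskal-Wallis p-values are uniform over replicates", {
  set.seed(63)
  ps <- replicate(200, {
    d <- mkDistances(rnorm(40, 10, 2))
    engel <- sample(rep(c("Ia", "Ib-d", "II", "III-IV"), each = 10))
    compareOutcomes(d, mkManifest(engel, d$subject_id))$total$kw_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("ROC handles perfect separation, a null, and matches pair counting", {
  d <- c(1, 2, 3, 10, 11)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  r <- rocUnfavourable(d, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$sens_at_optimal, 1)
  expect_equal(r$spec_at_optimal, 1)
  set.seed(64)
  rn <- rocUnfavourable(rnorm(200), rep(c(TRUE, FALSE), 100))
  expect_gt(rn$auc, 0.4); expect_lt(rn$auc, 0.6)
  # hand-built overlap with a tie
  x <- c(1, 2, 3, 4, 3, 5, 6, 7)
  l <- c(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(rocUnfavourable(x, l)$auc, bruteAUC(x, l), tolerance = 1e-9)
  set.seed(65)
  for (i in 1:20) {
    x <- sample(1:6, 30, replace = TRUE) + rnorm(30, 0, 1e-6)
    l <- rbinom(30, 1, 0.4) == 1
    if (length(unique(l)) < 2) next
    expect_equal(rocUnfavourable(x, l)$auc, bruteAUC(x, l),
                 tolerance = 1e-9)
  }
  expect_error(rocUnfavourable(d, rep(TRUE, 5)), "both")
})

test_that("Youden tie-break prefers the higher-specificity operating point", {
  # two thresholds reach the same J; the reported one has higher specificity
  x <- c(1, 2, 3, 4)
  l <- c(FALSE, TRUE, FALSE, TRUE)
  r <- rocUnfavourable(x, l)
  j <- r$sensitivities + r$specificities - 1
  expect_equal(r$sens_at_optimal + r$spec_at_optimal - 1, max(j))
  expect_equal(r$spec_at_optimal,
               max(r$specificities[j == max(j)]))
})

test_that("permutation rank sums stay within analytic bounds and reproduce", {
  co <- quickCohort(66)
  run <- fingerprintPipeline(co, seed = 660, nBoot = 6)
  mf <- co$manifest
  model <- mf$subject_id[mf$group == "model"]
  lo <- mf$subject_id[mf$group == "left_out"]
  unf <- mf$engel_1yr[match(lo, mf$subject_id)] == "III-IV"
  args <- list(lapply(run$oriented[model], `[[`, "fc"),
               lapply(run$oriented[model], `[[`, "sc"),
               lapply(run$oriented[lo], `[[`, "fc"),
               lapply(run$oriented[lo], `[[`, "sc"),
               unf, co$atlas)
  pt <- do.call(nodePermutationTest,
                c(args, nIter = 50, k = 10, seed = 9, nBoot = 6))
  u <- sum(unf); n <- length(unf)
  lower <- u * (u + 1) / 2
  upper <- sum((n - u + 1):n)
  expect_true(all(pt$null_rank_sums >= lower & pt$null_rank_sums <= upper))
  expect_gte(pt$observed_rank_sum, lower)
  expect_lte(pt$observed_rank_sum, upper)
  expect_gt(pt$p_upper, 0); expect_lte(pt$p_upper, 1)
  expect_equal(pt$n_exceeding, sum(pt$null_rank_sums > pt$observed_rank_sum))
  pt2 <- do.call(nodePermutationTest,
                 c(args, nIter = 50, k = 10, seed = 9, nBoot = 6))
  expect_identical(pt$null_rank_sums, pt2$null_rank_sums)
  expect_identical(pt$observed_rank_sum, pt2$observed_rank_sum)
  expect_error(do.call(nodePermutationTest, c(args, k = 1000)), "exceeds")
})

test_that("fast permutation profiles agree with the reference reduction", {
  co <- quickCohort(67)
  run <- fingerprintPipeline(co, seed = 670, nBoot = 6)
  a <- co$atlas
  sub <- run$oriented[[1]]
  noi <- noiIds(a)
  A <- tleFingerprint:::.stackIpsi(list(sub$fc), a)
  L <- tleFingerprint:::.lobeOperator(a)
  nIpsi <- length(tleFingerprint:::.ipsiIds(a))
  hemi <- tleFingerprint:::.hemi(a)
  w <- ifelse(hemi[noi] == "left", 2, 1)
  fast <- tleFingerprint:::.fastProfiles(A, L, nIpsi, match(noi, nodeIds(a)),
                                         w)
  slow <- lobeAverage(weightedDegree(sub$fc, a, noi), a)
  expect_equal(unname(drop(fast)), unname(slow), tolerance = 1e-10)
})

test_that("clinical associations flag planted signals and reject constants", {
  set.seed(68)
  n <- 60
  tot <- rnorm(n, 10, 2)
  d <- mkDistances(tot)
  P <- matrix(rnorm(n * 12), n,
              dimnames = list(d$subject_id, tleFingerprint:::.MEASURES))
  mf <- mkManifest(rep("Ia", n), d$subject_id)
  mf$corr_cov <- tot + rnorm(n, 0, 0.5)       # planted correlation
  mf$noise_cov <- rnorm(n)                     # independent
  mf$flag_cov <- as.integer(P[, "sc_temporal"] > 0)  # planted binary cell
  ca <- clinicalAssociations(d, P, mf,
                             c("corr_cov", "noise_cov", "flag_cov"))
  tt <- ca$total
  expect_true(tt$significant[tt$covariate == "corr_cov"])
  expect_gt(tt$statistic[tt$covariate == "corr_cov"], 0)
  expect_true(ca$measures$significant_unc_0.05["sc_temporal", "flag_cov"])
  expect_gt(ca$measures$direction["sc_temporal", "flag_cov"], 0)
  mf$const_cov <- 1
  expect_error(clinicalAssociations(d, P, mf, "const_cov"), "constant")
})

test_that("the covariate screen keeps its corrected type-I rate near nominal", {
  set.seed(69)
  hits <- replicate(200, {
    n <- 30
    d <- mkDistances(rnorm(n, 10, 2))
    P <- matrix(rnorm(n * 12), n,
                dimnames = list(d$subject_id, tleFingerprint:::.MEASURES))
    mf <- mkManifest(rep("Ia", n), d$subject_id)
    mf$c1 <- rnorm(n); mf$c2 <- rnorm(n); mf$c3 <- rbinom(n, 1, 0.5)
    any(clinicalAssociations(d, P, mf, c("c1", "c2", "c3"))$total$significant)
  })
  expect_lte(mean(hits), 0.10)  # familywise alpha 0.05 plus binomial slack
})
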
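mkModelSet <- function(atlas, n = 9, seed = 51, f = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    if (is.null(f)) list(fc = randomConn(atlas, paste0("m", i), "FC"),
                         sc = randomConn(atlas, paste0("m", i), "SC"))
    else f(i)
  })
}

test_that("bootstrap expansion of 9 model subjects yields 40 connectome pairs", {
  a <- smallAtlas(7)
  ms <- mkModelSet(a)
  exp40 <- bootstrapExpand(lapply(ms, `[[`, "fc"), lapply(ms, `[[`, "sc"),
                           seed = 99)
  expect_length(exp40, 40)
  expect_true(all(vapply(exp40, function(p)
    modality(p$fc) == "FC" && modality(p$sc) == "SC", TRUE)))
  expect_error(bootstrapExpand(list(ms[[1]]$fc), list(ms[[1]]$sc)),
               "at least 2")
  expect_error(bootstrapExpand(lapply(ms, `[[`, "fc"),
                               lapply(ms, `[[`, "sc"), sampleSize = 1),
               "sampleSize")
})

test_that("zero spread collapses every subsample onto the shared connectome", {
  a <- smallAtlas(7)
  set.seed(52)
  shared <- randomConn(a, "m", "FC")
  sharedSc <- randomConn(a, "m", "SC")
  ex <- bootstrapExpand(rep(list(shared), 4), rep(list(sharedSc), 4),
                        nBoot = 2, nSub = 2, seed = 1)
  for (p in ex) {
    expect_equal(connMatrix(p$fc), connMatrix(shared), tolerance = 1e-12)
    expect_equal(connMatrix(p$sc), connMatrix(sharedSc), tolerance = 1e-12)
  }
})

test_that("every expanded edge lies within the sample mean +/- 4 SD bounds", {
  a <- smallAtlas(7)
  # 3 distinct subjects, sampleSize 2: enumerate all possible samples and
  # check each subsample is consistent with at least one of them
  ms <- mkModelSet(a, n = 3, seed = 53)
  Vfc <- sapply(ms, function(p)
    connMatrix(p$fc)[upper.tri(connMatrix(p$fc))])
  ex <- bootstrapExpand(lapply(ms, `[[`, "fc"), lapply(ms, `[[`, "sc"),
                        nBoot = 5, sampleSize = 2, nSub = 3, sdBound = 4,
                        seed = 7)
  samples <- expand.grid(1:3, 1:3)
  okForSample <- function(v, take) {
    S <- Vfc[, unlist(take), drop = FALSE]
    m <- rowMeans(S)
    s <- apply(S, 1, sd)
    all(v >= m - 4 * s - 1e-9 & v <= m + 4 * s + 1e-9)
  }
  for (p in ex) {
    v <- connMatrix(p$fc)[upper.tri(connMatrix(p$fc))]
    ok <- any(apply(samples, 1, function(tk) okForSample(v, tk)))
    expect_true(ok)
  }
})

test_that("fingerprint means equal the stored model profiles' means", {
  a <- smallAtlas(7)
  ms <- mkModelSet(a, seed = 54)
  fp <- fitFingerprint(lapply(ms, `[[`, "fc"), lapply(ms, `[[`, "sc"), a,
                       seed = 3)
  P <- modelProfiles(fp)
  expect_equal(nrow(P), 40)
  expect_equal(unname(colMeans(P[, 1:6])), fp@fcMean, tolerance = 1e-12)
  expect_equal(unname(colMeans(P[, 7:12])), fp@scMean, tolerance = 1e-12)
  expect_equal(fp@fcCov, t(fp@fcCov))
})

test_that("degenerate fingerprints (identical profiles) score zero Mahalanobis", {
  P <- matrix(rep(1:12, each = 40), nrow = 40)
  fp <- fpFromMatrix(P)
  d <- scoreSubject(profileFromVector(1:12 + c(rep(1, 6), rep(0, 6))), fp)
  expect_equal(d@fcMahalanobis, 0)
  expect_equal(d@fcEuclidean, sqrt(6))
})

test_that("distances obey the stated identities", {
  set.seed(55)
  P <- matrix(rnorm(40 * 12), 40)
  fp <- fpFromMatrix(P)
  # profile at the mean scores zero everywhere
  mu <- colMeans(P)
  d0 <- scoreSubject(profileFromVector(mu), fp)
  expect_equal(d0@total, 0, tolerance = 1e-9)
  # Pythagorean identity on random subjects
  for (i in 1:10) {
    d <- scoreSubject(profileFromVector(rnorm(12)), fp)
    expect_equal(d@total^2, d@fcDistance^2 + d@scDistance^2,
                 tolerance = 1e-9)
    expect_equal(d@fcDistance, d@fcEuclidean + d@fcMahalanobis)
  }
  # fc_distance = 3 and sc_distance = 4 give total 5 (identity covariance:
  # Mahalanobis equals Euclidean, so each modality distance is 2x Euclid)
  fpI <- fp
  fpI@fcCov <- diag(6); fpI@scCov <- diag(6)
  fpI@fcMean <- rep(0, 6); fpI@scMean <- rep(0, 6)
  d5 <- scoreSubject(profileFromVector(c(1.5, rep(0, 5), 2, rep(0, 5))), fpI)
  expect_equal(d5@fcDistance, 3)
  expect_equal(d5@scDistance, 4)
  expect_equal(d5@total, 5)
})

test_that("Mahalanobis distance matches the quadratic-form oracle", {
  set.seed(56)
  P <- matrix(rnorm(40 * 12), 40)
  fp <- fpFromMatrix(P)
  for (i in 1:20) {
    p <- rnorm(12)
    d <- scoreSubject(profileFromVector(p), fp)
    expect_equal(d@fcMahalanobis,
                 bruteMahalanobis(p[1:6], colMeans(P[, 1:6]),
                                  cov(P[, 1:6])), tolerance = 1e-8)
    expect_equal(d@scEuclidean, sqrt(sum((p[7:12] - colMeans(P[, 7:12]))^2)),
                 tolerance = 1e-12)
  }
})

test_that("Mahalanobis is invariant under invertible linear reparameterization", {
  set.seed(57)
  P <- matrix(rnorm(40 * 12), 40)
  for (i in 1:10) {
    A <- matrix(rnorm(36), 6)
    while (abs(det(A)) < 1e-3) A <- matrix(rnorm(36), 6)
    p <- rnorm(12)
    d1 <- scoreSubject(profileFromVector(p), fpFromMatrix(P))
    P2 <- cbind(P[, 1:6] %*% t(A), P[, 7:12])
    p2 <- c(A %*% p[1:6], p[7:12])
    d2 <- scoreSubject(profileFromVector(p2), fpFromMatrix(P2))
    expect_equal(d1@fcMahalanobis, d2@fcMahalanobis, tolerance = 1e-8)
  }
})

test_that("Euclidean distance scales linearly and total is monotone", {
  set.seed(58)
  P <- matrix(rnorm(40 * 12), 40)
  fp0 <- fpFromMatrix(P)
  fp0@fcMean <- rep(0, 6); fp0@scMean <- rep(0, 6)
  p <- rnorm(12)
  d1 <- scoreSubject(profileFromVector(p), fp0)
  d3 <- scoreSubject(profileFromVector(3 * p), fp0)
  expect_equal(d3@fcEuclidean, 3 * d1@fcEuclidean, tolerance = 1e-10)
  expect_gte(d3@total, d1@total)
})

test_that("expansion and scoring are bit-reproducible under a fixed seed", {
  a <- smallAtlas(7)
  ms <- mkModelSet(a, seed = 59)
  fcs <- lapply(ms, `[[`, "fc"); scs <- lapply(ms, `[[`, "sc")
  e1 <- bootstrapExpand(fcs, scs, seed = 123)
  e2 <- bootstrapExpand(fcs, scs, seed = 123)
  for (i in seq_along(e1))
    expect_identical(connMatrix(e1[[i]]$fc), connMatrix(e2[[i]]$fc))
  fp1 <- fitFingerprint(fcs, scs, a, seed = 123)
  fp2 <- fitFingerprint(fcs, scs, a, seed = 123)
  expect_identical(modelProfiles(fp1), modelProfiles(fp2))
})

test_that("fingerprints serialize with provenance intact", {
  a <- smallAtlas(7)
  ms <- mkModelSet(a, seed = 60)
  fp <- fitFingerprint(lapply(ms, `[[`, "fc"), lapply(ms, `[[`, "sc"), a,
                       seed = 17)
  f <- tempfile(fileext = ".json")
  writeFingerprint(fp, f)
  back <- readFingerprint(f)
  expect_equal(modelProfiles(back), modelProfiles(fp))
  expect_equal(back@fcCov, fp@fcCov)
  expect_equal(provenance(back)$seed, 17)
  expect_equal(provenance(back)$n_boot, 10)
  expect_equal(provenance(back)$sample_size, 6)
})
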
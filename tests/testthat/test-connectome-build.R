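test_that("partial-correlation FC matches the residualization oracle", {
  set.seed(31)
  tp <- 50
  conf <- matrix(rnorm(tp), ncol = 1)
  series <- matrix(rnorm(tp * 3), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  series <- series + conf %*% matrix(c(0.5, -0.8, 0.3), nrow = 1)
  got <- connMatrix(timeseriesToFC(series, conf))
  oracle <- brutePartialFC(series, conf)
  expect_lt(max(abs(got - unname(oracle))), 1e-10)
})

test_that("orthogonal series give z = 0 and duplicates hit the clip bound", {
  s <- cbind(a = c(1, -1, 1, -1, 1, -1), b = c(1, 1, -1, -1, 1, -1))
  s[, 2] <- s[, 2] - s[, 1] * sum(s[, 1] * s[, 2]) / sum(s[, 1]^2)
  expect_equal(connMatrix(timeseriesToFC(s))["a", "b"], 0, tolerance = 1e-12)
  set.seed(32)
  dup <- matrix(rnorm(20), ncol = 1)
  z <- connMatrix(timeseriesToFC(cbind(a = dup[, 1], b = dup[, 1])))
  expect_true(is.finite(z["a", "b"]))
  expect_equal(z["a", "b"], atanh(1 - 1e-12))
})

test_that("degenerate time-series inputs are rejected", {
  set.seed(33)
  s <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  conf <- cbind(rnorm(20), rnorm(20))
  expect_error(timeseriesToFC(s[1:4, ], conf[1:4, ]), "time points")
  expect_error(timeseriesToFC(s, cbind(conf[, 1], conf[, 1])),
               "rank deficient")
  s0 <- s; s0[, 2] <- 0
  expect_error(timeseriesToFC(s0), "constant-zero")
})

test_that("SC volume scaling is counts / (v_i * v_j)", {
  a <- toyAtlas(names = c("x", "x"), hemispheres = c("left", "right"),
                lobes = c("temporal", "temporal"), isNoi = c(TRUE, TRUE),
                volumes = c(10, 20))
  counts <- matrix(c(0, 1000, 1000, 0), 2)
  sc <- countsToSC(counts, a)
  expect_equal(connMatrix(sc)["L_x", "R_x"], 5)  # 1000 / (10 * 20)
  expect_equal(connMatrix(countsToSC(matrix(0, 2, 2), a)),
               connMatrix(sc) * 0)
  # doubling both volumes quarters every incident edge
  a2 <- toyAtlas(names = c("x", "x"), hemispheres = c("left", "right"),
                 lobes = c("temporal", "temporal"), isNoi = c(TRUE, TRUE),
                 volumes = c(20, 40))
  expect_equal(connMatrix(countsToSC(counts, a2))["L_x", "R_x"], 5 / 4)
  expect_error(countsToSC(-counts, a), "negative")
})

test_that("edge norms recover planted slopes and noise at n = 200", {
  a <- smallAtlas(8)
  ids <- nodeIds(a)
  nE <- length(ids) * (length(ids) - 1) / 2
  set.seed(34)
  n <- 200
  ages <- runif(n, 18, 71)
  b0 <- rnorm(nE, 0.2, 0.3)
  b1 <- rnorm(nE, 0, 0.01)
  sigma <- 0.2
  conns <- lapply(seq_len(n), function(i) {
    e <- b0 + b1 * ages[i] + rnorm(nE, 0, sigma)
    new("Connectome", subjectId = paste0("c", i), modality = "FC",
        space = "anatomical", unitsTag = "raw",
        matrix = tleFingerprint:::.edgesToMatrix(e, length(ids), ids))
  })
  fit <- fitEdgeNorms(conns, ages, "FC")
  se <- fit@rmse / sqrt(sum((ages - mean(ages))^2))
  expect_gte(mean(abs(fit@slope - b1) / se < 3), 0.97)
  expect_lt(abs(median(fit@rmse) - sigma) / sigma, 0.1)
  # age-permuted controls lose the age signal
  fitPerm <- fitEdgeNorms(conns, sample(ages), "FC")
  expect_lt(median(abs(fitPerm@slope)), median(abs(fit@slope)))
})

test_that("degenerate normative fits are errors", {
  a <- smallAtlas(8)
  ids <- nodeIds(a)
  nE <- length(ids) * (length(ids) - 1) / 2
  mk <- function(age, noise = TRUE) {
    e <- 0.1 + 0.01 * age + if (noise) rnorm(nE, 0, 0.1) else 0
    new("Connectome", subjectId = "c", modality = "FC",
        space = "anatomical", unitsTag = "raw",
        matrix = tleFingerprint:::.edgesToMatrix(e, length(ids), ids))
  }
  set.seed(35)
  expect_error(fitEdgeNorms(list(mk(20), mk(30)), c(20, 30), "FC"),
               "at least 3")
  expect_error(fitEdgeNorms(list(mk(20), mk(20), mk(20)), c(20, 20, 20),
                            "FC"), "identical")
  # noise-free linear edges -> zero residual variance
  expect_error(fitEdgeNorms(list(mk(20, FALSE), mk(30, FALSE),
                                 mk(40, FALSE), mk(50, FALSE)),
                            c(20, 30, 40, 50), "FC"), "zero residual")
})

test_that("normative correction maps the regression line to 0 and +1 RMSE to 1", {
  a <- smallAtlas(8)
  ids <- nodeIds(a)
  nE <- length(ids) * (length(ids) - 1) / 2
  set.seed(36)
  ages <- runif(30, 20, 60)
  b0 <- rnorm(nE, 0, 0.3); b1 <- rnorm(nE, 0, 0.01)
  conns <- lapply(seq_along(ages), function(i)
    new("Connectome", subjectId = paste0("c", i), modality = "FC",
        space = "anatomical", unitsTag = "raw",
        matrix = tleFingerprint:::.edgesToMatrix(
          b0 + b1 * ages[i] + rnorm(nE, 0, 0.2), length(ids), ids)))
  fit <- fitEdgeNorms(conns, ages, "FC")
  age0 <- 41.5
  onLine <- tleFingerprint:::.edgesToMatrix(
    fit@intercept + fit@slope * age0, length(ids), ids)
  pat <- new("Connectome", subjectId = "p", modality = "FC",
             space = "anatomical", unitsTag = "raw", matrix = onLine)
  expect_equal(max(abs(connMatrix(applyNorm(pat, age0, fit)))), 0,
               tolerance = 1e-12)
  oneUp <- tleFingerprint:::.edgesToMatrix(
    fit@intercept + fit@slope * age0 + fit@rmse, length(ids), ids)
  pat1 <- new("Connectome", subjectId = "p", modality = "FC",
              space = "anatomical", unitsTag = "raw", matrix = oneUp)
  z <- connMatrix(applyNorm(pat1, age0, fit))
  expect_equal(unname(z[upper.tri(z)]), rep(1, nE), tolerance = 1e-10)
})

test_that("normative correction is invariant to affine rescaling (identity transform)", {
  a <- smallAtlas(7)
  ids <- nodeIds(a)
  nE <- length(ids) * (length(ids) - 1) / 2
  set.seed(37)
  ages <- runif(20, 20, 60)
  mkc <- function(e) new("Connectome", subjectId = "s", modality = "FC",
                         space = "anatomical", unitsTag = "raw",
                         matrix = tleFingerprint:::.edgesToMatrix(
                           e, length(ids), ids))
  edges <- lapply(seq_along(ages), function(i) rnorm(nE, 0.2, 0.5))
  patE <- rnorm(nE, 0.2, 0.5)
  z1 <- connMatrix(applyNorm(mkc(patE), 40,
                             fitEdgeNorms(lapply(edges, mkc), ages, "FC")))
  scale <- 3.7; shift <- -1.2
  z2 <- connMatrix(applyNorm(
    mkc(scale * patE + shift), 40,
    fitEdgeNorms(lapply(edges, function(e) mkc(scale * e + shift)),
                 ages, "FC")))
  expect_equal(z1, z2, tolerance = 1e-8)
})

test_that("edge-norm models serialize and restore exactly", {
  a <- smallAtlas(7)
  ids <- nodeIds(a)
  nE <- length(ids) * (length(ids) - 1) / 2
  set.seed(38)
  ages <- runif(10, 20, 60)
  conns <- lapply(seq_along(ages), function(i)
    new("Connectome", subjectId = paste0("c", i), modality = "SC",
        space = "anatomical", unitsTag = "raw",
        matrix = tleFingerprint:::.edgesToMatrix(
          exp(rnorm(nE, 2, 0.5)), length(ids), ids)))
  fit <- fitEdgeNorms(conns, ages, "SC")
  expect_equal(fit@transform, "log1p")
  f <- tempfile(fileext = ".tsv")
  writeEdgeNormModel(fit, f)
  back <- readEdgeNormModel(f)
  expect_identical(back@intercept, fit@intercept)
  expect_identical(back@slope, fit@slope)
  expect_identical(back@rmse, fit@rmse)
  expect_identical(back@nodeIds, fit@nodeIds)
  expect_equal(back@nControls, fit@nControls)
})
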
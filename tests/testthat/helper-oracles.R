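# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive loops / direct formulas so they share no code with
# the implementation they check.

# ---- fixture builders ------------------------------------------------------

# hand-built atlas from parallel vectors; homologues paired by shared `name`
toyAtlas <- function(names, hemispheres, lobes, isNoi, volumes = NULL) {
  n <- length(names)
  if (is.null(volumes)) volumes <- seq(1000, 2000, length.out = n)
  pre <- ifelse(hemispheres == "left", "L_",
                ifelse(hemispheres == "right", "R_", "M_"))
  id <- paste0(pre, names)
  hom <- ifelse(hemispheres == "midline", NA_character_,
                paste0(ifelse(hemispheres == "left", "R_", "L_"), names))
  new("Atlas", nodes = data.frame(
    node_id = id, name = names, hemisphere = hemispheres, lobe = lobes,
    homologue_id = hom, is_noi = isNoi, volume_mm3 = volumes,
    stringsAsFactors = FALSE))
}

# a small paired atlas covering all six lobes (via makeFixtureAtlas)
smallAtlas <- function(nPerHemisphere = 10) makeFixtureAtlas(nPerHemisphere)

# random symmetric connectome on an atlas
randomConn <- function(atlas, subjectId = "s1", modality = "FC",
                       space = "focus_oriented", units = "normative_sd",
                       sd = 1) {
  ids <- nodeIds(atlas)
  n <- length(ids)
  m <- matrix(rnorm(n * n, sd = sd), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (modality == "SC" && units == "raw") m <- abs(m)
  dimnames(m) <- list(ids, ids)
  new("Connectome", subjectId = subjectId, modality = modality,
      space = space, unitsTag = units, matrix = m)
}

# Fingerprint built directly from a profile matrix (rows = profiles)
fpFromMatrix <- function(P) {
  colnames(P) <- c(paste0("fc_", tleFingerprint:::.LOBES),
                   paste0("sc_", tleFingerprint:::.LOBES))
  new("Fingerprint", modelProfiles = P,
      fcMean = unname(colMeans(P[, 1:6])), fcCov = unname(cov(P[, 1:6])),
      scMean = unname(colMeans(P[, 7:12])), scCov = unname(cov(P[, 7:12])),
      provenance = list())
}

profileFromVector <- function(v, id = "p") {
  lb <- tleFingerprint:::.LOBES
  new("ConnectivityProfile", subjectId = id,
      fc = setNames(v[1:6], lb), sc = setNames(v[7:12], lb))
}

# ---- oracles ---------------------------------------------------------------

# exhaustive weighted degree: double loop over ipsilateral nodes and NOI
bruteWeightedDegree <- function(m, atlas, noi, wIpsi = 2, wContra = 1) {
  nd <- atlas@nodes
  ipsi <- nd$node_id[nd$hemisphere == "left"]
  out <- setNames(numeric(length(ipsi)), ipsi)
  for (i in ipsi) {
    acc <- 0
    for (j in noi) {
      if (j == i) next
      w <- if (nd$hemisphere[nd$node_id == j] == "left") wIpsi else wContra
      acc <- acc + w * m[i, j]
    }
    out[i] <- acc
  }
  out
}

bruteLobeAverage <- function(wdeg, atlas) {
  nd <- atlas@nodes
  sapply(tleFingerprint:::.LOBES, function(lb) {
    mem <- intersect(names(wdeg), nd$node_id[nd$lobe == lb])
    mean(wdeg[mem])
  })
}

# partial correlation by explicit per-pair residualization with lm()
brutePartialFC <- function(series, confounds = NULL) {
  n <- ncol(series)
  z <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is.null(confounds)) {
        r <- cor(series[, i], series[, j])
      } else {
        ri <- residuals(lm(series[, i] ~ confounds))
        rj <- residuals(lm(series[, j] ~ confounds))
        r <- cor(ri, rj)
      }
      r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
      z[i, j] <- z[j, i] <- atanh(r)
    }
  }
  z
}

bruteMahalanobis <- function(p, mu, S) sqrt(drop(t(p - mu) %*% solve(S) %*% (p - mu)))

# AUC by pair counting (ties count half)
bruteAUC <- function(x, labels) {
  pos <- x[labels]
  neg <- x[!labels]
  cnt <- 0
  for (p in pos) for (q in neg)
    cnt <- cnt + (p > q) + 0.5 * (p == q)
  cnt / (length(pos) * length(neg))
}

# small synthetic cohort for pipeline-level tests
quickCohort <- function(seed, ..., outlier = list()) {
  simulateCohort(simulationConfig(
    seed = seed, nControls = 25, nModel = 6, nTest = 0, nLeftOut = 16,
    nPerHemisphere = 12, outlier = outlier, ...))
}
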
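# fingerprint: bootstrap expansion of the seizure-free model group and
# dual-distance (Euclidean + Mahalanobis) scoring.

#' Bootstrap-expand the model group's connectomes
#'
#' Draws \code{nBoot} bootstrap samples (with replacement, size
#' \code{sampleSize}) from the model subjects. For each sample, the
#' per-edge mean \eqn{m} and standard deviation \eqn{s} across the sampled
#' connectomes are computed, and \code{nSub} subsample connectomes are
#' emitted with edge values \eqn{m + u s}, the multiplier \eqn{u} drawn
#' per edge and per subsample uniformly on \eqn{[-sdBound, +sdBound]}
#' ("mean +/- up to \code{sdBound} times the standard deviation of each
#' edge"). FC and SC share the subject sample within a bootstrap but use
#' independent multiplier draws. With the defaults (10 samples of six, four
#' subsamples) nine model subjects yield 40 connectomes per modality.
#'
#' @param fcConns,scConns parallel lists of the model subjects' FC and SC
#'   \linkS4class{Connectome}s (focus-oriented, normative-SD units).
#' @param nBoot number of bootstrap samples (default 10).
#' @param sampleSize subjects per sample, drawn with replacement (default 6).
#' @param nSub subsample connectomes per sample (default 4).
#' @param sdBound multiplier bound in per-edge SDs (default 4).
#' @param seed integer seed making the expansion fully reproducible;
#'   \code{NULL} uses the current RNG stream.
#' @return list of length \code{nBoot * nSub}; each element a list with
#'   elements \code{fc} and \code{sc}.
#' @export
bootstrapExpand <- function(fcConns, scConns, nBoot = 10, sampleSize = 6,
                            nSub = 4, sdBound = 4, seed = NULL) {
  n <- length(fcConns)
  if (n < 2) .stopf("need at least 2 model subjects, got %d", n)
  if (length(scConns) != n) .stopf("fcConns and scConns must be parallel")
  if (sampleSize < 2) .stopf("sampleSize must be at least 2")
  if (nBoot < 1 || nSub < 1 || sdBound <= 0)
    .stopf("nBoot, nSub must be positive and sdBound > 0")
  ids <- nodeIds(fcConns[[1]])
  nE <- length(ids) * (length(ids) - 1) / 2
  edgeMat <- function(conns)
    t(vapply(conns, function(cn) .matrixToEdges(connMatrix(cn)),
             numeric(nE)))
  Vfc <- edgeMat(fcConns)
  Vsc <- edgeMat(scConns)
  proto <- function(which) if (which == "fc") fcConns[[1]] else scConns[[1]]
  .withSeed(seed, {
    out <- vector("list", nBoot * nSub)
    pos <- 0L
    for (b in seq_len(nBoot)) {
      take <- sample.int(n, sampleSize, replace = TRUE)
      stats <- lapply(list(fc = Vfc, sc = Vsc), function(V) {
        S <- V[take, , drop = FALSE]
        m <- colMeans(S)
        s <- sqrt(colSums(sweep(S, 2, m)^2) / (sampleSize - 1))
        list(m = m, s = s)
      })
      for (k in seq_len(nSub)) {
        pos <- pos + 1L
        sid <- sprintf("boot%02d_sub%d", b, k)
        pair <- lapply(c(fc = "fc", sc = "sc"), function(w) {
          u <- stats::runif(nE, -sdBound, sdBound)
          v <- stats[[w]]$m + u * stats[[w]]$s
          p <- proto(w)
          .mkConn(sid, modality(p), .edgesToMatrix(v, length(ids), ids),
                  connSpace(p), unitsTag(p))
        })
        out[[pos]] <- pair
      }
    }
    out
  })
}

#' Build the fingerprint from expanded model connectomes
#'
#' Reduces every expanded connectome pair to its 12-measure profile and
#' stores, per modality, the mean 6-vector and the 6x6 sample covariance of
#' the model profiles, which later drive Euclidean and Mahalanobis scoring.
#'
#' @param expanded output of [bootstrapExpand()].
#' @param atlas the \linkS4class{Atlas}.
#' @param noiIds node-of-interest ids (default: atlas NOI flags).
#' @param wIpsi,wContra NOI weights, default 2:1.
#' @param provenance optional named list merged into the provenance block.
#' @return a \linkS4class{Fingerprint}.
#' @export
buildFingerprint <- function(expanded, atlas, noiIds = NULL,
                             wIpsi = 2, wContra = 1, provenance = list()) {
  profiles <- lapply(expanded, function(pair)
    buildProfile(pair$fc, pair$sc, atlas, noiIds, wIpsi, wContra))
  P <- profilesToMatrix(profiles)
  fc <- P[, 1:6, drop = FALSE]
  sc <- P[, 7:12, drop = FALSE]
  prov <- utils::modifyList(
    list(n_profiles = nrow(P), w_ipsi = wIpsi, w_contra = wContra), provenance)
  methods::new("Fingerprint", modelProfiles = P,
               fcMean = unname(colMeans(fc)), fcCov = unname(stats::cov(fc)),
               scMean = unname(colMeans(sc)), scCov = unname(stats::cov(sc)),
               provenance = prov)
}

#' Fit a fingerprint directly from the model subjects
#'
#' Convenience wrapper: [bootstrapExpand()] then [buildFingerprint()].
#'
#' @inheritParams bootstrapExpand
#' @inheritParams buildFingerprint
#' @return a \linkS4class{Fingerprint}.
#' @export
fitFingerprint <- function(fcConns, scConns, atlas, noiIds = NULL,
                           wIpsi = 2, wContra = 1, nBoot = 10,
                           sampleSize = 6, nSub = 4, sdBound = 4,
                           seed = NULL) {
  expanded <- bootstrapExpand(fcConns, scConns, nBoot, sampleSize, nSub,
                              sdBound, seed)
  buildFingerprint(expanded, atlas, noiIds, wIpsi, wContra,
                   provenance = list(
                     n_model_subjects = length(fcConns), n_boot = nBoot,
                     sample_size = sampleSize, n_sub_per_sample = nSub,
                     sd_multiplier_bound = sdBound,
                     seed = if (is.null(seed)) NA else seed))
}

# Pseudo-inverse of a profile covariance: eigenvalues below
# 1e-10 * trace/p are treated as null directions (degenerate fingerprints,
# e.g. 40 identical profiles, then contribute zero Mahalanobis distance).
.covPinv <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  floor <- 1e-10 * sum(diag(S)) / nrow(S)
  keep <- e$values > max(floor, 0)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

.modalityDistances <- function(p, mu, S) {
  d <- p - mu
  eu <- sqrt(sum(d^2))
  ma <- sqrt(max(0, sum(d * (.covPinv(S) %*% d))))
  c(euclidean = eu, mahalanobis = ma)
}

#' Score a subject's profile against the fingerprint
#'
#' Per modality, the Euclidean distance of the 6-vector to the fingerprint
#' mean and the Mahalanobis distance
#' \eqn{\sqrt{(p-\mu)^\top \Sigma^{-1} (p-\mu)}} with \eqn{\Sigma} the
#' model-profile covariance (pseudo-inverse with an eigenvalue floor of
#' 1e-10 x trace/6 guards degenerate covariances). The modality distance is
#' Euclidean + Mahalanobis, and the total distance the Pythagorean
#' combination \eqn{\sqrt{fc^2 + sc^2}} of the two modality distances.
#'
#' @param profile a \linkS4class{ConnectivityProfile}.
#' @param fingerprint a \linkS4class{Fingerprint}.
#' @return a \linkS4class{DistanceResult}.
#' @export
scoreSubject <- function(profile, fingerprint) {
  v <- profileMeasures(profile)
  if (any(!is.finite(v))) .stopf("non-finite profile")
  fc <- .modalityDistances(v[1:6], fingerprint@fcMean, fingerprint@fcCov)
  sc <- .modalityDistances(v[7:12], fingerprint@scMean, fingerprint@scCov)
  fcD <- sum(fc)
  scD <- sum(sc)
  methods::new("DistanceResult", subjectId = subjectId(profile),
               fcEuclidean = unname(fc[1]), fcMahalanobis = unname(fc[2]),
               scEuclidean = unname(sc[1]), scMahalanobis = unname(sc[2]),
               fcDistance = fcD, scDistance = scD,
               total = sqrt(fcD^2 + scD^2))
}

#' Score many subjects and tabulate the distances
#'
#' @param profiles list of \linkS4class{ConnectivityProfile}.
#' @param fingerprint a \linkS4class{Fingerprint}.
#' @return data.frame with one row per subject and columns
#'   \code{subject_id}, \code{fc_euclidean}, \code{fc_mahalanobis},
#'   \code{sc_euclidean}, \code{sc_mahalanobis}, \code{fc_distance},
#'   \code{sc_distance}, \code{total}.
#' @export
scoreSubjects <- function(profiles, fingerprint) {
  do.call(rbind, lapply(profiles, function(p)
    as.data.frame(scoreSubject(p, fingerprint))))
}

#' Serialize and restore a fingerprint
#'
#' One structured JSON file holding the provenance block, the expanded
#' profile table, the two mean 6-vectors and the two 6x6 covariances.
#'
#' @param fingerprint a \linkS4class{Fingerprint}.
#' @param path file path.
#' @return \code{writeFingerprint}: \code{path} invisibly;
#'   \code{readFingerprint}: the restored \linkS4class{Fingerprint}.
#' @export
writeFingerprint <- function(fingerprint, path) {
  obj <- list(provenance = fingerprint@provenance,
              profile_ids = rownames(fingerprint@modelProfiles),
              model_profiles = unname(fingerprint@modelProfiles),
              fc_mean = fingerprint@fcMean, fc_cov = fingerprint@fcCov,
              sc_mean = fingerprint@scMean, sc_cov = fingerprint@scCov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeFingerprint
#' @export
readFingerprint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- obj$model_profiles
  dimnames(P) <- list(obj$profile_ids, .MEASURES)
  methods::new("Fingerprint", modelProfiles = P,
               fcMean = obj$fc_mean, fcCov = obj$fc_cov,
               scMean = obj$sc_mean, scCov = obj$sc_cov,
               provenance = as.list(obj$provenance))
}
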
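# End-to-end convenience: cohort -> norms -> focus-oriented normative
# connectomes -> fingerprint -> distances.

#' Run the full fingerprint pipeline on a cohort
#'
#' Fits the per-edge age-normative models on the control group, expresses
#' every patient's FC and SC connectome in standard deviations from
#' age-matched control, converts them to the seizure-focus-oriented frame,
#' builds the fingerprint from the model group by bootstrap expansion, and
#' scores every patient's profile against it.
#'
#' @param cohort a \code{SimulatedCohort} from [simulateCohort()], or any
#'   list with elements \code{atlas}, \code{manifest}, \code{fc}, \code{sc}
#'   (named lists of raw anatomical \linkS4class{Connectome}s).
#' @param noiIds node-of-interest ids (default: atlas flags).
#' @param wIpsi,wContra NOI weights, default 2:1.
#' @param nBoot,sampleSize,nSub,sdBound bootstrap-expansion parameters.
#' @param seed seed for the bootstrap expansion.
#' @return list of class \code{FingerprintRun}: \code{fingerprint};
#'   \code{normModels} (FC and SC \linkS4class{EdgeNormModel}s);
#'   \code{oriented} (per-patient focus-oriented normative connectomes);
#'   \code{profiles} (list of \linkS4class{ConnectivityProfile});
#'   \code{distances} (data.frame from [scoreSubjects()] merged with the
#'   manifest's group, outcome and exclusion columns).
#' @export
fingerprintPipeline <- function(cohort, noiIds = NULL, wIpsi = 2,
                                wContra = 1, nBoot = 10, sampleSize = 6,
                                nSub = 4, sdBound = 4, seed = NULL) {
  atlas <- cohort$atlas
  mf <- cohort$manifest
  ctl <- mf$subject_id[mf$group == "control"]
  if (length(ctl) < 3) .stopf("need at least 3 controls")
  ages <- stats::setNames(mf$age, mf$subject_id)
  fcNorm <- fitEdgeNorms(cohort$fc[ctl], ages[ctl], "FC")
  scNorm <- fitEdgeNorms(cohort$sc[ctl], ages[ctl], "SC")
  pats <- mf$subject_id[mf$group != "control"]
  sides <- stats::setNames(mf$seizure_side, mf$subject_id)
  oriented <- lapply(stats::setNames(pats, pats), function(id) {
    list(fc = toFocusOriented(applyNorm(cohort$fc[[id]], ages[id], fcNorm),
                              sides[id], atlas),
         sc = toFocusOriented(applyNorm(cohort$sc[[id]], ages[id], scNorm),
                              sides[id], atlas))
  })
  model <- mf$subject_id[mf$group == "model"]
  fingerprint <- fitFingerprint(
    lapply(oriented[model], `[[`, "fc"),
    lapply(oriented[model], `[[`, "sc"),
    atlas, noiIds, wIpsi, wContra, nBoot, sampleSize, nSub, sdBound, seed)
  profiles <- lapply(oriented, function(pair)
    buildProfile(pair$fc, pair$sc, atlas, noiIds, wIpsi, wContra))
  distances <- scoreSubjects(profiles, fingerprint)
  distances <- cbind(distances,
                     mf[match(distances$subject_id, mf$subject_id),
                        c("group", "engel_1yr", "seizure_side",
                          "exclude_from_group_stats")])
  rownames(distances) <- NULL
  structure(list(fingerprint = fingerprint,
                 normModels = list(fc = fcNorm, sc = scNorm),
                 oriented = oriented, profiles = profiles,
                 distances = distances),
            class = "FingerprintRun")
}

#' @export
print.FingerprintRun <- function(x, ...) {
  d <- x$distances
  cat(sprintf("FingerprintRun: %d patients scored\n", nrow(d)))
  agg <- stats::aggregate(total ~ group + engel_1yr, d, stats::median)
  cat("median total distance by group/outcome:\n")
  print(agg, row.names = FALSE, digits = 3)
  invisible(x)
}
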
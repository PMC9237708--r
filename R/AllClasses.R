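#' @import methods
NULL

#' Atlas: the node table underlying every connectome
#'
#' An \code{Atlas} holds the parcellation used to index connectome matrices:
#' one row per node with its hemisphere, lobe membership, homologue pairing
#' across hemispheres, node-of-interest (NOI) flag and volume. The full
#' default atlas has 117 nodes (56 per hemisphere, one midline brainstem, and
#' anterior/posterior hippocampal composites per hemisphere) of which 14 are
#' flagged as nodes of interest: bilateral middle cingulate gyrus, precuneus,
#' thalamus, anterior and posterior insula, and anterior and posterior
#' hippocampus.
#'
#' Validity enforces: unique node ids; hemisphere in \code{left}, \code{right},
#' \code{midline}; every non-midline node assigned to one of the six lobes
#' (prefrontal, parietal, occipital, temporal, motor_somatosensory,
#' subcortical) and paired with a homologue in the opposite hemisphere by a
#' symmetric bijection; midline nodes have lobe \code{"none"} and no
#' homologue; volumes strictly positive.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{name},
#'   \code{hemisphere}, \code{lobe}, \code{homologue_id}, \code{is_noi},
#'   \code{volume_mm3}.
#'
#' @seealso [loadAtlas()], [makeFixtureAtlas()]
#' @exportClass Atlas
setClass("Atlas", representation(nodes = "data.frame"))

.validAtlas <- function(object) {
  nd <- object@nodes
  req <- c("node_id", "name", "hemisphere", "lobe", "homologue_id",
           "is_noi", "volume_mm3")
  miss <- setdiff(req, names(nd))
  if (length(miss)) return(paste("missing atlas columns:",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(nd$node_id))
    return(paste("duplicate node_id:",
                 paste(unique(nd$node_id[duplicated(nd$node_id)]),
                       collapse = ", ")))
  if (!all(nd$hemisphere %in% .HEMIS))
    return("hemisphere must be one of left, right, midline")
  lateral <- nd$hemisphere != "midline"
  bad <- lateral & !(nd$lobe %in% .LOBES)
  if (any(bad))
    return(paste("unknown lobe label for node(s):",
                 paste(nd$node_id[bad], collapse = ", ")))
  if (any(!lateral & nd$lobe != "none"))
    return("midline nodes must have lobe 'none'")
  if (!is.logical(nd$is_noi) || anyNA(nd$is_noi))
    return("is_noi must be TRUE/FALSE")
  if (!is.numeric(nd$volume_mm3) || anyNA(nd$volume_mm3) ||
      any(nd$volume_mm3 <= 0))
    return("volume_mm3 must be positive")
  # homologue pairing: symmetric bijection between hemispheres
  hom <- nd$homologue_id
  if (any(lateral & (is.na(hom) | hom == "")))
    return(paste("missing homologue for lateral node(s):",
                 paste(nd$node_id[lateral & (is.na(hom) | hom == "")],
                       collapse = ", ")))
  if (any(!lateral & !is.na(hom) & hom != ""))
    return("midline nodes must not have a homologue")
  idx <- match(hom[lateral], nd$node_id)
  if (anyNA(idx))
    return("homologue_id refers to unknown node")
  self <- which(lateral)
  opp <- c(left = "right", right = "left")
  if (any(nd$hemisphere[idx] != opp[nd$hemisphere[self]]))
    return("homologue must lie in the opposite hemisphere")
  back <- match(nd$homologue_id[idx], nd$node_id)
  if (any(back != self))
    return("homologue pairing is not symmetric")
  TRUE
}
setValidity("Atlas", .validAtlas)

#' Connectome: one subject's symmetric connectivity matrix
#'
#' A square symmetric matrix of edge values indexed in atlas node order,
#' tagged with its modality (\code{FC}: Fisher-z partial correlations;
#' \code{SC}: volume-scaled streamline counts), its spatial frame
#' (\code{anatomical} left/right, or \code{focus_oriented} where the
#' left-hemisphere slots hold the hemisphere ipsilateral to the seizure
#' focus) and its units (\code{raw}, or \code{normative_sd} after
#' age-normative correction, i.e. standard deviations from age-matched
#' control). The diagonal is ignored by all downstream operations; a
#' 117-node connectome has 6786 unique off-diagonal edges.
#'
#' @slot subjectId character scalar.
#' @slot modality \code{"FC"} or \code{"SC"}.
#' @slot space \code{"anatomical"} or \code{"focus_oriented"}.
#' @slot unitsTag \code{"raw"} or \code{"normative_sd"}.
#' @slot matrix symmetric numeric matrix with node-id dimnames.
#'
#' @seealso [readConnectome()], [toFocusOriented()], [applyNorm()]
#' @exportClass Connectome
setClass("Connectome", representation(
  subjectId = "character", modality = "character", space = "character",
  unitsTag = "character", matrix = "matrix"))

.validConnectome <- function(object) {
  m <- object@matrix
  if (!object@modality %in% c("FC", "SC")) return("modality must be FC or SC")
  if (!object@space %in% c("anatomical", "focus_oriented"))
    return("space must be anatomical or focus_oriented")
  if (!object@unitsTag %in% c("raw", "normative_sd"))
    return("unitsTag must be raw or normative_sd")
  if (!is.numeric(m) || nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    return("matrix must carry identical node-id row/column names")
  if (anyNA(m)) return("matrix contains missing values")
  if (max(abs(m - t(m))) > 1e-8 * max(abs(m), 1))
    return("matrix is not symmetric")
  if (object@modality == "SC" && object@unitsTag == "raw" && any(m < 0))
    return("raw SC values must be nonnegative")
  TRUE
}
setValidity("Connectome", .validConnectome)

#' Age-normative edge model
#'
#' Per-edge ordinary least squares fit of edge value on age across a healthy
#' control cohort, with the residual RMSE (df = n - 2) of each fit. Applying
#' the model expresses a subject's edges in standard deviations from
#' age-matched control. SC edges are fit after a log(x + 1) transform of the
#' volume-scaled values (tagged \code{"log1p"}); FC edges are fit on the
#' Fisher-z scale directly (\code{"identity"}).
#'
#' @slot modality \code{"FC"} or \code{"SC"}.
#' @slot transform \code{"identity"} (FC) or \code{"log1p"} (SC).
#' @slot nodeIds atlas node order the edge vectors refer to.
#' @slot intercept,slope,rmse numeric vectors, one entry per unique edge in
#'   upper-triangle order; \code{rmse} strictly positive.
#' @slot nControls number of controls used in the fit.
#'
#' @seealso [fitEdgeNorms()], [applyNorm()]
#' @exportClass EdgeNormModel
setClass("EdgeNormModel", representation(
  modality = "character", transform = "character", nodeIds = "character",
  intercept = "numeric", slope = "numeric", rmse = "numeric",
  nControls = "integer"))

.validEdgeNormModel <- function(object) {
  nE <- length(object@nodeIds) * (length(object@nodeIds) - 1) / 2
  if (length(object@intercept) != nE || length(object@slope) != nE ||
      length(object@rmse) != nE)
    return("coefficient vectors must have one entry per unique edge")
  if (any(!is.finite(object@rmse)) || any(object@rmse <= 0))
    return("rmse must be positive for every edge")
  ok <- (object@modality == "SC") == (object@transform == "log1p")
  if (!ok) return("transform must be log1p for SC and identity for FC")
  TRUE
}
setValidity("EdgeNormModel", .validEdgeNormModel)

#' Connectivity profile: 12 lobe-averaged weighted-degree measures
#'
#' The reduction of one subject's focus-oriented, age-normalized FC and SC
#' connectomes: the 2:1 ipsilateral:contralateral weighted degree over the
#' nodes of interest, averaged over the six ipsilateral lobes, per modality.
#' Units are standard deviations from age-matched control; zero is the
#' age-matched-control reference.
#'
#' @slot subjectId character scalar.
#' @slot fc,sc named numeric vectors of length 6 in lobe order prefrontal,
#'   parietal, occipital, temporal, motor_somatosensory, subcortical.
#'
#' @seealso [buildProfile()], [weightedDegree()], [lobeAverage()]
#' @exportClass ConnectivityProfile
setClass("ConnectivityProfile", representation(
  subjectId = "character", fc = "numeric", sc = "numeric"))

.validProfile <- function(object) {
  if (length(object@fc) != 6 || length(object@sc) != 6)
    return("fc and sc must each hold 6 lobe values")
  if (!identical(names(object@fc), .LOBES) ||
      !identical(names(object@sc), .LOBES))
    return("lobe values must be named in canonical lobe order")
  if (any(!is.finite(object@fc)) || any(!is.finite(object@sc)))
    return("profile values must be finite")
  TRUE
}
setValidity("ConnectivityProfile", .validProfile)

#' TLE fingerprint: bootstrap-expanded model profiles with mean and covariance
#'
#' The fingerprint of the seizure-free model group: the profiles of the
#' bootstrap-expanded model connectomes (by default 10 samples of six
#' subjects, four subsample connectomes each, hence 40 profiles), plus the
#' per-modality mean 6-vector and 6x6 sample covariance used for Euclidean
#' and Mahalanobis scoring.
#'
#' @slot modelProfiles numeric matrix, one row per expanded profile, 12
#'   columns named \code{fc_<lobe>}, \code{sc_<lobe>}.
#' @slot fcMean,scMean numeric length-6 means.
#' @slot fcCov,scCov 6x6 symmetric covariance matrices.
#' @slot provenance list recording how the expansion was made
#'   (\code{n_model_subjects}, \code{n_boot}, \code{sample_size},
#'   \code{n_sub_per_sample}, \code{sd_multiplier_bound}, \code{seed}).
#'
#' @seealso [fitFingerprint()], [scoreSubject()]
#' @exportClass Fingerprint
setClass("Fingerprint", representation(
  modelProfiles = "matrix", fcMean = "numeric", fcCov = "matrix",
  scMean = "numeric", scCov = "matrix", provenance = "list"))

.validFingerprint <- function(object) {
  if (ncol(object@modelProfiles) != 12 ||
      !identical(colnames(object@modelProfiles), .MEASURES))
    return("modelProfiles must have the 12 canonical measure columns")
  for (nm in c("fcCov", "scCov")) {
    cv <- slot(object, nm)
    if (!all(dim(cv) == c(6, 6)) || max(abs(cv - t(cv))) > 1e-8)
      return(paste(nm, "must be a symmetric 6x6 matrix"))
  }
  if (length(object@fcMean) != 6 || length(object@scMean) != 6)
    return("means must have length 6")
  TRUE
}
setValidity("Fingerprint", .validFingerprint)

#' Distance of one subject's profile from the fingerprint
#'
#' Per modality, the Euclidean distance of the 6-vector to the fingerprint
#' mean plus the Mahalanobis distance with respect to the model-profile
#' covariance; the modality distance is their sum, and the total distance is
#' the Pythagorean combination sqrt(fc^2 + sc^2) of the two modality
#' distances. Units follow the profile: standard deviations from
#' age-matched control.
#'
#' @slot subjectId character scalar.
#' @slot fcEuclidean,fcMahalanobis,scEuclidean,scMahalanobis,fcDistance,scDistance,total
#'   nonnegative numeric scalars.
#'
#' @seealso [scoreSubject()], [scoreSubjects()]
#' @exportClass DistanceResult
setClass("DistanceResult", representation(
  subjectId = "character", fcEuclidean = "numeric", fcMahalanobis = "numeric",
  scEuclidean = "numeric", scMahalanobis = "numeric", fcDistance = "numeric",
  scDistance = "numeric", total = "numeric"))

.validDistanceResult <- function(object) {
  v <- c(object@fcEuclidean, object@fcMahalanobis, object@scEuclidean,
         object@scMahalanobis, object@fcDistance, object@scDistance,
         object@total)
  if (any(!is.finite(v)) || any(v < 0)) return("distances must be nonnegative")
  if (abs(object@fcDistance - (object@fcEuclidean + object@fcMahalanobis)) >
      1e-9 * max(1, object@fcDistance))
    return("fcDistance must equal fcEuclidean + fcMahalanobis")
  if (abs(object@scDistance - (object@scEuclidean + object@scMahalanobis)) >
      1e-9 * max(1, object@scDistance))
    return("scDistance must equal scEuclidean + scMahalanobis")
  if (abs(object@total^2 - (object@fcDistance^2 + object@scDistance^2)) >
      1e-9 * max(1, object@total^2))
    return("total^2 must equal fcDistance^2 + scDistance^2")
  TRUE
}
setValidity("DistanceResult", .validDistanceResult)

#' Configuration of the synthetic cohort generator
#'
#' Holds every knob of the cohort simulator: group sizes mirroring the study
#' design (85 controls; 9 seizure-free model patients; 5 test patients; 38
#' left-out patients), the age range, the per-edge generative models for FC
#' (linear age effect plus Gaussian noise on the Fisher-z scale) and SC
#' (linear age effect plus Gaussian noise on the log1p scale of
#' volume-scaled streamline weights), the shared mild deviation of all
#' patients from controls, and the outlier specification for unfavourable
#' (Engel III-IV) patients: which of the 12 profile measures deviate and by
#' how many normative standard deviations.
#'
#' Use [simulationConfig()] to construct one.
#'
#' @slot seed integer RNG seed the whole cohort derives from.
#' @slot nControls,nModel,nTest,nLeftOut group sizes.
#' @slot ageRange length-2 numeric, years.
#' @slot fc list(baselineMean, baselineSd, slopeSd, noiseSd) on the Fisher-z
#'   scale; per-edge intercepts ~ N(baselineMean, baselineSd), age slopes
#'   ~ N(0, slopeSd) per year.
#' @slot sc list(logBaselineMean, logBaselineSd, slopeSd, noiseSd) on the
#'   log1p volume-scaled scale.
#' @slot outlier list(fractionUnfavourable, affectedMeasures, effectSize,
#'   dominanceScale); the dominant modality's affected measures are scaled
#'   by \code{dominanceScale}, the other modality's by
#'   \code{2 - dominanceScale} (1 = uniform effects).
#' @slot commonEffectSize shared deviation (normative SD) of every patient's
#'   12 measures from the control reference.
#' @slot nPerHemisphere,includeHippocampalComposites atlas size controls.
#' @slot volumeRange node volume range, mm^3.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  seed = "integer", nControls = "integer", nModel = "integer",
  nTest = "integer", nLeftOut = "integer", ageRange = "numeric",
  fc = "list", sc = "list", outlier = "list", commonEffectSize = "numeric",
  nPerHemisphere = "integer", includeHippocampalComposites = "logical",
  volumeRange = "numeric"))

.validSimulationConfig <- function(object) {
  if (any(c(object@nControls, object@nModel, object@nTest,
            object@nLeftOut) < 0)) return("group sizes must be nonnegative")
  if (object@nControls < 3) return("need at least 3 controls to fit norms")
  if (length(object@ageRange) != 2 || diff(object@ageRange) <= 0)
    return("ageRange must be an increasing pair")
  o <- object@outlier
  if (o$effectSize < 0) return("effect size must be nonnegative")
  if (!all(o$affectedMeasures %in% .MEASURES))
    return("affectedMeasures must be a subset of the 12 profile measures")
  if (o$fractionUnfavourable < 0 || o$fractionUnfavourable > 1)
    return("fractionUnfavourable must lie in [0, 1]")
  if (o$dominanceScale < 0 || o$dominanceScale > 2)
    return("dominanceScale must lie in [0, 2]")
  TRUE
}
setValidity("SimulationConfig", .validSimulationConfig)
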
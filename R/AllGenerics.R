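#' @include AllClasses.R
NULL

#' Accessors for atlas, connectome, profile and fingerprint objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{nodeIds} and \code{nNodes} give the atlas node order and count;
#' \code{noiIds} the node-of-interest ids; \code{subjectId},
#' \code{modality}, \code{connSpace}, \code{unitsTag} and
#' \code{connMatrix} the connectome tags and matrix;
#' \code{profileMeasures} the named 12-vector of a profile;
#' \code{modelProfiles} the fingerprint's expanded profile matrix; and
#' \code{provenance} its expansion metadata.
#'
#' @param x an \linkS4class{Atlas}, \linkS4class{Connectome},
#'   \linkS4class{ConnectivityProfile} or \linkS4class{Fingerprint}.
#' @return See the individual generic descriptions.
#' @name accessors
#' @aliases nodeIds nNodes noiIds subjectId modality connSpace unitsTag
#'   connMatrix profileMeasures modelProfiles provenance
#' @examples
#' atlas <- makeFixtureAtlas(nPerHemisphere = 10)
#' nNodes(atlas)
#' length(noiIds(atlas))
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("noiIds", function(x) standardGeneric("noiIds"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("connSpace", function(x) standardGeneric("connSpace"))
#' @rdname accessors
#' @export
setGeneric("unitsTag", function(x) standardGeneric("unitsTag"))
#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))
#' @rdname accessors
#' @export
setGeneric("profileMeasures", function(x) standardGeneric("profileMeasures"))
#' @rdname accessors
#' @export
setGeneric("modelProfiles", function(x) standardGeneric("modelProfiles"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
setMethod("nodeIds", "Atlas", function(x) x@nodes$node_id)
#' @rdname accessors
setMethod("nNodes", "Atlas", function(x) nrow(x@nodes))
#' @rdname accessors
setMethod("noiIds", "Atlas", function(x) x@nodes$node_id[x@nodes$is_noi])
#' @rdname accessors
setMethod("nodeIds", "Connectome", function(x) rownames(x@matrix))
#' @rdname accessors
setMethod("nNodes", "Connectome", function(x) nrow(x@matrix))
#' @rdname accessors
setMethod("subjectId", "Connectome", function(x) x@subjectId)
#' @rdname accessors
setMethod("modality", "Connectome", function(x) x@modality)
#' @rdname accessors
setMethod("connSpace", "Connectome", function(x) x@space)
#' @rdname accessors
setMethod("unitsTag", "Connectome", function(x) x@unitsTag)
#' @rdname accessors
setMethod("connMatrix", "Connectome", function(x) x@matrix)
#' @rdname accessors
setMethod("subjectId", "ConnectivityProfile", function(x) x@subjectId)
#' @rdname accessors
setMethod("profileMeasures", "ConnectivityProfile", function(x) {
  out <- c(x@fc, x@sc)
  names(out) <- .MEASURES
  out
})
#' @rdname accessors
setMethod("modelProfiles", "Fingerprint", function(x) x@modelProfiles)
#' @rdname accessors
setMethod("provenance", "Fingerprint", function(x) x@provenance)
#' @rdname accessors
setMethod("subjectId", "DistanceResult", function(x) x@subjectId)

# atlas lookup helpers (internal)
.hemi <- function(atlas) {
  structure(atlas@nodes$hemisphere, names = atlas@nodes$node_id)
}
.lobe <- function(atlas) {
  structure(atlas@nodes$lobe, names = atlas@nodes$node_id)
}
.volumes <- function(atlas) {
  structure(atlas@nodes$volume_mm3, names = atlas@nodes$node_id)
}
.homologues <- function(atlas) {
  structure(atlas@nodes$homologue_id, names = atlas@nodes$node_id)
}
# ipsilateral node ids: in the focus-oriented frame these occupy the
# left-hemisphere slots; midline is never ipsilateral.
.ipsiIds <- function(atlas) atlas@nodes$node_id[atlas@nodes$hemisphere == "left"]

setMethod("show", "Atlas", function(object) {
  nd <- object@nodes
  cat(sprintf("Atlas with %d nodes (%d left, %d right, %d midline), %d NOI\n",
              nrow(nd), sum(nd$hemisphere == "left"),
              sum(nd$hemisphere == "right"), sum(nd$hemisphere == "midline"),
              sum(nd$is_noi)))
  tab <- table(factor(nd$lobe[nd$hemisphere == "left"], levels = .LOBES))
  cat("  lobes (per hemisphere): ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "Connectome", function(object) {
  cat(sprintf("Connectome '%s': %s, %s space, %s units, %d nodes (%d edges)\n",
              object@subjectId, object@modality, object@space,
              object@unitsTag, nrow(object@matrix),
              nrow(object@matrix) * (nrow(object@matrix) - 1) / 2))
})

setMethod("show", "EdgeNormModel", function(object) {
  cat(sprintf(
    "EdgeNormModel (%s, transform=%s): %d edges fit on %d controls\n",
    object@modality, object@transform, length(object@rmse),
    object@nControls))
})

setMethod("show", "ConnectivityProfile", function(object) {
  cat(sprintf("ConnectivityProfile '%s' (normative SD units)\n",
              object@subjectId))
  print(round(rbind(fc = object@fc, sc = object@sc), 3))
})

setMethod("show", "Fingerprint", function(object) {
  p <- object@provenance
  cat(sprintf("Fingerprint: %d model profiles x 12 measures\n",
              nrow(object@modelProfiles)))
  if (length(p))
    cat(sprintf(
      "  expansion: %s model subjects, %s boots x %s subsamples, bound %s SD\n",
      p$n_model_subjects, p$n_boot, p$n_sub_per_sample,
      p$sd_multiplier_bound))
})

setMethod("show", "DistanceResult", function(object) {
  cat(sprintf("DistanceResult '%s': total %.3f (fc %.3f = %.3f+%.3f, sc %.3f = %.3f+%.3f)\n",
              object@subjectId, object@total, object@fcDistance,
              object@fcEuclidean, object@fcMahalanobis, object@scDistance,
              object@scEuclidean, object@scMahalanobis))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: seed %d; controls/model/test/left-out = %d/%d/%d/%d; ages %g-%g\n",
    object@seed, object@nControls, object@nModel, object@nTest,
    object@nLeftOut, object@ageRange[1], object@ageRange[2]))
  cat(sprintf("  outlier: %.0f%% unfavourable, effect %.2g SD on %s\n",
              100 * object@outlier$fractionUnfavourable,
              object@outlier$effectSize,
              paste(object@outlier$affectedMeasures, collapse = ", ")))
})

#' @describeIn scoreSubject coerce a \linkS4class{DistanceResult} to a
#'   one-row data.frame with the six distance columns.
#' @param x a \code{DistanceResult}.
#' @param row.names,optional,... passed on as in
#'   \code{\link[base]{as.data.frame}}.
#' @export
as.data.frame.DistanceResult <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(subject_id = x@subjectId,
             fc_euclidean = x@fcEuclidean, fc_mahalanobis = x@fcMahalanobis,
             sc_euclidean = x@scEuclidean, sc_mahalanobis = x@scMahalanobis,
             fc_distance = x@fcDistance, sc_distance = x@scDistance,
             total = x@total, stringsAsFactors = FALSE)
}
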
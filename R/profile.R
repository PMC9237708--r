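# profile_reduction: focus-oriented, age-normalized connectome -> 6
# lobe-averaged weighted-degree values per modality (12 measures total).

#' Weighted degree over the nodes of interest
#'
#' For each ipsilateral node \eqn{i} (the left-hemisphere slots of a
#' focus-oriented connectome; midline excluded), sums the edges from
#' \eqn{i} to the node-of-interest set with ipsilateral NOI weighted
#' \code{wIpsi} (default 2) and contralateral NOI weighted \code{wContra}
#' (default 1):
#' \deqn{wdeg(i) = w_{ipsi} \sum_{j \in NOI_{ipsi}, j \ne i} C(i,j) +
#'       w_{contra} \sum_{j \in NOI_{contra}} C(i,j).}
#' The diagonal never contributes. A midline node in \code{noiIds} (possible
#' when random node sets are drawn) takes the contralateral weight.
#'
#' @param conn a focus-oriented \linkS4class{Connectome}.
#' @param atlas the \linkS4class{Atlas}.
#' @param noiIds node-of-interest ids; defaults to the atlas NOI flags.
#' @param wIpsi,wContra weights for ipsilateral / contralateral NOI.
#' @return named numeric vector of weighted degrees over ipsilateral nodes.
#' @export
weightedDegree <- function(conn, atlas, noiIds = NULL,
                           wIpsi = 2, wContra = 1) {
  if (is.null(noiIds)) noiIds <- noiIds(atlas)
  if (length(noiIds) == 0) .stopf("empty node-of-interest set")
  ids <- nodeIds(atlas)
  unknown <- setdiff(noiIds, ids)
  if (length(unknown))
    .stopf("NOI id(s) not in atlas: %s", paste(unknown, collapse = ", "))
  if (conn@space != "focus_oriented")
    .stopf("connectome must be focus-oriented (got %s space)", conn@space)
  hemi <- .hemi(atlas)
  ipsi <- .ipsiIds(atlas)
  w <- ifelse(hemi[noiIds] == "left", wIpsi, wContra)
  m <- connMatrix(conn)
  diag(m) <- 0
  wd <- as.vector(m[ipsi, noiIds, drop = FALSE] %*% w)
  names(wd) <- ipsi
  wd
}

#' Average weighted degrees over the six ipsilateral lobes
#'
#' Arithmetic mean of the weighted-degree values over the ipsilateral
#' members of each lobe, in the fixed order prefrontal, parietal,
#' occipital, temporal, motor_somatosensory, subcortical. Midline nodes are
#' excluded; an empty lobe is an error.
#'
#' @param wdeg named vector from [weightedDegree()].
#' @param atlas the \linkS4class{Atlas}.
#' @return named numeric vector of length 6.
#' @export
lobeAverage <- function(wdeg, atlas) {
  lobe <- .lobe(atlas)[names(wdeg)]
  out <- vapply(.LOBES, function(lb) {
    members <- names(wdeg)[lobe == lb]
    if (length(members) == 0) .stopf("lobe '%s' has no ipsilateral node", lb)
    mean(wdeg[members])
  }, numeric(1))
  names(out) <- .LOBES
  out
}

#' Build the 12-measure connectivity profile of a subject
#'
#' Applies [weightedDegree()] then [lobeAverage()] to the subject's FC and
#' SC connectomes and concatenates the two 6-vectors. Both connectomes must
#' be the same subject, focus-oriented, and in normative-SD units; the
#' profile inherits those units, so zero denotes the age-matched-control
#' reference.
#'
#' @param fc,sc the subject's FC and SC \linkS4class{Connectome}s.
#' @param atlas the \linkS4class{Atlas}.
#' @param noiIds node-of-interest ids (default: atlas NOI flags).
#' @param wIpsi,wContra NOI weights, default 2:1.
#' @return a \linkS4class{ConnectivityProfile}.
#' @export
buildProfile <- function(fc, sc, atlas, noiIds = NULL,
                         wIpsi = 2, wContra = 1) {
  if (subjectId(fc) != subjectId(sc))
    .stopf("FC subject '%s' does not match SC subject '%s'",
           subjectId(fc), subjectId(sc))
  if (modality(fc) != "FC" || modality(sc) != "SC")
    .stopf("arguments must be an FC and an SC connectome, in that order")
  for (cn in list(fc, sc))
    if (unitsTag(cn) != "normative_sd")
      .stopf("profiles require normative_sd units (got %s)", unitsTag(cn))
  methods::new("ConnectivityProfile", subjectId = subjectId(fc),
               fc = lobeAverage(weightedDegree(fc, atlas, noiIds,
                                               wIpsi, wContra), atlas),
               sc = lobeAverage(weightedDegree(sc, atlas, noiIds,
                                               wIpsi, wContra), atlas))
}

#' Collect profiles into a subject x measure matrix
#'
#' @param profiles list of \linkS4class{ConnectivityProfile}.
#' @return numeric matrix, one row per subject (rownames = subject ids),
#'   12 columns \code{fc_<lobe>}, \code{sc_<lobe>}.
#' @export
profilesToMatrix <- function(profiles) {
  m <- t(vapply(profiles, profileMeasures, numeric(12)))
  rownames(m) <- vapply(profiles, subjectId, "")
  m
}

#' Export profiles as a comma-delimited table
#'
#' One row per subject: \code{subject_id} plus the 12 named measures.
#'
#' @param profiles list of \linkS4class{ConnectivityProfile} (or the matrix
#'   from [profilesToMatrix()]).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  m <- if (is.matrix(profiles)) profiles else profilesToMatrix(profiles)
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Polar plot of a connectivity profile
#'
#' Draws the 12 measures on a polar plot, FC lobes on the upper half and SC
#' lobes on the lower half, with the dashed unit circle at zero denoting the
#' age-matched-control reference. Optionally overlays the fingerprint mean.
#'
#' @param profile a \linkS4class{ConnectivityProfile}.
#' @param fingerprint optional \linkS4class{Fingerprint} whose mean profile
#'   is overlaid in black.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @return invisibly, the matrix of plotted polar coordinates.
#' @export
plotProfile <- function(profile, fingerprint = NULL, ...) {
  vals <- profileMeasures(profile)
  ang <- pi / 2 + (seq_len(12) - 1) * 2 * pi / 12  # fc on top half
  lim <- max(abs(vals), 1) + 1
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = subjectId(profile), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  ref <- max(abs(vals)) / 2 + 0.5
  graphics::lines(ref * cos(th), ref * sin(th), lty = 2, col = "grey50")
  rad <- vals + ref  # zero maps onto the dashed reference circle
  xy <- cbind(rad * cos(ang), rad * sin(ang))
  graphics::polygon(xy, border = "steelblue", lwd = 2)
  graphics::text(1.05 * lim * cos(ang), 1.05 * lim * sin(ang),
                 names(vals), cex = 0.6)
  if (!is.null(fingerprint)) {
    fv <- c(fingerprint@fcMean, fingerprint@scMean) + ref
    graphics::polygon(cbind(fv * cos(ang), fv * sin(ang)),
                      border = "black", lwd = 1.5)
  }
  invisible(xy)
}
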
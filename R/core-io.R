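# core_model: atlas / connectome / manifest I/O and the focus-orientation
# transform. File dialects: atlas and connectomes are tab-delimited with
# node-id headers; the manifest is comma-delimited. Missing values in a
# connectome file are errors, never zeros.

#' Load an atlas definition table
#'
#' Reads a tab-delimited node table (columns \code{node_id}, \code{name},
#' \code{hemisphere}, \code{lobe}, \code{homologue_id}, \code{is_noi},
#' \code{volume_mm3}) and returns a validated \linkS4class{Atlas}. All
#' structural invariants (unique ids, homologue bijection, lobe labels,
#' positive volumes) are enforced and violations raise with the offending
#' node named.
#'
#' @param path path to the atlas file.
#' @return an \linkS4class{Atlas}.
#' @seealso [makeFixtureAtlas()] to generate one, [writeAtlas()]
#' @export
loadAtlas <- function(path) {
  nd <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  req <- c("node_id", "name", "hemisphere", "lobe", "homologue_id",
           "is_noi", "volume_mm3")
  miss <- setdiff(req, names(nd))
  if (length(miss))
    .stopf("atlas file lacks column(s): %s", paste(miss, collapse = ", "))
  nd$is_noi <- as.logical(nd$is_noi) |
    (nd$is_noi %in% c("1", "yes"))
  nd$is_noi[is.na(nd$is_noi)] <- FALSE
  nd$volume_mm3 <- as.numeric(nd$volume_mm3)
  nd$homologue_id[nd$homologue_id == ""] <- NA_character_
  methods::new("Atlas", nodes = nd[req])
}

#' Write an atlas definition table
#'
#' @param atlas an \linkS4class{Atlas}.
#' @param path output path (tab-delimited).
#' @return \code{path}, invisibly.
#' @export
writeAtlas <- function(atlas, path) {
  nd <- atlas@nodes
  nd$homologue_id[is.na(nd$homologue_id)] <- ""
  nd$is_noi <- ifelse(nd$is_noi, "TRUE", "FALSE")
  nd$volume_mm3 <- .fmt(nd$volume_mm3)
  utils::write.table(nd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectome matrix file
#'
#' Reads a tab-delimited square matrix whose first row and first column are
#' node ids, reorders it to atlas node order (the header may be any
#' permutation of the atlas ids), enforces symmetry within a relative
#' tolerance of 1e-6 (smaller asymmetries are averaged away, larger ones are
#' an error), and tags the result. Missing values are errors that name the
#' offending edge; negative raw SC values are rejected.
#'
#' @param path path to the matrix file.
#' @param atlas the \linkS4class{Atlas} fixing node order.
#' @param modality \code{"FC"} or \code{"SC"}.
#' @param space \code{"anatomical"} (default) or \code{"focus_oriented"}.
#' @param unitsTag \code{"raw"} (default) or \code{"normative_sd"}.
#' @return a \linkS4class{Connectome}.
#' @export
readConnectome <- function(path, atlas, modality,
                           space = "anatomical", unitsTag = "raw") {
  raw <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  ids <- nodeIds(atlas)
  if (nrow(m) != ncol(m) || nrow(m) != length(ids))
    .stopf("connectome dimension %dx%d does not match the %d-node atlas",
           nrow(m), ncol(m), length(ids))
  if (!setequal(rownames(m), ids) || !setequal(colnames(m), ids))
    .stopf("connectome node ids do not match the atlas")
  m <- m[ids, ids]
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    .stopf("missing value at edge %s|%s in %s",
           ids[bad[1]], ids[bad[2]], path)
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6 * max(abs(m), .Machine$double.xmin))
    .stopf("matrix asymmetry %.3g exceeds relative tolerance 1e-6", asym)
  m <- (m + t(m)) / 2
  if (modality == "SC" && unitsTag == "raw" && any(m < 0))
    .stopf("negative raw SC value at edge %s|%s",
           ids[which(m < 0, arr.ind = TRUE)[1, 1]],
           ids[which(m < 0, arr.ind = TRUE)[1, 2]])
  methods::new("Connectome",
               subjectId = sub("_(FC|SC)$", "",
                               tools::file_path_sans_ext(basename(path))),
               modality = modality, space = space, unitsTag = unitsTag,
               matrix = m)
}

#' Write a connectome matrix file
#'
#' Tab-delimited square matrix, first row and first column node ids; values
#' written with 17 significant digits so that read/write round-trips are
#' exact on the binary values.
#'
#' @param conn a \linkS4class{Connectome}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConnectome <- function(conn, path) {
  m <- conn@matrix
  ids <- rownames(m)
  lines <- c(paste(c("node_id", ids), collapse = "\t"),
             vapply(seq_along(ids), function(i)
               paste(c(ids[i], .fmt(m[i, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

# constructor used internally once a matrix is already clean
.mkConn <- function(subjectId, modality, m, space, unitsTag) {
  methods::new("Connectome", subjectId = subjectId, modality = modality,
               space = space, unitsTag = unitsTag, matrix = m)
}

#' Convert a connectome from anatomical to seizure-focus-oriented space
#'
#' Relabels nodes so that the seizure-focus hemisphere is "ipsilateral" and
#' its homologues "contralateral". The left hemisphere is the reference
#' orientation: a left-focus connectome is unchanged up to relabelling,
#' while a right-focus connectome has every homologue pair's rows and
#' columns swapped so that ipsilateral values land in the left-hemisphere
#' slots. Midline nodes are untouched. The transform permutes edge values
#' consistently and is an involution for a fixed side.
#'
#' @param conn an anatomical-space \linkS4class{Connectome}.
#' @param seizureSide \code{"left"} or \code{"right"}.
#' @param atlas the \linkS4class{Atlas} supplying homologue pairing.
#' @return a \linkS4class{Connectome} with \code{space = "focus_oriented"}.
#' @export
toFocusOriented <- function(conn, seizureSide, atlas) {
  if (conn@space != "anatomical")
    .stopf("connectome is already in %s space", conn@space)
  if (!seizureSide %in% c("left", "right"))
    .stopf("seizureSide must be 'left' or 'right', got '%s'", seizureSide)
  ids <- nodeIds(atlas)
  if (!identical(rownames(conn@matrix), ids))
    .stopf("connectome node order does not match the atlas")
  m <- conn@matrix
  if (seizureSide == "right") {
    hom <- .homologues(atlas)
    perm <- ifelse(is.na(hom), ids, hom)
    perm <- match(perm, ids)
    m <- m[perm, perm]
    dimnames(m) <- list(ids, ids)
  }
  .mkConn(conn@subjectId, conn@modality, m, "focus_oriented", conn@unitsTag)
}

#' Read and write a cohort manifest
#'
#' The manifest is a comma-delimited table with one row per subject:
#' \code{subject_id}, \code{group} (control, model, test, left_out),
#' \code{age}, \code{seizure_side} (left, right, none), \code{engel_1yr}
#' (Ia, Ib-d, II, III-IV, none), \code{exclude_from_group_stats}, plus any
#' clinical covariate columns (continuous or binary). Controls must have no
#' seizure side and no outcome; every patient must have a side.
#'
#' @param path path to the manifest CSV.
#' @return \code{readManifest}: a data.frame; \code{writeManifest}:
#'   \code{path} invisibly.
#' @export
readManifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  .checkManifest(mf)
  mf
}

#' @rdname readManifest
#' @param manifest the manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  .checkManifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.checkManifest <- function(mf) {
  req <- c("subject_id", "group", "age", "seizure_side", "engel_1yr",
           "exclude_from_group_stats")
  miss <- setdiff(req, names(mf))
  if (length(miss))
    .stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(mf$subject_id))
    .stopf("duplicate subject_id in manifest")
  if (!all(mf$group %in% c("control", "model", "test", "left_out")))
    .stopf("unknown group label in manifest")
  ctrl <- mf$group == "control"
  if (any(mf$seizure_side[ctrl] != "none") ||
      any(mf$engel_1yr[ctrl] != "none"))
    .stopf("controls must have seizure_side and engel_1yr 'none'")
  if (any(!mf$seizure_side[!ctrl] %in% c("left", "right")))
    .stopf("every patient needs a seizure side")
  invisible(TRUE)
}
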
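# connectome_build: raw FC from nodal time series, raw SC from streamline
# counts, and the age-normative per-edge correction that expresses edges in
# standard deviations from age-matched control.

#' Functional connectome from nodal time series
#'
#' Computes, for each pair of nodes, the partial Pearson correlation of the
#' two nodal time series controlling jointly for all confound columns
#' (residualize both series on an intercept plus the confounds, then Pearson
#' on the residuals), and Fisher-z transforms it with \code{atanh}. To keep
#' degenerate pairs finite, correlations are clipped to
#' \eqn{\pm(1 - 10^{-12})} before the transform. The diagonal is zero.
#'
#' @param series time x node numeric matrix; column names are node ids.
#' @param confounds optional time x k confound matrix (e.g. six motion
#'   parameters and a mean white-matter series); must have full column rank.
#' @param subjectId subject identifier for the returned connectome.
#' @return a raw, anatomical-space FC \linkS4class{Connectome}.
#' @export
timeseriesToFC <- function(series, confounds = NULL, subjectId = "subject") {
  series <- as.matrix(series)
  if (is.null(colnames(series)))
    colnames(series) <- sprintf("node%03d", seq_len(ncol(series)))
  k <- if (is.null(confounds)) 0L else ncol(confounds)
  if (!is.null(confounds) && nrow(confounds) != nrow(series))
    .stopf("series and confounds must have the same number of time points")
  if (nrow(series) < k + 3)
    .stopf("need at least k+3 = %d time points, got %d", k + 3, nrow(series))
  zero <- apply(series, 2, function(x) all(x == 0))
  if (any(zero))
    .stopf("constant-zero node series: %s",
           paste(colnames(series)[zero], collapse = ", "))
  X <- if (is.null(confounds)) matrix(1, nrow(series), 1)
       else cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    .stopf("confound matrix is rank deficient")
  res <- series - X %*% qr.coef(qrX, series)
  sds <- sqrt(colSums(res^2))
  if (any(sds == 0))
    .stopf("zero-variance residual series for node(s): %s",
           paste(colnames(series)[sds == 0], collapse = ", "))
  r <- crossprod(sweep(res, 2, sds, "/"))
  clip <- 1 - 1e-12
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  .mkConn(subjectId, "FC", z, "anatomical", "raw")
}

#' Structural connectome from streamline counts
#'
#' Scales the streamline count between each pair of nodes by the inverse of
#' the product of the two node volumes:
#' \eqn{edge(i,j) = counts(i,j) / (v_i \, v_j)}.
#'
#' @param counts symmetric nonnegative node x node count matrix in atlas
#'   node order (node-id dimnames optional; atlas order assumed).
#' @param atlas the \linkS4class{Atlas} supplying node volumes (mm^3).
#' @param subjectId subject identifier.
#' @return a raw, anatomical-space SC \linkS4class{Connectome}.
#' @export
countsToSC <- function(counts, atlas, subjectId = "subject") {
  counts <- as.matrix(counts)
  ids <- nodeIds(atlas)
  if (nrow(counts) != length(ids) || ncol(counts) != length(ids))
    .stopf("counts must be %d x %d to match the atlas",
           length(ids), length(ids))
  if (any(counts < 0)) .stopf("negative streamline count")
  if (max(abs(counts - t(counts))) > 1e-6 * max(counts, 1))
    .stopf("count matrix is not symmetric")
  v <- .volumes(atlas)
  if (any(v <= 0)) .stopf("non-positive node volume")
  m <- (counts + t(counts)) / 2 / outer(v, v)
  dimnames(m) <- list(ids, ids)
  diag(m) <- 0
  .mkConn(subjectId, "SC", m, "anatomical", "raw")
}

# transform applied before fitting / normalisation
.edgeTransform <- function(vals, transform) {
  if (transform == "log1p") {
    if (any(vals < 0)) .stopf("log1p transform needs nonnegative values")
    log1p(vals)
  } else vals
}

#' Fit the age-normative model of every connectome edge
#'
#' For each unique edge, ordinary least squares of edge value on age across
#' the control cohort; the residual RMSE (df = n - 2) of each fit becomes
#' the edge's unit of deviation. SC edges are fit after a log(x + 1)
#' transform of the volume-scaled values, which renders them approximately
#' Gaussian; FC edges are fit on the Fisher-z scale directly.
#'
#' @param conns list of raw \linkS4class{Connectome} objects (controls), all
#'   of \code{modality}, identical node order.
#' @param ages numeric vector of control ages (years), parallel to
#'   \code{conns}; at least 3 controls with at least two distinct ages.
#' @param modality \code{"FC"} or \code{"SC"}.
#' @return an \linkS4class{EdgeNormModel}.
#' @seealso [applyNorm()]
#' @export
fitEdgeNorms <- function(conns, ages, modality) {
  n <- length(conns)
  if (n < 3) .stopf("need at least 3 controls, got %d", n)
  if (length(ages) != n) .stopf("ages must parallel conns")
  if (length(unique(ages)) < 2) .stopf("control ages are identical")
  ids <- nodeIds(conns[[1]])
  for (cn in conns) {
    if (modality(cn) != modality)
      .stopf("connectome modality %s does not match %s", modality(cn),
             modality)
    if (!identical(nodeIds(cn), ids)) .stopf("node order mismatch")
  }
  transform <- if (modality == "SC") "log1p" else "identity"
  Y <- t(vapply(conns, function(cn)
    .edgeTransform(.matrixToEdges(connMatrix(cn)), transform),
    numeric(length(ids) * (length(ids) - 1) / 2)))
  X <- cbind(1, ages)
  B <- solve(crossprod(X), crossprod(X, Y))
  resid <- Y - X %*% B
  rmse <- sqrt(colSums(resid^2) / (n - 2))
  degenerate <- rmse <= 1e-8 * pmax(1, colMeans(abs(Y)))
  if (any(degenerate)) {
    lab <- .edgeLabels(ids)[which(degenerate)[1], ]
    .stopf("zero residual variance at edge %s|%s (degenerate fit)",
           lab[1], lab[2])
  }
  methods::new("EdgeNormModel", modality = modality, transform = transform,
               nodeIds = ids, intercept = unname(B[1, ]),
               slope = unname(B[2, ]), rmse = unname(rmse),
               nControls = as.integer(n))
}

#' Express a connectome in standard deviations from age-matched control
#'
#' Applies an \linkS4class{EdgeNormModel}: per edge,
#' \eqn{z = (t(x) - a - b \cdot age) / rmse} where \eqn{t} is the model's
#' transform (log1p for SC, identity for FC) and \eqn{(a, b, rmse)} the
#' edge's control fit. The result is tagged \code{normative_sd}.
#'
#' @param conn a raw \linkS4class{Connectome} matching the model's modality
#'   and node order.
#' @param age the subject's age, years.
#' @param model the fitted \linkS4class{EdgeNormModel}.
#' @return a \linkS4class{Connectome} with \code{unitsTag = "normative_sd"}.
#' @export
applyNorm <- function(conn, age, model) {
  if (modality(conn) != model@modality)
    .stopf("connectome modality %s does not match model %s",
           modality(conn), model@modality)
  if (!identical(nodeIds(conn), model@nodeIds))
    .stopf("node order does not match the norm model")
  vals <- .edgeTransform(.matrixToEdges(connMatrix(conn)), model@transform)
  z <- (vals - model@intercept - model@slope * age) / model@rmse
  m <- .edgesToMatrix(z, length(model@nodeIds), model@nodeIds)
  .mkConn(conn@subjectId, conn@modality, m, conn@space, "normative_sd")
}

#' Serialize and restore an age-normative edge model
#'
#' One structured text file: a metadata header (lines starting \code{#}),
#' then a tab-delimited edge table (node_i, node_j, intercept, slope, rmse)
#' in upper-triangle order. Values round-trip exactly.
#'
#' @param model an \linkS4class{EdgeNormModel}.
#' @param path file path.
#' @return \code{writeEdgeNormModel}: \code{path} invisibly;
#'   \code{readEdgeNormModel}: the restored model.
#' @export
writeEdgeNormModel <- function(model, path) {
  lab <- .edgeLabels(model@nodeIds)
  head <- c(sprintf("# modality: %s", model@modality),
            sprintf("# transform: %s", model@transform),
            sprintf("# n_controls: %d", model@nControls),
            sprintf("# node_order: %s",
                    paste(model@nodeIds, collapse = ",")),
            "node_i\tnode_j\tintercept\tslope\trmse")
  body <- paste(lab[, 1], lab[, 2], .fmt(model@intercept),
                .fmt(model@slope), .fmt(model@rmse), sep = "\t")
  writeLines(c(head, body), path)
  invisible(path)
}

#' @rdname writeEdgeNormModel
#' @export
readEdgeNormModel <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s: ", key), meta, value = TRUE))
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  methods::new("EdgeNormModel", modality = get("modality"),
               transform = get("transform"),
               nodeIds = strsplit(get("node_order"), ",")[[1]],
               intercept = tab$intercept, slope = tab$slope, rmse = tab$rmse,
               nControls = as.integer(get("n_controls")))
}
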
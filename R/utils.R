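# Internal helpers shared across modules.

# Canonical lobe order used everywhere a 6-vector of lobe values appears.
.LOBES <- c("prefrontal", "parietal", "occipital", "temporal",
            "motor_somatosensory", "subcortical")

.HEMIS <- c("left", "right", "midline")

# Measure names for the 12-value connectivity profile (FC block then SC block).
.MEASURES <- c(paste0("fc_", .LOBES), paste0("sc_", .LOBES))

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL uses (and advances) the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Indices of the strictly-upper triangle, fixed column-major order shared by
# all edge-vector representations (EdgeNormModel, bootstrap expansion).
.upperTri <- function(n) which(upper.tri(matrix(0, n, n)))

# Rebuild a symmetric matrix (zero diagonal) from an upper-triangle vector.
.edgesToMatrix <- function(edges, n, ids) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[.upperTri(n)] <- edges
  m + t(m)
}

.matrixToEdges <- function(m) m[.upperTri(nrow(m))]

# Edge labels "i|j" in upper-triangle order, for error messages and
# serialized edge tables.
.edgeLabels <- function(ids) {
  n <- length(ids)
  idx <- .upperTri(n)
  row <- ((idx - 1L) %% n) + 1L
  col <- ((idx - 1L) %/% n) + 1L
  cbind(ids[row], ids[col])
}

.fmt <- function(x) sprintf("%.17g", x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
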
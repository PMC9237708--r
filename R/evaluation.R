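# evaluation: outcome-group comparisons, ROC prediction of unfavourable
# outcome, the random-node permutation null, and the clinical covariate
# screen.

.ENGEL <- c("Ia", "Ib-d", "II", "III-IV")

# distance variants examined alongside total distance
.distanceVariants <- function(d) {
  data.frame(subject_id = d$subject_id,
             total = d$total,
             fc = d$fc_distance,
             sc = d$sc_distance,
             euclidean = sqrt(d$fc_euclidean^2 + d$sc_euclidean^2),
             mahalanobis = sqrt(d$fc_mahalanobis^2 + d$sc_mahalanobis^2),
             stringsAsFactors = FALSE)
}

.rankSumP <- function(x, y) {
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

#' Compare fingerprint distances across Engel outcome groups
#'
#' Omnibus Kruskal-Wallis test of distance across the four 1-year Engel
#' outcome groups (Ia, Ib-d, II, III-IV), followed by all six pairwise
#' Wilcoxon rank-sum tests Bonferroni-corrected by the factor 6. The same
#' battery is run on total distance and on the fc-only, sc-only,
#' Euclidean-only and Mahalanobis-only variants (the latter two combine
#' the modalities Pythagorean-style, mirroring total distance). Subjects
#' flagged \code{exclude_from_group_stats} in the manifest are dropped
#' before any statistic is computed.
#'
#' @param distances data.frame from [scoreSubjects()] for the subjects to
#'   compare (typically the left-out group).
#' @param manifest the cohort manifest carrying \code{engel_1yr} and
#'   \code{exclude_from_group_stats} for these subjects.
#' @return a list of class \code{OutcomeComparison} with one element per
#'   distance variant (\code{total}, \code{fc}, \code{sc},
#'   \code{euclidean}, \code{mahalanobis}); each holds
#'   \code{kw_statistic}, \code{kw_p} and a \code{pairwise} data.frame
#'   (group_a, group_b, rank_sum_p_raw, p_bonferroni, significant_at_0.05).
#' @export
compareOutcomes <- function(distances, manifest) {
  dv <- .distanceVariants(distances)
  mf <- manifest[match(dv$subject_id, manifest$subject_id), ]
  if (anyNA(mf$subject_id))
    .stopf("manifest lacks subject(s): %s",
           paste(setdiff(dv$subject_id, manifest$subject_id),
                 collapse = ", "))
  groups0 <- intersect(.ENGEL, unique(mf$engel_1yr))
  keep <- !as.logical(mf$exclude_from_group_stats)
  dv <- dv[keep, ]
  grp <- factor(mf$engel_1yr[keep], levels = .ENGEL)
  grp <- droplevels(grp)
  empty <- setdiff(groups0, levels(grp))
  if (length(empty))
    .stopf("group(s) emptied by exclusions: %s", paste(empty, collapse = ", "))
  sizes <- table(grp)
  if (sum(sizes >= 2) < 2)
    .stopf("need at least two outcome groups with two members each")
  pairs <- utils::combn(levels(grp), 2)
  out <- lapply(c(total = "total", fc = "fc", sc = "sc",
                  euclidean = "euclidean", mahalanobis = "mahalanobis"),
                function(v) {
    x <- dv[[v]]
    kw <- stats::kruskal.test(x, grp)
    pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     stringsAsFactors = FALSE)
    pw$rank_sum_p_raw <- apply(pairs, 2, function(pr)
      .rankSumP(x[grp == pr[1]], x[grp == pr[2]]))
    pw$p_bonferroni <- pmin(1, 6 * pw$rank_sum_p_raw)
    pw$significant_at_0.05 <- pw$p_bonferroni < 0.05
    list(kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
         pairwise = pw)
  })
  structure(out, class = "OutcomeComparison")
}

#' @export
print.OutcomeComparison <- function(x, ...) {
  cat("Outcome-group comparison (Kruskal-Wallis + pairwise rank-sum, Bonferroni x6)\n")
  for (v in names(x))
    cat(sprintf("  %-12s KW chi2 = %.3f, p = %.4g; %d/%d pairs significant\n",
                v, x[[v]]$kw_statistic, x[[v]]$kw_p,
                sum(x[[v]]$pairwise$significant_at_0.05),
                nrow(x[[v]]$pairwise)))
  invisible(x)
}

#' ROC analysis of unfavourable-outcome prediction
#'
#' Receiver operating characteristic curve for predicting unfavourable
#' (Engel III-IV) outcome from total distance to the fingerprint: the full
#' curve over all thresholds, the trapezoidal AUC, and the Youden-optimal
#' operating point (ties in Youden's J broken toward higher specificity).
#'
#' @param distances numeric vector of total distances, or the data.frame
#'   from [scoreSubjects()] (its \code{total} column is used).
#' @param labels logical vector, \code{TRUE} for unfavourable outcome.
#' @return a list of class \code{RocSummary}: \code{thresholds},
#'   \code{sensitivities}, \code{specificities}, \code{auc},
#'   \code{optimal_threshold}, \code{sens_at_optimal},
#'   \code{spec_at_optimal}.
#' @export
rocUnfavourable <- function(distances, labels) {
  x <- if (is.data.frame(distances)) distances$total else distances
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    .stopf("both outcome classes must be present")
  r <- pROC::roc(response = labels, predictor = x,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  j <- co$sensitivity + co$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(co$specificity[best])]
  structure(list(thresholds = co$threshold,
                 sensitivities = co$sensitivity,
                 specificities = co$specificity,
                 auc = as.numeric(pROC::auc(r)),
                 optimal_threshold = co$threshold[best],
                 sens_at_optimal = co$sensitivity[best],
                 spec_at_optimal = co$specificity[best]),
            class = "RocSummary")
}

#' @export
print.RocSummary <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.4f; Youden optimum sens = %.1f%%, spec = %.1f%% at threshold %.3f\n",
    x$auc, 100 * x$sens_at_optimal, 100 * x$spec_at_optimal,
    x$optimal_threshold))
  invisible(x)
}

# ---- random-node permutation null ------------------------------------------

# Stack the ipsilateral rows of every connectome into one
# (nSubj * nIpsi) x nNodes matrix so that profiles for an arbitrary NOI
# set reduce to a single matrix product per modality.
.stackIpsi <- function(conns, atlas) {
  ipsiIdx <- match(.ipsiIds(atlas), nodeIds(atlas))
  do.call(rbind, lapply(conns, function(cn) {
    m <- connMatrix(cn)
    diag(m) <- 0
    m[ipsiIdx, , drop = FALSE]
  }))
}

# 6 x nIpsi lobe-averaging operator
.lobeOperator <- function(atlas) {
  ipsi <- .ipsiIds(atlas)
  lobe <- .lobe(atlas)[ipsi]
  L <- t(vapply(.LOBES, function(lb) {
    ind <- as.numeric(lobe == lb)
    if (sum(ind) == 0) .stopf("lobe '%s' has no ipsilateral node", lb)
    ind / sum(ind)
  }, numeric(length(ipsi))))
  rownames(L) <- .LOBES
  L
}

# profiles (6 x nSubj) for NOI indices S with per-node weights w
.fastProfiles <- function(A, L, nIpsi, S, w) {
  v <- A[, S, drop = FALSE] %*% w
  L %*% matrix(v, nrow = nIpsi)
}

.rankSumStat <- function(PfcM, PscM, PfcE, PscE, unf) {
  dist1 <- function(Pm, Pe) {
    mu <- rowMeans(Pm)
    S <- stats::cov(t(Pm))
    d <- Pe - mu
    sqrt(colSums(d^2)) + sqrt(pmax(0, colSums(d * (.covPinv(S) %*% d))))
  }
  fc <- dist1(PfcM, PfcE)
  sc <- dist1(PscM, PscE)
  sum(rank(sqrt(fc^2 + sc^2))[unf])
}

#' Random-node permutation null for the a priori node set
#'
#' Tests whether the hypothesized 14 nodes of interest outperform random
#' node sets at separating unfavourable outcome. Per iteration, \code{k}
#' nodes are drawn uniformly without replacement from the whole atlas and
#' treated as the NOI set (each sampled node weighted by its hemisphere:
#' ipsilateral \code{wIpsi}, contralateral or midline \code{wContra}); the
#' fingerprint is rebuilt from the same bootstrap-expanded model
#' connectomes, the evaluation subjects are scored and ranked ascending by
#' total distance (ties get average ranks), and the ranks of the
#' unfavourable subjects are summed. Higher sums mean the unfavourable
#' patients rank farther from the fingerprint. The observed statistic uses
#' the real NOI set; the null percentile uses the add-one estimator
#' \eqn{(1 + \#\{null \ge obs\})/(nIter + 1)}.
#'
#' @param modelFc,modelSc the model subjects' focus-oriented normative
#'   connectomes.
#' @param evalFc,evalSc the evaluation (left-out) subjects' connectomes.
#' @param unfavourable logical per evaluation subject (Engel III-IV).
#' @param atlas the \linkS4class{Atlas}.
#' @param nIter number of random node sets (study value 5000).
#' @param k nodes per random set (default 14).
#' @param seed seed for the node draws.
#' @param noiIds the real node-of-interest set (default: atlas flags).
#' @param wIpsi,wContra hemisphere weights, default 2:1.
#' @param nBoot,sampleSize,nSub,sdBound,expandSeed bootstrap-expansion
#'   parameters shared by every iteration (the expansion is computed once).
#' @return a list of class \code{NodePermutationNull}: \code{n_iter},
#'   \code{k}, \code{null_rank_sums}, \code{observed_rank_sum},
#'   \code{n_exceeding} (strictly greater), \code{p_upper} and
#'   \code{percentile} (0-100).
#' @export
nodePermutationTest <- function(modelFc, modelSc, evalFc, evalSc,
                                unfavourable, atlas, nIter = 5000, k = 14,
                                seed = NULL, noiIds = NULL,
                                wIpsi = 2, wContra = 1, nBoot = 10,
                                sampleSize = 6, nSub = 4, sdBound = 4,
                                expandSeed = NULL) {
  if (is.null(noiIds)) noiIds <- noiIds(atlas)
  ids <- nodeIds(atlas)
  if (k > length(ids)) .stopf("k = %d exceeds the %d atlas nodes", k,
                              length(ids))
  unfavourable <- as.logical(unfavourable)
  if (!any(unfavourable)) .stopf("need at least one unfavourable subject")
  if (length(unfavourable) != length(evalFc))
    .stopf("labels must parallel the evaluation subjects")
  if (is.null(expandSeed) && !is.null(seed)) expandSeed <- seed + 1L
  expanded <- bootstrapExpand(modelFc, modelSc, nBoot, sampleSize, nSub,
                              sdBound, seed = expandSeed)
  L <- .lobeOperator(atlas)
  nIpsi <- length(.ipsiIds(atlas))
  AfcM <- .stackIpsi(lapply(expanded, `[[`, "fc"), atlas)
  AscM <- .stackIpsi(lapply(expanded, `[[`, "sc"), atlas)
  AfcE <- .stackIpsi(evalFc, atlas)
  AscE <- .stackIpsi(evalSc, atlas)
  hemi <- .hemi(atlas)
  nodeW <- ifelse(hemi == "left", wIpsi, wContra)
  stat <- function(S, w) .rankSumStat(
    .fastProfiles(AfcM, L, nIpsi, S, w), .fastProfiles(AscM, L, nIpsi, S, w),
    .fastProfiles(AfcE, L, nIpsi, S, w), .fastProfiles(AscE, L, nIpsi, S, w),
    unfavourable)
  Sobs <- match(noiIds, ids)
  observed <- stat(Sobs, nodeW[Sobs])
  null <- .withSeed(seed, vapply(seq_len(nIter), function(i) {
    S <- sample.int(length(ids), k)
    stat(S, nodeW[S])
  }, numeric(1)))
  pUpper <- (1 + sum(null >= observed)) / (nIter + 1)
  structure(list(n_iter = nIter, k = k, null_rank_sums = null,
                 observed_rank_sum = observed,
                 n_exceeding = sum(null > observed),
                 p_upper = pUpper,
                 percentile = 100 * (1 - pUpper)),
            class = "NodePermutationNull")
}

#' @export
print.NodePermutationNull <- function(x, ...) {
  cat(sprintf(
    "Random-node null (%d iterations, k = %d): observed rank-sum %.1f,\n  %d null draws exceed it; percentile %.1f (upper-tail p = %.4g)\n",
    x$n_iter, x$k, x$observed_rank_sum, x$n_exceeding, x$percentile,
    x$p_upper))
  invisible(x)
}

# ---- clinical covariate screen ---------------------------------------------

.isBinary <- function(v) {
  u <- unique(v[!is.na(v)])
  is.logical(v) || (length(u) <= 2 && all(u %in% c(0, 1, TRUE, FALSE)))
}

#' Screen clinical covariates against fingerprint distance
#'
#' Total distance to the fingerprint is related to each continuous
#' covariate by Spearman rank correlation and to each binary covariate by
#' Wilcoxon rank-sum, Bonferroni-corrected over the number of covariates.
#' Additionally, each of the 12 profile measures is screened against each
#' covariate at uncorrected 0.05, flagging the direction of association
#' (sign of the rank correlation, or sign of the median difference
#' present minus absent).
#'
#' @param distances data.frame from [scoreSubjects()].
#' @param profiles list of \linkS4class{ConnectivityProfile} (or their
#'   matrix) for the same subjects.
#' @param manifest manifest rows carrying the covariates.
#' @param covariates character vector of manifest columns to screen;
#'   \code{NULL} screens every numeric or logical column outside the core
#'   manifest fields.
#' @return a list of class \code{ClinicalAssociations}: \code{total}, a
#'   data.frame (covariate, type, statistic, p_raw, p_bonferroni,
#'   significant); and \code{measures}, with matrices \code{p},
#'   \code{direction} and \code{significant_unc_0.05} of size 12 x
#'   covariates.
#' @export
clinicalAssociations <- function(distances, profiles, manifest,
                                 covariates = NULL) {
  P <- if (is.matrix(profiles)) profiles else profilesToMatrix(profiles)
  mf <- manifest[match(distances$subject_id, manifest$subject_id), ]
  P <- P[distances$subject_id, , drop = FALSE]
  if (is.null(covariates)) {
    core <- c("subject_id", "group", "age", "seizure_side", "engel_1yr",
              "exclude_from_group_stats")
    covariates <- setdiff(names(mf)[vapply(mf, function(v)
      is.numeric(v) || is.logical(v), TRUE)], core)
  }
  tot <- distances$total
  assoc1 <- function(y, v) {
    if (length(unique(v[!is.na(v)])) < 2) .stopf("constant covariate")
    if (.isBinary(v)) {
      v <- as.logical(v)
      w <- suppressWarnings(stats::wilcox.test(y[v], y[!v]))
      list(type = "binary", stat = unname(w$statistic), p = w$p.value,
           dir = sign(stats::median(y[v]) - stats::median(y[!v])))
    } else {
      ct <- suppressWarnings(stats::cor.test(y, v, method = "spearman",
                                             exact = FALSE))
      list(type = "continuous", stat = unname(ct$estimate), p = ct$p.value,
           dir = sign(unname(ct$estimate)))
    }
  }
  res <- lapply(covariates, function(cv) assoc1(tot, mf[[cv]]))
  totalTab <- data.frame(
    covariate = covariates,
    type = vapply(res, `[[`, "", "type"),
    statistic = vapply(res, `[[`, 0, "stat"),
    p_raw = vapply(res, `[[`, 0, "p"), stringsAsFactors = FALSE)
  totalTab$p_bonferroni <- pmin(1, length(covariates) * totalTab$p_raw)
  totalTab$significant <- totalTab$p_bonferroni < 0.05
  pM <- dirM <- matrix(NA_real_, 12, length(covariates),
                       dimnames = list(.MEASURES, covariates))
  for (cv in covariates) {
    for (ms in .MEASURES) {
      a <- assoc1(P[, ms], mf[[cv]])
      pM[ms, cv] <- a$p
      dirM[ms, cv] <- a$dir
    }
  }
  structure(list(total = totalTab,
                 measures = list(p = pM, direction = dirM,
                                 significant_unc_0.05 = pM < 0.05)),
            class = "ClinicalAssociations")
}

#' @export
print.ClinicalAssociations <- function(x, ...) {
  cat("Clinical covariate screen (total distance, Bonferroni over covariates)\n")
  print(x$total, row.names = FALSE, digits = 3)
  nsig <- sum(x$measures$significant_unc_0.05)
  cat(sprintf("Measure x covariate cells flagged at uncorrected 0.05: %d\n",
              nsig))
  invisible(x)
}
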
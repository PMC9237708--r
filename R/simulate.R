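# synthetic_data: deterministic fixture atlas and full synthetic cohorts
# (controls + model/test/left-out patients) with known ground truth.

# the five a priori lateral NOI regions and their fixture lobe assignments
.NOI_REGIONS <- data.frame(
  name = c("middle_cingulate", "precuneus", "thalamus",
           "anterior_insula", "posterior_insula"),
  lobe = c("prefrontal", "parietal", "subcortical", "temporal", "temporal"),
  stringsAsFactors = FALSE)

#' Deterministic fixture atlas
#'
#' Builds a fully specified atlas with \code{nPerHemisphere} paired nodes
#' per hemisphere, one midline brainstem node, and (by default) anterior
#' and posterior hippocampal composite nodes per hemisphere. The five
#' a priori lateral regions (middle cingulate, precuneus, thalamus,
#' anterior and posterior insula) are always present and NOI-flagged, the
#' hippocampal composites likewise, giving 14 NOI at full size. Remaining
#' nodes are filler regions cycled over the six lobes so every lobe has at
#' least one ipsilateral member; volumes are spread deterministically
#' (golden-ratio spacing) over \code{volumeRange}. The defaults yield the
#' 117-node atlas (2 x 56 + 1 + 4).
#'
#' Fixture lobe assignments (hippocampal composites and insula to temporal,
#' thalamus to subcortical, middle cingulate to prefrontal, precuneus to
#' parietal) stand in for the study parcellation and can be overridden by
#' editing the written atlas table.
#'
#' @param nPerHemisphere paired nodes per hemisphere (>= 7; default 56).
#' @param includeHippocampalComposites add anterior/posterior hippocampal
#'   composite nodes per hemisphere (default TRUE).
#' @param volumeRange node volume range in mm^3.
#' @return an \linkS4class{Atlas}.
#' @export
makeFixtureAtlas <- function(nPerHemisphere = 56,
                             includeHippocampalComposites = TRUE,
                             volumeRange = c(1500, 8000)) {
  n <- as.integer(nPerHemisphere)
  if (n < 7) .stopf("need at least 7 nodes per hemisphere, got %d", n)
  nFill <- n - nrow(.NOI_REGIONS)
  fillerLobes <- rep(.LOBES, length.out = max(nFill, 0))
  # guarantee occipital and motor_somatosensory coverage even at small n
  if (nFill >= 2) fillerLobes[1:2] <- c("occipital", "motor_somatosensory")
  regions <- rbind(.NOI_REGIONS,
                   data.frame(name = sprintf("region_%02d",
                                             seq_len(nFill) + 5L),
                              lobe = fillerLobes, stringsAsFactors = FALSE))
  regions$is_noi <- c(rep(TRUE, nrow(.NOI_REGIONS)), rep(FALSE, nFill))
  if (includeHippocampalComposites) {
    regions <- rbind(regions, data.frame(
      name = c("anterior_hippocampus", "posterior_hippocampus"),
      lobe = "temporal", is_noi = TRUE, stringsAsFactors = FALSE))
  }
  phi <- (sqrt(5) - 1) / 2
  vol <- volumeRange[1] +
    diff(volumeRange) * ((seq_len(nrow(regions)) * phi) %% 1)
  mk <- function(side) {
    pre <- if (side == "left") "L" else "R"
    opp <- if (side == "left") "R" else "L"
    data.frame(node_id = paste0(pre, "_", regions$name),
               name = regions$name, hemisphere = side, lobe = regions$lobe,
               homologue_id = paste0(opp, "_", regions$name),
               is_noi = regions$is_noi, volume_mm3 = vol,
               stringsAsFactors = FALSE)
  }
  brainstem <- data.frame(node_id = "M_brainstem", name = "brainstem",
                          hemisphere = "midline", lobe = "none",
                          homologue_id = NA_character_, is_noi = FALSE,
                          volume_mm3 = mean(volumeRange),
                          stringsAsFactors = FALSE)
  methods::new("Atlas", nodes = rbind(mk("left"), mk("right"), brainstem))
}

#' Construct a simulation configuration
#'
#' Defaults mirror the study design: 85 controls, 9 seizure-free model
#' patients, 5 test patients (one with unfavourable outcome), 38 left-out
#' patients with 1-year Engel outcomes split 15/11/5/7 across Ia, Ib-d, II
#' and III-IV; ages 18-71. FC edges live on the Fisher-z scale with
#' per-edge linear age effects and Gaussian noise; SC edges are generated
#' on the log1p scale of the volume-scaled streamline weights. All patients
#' share a mild common deviation from controls
#' (\code{commonEffectSize}, normative SD, on all 12 measures);
#' unfavourable patients additionally deviate on \code{affectedMeasures}
#' by \code{effectSize} normative SD, with per-subject FC- or SC-dominant
#' heterogeneity.
#'
#' @param seed integer seed.
#' @param nControls,nModel,nTest,nLeftOut group sizes.
#' @param ageRange age range in years.
#' @param fc,sc named lists overriding the edge-model parameters (see
#'   \linkS4class{SimulationConfig}).
#' @param outlier named list overriding \code{fractionUnfavourable},
#'   \code{affectedMeasures}, \code{effectSize}, \code{dominanceScale}
#'   (per-subject modality asymmetry of the planted effect; 1 makes every
#'   affected measure move by exactly \code{effectSize}).
#' @param commonEffectSize shared patient deviation, normative SD.
#' @param nPerHemisphere,includeHippocampalComposites,volumeRange atlas
#'   controls, passed to [makeFixtureAtlas()].
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nControls = 85, nModel = 9,
                             nTest = 5, nLeftOut = 38,
                             ageRange = c(18, 71), fc = list(), sc = list(),
                             outlier = list(), commonEffectSize = 0.5,
                             nPerHemisphere = 56,
                             includeHippocampalComposites = TRUE,
                             volumeRange = c(1500, 8000)) {
  fcDef <- list(baselineMean = 0.2, baselineSd = 0.3, slopeSd = 0.003,
                noiseSd = 0.15)
  scDef <- list(logBaselineMean = 3, logBaselineSd = 1.2, slopeSd = 0.004,
                noiseSd = 0.3)
  outDef <- list(fractionUnfavourable = 7 / 38,
                 affectedMeasures = c("fc_temporal", "fc_subcortical",
                                      "sc_temporal", "sc_subcortical"),
                 effectSize = 3, dominanceScale = 1.5)
  methods::new("SimulationConfig", seed = as.integer(seed),
               nControls = as.integer(nControls), nModel = as.integer(nModel),
               nTest = as.integer(nTest), nLeftOut = as.integer(nLeftOut),
               ageRange = as.numeric(ageRange),
               fc = utils::modifyList(fcDef, fc),
               sc = utils::modifyList(scDef, sc),
               outlier = utils::modifyList(outDef, outlier),
               commonEffectSize = commonEffectSize,
               nPerHemisphere = as.integer(nPerHemisphere),
               includeHippocampalComposites = includeHippocampalComposites,
               volumeRange = as.numeric(volumeRange))
}

# Unit edge pattern for one lobe measure in the focus-oriented frame:
# 1 on every edge between an ipsilateral member of `lobe` and a NOI node.
.lobePattern <- function(atlas, lobe) {
  ids <- nodeIds(atlas)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  rows <- ids[.hemi(atlas) == "left" & .lobe(atlas) == lobe]
  m[rows, noiIds(atlas)] <- 1
  m <- pmax(m, t(m))
  diag(m) <- 0
  m
}

# Solve for pattern coefficients so that the combined edge shift moves the
# six lobe measures of one modality by exactly `targets` (in normative SD).
# The reduction is linear, but patterns overlap on NOI-incident edges, so a
# 6x6 response system is solved rather than scaling each pattern alone.
.effectPatterns <- function(atlas, wIpsi = 2, wContra = 1) {
  pats <- lapply(.LOBES, function(lb) .lobePattern(atlas, lb))
  names(pats) <- .LOBES
  R <- vapply(pats, function(P) {
    cn <- .mkConn("pattern", "FC", P, "focus_oriented", "normative_sd")
    lobeAverage(weightedDegree(cn, atlas, NULL, wIpsi, wContra), atlas)
  }, numeric(6))
  list(patterns = pats, response = R)
}

.combineShift <- function(eff, targets) {
  if (any(!is.finite(targets))) .stopf("non-finite effect targets")
  co <- tryCatch(solve(eff$response, targets),
                 error = function(e) .stopf(
                   "infeasible effect placement: lobe response system is singular"))
  shift <- Reduce(`+`, Map(`*`, eff$patterns, co))
  list(shift = shift, coefficients = co)
}

# homologue-swap permutation indices (left<->right, midline fixed)
.homPerm <- function(atlas) {
  ids <- nodeIds(atlas)
  hom <- .homologues(atlas)
  match(ifelse(is.na(hom), ids, hom), ids)
}

#' Simulate a complete synthetic cohort
#'
#' Generates an atlas, per-subject FC and SC connectomes, a cohort manifest
#' and a ground-truth record, all reproducible from the configuration seed.
#' Controls follow per-edge linear age models with Gaussian noise (FC on
#' the Fisher-z scale; SC on the log1p scale of volume-scaled streamline
#' weights, floored at zero so weights stay nonnegative). Patients are
#' drawn from the control generative model at their age plus a shared mild
#' deviation on all 12 profile measures (the common seizure-free TLE
#' profile); unfavourable (Engel III-IV) patients are additionally shifted
#' on edges incident to the ipsilateral nodes of interest so that the
#' configured profile measures move by the configured effect size, with
#' per-subject FC- or SC-dominant heterogeneity (dominant modality scaled
#' 1.5x, the other 0.5x). Deviations are planted in each subject's
#' focus-oriented frame and mapped to anatomical space by their seizure
#' side; sides alternate left/right. Clinical covariates are generated
#' independently of the planted signal.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param dir optional directory; when given, writes \code{atlas.tsv},
#'   \code{manifest.csv}, \code{ground_truth.json} and
#'   \code{connectomes/<id>_FC.tsv}, \code{<id>_SC.tsv} in the file
#'   dialects of [readConnectome()] and friends.
#' @return invisibly-classed list \code{SimulatedCohort}: \code{atlas},
#'   \code{manifest}, \code{fc} and \code{sc} (named lists of raw
#'   anatomical \linkS4class{Connectome}s), \code{groundTruth},
#'   \code{config}.
#' @export
simulateCohort <- function(cfg, dir = NULL) {
  atlas <- makeFixtureAtlas(cfg@nPerHemisphere,
                            cfg@includeHippocampalComposites,
                            cfg@volumeRange)
  ids <- nodeIds(atlas)
  nN <- length(ids)
  nE <- nN * (nN - 1) / 2
  perm <- .homPerm(atlas)
  eff <- .effectPatterns(atlas)
  o <- cfg@outlier
  .withSeed(cfg@seed, {
    # per-edge generative parameters
    fcBase <- stats::rnorm(nE, cfg@fc$baselineMean, cfg@fc$baselineSd)
    fcSlope <- stats::rnorm(nE, 0, cfg@fc$slopeSd)
    # floor keeps every edge's control distribution clear of the zero clamp
    scBase <- pmax(stats::rnorm(nE, cfg@sc$logBaselineMean,
                                cfg@sc$logBaselineSd), 1)
    scSlope <- stats::rnorm(nE, 0, cfg@sc$slopeSd)

    # subject table
    nPat <- cfg@nModel + cfg@nTest + cfg@nLeftOut
    nSub <- cfg@nControls + nPat
    grp <- c(rep("control", cfg@nControls), rep("model", cfg@nModel),
             rep("test", cfg@nTest), rep("left_out", cfg@nLeftOut))
    sid <- sprintf("%s%03d", c(control = "ctl", model = "mod",
                               test = "tst", left_out = "out")[grp],
                   unlist(lapply(table(factor(grp, unique(grp))), seq_len)))
    age <- stats::runif(nSub, cfg@ageRange[1], cfg@ageRange[2])
    side <- rep("none", nSub)
    side[grp != "control"] <- rep(c("left", "right"),
                                  length.out = nPat)
    engel <- rep("none", nSub)
    engel[grp == "model"] <- "Ia"
    if (cfg@nTest > 0)
      engel[grp == "test"] <- c(rep("Ia", cfg@nTest - 1), "III-IV")
    engel[grp == "left_out"] <- .allocateOutcomes(cfg@nLeftOut,
                                                  o$fractionUnfavourable)
    unfav <- engel == "III-IV"
    dominance <- rep(NA_character_, nSub)
    dominance[unfav] <- sample(c("FC", "SC"), sum(unfav), replace = TRUE)

    # planted shift targets per subject (normative-SD units, per modality)
    shiftFor <- function(i) {
      if (grp[i] == "control") return(NULL)
      fcT <- rep(-cfg@commonEffectSize, 6)
      scT <- rep(-cfg@commonEffectSize, 6)
      names(fcT) <- names(scT) <- .LOBES
      if (unfav[i] && o$effectSize > 0) {
        wFc <- if (dominance[i] == "FC") o$dominanceScale
               else 2 - o$dominanceScale
        am <- o$affectedMeasures
        fcT[sub("^fc_", "", am[startsWith(am, "fc_")])] <-
          fcT[sub("^fc_", "", am[startsWith(am, "fc_")])] -
          o$effectSize * wFc
        scT[sub("^sc_", "", am[startsWith(am, "sc_")])] <-
          scT[sub("^sc_", "", am[startsWith(am, "sc_")])] -
          o$effectSize * (2 - wFc)
      }
      fcS <- .combineShift(eff, fcT)$shift
      scS <- .combineShift(eff, scT)$shift
      if (side[i] == "right") {
        fcS <- fcS[perm, perm]
        scS <- scS[perm, perm]
      }
      list(fc = .matrixToEdges(fcS), sc = .matrixToEdges(scS))
    }

    fcConns <- scConns <- stats::setNames(vector("list", nSub), sid)
    for (i in seq_len(nSub)) {
      sh <- shiftFor(i)
      fcE <- fcBase + fcSlope * age[i] +
        stats::rnorm(nE, 0, cfg@fc$noiseSd)
      if (!is.null(sh)) fcE <- fcE + sh$fc * cfg@fc$noiseSd
      scY <- scBase + scSlope * age[i] +
        stats::rnorm(nE, 0, cfg@sc$noiseSd)
      if (!is.null(sh)) scY <- scY + sh$sc * cfg@sc$noiseSd
      scE <- expm1(pmax(scY, 0))  # nonnegative volume-scaled weights
      fcConns[[i]] <- .mkConn(sid[i], "FC",
                              .edgesToMatrix(fcE, nN, ids),
                              "anatomical", "raw")
      scConns[[i]] <- .mkConn(sid[i], "SC",
                              .edgesToMatrix(scE, nN, ids),
                              "anatomical", "raw")
    }

    # clinical covariates, independent of the planted signal
    onset <- pmin(stats::runif(nSub, 3, 40), age - 1)
    manifest <- data.frame(
      subject_id = sid, group = grp, age = age, seizure_side = side,
      engel_1yr = engel, exclude_from_group_stats = FALSE,
      age_of_onset = ifelse(grp == "control", NA, round(onset, 1)),
      duration = ifelse(grp == "control", NA, round(age - onset, 1)),
      seizure_freq_total = ifelse(grp == "control", NA,
                                  round(stats::rlnorm(nSub, 2, 1), 1)),
      seizure_freq_fbtcs = ifelse(grp == "control", NA,
                                  round(stats::rlnorm(nSub, 0, 1), 1)),
      mts = ifelse(grp == "control", NA,
                   stats::rbinom(nSub, 1, 0.6)),
      pet_lateralizing = ifelse(grp == "control", NA,
                                stats::rbinom(nSub, 1, 0.75)),
      ictal_eeg_lateralizing = ifelse(grp == "control", NA,
                                      stats::rbinom(nSub, 1, 0.85)),
      interictal_eeg_lateralizing = ifelse(grp == "control", NA,
                                           stats::rbinom(nSub, 1, 0.7)),
      seeg = ifelse(grp == "control", NA, stats::rbinom(nSub, 1, 0.15)),
      fbtcs = ifelse(grp == "control", NA, stats::rbinom(nSub, 1, 0.55)),
      stringsAsFactors = FALSE)

    groundTruth <- list(
      config = .configAsList(cfg),
      edge_models = list(
        fc = list(baseline = fcBase, slope = fcSlope,
                  noise_sd = cfg@fc$noiseSd),
        sc = list(log_baseline = scBase, slope = scSlope,
                  noise_sd = cfg@sc$noiseSd)),
      lobe_pattern_note = paste(
        "planted deviations solved through the 6x6 lobe response system;",
        "per-edge baselines/slopes reproducible from config + seed"),
      subjects = data.frame(subject_id = sid, group = grp,
                            age = age, seizure_side = side,
                            engel_1yr = engel, unfavourable = unfav,
                            modality_dominance = dominance,
                            stringsAsFactors = FALSE))

    cohort <- structure(list(atlas = atlas, manifest = manifest,
                             fc = fcConns, sc = scConns,
                             groundTruth = groundTruth, config = cfg),
                        class = "SimulatedCohort")
    if (!is.null(dir)) .writeCohort(cohort, dir)
    cohort
  })
}

.allocateOutcomes <- function(nLeftOut, fracUnfav) {
  nU <- round(fracUnfav * nLeftOut)
  rest <- nLeftOut - nU
  # favourable outcomes split in the study's 15:11:5 proportions
  prop <- c(15, 11, 5) / 31
  nn <- floor(prop * rest)
  rem <- rest - sum(nn)
  if (rem > 0) nn[seq_len(rem)] <- nn[seq_len(rem)] + 1
  rep(c("Ia", "Ib-d", "II", "III-IV"), times = c(nn, nU))
}

.configAsList <- function(cfg) {
  list(seed = cfg@seed, n_controls = cfg@nControls, n_model = cfg@nModel,
       n_test = cfg@nTest, n_left_out = cfg@nLeftOut,
       age_range = cfg@ageRange, fc = cfg@fc, sc = cfg@sc,
       outlier = cfg@outlier, common_effect_size = cfg@commonEffectSize,
       n_per_hemisphere = cfg@nPerHemisphere,
       include_hippocampal_composites = cfg@includeHippocampalComposites,
       volume_range = cfg@volumeRange)
}

.writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "connectomes"), recursive = TRUE,
             showWarnings = FALSE)
  writeAtlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  writeManifest(cohort$manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(cohort$groundTruth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in names(cohort$fc)) {
    writeConnectome(cohort$fc[[id]],
                    file.path(dir, "connectomes", paste0(id, "_FC.tsv")))
    writeConnectome(cohort$sc[[id]],
                    file.path(dir, "connectomes", paste0(id, "_SC.tsv")))
  }
  invisible(dir)
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat(sprintf("SimulatedCohort: %d subjects (%s), %d-node atlas\n",
              nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", "),
              nNodes(x$atlas)))
  invisible(x)
}
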
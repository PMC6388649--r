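# synthetic multimodal cohort generation

# ---- assessment schemas -----------------------------------------------

.ASSESSMENTS <- c("prosac", "antisac", "mgsac", "naturalview", "dti", "psych")

.TRACE_CHANNELS <- c("C", "I", "O", "F", "M", "J", "Var",
                     "CIOFM", "CIOFMJ", "topdown")

.DTI_ROIS <- c("genu", "rostral", "anterior", "posterior", "isthmus",
               "splenium")
.DTI_RAW <- c("lambda1", "lambda2", "lambda3", "length_avg", "angle_avg")
.DTI_DERIVED <- c("FA", "MD", "lambda_perp")

# feature name lists; the first nInformative of each carry the group
# signal by default, ordered so that named, weight-bearing saccade and
# psychometric measures come first
.featureNames <- function(assessment) {
  switch(assessment,
    prosac = c("pct_step_saccades", "sd_srt_correct", "cv_srt_correct",
               "skew2", "srt_correct", "angle_first_saccade", "amplitude",
               "skew1", "pct_direction_errors_corrected", "skew_index",
               "pct_express_saccades", "pct_correct", "velocity",
               "duration", "pct_anticipatory", "pct_direction_errors",
               "gain_first_saccade", "pct_no_response"),
    antisac = c("angle_first_saccade", "pct_anticipatory", "pct_correct",
                "velocity", "pct_direction_errors",
                "pct_express_both_directions", "cv_srt_correct",
                "pct_direction_errors_corrected", "pct_step_saccades",
                "srt_correct", "sd_srt_correct", "amplitude", "duration",
                "skew1", "gain_first_saccade"),
    mgsac = c("pct_skip_first_target", "accuracy_first_saccade",
              "accuracy_final_fixation_second", "pct_timing_errors",
              "pct_all_timing_errors", "pct_false_starts",
              "pct_sequence_and_timing_errors", "cv_srt_first_correct",
              "angle_first_saccade", "cv_srt_second_correct",
              "pct_sequence_errors", "path_length_accuracy",
              "amplitude_second_saccade", "sd_srt_first_correct",
              "srt_first_correct", "pct_correct", "srt_second_correct",
              "sd_srt_second_correct", "amplitude_first_saccade",
              "velocity_first_saccade", "velocity_second_saccade",
              "duration_first_saccade", "pct_anticipatory", "pct_express",
              "gain_first_saccade", "gain_second_saccade"),
    dti = as.vector(t(outer(.DTI_ROIS, c(.DTI_RAW, .DTI_DERIVED),
                            paste, sep = "_"))),
    psych = c("quantitative_concepts", "inhibition_total_errors",
              "digit_recall", "attention_auditory", "inhibition_naming",
              "inhibition_switching", "memory_faces", "memory_names",
              "narrative_memory", "sentence_repetition",
              "visuospatial_arrows", "design_copying", "block_recall",
              "listening_recall", "counting_recall", "applied_problems",
              "word_comprehension", "word_attack", "picture_vocabulary",
              "visual_attention"),
    stop("unknown assessment: ", assessment))
}

.featureCount <- function(assessment) {
  c(prosac = 18L, antisac = 15L, mgsac = 26L, dti = 48L, psych = 20L,
    naturalview = NA_integer_)[[assessment]]
}

# informative DTI raw columns mirror the regions that carried weight in
# corpus callosum classification: genu, rostral body, posterior midbody,
# splenium
.DTI_INFORMATIVE <- c("genu_length_avg", "rostral_lambda3",
                      "splenium_lambda3", "posterior_lambda1",
                      "splenium_length_avg", "posterior_angle_avg")

# ---- CohortSpec -------------------------------------------------------

#' Construct a cohort specification
#'
#' Defaults reproduce the study conditions: 91 FASD / 116 control aged
#' 5-18 (FASD 11.9 +/- 3.4, control 10.8 +/- 3.5 years), the
#' per-assessment completion pattern (ProSac 71/115, MGSac 61/93,
#' AntiSac 67/106, natural viewing 47/53, DTI 41/35, psychometric 58/71)
#' with exactly 22 FASD and 24 controls completing all six, and 70
#' natural-viewing snippets of 2-4 s sampled at 500 Hz.  Group effects
#' default to a standardized difference of 0.8 on as many informative
#' features per assessment as the study's selected-feature counts
#' (ProSac 11, AntiSac 9, MGSac 15, DTI 6, psychometric 3).
#'
#' @param nFASD,nControl group sizes.
#' @param ageRange years, length 2.
#' @param effectSizes named numeric over assessments (Cohen's d per
#'   informative feature; `naturalview` scales the trace shift).
#' @param nInformative named integer over tabular assessments.
#' @param ageSlope SD units per year added to saccade features.
#' @param missingness named list of `c(FASD, control)` completion counts;
#'   `NULL` means full completion.  The default `"study"` applies the
#'   study completion pattern at the study group sizes and full
#'   completion otherwise.
#' @param allComplete `c(FASD, control)` counts completing all six;
#'   ignored (set to group sizes) when completion is full.
#' @param traceSpec list overriding `nSnippets`, `rateHz`,
#'   `durationRange`, `effectSnippets`, `effectChannels`.
#' @param seed RNG seed.
#' @return a validated [CohortSpec].
#' @examples
#' spec <- cohortSpec(seed = 1)
#' spec
#' @export
cohortSpec <- function(nFASD = 91, nControl = 116,
                       ageRange = c(5, 18),
                       effectSizes = NULL, nInformative = NULL,
                       ageSlope = 0.03,
                       missingness = "study",
                       allComplete = c(22L, 24L),
                       traceSpec = list(), seed = 1001L) {
  es <- c(prosac = 0.8, antisac = 0.8, mgsac = 0.8, dti = 0.8,
          psych = 0.8, naturalview = 0.8)
  if (!is.null(effectSizes)) es[names(effectSizes)] <- effectSizes
  ni <- c(prosac = 11L, antisac = 9L, mgsac = 15L, dti = 6L, psych = 3L)
  if (!is.null(nInformative)) ni[names(nInformative)] <-
      as.integer(nInformative)
  ts <- list(nSnippets = 70L, rateHz = 500, durationRange = c(2, 4),
             effectSnippets = 1:10,
             effectChannels = c("F", "J", "CIOFMJ", "topdown"))
  ts[names(traceSpec)] <- traceSpec
  if (identical(missingness, "study")) {
    missingness <- if (nFASD == 91 && nControl == 116) {
      .studyMissingness()
    } else NULL
  }
  if (is.null(missingness)) {
    missingness <- stats::setNames(
      lapply(.ASSESSMENTS, function(a) c(nFASD, nControl)), .ASSESSMENTS)
    allComplete <- c(nFASD, nControl)
  }
  spec <- new("CohortSpec",
              nFASD = as.integer(nFASD), nControl = as.integer(nControl),
              ageRange = as.numeric(ageRange),
              ageMean = c(FASD = 11.9, control = 10.8),
              ageSD = c(FASD = 3.4, control = 3.5),
              maleProp = c(FASD = 0.505, control = 0.440),
              rightProp = c(FASD = 0.758, control = 0.733),
              effectSizes = es, nInformative = ni,
              ageSlope = as.numeric(ageSlope),
              missingness = missingness,
              allComplete = as.integer(allComplete),
              traceSpec = ts, seed = as.integer(seed))
  validObject(spec)
  spec
}

# per-assessment completer counts of the reference screening cohort
.studyMissingness <- function() {
  list(prosac = c(71L, 115L), mgsac = c(61L, 93L), antisac = c(67L, 106L),
       naturalview = c(47L, 53L), dti = c(41L, 35L), psych = c(58L, 71L))
}

setValidity("CohortSpec", function(object) {
  if (object@nFASD < 1 || object@nControl < 1)
    return("nFASD/nControl: group sizes must be positive")
  if (length(object@ageRange) != 2 || diff(object@ageRange) <= 0)
    return("ageRange: must be increasing length-2")
  if (!all(is.finite(object@effectSizes)))
    return("effectSizes: must be finite")
  for (a in names(object@nInformative)) {
    if (object@nInformative[[a]] > .featureCount(a))
      return(sprintf("nInformative: %d exceeds %s feature count %d",
                     object@nInformative[[a]], a, .featureCount(a)))
  }
  sizes <- c(object@nFASD, object@nControl)
  for (a in names(object@missingness)) {
    if (!a %in% .ASSESSMENTS)
      return(sprintf("missingness: unknown assessment '%s'", a))
    if (any(object@missingness[[a]] > sizes) ||
        any(object@missingness[[a]] < 0))
      return(sprintf("missingness: %s counts must lie in [0, group size]", a))
  }
  compl <- do.call(rbind, object@missingness)
  if (any(object@allComplete > apply(compl, 2, min)))
    return("allComplete: exceeds some assessment's completion count")
  for (g in 1:2) {
    m <- sizes[g] - object@allComplete[g]
    if (sum(sizes[g] - compl[, g]) < m)
      return("allComplete: infeasible; too few missing slots to keep the all-six count")
  }
  ts <- object@traceSpec
  if (ts$nSnippets < 1) return("traceSpec: nSnippets must be positive")
  if (any(ts$durationRange <= 0) || ts$rateHz <= 0)
    return("traceSpec: durations and sampling rate must be positive")
  TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d FASD / %d control (%.1f%% FASD), ages %g-%g, seed %d\n",
              object@nFASD, object@nControl,
              100 * object@nFASD / (object@nFASD + object@nControl),
              object@ageRange[1], object@ageRange[2], object@seed))
  cat(sprintf("  effects (d): %s\n",
              paste(sprintf("%s=%.2g", names(object@effectSizes),
                            object@effectSizes), collapse = ", ")))
  cat(sprintf("  all-six completers: %d FASD / %d control\n",
              object@allComplete[1], object@allComplete[2]))
})

# ---- DTI scalar derivation --------------------------------------------

#' Derive FA, MD, and perpendicular diffusivity from tensor eigenvalues
#'
#' Standard diffusion-tensor scalar maps: mean diffusivity
#' `MD = (l1 + l2 + l3) / 3`, perpendicular diffusivity
#' `lambda_perp = (l2 + l3) / 2`, and fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((li - MD)^2)) / sqrt(sum(li^2))`.
#'
#' @param lambda1,lambda2,lambda3 eigenvalues (any diffusivity unit),
#'   ordered `lambda1 >= lambda2 >= lambda3 > 0`.
#' @return data.frame with columns `FA`, `MD`, `lambda_perp`.
#' @examples
#' deriveDTIScalars(1, 1, 1)              # isotropic: FA 0, MD 1
#' deriveDTIScalars(1.7e-3, 0.3e-3, 0.3e-3)
#' @export
deriveDTIScalars <- function(lambda1, lambda2, lambda3) {
  l <- cbind(lambda1, lambda2, lambda3)
  if (any(l <= 0)) stop("eigenvalues must be positive")
  if (any(lambda1 < lambda2 - 1e-12) || any(lambda2 < lambda3 - 1e-12))
    stop("eigenvalues must satisfy lambda1 >= lambda2 >= lambda3")
  md <- rowMeans(l)
  fa <- sqrt(3 / 2) * sqrt(rowSums((l - md)^2)) / sqrt(rowSums(l^2))
  data.frame(FA = fa, MD = md, lambda_perp = (lambda2 + lambda3) / 2)
}

# ---- completion assignment --------------------------------------------

# Deterministic completion mask for one group: the first `a` participants
# complete everything; every later participant misses at least one
# assessment; per-assessment missing quotas are filled greedily
# (largest remaining quota first, then fixed assessment order, scanning
# participants in order).  Returns n x 6 logical (TRUE = completed).
.assignCompletion <- function(n, complete, a) {
  k <- length(complete)
  q <- n - complete                      # missing quota per assessment
  m <- n - a                             # participants allowed to miss
  miss <- matrix(FALSE, n, k, dimnames = list(NULL, names(complete)))
  if (m > 0 && sum(q) > 0) {
    rows <- (a + 1):n
    # pass 1: one missing assessment per non-complete participant
    qq <- q
    for (i in rows) {
      if (sum(qq) == 0) break
      j <- which.max(qq)
      miss[i, j] <- TRUE
      qq[j] <- qq[j] - 1
    }
    # pass 2: distribute remaining quotas in fixed assessment order
    for (j in seq_len(k)) {
      while (qq[j] > 0) {
        cand <- rows[!miss[rows, j]]
        if (!length(cand)) stop("completion assignment infeasible")
        take <- head(cand, qq[j])
        miss[take, j] <- TRUE
        qq[j] <- qq[j] - length(take)
      }
    }
  }
  !miss
}

# ---- attentional eye traces -------------------------------------------

#' Generate attentional eye traces for one participant
#'
#' Emulates the 10-channel attentional eye trace of the natural-viewing
#' assessment: per snippet, a time series of standardized saliency values
#' (channels C, I, O, F, M, J, Var, CIOFM, CIOFMJ, topdown) sampled at
#' the gaze rate.  Each channel is a unit-variance AR(1) series; for
#' FASD participants a configurable mean shift is added on a configurable
#' subset of snippets and channels.
#'
#' Uses the ambient RNG stream (seed the caller).
#'
#' @param group `"FASD"` or `"control"`.
#' @param traceSpec list with `nSnippets`, `rateHz`, `durationRange`,
#'   `effectSnippets`, `effectChannels` (see [cohortSpec()]).
#' @param groupEffect standardized shift applied to FASD traces on the
#'   effect snippets/channels (0 = null).
#' @param durations optional per-snippet durations in seconds (drawn
#'   uniformly from `durationRange` when `NULL`); shared durations model
#'   a common video set.
#' @return list of `nSnippets` matrices (samples x 10 channels).
#' @examples
#' set.seed(1)
#' tr <- generateAttentionalTraces("control",
#'         list(nSnippets = 3L, rateHz = 50, durationRange = c(2, 4),
#'              effectSnippets = 1, effectChannels = "topdown"),
#'         groupEffect = 0)
#' length(tr); dim(tr[[1]])
#' @export
generateAttentionalTraces <- function(group, traceSpec, groupEffect = 0,
                                      durations = NULL) {
  stopifnot(group %in% c("FASD", "control"))
  ns <- traceSpec$nSnippets
  if (is.null(durations)) {
    durations <- runif(ns, traceSpec$durationRange[1],
                       traceSpec$durationRange[2])
  }
  stopifnot(length(durations) == ns)
  rho <- 0.9
  lapply(seq_len(ns), function(s) {
    len <- max(2L, as.integer(round(durations[s] * traceSpec$rateHz)))
    e <- matrix(rnorm(len * 10), len, 10)
    x <- rbind(e[1, ], vapply(seq_len(10), function(j) {
      as.numeric(stats::filter(sqrt(1 - rho^2) * e[-1, j], rho,
                               method = "recursive", init = e[1, j]))
    }, numeric(len - 1L)))
    colnames(x) <- .TRACE_CHANNELS
    if (group == "FASD" && groupEffect != 0 &&
        s %in% traceSpec$effectSnippets) {
      ch <- intersect(traceSpec$effectChannels, .TRACE_CHANNELS)
      x[, ch] <- x[, ch] + groupEffect
    }
    x
  })
}

# ---- tabular feature simulation ---------------------------------------

# baseline (control) mean/sd and informative columns per assessment
.assessmentModel <- function(assessment) {
  nm <- .featureNames(assessment)
  if (assessment == "psych") {
    list(names = nm, mean = rep(10, 20), sd = rep(3, 20),
         informativeOrder = nm)
  } else if (assessment == "dti") {
    base <- c(lambda1 = 1.70, lambda2 = 0.55, lambda3 = 0.35,
              length_avg = 70, angle_avg = 35)
    sds <- c(lambda1 = 0.10, lambda2 = 0.07, lambda3 = 0.06,
             length_avg = 8, angle_avg = 8)
    raw <- as.vector(t(outer(.DTI_ROIS, .DTI_RAW, paste, sep = "_")))
    met <- sub("^[a-z]+_", "", raw)
    list(names = raw, mean = unname(base[met]), sd = unname(sds[met]),
         informativeOrder = c(.DTI_INFORMATIVE,
                              setdiff(raw, .DTI_INFORMATIVE)))
  } else {
    k <- length(nm)
    list(names = nm, mean = rep(0, k), sd = rep(1, k),
         informativeOrder = nm)
  }
}

# simulate a completers-only feature matrix; FASD informative features are
# shifted down by d * sd (deficit direction); saccade features carry a
# linear age trend
.simulateFeatures <- function(assessment, group, age, spec) {
  mod <- .assessmentModel(assessment)
  n <- length(group)
  k <- length(mod$names)
  x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, mod$names))
  x <- sweep(x, 2, mod$sd, "*")
  x <- sweep(x, 2, mod$mean, "+")
  d <- spec@effectSizes[[assessment]]
  ninf <- spec@nInformative[[assessment]]
  inf <- head(mod$informativeOrder, ninf)
  if (d != 0 && length(inf)) {
    shift <- d * mod$sd[match(inf, mod$names)]
    x[group == "FASD", inf] <- sweep(
      x[group == "FASD", inf, drop = FALSE], 2, shift, "-")
  }
  if (assessment %in% c("prosac", "antisac", "mgsac") &&
      spec@ageSlope != 0) {
    x <- x + spec@ageSlope * (age - mean(spec@ageRange))
  }
  if (assessment == "dti") x <- .dtiFinalize(x)
  x
}

# enforce eigenvalue ordering/positivity per ROI and append derived
# scalars, giving the 48-column DTI table (8 per ROI)
.dtiFinalize <- function(raw) {
  out <- NULL
  for (roi in .DTI_ROIS) {
    l <- raw[, paste(roi, c("lambda1", "lambda2", "lambda3"), sep = "_"),
             drop = FALSE]
    l <- t(apply(l, 1, function(v) sort(pmax(v, 1e-3), decreasing = TRUE)))
    block <- cbind(l,
                   raw[, paste(roi, c("length_avg", "angle_avg"),
                               sep = "_"), drop = FALSE])
    der <- deriveDTIScalars(l[, 1], l[, 2], l[, 3])
    block <- cbind(block, as.matrix(der))
    colnames(block) <- paste(roi, c(.DTI_RAW, .DTI_DERIVED), sep = "_")
    out <- if (is.null(out)) block else cbind(out, block)
  }
  out
}

# ---- cohort generation ------------------------------------------------

#' Generate a synthetic multimodal cohort
#'
#' Draws participants (group, age, sex, handedness), assigns the
#' per-assessment completion pattern deterministically, simulates each
#' tabular assessment's features with the specified group effect sizes
#' and age trends, and generates attentional eye traces for
#' natural-viewing completers.  Deterministic given `spec@seed`.
#'
#' @param spec a [CohortSpec].
#' @param traces generate natural-viewing traces (default `TRUE`; set
#'   `FALSE` to skip the trace stage when only tabular assessments are
#'   needed).
#' @return a [FASDCohort].
#' @examples
#' spec <- cohortSpec(nFASD = 10, nControl = 12, missingness = NULL,
#'                    traceSpec = list(nSnippets = 2L, rateHz = 25),
#'                    seed = 7)
#' cohort <- generateCohort(spec)
#' cohort
#' @export
generateCohort <- function(spec, traces = TRUE) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nFASD + spec@nControl
  group <- .groupFactor(rep(c("FASD", "control"),
                            c(spec@nFASD, spec@nControl)))
  id <- c(sprintf("F%03d", seq_len(spec@nFASD)),
          sprintf("C%03d", seq_len(spec@nControl)))
  age <- numeric(n)
  for (g in c("FASD", "control")) {
    idx <- which(group == g)
    age[idx] <- .rtruncnorm(length(idx), spec@ageMean[[g]], spec@ageSD[[g]],
                            spec@ageRange[1], spec@ageRange[2])
  }
  sex <- ifelse(runif(n) < spec@maleProp[as.integer(group == "control") + 1],
                "M", "F")
  hand <- ifelse(runif(n) < spec@rightProp[as.integer(group == "control") + 1],
                 "R", "L")
  participants <- S4Vectors::DataFrame(
    id = id, group = group, age = age,
    sex = factor(sex, levels = c("F", "M")),
    handedness = factor(hand, levels = c("L", "R")), row.names = id)

  compl <- do.call(rbind, spec@missingness)  # assessments x 2
  completion <- rbind(
    .assignCompletion(spec@nFASD, compl[, 1], spec@allComplete[1]),
    .assignCompletion(spec@nControl, compl[, 2], spec@allComplete[2]))
  rownames(completion) <- id

  tabular <- setdiff(rownames(compl), "naturalview")
  assessments <- lapply(tabular, function(a) {
    keep <- completion[, a]
    x <- .simulateFeatures(a, group[keep], age[keep], spec)
    rownames(x) <- id[keep]
    featureTable(x, group = group[keep], age = age[keep], sex = sex[keep],
                 id = id[keep], assessment = a)
  })
  names(assessments) <- tabular

  traceList <- list()
  durations <- numeric(0)
  if (traces && "naturalview" %in% rownames(compl)) {
    ts <- spec@traceSpec
    durations <- runif(ts$nSnippets, ts$durationRange[1],
                       ts$durationRange[2])
    nv <- which(completion[, "naturalview"])
    traceList <- lapply(nv, function(i) {
      generateAttentionalTraces(as.character(group[i]), ts,
                                groupEffect = spec@effectSizes[["naturalview"]],
                                durations = durations)
    })
    names(traceList) <- id[nv]
  }

  new("FASDCohort", participants = participants,
      assessments = S4Vectors::SimpleList(assessments),
      traces = S4Vectors::SimpleList(traceList),
      snippetDurations = durations,
      completion = completion, spec = spec)
}

# truncated normal by rejection (bounded, deterministic given the stream)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# ---- cohort accessors -------------------------------------------------

#' Participant metadata of a cohort
#'
#' @param cohort a [FASDCohort].
#' @return [S4Vectors::DataFrame] of id, group, age, sex, handedness.
#' @export
participants <- function(cohort) {
  stopifnot(is(cohort, "FASDCohort"))
  cohort@participants
}

#' One assessment's FeatureTable from a cohort
#'
#' @param cohort a [FASDCohort].
#' @param assessment one of `prosac`, `antisac`, `mgsac`, `dti`, `psych`.
#' @return a [FeatureTable] of the participants completing it.
#' @export
assessmentTable <- function(cohort, assessment) {
  stopifnot(is(cohort, "FASDCohort"))
  if (!assessment %in% names(cohort@assessments))
    stop("no such assessment in cohort: ", assessment)
  cohort@assessments[[assessment]]
}

#' Completion mask of a cohort
#'
#' @param cohort a [FASDCohort].
#' @return logical matrix participants x assessments (TRUE = completed).
#' @export
completionMask <- function(cohort) {
  stopifnot(is(cohort, "FASDCohort"))
  cohort@completion
}

#' Attentional eye traces of a cohort
#'
#' @param cohort a [FASDCohort].
#' @return named [S4Vectors::SimpleList]; per natural-viewing completer a
#'   list of snippet matrices (samples x 10 channels).
#' @export
cohortTraces <- function(cohort) {
  stopifnot(is(cohort, "FASDCohort"))
  cohort@traces
}

#' Participants completing every assessment
#'
#' @param cohort a [FASDCohort].
#' @return character vector of participant ids.
#' @export
completeAllIds <- function(cohort) {
  m <- completionMask(cohort)
  rownames(m)[rowSums(m) == ncol(m)]
}

#' @rdname groups
#' @export
setMethod("groups", "FASDCohort", function(x) {
  .groupFactor(x@participants$group)
})

#' @rdname ages
#' @export
setMethod("ages", "FASDCohort", function(x) as.numeric(x@participants$age))

setMethod("show", "FASDCohort", function(object) {
  g <- groups(object)
  cat(sprintf("FASDCohort: %d participants (%d FASD, %d control; %.1f%% FASD)\n",
              length(g), sum(g == "FASD"), sum(g == "control"),
              100 * mean(g == "FASD")))
  cat(sprintf("  assessments: %s\n",
              paste(names(object@assessments), collapse = ", ")))
  cat(sprintf("  natural-viewing completers with traces: %d\n",
              length(object@traces)))
  cat(sprintf("  complete on all assessments: %d\n",
              length(completeAllIds(object))))
})
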
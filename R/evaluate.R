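# Scoring pipeline output against simulated ground truth: per-QTN power
# (1 kb matching rule), effect MSE, power SD (robustness) and type-1 error.

#' Match significant SNPs to the true QTNs
#'
#' A QTN counts as detected when a significant SNP lies on the same
#' chromosome within `window` base pairs. Each significant SNP is matched to
#' at most one QTN (the nearest; ties broken by higher LOD); significant
#' SNPs matching no QTN are false positives.
#'
#' @param result an [AssociationResult-class].
#' @param truth a [SimTruth-class] carrying QTN coordinates.
#' @param window matching window in base pairs (default 1000).
#' @return list with `detected` (logical per QTN), `effects` (matched
#'   significant SNP's effect estimate per QTN, `NA` when undetected),
#'   `nFalsePositives`, and `matches` (per significant SNP, the matched QTN
#'   index or `NA`).
#' @export
matchQtns <- function(result, truth, window = 1000) {
  stopifnot(is(result, "AssociationResult"), is(truth, "SimTruth"))
  if (anyNA(truth@qtnChrom) || anyNA(truth@qtnPos))
    stop("truth carries no QTN coordinates; use the truth returned by simulateScenario")
  sig <- significantSnps(result)
  m <- length(truth@qtnIndices)
  detected <- logical(m)
  effects <- rep(NA_real_, m)
  if (!nrow(sig))
    return(list(detected = detected, effects = effects,
                nFalsePositives = 0L, matches = integer(0)))
  matches <- rep(NA_integer_, nrow(sig))
  bestDist <- rep(NA_real_, nrow(sig))
  for (s in seq_len(nrow(sig))) {
    same <- which(truth@qtnChrom == sig$chrom[s])
    if (!length(same)) next
    d <- abs(truth@qtnPos[same] - sig$pos[s])
    ok <- d <= window
    if (!any(ok)) next
    cand <- same[ok][order(d[ok])]
    matches[s] <- cand[1]
    bestDist[s] <- min(d[ok])
  }
  for (q in seq_len(m)) {
    hit <- which(matches == q)
    if (!length(hit)) next
    detected[q] <- TRUE
    # nearest significant SNP; ties broken by LOD
    hit <- hit[order(bestDist[hit], -sig$lod[hit])]
    effects[q] <- sig$effect[hit[1]]
  }
  list(detected = detected, effects = effects,
       nFalsePositives = sum(is.na(matches)), matches = matches)
}

#' Number of null SNPs in a panel
#'
#' SNPs that are not within `window` base pairs of any QTN (the QTNs
#' themselves excluded); the per-replicate denominator of the type-1 error
#' ratio.
#'
#' @param map SNP map (`data.frame`) or [GenotypeMatrix-class].
#' @param truth a [SimTruth-class] with QTN coordinates.
#' @param window exclusion window in base pairs.
#' @return integer count.
#' @export
countNullSnps <- function(map, truth, window = 1000) {
  if (is(map, "GenotypeMatrix")) map <- snpMap(map)
  isNull <- rep(TRUE, nrow(map))
  for (q in seq_along(truth@qtnIndices)) {
    near <- map$chrom == truth@qtnChrom[q] &
      abs(map$pos - truth@qtnPos[q]) <= window
    isNull[near] <- FALSE
  }
  sum(isNull)
}

#' Per-QTN statistical power over repeated simulations
#'
#' Power of QTN `i` is the fraction of runs in which it was detected. The
#' standard deviation of the powers across a designated QTN subset (by
#' default the QTNs sharing a common heritability) measures robustness.
#'
#' @param detections logical matrix, runs x QTNs (or list of logical
#'   vectors).
#' @param sdSubset QTN indices over which the power SD is taken (default:
#'   all).
#' @return list with `power` (per QTN), `mean`, and `sd` (over `sdSubset`).
#' @export
powerPerQtn <- function(detections, sdSubset = NULL) {
  if (is.list(detections)) detections <- do.call(rbind, detections)
  if (!is.matrix(detections)) detections <- matrix(detections, nrow = 1)
  pw <- colMeans(detections)
  if (is.null(sdSubset)) sdSubset <- seq_along(pw)
  list(power = pw, mean = mean(pw),
       sd = stats::sd(pw[sdSubset]))
}

#' Per-QTN mean squared error of effect estimates
#'
#' \eqn{MSE_i = \mathrm{mean}_j (\hat\beta_{ij} - b_i)^2}. Runs in which a
#' QTN went undetected are, by default, omitted from its average (the
#' estimate does not exist); `undetected = "zero"` instead scores them as
#' \eqn{\hat\beta = 0}.
#'
#' @param estimates numeric matrix, runs x QTNs, `NA` where undetected.
#' @param truth a [SimTruth-class] (or numeric vector of true effects).
#' @param undetected `"omit"` (default) or `"zero"`.
#' @return list with `mse` (per QTN; `NA` if never detected under
#'   `"omit"`), `mean` (over QTNs with a value), and `nDetected`.
#' @export
msePerQtn <- function(estimates, truth, undetected = c("omit", "zero")) {
  undetected <- match.arg(undetected)
  b <- if (is(truth, "SimTruth")) truth@qtnEffects else as.numeric(truth)
  if (!is.matrix(estimates)) estimates <- matrix(estimates, ncol = length(b))
  if (ncol(estimates) != length(b))
    stop("estimates must have one column per QTN")
  nDet <- colSums(!is.na(estimates))
  if (undetected == "zero") estimates[is.na(estimates)] <- 0
  err2 <- sweep(estimates, 2, b)^2
  mse <- colMeans(err2, na.rm = TRUE)
  mse[colSums(!is.na(err2)) == 0] <- NA_real_
  list(mse = mse, mean = mean(mse, na.rm = TRUE), nDetected = nDet)
}

#' Type-1 error ratio in percent
#'
#' Total false-positive significant SNPs across runs divided by the total
#' number of null SNPs tested (null SNPs per panel times runs), expressed in
#' percent.
#'
#' @param falsePositives integer vector of per-run false-positive counts.
#' @param nNullSnps null SNPs per panel (scalar or per-run vector).
#' @return percentage in `[0, 100]`.
#' @export
type1ErrorRatio <- function(falsePositives, nNullSnps) {
  nRuns <- length(falsePositives)
  denom <- if (length(nNullSnps) == 1L) nNullSnps * nRuns else sum(nNullSnps)
  100 * sum(falsePositives) / denom
}

#' Repeated-simulation benchmark of the pipeline
#'
#' Runs `nReps` independent scenario simulations, applies the full pipeline
#' to each, matches calls to the truth with the 1 kb rule, and aggregates
#' power, effect MSE and the type-1 error ratio. Per-replicate seeds are
#' derived deterministically from `seed`.
#'
#' @param nReps replicate count.
#' @param n,p panel size per replicate.
#' @param scenario 1, 2 or 3 (see [simulateScenario()]).
#' @param seed master integer seed.
#' @param config a [mblassoConfig()] list.
#' @param window QTN matching window in base pairs.
#' @param sdSubset QTN indices for the power-SD robustness summary
#'   (default: the four heritability-0.05 QTNs of the reference layout).
#' @param mode `"mblasso"` (two-stage) or `"single-stage"`.
#' @param ... further arguments to [simulateScenario()].
#' @return list with `power`, `meanPower`, `powerSD`, `mse`, `meanMSE`,
#'   `type1Percent`, `nNullSnps`, `nullTests`, `falsePositives`,
#'   `detections`, `effects`, `truthEffects`, `nReps`.
#' @export
runSimulationStudy <- function(nReps = 100, n = 199, p = 2000, scenario = 1,
                               seed = 1, config = mblassoConfig(),
                               window = 1000, sdSubset = c(2, 3, 5, 6),
                               mode = c("mblasso", "single-stage"), ...) {
  mode <- match.arg(mode)
  detections <- matrix(NA, nReps, 0)
  effects <- NULL
  fps <- integer(nReps)
  nNull <- integer(nReps)
  truthEffects <- NULL
  for (r in seq_len(nReps)) {
    repSeed <- (as.integer(seed) + 104729L * r) %% 2147483647L
    sim <- simulateScenario(scenario = scenario, n = n, p = p,
                            seed = repSeed, ...)
    res <- if (mode == "mblasso")
      suppressWarnings(runMblasso(sim$genotypes, sim$phenotype,
                                  config = config))
    else
      suppressWarnings(runEmblassoSingleStage(sim$genotypes, sim$phenotype,
                                              config = config))
    mq <- matchQtns(res, sim$truth, window = window)
    if (r == 1L) {
      m <- length(mq$detected)
      detections <- matrix(NA, nReps, m)
      effects <- matrix(NA_real_, nReps, m)
      truthEffects <- sim$truth@qtnEffects
    }
    detections[r, ] <- mq$detected
    effects[r, ] <- mq$effects
    fps[r] <- mq$nFalsePositives
    nNull[r] <- countNullSnps(sim$genotypes, sim$truth, window)
  }
  pw <- powerPerQtn(detections, sdSubset = sdSubset)
  ms <- msePerQtn(effects, truthEffects)
  list(power = pw$power, meanPower = pw$mean, powerSD = pw$sd,
       mse = ms$mse, meanMSE = ms$mean,
       type1Percent = type1ErrorRatio(fps, nNull),
       nNullSnps = nNull, nullTests = sum(nNull), falsePositives = fps,
       detections = detections, effects = effects,
       truthEffects = truthEffects, nReps = nReps)
}
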
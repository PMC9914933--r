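#' Simulation configuration for synthetic rice contamination surveys
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' generator emulates a national market-surveillance survey of heavy
#' metals (Cd, Cr, inorganic As) in rice: per province-week, a fixed
#' number of samples is drawn from metal-specific lognormal concentration
#' distributions whose scale is shifted by (i) a random per-province
#' baseline, (ii) a seasonal elevation in the new-rice marketing weeks,
#' and (iii) a latent low/medium/high contamination regime that switches
#' in contiguous blocks of weeks.  Draws below a metal's limit of
#' detection are left-censored and stored at the LOD.
#'
#' Defaults mirror the survey the pipeline targets: 20 provinces, a
#' 159-week axis (three years), about 57 samples per province-week
#' (~180k samples in total), and seasonal elevation in weeks 24--44,
#' 77--97 and 130--150.
#'
#' @param nProvinces number of provinces.
#' @param nWeeks number of study weeks.
#' @param samplesPerWeek samples drawn per province-week.
#' @param baselineLogMean named numeric (cd, cr, as): baseline log
#'   concentration in log(mg/kg).
#' @param baselineLogSd named positive numeric: lognormal sdlog per metal.
#' @param provinceLogSd sd of the random per-province log-scale baseline
#'   offset (0 disables province heterogeneity).
#' @param seasonalWeeks integer vector of weeks with elevated contamination.
#' @param seasonalMultiplier multiplicative concentration elevation
#'   (>= 1) applied in seasonal weeks.
#' @param regimeMultipliers named numeric (low, medium, high), strictly
#'   increasing concentration scale factors of the latent regimes.
#' @param regimeProbs named numeric, marginal probabilities of the latent
#'   regimes when regime blocks are generated.
#' @param regimeBlockWeeks length (weeks) of a latent regime block; the default is one study year, so contamination status is a province-year attribute.
#' @param regimeAssignment optional data.frame (province, week, level)
#'   fixing the latent regime of every province-week; \code{NULL}
#'   generates block-wise regimes.
#' @param lod named numeric, limit of detection per metal (mg/kg).
#' @param consumptionRange length-2 numeric in (0, 1]: range (kg/d) of
#'   mean daily per-capita rice consumption across provinces.
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
#' @examples
#' cfg <- simulationConfig(nProvinces = 3, nWeeks = 20, samplesPerWeek = 5)
#' sim <- simulateRiceSurvey(cfg)
#' head(sim$samples)
simulationConfig <- function(nProvinces = 20L,
                             nWeeks = 159L,
                             samplesPerWeek = 57L,
                             baselineLogMean = c(cd = log(0.04), cr = log(0.15), as = log(0.06)),
                             baselineLogSd = c(cd = 0.7, cr = 0.5, as = 0.5),
                             provinceLogSd = 0.1,
                             seasonalWeeks = c(24:44, 77:97, 130:150),
                             seasonalMultiplier = 1.2,
                             regimeMultipliers = c(low = 1, medium = 8, high = 30),
                             regimeProbs = c(low = 0.80, medium = 0.13, high = 0.07),
                             regimeBlockWeeks = 53L,
                             regimeAssignment = NULL,
                             lod = c(cd = 0.01, cr = 0.05, as = 0.01),
                             consumptionRange = c(0.2, 0.3),
                             seed = 1L) {
  stopifnot(nProvinces >= 1, nWeeks >= 1, samplesPerWeek >= 1)
  baselineLogMean <- .check_metal_names(baselineLogMean, "baselineLogMean")
  baselineLogSd <- .stopifnot_positive(.check_metal_names(baselineLogSd, "baselineLogSd"),
                                       "baselineLogSd")
  lod <- .stopifnot_positive(.check_metal_names(lod, "lod"), "lod")
  if (provinceLogSd < 0) stop("'provinceLogSd' must be >= 0")
  if (seasonalMultiplier < 1) stop("'seasonalMultiplier' must be >= 1")
  seasonalWeeks <- intersect(as.integer(seasonalWeeks), seq_len(nWeeks))
  lv <- c("low", "medium", "high")
  if (!identical(names(regimeMultipliers), lv))
    stop("'regimeMultipliers' must be named low, medium, high")
  if (any(diff(regimeMultipliers) <= 0))
    stop("'regimeMultipliers' must be strictly increasing with level")
  .stopifnot_positive(regimeMultipliers, "regimeMultipliers")
  if (!identical(names(regimeProbs), lv) || any(regimeProbs < 0) ||
      abs(sum(regimeProbs) - 1) > 1e-8)
    stop("'regimeProbs' must be probabilities over low, medium, high")
  if (length(consumptionRange) != 2 || consumptionRange[1] <= 0 ||
      consumptionRange[2] > 1 || consumptionRange[1] > consumptionRange[2])
    stop("'consumptionRange' must lie within (0, 1] kg/d")
  if (!is.null(regimeAssignment)) {
    need <- c("province", "week", "level")
    if (!all(need %in% names(regimeAssignment)))
      stop("'regimeAssignment' needs columns province, week, level")
    if (!all(regimeAssignment$level %in% lv))
      stop("'regimeAssignment' levels must be low/medium/high")
  }
  structure(list(
    nProvinces = as.integer(nProvinces), nWeeks = as.integer(nWeeks),
    samplesPerWeek = as.integer(samplesPerWeek),
    baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
    provinceLogSd = provinceLogSd, seasonalWeeks = seasonalWeeks,
    seasonalMultiplier = seasonalMultiplier,
    regimeMultipliers = regimeMultipliers, regimeProbs = regimeProbs,
    regimeBlockWeeks = as.integer(regimeBlockWeeks), regimeAssignment = regimeAssignment,
    lod = lod, consumptionRange = consumptionRange, seed = as.integer(seed)),
    class = "SimulationConfig")
}

# Latent regime map for the whole survey: contamination status is a
# slowly evolving provincial attribute that changes only at block
# boundaries (default one study year).  Within each block the draw is
# stratified -- every block contains provinces of every level, with
# counts following the marginal shares -- mirroring surveyed reality,
# where some provinces are always at elevated levels.  Tiny surveys
# (too few provinces to stratify) fall back to independent draws.
.simulate_regime_map <- function(nProvinces, nWeeks, probs, blockWeeks) {
  nBlocks <- ceiling(nWeeks / blockWeeks)
  nHigh <- max(1L, round(probs[["high"]] * nProvinces))
  nMed <- max(1L, round(probs[["medium"]] * nProvinces))
  lv <- matrix("low", nProvinces, nWeeks)
  for (b in seq_len(nBlocks)) {
    cols <- ((b - 1L) * blockWeeks + 1L):min(b * blockWeeks, nWeeks)
    who <- if (nHigh + nMed < nProvinces) {
      ord <- sample.int(nProvinces)
      list(high = ord[seq_len(nHigh)],
           medium = ord[nHigh + seq_len(nMed)])
    } else {
      draw <- sample(names(probs), nProvinces, replace = TRUE, prob = probs)
      list(high = which(draw == "high"), medium = which(draw == "medium"))
    }
    lv[who$high, cols] <- "high"
    lv[who$medium, cols] <- "medium"
  }
  lv
}

#' Simulate a synthetic rice heavy-metal survey
#'
#' Draws the sampling table, the per-province consumption table and the
#' latent regime map described by a \code{\link{simulationConfig}}.  Each
#' sample's concentration for metal m in province p, week w is lognormal
#' with \code{meanlog = baselineLogMean[m] + provinceOffset[p, m] +
#' log(seasonalMultiplier) [if w seasonal] + log(regimeMultiplier[level(p, w)])}
#' and \code{sdlog = baselineLogSd[m]}.  Draws below \code{lod[m]} are
#' flagged censored and stored at the LOD (the measured value a lab would
#' report as "< LOD").
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{samples} (data.frame: province, week,
#'   cd, cr, as, cd_censored, cr_censored, as_censored), \code{consumption}
#'   (data.frame: province, f50_kg_per_day) and \code{regimes} (data.frame:
#'   province, week, level — the ground-truth latent contamination level).
#' @export
simulateRiceSurvey <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .with_seed(config$seed, {
    prov <- sprintf("P%02d", seq_len(config$nProvinces))
    consumption <- data.frame(
      province = prov,
      f50_kg_per_day = stats::runif(config$nProvinces,
                                    config$consumptionRange[1],
                                    config$consumptionRange[2]))
    provOffset <- matrix(stats::rnorm(config$nProvinces * 3, 0, config$provinceLogSd),
                         config$nProvinces, 3, dimnames = list(prov, .metals))
    if (is.null(config$regimeAssignment)) {
      lvmap <- .simulate_regime_map(config$nProvinces, config$nWeeks,
                                    config$regimeProbs,
                                    config$regimeBlockWeeks)
      regimes <- data.frame(
        province = rep(prov, each = config$nWeeks),
        week = rep(seq_len(config$nWeeks), config$nProvinces),
        level = as.vector(t(lvmap)))
    } else {
      regimes <- config$regimeAssignment[order(config$regimeAssignment$province,
                                               config$regimeAssignment$week), ]
      regimes <- regimes[, c("province", "week", "level")]
      rownames(regimes) <- NULL
    }
    nPW <- config$nProvinces * config$nWeeks
    n <- nPW * config$samplesPerWeek
    pwProv <- regimes$province
    pwWeek <- regimes$week
    seas <- pwWeek %in% config$seasonalWeeks
    logShift <- log(config$regimeMultipliers)[regimes$level] +
      ifelse(seas, log(config$seasonalMultiplier), 0)
    samples <- data.frame(
      province = rep(pwProv, each = config$samplesPerWeek),
      week = rep(pwWeek, each = config$samplesPerWeek))
    shiftRep <- rep(logShift, each = config$samplesPerWeek)
    provRep <- rep(match(pwProv, prov), each = config$samplesPerWeek)
    for (m in .metals) {
      meanlog <- config$baselineLogMean[[m]] + provOffset[provRep, m] + shiftRep
      x <- stats::rlnorm(n, meanlog = meanlog, sdlog = config$baselineLogSd[[m]])
      cens <- x < config$lod[[m]]
      x[cens] <- config$lod[[m]]
      samples[[m]] <- x
      samples[[paste0(m, "_censored")]] <- cens
    }
    list(samples = samples, consumption = consumption, regimes = regimes)
  })
}

#' Write/read the generator's delimited-text artifacts
#'
#' Plain CSV round-trip helpers for the sampling, consumption and
#' ground-truth regime tables produced by \code{\link{simulateRiceSurvey}}.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return \code{readSurveyTable} returns a data.frame;
#'   \code{writeSurveyTable} returns \code{path} invisibly.
#' @export
writeSurveyTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSurveyTable
#' @param columnMap optional named character vector adapting other CSV
#'   dialects: names are the standard column names used throughout the
#'   package (province, week, cd, cr, as, cd_censored, ...), values the
#'   headers found in the file.
#' @export
readSurveyTable <- function(path, columnMap = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    missing <- setdiff(unname(columnMap), names(d))
    if (length(missing))
      stop(sprintf("columns not found in '%s': %s", path,
                   paste(missing, collapse = ", ")))
    names(d)[match(columnMap, names(d))] <- names(columnMap)
  }
  d
}
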
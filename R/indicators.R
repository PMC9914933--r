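#' Exposure-assessment constants for heavy metals in rice
#'
#' Regulatory limits, reference doses, cancer slope factors and exposure
#' assumptions used by the risk indicators.  Defaults are the Chinese
#' national limits for Cd/Cr/inorganic-As in rice (0.2, 1.0, 0.2 mg/kg),
#' the JECFA/EPA reference doses (0.001, 0.003, 0.0003 mg/(kg d)), the
#' EPA cancer slope factors (6.3, 0.5, 1.5 kg d/mg), a 60 kg adult body
#' weight, exposure frequency 365 d/yr, exposure duration 70 yr and a
#' carcinogenic averaging time of 365 x 70 days.  With these defaults
#' EF x ED = ATC, so the total carcinogenic risk reduces to
#' \eqn{\sum_j CSF_j \cdot EDI_j}.
#'
#' @param limit named numeric, regulatory limit per metal (mg/kg).
#' @param rfd named numeric, oral reference dose per metal (mg/(kg d)).
#' @param csf named numeric, cancer slope factor per metal (kg d/mg).
#' @param bodyWeight adult body weight (kg).
#' @param ef exposure frequency (days/year).
#' @param ed exposure duration (years).
#' @param atc averaging time for carcinogenic effects (days).
#' @return validated list of class \code{"HMConstants"}.
#' @export
hmConstants <- function(limit = c(cd = 0.2, cr = 1.0, as = 0.2),
                        rfd = c(cd = 0.001, cr = 0.003, as = 0.0003),
                        csf = c(cd = 6.3, cr = 0.5, as = 1.5),
                        bodyWeight = 60, ef = 365, ed = 70,
                        atc = 365 * ed) {
  limit <- .stopifnot_positive(.check_metal_names(limit, "limit"), "limit")
  rfd <- .stopifnot_positive(.check_metal_names(rfd, "rfd"), "rfd")
  csf <- .stopifnot_positive(.check_metal_names(csf, "csf"), "csf")
  .stopifnot_positive(c(bodyWeight, ef, ed, atc), "bodyWeight/ef/ed/atc")
  structure(list(limit = limit, rfd = rfd, csf = csf,
                 bodyWeight = bodyWeight, ef = ef, ed = ed, atc = atc),
            class = "HMConstants")
}

#' Half-LOD substitution of censored measurements
#'
#' Replaces every left-censored (below limit-of-detection) concentration
#' in a sampling table by half the metal's LOD, the standard credible
#' treatment of non-detects for low-level food contaminants.  Uncensored
#' values pass through unchanged.
#'
#' @param samples sampling data.frame with columns \code{cd, cr, as} and
#'   \code{cd_censored, cr_censored, as_censored}.
#' @param lod named numeric, limit of detection per metal (mg/kg).
#' @return the sampling table with censored values replaced by lod/2.
#' @export
#' @examples
#' s <- data.frame(province = "P01", week = 1, cd = 0.01, cr = 0.3, as = 0.05,
#'                 cd_censored = TRUE, cr_censored = FALSE, as_censored = FALSE)
#' substituteLOD(s, c(cd = 0.01, cr = 0.05, as = 0.01))$cd  # 0.005
substituteLOD <- function(samples, lod) {
  lod <- .stopifnot_positive(.check_metal_names(lod, "lod"), "lod")
  for (m in .metals) {
    cf <- paste0(m, "_censored")
    if (!all(c(m, cf) %in% names(samples)))
      stop(sprintf("sampling table lacks columns '%s'/'%s'", m, cf))
    samples[[m]][samples[[cf]]] <- lod[[m]] / 2
  }
  samples
}

#' Single-factor pollution index
#'
#' Ratio of a measured (or aggregated) concentration to the regulatory
#' limit of that metal; values above 1 indicate contamination.
#'
#' @param conc concentration(s), mg/kg, >= 0.
#' @param limit regulatory limit, mg/kg, > 0 (recycled).
#' @return dimensionless index, same shape as \code{conc}.
#' @export
singleFactorIndex <- function(conc, limit) {
  .stopifnot_positive(limit, "limit")
  if (any(conc < 0)) stop("'conc' must be >= 0")
  conc / limit
}

#' Nemerow integrated pollution index
#'
#' Combines the per-metal single-factor indices of one province-week into
#' \eqn{\sqrt{(P_{max}^2 + P_{ave}^2)/2}}, emphasising the worst
#' contaminant while retaining the average.
#'
#' @param p numeric vector of single-factor indices (one unit), or a
#'   matrix with one unit per row and metals in columns.
#' @return the index (scalar, or vector over rows).
#' @export
#' @examples
#' nemerowIndex(c(0.5, 1.0, 0.2))  # 0.81274
nemerowIndex <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) == 0) stop("'p' must be non-empty")
    if (any(p < 0)) stop("'p' must be >= 0")
    pmax_ <- apply(p, 1, max)
    pave <- rowMeans(p)
  } else {
    if (length(p) == 0) stop("'p' must be non-empty")
    if (any(p < 0)) stop("'p' must be >= 0")
    pmax_ <- max(p)
    pave <- mean(p)
  }
  sqrt((pmax_^2 + pave^2) / 2)
}

#' Hazard quotient of one metal
#'
#' Non-carcinogenic risk factor
#' \eqn{HQ = (F_{50} \times C_{avg}) / (RfD \times W)}: mean daily intake
#' of the metal relative to its tolerable reference dose.
#'
#' @param f50 mean daily rice consumption (kg/d), > 0.
#' @param cavg mean concentration (mg/kg), >= 0.
#' @param rfd reference dose (mg/(kg d)), > 0.
#' @param w body weight (kg), > 0.
#' @return dimensionless hazard quotient.
#' @export
hazardQuotient <- function(f50, cavg, rfd, w) {
  .stopifnot_positive(f50, "f50"); .stopifnot_positive(rfd, "rfd")
  .stopifnot_positive(w, "w")
  if (any(cavg < 0)) stop("'cavg' must be >= 0")
  (f50 * cavg) / (rfd * w)
}

#' Target hazard quotient
#'
#' Cumulative non-carcinogenic risk: the sum of the per-metal hazard
#' quotients (additivity, no synergism/antagonism assumed).  THQ <= 1 is
#' read as low non-carcinogenic risk.
#'
#' @param hq numeric vector of hazard quotients (>= 0), or a matrix with
#'   metals in columns.
#' @return the sum (scalar, or vector over rows).
#' @export
targetHazardQuotient <- function(hq) {
  if (any(hq < 0)) stop("'hq' must be >= 0")
  if (is.matrix(hq)) rowSums(hq) else sum(hq)
}

#' Estimated daily intake of a metal
#'
#' \eqn{EDI = (F_{50} \times C_{avg}) / W}: metal intake through rice per
#' kg body weight per day.
#'
#' @inheritParams hazardQuotient
#' @return intake in mg/(kg d).
#' @export
estimatedDailyIntake <- function(f50, cavg, w) {
  .stopifnot_positive(f50, "f50"); .stopifnot_positive(w, "w")
  if (any(cavg < 0)) stop("'cavg' must be >= 0")
  (f50 * cavg) / w
}

#' Total carcinogenic risk over all metals
#'
#' \eqn{TCR = \sum_j EF \times ED \times CSF_j \times EDI_j / ATC}, the
#' incremental lifetime cancer probability from the combined intake.
#' With the default exposure assumptions (EF = 365 d/yr, ED = 70 yr,
#' ATC = 365 x 70 d) the prefactor cancels and TCR equals
#' \eqn{\sum_j CSF_j \times EDI_j} exactly.
#'
#' @param edi named numeric vector of per-metal estimated daily intakes
#'   (mg/(kg d)), or a matrix with metals in columns.
#' @param constants an \code{\link{hmConstants}} object.
#' @return dimensionless lifetime cancer risk.
#' @export
totalCarcinogenicRisk <- function(edi, constants = hmConstants()) {
  if (any(edi < 0)) stop("'edi' must be >= 0")
  k <- constants$ef * constants$ed / constants$atc
  if (is.matrix(edi)) {
    edi <- edi[, .metals, drop = FALSE]
    as.vector(k * (edi %*% constants$csf[.metals]))
  } else {
    edi <- .check_metal_names(edi, "edi")
    k * sum(constants$csf[.metals] * edi)
  }
}

#' Build the weekly province-level indicator series
#'
#' The full assessment path from raw samples to the three weekly risk
#' indicators.  Per province-week: censored values are replaced by half
#' the LOD; the weekly within-province mean concentration of each metal
#' is formed; the per-metal single-factor indices give the Nemerow index;
#' the same weekly means feed the hazard quotients (THQ) and estimated
#' daily intakes (TCR).  Weeks in which a province has no samples are
#' filled by carrying the last available indicator triplet forward
#' (leading gaps are back-filled from the first observed week) and
#' flagged in the \code{gapFilled} assay, so the forecaster always sees a
#' gapless series.
#'
#' @param samples sampling data.frame (see \code{\link{simulateRiceSurvey}}).
#' @param consumption data.frame with columns \code{province},
#'   \code{f50_kg_per_day}; every sampled province must appear.
#' @param constants an \code{\link{hmConstants}} object.
#' @param lod named numeric, limit of detection per metal (mg/kg).
#' @param nWeeks length of the week axis; defaults to the largest week
#'   observed in \code{samples}.
#' @return an \code{\link{IndicatorExperiment}}.
#' @export
buildIndicatorSeries <- function(samples, consumption,
                                 constants = hmConstants(),
                                 lod = c(cd = 0.01, cr = 0.05, as = 0.01),
                                 nWeeks = max(samples$week)) {
  stopifnot(inherits(constants, "HMConstants"))
  prov <- sort(unique(samples$province))
  missing <- setdiff(prov, consumption$province)
  if (length(missing))
    stop(sprintf("missing consumption record for province(s): %s",
                 paste(missing, collapse = ", ")))
  samples <- substituteLOD(samples, lod)
  f50 <- stats::setNames(consumption$f50_kg_per_day, consumption$province)[prov]
  .stopifnot_positive(f50, "f50_kg_per_day")

  lev <- paste(rep(prov, each = nWeeks),
               rep(seq_len(nWeeks), length(prov)), sep = "\r")
  key <- factor(paste(samples$province, samples$week, sep = "\r"), levels = lev)
  if (anyNA(key)) stop("sample week outside 1..nWeeks")
  # weekly within-province mean of the LOD-substituted values, per metal
  cnt <- as.vector(table(key))
  nPW <- length(lev)
  cmean <- vapply(.metals, function(m) {
    rs <- rowsum(samples[[m]], key)
    v <- rep(NA_real_, nPW)
    v[match(rownames(rs), lev)] <- rs[, 1]
    v / ifelse(cnt == 0, NA, cnt)
  }, numeric(nPW))
  if (!is.matrix(cmean))                 # single province-week
    cmean <- matrix(cmean, nrow = 1, dimnames = list(NULL, .metals))
  observed <- cnt > 0
  obs <- which(observed)

  nP <- length(prov)
  toMat <- function(v) matrix(v, nrow = nP, ncol = nWeeks, byrow = TRUE,
                              dimnames = list(prov, NULL))
  obsM <- toMat(observed)
  if (any(rowSums(obsM) == 0))
    stop("province with no samples over the whole week axis")

  P <- sweep(cmean, 2, constants$limit[.metals], "/")
  f50pw <- rep(f50, each = nWeeks)
  hq <- sweep(cmean * f50pw, 2, constants$rfd[.metals] * constants$bodyWeight, "/")
  edi <- cmean * f50pw / constants$bodyWeight
  nipiV <- thqV <- tcrV <- rep(NA_real_, nPW)
  nipiV[obs] <- nemerowIndex(P[obs, , drop = FALSE])
  thqV[obs] <- targetHazardQuotient(hq[obs, , drop = FALSE])
  tcrV[obs] <- totalCarcinogenicRisk(edi[obs, , drop = FALSE], constants)

  fill <- function(M) {
    for (i in seq_len(nrow(M))) {
      r <- M[i, ]
      first <- which(!is.na(r))[1]
      r[seq_len(first - 1)] <- r[first]           # back-fill leading gap
      for (j in seq_along(r)) if (is.na(r[j])) r[j] <- r[j - 1]
      M[i, ] <- r
    }
    M
  }
  IndicatorExperiment(nipi = fill(toMat(nipiV)), thq = fill(toMat(thqV)),
                      tcr = fill(toMat(tcrV)), gapFilled = !obsM,
                      provinces = prov, weeks = seq_len(nWeeks))
}

#' Long-format view and CSV round trip of an indicator series
#'
#' @param ie an \code{\link{IndicatorExperiment}}.
#' @return \code{indicatorTable}: data.frame with columns province, week,
#'   nipi, thq, tcr, gap_filled.
#' @export
indicatorTable <- function(ie) {
  stopifnot(is(ie, "IndicatorExperiment"))
  data.frame(province = rep(provinces(ie), each = ncol(ie)),
             week = rep(weekIndex(ie), nrow(ie)),
             nipi = as.vector(t(nipi(ie))), thq = as.vector(t(thq(ie))),
             tcr = as.vector(t(tcr(ie))),
             gap_filled = as.vector(t(gapFilled(ie))))
}

#' @rdname indicatorTable
#' @param path CSV file path.
#' @export
writeIndicatorTable <- function(ie, path) {
  utils::write.csv(indicatorTable(ie), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname indicatorTable
#' @export
readIndicatorTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  prov <- sort(unique(d$province))
  weeks <- sort(unique(d$week))
  toM <- function(col) {
    m <- matrix(NA_real_, length(prov), length(weeks),
                dimnames = list(prov, NULL))
    m[cbind(match(d$province, prov), match(d$week, weeks))] <- d[[col]]
    m
  }
  g <- toM("gap_filled")
  IndicatorExperiment(nipi = toM("nipi"), thq = toM("thq"), tcr = toM("tcr"),
                      gapFilled = matrix(as.logical(g), nrow(g), ncol(g),
                                         dimnames = dimnames(g)),
                      provinces = prov, weeks = weeks)
}
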
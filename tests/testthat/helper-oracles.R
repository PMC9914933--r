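# Independent straight-line oracles used across the suite.  These are
# deliberately coded with plain loops and share no code with the package
# implementation.

# Per-province-week indicators computed record by record from first
# principles (1/2-LOD substitution, weekly means, index formulas).
oracle_indicators <- function(samples, consumption, lod, constants = hmConstants()) {
  metals <- c("cd", "cr", "as")
  rows <- list()
  for (prov in sort(unique(samples$province))) {
    f50 <- consumption$f50_kg_per_day[consumption$province == prov]
    for (wk in sort(unique(samples$week[samples$province == prov]))) {
      sub <- samples[samples$province == prov & samples$week == wk, ]
      cm <- numeric(3)
      names(cm) <- metals
      for (m in metals) {
        v <- sub[[m]]
        v[sub[[paste0(m, "_censored")]]] <- lod[[m]] / 2
        cm[m] <- sum(v) / length(v)
      }
      P <- numeric(3)
      hq <- numeric(3)
      edi <- numeric(3)
      for (j in 1:3) {
        m <- metals[j]
        P[j] <- cm[m] / constants$limit[[m]]
        hq[j] <- f50 * cm[m] / (constants$rfd[[m]] * constants$bodyWeight)
        edi[j] <- f50 * cm[m] / constants$bodyWeight
      }
      nipi <- sqrt((max(P)^2 + (sum(P) / 3)^2) / 2)
      thq <- sum(hq)
      tcr <- 0
      for (j in 1:3)
        tcr <- tcr + constants$ef * constants$ed * constants$csf[[metals[j]]] *
          edi[j] / constants$atc
      rows[[length(rows) + 1]] <-
        data.frame(province = prov, week = wk, nipi = nipi, thq = thq, tcr = tcr)
    }
  }
  do.call(rbind, rows)
}

# Random small sampling + consumption tables.
random_tables <- function(nProv = 3, nWeeks = 4, nPerWeek = 5) {
  prov <- sprintf("P%02d", seq_len(nProv))
  grid <- expand.grid(province = prov, week = seq_len(nWeeks),
                      rep = seq_len(nPerWeek), stringsAsFactors = FALSE)
  samples <- data.frame(province = grid$province, week = grid$week,
                        cd = rlnorm(nrow(grid), log(0.05), 0.8),
                        cr = rlnorm(nrow(grid), log(0.1), 0.8),
                        as = rlnorm(nrow(grid), log(0.05), 0.8))
  lod <- c(cd = 0.01, cr = 0.05, as = 0.01)
  for (m in names(lod)) {
    cen <- samples[[m]] < lod[[m]]
    samples[[m]][cen] <- lod[[m]]
    samples[[paste0(m, "_censored")]] <- cen
  }
  consumption <- data.frame(province = prov,
                            f50_kg_per_day = runif(nProv, 0.15, 0.35))
  list(samples = samples, consumption = consumption, lod = lod)
}

# Dense softmax attention, computed row by row (the Eq-(7) oracle).
dense_attention <- function(Q, K, V, causal = FALSE) {
  d <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- as.vector(K %*% Q[i, ]) / sqrt(d)
    if (causal) s[seq_along(s) > i] <- -Inf
    w <- exp(s - max(s))
    w <- w / sum(w)
    out[i, ] <- colSums(V * w)
  }
  out
}

# Exhaustive K-medoids optimum for tiny instances.
exhaustive_kmedoids <- function(x, k) {
  n <- nrow(x)
  combos <- utils::combn(n, k)
  best <- Inf
  D <- as.matrix(dist(x))
  for (j in seq_len(ncol(combos))) {
    cost <- sum(apply(D[, combos[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# Shared full-scale pipeline run for the acceptance suite (computed once).
.acc_env <- new.env()
acceptance_run <- function() {
  if (!is.null(.acc_env$run)) return(.acc_env$run)
  sim <- simulateRiceSurvey(simulationConfig(seed = 1))
  ie <- buildIndicatorSeries(sim$samples, sim$consumption)
  space <- gradeRiskSpace(ie, seed = 1)
  fr <- forecastIndicators(ie, splitWeek = 138, horizon = 21,
                           config = forecastConfig(seed = 1))
  pf <- persistenceForecast(ie, 138, 21)
  .acc_env$run <- list(sim = sim, ie = ie, space = space, fr = fr, pf = pf)
  .acc_env$run
}
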
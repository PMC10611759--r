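## HDX uptake kinetics: mono-/biexponential fitting of %D time courses,
## differential deuteration maps with Welch tests, and opening free-energy
## differences from exchange-rate ratios.

# replicate means and standard errors per timepoint
uptake_summary <- function(series) {
  m <- series@percentD
  n <- rowSums(!is.na(m))
  mean <- rowMeans(m, na.rm = TRUE)
  sd <- apply(m, 1L, stats::sd, na.rm = TRUE)
  se <- sd / sqrt(n)
  data.frame(time_s = series@timepoints, mean = mean, sd = sd, se = se, n = n)
}

# progress of an exponential with rate k across the observed window; a rate
# is unidentifiable when exchange has moved < 5% by the last timepoint (too
# slow to observe) or is already > 99% complete at the first (too fast)
rate_identifiable <- function(k, tmin, tmax) {
  progress_end <- 1 - exp(-k * tmax)
  progress_first <- 1 - exp(-k * tmin)
  progress_end >= 0.05 && progress_first <= 0.99
}

aicc_from_rss <- function(rss, n, p) {
  k <- p + 1  # + residual variance
  if (n - k - 1 <= 0) return(NA_real_)
  n * log(max(rss, 1e-12) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

fit_uptake_order <- function(d, order, w) {
  t <- d$time_s
  y <- d$mean
  span <- max(y) - min(y)
  lo_y <- max(min(y) - 5, 0)
  rate_grid <- 10^seq(-5, 0, length.out = 6)
  best <- NULL
  for (k0 in rate_grid) {
    st <- if (order == 1L) {
      list(A0 = lo_y, A = max(span, 1), k = k0)
    } else {
      list(A0 = lo_y, A1 = max(span, 1) / 2, k1 = min(k0 * 10, 10),
           A2 = max(span, 1) / 2, k2 = k0)
    }
    fml <- if (order == 1L) {
      mean ~ A0 + A * (1 - exp(-k * time_s))
    } else {
      mean ~ A0 + A1 * (1 - exp(-k1 * time_s)) + A2 * (1 - exp(-k2 * time_s))
    }
    lower <- if (order == 1L) c(0, 0, 1e-7) else c(0, 0, 1e-7, 0, 1e-7)
    upper <- if (order == 1L) c(100, 100, 10) else c(100, 100, 10, 100, 10)
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = d, start = st, weights = w,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  best
}

#' Fit a deuterium uptake time course
#'
#' Nonlinear least squares of the mono- (`D(t) = A0 + A (1 - exp(-k t))`) or
#' biexponential (`D(t) = A0 + A1 (1 - exp(-k1 t)) + A2 (1 - exp(-k2 t))`,
#' k1 > k2) uptake model on replicate-mean %D, with amplitudes bounded in
#' [0, 100] %D and rates in [1e-7, 10] /s. Fits start from a fixed grid of
#' rate initialisations (deterministic multi-start). Means are weighted by
#' 1/SE^2 when every timepoint has >= 3 replicates, unweighted otherwise.
#' `order = "auto"` selects the model by small-sample-corrected AIC (order 2
#' is only considered with >= 5 distinct timepoints and when its AICc is
#' defined).
#'
#' @param series an [UptakeSeries-class].
#' @param order 1, 2 or "auto".
#' @return an [UptakeFit-class]; when no start converges the fit is returned
#'   with `converged = FALSE` (the peptide is then excluded downstream).
#' @export
fitUptake <- function(series, order = c("auto", "1", "2")) {
  order <- match.arg(as.character(order), c("auto", "1", "2"))
  d <- uptake_summary(series)
  n_tp <- nrow(d)
  if (n_tp < 3L)
    stop("need >= 3 distinct timepoints for a mono-exponential fit")
  if (order == "2" && n_tp < 5L)
    stop("need >= 5 distinct timepoints for a biexponential fit")
  w <- if (all(d$n >= 3L) && all(d$se > 0)) 1 / d$se^2 else rep(1, n_tp)

  failed <- function() new("UptakeFit", peptide = series@peptide,
                           modelOrder = 1L, A0 = NA_real_,
                           amplitudes = NA_real_, rates = NA_real_,
                           rss = NA_real_, aicc = NA_real_, converged = FALSE,
                           rateIdentifiable = FALSE,
                           temperature = series@temperature)
  # flat series: no exchange observed across the window; A ~ 0 with an
  # unidentifiable rate (nothing for the optimizer to do)
  if (max(d$mean) - min(d$mean) < 1e-9) {
    return(new("UptakeFit", peptide = series@peptide, modelOrder = 1L,
               A0 = mean(d$mean), amplitudes = 0,
               rates = 1 / max(d$time_s), rss = 0, aicc = NA_real_,
               converged = TRUE, rateIdentifiable = FALSE,
               temperature = series@temperature))
  }
  candidates <- list()
  if (order %in% c("auto", "1")) {
    b <- fit_uptake_order(d, 1L, w)
    if (!is.null(b))
      candidates$o1 <- list(order = 1L, coef = b$coef, rss = b$rss,
                            aicc = aicc_from_rss(b$rss, n_tp, 3L))
  }
  if (order == "2" || (order == "auto" && n_tp >= 5L)) {
    b <- fit_uptake_order(d, 2L, w)
    if (!is.null(b))
      candidates$o2 <- list(order = 2L, coef = b$coef, rss = b$rss,
                            aicc = aicc_from_rss(b$rss, n_tp, 5L))
  }
  if (!length(candidates)) return(failed())
  pick <- if (length(candidates) == 1L) candidates[[1L]] else {
    a1 <- candidates$o1$aicc
    a2 <- candidates$o2$aicc
    if (is.na(a2) || (!is.na(a1) && a1 <= a2)) candidates$o1 else candidates$o2
  }
  cf <- pick$coef
  if (pick$order == 1L) {
    A0 <- cf[["A0"]]; amps <- cf[["A"]]; ks <- cf[["k"]]
  } else {
    A0 <- cf[["A0"]]
    amps <- c(cf[["A1"]], cf[["A2"]])
    ks <- c(cf[["k1"]], cf[["k2"]])
    if (ks[1] < ks[2]) {  # enforce k_HX1 > k_HX2
      ks <- rev(ks); amps <- rev(amps)
    }
    if (ks[1] == ks[2]) ks[1] <- ks[1] * (1 + 1e-9)
  }
  ident <- vapply(ks, rate_identifiable, TRUE,
                  tmin = min(d$time_s), tmax = max(d$time_s))
  # a flat series carries no rate information regardless of the window
  ident <- ident & (amps > 0.5)
  new("UptakeFit", peptide = series@peptide, modelOrder = pick$order,
      A0 = A0, amplitudes = amps, rates = ks, rss = pick$rss,
      aicc = if (is.null(pick$aicc)) NA_real_ else pick$aicc,
      converged = TRUE, rateIdentifiable = ident,
      temperature = series@temperature)
}

#' Differential deuteration map between two protein states
#'
#' Peptides are matched across states by (start, end, sequence); unmatched
#' peptides are reported in the result, never silently dropped. Per matched
#' peptide and shared timepoint, delta %D = mean(state B) - mean(state A)
#' with a two-tailed Welch (unequal-variance) t-test. Where either state has
#' fewer than 2 replicates the delta is reported with the p-value marked
#' unavailable (NA). Degenerate variance (all replicates identical in both
#' states) yields p = 1 by convention, never NaN. Benjamini-Hochberg
#' adjustment is available behind `adjust` and off by default.
#'
#' @param stateA,stateB lists of [UptakeSeries-class] (one per peptide).
#' @param adjust apply Benjamini-Hochberg adjustment (`p_adjusted` column).
#' @return a [DifferentialMap-class].
#' @export
differentialMap <- function(stateA, stateB, adjust = FALSE) {
  if (is(stateA, "UptakeSeries")) stateA <- list(stateA)
  if (is(stateB, "UptakeSeries")) stateB <- list(stateB)
  key <- function(s) sprintf("%d|%d|%s", s@peptide@start, s@peptide@end,
                             s@peptide@sequence)
  ka <- vapply(stateA, key, "")
  kb <- vapply(stateB, key, "")
  common <- intersect(ka, kb)
  if (!length(common)) stop("no common peptides between the two states")
  unmatched_of <- function(lst, keys, keep, state_side) {
    idx <- which(!keys %in% keep)
    if (!length(idx)) return(NULL)
    do.call(rbind, lapply(lst[idx], function(s)
      data.frame(state = s@peptide@state, start = s@peptide@start,
                 end = s@peptide@end, sequence = s@peptide@sequence,
                 side = state_side, stringsAsFactors = FALSE)))
  }
  unmatched <- rbind(unmatched_of(stateA, ka, common, "A"),
                     unmatched_of(stateB, kb, common, "B"))
  if (is.null(unmatched))
    unmatched <- data.frame(state = character(), start = integer(),
                            end = integer(), sequence = character(),
                            side = character(), stringsAsFactors = FALSE)
  rows <- list()
  for (k in common) {
    sa <- stateA[[match(k, ka)]]
    sb <- stateB[[match(k, kb)]]
    shared_t <- intersect(sa@timepoints, sb@timepoints)
    for (t in shared_t) {
      xa <- sa@percentD[match(t, sa@timepoints), ]
      xb <- sb@percentD[match(t, sb@timepoints), ]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      nA <- length(xa); nB <- length(xb)
      delta <- mean(xb) - mean(xa)
      p <- if (nA < 2L || nB < 2L) {
        NA_real_
      } else if (stats::var(xa) == 0 && stats::var(xb) == 0) {
        1
      } else {
        stats::t.test(xb, xa, var.equal = FALSE)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = sa@peptide@start, end = sa@peptide@end,
        sequence = sa@peptide@sequence, time_s = t,
        mean_A = mean(xa), mean_B = mean(xb), delta_percentD = delta,
        p_value = p, n_A = nA, n_B = nB, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$start, tab$end, tab$time_s), ]
  rownames(tab) <- NULL
  tab$p_adjusted <- if (adjust) stats::p.adjust(tab$p_value, "BH")
                    else NA_real_
  new("DifferentialMap",
      stateA = stateA[[1L]]@peptide@state, stateB = stateB[[1L]]@peptide@state,
      table = tab, unmatched = unmatched)
}

#' Export a differential map as a tidy CSV
#'
#' @param map a [DifferentialMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDifferentialMap <- function(map, path) {
  write_table_deterministic(map@table, path)
  invisible(path)
}

#' Project a differential map onto residues
#'
#' Peptide-level delta %D at one timepoint is averaged per residue over all
#' covering peptides (a stated convention; overlapping-peptide projection
#' has no unique definition). Residues covered by no peptide get NA.
#'
#' @param map a [DifferentialMap-class].
#' @param time_s the timepoint to project.
#' @param residueIds residues to report.
#' @return named numeric vector of per-residue mean delta %D.
#' @export
projectDifferentialMap <- function(map, time_s, residueIds) {
  tab <- map@table[map@table$time_s == time_s, , drop = FALSE]
  vals <- vapply(residueIds, function(r) {
    cov <- tab$start <= r & tab$end >= r
    if (!any(cov)) NA_real_ else mean(tab$delta_percentD[cov])
  }, 0)
  names(vals) <- residueIds
  vals
}

#' Opening free-energy difference from an exchange-rate ratio
#'
#' `ddG_open = -R T ln(k_A / k_B)` with R = 1.986e-3 kcal/(K mol): the
#' A-minus-B opening free energy under EX2 exchange, negative when state B
#' exchanges slower (is more protected). For biexponential fits the slower
#' rate k_HX2 is used (`component = "slow"`); mono-exponential fits use
#' their single rate. Values are approximate (EX2 assumed; temperature-jump
#' labeling protocol) and flagged as such in the result.
#'
#' @param fitA,fitB converged [UptakeFit-class] objects for the two states.
#' @param temperature kelvin (default 310.15 K = 37 C).
#' @param component "slow" (k_HX2 of order-2 fits) or "single".
#' @return a [DifferentialEnergetics-class].
#' @examples
#' \dontrun{ddGFromRates(fitA, fitB, temperature = 310.15)}
#' @export
ddGFromRates <- function(fitA, fitB, temperature = 310.15,
                         component = c("slow", "single")) {
  component <- match.arg(component)
  pick_rate <- function(fit) {
    if (!fit@converged) stop("fit did not converge; no rate available")
    i <- if (fit@modelOrder == 2L) {
      if (component == "single")
        stop("component='single' requires an order-1 fit")
      2L
    } else 1L
    if (!fit@rateIdentifiable[i])
      stop("rate is flagged unidentifiable for peptide ",
           fit@peptide@start, "-", fit@peptide@end,
           "; ddG_open not computed")
    fit@rates[i]
  }
  kA <- pick_rate(fitA)
  kB <- pick_rate(fitB)
  new("DifferentialEnergetics", peptide = fitA@peptide,
      ddG = -GAS_CONSTANT_KCAL * temperature * log(kA / kB),
      rateA = kA, rateB = kB, temperature = temperature,
      note = "approximate (EX2 assumed; temperature-jump protocol)")
}
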
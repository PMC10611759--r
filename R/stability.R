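## Two-state equilibrium stability: urea titrations (dG0 and m-value with
## linear extrapolation to water), temperature extrapolation of dG0 and of
## unfolding rates to 37 C, and Boltzmann melt fits.

# axis value where the signal first crosses `target` (linear interpolation);
# NA when it never does
signal_crossing <- function(axis, y, target) {
  s <- y - target
  for (i in seq_len(length(s) - 1L)) {
    if (s[i] == 0) return(axis[i])
    if (s[i] * s[i + 1L] < 0)
      return(axis[i] + (axis[i + 1L] - axis[i]) * s[i] / (s[i] - s[i + 1L]))
  }
  if (s[length(s)] == 0) return(axis[length(s)])
  NA_real_
}

#' Two-state analysis of a urea unfolding curve
#'
#' A global sigmoid fit with (optionally linear) folded/unfolded baselines
#' establishes the baselines; the fraction unfolded is then computed
#' pointwise from replicate-mean signal, the equilibrium constant
#' `K = f_u / (1 - f_u)` gives `dG([urea]) = -R T ln K`, and a linear fit of
#' dG on [urea] yields the water-extrapolated `dG0` (intercept) and
#' `m`-value (negative slope). Points with f_u outside [0.05, 0.95] are
#' excluded from the linear fit (log-odds blow-up guard). With
#' `mValueMode = "fixed"` the slope is fixed at `mFixed` and only the
#' intercept is estimated.
#'
#' @param curve a denaturant-axis [UnfoldingCurve-class].
#' @param baselines "linear" (default) or "constant".
#' @param mValueMode "fit" (default) or "fixed".
#' @param mFixed m-value (kcal/mol/M) used when `mValueMode = "fixed"`.
#' @return an [UreaUnfoldingFit-class].
#' @export
fitUreaUnfolding <- function(curve, baselines = c("linear", "constant"),
                             mValueMode = c("fit", "fixed"), mFixed = NULL) {
  baselines <- match.arg(baselines)
  mValueMode <- match.arg(mValueMode)
  if (curve@axisKind != "denaturant_molar")
    stop("fitUreaUnfolding needs a denaturant-axis curve")
  Tk <- curve@temperature
  RT <- GAS_CONSTANT_KCAL * Tk
  u <- curve@axisValues
  y <- rowMeans(curve@signal, na.rm = TRUE)
  d <- data.frame(u = u, y = y, RT = RT)

  # global two-state fit to establish the baselines
  span <- y[length(y)] - y[1L]
  mid0 <- signal_crossing(u, y, y[1L] + span / 2)
  if (is.na(mid0)) mid0 <- stats::median(u)
  best <- NULL
  for (m0 in c(0.5, 1, 2, 4)) {
    st <- list(bf = y[1L], bu = y[length(y)], dG0 = m0 * mid0, m = m0)
    lower <- c(-Inf, -Inf, -Inf, 1e-3)
    upper <- c(Inf, Inf, Inf, Inf)
    if (baselines == "linear") {
      st <- c(st, list(sf = 0, su = 0))
      lower <- c(lower, -Inf, -Inf)
      upper <- c(upper, Inf, Inf)
      fml <- y ~ (bf + sf * u) +
        ((bu + su * u) - (bf + sf * u)) / (1 + exp((dG0 - m * u) / RT))
    } else {
      fml <- y ~ bf + (bu - bf) / (1 + exp((dG0 - m * u) / RT))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = d, start = st, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best))
    stop("no transition: the curve could not be fit by a two-state model")
  cf <- as.list(best$coef)
  if (baselines == "constant") cf$sf <- cf$su <- 0
  midpoint <- cf$dG0 / cf$m
  if (midpoint < min(u) || midpoint > max(u))
    stop("no transition within the sampled urea range ",
         "(fitted midpoint at ", sprintf("%.2f", midpoint), " M)")

  # pointwise fraction unfolded from the fitted baselines
  bf <- cf$bf + cf$sf * u
  bu <- cf$bu + cf$su * u
  fu <- (y - bf) / (bu - bf)
  keep <- fu >= 0.05 & fu <= 0.95
  if (sum(keep) < 2L)
    stop("no transition: fewer than 2 points with f_u in [0.05, 0.95]")
  dG <- -RT * log(fu[keep] / (1 - fu[keep]))
  # delta-method weights: var(dG) from signal noise scales as
  # 1 / (f_u (1 - f_u))^2, so near-baseline points count less
  w <- (fu[keep] * (1 - fu[keep]))^2
  if (mValueMode == "fit") {
    lf <- stats::lm(dG ~ uk, data = data.frame(dG = dG, uk = u[keep]),
                    weights = w)
    dG0 <- stats::coef(lf)[[1L]]
    mval <- -stats::coef(lf)[[2L]]
  } else {
    if (is.null(mFixed)) stop("mValueMode='fixed' requires mFixed")
    mval <- mFixed
    dG0 <- stats::weighted.mean(dG + mval * u[keep], w)
  }
  if (mval <= 0)
    stop("non-positive m-value; curve is not a two-state unfolding transition")
  new("UreaUnfoldingFit", dG0 = dG0, mValue = mval, temperature = Tk,
      pointwise = data.frame(urea_M = u[keep], fraction_unfolded = fu[keep],
                             dG = dG),
      baselines = c(bf = cf$bf, bu = cf$bu, sf = cf$sf, su = cf$su),
      rss = best$rss)
}

#' Extrapolate per-temperature dG0 values to a target temperature
#'
#' Ordinary least squares of dG0 on temperature through the per-temperature
#' water values (>= 3 temperatures required), evaluated at the target with a
#' 95% OLS prediction interval. This mirrors linear extrapolation of the
#' zero-urea trendline measured between 20 and 32 C to 37 C.
#'
#' @param dG0 per-temperature unfolding free energies, kcal/mol (or a list
#'   of [UreaUnfoldingFit-class] objects).
#' @param temperatures matching temperatures, kelvin (ignored when `dG0` is
#'   a list of fits).
#' @param target target temperature, kelvin (default 310.15 = 37 C).
#' @return a [StabilityEstimate-class].
#' @examples
#' Tc <- c(20, 22, 23, 28, 32)
#' extrapolateDGToTemperature(10 - 0.2 * Tc, Tc + 273.15)  # 2.60 at 37 C
#' @export
extrapolateDGToTemperature <- function(dG0, temperatures = NULL,
                                       target = 310.15) {
  mval <- NA_real_
  if (is.list(dG0)) {
    temperatures <- vapply(dG0, function(f) f@temperature, 0)
    mval <- mean(vapply(dG0, function(f) f@mValue, 0))
    dG0 <- vapply(dG0, function(f) f@dG0, 0)
  }
  if (length(dG0) < 3L)
    stop("need >= 3 temperatures for the extrapolation")
  df <- data.frame(dG = dG0, Tk = temperatures)
  fit <- stats::lm(dG ~ Tk, data = df)
  pr <- stats::predict(fit, newdata = data.frame(Tk = target),
                       interval = "prediction", level = 0.95)
  new("StabilityEstimate", dG0Water = pr[1L, "fit"], mValue = mval,
      temperatures = temperatures, dG0PerTemperature = dG0,
      slope = stats::coef(fit)[[2L]], intercept = stats::coef(fit)[[1L]],
      predictionInterval = c(pr[1L, "lwr"], pr[1L, "upr"]),
      targetTemperature = target)
}

#' Extrapolate urea-dependent unfolding rates to water and a target
#' temperature
#'
#' Per temperature, `log10(k_u)` is fit linearly in [urea]
#' (`log k_u = log k_u_water + m_ku [urea]`); the zero-urea intercepts are
#' then extrapolated linearly in temperature to the target. Two activation
#' energies are reported at the target: the bare form `-R T ln(k_u)` and the
#' Eyring form `R T ln(k_B T / (h k_u))`; their difference equals
#' `R T ln(k_B T / h)` exactly. A negative m_ku is reported with a warning,
#' not an error (its sign is data-dependent).
#'
#' @param rateTable data.frame with columns `temperature_K`, `urea_M`, `ku`
#'   (1/s); >= 3 urea concentrations per temperature, >= 2 temperatures.
#' @param target target temperature, kelvin (default 310.15 = 37 C).
#' @param logBase base of the `ku` column if already logged; NULL (default)
#'   means the column holds raw rates.
#' @return a [RateExtrapolation-class].
#' @export
extrapolateRate <- function(rateTable, target = 310.15, logBase = NULL) {
  need <- c("temperature_K", "urea_M", "ku")
  miss <- setdiff(need, names(rateTable))
  if (length(miss))
    stop("rate table missing column(s): ", paste(miss, collapse = ", "))
  lk <- if (is.null(logBase)) log10(rateTable$ku)
        else rateTable$ku * log(logBase) / log(10)
  temps <- sort(unique(rateTable$temperature_K))
  if (length(temps) < 2L) stop("need >= 2 temperatures")
  per_T <- t(vapply(temps, function(Tk) {
    sel <- rateTable$temperature_K == Tk
    if (sum(sel) < 3L)
      stop("need >= 3 urea concentrations at ", Tk, " K")
    cf <- stats::coef(stats::lm(lk[sel] ~ rateTable$urea_M[sel]))
    c(logKuWater = cf[[1L]], mKu = cf[[2L]])
  }, c(logKuWater = 0, mKu = 0)))
  if (any(per_T[, "mKu"] < 0))
    warning("negative m_ku at one or more temperatures; ",
            "check the rate table orientation")
  fit <- stats::lm(lw ~ Tk, data = data.frame(lw = per_T[, "logKuWater"],
                                              Tk = temps))
  if (nrow(per_T) > 2L) {
    pr <- stats::predict(fit, newdata = data.frame(Tk = target),
                         interval = "prediction", level = 0.95)
    pi <- c(pr[1L, "lwr"], pr[1L, "upr"])
    lk_t <- pr[1L, "fit"]
  } else {
    # two temperatures: the line is exact, no residual df for an interval
    lk_t <- sum(stats::coef(fit) * c(1, target))
    pi <- c(NA_real_, NA_real_)
  }
  ku_t <- 10^lk_t
  new("RateExtrapolation", logKuWater = per_T[, "logKuWater"],
      mKu = per_T[, "mKu"], temperatures = temps, kuTarget = ku_t,
      dGactBare = -GAS_CONSTANT_KCAL * target * log(ku_t),
      dGactEyring = eyringActivationEnergy(ku_t, target),
      predictionInterval = pi, targetTemperature = target)
}

#' Boltzmann sigmoid fit of a thermal melt
#'
#' Four-parameter Boltzmann model
#' `signal(T) = pre + (post - pre) / (1 + exp((T_m - T) / slope))`; T_m is
#' the inflection, where the signal equals the baseline midpoint.
#'
#' @param curve a temperature-axis [UnfoldingCurve-class] (kelvin axis).
#' @return a [MeltCurveFit-class] with T_m in degrees Celsius.
#' @export
fitMelt <- function(curve) {
  if (curve@axisKind != "temperature_kelvin")
    stop("fitMelt needs a temperature-axis curve")
  Tk <- curve@axisValues
  y <- rowMeans(curve@signal, na.rm = TRUE)
  span <- y[length(y)] - y[1L]
  if (abs(span) < 1e-12) stop("no inflection in range: flat melt signal")
  tm0 <- signal_crossing(Tk, y, y[1L] + span / 2)
  if (is.na(tm0)) stop("no inflection in the sampled temperature range")
  d <- data.frame(Tk = Tk, y = y)
  best <- NULL
  for (s0 in c(diff(range(Tk)) / 20, diff(range(Tk)) / 5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ pre + (post - pre) / (1 + exp((tm - Tk) / slope)), data = d,
        start = list(pre = y[1L], post = y[length(y)], tm = tm0, slope = s0),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15)
      best <- list(coef = stats::coef(fit), rss = rss)
  }
  if (is.null(best)) stop("Boltzmann fit did not converge")
  cf <- best$coef
  if (cf[["tm"]] < min(Tk) || cf[["tm"]] > max(Tk))
    stop("no inflection in the sampled temperature range")
  new("MeltCurveFit", tm = kelvin_to_celsius(cf[["tm"]]),
      slopeFactor = cf[["slope"]], baselinePre = cf[["pre"]],
      baselinePost = cf[["post"]], rss = best$rss)
}
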
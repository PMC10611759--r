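## EX1 kinetics: bimodal envelope deconvolution into folded fractions,
## origin-constrained ln-fit of the unfolding rate, Eyring activation
## energies and activation-energy differences.

# normalize an envelope to unit area (trapezoid rule on the mass grid)
normalize_envelope <- function(e) {
  m <- e[, 1L]; y <- e[, 2L]
  area <- sum(diff(m) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (area <= 0) stop("envelope has zero total intensity")
  cbind(m, y / area)
}

# profile the mixing fraction: for fixed component shapes the residual is
# linear in F_f, so the optimal fraction is closed-form, clipped to [0, 1]
profile_Ff <- function(y, gf, gu) {
  num <- sum((y - gu) * (gf - gu))
  den <- sum((gf - gu)^2)
  if (den <= 0) return(0.5)
  min(max(num / den, 0), 1)
}

mixture_rss <- function(envs, cf, cu, wf, wu) {
  total <- 0
  Ff <- numeric(length(envs))
  for (i in seq_along(envs)) {
    m <- envs[[i]][, 1L]; y <- envs[[i]][, 2L]
    gf <- stats::dnorm(m, cf, wf)
    gu <- stats::dnorm(m, cu, wu)
    Ff[i] <- profile_Ff(y, gf, gu)
    total <- total + sum((Ff[i] * gf + (1 - Ff[i]) * gu - y)^2)
  }
  list(rss = total, Ff = Ff)
}

envelope_moments <- function(e) {
  w <- e[, 2L] / sum(e[, 2L])
  mu <- sum(w * e[, 1L])
  sd <- sqrt(max(sum(w * (e[, 1L] - mu)^2), 1e-6))
  c(mu = mu, sd = sd)
}

#' Deconvolute bimodal isotope envelopes into folded fractions
#'
#' Fits a two-Gaussian mixture to the unit-area-normalised envelopes.
#' By default the component centroids and widths are shared across all
#' timepoints (joint fit; stabilises small-n series), with a per-timepoint
#' mixing fraction F_f obtained in closed form by profiling. Set
#' `shared = FALSE` for independent per-timepoint fits. Unimodal envelopes
#' resolve to F_f at a bound (0 or 1), the absent component carrying zero
#' weight.
#'
#' @param env an [EnvelopeSeries-class] with >= 2 timepoints.
#' @param shared share centroids/widths across timepoints (default TRUE).
#' @return a [BimodalFit-class].
#' @export
deconvoluteEnvelope <- function(env, shared = TRUE) {
  if (length(env@timepoints) < 2L)
    stop("need >= 2 timepoints for deconvolution")
  envs <- lapply(env@envelopes, normalize_envelope)

  fit_joint <- function(sub) {
    # initial shapes from first/last envelope moments
    m1 <- envelope_moments(sub[[1L]])
    m2 <- envelope_moments(sub[[length(sub)]])
    cf0 <- min(m1["mu"], m2["mu"])
    cu0 <- max(m1["mu"], m2["mu"])
    w0 <- min(m1["sd"], m2["sd"])
    if (cu0 - cf0 < 0.5 * w0) cu0 <- cf0 + 2 * w0  # unimodal-looking series
    obj <- function(par) {
      cf <- par[1L]
      cu <- cf + exp(par[2L])
      wf <- exp(par[3L])
      wu <- exp(par[4L])
      mixture_rss(sub, cf, cu, wf, wu)$rss
    }
    starts <- list(c(cf0, log(max(cu0 - cf0, 1e-3)), log(w0), log(w0)),
                   c(cf0 - w0, log(max(cu0 - cf0 + 2 * w0, 1e-3)),
                     log(w0 / 2), log(w0 / 2)))
    best <- NULL
    for (st in starts) {
      o <- tryCatch(stats::optim(st, obj, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) return(NULL)
    par <- best$par
    list(cf = par[1L], cu = par[1L] + exp(par[2L]), wf = exp(par[3L]),
         wu = exp(par[4L]), rss = best$value)
  }

  if (shared) {
    sol <- fit_joint(envs)
    if (is.null(sol)) {
      # per-timepoint fallback, reported in the error per contract
      fb <- lapply(seq_along(envs), function(i) fit_joint(envs[i]))
      stop("joint envelope fit did not converge; per-timepoint fallback ",
           "fractions: ",
           paste(vapply(fb, function(s) {
             if (is.null(s)) return("NA")
             sprintf("%.3f", mixture_rss(envs[1], s$cf, s$cu, s$wf,
                                         s$wu)$Ff[1])
           }, ""), collapse = ", "))
    }
    mr <- mixture_rss(envs, sol$cf, sol$cu, sol$wf, sol$wu)
    new("BimodalFit", timepoints = env@timepoints, Ff = mr$Ff,
        centroidFolded = sol$cf, centroidUnfolded = sol$cu,
        widthFolded = sol$wf, widthUnfolded = sol$wu, residual = mr$rss,
        shared = TRUE)
  } else {
    sols <- lapply(seq_along(envs), function(i) {
      s <- fit_joint(envs[i])
      if (is.null(s)) stop("per-timepoint fit failed at timepoint ", i)
      c(Ff = mixture_rss(envs[i], s$cf, s$cu, s$wf, s$wu)$Ff,
        cf = s$cf, cu = s$cu, wf = s$wf, wu = s$wu, rss = s$rss)
    })
    sols <- do.call(rbind, sols)
    new("BimodalFit", timepoints = env@timepoints, Ff = sols[, "Ff"],
        centroidFolded = mean(sols[, "cf"]),
        centroidUnfolded = mean(sols[, "cu"]),
        widthFolded = mean(sols[, "wf"]), widthUnfolded = mean(sols[, "wu"]),
        residual = sum(sols[, "rss"]), shared = FALSE)
  }
}

#' Bimodality call for an isotope envelope
#'
#' Convention-based diagnostic: an envelope is called bimodal when, after
#' unit-area normalisation and light smoothing, it has two local maxima
#' separated by a dip of at least `dipFraction` of the smaller peak. The
#' threshold is a stated convention, not a reproduction of any published
#' noise floor.
#'
#' @param envelope 2-column matrix (mass_offset_Da, intensity).
#' @param dipFraction required relative dip depth (default 0.1).
#' @return logical.
#' @export
isBimodal <- function(envelope, dipFraction = 0.1) {
  e <- normalize_envelope(envelope)
  y <- stats::filter(e[, 2L], rep(1 / 3, 3), sides = 2)
  y[is.na(y)] <- e[is.na(y), 2L]
  y <- as.numeric(y)
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) < 2L) return(FALSE)
  peaks <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(peaks); hi <- max(peaks)
  dip <- min(y[lo:hi])
  smaller <- min(y[lo], y[hi])
  (smaller - dip) >= dipFraction * smaller
}

#' Unfolding rate from a folded-fraction time course
#'
#' Least-squares fit of `ln(F_f) = -k_u t` constrained through the origin
#' (the underlying first-order decay law has no intercept), followed by the
#' Eyring inversion `dG_act = R T ln(k_B T / (h k_u))`. Fractions below 0.02
#' are treated as 0 (log blow-up guard) and excluded, as are exact zeros.
#' `intercept = TRUE` exposes an unconstrained diagnostic variant (the
#' reported rate is then the slope magnitude).
#'
#' @param fractions a [BimodalFit-class] (or list with `timepoints`, `Ff`).
#' @param temperature kelvin.
#' @param intercept fit an unconstrained line for diagnostics.
#' @return an [UnfoldingKineticsFit-class].
#' @examples
#' bf <- new("BimodalFit", timepoints = c(0, 693.1, 1386.3),
#'           Ff = c(1, 0.5, 0.25), centroidFolded = 0, centroidUnfolded = 6,
#'           widthFolded = 1, widthUnfolded = 1, residual = 0, shared = TRUE)
#' fitUnfoldingRate(bf, temperature = 310.15)  # k_u = 1.000e-3 /s
#' @export
fitUnfoldingRate <- function(fractions, temperature, intercept = FALSE) {
  t <- fractions@timepoints
  Ff <- fractions@Ff
  usable <- Ff > 0.02 & Ff <= 1
  if (sum(Ff >= 0.999 | Ff <= 0.02) == length(Ff))
    stop("no EX1 signal: all folded fractions at bounds")
  t <- t[usable]; lf <- log(Ff[usable])
  if (length(t) < 2L)
    stop("need >= 2 usable timepoints with F_f in (0, 1]")
  if (intercept) {
    fit <- stats::lm(lf ~ t)
    ku <- -stats::coef(fit)[["t"]]
    rss <- sum(stats::residuals(fit)^2)
  } else {
    ku <- -sum(t * lf) / sum(t^2)
    rss <- sum((lf + ku * t)^2)
  }
  if (ku <= 0) stop("non-positive unfolding rate; F_f does not decay")
  new("UnfoldingKineticsFit", ku = ku, temperature = temperature,
      dGact = eyringActivationEnergy(ku, temperature),
      nPoints = length(t), rss = rss)
}

#' Eyring transition-state conversions
#'
#' `eyringActivationEnergy` inverts the Eyring equation
#' `k = (k_B T / h) exp(-dG / (R T))` to an activation free energy in
#' kcal/mol; `eyringRate` is its exact inverse. Constants: k_B =
#' 1.380649e-23 J/K, h = 6.62607e-34 J s, R = 1.986e-3 kcal/(K mol).
#'
#' @param k rate constant, 1/s.
#' @param dG activation free energy, kcal/mol.
#' @param temperature kelvin.
#' @return kcal/mol (`eyringActivationEnergy`) or 1/s (`eyringRate`).
#' @examples
#' eyringActivationEnergy(1e-3, 310.15)  # 22.42 kcal/mol
#' eyringRate(eyringActivationEnergy(1e-3, 310.15), 310.15)  # 1e-3
#' @export
eyringActivationEnergy <- function(k, temperature) {
  GAS_CONSTANT_KCAL * temperature *
    log(BOLTZMANN_J_PER_K * temperature / PLANCK_J_S / k)
}

#' @rdname eyringActivationEnergy
#' @export
eyringRate <- function(dG, temperature) {
  BOLTZMANN_J_PER_K * temperature / PLANCK_J_S *
    exp(-dG / (GAS_CONSTANT_KCAL * temperature))
}

#' Unfolding activation-energy difference between two states
#'
#' `ddG_act = -R T ln(k_u(B) / k_u(A))`: positive when state B unfolds
#' slower than state A. Both fits must share the same temperature.
#'
#' @param fitA,fitB [UnfoldingKineticsFit-class] objects.
#' @return an [ActivationDifference-class].
#' @export
ddGActivation <- function(fitA, fitB) {
  if (abs(fitA@temperature - fitB@temperature) > 1e-9)
    stop("temperature mismatch between fits (", fitA@temperature, " vs ",
         fitB@temperature, " K)")
  Tk <- fitA@temperature
  new("ActivationDifference",
      ddGact = -GAS_CONSTANT_KCAL * Tk * log(fitB@ku / fitA@ku),
      kuA = fitA@ku, kuB = fitB@ku, temperature = Tk)
}

#' Export an EX1 analysis as a tidy CSV
#'
#' @param fit a [BimodalFit-class].
#' @param kinetics an [UnfoldingKineticsFit-class] derived from it.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEx1Table <- function(fit, kinetics, path) {
  df <- data.frame(time_s = fit@timepoints, Ff = fit@Ff,
                   ku = kinetics@ku, dG_act_kcal = kinetics@dGact)
  write_table_deterministic(df, path)
  invisible(path)
}
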
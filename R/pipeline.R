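## End-to-end orchestration from a single structured-text (YAML) config:
## simulate, fit-uptake, diff-map, ex1, stability, network, report.

pipeline_stage_schema <- list(
  simulate = c("what", "params", "output"),
  `fit-uptake` = c("input", "order", "output"),
  `diff-map` = c("input_a", "input_b", "adjust", "output"),
  ex1 = c("manifest", "temperature_K", "output"),
  stability = c("curves", "target_K", "output"),
  network = c("trajectory", "k", "contact_cutoff", "occupancy", "floor",
              "max_frames", "output_prefix"),
  report = c("output")
)

validate_config <- function(config) {
  known_top <- c("seed", "outdir", "stages")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || !length(config$stages))
    stop("config must name at least one stage")
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage))
      stop("stage ", i, " lacks a 'stage' key")
    if (!st$stage %in% names(pipeline_stage_schema))
      stop("unknown stage '", st$stage, "' (stage ", i, ")")
    extra <- setdiff(names(st), c("stage", pipeline_stage_schema[[st$stage]]))
    if (length(extra))
      stop("unknown key(s) in stage '", st$stage, "': ",
           paste(extra, collapse = ", "))
  }
  config
}

pipeline_log <- function(con, level, ...) {
  msg <- sprintf("[%s] %s", level, paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in the order given, from a structured-text
#' (YAML) config or an equivalent nested list. Unknown keys anywhere in the
#' config are rejected by name; every parameter is echoed verbatim into the
#' run log. All tabular outputs are written at fixed precision so that the
#' same (config, seed) pair reproduces byte-identical files. Stage names:
#' `simulate`, `fit-uptake`, `diff-map`, `ex1`, `stability`, `network`,
#' `report`. A stage whose input is produced by an earlier stage refers to
#' it by output path; a missing upstream file is a dependency error naming
#' the stage.
#'
#' @param config path to a YAML config, or a list.
#' @param seed integer seed overriding the config's `seed`.
#' @param outdir output directory overriding the config's `outdir`.
#' @return named list of per-stage outputs, invisibly.
#' @export
runPipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(outdir)) config$outdir <- outdir
  if (is.null(config$outdir)) config$outdir <- "."
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$outdir, "run.log"), "w")
  on.exit(close(logcon))
  pipeline_log(logcon, "INFO", "seed = ", config$seed,
               "; outdir = ", config$outdir)
  results <- list()
  summary_lines <- character()
  need_input <- function(path, stage) {
    if (!file.exists(path))
      stop("dependency error in stage '", stage, "': missing input ", path,
           " (run the producing stage first)")
    path
  }
  out_path <- function(p) {
    if (is.null(p)) stop("stage lacks an output path")
    file.path(config$outdir, p)
  }
  for (st in config$stages) {
    pipeline_log(logcon, "INFO", "stage ", st$stage, ": ",
                 paste(sprintf("%s=%s", names(st)[-1],
                               vapply(st[-1], function(v)
                                 paste(deparse(v), collapse = ""), "")),
                       collapse = " "))
    if (st$stage == "simulate") {
      res <- run_simulate_stage(st, config, out_path)
      summary_lines <- c(summary_lines, res$summary)
      results[[length(results) + 1L]] <- res
    } else if (st$stage == "fit-uptake") {
      series <- readUptakeTable(need_input(out_path(st$input), "fit-uptake"))
      ord <- if (is.null(st$order)) "auto" else st$order
      fits <- lapply(series, fitUptake, order = ord)
      tab <- do.call(rbind, lapply(fits, function(f) {
        data.frame(state = f@peptide@state, start = f@peptide@start,
                   end = f@peptide@end, converged = f@converged,
                   order = f@modelOrder, A0 = f@A0,
                   A1 = f@amplitudes[1L],
                   k1 = f@rates[1L],
                   A2 = if (f@modelOrder == 2L) f@amplitudes[2L] else NA,
                   k2 = if (f@modelOrder == 2L) f@rates[2L] else NA,
                   rss = f@rss)
      }))
      write_table_deterministic(tab, out_path(st$output))
      summary_lines <- c(summary_lines, sprintf(
        "fit-uptake: %d peptides fitted (%d converged)", length(fits),
        sum(tab$converged)))
      results[[length(results) + 1L]] <- list(stage = "fit-uptake",
                                              fits = fits)
    } else if (st$stage == "diff-map") {
      a <- readUptakeTable(need_input(out_path(st$input_a), "diff-map"))
      b <- readUptakeTable(need_input(out_path(st$input_b), "diff-map"))
      adj <- isTRUE(st$adjust)
      map <- differentialMap(a, b, adjust = adj)
      writeDifferentialMap(map, out_path(st$output))
      summary_lines <- c(summary_lines, sprintf(
        "diff-map %s vs %s: %d rows, %d significant at p < 0.05",
        map@stateB, map@stateA, nrow(map@table),
        sum(map@table$p_value < 0.05, na.rm = TRUE)))
      results[[length(results) + 1L]] <- list(stage = "diff-map", map = map)
    } else if (st$stage == "ex1") {
      envs <- readEnvelopeManifest(need_input(out_path(st$manifest), "ex1"))
      Tk <- if (is.null(st$temperature_K)) 310.15 else st$temperature_K
      rows <- lapply(envs, function(e) {
        bf <- deconvoluteEnvelope(e)
        kf <- fitUnfoldingRate(bf, temperature = Tk)
        data.frame(state = e@peptide@state, start = e@peptide@start,
                   end = e@peptide@end, time_s = bf@timepoints, Ff = bf@Ff,
                   ku = kf@ku, dG_act_kcal = kf@dGact)
      })
      tab <- do.call(rbind, rows)
      write_table_deterministic(tab, out_path(st$output))
      summary_lines <- c(summary_lines, sprintf(
        "ex1: %d envelope series; k_u range %.3g-%.3g /s", length(envs),
        min(tab$ku), max(tab$ku)))
      results[[length(results) + 1L]] <- list(stage = "ex1", table = tab)
    } else if (st$stage == "stability") {
      fits <- lapply(st$curves, function(cv)
        fitUreaUnfolding(readUnfoldingCurve(
          need_input(out_path(cv), "stability"))))
      target <- if (is.null(st$target_K)) 310.15 else st$target_K
      est <- extrapolateDGToTemperature(fits, target = target)
      tab <- data.frame(temperature_K = est@temperatures,
                        dG0_kcal = est@dG0PerTemperature,
                        m_value = vapply(fits, function(f) f@mValue, 0),
                        dG0_at_target = est@dG0Water,
                        target_K = target)
      write_table_deterministic(tab, out_path(st$output))
      summary_lines <- c(summary_lines, sprintf(
        "stability: dG0(%.2f K) = %.3f kcal/mol [%.3f, %.3f]", target,
        est@dG0Water, est@predictionInterval[1], est@predictionInterval[2]))
      results[[length(results) + 1L]] <- list(stage = "stability",
                                              estimate = est)
    } else if (st$stage == "network") {
      traj <- readTrajectory(need_input(out_path(st$trajectory), "network"))
      k <- if (is.null(st$k)) 6 else st$k
      mf <- if (is.null(st$max_frames)) 2000 else st$max_frames
      C <- generalizedCorrelation(traj, k = k, maxFrames = mf)
      net <- buildNetwork(
        C, traj,
        contactCutoff = if (is.null(st$contact_cutoff)) 10
                        else st$contact_cutoff,
        occupancy = if (is.null(st$occupancy)) 0.75 else st$occupancy,
        floor = if (is.null(st$floor)) 0.01 else st$floor)
      part <- communities(net)
      prof <- rmsf(traj)
      prefix <- out_path(if (is.null(st$output_prefix)) "network"
                         else st$output_prefix)
      writeNetworkEdges(net, paste0(prefix, "_edges.csv"))
      writeCommunityTable(part, paste0(prefix, "_communities.csv"))
      write_table_deterministic(
        data.frame(residue = prof@residueIds, rmsf_A = prof@rmsf),
        paste0(prefix, "_rmsf.csv"))
      summary_lines <- c(summary_lines, sprintf(
        "network: %d edges, %d communities (modularity %.3f)",
        nrow(net@edges), length(unique(part@membership)), part@modularity))
      results[[length(results) + 1L]] <- list(stage = "network", net = net,
                                              partition = part, rmsf = prof)
    } else if (st$stage == "report") {
      header <- c("DomainCoupling pipeline report",
                  sprintf("seed: %d", config$seed), "")
      writeLines(c(header, summary_lines), out_path(st$output))
      results[[length(results) + 1L]] <- list(stage = "report",
                                              lines = summary_lines)
    }
    pipeline_log(logcon, "INFO", "stage ", st$stage, " done")
  }
  invisible(results)
}

# 'simulate' stage: what = uptake | ex1 | unfolding | trajectory
run_simulate_stage <- function(st, config, out_path) {
  what <- st$what
  p <- st$params
  if (is.null(what) || is.null(p))
    stop("simulate stage needs 'what' and 'params'")
  seed <- if (is.null(p$seed)) config$seed else p$seed
  if (what == "uptake") {
    spec <- uptakeSimSpec(
      A0 = p$A0, amplitudes = unlist(p$amplitudes),
      rates = unlist(p$rates),
      noiseSd = if (is.null(p$noise_sd)) 1 else p$noise_sd,
      timepoints = if (is.null(p$timepoints)) c(10, 240, 1200)
                   else unlist(p$timepoints),
      nReplicates = if (is.null(p$n_replicates)) 3 else p$n_replicates,
      seed = seed)
    pep <- PeptideRecord(if (is.null(p$state)) "sim" else p$state, 1L, 10L)
    s <- simulateUptake(spec, peptide = pep)
    writeUptakeTable(list(s), out_path(st$output))
    list(stage = "simulate", series = s,
         summary = sprintf("simulate uptake (%s): planted k = %s /s",
                           pep@state,
                           paste(signif(spec@rates, 4), collapse = ", ")))
  } else if (what == "ex1") {
    spec <- ex1SimSpec(
      ku = p$ku,
      timepoints = if (is.null(p$timepoints)) c(0, 60, 240, 600, 1200)
                   else unlist(p$timepoints),
      noiseSd = if (is.null(p$noise_sd)) 0.02 else p$noise_sd, seed = seed)
    pep <- PeptideRecord(if (is.null(p$state)) "sim" else p$state, 1L, 10L)
    env <- simulateEx1Envelopes(spec, peptide = pep)
    manifest <- writeEnvelopeSeries(env, dirname(out_path(st$output)),
                                    prefix = sub("\\.csv$", "",
                                                 basename(st$output)))
    file.copy(manifest, out_path(st$output), overwrite = TRUE)
    list(stage = "simulate", env = env,
         summary = sprintf("simulate ex1: planted k_u = %g /s", spec@ku))
  } else if (what == "unfolding") {
    spec <- stabilitySimSpec(
      dG0 = p$dG0, mValue = p$m_value,
      noiseSd = if (is.null(p$noise_sd)) 0 else p$noise_sd, seed = seed)
    axis <- if (is.null(p$axis)) seq(0, 6, by = 0.5) else unlist(p$axis)
    Tk <- if (is.null(p$temperature_K)) 293.15 else p$temperature_K
    cv <- simulateUnfoldingCurve(spec, axis, temperature = Tk)
    writeUnfoldingCurve(cv, out_path(st$output))
    list(stage = "simulate", curve = cv,
         summary = sprintf("simulate unfolding: planted dG0 = %g, m = %g",
                           spec@dG0, spec@mValue))
  } else if (what == "trajectory") {
    n <- p$n_residues
    comms <- if (is.null(p$communities)) list(seq_len(n))
             else lapply(p$communities, function(cm) cm[1]:cm[2])
    spec <- trajectorySimSpec(
      nResidues = n,
      nFrames = if (is.null(p$n_frames)) 1000 else p$n_frames,
      communities = comms,
      intraCorr = if (is.null(p$intra_corr)) 0.8 else p$intra_corr,
      interCorr = if (is.null(p$inter_corr)) 0.1 else p$inter_corr,
      fluctuationSd = if (is.null(p$fluctuation_sd)) 0.5
                      else p$fluctuation_sd,
      seed = seed)
    traj <- simulateTrajectory(spec)
    writeTrajectoryCSV(traj, out_path(st$output))
    list(stage = "simulate", traj = traj,
         summary = sprintf(
           "simulate trajectory: %d residues x %d frames, %d communities",
           spec@nResidues, spec@nFrames, length(comms)))
  } else stop("unknown simulate target '", what, "'")
}
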
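# Pipeline orchestration: simulate -> idealize -> classify -> histogram ->
# I-V fits -> total conductance -> reversal -> GHK -> pore (-> swelling),
# with a plain-text log and TSV result tables carrying provenance headers.

PIPELINE_STAGES <- c("simulate", "idealize", "classify", "histogram",
                     "iv_fit", "total_g", "ramp", "ghk", "pore", "swell")

#' Pipeline configuration
#'
#' Bundles every stage parameter of [run_pipeline()] with a master seed and
#' a set of stage toggles. Per-trace RNG streams are derived
#' deterministically from the master seed so that adding traces never
#' perturbs earlier streams.
#'
#' @param out_dir output directory (created if absent); traces, tables and
#'   the log are written beneath it.
#' @param seed master integer seed.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "idealize", "classify", "histogram", "iv_fit",
#'   "total_g", "ramp", "ghk", "pore", "swell")`.
#' @param model [channel_model()] used by the simulate stage.
#' @param step_voltages_mV step-protocol voltages (mV).
#' @param step_duration_s,step_sample_rate_Hz duration and sampling rate of
#'   each constant-voltage trace.
#' @param n_ramps,ramp_range_mV,ramp_duration_s,ramp_sample_rate_Hz ramp
#'   protocol settings; successive ramps alternate direction, as in a
#'   back-and-forth ramp series.
#' @param sym_buffer,asym_buffer [buffer_condition()]s for the step
#'   (symmetric) and ramp (asymmetric) recordings.
#' @param idealization [idealization_params()].
#' @param classes [class_defs()].
#' @param bin_width_pS histogram bin width (pS).
#' @param hille [hille_params()], or `NULL` to build one from the largest
#'   fitted class-II slope.
#' @param ghk_e_rev_mV optional reversal potential (mV) for a ghk-only run;
#'   by default the ramp stage's pooled estimate is used.
#' @param swelling optional named list of [swelling_params()] for the swell
#'   stage, e.g. `list(positive = ..., negative = ...)`.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = setdiff(PIPELINE_STAGES, "swell"),
                            model = tic20_channel_model(),
                            step_voltages_mV = seq(-140, 140, by = 20),
                            step_duration_s = 10,
                            step_sample_rate_Hz = 5000,
                            n_ramps = 16,
                            ramp_range_mV = c(-100, 100),
                            ramp_duration_s = 20,
                            ramp_sample_rate_Hz = 2000,
                            sym_buffer = buffer_condition(250, 250),
                            asym_buffer = buffer_condition(250, 20),
                            idealization = idealization_params(),
                            classes = class_defs(),
                            bin_width_pS = 25,
                            hille = NULL,
                            ghk_e_rev_mV = NULL,
                            swelling = NULL) {
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop_invalid("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
         model = model, step_voltages_mV = step_voltages_mV,
         step_duration_s = step_duration_s,
         step_sample_rate_Hz = step_sample_rate_Hz, n_ramps = n_ramps,
         ramp_range_mV = ramp_range_mV, ramp_duration_s = ramp_duration_s,
         ramp_sample_rate_Hz = ramp_sample_rate_Hz, sym_buffer = sym_buffer,
         asym_buffer = asym_buffer, idealization = idealization,
         classes = classes, bin_width_pS = bin_width_pS, hille = hille,
         ghk_e_rev_mV = ghk_e_rev_mV, swelling = swelling),
    class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, logging every stage and
#' warning to `<out_dir>/pipeline.log`, writing each stage's table as TSV
#' with a `# key=value` provenance header, and returning a consolidated
#' report. Identical `(config, seed)` yield byte-identical result tables. A
#' stage error halts the pipeline with the stage name; tables already
#' written are preserved.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `"analysis_report"` with (depending on the
#'   enabled stages) `total_conductance`, `class_fits`, `histograms`,
#'   `reversal`, `selectivity`, `pore`, `swelling`, `events`, plus
#'   `stage_status` and `provenance` (seed, stage list, package version).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_invalid("'config' must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  traces_dir <- file.path(config$out_dir, "traces")
  dir.create(traces_dir, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)
  logln <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  status <- data.frame(stage = character(0), status = character(0))
  note <- function(stage, st) {
    status <<- rbind(status, data.frame(stage = stage, status = st))
  }
  env <- new.env(parent = emptyenv())
  prov <- c(seed = config$seed,
            stages = paste(config$stages, collapse = ","),
            package_version = as.character(utils::packageVersion("bilayertools")))

  run_stage <- function(name, expr) {
    if (!(name %in% config$stages)) {
      note(name, "skipped")
      return(invisible(NULL))
    }
    logln("stage ", name, ": start")
    tryCatch(
      withCallingHandlers(expr, warning = function(w) {
        logln("stage ", name, ": warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        note(name, "failed")
        logln("stage ", name, ": error: ", conditionMessage(e))
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    note(name, "ok")
    logln("stage ", name, ": done")
    invisible(NULL)
  }

  run_stage("simulate", {
    logln(sprintf("  model: %d levels, P_K/P_Cl = %g, noise %g pA",
                  length(config$model$levels), config$model$permeability_ratio,
                  config$model$noise_sd_pA))
    env$step_traces <- lapply(seq_along(config$step_voltages_mV), function(i) {
      v <- config$step_voltages_mV[i]
      prot <- voltage_protocol("step", v, v, config$step_duration_s)
      path <- sample_state_path(config$model, config$step_duration_s,
                                seed = derive_seed(config$seed, 2L * i))
      tr <- render_current(path, config$model, prot, config$sym_buffer,
                           config$step_sample_rate_Hz,
                           seed = derive_seed(config$seed, 2L * i + 1L),
                           trace_id = sprintf("step_%+04d_mV", v))
      write_trace(tr, file.path(traces_dir, paste0(tr$trace_id, ".tsv")))
      attr(tr, "state_path") <- path
      tr
    })
    off <- 2L * length(config$step_voltages_mV) + 2L
    env$ramp_traces <- lapply(seq_len(config$n_ramps), function(j) {
      ends <- if (j %% 2L == 1L) config$ramp_range_mV
              else rev(config$ramp_range_mV)
      prot <- voltage_protocol("ramp", ends[1L], ends[2L],
                               config$ramp_duration_s)
      path <- sample_state_path(config$model, config$ramp_duration_s,
                                seed = derive_seed(config$seed, off + 2L * j))
      tr <- render_current(path, config$model, prot, config$asym_buffer,
                           config$ramp_sample_rate_Hz,
                           seed = derive_seed(config$seed, off + 2L * j + 1L),
                           trace_id = sprintf("ramp_%02d", j))
      write_trace(tr, file.path(traces_dir, paste0(tr$trace_id, ".tsv")))
      tr
    })
  })

  run_stage("idealize", {
    if (is.null(env$step_traces)) {
      files <- list.files(traces_dir, pattern = "^step_.*\\.tsv$",
                          full.names = TRUE)
      if (!length(files))
        stop("no step traces available (enable the simulate stage or ",
             "populate ", traces_dir, ")")
      env$step_traces <- lapply(files, read_trace)
    }
    env$ideals <- lapply(env$step_traces, idealize_trace,
                         params = config$idealization)
    env$events <- do.call(rbind, lapply(seq_along(env$ideals), function(i) {
      extract_gating_events(env$ideals[[i]], env$step_traces[[i]],
                            config$idealization)
    }))
    segs <- do.call(rbind, lapply(env$ideals, function(id)
      cbind(trace_id = id$trace_id, id$segments)))
    write_result_tsv(segs, file.path(config$out_dir, "segments.tsv"),
                     c(prov, stage = "idealize",
                       threshold_k = config$idealization$threshold_k,
                       min_dwell_s = config$idealization$min_dwell_s))
    write_result_tsv(env$events, file.path(config$out_dir, "events.tsv"),
                     c(prov, stage = "idealize"))
    logln(sprintf("  %d traces -> %d events", length(env$ideals),
                  nrow(env$events)))
  })

  run_stage("classify", {
    if (is.null(env$events)) stop("no events (enable the idealize stage)")
    env$events <- assign_classes(env$events, config$classes)
    write_result_tsv(env$events,
                     file.path(config$out_dir, "classed_events.tsv"),
                     c(prov, stage = "classify"))
  })

  run_stage("histogram", {
    if (is.null(env$events)) stop("no events (enable the idealize stage)")
    env$histograms <- lapply(c("negative", "positive"), function(p)
      conductance_histogram(env$events, p, config$bin_width_pS))
    names(env$histograms) <- c("negative", "positive")
    hg <- do.call(rbind, lapply(env$histograms, function(h) {
      if (!length(h$counts)) return(NULL)
      data.frame(polarity = h$polarity,
                 bin_lo_pS = h$bin_edges_pS[-length(h$bin_edges_pS)],
                 bin_hi_pS = h$bin_edges_pS[-1L], count = h$counts)
    }))
    write_result_tsv(hg %||% data.frame(),
                     file.path(config$out_dir, "histograms.tsv"),
                     c(prov, stage = "histogram",
                       bin_width_pS = config$bin_width_pS))
  })

  run_stage("iv_fit", {
    if (is.null(env$events$class_id)) stop("events not classified")
    env$class_fits <- fit_class_iv(env$events)
    write_result_tsv(env$class_fits,
                     file.path(config$out_dir, "class_fits.tsv"),
                     c(prov, stage = "iv_fit"))
  })

  run_stage("total_g", {
    if (is.null(env$ideals)) stop("no idealized traces")
    env$total_g <- fully_open_conductance(env$ideals)
    tg <- env$total_g
    write_result_tsv(
      data.frame(polarity = c("negative", "positive"),
                 g_pS = c(tg$g_neg_pS, tg$g_pos_pS),
                 se_pS = c(tg$se_neg_pS, tg$se_pos_pS),
                 n_voltages = as.integer(tg$n_voltages)),
      file.path(config$out_dir, "total_conductance.tsv"),
      c(prov, stage = "total_g"))
  })

  run_stage("ramp", {
    if (is.null(env$ramp_traces)) {
      files <- list.files(traces_dir, pattern = "^ramp_.*\\.tsv$",
                          full.names = TRUE)
      if (!length(files)) stop("no ramp traces available")
      env$ramp_traces <- lapply(files, read_trace)
    }
    env$reversal <- find_reversal_potential(env$ramp_traces)
    write_result_tsv(
      data.frame(ramp = seq_len(env$reversal$n_ramps),
                 e_rev_mV = env$reversal$per_ramp_mV),
      file.path(config$out_dir, "reversal.tsv"),
      c(prov, stage = "ramp",
        e_rev_mV = sprintf("%.6g", env$reversal$e_rev_mV),
        sem_mV = sprintf("%.6g", env$reversal$sem_mV)))
    logln(sprintf("  E_rev = %.2f +/- %.2f mV over %d ramps",
                  env$reversal$e_rev_mV, env$reversal$sem_mV,
                  env$reversal$n_ramps))
  })

  run_stage("ghk", {
    e_rev <- config$ghk_e_rev_mV %||% env$reversal$e_rev_mV
    if (is.null(e_rev))
      stop("no reversal potential (enable the ramp stage or set ghk_e_rev_mV)")
    env$selectivity <- ghk_permeability_ratio(e_rev, config$asym_buffer)
    write_result_tsv(
      data.frame(e_rev_mV = e_rev,
                 permeability_ratio = env$selectivity$permeability_ratio),
      file.path(config$out_dir, "selectivity.tsv"),
      c(prov, stage = "ghk"))
  })

  run_stage("pore", {
    hp <- config$hille
    if (is.null(hp)) {
      if (is.null(env$class_fits) || !nrow(env$class_fits))
        stop("no hille_params given and no class fits to take g from")
      hp <- hille_params(max(env$class_fits$slope_conductance_pS))
    }
    env$pore <- hille_pore_diameter(hp)
    write_result_tsv(
      data.frame(variant = hp$variant, conductance_pS = hp$conductance_pS,
                 length_min_nm = hp$length_min_nm,
                 length_max_nm = hp$length_max_nm,
                 diameter_min_A = env$pore$diameter_min_A,
                 diameter_max_A = env$pore$diameter_max_A),
      file.path(config$out_dir, "pore.tsv"),
      c(prov, stage = "pore"))
  })

  run_stage("swell", {
    if (is.null(config$swelling)) stop("no swelling parameters configured")
    env$swelling <- lapply(names(config$swelling), function(nm) {
      summarize_swelling(simulate_swelling(config$swelling[[nm]]))
    })
    names(env$swelling) <- names(config$swelling)
    write_result_tsv(
      do.call(rbind, lapply(names(env$swelling), function(nm) {
        s <- env$swelling[[nm]]
        data.frame(label = nm, od_baseline = s$od_baseline,
                   od_min = s$od_min,
                   recovery_slope_per_min = s$recovery_slope_per_min,
                   call = s$call)
      })),
      file.path(config$out_dir, "swelling.tsv"),
      c(prov, stage = "swell"))
  })

  structure(
    list(total_conductance = env$total_g, class_fits = env$class_fits,
         histograms = env$histograms, reversal = env$reversal,
         selectivity = env$selectivity, pore = env$pore,
         swelling = env$swelling, events = env$events,
         stage_status = status,
         provenance = as.list(prov)),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report\n")
  for (i in seq_len(nrow(x$stage_status)))
    cat(sprintf("  %-9s %s\n", x$stage_status$stage[i],
                x$stage_status$status[i]))
  if (!is.null(x$total_conductance)) print(x$total_conductance)
  if (!is.null(x$reversal)) print(x$reversal)
  if (!is.null(x$selectivity)) print(x$selectivity)
  if (!is.null(x$pore)) print(x$pore)
  invisible(x)
}
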
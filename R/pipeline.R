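#' Run configuration for the end-to-end pipeline
#'
#' One structured object drives stimulus synthesis, sequence generation,
#' EEG simulation, ERP processing, MMN quantification and model fitting.
#' Every stochastic stage derives its own child seed from the master seed,
#' so re-running a config is fully deterministic.
#'
#' @param n_per_domain simulated participants per domain.
#' @param lead_in,train_lengths,reps_per_length,soa roving-plan parameters
#'   (see [roving_plan()]).
#' @param sample_rate simulated EEG rate in Hz.
#' @param target_rate rate after downsampling (must divide
#'   \code{sample_rate}).
#' @param channels montage channel labels.
#' @param mmn_amplitudes data frame (domain, dimension, deviant,
#'   amplitude_uv) of injected MMN peak amplitudes in microvolts.
#' @param mmn_shape \code{"gaussian"} or \code{"rect"}.
#' @param mmn_width Gaussian SD in ms.
#' @param short_duration_ms durational change onset (short-stimulus
#'   duration).
#' @param erp base [erp_component()] list added to every event.
#' @param noise a [noise_spec()] for the EEG background.
#' @param artifact_rate per-event artifact probability.
#' @param filter apply the 0.2-40 Hz band-pass (disable for analytic
#'   zero-noise runs where the injected waveform must survive untouched).
#' @param smooth apply Savitzky-Golay smoothing to difference waves.
#' @param reject_threshold_uv epoch rejection threshold.
#' @param seed master seed.
#' @return a \code{run_config} list.
#' @export
run_config <- function(n_per_domain = 4, lead_in = 8, train_lengths = 4:8,
                       reps_per_length = 20, soa = 1.09, sample_rate = 3000,
                       target_rate = 300, channels = default_channels(),
                       mmn_amplitudes = default_mmn_amplitudes(),
                       mmn_shape = "gaussian", mmn_width = 25,
                       short_duration_ms = 180,
                       erp = list(erp_component(100, 30, 4),
                                  erp_component(200, 40, -2)),
                       noise = noise_spec(exponent = 1, rms = 10),
                       artifact_rate = 0, filter = TRUE, smooth = TRUE,
                       reject_threshold_uv = 50, seed = 1L) {
  cfg <- list(n_per_domain = n_per_domain, lead_in = lead_in,
              train_lengths = train_lengths,
              reps_per_length = reps_per_length, soa = soa,
              sample_rate = sample_rate, target_rate = target_rate,
              channels = channels, mmn_amplitudes = mmn_amplitudes,
              mmn_shape = mmn_shape, mmn_width = mmn_width,
              short_duration_ms = short_duration_ms, erp = erp,
              noise = noise, artifact_rate = artifact_rate, filter = filter,
              smooth = smooth, reject_threshold_uv = reject_threshold_uv,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Default injected MMN peak amplitudes (microvolts)
#'
#' Same qualitative pattern as [default_cell_means()] scaled to waveform
#' peak amplitude: asymmetric deviants only in the speech-spectral cell.
#'
#' @return data frame with domain, dimension, deviant, amplitude_uv.
#' @export
default_mmn_amplitudes <- function() {
  cm <- default_cell_means()
  data.frame(cm[, c("domain", "dimension", "deviant")],
             amplitude_uv = cm$mean / 100, stringsAsFactors = FALSE)
}

block_stimuli <- function(domain, dimension) {
  pre <- if (domain == "speech") "f" else "t"
  if (dimension == "spectral") {
    list(stim_a = paste0(pre, "e220"), stim_b = paste0(pre, "a220"))
  } else {
    list(stim_a = paste0(pre, "e180"), stim_b = paste0(pre, "e360"))
  }
}

block_stim_meta <- function(domain) {
  pre <- if (domain == "speech") "f" else "t"
  data.frame(
    label = paste0(pre, c("e220", "a220", "e180", "e360")),
    dimension = c("spectral", "spectral", "durational", "durational"),
    prominence = c("non-prominent", "prominent", "non-prominent", "prominent"),
    duration_ms = c(220, 220, 180, 360), stringsAsFactors = FALSE)
}

#' Simulate one participant block (continuous EEG)
#'
#' Builds the roving sequence for the requested domain and dimension,
#' configures per-stimulus MMN components from the config's amplitude
#' table, and renders the continuous recording.
#'
#' @param config a [run_config()].
#' @param participant participant id string.
#' @param domain \code{"speech"} or \code{"tone"}.
#' @param dimension \code{"spectral"} or \code{"durational"}.
#' @return an \code{eeg_recording} (with \code{$events}).
#' @export
simulate_block <- function(config, participant, domain, dimension) {
  stims <- block_stimuli(domain, dimension)
  meta <- block_stim_meta(domain)
  seed_block <- child_seed(config$seed, paste(participant, domain, dimension))
  plan <- roving_plan(stim_a = stims$stim_a, stim_b = stims$stim_b,
                      lead_in = config$lead_in,
                      train_lengths = config$train_lengths,
                      reps_per_length = config$reps_per_length,
                      soa = config$soa, seed = child_seed(seed_block, "plan"))
  events <- generate_sequence(plan)
  onset_ms <- if (domain == "speech") 150 else 0
  carrier <- stats::setNames(rep(onset_ms, 2), c(stims$stim_a, stims$stim_b))
  amp_of <- function(label) {
    prom <- meta$prominence[match(label, meta$label)]
    a <- config$mmn_amplitudes
    a$amplitude_uv[a$domain == domain & a$dimension == dimension &
                   a$deviant == prom]
  }
  change <- if (dimension == "spectral") 0 else config$short_duration_ms
  mmn <- lapply(stats::setNames(nm = c(stims$stim_a, stims$stim_b)),
                function(lb) mmn_component(amplitude = amp_of(lb),
                                           change_onset = change,
                                           shape = config$mmn_shape,
                                           width = config$mmn_width))
  rec <- simulate_recording(events, carrier, erp = config$erp, mmn = mmn,
                            noise = config$noise,
                            montage = montage_spec(config$channels),
                            sample_rate = config$sample_rate,
                            seed = seed_block)
  if (config$artifact_rate > 0)
    rec <- inject_artifacts(rec, config$artifact_rate,
                            seed = seed_block)$recording
  rec$participant <- participant
  rec$domain <- domain
  rec$dimension <- dimension
  rec
}

#' Preprocess one recording into its per-channel MMN rows
#'
#' The full ERP chain: band-pass filter, downsample, epoch around carrier
#' onset, baseline-correct, reject supra-threshold trials, average by
#' stimulus and role, and measure windowed difference-wave AUCs on the
#' analysis grid.
#'
#' @param rec an \code{eeg_recording} from [simulate_block()].
#' @param config a [run_config()].
#' @param channels channels to measure (defaults to the intersection of
#'   the montage with [analysis_grid()]).
#' @return list with \code{mmn} (table rows), \code{erps}, \code{rejection}
#'   (counts and log).
#' @export
process_block <- function(rec, config, channels = NULL) {
  if (is.null(channels))
    channels <- intersect(rec$channels, analysis_grid())
  if (config$filter) rec <- bandpass(rec)
  rec <- downsample(rec, config$target_rate)
  ep <- epoch(rec)
  ep <- baseline_correct(ep)
  rj <- reject(ep, threshold = config$reject_threshold_uv)
  erps <- average_epochs(rj$epochs)
  win <- window_for(rec$dimension, config$short_duration_ms)
  tab <- build_mmn_table(erps, rec$participant, rec$domain, rec$dimension,
                         block_stim_meta(rec$domain), channels = channels,
                         window = win, smooth = config$smooth)
  list(mmn = tab, erps = erps,
       rejection = rj[c("n_extracted", "n_retained", "n_rejected")],
       rejection_log = rj$log)
}

#' Run the full pipeline for every participant and block
#'
#' Simulates all participants (domain between participants, dimension
#' within), processes every block, assembles the pooled MMN table, fits the
#' mixed model and summarizes cell means and asymmetry flags. When
#' \code{out_dir} is given, writes \code{events/*.tsv}, \code{mmn.csv},
#' \code{fixed_effects.csv}, \code{cell_means.csv},
#' \code{asymmetry.csv} and a JSON \code{manifest.json} with seeds and
#' per-stage counts; outputs are byte-identical across re-runs of the same
#' config.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param fit_method method for [fit_mmn_model()].
#' @return list with \code{mmn_table}, \code{fit}, \code{cell_means},
#'   \code{asymmetry}, \code{log}.
#' @export
run_all <- function(config, out_dir = NULL, fit_method = "lmm") {
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "events"), recursive = TRUE,
               showWarnings = FALSE)
  }
  tabs <- list(); log <- list()
  for (domain in c("speech", "tone")) {
    for (p in seq_len(config$n_per_domain)) {
      participant <- sprintf("%s-%02d", substr(domain, 1, 2), p)
      for (dimension in c("spectral", "durational")) {
        rec <- simulate_block(config, participant, domain, dimension)
        if (!is.null(out_dir))
          write_events(rec$events,
                       file.path(out_dir, "events",
                                 sprintf("%s_%s.tsv", participant, dimension)))
        res <- process_block(rec, config)
        tabs[[length(tabs) + 1]] <- res$mmn
        log[[length(log) + 1]] <- data.frame(
          participant = participant, domain = domain, dimension = dimension,
          n_events = nrow(rec$events), n_extracted = res$rejection$n_extracted,
          n_retained = res$rejection$n_retained,
          n_rejected = res$rejection$n_rejected, stringsAsFactors = FALSE)
      }
    }
  }
  mmn_table <- do.call(rbind, tabs)
  log <- do.call(rbind, log)
  fit <- fit_mmn_model(mmn_table, method = fit_method)
  cm <- estimate_cell_means(fit)
  fl <- asymmetry_flags(cm)
  if (!is.null(out_dir)) {
    utils::write.csv(mmn_table, file.path(out_dir, "mmn.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$coefficients, file.path(out_dir, "fixed_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(cm, file.path(out_dir, "cell_means.csv"),
                     row.names = FALSE)
    utils::write.csv(fl, file.path(out_dir, "asymmetry.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_per_domain = config$n_per_domain,
           sample_rate = config$sample_rate,
           target_rate = config$target_rate,
           fit_method = fit_method, singular = fit$singular,
           counts = log),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(mmn_table = mmn_table, fit = fit, cell_means = cm, asymmetry = fl,
       log = log)
}

#' Ready-made fixture configurations
#'
#' Three scales of the same design: \code{tiny} (seconds of simulated EEG:
#' two short trains per stimulus, 4 channels, 500 Hz) for unit tests,
#' \code{demo} (minutes-scale: 2 trains per length 4-5, 9-channel grid,
#' 900 Hz) for end-to-end checks, and \code{full} (the complete 1208-event,
#' 31-channel, 3000-Hz block design).
#'
#' @param size \code{"tiny"}, \code{"demo"} or \code{"full"}.
#' @param seed master seed.
#' @return list with \code{config} (a [run_config()]) and \code{events}
#'   (one example spectral-block event list per domain).
#' @export
make_fixtures <- function(size = c("tiny", "demo", "full"), seed = 1L) {
  size <- match.arg(size)
  config <- switch(size,
    tiny = run_config(n_per_domain = 1, lead_in = 2, train_lengths = 4:5,
                      reps_per_length = 1, soa = 1.09, sample_rate = 500,
                      target_rate = 250,
                      channels = c("F3", "Fz", "Cz", "Pz"),
                      noise = noise_spec(1, 2), seed = seed),
    demo = run_config(n_per_domain = 2, lead_in = 4, train_lengths = 4:5,
                      reps_per_length = 2, sample_rate = 900,
                      target_rate = 300, channels = analysis_grid(),
                      noise = noise_spec(1, 5), seed = seed),
    full = run_config(n_per_domain = 16, seed = seed)
  )
  events <- lapply(stats::setNames(nm = c("speech", "tone")), function(dm) {
    stims <- block_stimuli(dm, "spectral")
    generate_sequence(roving_plan(
      stim_a = stims$stim_a, stim_b = stims$stim_b,
      lead_in = config$lead_in, train_lengths = config$train_lengths,
      reps_per_length = config$reps_per_length, soa = config$soa,
      seed = child_seed(seed, paste0("fixture", dm))))
  })
  list(size = size, config = config, events = events)
}
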
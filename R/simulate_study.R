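#' Default generating cell means for simulation studies
#'
#' Per-condition mean AUC (microvolt-ms) of the study-level generative
#' model. The default pattern carries an asymmetry only in the
#' speech-spectral cell (a strongly negative MMN to the prominent deviant,
#' a weak one to the non-prominent deviant) and symmetric deviants
#' everywhere else, mirroring the qualitative result structure the pipeline
#' is designed to detect.
#'
#' @return data frame with domain, dimension, deviant, mean columns.
#' @export
default_cell_means <- function() {
  data.frame(
    domain = rep(c("speech", "tone"), each = 4),
    dimension = rep(rep(c("spectral", "durational"), each = 2), 2),
    deviant = rep(c("prominent", "non-prominent"), 4),
    mean = c(-95, -17, -44, -44, -48, -48, -48, -48),
    stringsAsFactors = FALSE
  )
}

#' Null cell means (no condition effects)
#' @param level common mean AUC for every cell.
#' @return data frame as [default_cell_means()].
#' @export
null_cell_means <- function(level = -48) {
  cm <- default_cell_means()
  cm$mean <- level
  cm
}

#' Default additive channel offsets over the analysis grid
#'
#' Encodes the frontally maximal MMN topography as additive per-channel
#' offsets (microvolt-ms), centered to zero mean so the grand intercept is
#' untouched: frontal rows more negative than central, parietal rows more
#' positive, plus a small right-minus-left and midline-versus-lateral
#' structure.
#'
#' @return named numeric vector over [analysis_grid()].
#' @export
default_channel_offsets <- function() {
  ant <- c(F = -46, C = 0, P = 31)
  lat <- c(left = -4, right = 4, midline = -20)
  grid <- analysis_grid()
  off <- ant[substr(grid, 1, 1)] + lat[laterality_of(grid)]
  off <- off - mean(off)
  stats::setNames(off, grid)
}

#' Noise model of the study-level generator
#'
#' Standard deviations (microvolt-ms) of the participant random intercept,
#' the per-participant Dimension and Deviant slopes, and the residual AUC
#' noise per table row. The defaults are deliberately generous (high SNR):
#' they are calibrated so that detecting the default speech-spectral
#' asymmetry with 16 participants per domain has power near 1, which is
#' what makes the recovery studies sharp tests of the machinery rather
#' than of sampling luck.
#'
#' @param sd_intercept,sd_dimension,sd_deviant,sd_resid SDs in
#'   microvolt-ms.
#' @return a \code{study_noise} list.
#' @export
study_noise <- function(sd_intercept = 40, sd_dimension = 30,
                        sd_deviant = 30, sd_resid = 90) {
  structure(list(sd_intercept = sd_intercept, sd_dimension = sd_dimension,
                 sd_deviant = sd_deviant, sd_resid = sd_resid),
            class = "study_noise")
}

#' Simulate an MMN table directly from the study-level model
#'
#' Generates the per-participant x condition x channel AUC table from the
#' same linear structure the statistical model assumes: cell mean plus
#' additive channel offset plus participant random intercept and
#' Dimension/Deviant slopes plus residual noise. Domain varies between
#' participants (16 per domain by default), dimension and deviant within.
#' This is the fast testbed for parameter-recovery, type-I and power
#' studies; the waveform-level generator ([simulate_recording()]) feeds the
#' same table format through the full signal chain at smaller scale.
#'
#' @param n_per_domain participants per domain.
#' @param cell_means data frame as [default_cell_means()].
#' @param channel_offsets named numeric as [default_channel_offsets()].
#' @param noise a [study_noise()].
#' @param seed integer seed.
#' @return an \code{mmn_table} data frame.
#' @export
simulate_mmn_table <- function(n_per_domain = 16,
                               cell_means = default_cell_means(),
                               channel_offsets = default_channel_offsets(),
                               noise = study_noise(), seed = 1L) {
  set.seed(seed)
  channels <- names(channel_offsets)
  cells <- expand.grid(dimension = c("spectral", "durational"),
                       deviant = c("prominent", "non-prominent"),
                       channel = channels, stringsAsFactors = FALSE)
  rows <- vector("list", 2 * n_per_domain)
  pid <- 0
  for (domain in c("speech", "tone")) {
    for (p in seq_len(n_per_domain)) {
      pid <- pid + 1
      b0 <- stats::rnorm(1, 0, noise$sd_intercept)
      b_dim <- stats::rnorm(1, 0, noise$sd_dimension)
      b_dev <- stats::rnorm(1, 0, noise$sd_deviant)
      mu <- cell_means$mean[match(
        paste(domain, cells$dimension, cells$deviant),
        paste(cell_means$domain, cell_means$dimension, cell_means$deviant))]
      dim_c <- ifelse(cells$dimension == "spectral", 0.5, -0.5)
      dev_c <- ifelse(cells$deviant == "non-prominent", 0.5, -0.5)
      auc <- mu + channel_offsets[cells$channel] + b0 + b_dim * dim_c +
        b_dev * dev_c + stats::rnorm(nrow(cells), 0, noise$sd_resid)
      rows[[pid]] <- data.frame(
        participant = sprintf("sub-%02d", pid), domain = domain,
        dimension = cells$dimension, deviant = cells$deviant,
        channel = cells$channel, auc_uv_ms = unname(auc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mmn_table", "data.frame")
  out
}

#' True fixed effects implied by a generating configuration
#'
#' Maps cell means and channel offsets to the 12 fixed-effect coefficients
#' of the MMN model by solving the exactly balanced, noiseless design: the
#' coefficients a correct fit must recover.
#'
#' @inheritParams simulate_mmn_table
#' @return named numeric vector over [mmn_term_names()].
#' @export
true_fixed_effects <- function(cell_means = default_cell_means(),
                               channel_offsets = default_channel_offsets()) {
  grid <- expand.grid(domain = c("speech", "tone"),
                      dimension = c("spectral", "durational"),
                      deviant = c("prominent", "non-prominent"),
                      channel = names(channel_offsets),
                      stringsAsFactors = FALSE)
  grid$participant <- "truth"
  grid$auc_uv_ms <- cell_means$mean[match(
    paste(grid$domain, grid$dimension, grid$deviant),
    paste(cell_means$domain, cell_means$dimension, cell_means$deviant))] +
    channel_offsets[grid$channel]
  d <- build_design(grid)
  X <- stats::model.matrix(mmn_fixed_formula()[-2], data = d)
  beta <- qr.solve(crossprod(X), crossprod(X, d$auc_uv_ms))
  stats::setNames(drop(beta), colnames(X))
}

#' Replicated simulation-and-refit study
#'
#' Repeatedly simulates an MMN table from a known configuration, refits the
#' mixed model, and records the fixed-effect estimates, the three-way
#' interaction p-value, and the asymmetry flags per domain x dimension --
#' the engine behind the parameter-recovery, type-I-error and
#' power/asymmetry-detection checks.
#'
#' @param n_rep number of replicates.
#' @param seed integer master seed (replicate r uses a derived child seed).
#' @inheritParams simulate_mmn_table
#' @param method model fitting method, see [fit_mmn_model()].
#' @param df_method degrees-of-freedom method; the fast residual-df path
#'   is the default here because the study refits the model hundreds of
#'   times and the terms of interest carry around a thousand df, where
#'   residual and Satterthwaite tests coincide for practical purposes.
#' @return list with \code{estimates} (n_rep x 12 matrix),
#'   \code{p_threeway} (length n_rep), \code{asymmetry} (data frame of
#'   per-replicate flags), \code{truth} (named vector).
#' @export
run_recovery_study <- function(n_rep = 200, n_per_domain = 16,
                               cell_means = default_cell_means(),
                               channel_offsets = default_channel_offsets(),
                               noise = study_noise(), seed = 1L,
                               method = "lmm", df_method = "residual") {
  truth <- true_fixed_effects(cell_means, channel_offsets)
  est <- matrix(NA_real_, n_rep, length(truth),
                dimnames = list(NULL, names(truth)))
  p3 <- numeric(n_rep)
  asym <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    tab <- simulate_mmn_table(n_per_domain, cell_means, channel_offsets,
                              noise, seed = child_seed(seed, paste0("rep", r)))
    fit <- fit_mmn_model(tab, method = method, df_method = df_method)
    est[r, ] <- fit$coefficients$estimate[
      match(colnames(est), fit$coefficients$term)]
    p3[r] <- threeway_p(fit)
    fl <- asymmetry_flags(estimate_cell_means(fit))
    fl$replicate <- r
    asym[[r]] <- fl
  }
  list(estimates = est, p_threeway = p3, asymmetry = do.call(rbind, asym),
       truth = truth)
}
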
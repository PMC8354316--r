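#' Configuration of a synthetic EEG listening study
#'
#' Bundles every knob of the synthetic-study generator: panel size, stimulus
#' set, acquisition parameters, the per-stimulus coupling of the shared
#' alpha-band component, the per-stimulus valence that drives frontal alpha
#' asymmetry and ratings, and the log-linear outcome model that turns neural
#' coupling into streaming counts.
#'
#' Per-stimulus vectors (`shared_weight`, `valence`, `single_flag`,
#' `artist_label`) may be left `NULL`, in which case they are drawn or laid
#' out reproducibly from `seed` when the study is simulated: coupling weights
#' uniform on \[0.2, 0.8\], valence normal with SD 0.5, artists split 13/11
#' across two labels with the first four stimuli of each artist flagged as
#' promotional singles.
#'
#' @param n_subjects Number of panel participants (>= 2).
#' @param n_stimuli Number of music fragments.
#' @param duration_s Fragment duration in seconds.
#' @param fs Sampling rate in Hz; must exceed twice the 40 Hz gamma edge.
#' @param channels Ordered electrode labels (10/20 system). The default nine
#'   channels are assumed by the downstream metrics (C3/Cz/C4 for synchrony,
#'   F3/F4 for asymmetry).
#' @param shared_weight Per-stimulus coupling w in \[0,1\] of the common
#'   stimulus-locked alpha envelope; scalar values are recycled.
#' @param valence Per-stimulus scalar driving asymmetry and ratings.
#' @param single_flag Per-stimulus logical: released as a promotional single.
#' @param artist_label Per-stimulus factor with two levels.
#' @param beta0,beta_synch,beta_single Coefficients of the generative
#'   log-streams model (natural-log scale, streams in millions).
#' @param noise_sd Residual SD of the log-streams model.
#' @param growth_factor Multiplicative growth from the early to the late
#'   streaming horizon.
#' @param artifact_rate Expected number of high-amplitude (>400 uV)
#'   artifact excursions per minute of recording.
#' @param alpha_uv Mean amplitude (uV) of the alpha-band envelope.
#' @param pink_uv RMS (uV) of the 1/f background. The default (28 uV over a
#'   24 s fragment) makes the pink background's 8-12 Hz power match the
#'   shared alpha component's power at `shared_weight = 0.5`, i.e. an
#'   alpha-band SNR near 1 in the half-coupled regime.
#' @param white_uv RMS (uV) of broadband sensor noise.
#' @param engagement_loading Loading of stimulus valence on the latent
#'   engagement score; negative by default, so engagement falls as liking
#'   rises.
#' @param seed Integer seed; the whole study is a pure function of
#'   (config, seed).
#'
#' @return An object of class `study_config` (a named list).
#' @export
#' @examples
#' cfg <- study_config(n_subjects = 4, n_stimuli = 2, duration_s = 4)
#' cfg$fs
study_config <- function(n_subjects = 30,
                         n_stimuli = 24,
                         duration_s = 24,
                         fs = 256,
                         channels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                                      "P3", "POz", "P4"),
                         shared_weight = NULL,
                         valence = NULL,
                         single_flag = NULL,
                         artist_label = NULL,
                         beta0 = -19,
                         beta_synch = 0.7,
                         beta_single = 0.75,
                         noise_sd = 0.3,
                         growth_factor = 3.2,
                         artifact_rate = 1,
                         alpha_uv = 10,
                         pink_uv = 28,
                         white_uv = 2,
                         engagement_loading = -0.8,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_stimuli = as.integer(n_stimuli),
    duration_s = duration_s, fs = fs, channels = as.character(channels),
    shared_weight = shared_weight, valence = valence,
    single_flag = single_flag, artist_label = artist_label,
    beta0 = beta0, beta_synch = beta_synch, beta_single = beta_single,
    noise_sd = noise_sd, growth_factor = growth_factor,
    artifact_rate = artifact_rate, alpha_uv = alpha_uv, pink_uv = pink_uv,
    white_uv = white_uv, engagement_loading = engagement_loading,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
}

validate_study_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    abort(sprintf("Invalid study_config field `%s`: %s", field, msg),
          class = "neurosync_config_error")
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 2)
    stop_cfg("n_subjects", "need at least 2 subjects")
  if (is.na(cfg$n_stimuli) || cfg$n_stimuli < 1)
    stop_cfg("n_stimuli", "need at least 1 stimulus")
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0)
    stop_cfg("duration_s", "must be a positive duration in seconds")
  if (!is.numeric(cfg$fs) || cfg$fs <= 80)
    stop_cfg("fs", "sampling rate must exceed twice the 40 Hz gamma edge")
  if (anyDuplicated(cfg$channels))
    stop_cfg("channels", "labels must be unique")
  recycle <- function(x, field) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1L) x <- rep(x, cfg$n_stimuli)
    if (length(x) != cfg$n_stimuli)
      stop_cfg(field, sprintf("length must be 1 or n_stimuli (%d)",
                              cfg$n_stimuli))
    x
  }
  cfg$shared_weight <- recycle(cfg$shared_weight, "shared_weight")
  if (!is.null(cfg$shared_weight) &&
      (any(!is.finite(cfg$shared_weight)) ||
       any(cfg$shared_weight < 0 | cfg$shared_weight > 1)))
    stop_cfg("shared_weight", "coupling weights must lie in [0, 1]")
  cfg$valence <- recycle(cfg$valence, "valence")
  cfg$single_flag <- recycle(cfg$single_flag, "single_flag")
  cfg$artist_label <- recycle(cfg$artist_label, "artist_label")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0)
    stop_cfg("noise_sd", "must be a non-negative SD")
  if (!is.numeric(cfg$artifact_rate) || cfg$artifact_rate < 0)
    stop_cfg("artifact_rate", "must be a non-negative rate per minute")
  if (is.na(cfg$seed)) stop_cfg("seed", "must be an integer")
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %d subjects x %d stimuli, %g s @ %g Hz, %d channels\n",
    x$n_subjects, x$n_stimuli, x$duration_s, x$fs, length(x$channels)))
  cat(sprintf("  outcome model: log(streams) = %g + %g*synchrony + %g*single, sd %g\n",
              x$beta0, x$beta_synch, x$beta_single, x$noise_sd))
  invisible(x)
}
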
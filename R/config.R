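#' Default configuration for the staging pipeline
#'
#' All tunable constants of the pipeline live in one nested list. Every
#' printed constant of the staging cascade is a default here, never
#' hard-coded at its point of use, so a YAML config file can override any
#' of them.
#'
#' @param ... named overrides, either top-level sections (e.g.
#'   `staging = list(density_fraction = 0.2)`) or full replacement values.
#'   Overrides are merged recursively into the defaults.
#'
#' @return a nested named list with sections `welch`, `irasa`, `smooth`,
#'   `umap`, `kde`, `otsu`, `psp`, `so`, `artifact` and `staging`.
#'
#' @details Sections and their meaning:
#' \describe{
#'   \item{welch}{`segment_s` (segment length, s), `overlap` (fraction).}
#'   \item{irasa}{resampling factor grid `h_min`, `h_max`, `h_step`.}
#'   \item{smooth}{`sigma_time` (epochs), `sigma_freq` (Hz) of the 2-D
#'     Gaussian filter applied to the oscillatory component.}
#'   \item{umap}{`n_neighbors`, `min_dist`, `seed`, `standardize`
#'     (per-frequency-bin z-scoring before embedding, default off),
#'     `fmin`/`fmax` (Hz range of PSD columns fed to the embedder).}
#'   \item{kde}{`raw_bandwidth`: use the literal n^(-1/(4+d)) bandwidth
#'     without per-axis standard-deviation scaling.}
#'   \item{otsu}{`n_bins` of the histogram.}
#'   \item{psp}{`source` of the spindle power: "psd" (default, the raw PSD
#'     as the cascade prints it) or "psd_osc" (the oscillatory residual).}
#'   \item{so}{slow-oscillation detector: `band` (Hz), `transition`
#'     (filter transition width, Hz), amplitude/duration criteria.}
#'   \item{artifact}{`max_abs_uv`: epochs whose absolute amplitude exceeds
#'     this are excluded from slow-oscillation weighting.}
#'   \item{staging}{cascade constants: `gamma_band`, `density_fraction`,
#'     `spindle_search`, `spindle_target`, `spindle_pref` (preferred range
#'     for the peak), `so_weight_floor`, `kernel_size` (epochs),
#'     `min_rem_epochs` (runs at least this long stay REM),
#'     `literal_sign`, `distance` ("centroid" or "median_pairwise"),
#'     `resmooth` ("run" or "epoch").}
#' }
#' @export
ais_config <- function(...) {
  defaults <- list(
    welch = list(segment_s = 5, overlap = 0.5),
    irasa = list(h_min = 1.1, h_max = 1.9, h_step = 0.05),
    smooth = list(sigma_time = 1, sigma_freq = 0.5),
    umap = list(n_neighbors = 15, min_dist = 0.1, seed = 42L,
                standardize = FALSE, fmin = 0.2, fmax = 30),
    kde = list(raw_bandwidth = FALSE),
    otsu = list(n_bins = 256L),
    psp = list(source = "psd"),
    so = list(band = c(0.5, 2.0), transition = 0.2,
              ptp_min_uv = 75, neg_peak_max_uv = -10, pos_peak_min_uv = 10,
              neg_dur_s = c(0.3, 1.5), pos_dur_s = c(0.1, 1.0)),
    artifact = list(max_abs_uv = 500),
    staging = list(gamma_band = c(25, 50), density_fraction = 0.1,
                   spindle_search = c(5, 20), spindle_target = 14,
                   spindle_pref = c(12, 16), so_weight_floor = 0.10,
                   kernel_size = 20L, min_rem_epochs = 20L,
                   literal_sign = FALSE, distance = "nearest",
                   resmooth = "run")
  )
  merge_config(defaults, list(...))
}

# Recursive merge: values in `over` win; unnamed/unknown keys are added.
merge_config <- function(base, over) {
  if (length(over) == 0L) return(base)
  stopifnot(is.list(over))
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a YAML configuration file, merged over the defaults
#'
#' @param path YAML file; keys mirror the structure of [ais_config()].
#'   Missing keys fall back to defaults.
#' @return a full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(ais_config(), user)
}

#' Write a resolved configuration next to an output for provenance
#'
#' @param cfg configuration list.
#' @param path destination YAML file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
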
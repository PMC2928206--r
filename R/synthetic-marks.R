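#' Describe a synthetic histone mark
#'
#' A mark is defined by the spatial shape of its metagene template and by a
#' model for its per-gene amplitude. Template shapes are smooth functions of a
#' normalised position `u`, with the gene body mapped to `[0, 1]` and each
#' 2 kbp flank to a fixed quarter-body width on either side, so the same shape
#' evaluated at base pairs or at scaled bins yields consistent templates.
#'
#' Amplitude families:
#' * `"lognormal"` - `A = baseline + exp(meanlog + loading * z + sdlog * eps)`,
#'   the skewed marginal typical of ChIP enrichment;
#' * `"gaussian"` - `A = max(floor, center + loading * z + sd * eps)`, used
#'   where exact covariance algebra is needed;
#' * `"confounded"` - built by [make_confounded_repressor()]; parameters are
#'   the loadings of the expression model it must cancel against.
#'
#' `z` is the latent per-gene activity factor shared across marks.
#'
#' @param name mark name (unique within a panel).
#' @param shape one of `"tss_peak"`, `"body_ramp_3prime"`, `"body_uniform"`,
#'   `"bimodal_tss_tes"`.
#' @param shape_params named list overriding shape defaults (`baseline`,
#'   `height`, `width`, `slope`, `height3`).
#' @param amplitude named list selecting the amplitude family and parameters.
#' @return an object of class `cv_mark_spec`.
#' @export
mark_spec <- function(name,
                      shape = c("tss_peak", "body_ramp_3prime",
                                "body_uniform", "bimodal_tss_tes"),
                      shape_params = list(),
                      amplitude = list(family = "lognormal",
                                       meanlog = 0, sdlog = 0.5,
                                       loading = 0, baseline = 0)) {
  shape <- match.arg(shape)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, shape = shape,
                 shape_params = shape_params, amplitude = amplitude),
            class = "cv_mark_spec")
}

# Fraction of body width allotted to each flank in normalised-u space.
FLANK_FRAC <- 0.25

# Unnormalised template intensity as a function of normalised position u
# (body = [0,1], 5' flank = [-FLANK_FRAC, 0), 3' flank = (1, 1 + FLANK_FRAC]).
#' @noRd
shape_intensity <- function(shape, u, params = list()) {
  p <- function(key, default) params[[key]] %||% default
  switch(shape,
    body_uniform = rep(1, length(u)),
    tss_peak = p("baseline", 0.25) +
      p("height", 8) * exp(-u^2 / (2 * p("width", 0.05)^2)),
    body_ramp_3prime = p("baseline", 0.3) +
      p("slope", 2.5) * pmin(pmax(u, 0), 1),
    bimodal_tss_tes = p("baseline", 0.25) +
      p("height", 6) * exp(-u^2 / (2 * p("width", 0.05)^2)) +
      p("height3", 4) * exp(-(u - 1)^2 / (2 * p("width", 0.05)^2)),
    stop_invalid("unknown template_shape: ", shape)
  )
}

# Normalised positions for a flank5 | body | flank3 layout.
#' @noRd
layout_u <- function(n_body_bins, flank_bins) {
  u <- numeric(0)
  if (flank_bins > 0)
    u <- c(u, -FLANK_FRAC + FLANK_FRAC * (seq_len(flank_bins) - 0.5) / flank_bins)
  u <- c(u, (seq_len(n_body_bins) - 0.5) / n_body_bins)
  if (flank_bins > 0)
    u <- c(u, 1 + FLANK_FRAC * (seq_len(flank_bins) - 0.5) / flank_bins)
  u
}

#' Build a mark's true metagene template
#'
#' Evaluates the mark's shape over a `flank5 | scaled body | flank3` layout and
#' rescales so the mean over all positions is exactly 1, making the per-gene
#' amplitude interpretable as an effective per-bin read density.
#'
#' @param spec a [mark_spec()].
#' @param n_body_bins number of scaled gene-body bins (>= 2).
#' @param flank_bins number of bins per flank (>= 0).
#' @return object of class `cv_template`: list with `mark_id`, `values`,
#'   `n_body_bins`, `flank_bins`.
#' @export
make_true_template <- function(spec, n_body_bins, flank_bins = 0L) {
  if (!inherits(spec, "cv_mark_spec")) stop_invalid("'spec' must be a cv_mark_spec")
  if (n_body_bins < 2) stop_invalid("n_body_bins must be >= 2")
  if (flank_bins < 0) stop_invalid("flank_bins must be >= 0")
  v <- shape_intensity(spec$shape, layout_u(n_body_bins, flank_bins),
                       spec$shape_params)
  if (any(v <= 0)) stop_invalid("template must be strictly positive")
  new_template(spec$name, v / mean(v), n_body_bins, flank_bins)
}

#' @noRd
new_template <- function(mark_id, values, n_body_bins, flank_bins) {
  structure(list(mark_id = mark_id, values = values,
                 n_body_bins = as.integer(n_body_bins),
                 flank_bins = as.integer(flank_bins)),
            class = "cv_template")
}

#' Default 8-mark synthetic panel
#'
#' Four activating marks, three repressive marks and one confounded repressor,
#' chosen so the full 92-term multivalent stepwise search runs in minutes.
#' `actTSS` is the activity-coupled activator (shifted-Gaussian amplitude,
#' loading 1 on the latent activity); `repArg` is the confounded repressor
#' whose marginal covariance with expression cancels exactly (see
#' [make_confounded_repressor()]); the remaining marks have independent
#' log-normal amplitudes.
#'
#' @return named list of `cv_mark_spec`.
#' @export
default_mark_panel <- function() {
  specs <- list(
    mark_spec("actTSS", "tss_peak",
              amplitude = list(family = "gaussian", center = 3, loading = 1,
                               sd = 0.5, floor = 0.05)),
    mark_spec("actBody", "body_ramp_3prime",
              amplitude = list(family = "lognormal", meanlog = 0, sdlog = 0.5,
                               loading = 0, baseline = 0)),
    mark_spec("actK9", "tss_peak", shape_params = list(height = 5, width = 0.08),
              amplitude = list(family = "lognormal", meanlog = 0, sdlog = 0.5,
                               loading = 0, baseline = 0)),
    mark_spec("actEnh", "bimodal_tss_tes",
              amplitude = list(family = "lognormal", meanlog = 0, sdlog = 0.5,
                               loading = 0, baseline = 0)),
    mark_spec("repPolyA", "body_uniform",
              amplitude = list(family = "lognormal", meanlog = 0, sdlog = 0.5,
                               loading = 0, baseline = 0)),
    mark_spec("repPolyB", "body_uniform",
              amplitude = list(family = "lognormal", meanlog = 0, sdlog = 0.5,
                               loading = 0, baseline = 0)),
    mark_spec("repK20", "body_ramp_3prime", shape_params = list(slope = 1.2),
              amplitude = list(family = "lognormal", meanlog = 0, sdlog = 0.5,
                               loading = 0, baseline = 0)),
    mark_spec("repArg", "tss_peak", shape_params = list(height = 3, width = 0.1),
              amplitude = list(family = "confounded", act_coef = 4,
                               act_loading = 1, rep_coef = 6,
                               noise_sd = 0.3, shift = 2))
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' A 21-mark panel for scale tests
#'
#' Generic log-normal marks cycling through the four template shapes; mirrors
#' the size of a 21-modification ChIP-Seq compendium (1561 candidate terms).
#'
#' @return named list of 21 `cv_mark_spec`.
#' @export
mark_panel_21 <- function() {
  shapes <- c("tss_peak", "body_ramp_3prime", "body_uniform", "bimodal_tss_tes")
  specs <- lapply(seq_len(21L), function(i) {
    mark_spec(sprintf("mark%02d", i), shapes[(i - 1L) %% 4L + 1L],
              amplitude = list(family = "lognormal", meanlog = 0, sdlog = 0.5,
                               loading = ifelse(i %% 5L == 0L, 0.3, 0),
                               baseline = 0))
  })
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}
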
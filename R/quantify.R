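#' Quantification configuration
#'
#' Holds the parameters of the intensity-processing chain: the spectral
#' crosstalk proportionality factor (GFP receiver from CFP donor; the
#' experimentally determined value for the eGFP/mCerulean pair is 0.456),
#' the fluorophore brightness table used for nRF normalization
#' (eGFP 33, mCerulean 16, mCherry 15), the offset in the log transform
#' `log(x + offset)`, and whether negative corrected intensities are
#' clipped to zero.
#'
#' @param crosstalk_factor unitless, `>= 0`; default 0.456.
#' @param brightness named numeric vector of fluorophore brightness values,
#'   all `> 0`.
#' @param log_offset offset in `log(x + offset)`; default 1.
#' @param clip_negative clip negative corrected intensities to 0; default
#'   `TRUE`.
#' @return an object of class `"quant_config"`.
#' @export
quant_config <- function(crosstalk_factor = 0.456,
                         brightness = c(eGFP = 33, mCerulean = 16, mCherry = 15),
                         log_offset = 1, clip_negative = TRUE) {
  if (crosstalk_factor < 0) stop("`crosstalk_factor` must be >= 0")
  if (is.null(names(brightness)) || any(brightness <= 0))
    stop("`brightness` must be a named vector of positive values")
  if (log_offset <= 0) stop("`log_offset` must be > 0")
  structure(list(crosstalk_factor = crosstalk_factor, brightness = brightness,
                 log_offset = log_offset, clip_negative = clip_negative),
            class = "quant_config")
}

#' Subtract per-field background from raw cell intensities
#'
#' The background of the imaging pad is estimated per field of view and
#' subtracted from every cell in that field, channel by channel.
#'
#' @param cells data frame with a `field` column and raw intensity columns
#'   `<channel>_raw`.
#' @param backgrounds data frame with columns `field`, `channel`,
#'   `background`; every (field, channel) present in `cells` must have an
#'   entry.
#' @param channels character vector of channel names; default: all
#'   channels with a `<channel>_raw` column.
#' @param clip_negative clip results below zero to 0.
#' @return `cells` with one added column `<channel>_rf` per channel.
#' @export
subtract_background <- function(cells, backgrounds, channels = NULL,
                                clip_negative = TRUE) {
  stopifnot(is.data.frame(cells), is.data.frame(backgrounds))
  if (!all(c("field", "channel", "background") %in% names(backgrounds)))
    stop("`backgrounds` needs columns field, channel, background")
  if (!"field" %in% names(cells)) stop("`cells` needs a `field` column")
  if (is.null(channels))
    channels <- sub("_raw$", "", grep("_raw$", names(cells), value = TRUE))
  for (ch in channels) {
    raw_col <- paste0(ch, "_raw")
    if (!raw_col %in% names(cells)) stop("missing column ", raw_col)
    bgch <- backgrounds[backgrounds$channel == ch, ]
    bg <- bgch$background[match(cells$field, bgch$field)]
    if (anyNA(bg)) {
      missing_fields <- unique(cells$field[is.na(bg)])
      stop("no background for channel `", ch, "` in field(s): ",
           paste(missing_fields, collapse = ", "))
    }
    v <- cells[[raw_col]] - bg
    if (clip_negative) v <- pmax(v, 0)
    cells[[paste0(ch, "_rf")]] <- v
  }
  cells
}

#' Estimate per-field background from an image and its cell masks
#'
#' Median intensity of the non-cell pixels of a field of view.
#'
#' @param image numeric matrix.
#' @param masks list of logical cell masks for that field.
#' @return scalar background estimate.
#' @export
estimate_background <- function(image, masks) {
  stopifnot(is.matrix(image))
  fg <- Reduce(`|`, masks, matrix(FALSE, nrow(image), ncol(image)))
  stats::median(image[!fg])
}

#' Fit the spectral crosstalk proportionality factor
#'
#' Zero-intercept least-squares regression of the receiver channel on the
#' donor channel: `factor = sum(donor * receiver) / sum(donor^2)`. A pure
#' bleed-through model has no offset (background is removed beforehand),
#' so the intercept is fixed at zero.
#'
#' @param donor,receiver equal-length numeric vectors of background-
#'   corrected intensities, `n >= 2`.
#' @return an object of class `"crosstalk_model"`: `factor`, `r_squared`
#'   (uncentered), `n_points`.
#' @export
fit_crosstalk <- function(donor, receiver) {
  if (length(donor) != length(receiver)) stop("unequal lengths")
  if (length(donor) < 2) stop("need n >= 2 points")
  if (all(donor == 0)) stop("all-zero donor: factor unidentifiable")
  f <- sum(donor * receiver) / sum(donor^2)
  ss_res <- sum((receiver - f * donor)^2)
  ss_tot <- sum(receiver^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(factor = f, r_squared = r2, n_points = length(donor)),
            class = "crosstalk_model")
}

#' @export
print.crosstalk_model <- function(x, ...) {
  cat(sprintf("Crosstalk model: factor = %.4f (R^2 = %.4f, n = %d)\n",
              x$factor, x$r_squared, x$n_points))
  invisible(x)
}

#' Correct a receiver channel for spectral bleed-through
#'
#' Subtracts `factor * donor` from the receiver intensity (the GFP channel
#' corrected for the overlapping CFP signal, in the study's setup).
#'
#' @param receiver,donor numeric vectors of corrected intensities.
#' @param factor proportionality factor, `>= 0`.
#' @param clip_negative clip results below zero to 0.
#' @return corrected receiver intensities.
#' @export
correct_crosstalk <- function(receiver, donor, factor = 0.456,
                              clip_negative = TRUE) {
  if (factor < 0) stop("`factor` must be >= 0")
  v <- receiver - factor * donor
  if (clip_negative) v <- pmax(v, 0)
  v
}

#' Normalize relative fluorescence for fluorophore brightness
#'
#' Rescales RF values so the three fluorophores are comparable: each
#' channel is multiplied by `B_max / B_fluorophore`, where `B_max` is the
#' largest brightness in the table (eGFP with the default table). A
#' separate optional step, [max_scale()], rescales a population to \[0,1\]
#' by its maximum for histogram axes.
#'
#' @param rf numeric vector of RF values.
#' @param fluorophore name, must be present in `config$brightness`.
#' @param config a [quant_config()].
#' @return nRF values.
#' @export
normalize_brightness <- function(rf, fluorophore, config = quant_config()) {
  b <- config$brightness
  if (!fluorophore %in% names(b))
    stop("unknown fluorophore `", fluorophore, "`; known: ",
         paste(names(b), collapse = ", "))
  rf * (max(b) / b[[fluorophore]])
}

#' Rescale a population of intensities to \[0,1\] by its maximum
#'
#' @param values nonnegative numeric vector with a positive maximum.
#' @return `values / max(values)`.
#' @export
max_scale <- function(values) {
  m <- max(values)
  if (!is.finite(m) || m <= 0) stop("maximum must be positive and finite")
  values / m
}

#' Noise of a single-cell intensity sample
#'
#' The heterogeneity metric: standard deviation divided by mean of the
#' log-transformed per-cell intensities, `y_i = log(x_i + offset)` with the
#' natural log and offset 1 by default. The log transform makes the
#' coefficient of variation comparable across non-normal samples and damps
#' the inflation of noise at low expression. The sample (n-1) standard
#' deviation is used.
#'
#' @param values nonnegative intensities, `n >= 2`.
#' @param config a [quant_config()] (for `log_offset`).
#' @return a list: `mean_rf` (arithmetic mean of the untransformed values),
#'   `noise` (sd/mean of the log-transformed values), `n`.
#' @export
compute_noise <- function(values, config = quant_config()) {
  if (length(values) < 2) stop("need n >= 2 values")
  if (any(values < 0)) stop("values must be >= 0")
  y <- log(values + config$log_offset)
  my <- mean(y)
  if (my == 0)
    stop("mean of log-transformed values is zero; noise undefined ",
         "(all intensities zero?)")
  list(mean_rf = mean(values), noise = stats::sd(y) / my, n = length(values))
}

#' Run the full intensity-processing chain on a cell table
#'
#' Per-field background subtraction, GFP-from-CFP crosstalk correction,
#' and brightness normalization, producing `<channel>_rf` and
#' `<channel>_nrf` columns.
#'
#' @param cells data frame with `field` and `<channel>_raw` columns.
#' @param backgrounds per-field background table (see
#'   [subtract_background()]); `NULL` for none.
#' @param channel_fluor named character vector mapping channel name ->
#'   fluorophore name in the brightness table.
#' @param crosstalk `NULL`, or a list `list(receiver=, donor=)` of channel
#'   names to apply the configured factor to.
#' @param config a [quant_config()].
#' @return the table with added `<channel>_rf` and `<channel>_nrf` columns.
#' @export
quantify_cells <- function(cells, backgrounds = NULL, channel_fluor,
                           crosstalk = list(receiver = NULL, donor = NULL),
                           config = quant_config()) {
  channels <- names(channel_fluor)
  if (is.null(channels)) stop("`channel_fluor` must be named by channel")
  if (!is.null(backgrounds)) {
    cells <- subtract_background(cells, backgrounds, channels,
                                 clip_negative = config$clip_negative)
  } else {
    for (ch in channels) cells[[paste0(ch, "_rf")]] <- cells[[paste0(ch, "_raw")]]
  }
  if (!is.null(crosstalk$receiver)) {
    rc <- paste0(crosstalk$receiver, "_rf")
    dc <- paste0(crosstalk$donor, "_rf")
    cells[[rc]] <- correct_crosstalk(cells[[rc]], cells[[dc]],
                                     config$crosstalk_factor,
                                     clip_negative = config$clip_negative)
  }
  for (ch in channels) {
    cells[[paste0(ch, "_nrf")]] <-
      normalize_brightness(cells[[paste0(ch, "_rf")]], channel_fluor[[ch]],
                           config)
  }
  cells
}
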
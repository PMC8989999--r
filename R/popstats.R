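#' Call ON/OFF state against a non-fluorescent control
#'
#' A cell is ON when its intensity exceeds `mean(control) + k * sd(control)`,
#' the control being a non-tagged population measured under the same
#' conditions. k defaults to 3.
#'
#' @param values intensities of the reporter population.
#' @param control_values intensities of the non-tagged control, `n >= 2`.
#' @param k threshold multiplier.
#' @return a list of class `"on_off_call"`: `threshold`, `rule`,
#'   `on_fraction`, `n_on`, `n_off`.
#' @export
call_on_off <- function(values, control_values, k = 3) {
  if (!length(values) || length(control_values) < 2)
    stop("need non-empty `values` and n >= 2 control values")
  thr <- mean(control_values) + k * stats::sd(control_values)
  on <- values > thr
  structure(list(threshold = thr,
                 rule = sprintf("value > mean(control) + %g * sd(control)", k),
                 on_fraction = mean(on), n_on = sum(on), n_off = sum(!on)),
            class = "on_off_call")
}

#' Pearson correlation between two channels
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, both with nonzero
#'   variance.
#' @param channel_x,channel_y labels carried into the result.
#' @return a list of class `"correlation_result"`: `channel_x`,
#'   `channel_y`, `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y, channel_x = "x", channel_y = "y") {
  if (length(x) != length(y)) stop("unequal lengths")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(channel_x = channel_x, channel_y = channel_y,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' Chi-square homogeneity test on two binned samples
#'
#' Bins both samples on shared equal-width edges spanning the pooled
#' range, pools bins from the tails inward until every expected count in
#' the 2 x B homogeneity table is at least 5 (stopping at 2 bins), and
#' computes the chi-square statistic without continuity correction with
#' `B - 1` degrees of freedom.
#'
#' @param values_a,values_b nonempty numeric samples.
#' @param n_bins initial number of equal-width bins; default 20.
#' @param min_expected pooling target for expected counts; default 5.
#' @return a list of class `"histogram_comparison"`: `bin_edges` (after
#'   pooling), `counts_a`, `counts_b`, `chi2`, `dof`, `p_value`.
#' @export
chi_square_compare <- function(values_a, values_b, n_bins = 20,
                               min_expected = 5) {
  if (!length(values_a) || !length(values_b)) stop("empty sample")
  pooled <- c(values_a, values_b)
  rng <- range(pooled)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- function(v) tabulate(findInterval(v, edges, rightmost.closed = TRUE,
                                           all.inside = TRUE), n_bins)
  ca <- bin(values_a); cb <- bin(values_b)
  ## pool from the tails until all expected >= min_expected
  repeat {
    B <- length(ca)
    if (B <= 2) break
    tot <- ca + cb
    ea <- tot * sum(ca) / sum(tot)
    eb <- tot * sum(cb) / sum(tot)
    low <- pmin(ea, eb) < min_expected
    if (!any(low)) break
    i <- which(low)[which.min(pmin(ea, eb)[low])]
    if (i <= B / 2) {      # merge toward the centre
      ca[i + 1] <- ca[i + 1] + ca[i]; cb[i + 1] <- cb[i + 1] + cb[i]
      ca <- ca[-i]; cb <- cb[-i]; edges <- edges[-(i + 1)]
    } else {
      ca[i - 1] <- ca[i - 1] + ca[i]; cb[i - 1] <- cb[i - 1] + cb[i]
      ca <- ca[-i]; cb <- cb[-i]; edges <- edges[-i]
    }
  }
  if (length(ca) < 2) stop("fewer than 2 usable bins after pooling")
  res <- chi_square_counts(ca, cb)
  res$bin_edges <- edges
  res
}

#' Chi-square homogeneity test on precomputed histogram counts
#'
#' @param counts_a,counts_b nonnegative integer counts over shared bins.
#' @return a list of class `"histogram_comparison"`: `counts_a`,
#'   `counts_b`, `chi2`, `dof` (bins - 1), `p_value`.
#' @export
chi_square_counts <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) stop("unequal bin counts")
  if (length(counts_a) < 2) stop("need >= 2 bins")
  if (sum(counts_a) == 0 || sum(counts_b) == 0) stop("empty sample")
  O <- rbind(counts_a, counts_b)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  use <- E > 0
  chi2 <- sum((O[use] - E[use])^2 / E[use])
  dof <- ncol(O) - 1L
  structure(list(bin_edges = NULL, counts_a = counts_a, counts_b = counts_b,
                 chi2 = chi2, dof = dof,
                 p_value = stats::pchisq(chi2, dof, lower.tail = FALSE)),
            class = "histogram_comparison")
}

#' Moment skewness with a symmetric/right-skewed classification
#'
#' Population (biased) moment skewness `g1 = m3 / m2^(3/2)`. Samples with
#' `g1` above the cutoff are classified right-skewed (the Cad reporter
#' pattern), otherwise symmetric (the Gad/Adi pattern).
#'
#' @param values numeric vector, `n >= 3`, nonzero variance.
#' @param cutoff classification threshold on g1; default 0.5.
#' @return `g1`, with attribute `classification` of `"right-skewed"` or
#'   `"symmetric"`.
#' @export
skewness_g1 <- function(values, cutoff = 0.5) {
  if (length(values) < 3) stop("need n >= 3")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance")
  m3 <- mean((values - m)^3)
  g1 <- m3 / m2^1.5
  attr(g1, "classification") <- if (g1 > cutoff) "right-skewed" else "symmetric"
  g1
}

#' Normalize a luminescence time course to relative light units
#'
#' RLU = counts per second per milliliter per OD600. Also reports the time
#' and value of the maximal RLU.
#'
#' @param timecourse data frame with columns `time_min`, `counts_per_s`,
#'   `volume_ml`, `od600` (all OD values `> 0`, volumes `> 0`).
#' @return a list: `records` (the input with an `rlu` column), `t_max`
#'   (minutes), `rlu_max`.
#' @export
rlu_normalize <- function(timecourse) {
  need <- c("time_min", "counts_per_s", "volume_ml", "od600")
  miss <- setdiff(need, names(timecourse))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(timecourse$od600 <= 0)) stop("od600 must be > 0 at all points")
  if (any(timecourse$volume_ml <= 0)) stop("volume_ml must be > 0")
  timecourse$rlu <- timecourse$counts_per_s /
    (timecourse$volume_ml * timecourse$od600)
  i <- which.max(timecourse$rlu)
  list(records = timecourse, t_max = timecourse$time_min[i],
       rlu_max = timecourse$rlu[i])
}

#' Population summary of one channel under one condition
#'
#' Mean RF, noise (sd/mean of log-transformed values), ON fraction against
#' a control, and skewness — the per-sample summary underlying the
#' heterogeneity comparisons.
#'
#' @param values per-cell intensities for the channel.
#' @param channel,condition,time_min labels.
#' @param control_values control intensities for ON/OFF calling; `NULL`
#'   to skip.
#' @param k ON/OFF threshold multiplier.
#' @param config a [quant_config()].
#' @return one-row data frame: `channel`, `condition`, `time_min`, `n`,
#'   `mean_rf`, `noise`, `on_fraction`, `skewness`.
#' @export
population_summary <- function(values, channel, condition = "cond",
                               time_min = 0, control_values = NULL, k = 3,
                               config = quant_config()) {
  nz <- compute_noise(values, config)
  onf <- if (!is.null(control_values))
    call_on_off(values, control_values, k)$on_fraction else NA_real_
  data.frame(channel = channel, condition = condition, time_min = time_min,
             n = nz$n, mean_rf = nz$mean_rf, noise = nz$noise,
             on_fraction = onf, skewness = as.numeric(skewness_g1(values)),
             stringsAsFactors = FALSE)
}
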
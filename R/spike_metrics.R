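#' Detect spikes in a voltage series
#'
#' A spike is the local maximum of the suprathreshold excursion that
#' follows an upward crossing of `threshold`; crossings that occur within
#' `refractory` ms of the previously accepted crossing are ignored.
#'
#' @param voltage_series Numeric vector of membrane potentials, mV
#'   (length >= 2).
#' @param dt Sample interval, ms, > 0. Sample `k` is at time `(k - 1) * dt`.
#' @param threshold Crossing threshold, mV. Default 0 (conventional
#'   action-potential criterion).
#' @param refractory Minimum separation between accepted crossings, ms.
#' @param node Optional node index carried into the result.
#' @return An object of class `spike_train`: list with `node`,
#'   `spike_times` (ms, strictly increasing) and `peak_voltages` (mV).
#' @examples
#' v <- -65 + 100 * exp(-((seq(0, 50, 0.1) - 20) / 1)^2)
#' detect_spikes(v, dt = 0.1)
#' @export
detect_spikes <- function(voltage_series, dt, threshold = 0, refractory = 2,
                          node = NA_integer_) {
  if (length(voltage_series) < 2L)
    stop("detect_spikes: voltage series must have length >= 2")
  if (!is.numeric(voltage_series) || any(!is.finite(voltage_series)))
    stop("detect_spikes: voltage series must be finite numeric")
  if (!is.numeric(dt) || dt <= 0) stop("detect_spikes: dt must be > 0")
  v <- voltage_series
  nv <- length(v)
  crossings <- which(v[-nv] <= threshold & v[-1L] > threshold) + 1L
  times <- numeric(0)
  peaks <- numeric(0)
  last_cross <- -Inf
  for (ci in crossings) {
    t_cross <- (ci - 1L) * dt
    if (t_cross - last_cross < refractory) next
    last_cross <- t_cross
    j <- ci
    while (j < nv && v[j + 1L] > threshold) j <- j + 1L
    seg <- ci:j
    pk <- seg[which.max(v[seg])]
    times <- c(times, (pk - 1L) * dt)
    peaks <- c(peaks, v[pk])
  }
  structure(list(node = node, spike_times = times, peak_voltages = peaks,
                 threshold = threshold, refractory = refractory),
            class = "spike_train")
}

#' Summarize a spike train
#'
#' @param train A `spike_train`.
#' @param v_rest Resting potential used as the amplitude reference, mV.
#' @param duration Duration of the underlying recording, ms.
#' @return An object of class `train_summary`: list with `count`,
#'   `mean_amplitude` (mV above `v_rest`; 0 when no spikes), `mean_isi`
#'   (ms; `NA` when fewer than 2 spikes) and `frequency`
#'   (Hz, `(count - 1) / span`; 0 when fewer than 2 spikes).
#' @examples
#' tr <- list(spike_times = c(100, 200, 300), peak_voltages = rep(35, 3))
#' class(tr) <- "spike_train"
#' summarize_train(tr, v_rest = -65, duration = 500)
#' @export
summarize_train <- function(train, v_rest = -65, duration) {
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(duration) || duration <= 0)
    stop("summarize_train: duration must be > 0")
  k <- length(train$spike_times)
  amp <- if (k > 0) mean(train$peak_voltages) - v_rest else 0
  if (k >= 2) {
    span <- train$spike_times[k] - train$spike_times[1]
    isi <- span / (k - 1)
    freq <- (k - 1) / span * 1000  # ms^-1 -> Hz
  } else {
    isi <- NA_real_
    freq <- 0
  }
  structure(list(count = k, mean_amplitude = amp, mean_isi = isi,
                 frequency = freq, duration = duration, v_rest = v_rest),
            class = "train_summary")
}

#' Compare a modified spike train against its baseline
#'
#' Quantifies the modulation induced by the dielectric element as ratios of
#' modified to baseline mean amplitude and firing frequency (0 when the
#' baseline value is 0), plus a conduction-block flag.
#'
#' @param baseline,modified `train_summary` objects from runs of equal
#'   duration.
#' @return An object of class `modulation_summary`: list with
#'   `amplitude_ratio`, `frequency_ratio` and `blocked` (`TRUE` when the
#'   baseline fires and the modified run does not).
#' @export
compare_modulation <- function(baseline, modified) {
  stopifnot(inherits(baseline, "train_summary"),
            inherits(modified, "train_summary"))
  if (!isTRUE(all.equal(baseline$duration, modified$duration)))
    stop("compare_modulation: summaries must come from equal-duration runs")
  ratio <- function(num, den) if (den == 0) 0 else num / den
  structure(list(
    amplitude_ratio = ratio(modified$mean_amplitude, baseline$mean_amplitude),
    frequency_ratio = ratio(modified$frequency, baseline$frequency),
    blocked = baseline$count >= 1 && modified$count == 0
  ), class = "modulation_summary")
}

#' Per-node spike summary of a simulation trace
#'
#' Runs [detect_spikes()] and [summarize_train()] on every node of a trace.
#'
#' @param trace A `simulation_trace` from [simulate_axon()].
#' @param threshold,refractory Passed to [detect_spikes()].
#' @return A data frame with columns `node`, `count`, `mean_amplitude_mv`,
#'   `mean_isi_ms`, `frequency_hz`.
#' @export
summarize_trace <- function(trace, threshold = 0, refractory = 2) {
  stopifnot(inherits(trace, "simulation_trace"))
  duration <- trace$times[length(trace$times)]
  rows <- lapply(seq_len(nrow(trace$V)), function(i) {
    tr <- detect_spikes(trace$V[i, ], dt = trace$dt, threshold = threshold,
                        refractory = refractory, node = i)
    s <- summarize_train(tr, v_rest = trace$v_rest, duration = duration)
    data.frame(node = i, count = s$count, mean_amplitude_mv = s$mean_amplitude,
               mean_isi_ms = s$mean_isi, frequency_hz = s$frequency)
  })
  do.call(rbind, rows)
}

#' Write a per-node train summary as CSV
#'
#' @param summary_df Data frame from [summarize_trace()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_train_summary_csv <- function(summary_df, path) {
  need <- c("node", "count", "mean_amplitude_mv", "mean_isi_ms",
            "frequency_hz")
  if (!all(need %in% names(summary_df)))
    stop("write_train_summary_csv: missing columns: ",
         paste(setdiff(need, names(summary_df)), collapse = ", "))
  write.csv(summary_df[, need], path, row.names = FALSE)
  invisible(path)
}
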
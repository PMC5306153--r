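# Spike-train and trace analysis: Gaussian-kernel firing-rate estimation,
# selection detection, CSV export and plotting.

#' Gaussian-kernel firing-rate estimate
#'
#' Convolves a spike train with a unit-area Gaussian kernel:
#' `r(t) = sum_k N(t - t_k; sigma)`, in spikes per second (Hz).  An empty
#' spike train gives an all-zero trace.  Because the kernel has unit area,
#' the trace integrates to the spike count, and a regular train of period
#' `sigma` is recovered as a flat `1/period` Hz away from the edges.
#'
#' @param spike_times Spike times in seconds (one train), or a list of
#'   trains (one per channel).
#' @param sigma Kernel width in seconds (> 0).
#' @param grid Time grid in seconds at which to evaluate the estimate.
#' @return An `spml_rate_trace`: `$time` and a `length(grid) x channels`
#'   matrix `$values`.
#' @export
gaussian_rate <- function(spike_times, sigma, grid) {
  if (sigma <= 0) spml_error("spml_contract_error", "sigma must be > 0")
  trains <- if (is.list(spike_times)) spike_times else list(spike_times)
  values <- vapply(trains, function(tk) {
    if (length(tk) == 0L) return(numeric(length(grid)))
    vapply(grid, function(t) sum(stats::dnorm(t - tk, sd = sigma)), 0)
  }, numeric(length(grid)))
  values <- matrix(values, nrow = length(grid))
  structure(list(time = as.numeric(grid), values = values),
            class = "spml_rate_trace")
}

#' @export
print.spml_rate_trace <- function(x, ...) {
  cat(sprintf("<rate trace: %d time point(s) x %d channel(s)>\n",
              length(x$time), ncol(x$values)))
  invisible(x)
}

#' Detect selected channels
#'
#' A channel counts as selected at time t when its output value is strictly
#' below `threshold` (disinhibition of the output nucleus).  The defaults in
#' use are 0.1 for the normalised rate model and 10 Hz for kernel rate
#' estimates of the spiking model.
#'
#' @param trace An `spml_rate_trace` (or a numeric matrix time x channels).
#' @param threshold Positive selection threshold.
#' @return Logical matrix time x channels; TRUE where selected.
#' @export
detect_selection <- function(trace, threshold = 0.1) {
  if (threshold <= 0) spml_error("spml_contract_error", "threshold must be > 0")
  values <- if (inherits(trace, "spml_rate_trace")) trace$values else trace
  values < threshold
}

#' Export a log set to CSV files
#'
#' Analog logs become `time,channel<i>,...` tables; event logs `time,index`.
#'
#' @param logs An `spml_logset`.
#' @param dir Output directory.
#' @return Paths written.
#' @export
export_csv <- function(logs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(logs$analog)) {
    al <- logs$analog[[nm]]
    df <- data.frame(time = al$time)
    for (j in seq_along(al$indices))
      df[[paste0("channel", al$indices[[j]])]] <- al$data[, j]
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(logs$events)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(logs$events[[nm]]$spikes, p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }
  paths
}

#' Line plot of analog logs
#'
#' One line per recorded index.  The plot's data model (the long-format
#' data frame behind the lines) is what tests assert on; rendering to file
#' is optional.
#'
#' @param logs An `spml_logset`.
#' @param which Name of the analog log (default: first).
#' @param path Optional output file (`.png` or `.pdf`).
#' @return A ggplot object.
#' @export
plot_lines <- function(logs, which = NULL, path = NULL) {
  nm <- which %||% names(logs$analog)[[1L]]
  al <- logs$analog[[nm]]
  df <- data.frame(
    time = rep(al$time, times = length(al$indices)),
    value = as.vector(al$data),
    channel = factor(rep(al$indices, each = length(al$time))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                        colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = nm, colour = "index") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 4)
  p
}

#' Raster plot of an event log
#'
#' One mark per spike (time on x, neuron index on y).
#'
#' @param logs An `spml_logset`.
#' @param which Name of the event log (default: first).
#' @param path Optional output file (`.png` or `.pdf`).
#' @return A ggplot object whose data has one row per spike.
#' @export
plot_raster <- function(logs, which = NULL, path = NULL) {
  nm <- which %||% names(logs$events)[[1L]]
  df <- logs$events[[nm]]$spikes
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$index)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "neuron index", title = nm) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 4)
  p
}
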
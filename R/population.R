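#' Population-level motility summary
#'
#' Runs the full motility pipeline on a set of trajectories: length filter,
#' MSD, power-law exponent fit, three-way classification, active/passive
#' phase segmentation and run lengths — then aggregates class fractions and
#' a run-length histogram over half-open 1-µm bins \[0,1), \[1,2), ...
#'
#' @param tracks List of [trajectory()] objects.
#' @param config A [classifier_config()].
#' @return An object of class `"motility_summary"`: list with
#'   \item{tracks}{per-track data frame: `track_id`, `n_frames`, `alpha`,
#'     `r_squared`, `class`, `n_runs`, `max_run_um`;}
#'   \item{run_lengths}{data frame `track_id`, `run_um`, one row per active
#'     phase;}
#'   \item{fractions}{named fractions over retained tracks (processive,
#'     diffusive, non_processive); all `NA` when nothing is retained, with
#'     `undefined_fractions = TRUE`;}
#'   \item{histogram}{data frame `bin_lo`, `bin_hi`, `count` of run lengths;}
#'   \item{n_tracks_input}{input track count;}
#'   \item{n_tracks_retained}{tracks passing the length filter;}
#'   \item{config}{the configuration used.}
#' @examples
#' pop <- simulate_population(
#'   list(list(model = motion_model("ballistic", speed = 1), weight = 1)),
#'   n_tracks = 20, n_frames = 40, dt = 1, seed = 3)
#' summarize_population(pop$tracks)
#' @export
summarize_population <- function(tracks, config = classifier_config()) {
  stopifnot(is.list(tracks), inherits(config, "classifier_config"))
  retained <- filter_tracks(tracks, config)
  n_in <- length(tracks); n_ret <- length(retained)
  rows <- vector("list", n_ret)
  runs <- vector("list", n_ret)
  for (i in seq_len(n_ret)) {
    tr <- retained[[i]]
    fit <- fit_power_law(compute_msd(tr, config$max_lag_fraction))
    cls <- classify_track(fit, config)
    ph <- segment_phases(tr, config)
    rl <- compute_run_lengths(tr, ph)
    rows[[i]] <- data.frame(
      track_id = tr$track_id, n_frames = n_frames(tr),
      alpha = fit$alpha, r_squared = fit$r_squared, class = cls,
      n_runs = length(rl),
      max_run_um = if (length(rl)) max(rl) else NA_real_,
      stringsAsFactors = FALSE)
    runs[[i]] <- if (length(rl)) {
      data.frame(track_id = tr$track_id, run_um = rl, stringsAsFactors = FALSE)
    } else NULL
  }
  track_df <- if (n_ret) do.call(rbind, rows) else
    data.frame(track_id = character(), n_frames = integer(), alpha = numeric(),
               r_squared = numeric(), class = character(), n_runs = integer(),
               max_run_um = numeric(), stringsAsFactors = FALSE)
  run_df <- if (n_ret && length(Filter(Negate(is.null), runs))) {
    do.call(rbind, Filter(Negate(is.null), runs))
  } else data.frame(track_id = character(), run_um = numeric(),
                    stringsAsFactors = FALSE)
  classes <- c("processive", "diffusive", "non_processive")
  if (n_ret > 0L) {
    fractions <- vapply(classes, function(cl) mean(track_df$class == cl),
                        numeric(1))
    undefined <- FALSE
  } else {
    fractions <- stats::setNames(rep(NA_real_, 3L), classes)
    undefined <- TRUE
  }
  hist_df <- run_length_histogram(run_df$run_um)
  structure(
    list(tracks = track_df, run_lengths = run_df, fractions = fractions,
         undefined_fractions = undefined, histogram = hist_df,
         n_tracks_input = n_in, n_tracks_retained = n_ret, config = config),
    class = "motility_summary"
  )
}

## Half-open 1-um bins [0,1), [1,2), ... covering all observed run lengths.
run_length_histogram <- function(run_um) {
  if (length(run_um) == 0L) {
    return(data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer()))
  }
  top <- max(1, ceiling(max(run_um) + 1e-12))
  lo <- as.numeric(seq(0, top - 1))
  counts <- vapply(lo, function(l) sum(run_um >= l & run_um < l + 1),
                   numeric(1))
  data.frame(bin_lo = lo, bin_hi = lo + 1, count = as.integer(counts))
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("<motility_summary: %d/%d tracks retained (>= %d frames)>\n",
              x$n_tracks_retained, x$n_tracks_input, x$config$min_frames))
  if (x$undefined_fractions) {
    cat("  class fractions undefined (no retained tracks)\n")
  } else {
    cat(sprintf("  processive %.1f%%  diffusive %.1f%%  non-processive %.1f%%\n",
                100 * x$fractions[["processive"]],
                100 * x$fractions[["diffusive"]],
                100 * x$fractions[["non_processive"]]))
    cat(sprintf("  %d run-length records, median %.2f um\n",
                nrow(x$run_lengths),
                if (nrow(x$run_lengths)) stats::median(x$run_lengths$run_um) else NA))
  }
  invisible(x)
}

#' @export
summary.motility_summary <- function(object, ...) {
  cat("Motility analysis summary\n")
  print(object)
  if (!object$undefined_fractions && nrow(object$tracks)) {
    cat("\nAlpha by class:\n")
    print(vapply(split(object$tracks$alpha, object$tracks$class),
                 function(v) c(mean = mean(v), sd = stats::sd(v)),
                 numeric(2)))
  }
  if (nrow(object$histogram)) {
    cat("\nRun-length histogram (1-um bins):\n")
    print(object$histogram, row.names = FALSE)
  }
  invisible(object)
}

#' Plot a motility summary
#'
#' Two panels: the class-fraction bar chart and the run-length histogram,
#' mirroring the standard presentation of particle-motility assays.
#'
#' @param x A `"motility_summary"`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.motility_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(100 * x$fractions, ylab = "% of tracks",
                    main = "Track classes", las = 2,
                    col = c("firebrick", "grey70", "steelblue"))
  if (nrow(x$histogram)) {
    graphics::barplot(x$histogram$count,
                      names.arg = sprintf("%g-%g", x$histogram$bin_lo,
                                          x$histogram$bin_hi),
                      xlab = "run length (um)", ylab = "count",
                      main = "Run lengths")
  } else {
    graphics::plot.new(); graphics::title("Run lengths (none)")
  }
  invisible(x)
}
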
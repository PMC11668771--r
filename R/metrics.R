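labels_vector <- function(labels) {
  if (inherits(labels, "label_sequence")) labels$label else as.character(labels)
}

check_aoi <- function(labels, aoi) {
  nm <- attr(labels, "aoi_names")
  if (!is.null(nm) && !aoi %in% nm)
    stop("unknown AOI '", aoi, "' (stimulus declares: ",
         paste(nm, collapse = ", "), ")", call. = FALSE)
}

#' Total gaze count (TGC)
#'
#' Number of gaze samples labeled with an AOI, optionally restricted to a
#' half-open time window. One gaze count is one valid gaze sample, making
#' TGC proportional to the sampling rate; [per_second_series()] and the
#' vacancy rate are the rate-independent normalisations.
#'
#' @param labels a `label_sequence` from [assign_labels()].
#' @param aoi AOI name.
#' @param window optional `c(start_ms, end_ms)` half-open window.
#' @return non-negative integer count.
#' @export
total_gaze_count <- function(labels, aoi, window = NULL) {
  check_aoi(labels, aoi)
  keep <- labels$label == aoi
  if (!is.null(window))
    keep <- keep & labels$t >= window[1] & labels$t < window[2]
  sum(keep)
}

#' Total fixation time (TFT), dwell-time convention
#'
#' Cumulative time gaze dwells in an AOI, approximated as sample count times
#' the sampling interval. No fixation-event filter is applied: every valid
#' sample inside the AOI contributes one interval of dwell. See
#' [dispersion_prefilter()] for an optional fixation pre-filter.
#'
#' @inheritParams total_gaze_count
#' @return dwell time in seconds.
#' @export
total_fixation_time <- function(labels, aoi) {
  si <- attr(labels, "sampling_interval")
  if (is.null(si) || is.na(si))
    stop("label sequence carries no sampling interval", call. = FALSE)
  total_gaze_count(labels, aoi) * si / 1000
}

#' Mean pupil diameter over an AOI
#'
#' Per-sample pupil diameter is the mean of the available (non-missing)
#' eye measurements; samples with no pupil data are excluded pairwise,
#' never imputed.
#'
#' @param recording the [gaze_recording()] the labels came from.
#' @param labels its `label_sequence`.
#' @param aoi AOI name.
#' @return mean diameter in mm, or `NA` when no labeled sample has pupil
#'   data.
#' @export
mean_pupil_size <- function(recording, labels, aoi) {
  check_aoi(labels, aoi)
  s <- recording$samples
  stopifnot(nrow(s) == nrow(labels))
  sel <- labels$label == aoi
  p <- rowMeans(cbind(s$pupil_left[sel], s$pupil_right[sel]), na.rm = TRUE)
  p <- p[is.finite(p)]
  if (length(p) == 0L) return(NA_real_)
  mean(p)
}

#' AOI switch count (ASC)
#'
#' Collapses the label sequence to runs of AOI labels only (dropping
#' `VACANT`/`OFFSCREEN`/`INVALID` samples), discards runs shorter than
#' `min_dwell_samples`, and counts adjacent runs whose AOI names differ —
#' the number of gaze switches between AOIs. The default
#' `min_dwell_samples = 1` applies no debouncing; larger values suppress
#' single-sample flickers.
#'
#' @param labels a `label_sequence`, or a plain character vector of labels.
#' @param min_dwell_samples minimum run length to count, `>= 1`.
#' @return non-negative integer switch count.
#' @export
aoi_switch_count <- function(labels, min_dwell_samples = 1L) {
  stopifnot(min_dwell_samples >= 1L)
  lab <- labels_vector(labels)
  lab <- lab[!lab %in% NON_AOI_LABELS]
  if (length(lab) < 2L) return(0L)
  r <- rle(lab)
  v <- r$values[r$lengths >= min_dwell_samples]
  if (length(v) < 2L) return(0L)
  sum(v[-1L] != v[-length(v)])
}

#' Favored and unfavored AOI shifts (FAS / UAS)
#'
#' Scores gaze against the stimulus's declared attention pathway: within
#' each time block, samples on that block's favored AOI count toward FAS
#' and samples on any other AOI count toward UAS. `fas - uas` is the net
#' pathway-adherence score. Both are gaze counts (TGC along the pathway),
#' not discrete shift events. An optional response window restricts
#' counting to the first `response_window_ms` of each block, the interval
#' in which a reorienting attention shift would land.
#'
#' @param labels a `label_sequence` from [assign_labels()].
#' @param spec the matching [stimulus_spec()]; every block must declare a
#'   `favored_aoi`.
#' @param response_window_ms optional window length after each block onset;
#'   `NULL` (default) counts over whole blocks.
#' @return list with integer components `fas`, `uas`, `fas_minus_uas`.
#' @export
favored_shift_counts <- function(labels, spec, response_window_ms = NULL) {
  if (!has_favored_pathway(spec))
    stop("stimulus '", spec$stimulus_id,
         "' declares no favored pathway: FAS/UAS not applicable",
         call. = FALSE)
  nm <- aoi_names(spec)
  fas <- 0L; uas <- 0L
  for (b in spec$blocks) {
    end <- if (is.null(response_window_ms)) b$end_ms
           else min(b$end_ms, b$start_ms + response_window_ms)
    inb <- labels$t >= b$start_ms & labels$t < end
    lab <- labels$label[inb]
    fas <- fas + sum(lab == b$favored_aoi)
    uas <- uas + sum(lab %in% setdiff(nm, b$favored_aoi))
  }
  list(fas = fas, uas = uas, fas_minus_uas = fas - uas)
}

#' AOI vacancy count (AVC) and vacancy rate
#'
#' AVC counts gaze samples that land on-screen but on neither AOI (label
#' `VACANT`). The vacancy rate normalises it per time unit of attended
#' screen: `avc / (vacant + AOI-labeled samples)`, 0 when the denominator
#' is 0. Off-screen and invalid samples enter neither numerator nor
#' denominator.
#'
#' @param labels a `label_sequence`, or a plain character vector of labels.
#' @return list with integer `avc` and numeric `vacancy_rate` in `[0, 1]`.
#' @export
vacancy_metrics <- function(labels) {
  lab <- labels_vector(labels)
  avc <- sum(lab == LABEL_VACANT)
  n_aoi <- sum(!lab %in% NON_AOI_LABELS)
  denom <- avc + n_aoi
  list(avc = avc, vacancy_rate = if (denom == 0) 0 else avc / denom)
}

#' Per-second gaze-count series for an AOI
#'
#' Counts AOI-labeled samples in consecutive `[k, k+1)`-second bins covering
#' the whole stimulus duration.
#'
#' @inheritParams total_gaze_count
#' @return integer vector of length `ceiling(duration_ms / 1000)`.
#' @export
per_second_series <- function(labels, aoi) {
  check_aoi(labels, aoi)
  dur <- attr(labels, "duration_ms")
  nbin <- ceiling(dur / 1000)
  sel <- labels$label == aoi
  bins <- floor(labels$t[sel] / 1000)
  bins <- bins[bins < nbin]
  counts <- tabulate(bins + 1L, nbins = nbin)
  as.integer(counts)
}

#' Optional dispersion-based fixation pre-filter
#'
#' Relabels as `INVALID` every valid sample that does not belong to a
#' fixation, where a fixation is a maximal run of valid samples staying
#' within a square dispersion window of side `dispersion_px` for at least
#' `min_duration_ms`. Off by default in the pipeline: the shipped metrics
#' use the raw dwell-time convention, and this filter is provided for
#' sensitivity analyses against event-filtered exports.
#'
#' @param recording a [gaze_recording()].
#' @param labels its `label_sequence`.
#' @param dispersion_px window side length in pixels.
#' @param min_duration_ms minimum fixation duration.
#' @return a new `label_sequence` with non-fixation samples set to `INVALID`.
#' @export
dispersion_prefilter <- function(recording, labels, dispersion_px = 50,
                                 min_duration_ms = 100) {
  s <- recording$samples
  n <- nrow(s)
  valid <- (s$valid_left | s$valid_right) & !is.na(s$x) & !is.na(s$y)
  keep <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (!valid[i]) { i <- i + 1L; next }
    j <- i
    xmin <- s$x[i]; xmax <- s$x[i]; ymin <- s$y[i]; ymax <- s$y[i]
    while (j < n && valid[j + 1L]) {
      nx <- s$x[j + 1L]; ny <- s$y[j + 1L]
      if (max(xmax, nx) - min(xmin, nx) > dispersion_px ||
          max(ymax, ny) - min(ymin, ny) > dispersion_px) break
      xmin <- min(xmin, nx); xmax <- max(xmax, nx)
      ymin <- min(ymin, ny); ymax <- max(ymax, ny)
      j <- j + 1L
    }
    if (s$t[j] - s$t[i] + recording$sampling_interval >= min_duration_ms)
      keep[i:j] <- TRUE
    i <- j + 1L
  }
  out <- labels
  out$label[!keep] <- LABEL_INVALID
  out
}

#' Compute the full per-recording metrics bundle
#'
#' Runs every metric on one labeled recording: per-AOI TGC, TFT and mean
#' pupil size, the AOI switch count, the vacancy count and rate, and — when
#' the stimulus declares a favored pathway — FAS, UAS and their difference.
#'
#' @param recording a [gaze_recording()] that passed the inclusion filters.
#' @param spec the matching [stimulus_spec()].
#' @param min_dwell_samples passed to [aoi_switch_count()].
#' @param response_window_ms passed to [favored_shift_counts()].
#' @return an object of class `metrics_result`; FAS fields are `NULL` for
#'   pathway-free stimuli.
#' @export
compute_all <- function(recording, spec, min_dwell_samples = 1L,
                        response_window_ms = NULL) {
  labels <- assign_labels(recording, spec)
  nm <- aoi_names(spec)
  tgc <- vapply(nm, function(a) total_gaze_count(labels, a), numeric(1))
  tft <- vapply(nm, function(a) total_fixation_time(labels, a), numeric(1))
  pupil <- vapply(nm, function(a) mean_pupil_size(recording, labels, a),
                  numeric(1))
  vac <- vacancy_metrics(labels)
  res <- list(subject_id = recording$subject_id,
              stimulus_id = recording$stimulus_id,
              tgc = tgc, tft = tft, pupil = pupil,
              asc = aoi_switch_count(labels, min_dwell_samples),
              fas = NULL, uas = NULL, fas_minus_uas = NULL,
              avc = vac$avc, vacancy_rate = vac$vacancy_rate,
              offscreen = sum(labels$label == LABEL_OFFSCREEN),
              invalid = sum(labels$label == LABEL_INVALID),
              n_samples = nrow(labels))
  if (has_favored_pathway(spec)) {
    fs <- favored_shift_counts(labels, spec, response_window_ms)
    res$fas <- fs$fas; res$uas <- fs$uas
    res$fas_minus_uas <- fs$fas_minus_uas
  }
  structure(res, class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("<metrics_result> %s / %s\n", x$subject_id, x$stimulus_id))
  cat("  TGC:", paste(names(x$tgc), x$tgc, sep = "=", collapse = " "), "\n")
  cat(sprintf("  ASC=%d AVC=%d vacancy_rate=%.3f\n", x$asc, x$avc,
              x$vacancy_rate))
  if (!is.null(x$fas))
    cat(sprintf("  FAS=%d UAS=%d FAS-UAS=%d\n", x$fas, x$uas,
                x$fas_minus_uas))
  invisible(x)
}

#' Flatten metrics results into one row per (subject, stimulus)
#'
#' Per-AOI metrics become columns `tgc_<aoi>`, `tft_<aoi>`, `pupil_<aoi>`;
#' pathway-free stimuli carry `NA` in the FAS columns. Suitable for
#' [utils::write.csv()] (missing values as empty cells).
#'
#' @param results list of `metrics_result` objects.
#' @return data frame with one row per result.
#' @export
metrics_table <- function(results) {
  rows <- lapply(results, function(r) {
    row <- data.frame(subject_id = r$subject_id, stimulus_id = r$stimulus_id,
                      stringsAsFactors = FALSE)
    for (a in names(r$tgc)) {
      row[[paste0("tgc_", a)]] <- unname(r$tgc[a])
      row[[paste0("tft_", a)]] <- unname(r$tft[a])
      row[[paste0("pupil_", a)]] <- unname(r$pupil[a])
    }
    row$asc <- r$asc
    row$fas <- if (is.null(r$fas)) NA_integer_ else r$fas
    row$uas <- if (is.null(r$uas)) NA_integer_ else r$uas
    row$fas_minus_uas <- if (is.null(r$fas_minus_uas)) NA_integer_ else r$fas_minus_uas
    row$avc <- r$avc
    row$vacancy_rate <- r$vacancy_rate
    row$offscreen <- r$offscreen
    row$invalid <- r$invalid
    row$n_samples <- r$n_samples
    row
  })
  # column union across stimuli with different AOI sets
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(row) {
    for (cn in setdiff(all_cols, names(row))) row[[cn]] <- NA
    row[all_cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
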
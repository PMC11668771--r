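#' Describe the on-disk layout of a gaze-sample table
#'
#' A table dialect declares how the columns of a delimited gaze export map
#' onto the logical fields the package needs: the timestamp, the gaze
#' coordinates (either a single averaged pair or one pair per eye), the
#' per-eye validity codes, and (optionally) per-eye pupil diameters.
#'
#' Coordinates are screen pixels with the origin at the top-left corner and
#' y increasing downward; the screen occupies the half-open rectangle
#' `[0, width) x [0, height)`.
#'
#' @param delimiter field separator, e.g. `"\t"` or `","`.
#' @param columns named character vector mapping logical names to physical
#'   column names. Required logical names: `t`, `valid_left`, `valid_right`,
#'   plus either `x`/`y` or `x_left`/`y_left`/`x_right`/`y_right`.
#'   Optional: `pupil_left`, `pupil_right`.
#' @param valid_codes character vector of validity-column values that mean
#'   "this eye's measurement is valid". Everything else is invalid.
#' @param origin coordinate origin declaration; only `"topleft"` is defined.
#' @return an object of class `table_dialect`.
#' @export
table_dialect <- function(delimiter = "\t",
                          columns = c(t = "t", x = "x", y = "y",
                                      valid_left = "valid_left",
                                      valid_right = "valid_right",
                                      pupil_left = "pupil_left",
                                      pupil_right = "pupil_right"),
                          valid_codes = c("1", "TRUE", "true", "valid"),
                          origin = "topleft") {
  origin <- match.arg(origin, "topleft")
  if (is.null(names(columns)) || any(!nzchar(names(columns))))
    stop("`columns` must be a fully named character vector", call. = FALSE)
  if (anyDuplicated(names(columns)))
    stop("each logical column must map to exactly one physical column",
         call. = FALSE)
  required <- c("t", "valid_left", "valid_right")
  missing_req <- setdiff(required, names(columns))
  if (length(missing_req))
    stop("dialect is missing required logical column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  mono <- all(c("x", "y") %in% names(columns))
  bino <- all(c("x_left", "y_left", "x_right", "y_right") %in% names(columns))
  if (!mono && !bino)
    stop("dialect must map either x/y or x_left/y_left/x_right/y_right",
         call. = FALSE)
  structure(list(delimiter = delimiter, columns = columns,
                 valid_codes = as.character(valid_codes), origin = origin,
                 binocular = bino && !mono),
            class = "table_dialect")
}

#' @export
print.table_dialect <- function(x, ...) {
  cat("<table_dialect> delimiter=", deparse(x$delimiter),
      if (x$binocular) " (per-eye coordinates)" else " (averaged coordinates)",
      "\n", sep = "")
  invisible(x)
}

#' Construct a gaze recording
#'
#' One recording is one presentation of one stimulus to one subject: an
#' ordered table of time-stamped gaze samples. Timestamps are milliseconds
#' since stimulus onset and must be finite, non-negative and strictly
#' increasing. Samples with no valid eye carry missing coordinates.
#'
#' @param subject_id,stimulus_id opaque identifiers.
#' @param samples data frame with columns `t`, `x`, `y`, `valid_left`,
#'   `valid_right`, `pupil_left`, `pupil_right`.
#' @param sampling_interval milliseconds per sample; defaults to the median
#'   inter-sample gap of `samples$t`.
#' @return an object of class `gaze_recording`.
#' @export
gaze_recording <- function(subject_id, stimulus_id, samples,
                           sampling_interval = NULL) {
  needed <- c("t", "x", "y", "valid_left", "valid_right",
              "pupil_left", "pupil_right")
  miss <- setdiff(needed, names(samples))
  if (length(miss))
    stop("samples lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(samples) == 0L)
    stop("empty recording: no gaze samples", call. = FALSE)
  if (any(!is.finite(samples$t)) || any(samples$t < 0))
    stop("timestamps must be finite and non-negative", call. = FALSE)
  if (is.unsorted(samples$t, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  no_eye <- !samples$valid_left & !samples$valid_right
  samples$x[no_eye] <- NA_real_
  samples$y[no_eye] <- NA_real_
  bad_pupil <- function(p) !is.na(p) & (p <= 0 | p >= 10)
  if (any(bad_pupil(samples$pupil_left)) || any(bad_pupil(samples$pupil_right)))
    stop("pupil diameters must lie in (0, 10) mm or be missing", call. = FALSE)
  if (is.null(sampling_interval)) {
    sampling_interval <- if (nrow(samples) >= 2L)
      stats::median(diff(samples$t)) else NA_real_
  }
  if (!is.na(sampling_interval) && sampling_interval <= 0)
    stop("sampling_interval must be > 0", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 stimulus_id = as.character(stimulus_id),
                 samples = samples,
                 sampling_interval = sampling_interval),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> subject=%s stimulus=%s: %d samples, %.3g ms/sample\n",
              x$subject_id, x$stimulus_id, nrow(x$samples),
              x$sampling_interval))
  invisible(x)
}

parse_num <- function(v) suppressWarnings(as.numeric(v))

#' Read a delimited gaze-sample table
#'
#' Parses one eye-tracker export into a [gaze_recording()]. Validity columns
#' are matched against the dialect's `valid_codes`; a row whose coordinate or
#' pupil fields fail numeric parsing is kept as a sample with both validity
#' flags forced to `FALSE` (so it counts as gaze loss, not as data). Rows
#' whose timestamp fails to parse cannot be placed on the time axis and are
#' dropped with a warning, as are duplicate timestamps (first kept). When the
#' dialect declares per-eye coordinates, the reported gaze point is the mean
#' over the valid eyes.
#'
#' @param path file to read.
#' @param dialect a [table_dialect()].
#' @param subject_id,stimulus_id identifiers attached to the recording (the
#'   table itself carries neither).
#' @return a [gaze_recording()] sorted by `t`, with `sampling_interval` set
#'   to the median inter-sample gap.
#' @export
read_gaze_table <- function(path, dialect = table_dialect(),
                            subject_id = "unknown", stimulus_id = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = dialect$delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"))
  cols <- dialect$columns
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss))
    stop("gaze table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(raw) == 0L)
    stop("empty gaze table: ", path, call. = FALSE)

  get <- function(logical_name) {
    if (logical_name %in% names(cols)) raw[[cols[[logical_name]]]] else NULL
  }
  t <- parse_num(get("t"))
  if (anyNA(t)) {
    warning(sum(is.na(t)), " row(s) with unparseable timestamps dropped")
    keep <- !is.na(t)
    raw <- raw[keep, , drop = FALSE]
    t <- t[keep]
  }
  vl <- get("valid_left") %in% dialect$valid_codes
  vr <- get("valid_right") %in% dialect$valid_codes
  pl <- if (!is.null(get("pupil_left"))) parse_num(get("pupil_left")) else NA_real_
  pr <- if (!is.null(get("pupil_right"))) parse_num(get("pupil_right")) else NA_real_

  if (dialect$binocular) {
    xl <- parse_num(get("x_left")); yl <- parse_num(get("y_left"))
    xr <- parse_num(get("x_right")); yr <- parse_num(get("y_right"))
    # an eye whose coordinates fail to parse is not usable
    vl <- vl & !is.na(xl) & !is.na(yl)
    vr <- vr & !is.na(xr) & !is.na(yr)
    wl <- ifelse(vl, 1, 0); wr <- ifelse(vr, 1, 0)
    denom <- wl + wr
    x <- ifelse(denom > 0,
                (ifelse(vl, xl, 0) + ifelse(vr, xr, 0)) / pmax(denom, 1),
                NA_real_)
    y <- ifelse(denom > 0,
                (ifelse(vl, yl, 0) + ifelse(vr, yr, 0)) / pmax(denom, 1),
                NA_real_)
  } else {
    x <- parse_num(get("x")); y <- parse_num(get("y"))
    bad <- (vl | vr) & (is.na(x) | is.na(y))
    vl[bad] <- FALSE
    vr[bad] <- FALSE
  }
  # out-of-range pupil readings are treated as missing, not fatal
  pl[!is.na(pl) & (pl <= 0 | pl >= 10)] <- NA_real_
  pr[!is.na(pr) & (pr <= 0 | pr >= 10)] <- NA_real_

  ord <- order(t)
  samples <- data.frame(t = t, x = x, y = y, valid_left = vl, valid_right = vr,
                        pupil_left = rep_len(pl, length(t)),
                        pupil_right = rep_len(pr, length(t)))[ord, , drop = FALSE]
  dup <- duplicated(samples$t)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) dropped (first kept)")
    samples <- samples[!dup, , drop = FALSE]
  }
  rownames(samples) <- NULL
  gaze_recording(subject_id, stimulus_id, samples)
}

#' Write a recording back out as a delimited gaze table
#'
#' Inverse of [read_gaze_table()] for the single-coordinate (averaged)
#' dialect: validity flags are written as `1`/`0` and missing values as
#' empty cells, so a round trip through [read_gaze_table()] reproduces the
#' recording.
#'
#' @param recording a [gaze_recording()].
#' @param path output file.
#' @param dialect a non-binocular [table_dialect()].
#' @export
write_gaze_table <- function(recording, path, dialect = table_dialect()) {
  if (dialect$binocular)
    stop("writing per-eye coordinate dialects is not supported", call. = FALSE)
  s <- recording$samples
  cols <- dialect$columns
  out <- data.frame(t = s$t, x = s$x, y = s$y,
                    valid_left = as.integer(s$valid_left),
                    valid_right = as.integer(s$valid_right),
                    pupil_left = s$pupil_left, pupil_right = s$pupil_right)
  names(out) <- unname(cols[c("t", "x", "y", "valid_left", "valid_right",
                              "pupil_left", "pupil_right")])
  utils::write.table(out, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Read a clinical roster
#'
#' A roster lists one row per subject: group membership (`ASD` / `non-ASD`)
#' and ADOS-2 calibrated severity scores (total and the SA and RRB
#' subscales, each on the 1-10 CSS scale, possibly missing).
#'
#' @param path CSV file with header columns `subject_id`, `group`,
#'   `ados_total`, `ados_sa`, `ados_rrb`, `age_months`, `sex`.
#' @return a data frame of class `subject_roster`.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "ados_total", "ados_sa", "ados_rrb",
              "age_months", "sex")
  miss <- setdiff(needed, names(r))
  if (length(miss))
    stop("roster is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as_roster(r)
}

as_roster <- function(r) {
  r$subject_id <- as.character(r$subject_id)
  if (anyDuplicated(r$subject_id))
    stop("duplicate subject_id in roster", call. = FALSE)
  bad_group <- !r$group %in% c("ASD", "non-ASD")
  if (any(bad_group))
    stop("roster group must be 'ASD' or 'non-ASD'; got: ",
         paste(unique(r$group[bad_group]), collapse = ", "), call. = FALSE)
  for (sc in c("ados_total", "ados_sa", "ados_rrb")) {
    v <- r[[sc]]
    if (any(!is.na(v) & (v < 1 | v > 10)))
      stop(sc, " must lie in [1, 10] when present", call. = FALSE)
  }
  class(r) <- c("subject_roster", "data.frame")
  r
}

#' Fraction of samples spent looking at the screen
#'
#' A sample is "screen-looking" when at least one eye is valid and the gaze
#' point falls inside the half-open screen rectangle
#' `[0, width) x [0, height)`. This is the quantity the segment-level
#' inclusion filter thresholds (segments under 25% screen-looking time are
#' excluded by default).
#'
#' @param recording a [gaze_recording()].
#' @param screen_width,screen_height screen size in pixels.
#' @return fraction in `[0, 1]`.
#' @export
screen_looking_fraction <- function(recording, screen_width, screen_height) {
  s <- recording$samples
  if (nrow(s) == 0L) stop("empty recording", call. = FALSE)
  ok <- (s$valid_left | s$valid_right) &
    !is.na(s$x) & !is.na(s$y) &
    s$x >= 0 & s$x < screen_width & s$y >= 0 & s$y < screen_height
  sum(ok) / nrow(s)
}

#' Apply the two-stage inclusion filters
#'
#' Stage 1 drops every recording whose [screen_looking_fraction()] falls
#' below `segment_min` (default 25%). Stage 2 drops every subject whose
#' fraction of retained recordings, out of trials presented, falls below
#' `subject_min` (default 50%). Both drops are logged.
#'
#' @param recordings list of [gaze_recording()] objects.
#' @param spec a [stimulus_spec()], or a list of them; each recording's
#'   screen bounds are taken from the spec whose `stimulus_id` matches (a
#'   single spec is applied to all recordings).
#' @param segment_min,subject_min fractions in `[0, 1]`.
#' @param presented optional named integer vector: trials presented per
#'   subject (the subject-stage denominator). Defaults to the number of
#'   recordings supplied per subject.
#' @return list with `retained` (list of recordings) and `exclusions`
#'   (data frame: `subject_id`, `stimulus_id`, `stage`, `fraction`,
#'   `threshold`). Subject-stage rows carry `NA` for `stimulus_id`.
#' @export
apply_inclusion_filters <- function(recordings, spec,
                                    segment_min = 0.25, subject_min = 0.50,
                                    presented = NULL) {
  stopifnot(segment_min >= 0, segment_min <= 1,
            subject_min >= 0, subject_min <= 1)
  empty_log <- data.frame(subject_id = character(), stimulus_id = character(),
                          stage = character(), fraction = numeric(),
                          threshold = numeric(), stringsAsFactors = FALSE)
  if (length(recordings) == 0L)
    return(list(retained = list(), exclusions = empty_log))

  spec_for <- function(rec) {
    if (inherits(spec, "stimulus_spec")) return(spec)
    for (sp in spec) if (sp$stimulus_id == rec$stimulus_id) return(sp)
    stop("no stimulus spec for stimulus_id ", rec$stimulus_id, call. = FALSE)
  }
  subj <- vapply(recordings, function(r) r$subject_id, character(1))
  frac <- vapply(recordings, function(r) {
    sp <- spec_for(r)
    screen_looking_fraction(r, sp$screen_width, sp$screen_height)
  }, numeric(1))

  seg_ok <- frac >= segment_min
  log <- empty_log
  if (any(!seg_ok)) {
    log <- rbind(log, data.frame(
      subject_id = subj[!seg_ok],
      stimulus_id = vapply(recordings[!seg_ok], function(r) r$stimulus_id,
                           character(1)),
      stage = "segment", fraction = frac[!seg_ok],
      threshold = segment_min, stringsAsFactors = FALSE))
  }

  if (is.null(presented)) {
    presented <- table(subj)
    presented <- stats::setNames(as.integer(presented), names(presented))
  }
  kept_per_subj <- vapply(names(presented), function(id)
    sum(seg_ok & subj == id), integer(1))
  subj_frac <- kept_per_subj / as.numeric(presented)
  subj_ok <- subj_frac >= subject_min
  if (any(!subj_ok)) {
    drop_ids <- names(presented)[!subj_ok]
    log <- rbind(log, data.frame(
      subject_id = drop_ids, stimulus_id = NA_character_,
      stage = "subject", fraction = subj_frac[!subj_ok],
      threshold = subject_min, stringsAsFactors = FALSE))
  }
  keep <- seg_ok & subj %in% names(presented)[subj_ok]
  rownames(log) <- NULL
  list(retained = recordings[keep], exclusions = log)
}
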
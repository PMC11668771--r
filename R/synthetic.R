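SIM_STATES <- c("FAVORED", "OTHER", "VACANT", "OFFSCREEN")

#' Parameters of the Markov gaze generator
#'
#' The simulator emits one attention state per sampling step from a
#' first-order Markov chain over `{FAVORED, OTHER, VACANT, OFFSCREEN}`:
#' looking at the current block's favored AOI, at a competing AOI, at the
#' screen outside every AOI, or off the screen. Each emitted state is
#' rendered as a gaze point drawn uniformly within the corresponding
#' region. Sample-level dropout (both eyes invalid) is overlaid with
#' probability `invalid_rate`. After a block change the chain keeps
#' treating the previous block's target as FAVORED for a geometrically
#' distributed number of samples with mean `reorient_latency_ms`,
#' emulating reorientation latency.
#'
#' @param transition 4x4 row-stochastic matrix over the states above (rows
#'   in the order FAVORED, OTHER, VACANT, OFFSCREEN), or a list of one such
#'   matrix per stimulus block.
#' @param reorient_latency_ms mean reorientation lag after a block change.
#' @param invalid_rate per-sample probability that both eyes are invalid,
#'   in `[0, 1)`.
#' @param pupil_mean,pupil_sd pupil diameter distribution (mm).
#' @param sampling_rate_hz simulated sampling rate; defaults to 120 Hz,
#'   the native rate of the reference tracker hardware.
#' @return an object of class `gaze_model_params`.
#' @export
gaze_model_params <- function(transition, reorient_latency_ms = 250,
                              invalid_rate = 0.08, pupil_mean = 3.5,
                              pupil_sd = 0.4, sampling_rate_hz = 120) {
  if (is.matrix(transition)) transition <- list(transition)
  transition <- lapply(transition, function(P) {
    P <- as.matrix(P)
    if (!all(dim(P) == c(4L, 4L)))
      stop("each transition matrix must be 4x4 over ",
           paste(SIM_STATES, collapse = ", "), call. = FALSE)
    if (any(P < 0)) stop("transition probabilities must be >= 0",
                         call. = FALSE)
    if (any(abs(rowSums(P) - 1) > 1e-9))
      stop("each transition row must sum to 1 (within 1e-9)", call. = FALSE)
    dimnames(P) <- list(SIM_STATES, SIM_STATES)
    P
  })
  stopifnot(reorient_latency_ms >= 0, invalid_rate >= 0, invalid_rate < 1,
            pupil_sd >= 0, pupil_mean > 0, sampling_rate_hz > 0)
  structure(list(transition = transition,
                 reorient_latency_ms = reorient_latency_ms,
                 invalid_rate = invalid_rate, pupil_mean = pupil_mean,
                 pupil_sd = pupil_sd, sampling_rate_hz = sampling_rate_hz),
            class = "gaze_model_params")
}

#' @export
print.gaze_model_params <- function(x, ...) {
  cat(sprintf("<gaze_model_params> %d block matrix/matrices, %g Hz, invalid_rate=%g\n",
              length(x$transition), x$sampling_rate_hz, x$invalid_rate))
  invisible(x)
}

# lazy chain (1-a) I + a 1 pi': stationary distribution is exactly pi and
# mean dwell in a state scales with 1/a
lazy_chain <- function(pi, a) {
  (1 - a) * diag(4) + a * matrix(pi, 4, 4, byrow = TRUE)
}

#' Preset generator parameters for the two screening groups
#'
#' Two labeled presets whose effect directions mirror the screening
#' findings: the `asd_like` preset has lower favored-AOI occupancy (lower
#' FAS), a stickier chain with less AOI-to-AOI traffic (lower ASC), and
#' higher vacancy occupancy (higher AVC) than `non_asd_like`. Transition
#' matrices are lazy chains, so the stationary occupancy equals the preset
#' occupancy vector exactly: conditional on being on-screen-and-attending,
#' vacancy occupancy is 0.40 for `asd_like` and 0.15 for `non_asd_like`.
#' Magnitudes are synthetic presets for testing and power analysis; they
#' are not fitted to any cohort.
#'
#' @param group `"asd_like"` or `"non_asd_like"`.
#' @return a [gaze_model_params()].
#' @export
preset_gaze_params <- function(group = c("asd_like", "non_asd_like")) {
  group <- match.arg(group)
  if (group == "asd_like")
    gaze_model_params(lazy_chain(c(0.35, 0.22, 0.38, 0.05), a = 0.02),
                      invalid_rate = 0.12)
  else
    gaze_model_params(lazy_chain(c(0.68, 0.153, 0.147, 0.02), a = 0.05),
                      invalid_rate = 0.08)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi = pi P` by eigen-decomposition of `t(P)`.
#'
#' @param P row-stochastic square matrix.
#' @return probability vector named like the columns of `P`.
#' @export
markov_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), colnames(P))
}

sample_in_polygon <- function(n, polygon) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  for (iter in 1:1000) {
    m <- max(2L * (n - length(out_x)), 16L)
    cx <- stats::runif(m, xr[1], xr[2]); cy <- stats::runif(m, yr[1], yr[2])
    keep <- pracma::inpolygon(cx, cy, polygon[, 1], polygon[, 2],
                              boundary = TRUE)
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
    if (length(out_x) >= n) break
  }
  if (length(out_x) < n)
    stop("rejection sampling failed: polygon acceptance rate too low",
         call. = FALSE)
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

sample_vacant_point <- function(n, spec) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  out_x <- numeric(0); out_y <- numeric(0)
  for (iter in 1:1000) {
    m <- max(2L * (n - length(out_x)), 16L)
    cx <- stats::runif(m, 0, spec$screen_width)
    cy <- stats::runif(m, 0, spec$screen_height)
    inside <- rep(FALSE, m)
    for (a in spec$aois)
      inside <- inside | points_in_aoi(cx, cy, a)
    out_x <- c(out_x, cx[!inside]); out_y <- c(out_y, cy[!inside])
    if (length(out_x) >= n) break
  }
  if (length(out_x) < n)
    stop("rejection sampling failed: AOIs leave no vacant screen area",
         call. = FALSE)
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

sample_offscreen_point <- function(n, spec) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  w <- spec$screen_width; h <- spec$screen_height
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2L * (n - length(out_x)), 16L)
    cx <- stats::runif(m, -0.15 * w, 1.15 * w)
    cy <- stats::runif(m, -0.15 * h, 1.15 * h)
    off <- cx < 0 | cx >= w | cy < 0 | cy >= h
    out_x <- c(out_x, cx[off]); out_y <- c(out_y, cy[off])
  }
  cbind(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Simulate one gaze recording
#'
#' Runs the Markov attention chain over the stimulus's time blocks and
#' renders each state as a gaze sample: FAVORED/OTHER states land uniformly
#' inside the corresponding AOI polygon of the current block (with
#' geometric reorientation lag after block changes), VACANT lands uniformly
#' on the screen outside every AOI, OFFSCREEN lands in a band outside the
#' screen. Dropout samples have both eyes invalid and missing coordinates.
#' For stimuli without a favored pathway, FAVORED maps to the
#' first-declared AOI throughout.
#'
#' @param params a [gaze_model_params()]; block-specific matrices are
#'   recycled when fewer matrices than blocks are supplied.
#' @param spec a [stimulus_spec()].
#' @param seed optional integer; when supplied, the recording is a pure
#'   function of `(params, spec, seed)`.
#' @param subject_id identifier for the resulting recording.
#' @return a [gaze_recording()].
#' @export
simulate_recording <- function(params, spec, seed = NULL,
                               subject_id = "sim") {
  stopifnot(inherits(params, "gaze_model_params"),
            inherits(spec, "stimulus_spec"))
  if (!is.null(seed)) set.seed(seed)
  interval <- 1000 / params$sampling_rate_hz
  n <- floor(spec$duration_ms / interval)
  t <- (seq_len(n) - 1L) * interval

  blk <- block_index_of(t, spec)
  # samples in inter-block gaps follow the most recent block's dynamics
  if (anyNA(blk)) {
    last <- 1L
    for (i in seq_len(n)) {
      if (is.na(blk[i])) blk[i] <- last else last <- blk[i]
    }
  }
  n_blocks <- length(spec$blocks)
  trans <- rep_len(params$transition, n_blocks)
  cum <- lapply(trans, function(P) t(apply(P, 1, cumsum)))
  states <- markov_path_cpp(n, blk, cum, init_state = 1L)

  nm <- aoi_names(spec)
  fav_by_block <- vapply(spec$blocks, function(b)
    if (is.null(b$favored_aoi)) nm[1] else b$favored_aoi, character(1))
  eff_fav <- fav_by_block[blk]
  if (params$reorient_latency_ms > 0 && n > 1L) {
    p_reorient <- interval / (interval + params$reorient_latency_ms)
    changes <- which(diff(blk) != 0L) + 1L
    for (ch in changes) {
      lag <- stats::rgeom(1, p_reorient)
      if (lag > 0)
        eff_fav[ch:min(ch + lag - 1L, n)] <- eff_fav[ch - 1L]
    }
  }

  label <- character(n)
  label[states == 1L] <- eff_fav[states == 1L]
  if (any(states == 2L)) {
    oth <- which(states == 2L)
    if (length(nm) == 1L) {
      label[oth] <- LABEL_VACANT
    } else {
      pick <- function(fav) {
        rest <- setdiff(nm, fav)
        if (length(rest) == 1L) rest else sample(rest, 1L)
      }
      label[oth] <- vapply(eff_fav[oth], pick, character(1))
    }
  }
  label[states == 3L] <- LABEL_VACANT
  label[states == 4L] <- LABEL_OFFSCREEN

  x <- numeric(n); y <- numeric(n)
  for (a in spec$aois) {
    idx <- which(label == a$name)
    pts <- sample_in_polygon(length(idx), a$polygon)
    x[idx] <- pts[, 1]; y[idx] <- pts[, 2]
  }
  idx <- which(label == LABEL_VACANT)
  pts <- sample_vacant_point(length(idx), spec)
  x[idx] <- pts[, 1]; y[idx] <- pts[, 2]
  idx <- which(label == LABEL_OFFSCREEN)
  pts <- sample_offscreen_point(length(idx), spec)
  x[idx] <- pts[, 1]; y[idx] <- pts[, 2]

  invalid <- stats::runif(n) < params$invalid_rate
  x[invalid] <- NA_real_; y[invalid] <- NA_real_
  clamp_pupil <- function(p) pmin(pmax(p, 0.5), 9.5)
  pl <- clamp_pupil(stats::rnorm(n, params$pupil_mean, params$pupil_sd))
  pr <- clamp_pupil(stats::rnorm(n, params$pupil_mean, params$pupil_sd))
  pl[invalid] <- NA_real_; pr[invalid] <- NA_real_

  samples <- data.frame(t = t, x = x, y = y,
                        valid_left = !invalid, valid_right = !invalid,
                        pupil_left = pl, pupil_right = pr)
  gaze_recording(subject_id, spec$stimulus_id, samples,
                 sampling_interval = interval)
}

#' Parameters of a synthetic two-group cohort
#'
#' Bundles group sizes, per-group generator parameters and the severity
#' link: ADOS-like total score = `severity_base` + `severity_gain` x group
#' latent trait (1 for the ASD-like group, 0 otherwise) + Gaussian noise,
#' rounded to an integer and truncated to the 1-10 CSS range. SA and RRB
#' subscale scores are the total plus unit-variance noise, truncated the
#' same way.
#'
#' @param n_asd,n_nonasd subjects per group, each `>= 1`.
#' @param params_asd,params_nonasd [gaze_model_params()] per group.
#' @param severity_base,severity_gain,severity_sd severity link parameters.
#' @param seed optional integer seed governing the whole cohort.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_asd, n_nonasd,
                          params_asd = preset_gaze_params("asd_like"),
                          params_nonasd = preset_gaze_params("non_asd_like"),
                          severity_base = 2.5, severity_gain = 4,
                          severity_sd = 1.5, seed = NULL) {
  stopifnot(n_asd >= 1, n_nonasd >= 1, severity_sd >= 0)
  structure(list(n_asd = as.integer(n_asd), n_nonasd = as.integer(n_nonasd),
                 params_asd = params_asd, params_nonasd = params_nonasd,
                 severity_base = severity_base,
                 severity_gain = severity_gain, severity_sd = severity_sd,
                 seed = seed),
            class = "cohort_params")
}

clamp_css <- function(v) pmin(pmax(round(v), 1), 10)

#' Simulate a two-group cohort
#'
#' Draws a roster (group labels, severity scores under the cohort's
#' severity link, age and sex) and one recording per subject per stimulus.
#' With `cohort$seed` set, the output is a pure function of the inputs.
#'
#' @param cohort a [cohort_params()].
#' @param specs a [stimulus_spec()] or list of them (one recording per
#'   subject per spec).
#' @return list with `recordings` (list of [gaze_recording()]) and
#'   `roster` (a `subject_roster` data frame).
#' @export
simulate_cohort <- function(cohort, specs) {
  stopifnot(inherits(cohort, "cohort_params"))
  if (inherits(specs, "stimulus_spec")) specs <- list(specs)
  if (!is.null(cohort$seed)) set.seed(cohort$seed)

  n <- cohort$n_asd + cohort$n_nonasd
  group <- c(rep("ASD", cohort$n_asd), rep("non-ASD", cohort$n_nonasd))
  ids <- sprintf("%s_%02d", ifelse(group == "ASD", "asd", "nonasd"),
                 c(seq_len(cohort$n_asd), seq_len(cohort$n_nonasd)))
  trait <- as.numeric(group == "ASD")
  total <- clamp_css(cohort$severity_base + cohort$severity_gain * trait +
                       stats::rnorm(n, 0, cohort$severity_sd))
  roster <- as_roster(data.frame(
    subject_id = ids, group = group,
    ados_total = total,
    ados_sa = clamp_css(total + stats::rnorm(n)),
    ados_rrb = clamp_css(total + stats::rnorm(n)),
    age_months = round(stats::runif(n, 18, 84)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE))

  recordings <- list()
  for (i in seq_len(n)) {
    par <- if (group[i] == "ASD") cohort$params_asd else cohort$params_nonasd
    for (sp in specs)
      recordings[[length(recordings) + 1L]] <-
        simulate_recording(par, sp, seed = NULL, subject_id = ids[i])
  }
  list(recordings = recordings, roster = roster)
}
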
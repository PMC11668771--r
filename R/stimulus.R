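#' Declare an area of interest
#'
#' An AOI is a named simple polygon in screen-pixel coordinates. Rectangles
#' are the common case and are expressed as 4-vertex polygons; any simple
#' (non-self-intersecting) polygon with positive area is accepted.
#'
#' @param name unique (within a stimulus) non-empty identifier.
#' @param polygon numeric matrix or data frame with two columns (x, y) and
#'   at least 3 rows, listing vertices in order, unclosed.
#' @return an object of class `aoi_region`.
#' @export
aoi_region <- function(name, polygon) {
  if (!nzchar(name)) stop("AOI name must be non-empty", call. = FALSE)
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("AOI '", name, "': polygon needs >= 3 (x, y) vertices", call. = FALSE)
  if (anyNA(polygon))
    stop("AOI '", name, "': polygon vertices must be finite", call. = FALSE)
  if (abs(polygon_area(polygon)) <= 0)
    stop("AOI '", name, "': degenerate polygon (zero area)", call. = FALSE)
  if (!polygon_is_simple(polygon))
    stop("AOI '", name, "': polygon is self-intersecting", call. = FALSE)
  dimnames(polygon) <- list(NULL, c("x", "y"))
  structure(list(name = name, polygon = polygon), class = "aoi_region")
}

# shoelace signed area
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# O(n^2) proper-crossing check between non-adjacent edges; adequate for the
# handful of small polygons a stimulus declares
polygon_is_simple <- function(p) {
  n <- nrow(p)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (segments_intersect(p[idx[i], ], p[idx[i + 1L], ],
                             p[idx[j], ], p[idx[j + 1L], ])) return(FALSE)
    }
  }
  TRUE
}

#' Declare a stimulus time block
#'
#' A block is a half-open interval `[start_ms, end_ms)` of the stimulus,
#' optionally carrying the AOI a typically developing viewer is expected to
#' attend during it (the favored AOI of the attention pathway).
#'
#' @param index 1-based block number.
#' @param start_ms,end_ms interval bounds in milliseconds, `start < end`.
#' @param favored_aoi name of the block's favored AOI, or `NULL` when the
#'   stimulus declares no attention pathway.
#' @return an object of class `time_block`.
#' @export
time_block <- function(index, start_ms, end_ms, favored_aoi = NULL) {
  if (!(start_ms < end_ms))
    stop("block ", index, ": start_ms must be < end_ms", call. = FALSE)
  structure(list(index = as.integer(index), start_ms = start_ms,
                 end_ms = end_ms, favored_aoi = favored_aoi),
            class = "time_block")
}

#' Declare a stimulus
#'
#' Bundles the screen geometry, duration, AOI polygons and time blocks of
#' one stimulus presentation. Validity rules: AOI names unique; blocks
#' ordered, non-overlapping, inside `[0, duration_ms)`; every declared
#' `favored_aoi` names an AOI of this stimulus; all polygons lie within the
#' screen bounds.
#'
#' @param stimulus_id identifier.
#' @param screen_width,screen_height screen size in pixels.
#' @param duration_ms stimulus duration.
#' @param aois list of [aoi_region()] objects.
#' @param blocks list of [time_block()] objects (a single block spanning the
#'   stimulus is the degenerate, pathway-free case).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(stimulus_id, screen_width, screen_height,
                          duration_ms, aois, blocks) {
  stopifnot(screen_width > 0, screen_height > 0, duration_ms > 0)
  if (length(aois) == 0L) stop("a stimulus needs at least one AOI", call. = FALSE)
  nm <- vapply(aois, function(a) a$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate AOI name(s): ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  for (a in aois) {
    p <- a$polygon
    if (any(p[, 1] < 0 | p[, 1] > screen_width |
            p[, 2] < 0 | p[, 2] > screen_height))
      stop("AOI '", a$name, "' extends beyond the screen bounds", call. = FALSE)
  }
  if (length(blocks) == 0L) stop("a stimulus needs at least one block", call. = FALSE)
  starts <- vapply(blocks, function(b) b$start_ms, numeric(1))
  ends <- vapply(blocks, function(b) b$end_ms, numeric(1))
  if (is.unsorted(starts, strictly = TRUE))
    stop("blocks must be ordered by start_ms", call. = FALSE)
  if (any(ends[-length(ends)] > starts[-1]))
    stop("blocks must not overlap", call. = FALSE)
  if (any(starts < 0) || any(ends > duration_ms))
    stop("blocks must lie within [0, duration_ms)", call. = FALSE)
  for (b in blocks) {
    if (!is.null(b$favored_aoi) && !b$favored_aoi %in% nm)
      stop("block ", b$index, ": favored_aoi '", b$favored_aoi,
           "' names no AOI of this stimulus", call. = FALSE)
  }
  structure(list(stimulus_id = as.character(stimulus_id),
                 screen_width = screen_width, screen_height = screen_height,
                 duration_ms = duration_ms, aois = aois, blocks = blocks),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  path <- favored_pathway(x)
  cat(sprintf("<stimulus_spec> %s: %gx%g px, %g ms, %d AOI(s) [%s], %d block(s)%s\n",
              x$stimulus_id, x$screen_width, x$screen_height, x$duration_ms,
              length(x$aois),
              paste(vapply(x$aois, `[[`, character(1), "name"), collapse = ", "),
              length(x$blocks),
              if (length(path)) paste0(", pathway: ", paste(path, collapse = "-"))
              else ", no pathway"))
  invisible(x)
}

aoi_names <- function(spec) vapply(spec$aois, `[[`, character(1), "name")

#' Favored-AOI pathway of a stimulus
#'
#' @param spec a [stimulus_spec()].
#' @return character vector of per-block favored AOI names, or a
#'   zero-length vector when no block declares one.
#' @export
favored_pathway <- function(spec) {
  path <- lapply(spec$blocks, `[[`, "favored_aoi")
  unlist(path[!vapply(path, is.null, logical(1))])
}

has_favored_pathway <- function(spec)
  all(!vapply(spec$blocks, function(b) is.null(b$favored_aoi), logical(1)))

#' Load a stimulus specification from JSON or YAML
#'
#' Schema: `{stimulus_id, screen: {width, height}, duration_ms,
#' aois: [{name, polygon: [[x, y], ...]}],
#' blocks: [{index, start_ms, end_ms, favored_aoi}]}` (`favored_aoi`
#' optional per block). Files ending in `.json` are parsed as JSON,
#' everything else as YAML (JSON being a YAML subset, either works).
#'
#' @param path config file.
#' @return a validated [stimulus_spec()].
#' @export
load_stimulus_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  stimulus_spec_from_list(cfg)
}

stimulus_spec_from_list <- function(cfg) {
  for (f in c("stimulus_id", "screen", "duration_ms", "aois", "blocks"))
    if (is.null(cfg[[f]])) stop("stimulus config lacks field '", f, "'",
                                call. = FALSE)
  aois <- lapply(cfg$aois, function(a) {
    poly <- do.call(rbind, lapply(a$polygon, function(v) unlist(v)))
    aoi_region(a$name, poly)
  })
  blocks <- lapply(cfg$blocks, function(b)
    time_block(b$index, b$start_ms, b$end_ms, b$favored_aoi))
  stimulus_spec(cfg$stimulus_id, cfg$screen$width, cfg$screen$height,
                cfg$duration_ms, aois, blocks)
}

#' Built-in stimulus specifications
#'
#' Two ready-made specs matching the screening paradigm's videos on a
#' 1024x768 screen. `video1_joint_attention()` (25 s): a woman's face on the
#' left half and a tablet on the right half, four equal 6250 ms blocks with
#' the favored pathway tablet-face-tablet-face (tablet on-off-on-off).
#' `video2_speaking()` (10 s): a speaking face with an eyes AOI and a
#' nose-and-mouth AOI, a single block and no favored pathway. The default
#' polygons are nominal rectangles standing in for unpublished stimulus
#' geometry; real analyses should load measured polygons via
#' [load_stimulus_config()].
#'
#' @return a [stimulus_spec()].
#' @export
video1_joint_attention <- function() {
  face <- aoi_region("face", rbind(c(64, 96), c(448, 96),
                                   c(448, 672), c(64, 672)))
  tablet <- aoi_region("tablet", rbind(c(576, 192), c(960, 192),
                                       c(960, 576), c(576, 576)))
  q <- 25000 / 4
  path <- c("tablet", "face", "tablet", "face")
  blocks <- lapply(1:4, function(i)
    time_block(i, (i - 1) * q, i * q, path[i]))
  stimulus_spec("video1_joint_attention", 1024, 768, 25000,
                list(face, tablet), blocks)
}

#' @rdname video1_joint_attention
#' @export
video2_speaking <- function() {
  eyes <- aoi_region("eyes", rbind(c(352, 192), c(672, 192),
                                   c(672, 320), c(352, 320)))
  mouth <- aoi_region("mouth", rbind(c(384, 384), c(640, 384),
                                     c(640, 544), c(384, 544)))
  stimulus_spec("video2_speaking", 1024, 768, 10000, list(eyes, mouth),
                list(time_block(1, 0, 10000)))
}

#' Time block containing a timestamp
#'
#' @param t milliseconds since stimulus onset, `t >= 0`.
#' @param spec a [stimulus_spec()].
#' @return the 1-based index of the block with `start_ms <= t < end_ms`, or
#'   `NA_integer_` when `t` falls in no block.
#' @export
block_of <- function(t, spec) {
  stopifnot(t >= 0)
  for (b in spec$blocks) if (t >= b$start_ms && t < b$end_ms) return(b$index)
  NA_integer_
}

# vectorised block lookup: index per timestamp, NA outside all blocks
block_index_of <- function(t, spec) {
  out <- rep(NA_integer_, length(t))
  for (b in spec$blocks)
    out[t >= b$start_ms & t < b$end_ms] <- b$index
  out
}

points_in_aoi <- function(x, y, aoi) {
  p <- aoi$polygon
  pracma::inpolygon(x, y, p[, 1], p[, 2], boundary = TRUE)
}

#' Label every gaze sample of a recording
#'
#' Assigns each sample exactly one categorical label: `INVALID` when no eye
#' is valid, otherwise `OFFSCREEN` when the gaze point lies outside the
#' half-open screen rectangle, otherwise the name of the first declared AOI
#' whose polygon contains the point (boundary-inclusive; first-declared wins
#' where test AOIs overlap), otherwise `VACANT` — on-screen but on neither
#' AOI, the raw material of the AOI vacancy count.
#'
#' @param recording a [gaze_recording()].
#' @param spec the matching [stimulus_spec()].
#' @return an object of class `label_sequence`: a data frame `(t, label)`
#'   with the sampling interval, stimulus duration and AOI names attached as
#'   attributes.
#' @export
assign_labels <- function(recording, spec) {
  if (!identical(recording$stimulus_id, spec$stimulus_id))
    stop("recording stimulus_id '", recording$stimulus_id,
         "' does not match spec '", spec$stimulus_id, "'", call. = FALSE)
  s <- recording$samples
  n <- nrow(s)
  label <- rep(LABEL_VACANT, n)
  invalid <- !(s$valid_left | s$valid_right) | is.na(s$x) | is.na(s$y)
  off <- !invalid & (s$x < 0 | s$x >= spec$screen_width |
                     s$y < 0 | s$y >= spec$screen_height)
  open <- !invalid & !off   # candidates for AOI / VACANT
  for (a in rev(spec$aois)) {
    # reverse order so that the first-declared AOI overwrites later ones
    hit <- open
    hit[open] <- points_in_aoi(s$x[open], s$y[open], a)
    label[hit] <- a$name
  }
  label[off] <- LABEL_OFFSCREEN
  label[invalid] <- LABEL_INVALID
  label_sequence(s$t, label, recording$sampling_interval, spec)
}

label_sequence <- function(t, label, sampling_interval, spec) {
  structure(data.frame(t = t, label = label, stringsAsFactors = FALSE),
            sampling_interval = sampling_interval,
            duration_ms = spec$duration_ms,
            stimulus_id = spec$stimulus_id,
            aoi_names = aoi_names(spec),
            class = c("label_sequence", "data.frame"))
}

#' @export
print.label_sequence <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<label_sequence> %s: %d samples (%s)\n",
              attr(x, "stimulus_id"), nrow(x),
              paste(names(tab), as.integer(tab), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Export a label sequence as a two-column CSV for audit
#'
#' @param labels a `label_sequence` from [assign_labels()].
#' @param path output CSV file.
#' @export
write_label_sequence <- function(labels, path) {
  utils::write.csv(as.data.frame(labels)[, c("t", "label")], path,
                   row.names = FALSE)
  invisible(path)
}
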
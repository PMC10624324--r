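# Reading, validating and cleaning OpenPose BODY_25 keypoint data.

#' Construct a pose sequence
#'
#' Low-level constructor for the container holding one recording (one subject
#' performing one functional test): an ordered series of BODY_25 skeleton
#' frames with per-keypoint confidences and missingness flags.
#'
#' @param coords Numeric array `n_frames x 25 x 2` of pixel coordinates
#'   (image convention: origin top-left, y increases downward).
#' @param confidence Numeric matrix `n_frames x 25` of detector confidences
#'   in `[0, 1]`.
#' @param missing Logical matrix `n_frames x 25`; `TRUE` marks keypoints whose
#'   coordinates must not be consumed by kinematics.
#' @param fps Frames per second (> 0; the study camera recorded at 30).
#' @param subject_id Opaque recording/subject identifier.
#' @param test_id One of `"SLST"`, `"SDT"`.
#' @param limb One of `"left"`, `"right"`, `"unspecified"`.
#' @param frame_index Strictly increasing integer frame ordinals (>= 0);
#'   defaults to `0:(n_frames - 1)`.
#'
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, confidence, missing, fps = 30,
                          subject_id = "subject", test_id = "SLST",
                          limb = "unspecified", frame_index = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 25, dim(coords)[3] == 2)
  n <- dim(coords)[1]
  if (n < 2) ms_stop("insufficient_data", "a pose sequence needs >= 2 frames, got %d", n)
  if (!is.numeric(fps) || fps <= 0) ms_stop("bad_argument", "fps must be > 0")
  test_id <- match.arg(test_id, c("SLST", "SDT"))
  limb <- match.arg(limb, c("left", "right", "unspecified"))
  if (is.null(frame_index)) frame_index <- 0:(n - 1)
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n || any(diff(frame_index) <= 0) || frame_index[1] < 0)
    ms_stop("bad_argument", "frame_index must be strictly increasing and >= 0")
  dimnames(coords) <- list(NULL, BODY25_NAMES, c("x", "y"))
  colnames(confidence) <- BODY25_NAMES
  colnames(missing) <- BODY25_NAMES
  structure(
    list(coords = coords, confidence = confidence, missing = missing,
         fps = fps, subject_id = subject_id, test_id = test_id, limb = limb,
         frame_index = frame_index),
    class = "pose_sequence"
  )
}

#' @export
print.pose_sequence <- function(x, ...) {
  n <- dim(x$coords)[1]
  cat(sprintf(
    "<pose_sequence> %s / %s / %s limb: %d frames @ %g fps (%.2f s), %d keypoints missing\n",
    x$subject_id, x$test_id, x$limb, n, x$fps, n / x$fps, sum(x$missing)))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Timestamps of a pose sequence
#' @param seq A `pose_sequence`.
#' @return Numeric vector of seconds, `frame_index / fps`.
#' @export
timestamps <- function(seq) seq$frame_index / seq$fps

#' Read one OpenPose frame document
#'
#' Parses a single per-frame JSON document in the OpenPose output dialect: a
#' top-level `"people"` array whose entries carry a flat `"pose_keypoints_2d"`
#' vector of 75 numbers (25 keypoints times x, y, confidence). Keypoints with
#' confidence below `missing_threshold` or with coordinates exactly `(0, 0)`
#' (OpenPose's convention for undetected joints) are flagged missing.
#'
#' @param doc A parsed JSON document (list), a JSON string, or a path to a
#'   JSON file.
#' @param person_policy How to resolve frames with several detected people:
#'   `"best_confidence"` (default; keep the person with the highest mean
#'   keypoint confidence, first wins ties) or `"first"`.
#' @param missing_threshold Confidence below which a keypoint is flagged
#'   missing (default 0.1).
#'
#' @return A list with `xy` (25 x 2 matrix), `confidence` (length 25) and
#'   `missing` (logical length 25), of class `pose_frame`.
#' @export
read_openpose_frame <- function(doc,
                                person_policy = c("best_confidence", "first"),
                                missing_threshold = 0.1) {
  person_policy <- match.arg(person_policy)
  if (is.character(doc) && length(doc) == 1) {
    doc <- if (file.exists(doc)) jsonlite::read_json(doc, simplifyVector = FALSE)
           else jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  if (!is.list(doc) || is.null(doc[["people"]]))
    ms_stop("format_error", "frame document lacks required key 'people'")
  people <- doc[["people"]]
  if (length(people) == 0)
    ms_stop("empty_frame", "frame document contains zero people")
  mats <- lapply(people, function(p) {
    kp <- p[["pose_keypoints_2d"]]
    if (is.null(kp))
      ms_stop("format_error", "person record lacks required key 'pose_keypoints_2d'")
    kp <- suppressWarnings(as.numeric(unlist(kp)))
    if (length(kp) != 75 || anyNA(kp))
      ms_stop("format_error",
              "'pose_keypoints_2d' must hold 75 numbers, got %d", length(kp))
    matrix(kp, nrow = 25, ncol = 3, byrow = TRUE,
           dimnames = list(BODY25_NAMES, c("x", "y", "confidence")))
  })
  pick <- if (person_policy == "first" || length(mats) == 1) 1L
          else which.max(vapply(mats, function(m) mean(m[, "confidence"]), 0))
  m <- mats[[pick]]
  missing <- m[, "confidence"] < missing_threshold |
             (m[, "x"] == 0 & m[, "y"] == 0)
  structure(
    list(xy = m[, c("x", "y"), drop = FALSE],
         confidence = unname(m[, "confidence"]),
         missing = unname(missing)),
    class = "pose_frame"
  )
}

#' Read an ordered collection of frame documents into a pose sequence
#'
#' @param docs Either a character vector of per-frame JSON file paths (read in
#'   the given order; the standard `*_keypoints.json` layout sorts correctly),
#'   the path of a single JSON-lines file (one frame document per line), or a
#'   list of parsed frame documents.
#' @param fps Frames per second (default 30).
#' @param subject_id,test_id,limb Recording metadata, see [pose_sequence()].
#' @param person_policy,missing_threshold Passed to [read_openpose_frame()].
#'
#' @return A `pose_sequence`. Frames with zero people are dropped; the gaps
#'   they leave are recorded in `attr(, "cleaning_report")` (fields
#'   `frames_read`, `frames_dropped`, `dropped_indices`).
#' @export
read_pose_sequence <- function(docs, fps = 30, subject_id = "subject",
                               test_id = "SLST", limb = "unspecified",
                               person_policy = "best_confidence",
                               missing_threshold = 0.1) {
  if (is.character(docs) && length(docs) == 1 && file.exists(docs) &&
      !dir.exists(docs) && grepl("\\.jsonl$", docs)) {
    docs <- lapply(readLines(docs), jsonlite::fromJSON, simplifyVector = FALSE)
  } else if (is.character(docs)) {
    docs <- lapply(docs, jsonlite::read_json, simplifyVector = FALSE)
  }
  n_in <- length(docs)
  frames <- vector("list", n_in)
  dropped <- integer(0)
  for (i in seq_len(n_in)) {
    f <- tryCatch(
      read_openpose_frame(docs[[i]], person_policy = person_policy,
                          missing_threshold = missing_threshold),
      motionscreen_error = function(e) {
        if (inherits(e, "empty_frame")) NULL else stop(e)
      })
    if (is.null(f)) dropped <- c(dropped, i - 1L) else frames[[i]] <- f
  }
  keep <- !vapply(frames, is.null, TRUE)
  frames <- frames[keep]
  if (length(frames) < 2)
    ms_stop("insufficient_data", "need >= 2 usable frames, got %d", length(frames))
  n <- length(frames)
  coords <- array(NA_real_, c(n, 25, 2))
  conf <- matrix(NA_real_, n, 25)
  miss <- matrix(NA, n, 25)
  for (i in seq_len(n)) {
    coords[i, , ] <- frames[[i]]$xy
    conf[i, ] <- frames[[i]]$confidence
    miss[i, ] <- frames[[i]]$missing
  }
  seq <- pose_sequence(coords, conf, miss, fps = fps, subject_id = subject_id,
                       test_id = test_id, limb = limb,
                       frame_index = (0:(n_in - 1))[keep])
  attr(seq, "cleaning_report") <- list(
    frames_read = n_in, frames_dropped = length(dropped),
    dropped_indices = dropped)
  seq
}

#' Interpolate short keypoint dropouts
#'
#' Linearly interpolates the x and y coordinates of missing keypoints across
#' gaps of at most `max_gap_frames` frames, bounded on both sides by observed
#' frames. Longer gaps, and gaps touching the sequence ends, are left missing
#' and listed in the cleaning report. Fully observed sequences are returned
#' unchanged.
#'
#' @param seq A `pose_sequence`.
#' @param max_gap_frames Longest run of consecutive missing frames that will
#'   be filled (default 5, about 167 ms at 30 fps).
#'
#' @return The sequence with interpolated coordinates, `missing` cleared on
#'   filled frames, and `attr(, "fill_report")` listing filled and unfilled
#'   gaps as `(keypoint, start_frame, length)` rows.
#' @export
fill_missing <- function(seq, max_gap_frames = 5) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- n_frames(seq)
  filled <- unfilled <- list()
  for (k in 1:25) {
    mk <- seq$missing[, k]
    if (!any(mk)) next
    r <- rle(mk)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      a <- starts[j]; b <- ends[j]; len <- b - a + 1L
      gap <- list(keypoint = k - 1L, start_frame = seq$frame_index[a], length = len)
      if (a > 1 && b < n && len <= max_gap_frames) {
        for (d in 1:2) {
          seq$coords[a:b, k, d] <- stats::approx(
            x = c(a - 1L, b + 1L), y = seq$coords[c(a - 1L, b + 1L), k, d],
            xout = a:b)$y
        }
        seq$missing[a:b, k] <- FALSE
        filled[[length(filled) + 1L]] <- gap
      } else {
        unfilled[[length(unfilled) + 1L]] <- gap
      }
    }
  }
  attr(seq, "fill_report") <- list(filled = filled, unfilled = unfilled)
  seq
}

#' Write a pose sequence in the OpenPose JSON-lines dialect
#'
#' One frame document per line, each `{"frame_index": i, "people":
#' [{"pose_keypoints_2d": [x0, y0, c0, ...]}]}`. Missing keypoints are written
#' as `(0, 0, 0)`, OpenPose's own convention, so re-reading reproduces the
#' coordinates and missingness flags of observed keypoints exactly.
#'
#' @param seq A `pose_sequence`.
#' @param path Output file path (`.jsonl`).
#' @return `path`, invisibly.
#' @export
write_openpose_jsonl <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  n <- n_frames(seq)
  lines <- character(n)
  for (i in seq_len(n)) {
    flat <- as.vector(t(cbind(seq$coords[i, , ], seq$confidence[i, ])))
    flat[rep(seq$missing[i, ], each = 3)] <- 0
    lines[i] <- jsonlite::toJSON(
      list(frame_index = jsonlite::unbox(seq$frame_index[i]),
           people = list(list(pose_keypoints_2d = flat))),
      digits = I(17))   # shortest exact double round-trip needs 17 digits
  }
  writeLines(lines, path)
  invisible(path)
}

#' Tidy per-keypoint data frame of a pose sequence
#'
#' @param x A `pose_sequence`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data frame with columns `frame`, `keypoint_index`, `keypoint`,
#'   `x`, `y`, `confidence`, `missing`.
#' @export
as.data.frame.pose_sequence <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- n_frames(x)
  data.frame(
    frame = rep(x$frame_index, times = 25),
    keypoint_index = rep(0:24, each = n),
    keypoint = rep(BODY25_NAMES, each = n),
    x = as.vector(x$coords[, , 1]),
    y = as.vector(x$coords[, , 2]),
    confidence = as.vector(x$confidence),
    missing = as.vector(x$missing)
  )
}
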
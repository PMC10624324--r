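# Kinematic signals over BODY_25 keypoint series: joint angles,
# keypoint-pair orientations and trunk-normalized relative distances.
# Angles are held in degrees externally and radians internally.

deg <- function(rad) rad * 180 / pi

#' Interior angle at the vertex of three 2D points
#'
#' The angle ABC subtended at vertex `B` by points `A` and `C`, computed as
#' `arccos` of the normalized dot product of the vectors B->A and B->C. The
#' dot-product argument is clamped to `[-1, 1]` so collinear configurations
#' never overshoot the arccos domain through floating point.
#'
#' All arguments are either length-2 vectors or `n x 2` matrices (vectorized
#' over rows).
#'
#' @param A,B,C 2D points, `c(x, y)` or `n x 2` matrices.
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @export
joint_angle <- function(A, B, C) {
  A <- rbind(A); B <- rbind(B); C <- rbind(C)
  BA <- A - B[rep_len(seq_len(nrow(B)), nrow(A)), , drop = FALSE]
  BC <- C - B[rep_len(seq_len(nrow(B)), nrow(C)), , drop = FALSE]
  na <- sqrt(rowSums(BA^2)); nc <- sqrt(rowSums(BC^2))
  if (any(na == 0 | nc == 0))
    ms_stop("degenerate_geometry", "joint_angle: zero-length limb vector (point equals vertex)")
  cosang <- pmin(1, pmax(-1, rowSums(BA * BC) / (na * nc)))
  as.numeric(deg(acos(cosang)))
}

#' Orientation of a keypoint pair against the image horizontal
#'
#' The quadrant-aware angle of the vector A->B measured from the horizontal
#' of the image. Image coordinates grow downward, so y is negated before the
#' arctangent: a pair whose second point lies above the first on screen has a
#' positive orientation, and a vertical upward pair measures +90 degrees.
#'
#' @param A,B 2D points in image coordinates, `c(x, y)` or `n x 2` matrices.
#' @return Angle(s) in degrees, in `(-180, 180]`.
#' @export
pair_orientation <- function(A, B) {
  A <- rbind(A); B <- rbind(B)
  v <- B - A[rep_len(seq_len(nrow(A)), nrow(B)), , drop = FALSE]
  if (any(v[, 1] == 0 & v[, 2] == 0))
    ms_stop("degenerate_geometry", "pair_orientation: coincident points")
  ang <- deg(atan2(-v[, 2], v[, 1]))  # y-flip: image -> mathematical convention
  as.numeric(ifelse(ang <= -180, ang + 360, ang))
}

#' Trunk-normalized distance between two keypoints
#'
#' Euclidean pixel distance between `A` and `B` divided by the same frame's
#' trunk length, the neck (keypoint 1) to mid-hip (keypoint 8) distance. The
#' normalization removes body-height and camera-distance scale from the
#' signal, so values are dimensionless and comparable across subjects.
#'
#' @param A,B 2D points, `c(x, y)` or `n x 2` matrices.
#' @param neck,midhip The frame's neck and mid-hip keypoints (same shapes).
#' @param eps Smallest admissible trunk length in pixels (default 1).
#' @return Dimensionless ratio(s), `>= 0`.
#' @export
relative_distance <- function(A, B, neck, midhip, eps = 1) {
  A <- rbind(A); B <- rbind(B); neck <- rbind(neck); midhip <- rbind(midhip)
  d <- sqrt(rowSums((B - A)^2))
  trunk <- sqrt(rowSums((midhip - neck)^2))
  if (any(trunk <= eps))
    ms_stop("degenerate_normalizer",
            "relative_distance: trunk length <= %g px in %d frame(s)",
            eps, sum(trunk <= eps))
  as.numeric(d / trunk)
}

#' Define a kinematic signal
#'
#' @param name Signal identifier.
#' @param category One of `"joint_angle"`, `"pair_orientation"`,
#'   `"relative_distance"`.
#' @param keypoints BODY_25 indices (0-based): three for `joint_angle`
#'   (A, vertex B, C), two otherwise. Must be pairwise distinct and in
#'   `[0, 24]`.
#' @return A `signal_def` list.
#' @export
signal_def <- function(name, category, keypoints) {
  category <- match.arg(category,
                        c("joint_angle", "pair_orientation", "relative_distance"))
  keypoints <- as.integer(keypoints)
  arity <- if (category == "joint_angle") 3L else 2L
  if (length(keypoints) != arity)
    ms_stop("bad_argument", "%s '%s' needs %d keypoints, got %d",
            category, name, arity, length(keypoints))
  if (any(keypoints < 0 | keypoints > 24) || anyDuplicated(keypoints))
    ms_stop("bad_argument", "keypoints must be distinct BODY_25 indices in [0, 24]")
  structure(list(name = name, category = category, keypoints = keypoints),
            class = "signal_def")
}

#' The default 15-signal catalogue
#'
#' The selected ranges of movement monitored during SLST/SDT assessment:
#' three keypoint-pair orientations (pelvis, shoulder girdle, spine), seven
#' joint angles (shoulders, hips, knees, trunk) and five relative distances.
#' The index tuples are kept exactly as published for the study cohort, even
#' where a signal's name and the BODY_25 anatomy of its indices disagree;
#' pass a custom catalogue (or [read_catalogue_yaml()]) to use corrected
#' anatomical definitions.
#'
#' @return A named list of 15 [signal_def()] objects, in catalogue order.
#' @export
default_catalogue <- function() {
  defs <- list(
    signal_def("Hips",                "pair_orientation",  c(9, 12)),
    signal_def("BothShoulders",       "pair_orientation",  c(2, 5)),
    signal_def("Spine",               "pair_orientation",  c(1, 8)),
    signal_def("NeckRShoulderRElbow", "joint_angle",       c(1, 2, 3)),
    signal_def("NeckLShoulderLElbow", "joint_angle",       c(1, 5, 6)),
    signal_def("MidHipRHipRKnee",     "joint_angle",       c(8, 9, 10)),
    signal_def("MidHipLHipLKnee",     "joint_angle",       c(8, 12, 13)),
    signal_def("RHipRKneeRAnkle",     "joint_angle",       c(9, 10, 11)),
    signal_def("LHipLKneeLAnkle",     "joint_angle",       c(12, 13, 14)),
    signal_def("NoseNeckMidHip",      "joint_angle",       c(0, 1, 8)),
    signal_def("NeckMidHip",          "relative_distance", c(1, 8)),
    signal_def("RWristMidHip",        "relative_distance", c(4, 7)),
    signal_def("RWristLWrist",        "relative_distance", c(4, 8)),
    signal_def("MidHipLSmallToe",     "relative_distance", c(8, 13)),
    signal_def("MidHipLRSmallToe",    "relative_distance", c(8, 10))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Read a signal catalogue from YAML
#'
#' The file holds a list of `{name, category, keypoints}` entries mirroring
#' [signal_def()].
#'
#' @param path YAML file path.
#' @return Named list of `signal_def` objects.
#' @export
read_catalogue_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(e)
    signal_def(e$name, e$category, unlist(e$keypoints)))
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Evaluate one signal definition over a pose sequence
#'
#' Applies the definition's category formula frame by frame. Frames in which
#' any contributing keypoint is missing — for `relative_distance` this
#' includes the neck and mid-hip normalizer keypoints — or whose geometry is
#' degenerate (coincident points, vanishing trunk) are marked invalid rather
#' than propagating errors.
#'
#' @param seq A `pose_sequence`.
#' @param def A [signal_def()].
#' @param eps Trunk-length floor in pixels for `relative_distance`.
#' @return A `kin_signal`: list with `name`, `values` (per-frame scalar,
#'   `NA` where invalid), `valid` (logical), `category`.
#' @export
compute_signal <- function(seq, def, eps = 1) {
  stopifnot(inherits(seq, "pose_sequence"), inherits(def, "signal_def"))
  idx <- kp_idx(def$keypoints)
  need <- if (def$category == "relative_distance") unique(c(idx, kp_idx(c(1, 8)))) else idx
  valid <- !apply(seq$missing[, need, drop = FALSE], 1, any)
  n <- n_frames(seq)
  values <- rep(NA_real_, n)
  if (any(valid)) {
    P <- lapply(idx, function(k) seq$coords[valid, k, , drop = FALSE][, 1, ])
    P <- lapply(P, rbind)  # keep matrix shape when one frame is valid
    res <- switch(def$category,
      joint_angle = {
        ok <- rowSums((P[[1]] - P[[2]])^2) > 0 & rowSums((P[[3]] - P[[2]])^2) > 0
        out <- rep(NA_real_, sum(valid))
        if (any(ok)) out[ok] <- joint_angle(P[[1]][ok, , drop = FALSE],
                                            P[[2]][ok, , drop = FALSE],
                                            P[[3]][ok, , drop = FALSE])
        out
      },
      pair_orientation = {
        ok <- rowSums((P[[2]] - P[[1]])^2) > 0
        out <- rep(NA_real_, sum(valid))
        if (any(ok)) out[ok] <- pair_orientation(P[[1]][ok, , drop = FALSE],
                                                 P[[2]][ok, , drop = FALSE])
        out
      },
      relative_distance = {
        neck <- rbind(seq$coords[valid, kp_idx(1), , drop = FALSE][, 1, ])
        hip <- rbind(seq$coords[valid, kp_idx(8), , drop = FALSE][, 1, ])
        trunk <- sqrt(rowSums((hip - neck)^2))
        ok <- trunk > eps
        out <- rep(NA_real_, sum(valid))
        if (any(ok)) out[ok] <- relative_distance(P[[1]][ok, , drop = FALSE],
                                                  P[[2]][ok, , drop = FALSE],
                                                  neck[ok, , drop = FALSE],
                                                  hip[ok, , drop = FALSE], eps = eps)
        out
      })
    values[valid] <- res
    valid[valid] <- !is.na(res)
  }
  if (!any(valid))
    ms_stop("empty_signal", "signal '%s': no valid frame", def$name)
  structure(list(name = def$name, values = values, valid = valid,
                 category = def$category),
            class = "kin_signal")
}

#' Evaluate a whole catalogue over a pose sequence
#'
#' @param seq A `pose_sequence`.
#' @param catalogue Named list of [signal_def()]s (default
#'   [default_catalogue()]).
#' @return Named list of `kin_signal` objects in catalogue order.
#' @export
compute_signals <- function(seq, catalogue = default_catalogue()) {
  lapply(catalogue, function(d) compute_signal(seq, d))
}

#' Tidy data frame of computed signals
#'
#' @param signals Named list of `kin_signal`s, as from [compute_signals()].
#' @return Data frame with columns `frame`, `signal`, `value`, `valid`.
#' @export
signals_to_df <- function(signals) {
  do.call(rbind, lapply(signals, function(s)
    data.frame(frame = seq_along(s$values) - 1L, signal = s$name,
               value = s$values, valid = s$valid, row.names = NULL)))
}
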
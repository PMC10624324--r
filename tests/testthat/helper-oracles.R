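# Independent reference implementations used to cross-check the package.
# These deliberately take different computational routes from the package
# code (law of cosines instead of dot products, pairwise agreement counting
# instead of the count-matrix kappa formula, flat stump enumeration instead
# of the recursive tree builder).

# Interior angle at B via the law of cosines on the triangle side lengths.
oracle_joint_angle <- function(A, B, C) {
  a <- sqrt(sum((C - B)^2))   # side opposite A
  c <- sqrt(sum((A - B)^2))   # side opposite C
  b <- sqrt(sum((C - A)^2))   # side opposite B
  acos(min(1, max(-1, (a^2 + c^2 - b^2) / (2 * a * c)))) * 180 / pi
}

# Orientation against the horizontal via acos of the normalized x component,
# signed by the mathematical-convention y component.
oracle_pair_orientation <- function(A, B) {
  dx <- B[1] - A[1]
  dy <- -(B[2] - A[2])  # image -> math convention
  r <- sqrt(dx^2 + dy^2)
  ang <- acos(min(1, max(-1, dx / r))) * 180 / pi
  if (dy < 0) ang <- -ang
  if (ang <= -180) ang + 360 else ang
}

# Fleiss kappa by explicit pairwise agreement counting.
oracle_fleiss <- function(ratings) {
  n <- nrow(ratings); r <- ncol(ratings)
  agree <- vapply(seq_len(n), function(i) {
    pairs <- utils::combn(r, 2)
    mean(apply(pairs, 2, function(p) ratings[i, p[1]] == ratings[i, p[2]]))
  }, 0)
  Pbar <- mean(agree)
  p1 <- mean(ratings); p0 <- 1 - p1
  Pe <- p0^2 + p1^2
  if (abs(1 - Pe) < 1e-12) return(1)
  (Pbar - Pe) / (1 - Pe)
}

# Discrete AdaBoost with exhaustive decision stumps, as one flat loop.
# Shares the package's documented split-determinism contract (midpoint
# thresholds, impurity at 1e-9 resolution, ties to lower feature then lower
# threshold, leaf ties to class 0) but none of its code.
oracle_adaboost_predict <- function(X, y, X_new, n_rounds, learning_rate = 1) {
  res <- 1e-9
  gini <- function(w1, w0) {
    s <- w1 + w0
    if (s <= 0) 0 else 1 - (w1 / s)^2 - (w0 / s)^2
  }
  fit_stump <- function(w) {
    best <- NULL
    best_imp <- round(gini(sum(w[y == 1]), sum(w[y == 0])) / res) * res
    for (j in seq_len(ncol(X))) {
      vals <- sort(unique(X[, j]))
      if (length(vals) < 2) next
      for (v in seq_len(length(vals) - 1)) {
        thr <- (vals[v] + vals[v + 1]) / 2
        L <- X[, j] <= thr
        wl1 <- sum(w[L & y == 1]); wl0 <- sum(w[L & y == 0])
        wr1 <- sum(w[!L & y == 1]); wr0 <- sum(w[!L & y == 0])
        imp <- (wl1 + wl0) * gini(wl1, wl0) + (wr1 + wr0) * gini(wr1, wr0)
        imp <- round((imp / sum(w)) / res) * res
        if (is.null(best) || imp < best_imp) {
          best <- list(j = j, thr = thr,
                       left = if (wl1 > wl0) 1L else 0L,
                       right = if (wr1 > wr0) 1L else 0L)
          best_imp <- imp
        }
      }
    }
    best
  }
  stump_pred <- function(st, M) {
    ifelse(M[, st$j] <= st$thr, st$left, st$right)
  }
  n <- nrow(X)
  w <- rep(1 / n, n)
  score <- rep(0, nrow(X_new))
  for (t in seq_len(n_rounds)) {
    st <- fit_stump(w)
    if (is.null(st)) {
      # no improving split: the weak learner degenerates to the weighted
      # majority constant (ties to class 0), as per the split contract
      maj <- if (sum(w[y == 1]) > sum(w[y == 0])) 1L else 0L
      st <- list(j = 1L, thr = Inf, left = maj, right = maj)
    }
    pred <- stump_pred(st, X)
    eps <- sum(w[pred != y])
    if (eps >= 0.5) break
    eps_c <- max(eps, 1e-10)
    alpha <- learning_rate * log((1 - eps_c) / eps_c)
    score <- score + alpha * (2 * stump_pred(st, X_new) - 1)
    if (eps == 0) break
    mis <- pred != y
    w[mis] <- w[mis] * exp(alpha)
    w <- w / sum(w)
  }
  as.integer(score > 0)
}

# 0-based BODY_25 index -> 1-based array index (mirrors the package internal)
kp_idx_test <- function(i) i + 1L

# An OpenPose frame document (parsed-list form) for given keypoint matrices.
make_frame_doc <- function(...) {
  people <- lapply(list(...), function(m) {
    list(pose_keypoints_2d = as.list(as.vector(t(m))))
  })
  list(version = 1.3, people = people)
}

# A 25 x 3 keypoint matrix with constant confidence.
flat_pose <- function(conf = 0.9, x0 = 600, y0 = 100) {
  cbind(x = x0 + seq(0, 240, by = 10), y = y0 + seq(0, 480, by = 20),
        confidence = rep(conf, 25))
}

# Random similarity transform applied to a set of 2D points (rows).
random_similarity <- function(pts, theta, scale, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t(scale * R %*% t(pts)) + matrix(shift, nrow(pts), 2, byrow = TRUE)
}
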
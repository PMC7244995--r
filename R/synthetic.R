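# Synthetic finger-to-nose videos with graded ataxia severity.
#
# Frame coordinates are (row, col), 0-based, origin at the top-left corner;
# this convention is used everywhere in the package.

#' Kinematics for an ataxia grade
#'
#' Grade-dependent trajectory noise at a given resolution: tremor amplitude
#' `2 * grade` pixels and jitter standard deviation `0.5 * grade` pixels at
#' 64x64, both scaled linearly with resolution. Grade 0 has exactly zero
#' tremor and jitter (a clean straight reach); higher grades add an
#' increasingly visible sinusoidal tremor, Gaussian clumsiness, and a chance
#' of an overshoot-and-correct excursion (`0.1 * grade`).
#'
#' @param grade integer ataxia grade in 0..4.
#' @param nFrames frames in the trajectory.
#' @param startPoint,endPoint (row, col) endpoints of the reach.
#' @param resolution frame side in pixels (noise scale reference).
#' @return a [TrajectorySpec-class].
#' @export
trajectoryForGrade <- function(grade, nFrames, startPoint, endPoint,
                               resolution = 64) {
  stopifnot(grade %in% 0:4)
  s <- resolution / 64
  trajectorySpec(nFrames = nFrames, startPoint = startPoint,
                 endPoint = endPoint,
                 tremorAmplitude = 2 * grade * s,
                 tremorFrequency = 3,
                 jitterSd = 0.5 * grade * s,
                 overshootProb = 0.1 * grade)
}

#' Simulate a fingertip trajectory
#'
#' Linear interpolation from the abducted-arm start to the nose target, plus
#' `tremorAmplitude * sin(2 pi tremorFrequency t/n)` applied perpendicular
#' to the path, Gaussian jitter of `jitterSd` pixels, and (with probability
#' `overshootProb`) an overshoot bump along the path near the end of the
#' reach. The first frame is exactly the start point and the final frame
#' touches the target up to tremor (jitter is suppressed on the first and
#' last frames: the hand is steady at rest and at touch).
#'
#' @param spec a [TrajectorySpec-class].
#' @param seed integer; output is a pure function of `(spec, seed)`.
#' @return numeric matrix `nFrames x 2` of (row, col) fingertip positions.
#' @export
simulateTrajectory <- function(spec, seed = 1) {
  stopifnot(is(spec, "TrajectorySpec"))
  validObject(spec)
  n <- spec@nFrames
  u <- seq(0, 1, length.out = n)
  delta <- spec@endPoint - spec@startPoint
  len <- sqrt(sum(delta^2))
  perp <- if (len > 0) c(-delta[2], delta[1]) / len else c(0, 1)

  with_seed(seed, {
    overshoot <- runif(1) < spec@overshootProb
    jitter <- matrix(rnorm(2 * n, 0, spec@jitterSd), n, 2)
  })
  jitter[c(1, n), ] <- 0
  u_eff <- u
  if (overshoot) u_eff <- u + 0.35 * exp(-((u - 0.75) / 0.12)^2) * (1 - u)

  tremor <- spec@tremorAmplitude * sin(2 * pi * spec@tremorFrequency * u)
  pts <- cbind(spec@startPoint[1] + u_eff * delta[1],
               spec@startPoint[2] + u_eff * delta[2]) +
    outer(tremor, perp) + jitter
  pts[1, ] <- spec@startPoint
  pts
}

#' Mean perpendicular deviation of a trajectory from the straight path
#'
#' The severity signal the generator encodes: the average unsigned distance
#' of the fingertip from the straight start-to-end line. Exactly 0 for a
#' grade-0 trajectory and increasing with grade.
#'
#' @param points `n x 2` trajectory matrix.
#' @param startPoint,endPoint (row, col) endpoints of the intended path.
#' @return numeric scalar (pixels).
#' @export
pathDeviation <- function(points, startPoint, endPoint) {
  delta <- endPoint - startPoint
  len <- sqrt(sum(delta^2))
  if (len == 0) {
    d <- sweep(points, 2, startPoint)
    return(mean(sqrt(rowSums(d^2))))
  }
  rel <- sweep(points, 2, startPoint)
  # signed perpendicular component (2-D cross product / path length)
  mean(abs(rel[, 1] * delta[2] - rel[, 2] * delta[1]) / len)
}

#' Generate a random subject identity
#'
#' Per-subject nuisance features: limb thickness, skin tone, background
#' texture seed, nose-target position and body depth offset, all drawn
#' deterministically from the seed.
#'
#' @param subjectId identifier.
#' @param resolution frame side in pixels.
#' @param seed integer seed.
#' @return a [SubjectIdentity-class].
#' @export
randomSubject <- function(subjectId, resolution = 64, seed = 1) {
  s <- resolution / 64
  with_seed(seed, {
    tone <- pmin(1, pmax(0, c(0.85, 0.65, 0.5) + rnorm(3, 0, 0.06)))
    subj <- subjectIdentity(
      subjectId = subjectId,
      limbThickness = max(1, (2.5 + runif(1, 0, 1.5)) * s),
      skinTone = tone,
      backgroundPatternSeed = sample.int(1e6, 1),
      noseTarget = c(0.3 * (resolution - 1) + runif(1, -2, 2) * s,
                     0.3 * (resolution - 1) + runif(1, -2, 2) * s),
      bodyDepthOffset = runif(1, 0.45, 0.75))
  })
  subj
}

# smooth background texture from the subject's pattern seed
render_background <- function(seed, res) {
  with_seed(seed, {
    fr <- runif(3, 0.5, 3); fc <- runif(3, 0.5, 3); ph <- runif(3, 0, 2 * pi)
    amp <- runif(3, 0.04, 0.1)
    chan_gain <- runif(3, 0.8, 1.2)
  })
  r <- matrix(seq_len(res) - 1, res, res)
  cc <- t(r)
  g <- 0.35
  for (i in 1:3)
    g <- g + amp[i] * sin(2 * pi * (fr[i] * r + fc[i] * cc) / res + ph[i])
  g <- pmin(0.7, pmax(0.05, g))
  bg <- array(0, dim = c(res, res, 3))
  for (ch in 1:3) bg[, , ch] <- pmin(1, g * chan_gain[ch])
  bg
}

#' Render one video frame
#'
#' Draws, over the subject's background texture: a head disc around the nose
#' target, an arm segment of the subject's limb thickness from a fixed
#' shoulder anchor to the fingertip, and a bright fingertip marker. With
#' `channels = 4` a synthetic depth channel is added: background far, body at
#' the subject's depth offset, and the arm's depth increasing as the
#' fingertip approaches the nose. All values lie in `[0,1]`. A fingertip
#' outside the frame is clipped to the frame bounds with a warning.
#'
#' @param subject a [SubjectIdentity-class].
#' @param fingertip (row, col) fingertip position, 0-based.
#' @param resolution square frame side in pixels.
#' @param channels 3 (RGB) or 4 (RGB-D).
#' @return `[resolution, resolution, channels]` array; attribute
#'   `"foreground"` holds the logical body-pixel mask.
#' @export
renderFrame <- function(subject, fingertip, resolution = 64, channels = 3) {
  stopifnot(is(subject, "SubjectIdentity"), channels %in% c(3, 4))
  res <- as.integer(resolution)
  if (any(fingertip < 0) || any(fingertip > res - 1)) {
    warning("fingertip outside frame bounds; clipped")
    fingertip <- pmin(pmax(fingertip, 0), res - 1)
  }
  bg <- render_background(subject@backgroundPatternSeed, res)
  frame <- array(0, dim = c(res, res, channels))
  frame[, , 1:3] <- bg

  rows <- matrix(seq_len(res) - 1, res, res)
  cols <- t(rows)
  nose <- subject@noseTarget
  s <- res / 64

  # head disc around the nose target
  head_r <- 9 * s
  head_mask <- (rows - nose[1])^2 + (cols - nose[2])^2 <= head_r^2
  # arm: distance from pixel to the shoulder->fingertip segment
  shoulder <- c(0.85, 0.8) * (res - 1)
  v <- fingertip - shoulder
  vv <- sum(v^2)
  t_par <- if (vv > 0)
    pmin(1, pmax(0, ((rows - shoulder[1]) * v[1] + (cols - shoulder[2]) * v[2]) / vv))
  else 0 * rows
  dist2 <- (rows - (shoulder[1] + t_par * v[1]))^2 +
           (cols - (shoulder[2] + t_par * v[2]))^2
  arm_mask <- dist2 <= (subject@limbThickness / 2)^2
  tip_r <- max(1.2, 0.7 * subject@limbThickness)
  tip_mask <- (rows - fingertip[1])^2 + (cols - fingertip[2])^2 <= tip_r^2
  nose_dot <- (rows - nose[1])^2 + (cols - nose[2])^2 <= (1.2 * s)^2

  tone <- subject@skinTone
  tip_col <- c(0.95, 0.95, 0.9)
  for (ch in 1:3) {
    plane <- frame[, , ch]
    plane[head_mask] <- 0.9 * tone[ch]
    plane[nose_dot] <- 0.5 * tone[ch]
    plane[arm_mask] <- tone[ch]
    plane[tip_mask] <- tip_col[ch]
    frame[, , ch] <- plane
  }

  if (channels == 4) {
    depth <- matrix(0.15, res, res)
    off <- subject@bodyDepthOffset
    depth[head_mask] <- off
    # fingertip proximity to the nose raises the arm's depth value
    prox <- 1 - sqrt(sum((fingertip - nose)^2)) / (sqrt(2) * res)
    depth[arm_mask] <- min(1, off + 0.3 * prox)
    depth[tip_mask] <- min(1, off + 0.3 * prox + 0.1)
    frame[, , 4] <- depth
  }
  frame[] <- pmin(1, pmax(0, frame))
  attr(frame, "foreground") <- head_mask | arm_mask | tip_mask | nose_dot
  frame
}

#' Build the full generative specification of one synthetic video
#'
#' Combines a (seed-derived) subject identity with the grade-dependent
#' trajectory model: the reach starts at the abducted-arm position at the
#' right edge of the frame and ends at the subject's nose target.
#'
#' @param subjectId identifier (also seeds the subject features together
#'   with `seed`).
#' @param grade integer ataxia grade 0..4.
#' @param resolution square frame side, a power of two (default 64;
#'   full-scale 256).
#' @param channels 3 or 4.
#' @param nFrames frames per video (default 30).
#' @param seed integer master seed; the rendered video is a pure function of
#'   the returned spec.
#' @return a [SyntheticVideoSpec-class].
#' @export
syntheticVideoSpec <- function(subjectId, grade, resolution = 64,
                               channels = 3, nFrames = 30, seed = 1) {
  subj <- randomSubject(subjectId, resolution,
                        seed = seed + 1000L * (grade + 1L))
  start <- c(0.5 * (resolution - 1), 0.92 * (resolution - 1))
  traj <- trajectoryForGrade(grade, nFrames, start, subj@noseTarget,
                             resolution)
  new("SyntheticVideoSpec", subject = subj, grade = as.integer(grade),
      trajectory = traj, resolution = as.integer(resolution),
      channels = as.integer(channels), seed = as.integer(seed))
}

#' Render a synthetic finger-to-nose video
#'
#' @param spec a [SyntheticVideoSpec-class].
#' @return list with `frames` (`[res, res, channels, nFrames]` array,
#'   bitwise reproducible from the spec) and `spec`.
#' @export
simulateVideo <- function(spec) {
  stopifnot(is(spec, "SyntheticVideoSpec"))
  validObject(spec)
  pts <- simulateTrajectory(spec@trajectory, seed = spec@seed)
  pts <- pmin(pmax(pts, 0), spec@resolution - 1)
  frames <- array(0, dim = c(spec@resolution, spec@resolution,
                             spec@channels, spec@trajectory@nFrames))
  for (i in seq_len(nrow(pts)))
    frames[, , , i] <- renderFrame(spec@subject, pts[i, ], spec@resolution,
                                   spec@channels)
  list(frames = frames, spec = spec)
}

#' Simulate a graded video dataset
#'
#' One subject per video; grades cycle through `grades`. Every video is
#' reproducible from its returned spec.
#'
#' @param nVideos number of videos.
#' @param grades grades to cycle over (default 0:4).
#' @param resolution,channels,nFrames frame geometry (see
#'   [syntheticVideoSpec()]).
#' @param seed master seed.
#' @return list of `list(frames, spec)` entries.
#' @export
simulateDataset <- function(nVideos, grades = 0:4, resolution = 64,
                            channels = 3, nFrames = 30, seed = 1) {
  stopifnot(nVideos >= 1)
  g <- rep_len(grades, nVideos)
  lapply(seq_len(nVideos), function(i) {
    simulateVideo(syntheticVideoSpec(
      subjectId = sprintf("S%03d", i), grade = g[i], resolution = resolution,
      channels = channels, nFrames = nFrames, seed = seed + 7919L * i))
  })
}

#' Simulate ordinal ratings from a panel of raters
#'
#' Each rater rates each video's true grade as
#' `clip(round(grade + bias + Normal(0, miscodeSd)), 0, 4)`, or emits the
#' not-ratable value with probability `notRatableProb`. Deterministic given
#' the rater seeds.
#'
#' @param trueGrades integer vector of true grades (0..4), one per video.
#' @param raters list of [RaterModel-class] objects (>= 1).
#' @param videoIds,condition identifiers for the resulting table.
#' @return a [RatingTable-class] (videos x raters, `NA` = not ratable).
#' @export
simulateRatings <- function(trueGrades, raters,
                            videoIds = sprintf("V%03d", seq_along(trueGrades)),
                            condition = "original") {
  if (!length(trueGrades)) stop("need at least one video")
  if (!length(raters)) stop("need at least one rater")
  stopifnot(all(trueGrades %in% 0:4))
  n <- length(trueGrades)
  m <- matrix(NA_integer_, n, length(raters))
  for (j in seq_along(raters)) {
    r <- raters[[j]]
    stopifnot(is(r, "RaterModel"))
    with_seed(r@seed, {
      vals <- as.integer(pmin(4, pmax(0, round(
        trueGrades + r@bias + rnorm(n, 0, r@miscodeSd)))))
      nr <- runif(n) < r@notRatableProb
    })
    vals[nr] <- NA_integer_
    m[, j] <- vals
  }
  new("RatingTable", ratings = m, videoIds = videoIds,
      raterIds = sprintf("R%02d", seq_along(raters)), condition = condition)
}
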
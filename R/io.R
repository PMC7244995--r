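# File formats: PNG frame-sequence videos, the binary latent-code container,
# ratings CSV, and the YAML run configuration.

#' Quantize frame intensities to the PNG sample grid
#'
#' PNG stores 8-bit samples; [writeVideo()] applies this quantization, after
#' which PNG round trips are bitwise lossless.
#'
#' @param frames frame array.
#' @param bits bits per sample (8).
#' @return quantized array of the same shape.
#' @export
quantizeFrames <- function(frames, bits = 8) {
  q <- 2^bits - 1
  round(frames * q) / q
}

#' Write / read a video as a PNG frame sequence
#'
#' Frames are written as `frame_0001.png`, ... in `dir`, 8-bit per sample;
#' an RGB-D video stores the depth channel as the 4th PNG channel (the alpha
#' slot; it carries depth, not opacity). A JSON sidecar `spec.json` records
#' the generative spec if one is supplied. Reading maps samples back to
#' `[0,1]` and validates that all frames share one shape.
#'
#' @param frames `[H,W,C,N]` array or list of frames, values in `[0,1]`.
#' @param dir target directory (created if needed).
#' @param spec optional [SyntheticVideoSpec-class] to record alongside.
#' @return `writeVideo`: the directory, invisibly. `readVideo`: an
#'   `[H,W,C,N]` array.
#' @export
writeVideo <- function(frames, dir, spec = NULL) {
  x <- quantizeFrames(as_frame_stack(frames))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(x)[4]
  for (i in seq_len(n)) {
    png::writePNG(x[, , , i],
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  if (!is.null(spec))
    writeLines(spec_to_json(spec), file.path(dir, "spec.json"))
  invisible(dir)
}

#' @rdname writeVideo
#' @param channels if given, the expected channel count; a mismatch is an
#'   error.
#' @export
readVideo <- function(dir, channels = NULL) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame_*.png files in ", dir)
  frames <- lapply(files, png::readPNG)
  dims <- lapply(frames, function(f) {
    d <- dim(f)
    if (length(d) == 2L) d <- c(d, 1L)
    d
  })
  ref <- dims[[1]]
  bad <- which(!vapply(dims, identical, logical(1), y = ref))
  if (length(bad))
    stop("frames with mismatched shapes: ",
         paste(basename(files[bad]), collapse = ", "),
         sprintf(" (expected %s)", paste(ref, collapse = "x")))
  if (!is.null(channels) && ref[3] != channels)
    stop(sprintf("video has %d channels but %d were expected%s", ref[3],
                 channels,
                 if (channels == 4) " (depth channel missing?)" else ""))
  out <- array(0, dim = c(ref, length(files)))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (length(dim(f)) == 2L) dim(f) <- c(dim(f), 1L)
    out[, , , i] <- f
  }
  out
}

spec_to_json <- function(spec) {
  jsonlite::toJSON(list(
    subject = list(subject_id = spec@subject@subjectId,
                   limb_thickness = spec@subject@limbThickness,
                   skin_tone = spec@subject@skinTone,
                   background_pattern_seed = spec@subject@backgroundPatternSeed,
                   nose_target = spec@subject@noseTarget,
                   body_depth_offset = spec@subject@bodyDepthOffset),
    grade = spec@grade,
    trajectory = list(n_frames = spec@trajectory@nFrames,
                      start_point = spec@trajectory@startPoint,
                      end_point = spec@trajectory@endPoint,
                      tremor_amplitude = spec@trajectory@tremorAmplitude,
                      tremor_frequency = spec@trajectory@tremorFrequency,
                      jitter_sd = spec@trajectory@jitterSd,
                      overshoot_prob = spec@trajectory@overshootProb),
    resolution = spec@resolution, channels = spec@channels,
    seed = spec@seed), auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Read a video spec sidecar written by [writeVideo()]
#' @param path path to a `spec.json` file.
#' @return a [SyntheticVideoSpec-class].
#' @export
readVideoSpec <- function(path) {
  x <- jsonlite::fromJSON(path)
  new("SyntheticVideoSpec",
      subject = subjectIdentity(
        subjectId = x$subject$subject_id,
        limbThickness = x$subject$limb_thickness,
        skinTone = x$subject$skin_tone,
        backgroundPatternSeed = x$subject$background_pattern_seed,
        noseTarget = x$subject$nose_target,
        bodyDepthOffset = x$subject$body_depth_offset),
      grade = as.integer(x$grade),
      trajectory = trajectorySpec(
        nFrames = x$trajectory$n_frames,
        startPoint = x$trajectory$start_point,
        endPoint = x$trajectory$end_point,
        tremorAmplitude = x$trajectory$tremor_amplitude,
        tremorFrequency = x$trajectory$tremor_frequency,
        jitterSd = x$trajectory$jitter_sd,
        overshootProb = x$trajectory$overshoot_prob),
      resolution = as.integer(x$resolution),
      channels = as.integer(x$channels), seed = as.integer(x$seed))
}

.codes_magic <- charToRaw("VAEC")

#' Write / read a latent code sequence container
#'
#' Binary layout: 4 magic bytes `VAEC`, an int32 (little-endian) header
#' length, the JSON header (format version, code length, frame count, source
#' resolution, model fingerprint), then `n_frames * code_length`
#' little-endian 32-bit floats in frame order. Values round-trip bit-exactly
#' at 32-bit float precision. Reading validates the magic bytes, the header,
#' and the payload length (a truncated file is an error, never garbage
#' codes).
#'
#' @param seq a [CodeSequence-class].
#' @param path file path.
#' @return `writeCodes`: the path, invisibly. `readCodes`: a
#'   [CodeSequence-class].
#' @export
writeCodes <- function(seq, path) {
  stopifnot(is(seq, "CodeSequence"))
  validObject(seq)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.codes_magic, con)
  hdr <- charToRaw(as.character(jsonlite::toJSON(seq@header,
                                                 auto_unbox = TRUE)))
  writeBin(length(hdr), con, size = 4L, endian = "little")
  writeBin(hdr, con)
  writeBin(as.numeric(t(seq@codes)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname writeCodes
#' @export
readCodes <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, .codes_magic))
    stop("not a code-sequence container (bad magic bytes): ", path)
  hlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!length(hlen) || hlen <= 0) stop("truncated code-sequence header: ", path)
  hraw <- readBin(con, "raw", hlen)
  if (length(hraw) < hlen) stop("truncated code-sequence header: ", path)
  header <- jsonlite::fromJSON(rawToChar(hraw))
  want <- header$n_frames * header$code_length
  payload <- readBin(con, "numeric", want + 1L, size = 4L, endian = "little")
  if (length(payload) < want)
    stop(sprintf("truncated code payload: expected %d values, found %d",
                 want, length(payload)))
  if (length(payload) > want)
    stop("code payload longer than the header declares: ", path)
  codes <- matrix(payload, nrow = header$n_frames,
                  ncol = header$code_length, byrow = TRUE)
  new("CodeSequence", codes = codes, header = header)
}

#' Export a code sequence as CSV (one row per frame)
#'
#' Interoperability export: columns `frame`, `c1..c<codeLength>`.
#'
#' @param seq a [CodeSequence-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeCodesCSV <- function(seq, path) {
  stopifnot(is(seq, "CodeSequence"))
  df <- as.data.frame(seq@codes)
  names(df) <- sprintf("c%d", seq_len(ncol(df)))
  df <- cbind(frame = seq_len(nrow(df)), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a rating table as CSV
#'
#' Long format with columns `video_id, rater_id, rating`; `rating` is an
#' integer grade 0-4 or the string `NR` (not ratable).
#'
#' @param table a [RatingTable-class].
#' @param path file path.
#' @param condition condition label attached on read.
#' @return `writeRatings`: the path, invisibly. `readRatings`: a
#'   [RatingTable-class].
#' @export
writeRatings <- function(table, path) {
  stopifnot(is(table, "RatingTable"))
  df <- data.frame(
    video_id = rep(table@videoIds, times = length(table@raterIds)),
    rater_id = rep(table@raterIds, each = length(table@videoIds)),
    rating = ifelse(is.na(as.vector(table@ratings)), "NR",
                    as.character(as.vector(table@ratings))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRatings
#' @export
readRatings <- function(path, condition = "original") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("video_id", "rater_id", "rating")
  if (!all(need %in% names(df)))
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "))
  vids <- unique(df$video_id)
  rids <- unique(df$rater_id)
  m <- matrix(NA_integer_, length(vids), length(rids))
  vals <- as_rating_vec(df$rating)
  m[cbind(match(df$video_id, vids), match(df$rater_id, rids))] <- vals
  new("RatingTable", ratings = m, videoIds = as.character(vids),
      raterIds = as.character(rids), condition = condition)
}

# known run-config keys per section (YAML surface)
.runconfig_schema <- list(
  model = names(formals(modelConfig)),
  loss = setdiff(names(formals(lossConfig)), "resolution"),
  train = names(formals(trainConfig)),
  simulate = c("nVideos", "grades", "resolution", "channels", "nFrames",
               "seed"),
  paths = c("videos", "codes", "model", "output", "ratings_original",
            "ratings_decoded"))

#' Read and validate a YAML run configuration
#'
#' Sections `model`, `loss`, `train`, `simulate`, `paths`, all optional;
#' unknown sections or keys are rejected (typos must not silently fall back
#' to defaults). Returns constructed [ModelConfig-class], [LossConfig-class]
#' and [TrainConfig-class] objects plus the raw `simulate` and `paths`
#' lists.
#'
#' @param path YAML file path.
#' @param overrides named list merged over the file content (CLI flags).
#' @return list with `model`, `loss`, `train`, `simulate`, `paths`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (!is.list(cfg)) stop("run config must be a YAML mapping")
  unknown <- setdiff(names(cfg), names(.runconfig_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(overrides)) {
    cfg[[sec]] <- modifyList(cfg[[sec]] %||% list(), overrides[[sec]])
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .runconfig_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  model <- do.call(modelConfig, cfg$model %||% list())
  loss_args <- cfg$loss %||% list()
  loss_args$resolution <- model@inputResolution
  list(model = model,
       loss = do.call(lossConfig, loss_args),
       train = do.call(trainConfig, cfg$train %||% list()),
       simulate = cfg$simulate %||% list(),
       paths = cfg$paths %||% list())
}
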
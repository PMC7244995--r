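# accessors and show methods

#' Number of frames represented by an object
#' @param x a [CodeSequence-class] or [SyntheticVideoSpec-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "CodeSequence", function(x) nrow(x@codes))

#' @rdname nFrames
#' @export
setMethod("nFrames", "SyntheticVideoSpec", function(x) x@trajectory@nFrames)

#' Latent code matrix of a code sequence
#' @param x a [CodeSequence-class].
#' @return numeric matrix, frames x codeLength.
#' @export
setGeneric("codeMatrix", function(x) standardGeneric("codeMatrix"))

#' @rdname codeMatrix
#' @export
setMethod("codeMatrix", "CodeSequence", function(x) x@codes)

#' Provenance header of a code sequence
#' @param x a [CodeSequence-class].
#' @return named list.
#' @export
setGeneric("codeHeader", function(x) standardGeneric("codeHeader"))

#' @rdname codeHeader
#' @export
setMethod("codeHeader", "CodeSequence", function(x) x@header)

#' Rating matrix of a rating table (NA = not ratable)
#' @param x a [RatingTable-class].
#' @return integer matrix, videos x raters.
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))

#' @rdname ratings
#' @export
setMethod("ratings", "RatingTable", function(x) {
  m <- x@ratings
  dimnames(m) <- list(x@videoIds, x@raterIds)
  m
})

#' Video identifiers of a rating table
#' @param x a [RatingTable-class].
#' @return character vector.
#' @export
setGeneric("videoIds", function(x) standardGeneric("videoIds"))

#' @rdname videoIds
#' @export
setMethod("videoIds", "RatingTable", function(x) x@videoIds)

#' Rater identifiers of a rating table
#' @param x a [RatingTable-class].
#' @return character vector.
#' @export
setGeneric("raterIds", function(x) standardGeneric("raterIds"))

#' @rdname raterIds
#' @export
setMethod("raterIds", "RatingTable", function(x) x@raterIds)

#' Kappa coefficient of a kappa result
#' @param x a [KappaResult-class].
#' @return numeric scalar (NA when kappa is undefined).
#' @export
setGeneric("kappaValue", function(x) standardGeneric("kappaValue"))

#' @rdname kappaValue
#' @export
setMethod("kappaValue", "KappaResult", function(x) x@kappa)

#' Model configuration of a trained model
#' @param x a [VAEModel-class].
#' @return the [ModelConfig-class].
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname modelConfigOf
#' @export
setMethod("modelConfigOf", "VAEModel", function(x) x@config)

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %dx%dx%d input, %d blocks, %d initial filters, kernel %d, code length %d\n",
    object@inputResolution, object@inputResolution, object@inputChannels,
    object@nBlocks, object@initialFilters, object@kernelSize,
    object@codeLength))
})

setMethod("show", "VAEModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("VAEModel (%s parameters, %d epochs trained)\n",
              format(np, big.mark = ","), object@epochsTrained))
  show(object@config)
  cat(sprintf("fingerprint: %s\n", modelFingerprint(object)))
})

setMethod("show", "CodeSequence", function(object) {
  h <- object@header
  cat(sprintf(
    "CodeSequence: %d frames x code length %d (source %dx%d, model %s)\n",
    h$n_frames, h$code_length, h$source_resolution, h$source_resolution,
    h$model_fingerprint))
})

setMethod("show", "RatingTable", function(object) {
  cat(sprintf("RatingTable [%s]: %d videos x %d raters, %.1f%% ratable\n",
              object@condition, nrow(object@ratings), ncol(object@ratings),
              100 * mean(!is.na(object@ratings))))
})

setMethod("show", "KappaResult", function(object) {
  if (is.na(object@kappa)) {
    cat(sprintf("KappaResult: undefined (%s), n = %d\n",
                object@reason, object@nPairsUsed))
  } else {
    cat(sprintf("KappaResult: kappa = %.4f (%s weights, %s), n = %d\n",
                object@kappa, object@weightScheme, object@interpretation,
                object@nPairsUsed))
  }
})

setMethod("show", "SyntheticVideoSpec", function(object) {
  cat(sprintf(
    "SyntheticVideoSpec: subject %s, grade %d, %d frames, %dx%dx%d, seed %d\n",
    object@subject@subjectId, object@grade, object@trajectory@nFrames,
    object@resolution, object@resolution, object@channels, object@seed))
})
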
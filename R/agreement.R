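# Rater-agreement statistics for ordinal 0-4 severity ratings.
#
# The agreement coefficient is the weighted Cohen kappa with linear weights:
# a disagreement of k categories is penalized proportionally to k
# (disagreements of 1, 2 and 3 grades weigh 1, 2 and 3). Not-ratable (NR)
# cells are excluded pairwise-complete and counted.

.grades <- 0:4

#' Map a kappa value to its agreement band
#'
#' Bands: `<= 0` chance-or-worse, `(0, 0.2]` slight, `(0.2, 0.4]` fair,
#' `(0.4, 0.6]` moderate, `(0.6, 0.8]` substantial, `(0.8, 1]` almost
#' perfect.
#'
#' @param k numeric kappa in `[-1, 1]` (NA allowed).
#' @return character label.
#' @examples
#' interpretKappa(0.317) # "fair"
#' interpretKappa(0.459) # "moderate"
#' @export
interpretKappa <- function(k) {
  if (is.na(k)) return("undefined")
  stopifnot(k >= -1 - 1e-12, k <= 1 + 1e-12)
  if (k <= 0) "chance-or-worse"
  else if (k <= 0.2) "slight"
  else if (k <= 0.4) "fair"
  else if (k <= 0.6) "moderate"
  else if (k <= 0.8) "substantial"
  else "almost perfect"
}

# weight matrix over the 5 grade categories
kappa_weights <- function(scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(.grades, .grades, "-"))
  if (scheme == "quadratic") d^2 else d
}

kappa_result <- function(kappa, n, scheme, reason = "") {
  new("KappaResult", kappa = kappa, nPairsUsed = as.integer(n),
      weightScheme = scheme,
      interpretation = interpretKappa(kappa), reason = reason)
}

#' Weighted Cohen kappa from a 5x5 cross-rating contingency table
#'
#' `kappa = 1 - sum(w * O) / sum(w * E)` with `w[i,j] = |i - j|` (linear
#' weights), `O` the observed table and `E` the chance table formed from the
#' outer product of O's marginals. A table whose cells equal the outer
#' product of its own marginals (statistically independent raters) yields
#' kappa = 0 exactly; identical raters yield 1.
#'
#' @param O 5x5 numeric table of pair counts, rows/cols = grades 0..4.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return a [KappaResult-class]. When neither rater shows any marginal
#'   variation the kappa is undefined and reported as `NA` with a reason,
#'   never silently coerced to a number.
#' @export
weightedKappaFromTable <- function(O, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  stopifnot(is.matrix(O), all(dim(O) == c(5, 5)), all(O >= 0))
  n <- sum(O)
  if (n < 2) stop("need at least 2 usable rating pairs")
  w <- kappa_weights(weights)
  E <- outer(rowSums(O), colSums(O)) / n
  denom <- sum(w * E)
  if (denom == 0)
    return(kappa_result(NA_real_, n, weights,
                        reason = "no marginal variation: chance disagreement is zero"))
  kappa_result(1 - sum(w * O) / denom, n, weights)
}

# coerce a ratings vector: integers 0..4 with NA for not-ratable
as_rating_vec <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    x[toupper(x) == "NR"] <- NA
    x <- as.numeric(x)
  }
  bad <- !is.na(x) & (x < 0 | x > 4 | x != round(x))
  if (any(bad)) stop("ratings must be integers in 0..4 or NR")
  as.integer(x)
}

#' Weighted Cohen kappa between two ratings vectors
#'
#' Pairs where either vector is not-ratable (`NA` or `"NR"`) are excluded
#' (pairwise-complete) and the usable count reported.
#'
#' @param a,b ratings vectors of equal length: integers 0..4, with `NA` or
#'   `"NR"` for not ratable.
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @return a [KappaResult-class].
#' @export
weightedKappa <- function(a, b, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  a <- as_rating_vec(a); b <- as_rating_vec(b)
  if (length(a) != length(b))
    stop(sprintf("rating vectors differ in length: %d vs %d",
                 length(a), length(b)))
  use <- !is.na(a) & !is.na(b)
  if (sum(use) < 2)
    stop(sprintf("only %d usable pairs after not-ratable exclusion (need >= 2)",
                 sum(use)))
  O <- table(factor(a[use], levels = .grades), factor(b[use], levels = .grades))
  weightedKappaFromTable(unclass(O), weights)
}

check_aligned <- function(original, decoded) {
  stopifnot(is(original, "RatingTable"), is(decoded, "RatingTable"))
  mism <- c(
    if (!identical(original@videoIds, decoded@videoIds))
      paste("videos:", paste(union(setdiff(original@videoIds, decoded@videoIds),
                                   setdiff(decoded@videoIds, original@videoIds)),
                             collapse = ", ")),
    if (!identical(original@raterIds, decoded@raterIds))
      paste("raters:", paste(union(setdiff(original@raterIds, decoded@raterIds),
                                   setdiff(decoded@raterIds, original@raterIds)),
                             collapse = ", ")))
  if (length(mism))
    stop("rating tables are not aligned - ", paste(mism, collapse = "; "))
  invisible(TRUE)
}

#' Intra-rater agreement between two rating conditions
#'
#' For each rater, the weighted kappa between their ratings of the original
#' and the decoded videos; plus a pooled kappa over all (rater, video) pairs
#' concatenated. Raters with fewer than 2 usable pairs (e.g. all not-ratable
#' in one condition) are excluded and flagged.
#'
#' @param original,decoded aligned [RatingTable-class] objects (same videos,
#'   same raters).
#' @param weights `"linear"` or `"quadratic"`.
#' @return list with `perRater` (named list of [KappaResult-class]),
#'   `pooled` (a [KappaResult-class]), `meanPerRater` (mean of the defined
#'   per-rater kappas) and `excludedRaters`.
#' @export
intraraterAgreement <- function(original, decoded,
                                weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  check_aligned(original, decoded)
  per <- list()
  excluded <- character()
  for (j in seq_along(original@raterIds)) {
    id <- original@raterIds[j]
    a <- original@ratings[, j]; b <- decoded@ratings[, j]
    if (sum(!is.na(a) & !is.na(b)) < 2) {
      excluded <- c(excluded, id)
    } else {
      per[[id]] <- weightedKappa(a, b, weights)
    }
  }
  pooled <- weightedKappa(as.vector(original@ratings),
                          as.vector(decoded@ratings), weights)
  ks <- vapply(per, function(x) x@kappa, numeric(1))
  list(perRater = per, pooled = pooled,
       meanPerRater = mean(ks, na.rm = TRUE), excludedRaters = excluded)
}

#' Inter-rater agreement within one rating condition
#'
#' Weighted kappa for every rater pair on their shared ratable videos; the
#' summary is the unweighted mean of the defined pairwise kappas. Pairs with
#' fewer than 2 shared usable videos are flagged and excluded from the mean.
#'
#' @param table a [RatingTable-class] with >= 2 raters.
#' @param weights `"linear"` or `"quadratic"`.
#' @return list with `meanKappa`, `pairwise` (raters x raters numeric matrix,
#'   `NA` off-diagonal where undefined), and `excludedPairs`.
#' @export
interraterAgreement <- function(table, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  stopifnot(is(table, "RatingTable"))
  R <- length(table@raterIds)
  if (R < 2) stop("need at least 2 raters")
  pw <- matrix(NA_real_, R, R, dimnames = list(table@raterIds, table@raterIds))
  diag(pw) <- 1
  excluded <- character()
  vals <- numeric()
  for (i in seq_len(R - 1)) for (j in seq.int(i + 1, R)) {
    a <- table@ratings[, i]; b <- table@ratings[, j]
    pair_id <- paste(table@raterIds[i], table@raterIds[j], sep = "-")
    if (sum(!is.na(a) & !is.na(b)) < 2) {
      excluded <- c(excluded, pair_id)
      next
    }
    k <- weightedKappa(a, b, weights)
    pw[i, j] <- pw[j, i] <- k@kappa
    if (!is.na(k@kappa)) vals <- c(vals, k@kappa)
  }
  list(meanKappa = if (length(vals)) mean(vals) else NA_real_,
       pairwise = pw, excludedPairs = excluded)
}

#' Mean rating difference between two conditions
#'
#' Mean of `original - decoded` over all (video, rater) cells that are
#' ratable in both conditions; positive values mean the originals were rated
#' as more severe.
#'
#' @param original,decoded aligned [RatingTable-class] objects, or plain
#'   ratings vectors.
#' @return numeric scalar.
#' @export
meanRatingDifference <- function(original, decoded) {
  if (is(original, "RatingTable")) {
    check_aligned(original, decoded)
    a <- as.vector(original@ratings); b <- as.vector(decoded@ratings)
  } else {
    a <- as_rating_vec(original); b <- as_rating_vec(decoded)
    if (length(a) != length(b)) stop("rating vectors differ in length")
  }
  use <- !is.na(a) & !is.na(b)
  if (!any(use)) stop("no pairs ratable in both conditions")
  mean(a[use] - b[use])
}

#' Proportion of ratable cells in a rating table
#'
#' @param table a [RatingTable-class] (or a ratings vector/matrix with `NA`
#'   or `"NR"` for not ratable).
#' @return numeric in `[0, 1]`.
#' @export
ratableProportion <- function(table) {
  x <- if (is(table, "RatingTable")) table@ratings else {
    if (is.matrix(table)) matrix(as_rating_vec(table), nrow(table))
    else as_rating_vec(table)
  }
  if (!length(x)) stop("empty rating table")
  mean(!is.na(x))
}

#' Agreement-grid plot of a rating table
#'
#' Videos x raters tile grid: grade as grey shade (dark = 0, light = 4),
#' not-ratable in blue.
#'
#' @param table a [RatingTable-class].
#' @return a ggplot object.
#' @export
plotRatingGrid <- function(table) {
  stopifnot(is(table, "RatingTable"))
  df <- expand.grid(video = table@videoIds, rater = table@raterIds,
                    stringsAsFactors = FALSE)
  df$rating <- as.vector(table@ratings)
  df$label <- factor(ifelse(is.na(df$rating), "NR", as.character(df$rating)),
                     levels = c(as.character(.grades), "NR"))
  shades <- grDevices::grey.colors(5, start = 0, end = 1)
  cols <- c(stats::setNames(shades, as.character(.grades)), NR = "#3366CC")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rater, y = .data$video,
                                   fill = .data$label)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::scale_fill_manual(values = cols, name = "grade", drop = FALSE) +
    ggplot2::labs(title = sprintf("Ratings (%s)", table@condition),
                  x = "rater", y = "video") +
    ggplot2::theme_minimal()
}
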
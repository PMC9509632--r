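## Equalized binarization of binned signal tracks.
##
## A feature is binarized per 200-bp bin against a Poisson background, then
## the two conditions' call counts are equalized per chromosome by keeping
## only the top-signal n calls in each, n being the smaller condition's
## count. This removes sequencing-depth / IP-efficiency bias before joint
## two-condition chromatin-state modeling.

#' Binned signal track
#'
#' @param values named list (by chromosome) of non-negative numeric vectors,
#'   one value per fixed-width bin.
#' @param feature,condition track labels.
#' @param bin_size bin width in bp (default 200).
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(values, feature, condition, bin_size = 200) {
  stopifnot(is.list(values), length(values) > 0)
  if (is.null(names(values))) stop("values must be named by chromosome")
  for (v in values) {
    if (any(v < 0) || any(!is.finite(v))) stop("track values must be finite and >= 0")
  }
  structure(list(values = values, feature = feature, condition = condition,
                 bin_size = bin_size),
            class = "binned_track")
}

#' Per-bin presence calls
#'
#' @param calls named list (by chromosome) of logical vectors, same shape
#'   as the source [binned_track()].
#' @inheritParams binned_track
#' @return Object of class `binary_calls`.
#' @export
binary_calls <- function(calls, feature, condition, bin_size = 200) {
  stopifnot(is.list(calls), length(calls) > 0)
  structure(list(calls = calls, feature = feature, condition = condition,
                 bin_size = bin_size),
            class = "binary_calls")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %s / %s, %d bp bins, %d chromosome(s), %d bins\n",
              x$feature, x$condition, x$bin_size, length(x$values),
              sum(lengths(x$values))))
  invisible(x)
}

#' @export
print.binary_calls <- function(x, ...) {
  cat(sprintf("binary_calls: %s / %s, %d bp bins, %d present of %d bins\n",
              x$feature, x$condition, x$bin_size,
              sum(unlist(x$calls)), sum(lengths(x$calls))))
  invisible(x)
}

check_same_shape <- function(a, b) {
  if (!identical(names(a$values %||% a$calls), names(b$values %||% b$calls)) ||
      !identical(lengths(a$values %||% a$calls), lengths(b$values %||% b$calls)))
    stop("tracks do not share the same chromosomes/bins")
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Background-subtract a signal track by its control
#'
#' The control is scaled to the signal's total (so subtraction is
#' depth-matched), then subtracted elementwise with flooring at zero.
#' With no control (e.g. accessibility data) the signal passes through.
#'
#' @param signal a [binned_track()].
#' @param control matching control [binned_track()] or `NULL`.
#' @return A [binned_track()] of the same shape.
#' @export
background_subtract <- function(signal, control = NULL) {
  stopifnot(inherits(signal, "binned_track"))
  if (is.null(control)) return(signal)
  stopifnot(inherits(control, "binned_track"))
  check_same_shape(signal, control)
  tot_s <- sum(unlist(signal$values)); tot_c <- sum(unlist(control$values))
  scale <- if (tot_c > 0) tot_s / tot_c else 0
  out <- lapply(names(signal$values), function(chr)
    pmax(signal$values[[chr]] - scale * control$values[[chr]], 0))
  names(out) <- names(signal$values)
  binned_track(out, signal$feature, signal$condition, signal$bin_size)
}

#' Binarize a count track against a Poisson background
#'
#' A bin is called present iff the upper-tail Poisson probability of its
#' count, under a background rate taken from the (depth-scaled) control and
#' floored at the genome-wide mean signal, is at most `p_threshold`.
#'
#' @param track a [binned_track()] of counts.
#' @param control matching control [binned_track()] or `NULL` (background
#'   rate is then the genome-wide mean everywhere).
#' @param p_threshold Poisson upper-tail significance (default `1e-4`).
#' @return A [binary_calls()] object.
#' @export
poisson_binarize <- function(track, control = NULL, p_threshold = 1e-4) {
  stopifnot(inherits(track, "binned_track"))
  if (sum(lengths(track$values)) == 0L) stop("empty track")
  all_vals <- unlist(track$values, use.names = FALSE)
  gmean <- mean(all_vals)
  scale <- if (!is.null(control)) {
    check_same_shape(track, control)
    tot_c <- sum(unlist(control$values))
    if (tot_c > 0) sum(all_vals) / tot_c else 0
  } else 0
  calls <- lapply(names(track$values), function(chr) {
    x <- track$values[[chr]]
    lambda <- if (!is.null(control)) pmax(scale * control$values[[chr]], gmean)
              else rep(gmean, length(x))
    p <- stats::ppois(x - 1, lambda, lower.tail = FALSE)   # P(X >= x)
    p <= p_threshold
  })
  names(calls) <- names(track$values)
  binary_calls(calls, track$feature, track$condition, track$bin_size)
}

#' Equalize presence-call counts between two conditions
#'
#' For each chromosome, the signal values underlying the present calls are
#' ranked and only the top `n` calls are retained in each condition, where
#' `n` is the lower call count among the two conditions for that
#' chromosome. Ties in signal are broken deterministically by chromosome
#' position (ascending). After equalization both conditions carry exactly
#' the same number of present calls per chromosome.
#'
#' @param signalA,signalB (background-subtracted) [binned_track()]s used
#'   for ranking, one per condition.
#' @param callsA,callsB matching [binary_calls()].
#' @return List with elements `A` and `B`, the equalized [binary_calls()].
#' @export
equalize_calls <- function(signalA, callsA, signalB, callsB) {
  stopifnot(inherits(signalA, "binned_track"), inherits(callsA, "binary_calls"),
            inherits(signalB, "binned_track"), inherits(callsB, "binary_calls"))
  if (callsA$feature != callsB$feature) stop("conditions must share a feature")
  check_same_shape(signalA, signalB)
  top_n <- function(signal, calls, n) {
    idx <- which(calls)
    if (length(idx) <= n) return(calls)
    o <- order(-signal[idx], idx)          # signal desc, position asc
    keep <- idx[o[seq_len(n)]]
    out <- logical(length(calls)); out[keep] <- TRUE
    out
  }
  outA <- list(); outB <- list()
  for (chr in names(callsA$calls)) {
    nA <- sum(callsA$calls[[chr]]); nB <- sum(callsB$calls[[chr]])
    n <- min(nA, nB)
    outA[[chr]] <- top_n(signalA$values[[chr]], callsA$calls[[chr]], n)
    outB[[chr]] <- top_n(signalB$values[[chr]], callsB$calls[[chr]], n)
  }
  list(A = binary_calls(outA, callsA$feature, callsA$condition, callsA$bin_size),
       B = binary_calls(outB, callsB$feature, callsB$condition, callsB$bin_size))
}
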
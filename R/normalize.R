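#' Common sequence set across all samples
#'
#' @param counts numeric matrix, sequences/miRNAs x libraries.
#' @return character vector of row ids with a positive count in every
#'   library.
#' @export
build_common_set <- function(counts) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  ids <- rownames(counts)[apply(counts > 0, 1, all)]
  if (length(ids) == 0)
    stop("common set is empty: no sequence is observed in every sample; ",
         "sequence deeper or supply a less sparse matrix")
  ids
}

#' Median reference profile over the common set
#'
#' Per-sequence median of copy numbers across samples (mean-of-central-pair
#' for an even number of samples).
#'
#' @param counts sequences x libraries count matrix.
#' @param common ids from [build_common_set()].
#' @return named numeric vector of reference copy numbers (> 0).
#' @export
build_reference <- function(counts, common = build_common_set(counts)) {
  if (length(common) == 0) stop("empty common set")
  apply(counts[common, , drop = FALSE], 1, stats::median)
}

#' Per-sample regression correction factor
#'
#' Ordinary least squares of the sample's log2 copy numbers (y) on the
#' reference log2 copy numbers (x), restricted to sequences with
#' |y - x| < `delta_cutoff` (less than 4-fold off the reference at the
#' default of 2). The correction factor is read off at the reference
#' mid-value x_mid: f = 2^(x_mid - (a * x_mid + b)).
#'
#' @param sample named numeric vector of the sample's copy numbers on (at
#'   least) the common set.
#' @param reference named numeric reference profile from [build_reference()].
#' @param delta_cutoff subset half-width on the log2 difference scale
#'   (default 2; `Inf` uses the whole common set).
#' @param midpoint `"half-range"` computes x_mid = (max(x) - min(x)) / 2 (the
#'   convention this normalization was described with); `"midrange"` uses
#'   the conventional (max(x) + min(x)) / 2.
#' @return object of class `mrn_sample_fit`: `a` (slope), `b` (intercept),
#'   `n` (subset size), `x_mid`, `y_mid`, `delta_y`, `f`.
#' @export
fit_correction <- function(sample, reference, delta_cutoff = 2,
                           midpoint = c("half-range", "midrange")) {
  midpoint <- match.arg(midpoint)
  common <- names(reference)
  s <- sample[common]
  if (any(is.na(s) | s <= 0))
    stop("sample lacks positive counts on the common set")
  x <- log2(reference)
  y <- log2(s)
  sub <- abs(y - x) < delta_cutoff
  if (sum(sub) < 3)
    stop("fewer than 3 sequences within |delta log2| < ", delta_cutoff,
         " for this sample; cannot fit")
  xs <- x[sub]; ys <- y[sub]
  if (stats::var(xs) == 0) stop("zero variance in reference log2 values")
  a <- stats::cov(xs, ys) / stats::var(xs)
  b <- mean(ys) - a * mean(xs)
  x_mid <- if (midpoint == "half-range") (max(x) - min(x)) / 2
           else (max(x) + min(x)) / 2
  y_mid <- a * x_mid + b
  delta_y <- x_mid - y_mid
  structure(list(a = a, b = b, n = sum(sub), x_mid = x_mid, y_mid = y_mid,
                 delta_y = delta_y, f = 2^delta_y),
            class = "mrn_sample_fit")
}

#' @export
print.mrn_sample_fit <- function(x, ...) {
  cat(sprintf("y = %.4f x + %.4f on %d sequences; x_mid = %.3f, dy = %.4f, f = %.4f\n",
              x$a, x$b, x$n, x$x_mid, x$delta_y, x$f))
  invisible(x)
}

#' Median-reference regression normalization
#'
#' Fits one regression correction per library against the median reference
#' profile of the common sequence set, and scales every count (all
#' sequences, not only the common set) by its library's arithmetic
#' correction factor f = 2^(delta y).
#'
#' @param counts sequences/miRNAs x libraries count matrix.
#' @inheritParams fit_correction
#' @return object of class `mrn_fit`: `fits` (per-library
#'   `mrn_sample_fit`s), `factors` (named numeric f per library),
#'   `reference`, `common`, `normalized` (the corrected matrix), plus the
#'   call parameters.
#' @export
normalize_counts <- function(counts, delta_cutoff = 2,
                             midpoint = c("half-range", "midrange")) {
  midpoint <- match.arg(midpoint)
  common <- build_common_set(counts)
  reference <- build_reference(counts, common)
  fits <- lapply(colnames(counts), function(lib)
    fit_correction(counts[, lib], reference, delta_cutoff, midpoint))
  names(fits) <- colnames(counts)
  f <- vapply(fits, `[[`, 0, "f")
  structure(list(fits = fits, factors = f, reference = reference,
                 common = common,
                 normalized = apply_correction(counts, f),
                 delta_cutoff = delta_cutoff, midpoint = midpoint),
            class = "mrn_fit")
}

#' Apply per-library correction factors
#'
#' @param counts sequences x libraries matrix.
#' @param factors named numeric vector of correction factors, one per
#'   library (or a list of `mrn_sample_fit`s).
#' @return the column-scaled matrix.
#' @export
apply_correction <- function(counts, factors) {
  if (is.list(factors)) factors <- vapply(factors, `[[`, 0, "f")
  if (length(factors) != ncol(counts))
    stop("need one correction factor per library")
  if (!is.null(names(factors)) && !is.null(colnames(counts)))
    factors <- factors[colnames(counts)]
  sweep(counts, 2, factors, "*")
}

#' @export
print.mrn_fit <- function(x, ...) {
  cat(sprintf("Median-reference regression normalization: %d libraries, %d common sequences\n",
              length(x$fits), length(x$common)))
  cat("correction factors:\n")
  print(round(x$factors, 4))
  invisible(x)
}

#' @method summary mrn_fit
#' @export
summary.mrn_fit <- function(object, ...) {
  d <- do.call(rbind, lapply(names(object$fits), function(lib) {
    f <- object$fits[[lib]]
    data.frame(library = lib, a = f$a, b = f$b, n = f$n, x_mid = f$x_mid,
               delta_y = f$delta_y, f = f$f, stringsAsFactors = FALSE)
  }))
  rownames(d) <- NULL
  d
}

#' @method coef mrn_fit
#' @export
coef.mrn_fit <- function(object, ...) object$factors
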
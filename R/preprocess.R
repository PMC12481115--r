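#' Default 16-muscle montage for upper-limb throwing EMG
#'
#' Muscle label set used when trial files carry no header row:
#' infraspinatus (IF), supraspinatus (SSP), lower/middle/upper trapezius
#' (LT, MT, UT), anterior/middle/posterior deltoid (DA, DM, DP), serratus
#' anterior (SA), pectoralis major (PC), biceps brachii long head (BCl),
#' triceps brachii long head (TLo), brachioradialis (BR), flexor carpi
#' ulnaris (FCU), extensor carpi radialis longus (ECR), latissimus dorsi
#' (LD).
#'
#' @return Character vector of 16 muscle labels.
#' @export
default_muscle_labels <- function() {
  c("IF", "SSP", "LT", "MT", "UT", "DA", "DM", "DP",
    "SA", "PC", "BCl", "TLo", "BR", "FCU", "ECR", "LD")
}

new_raw_trial <- function(samples, sample_rate, muscle_labels, window) {
  if (length(muscle_labels) != ncol(samples)) {
    stop("muscle_labels length (", length(muscle_labels),
         ") does not match column count (", ncol(samples), ")")
  }
  if (anyDuplicated(muscle_labels)) stop("muscle labels must be unique")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         muscle_labels = muscle_labels, window = window),
    class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> %d samples x %d muscles @ %g Hz, window [%d, %d]\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Read a single EMG trial from delimited text
#'
#' Reads one trial (rows = time samples, columns = muscles) from a comma-
#' or tab-delimited file, auto-detecting the delimiter. An optional single
#' header row supplies muscle labels; otherwise labels default to the
#' 16-muscle montage of [default_muscle_labels()] (or `V1..Vm` when the
#' column count differs from 16).
#'
#' @param path Path to the delimited text file.
#' @param sample_rate Sampling rate in Hz (default 2000).
#' @param label_row `TRUE` if the first row holds muscle labels, `FALSE`
#'   if it is data, or `"auto"` (default) to detect a non-numeric first
#'   row.
#' @return A `raw_trial` with fields `samples`, `sample_rate`,
#'   `muscle_labels` and `window` (defaults to the full extent).
#' @export
read_trial <- function(path, sample_rate = 2000, label_row = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  nf <- count.fields(path, sep = sep)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged rows in ", path, ": row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  header <- if (identical(label_row, "auto")) {
    any(is.na(suppressWarnings(as.numeric(strsplit(first, sep, fixed = TRUE)[[1]]))))
  } else {
    isTRUE(label_row)
  }
  df <- read.table(path, sep = sep, header = header,
                   colClasses = "character", check.names = FALSE)
  mat <- suppressWarnings(apply(as.matrix(df), 2, as.numeric))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(df))
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric value in ", path, " at row ", idx[1],
         ", column ", idx[2])
  }
  dimnames(mat) <- NULL
  labels <- if (header) {
    colnames(df)
  } else if (ncol(mat) == 16L) {
    default_muscle_labels()
  } else {
    paste0("V", seq_len(ncol(mat)))
  }
  new_raw_trial(mat, sample_rate, labels, c(1L, nrow(mat)))
}

# Zero-phase forward-backward application of an IIR filter with
# reflective (odd) edge padding of length 3 * max(filter lengths),
# mirroring common practice for EMG envelopes.
filtfilt_refl <- function(flt, x) {
  b <- flt$b; a <- flt$a
  npad <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= npad) {
    stop("signal too short for zero-phase filtering: needs more than ",
         npad, " samples, got ", n)
  }
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  ext <- c(pre, x, post)
  y <- signal::filter(flt, ext)
  y <- rev(signal::filter(flt, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Compute the EMG linear envelope of a trial
#'
#' Per muscle channel: demean, high-pass filter (motion-artifact
#' removal), full-wave rectify, then low-pass filter to obtain the
#' smooth activation envelope. Both filters are 4th-order Butterworth
#' designs applied forward-backward (zero phase; effective order
#' doubles), with reflective edge padding. Residual negative values
#' after low-pass filtering are clipped at zero so the output is a
#' valid non-negative NMF input.
#'
#' @param trial A `raw_trial`.
#' @param hp_cutoff High-pass cutoff in Hz (default 40).
#' @param lp_cutoff Low-pass cutoff in Hz (default 15).
#' @param order Butterworth design order (default 4).
#' @return A `raw_trial` holding the non-negative envelopes, same shape.
#' @export
emg_envelope <- function(trial, hp_cutoff = 40, lp_cutoff = 15, order = 4) {
  stopifnot(inherits(trial, "raw_trial"))
  fs <- trial$sample_rate
  if (fs <= 2 * hp_cutoff) {
    stop("sample rate (", fs, " Hz) must exceed twice the high-pass cutoff")
  }
  hp <- signal::butter(order, hp_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(order, lp_cutoff / (fs / 2), type = "low")
  env <- apply(trial$samples, 2, function(x) {
    x <- x - mean(x)
    x <- filtfilt_refl(hp, x)
    x <- abs(x)
    x <- filtfilt_refl(lp, x)
    pmax(x, 0)
  })
  new_raw_trial(env, fs, trial$muscle_labels, trial$window)
}

#' Time-normalize a trial window onto a fixed number of points
#'
#' Linearly interpolates each muscle channel over the trial's analysis
#' window (movement start to ball release) onto `n_points` equally
#' spaced samples, inclusive of both endpoints, so trials of different
#' durations become comparable 200-point movement cycles.
#'
#' @param trial A `raw_trial`.
#' @param n_points Number of output time points (default 200).
#' @return Numeric matrix `n_points` x muscles with muscle labels as
#'   column names.
#' @export
time_normalize <- function(trial, n_points = 200) {
  stopifnot(inherits(trial, "raw_trial"))
  w <- trial$window
  n <- nrow(trial$samples)
  if (w[1] < 1 || w[2] > n || w[2] <= w[1]) {
    stop("window [", w[1], ", ", w[2], "] invalid for trial of ", n, " samples")
  }
  idx <- seq(w[1], w[2], length.out = n_points)
  out <- apply(trial$samples[w[1]:w[2], , drop = FALSE], 2, function(x) {
    approx(seq(w[1], w[2]), x, xout = idx)$y
  })
  colnames(out) <- trial$muscle_labels
  out
}

#' Assemble a subject's concatenated, scaled EMG matrix
#'
#' Takes the subject's time-normalized envelope trials, keeps the first
#' `n_keep` in recorded order, concatenates them along time, then scales
#' each muscle: first by its maximum amplitude across the concatenated
#' trials (so activity is expressed relative to the subject's peak), then
#' to unit variance (so every muscle is weighted equally in the
#' factorization). Both per-muscle factors are retained so envelopes can
#' be mapped back to original units.
#'
#' @param trials List of time-normalized trials: numeric matrices
#'   (time x muscles) as returned by [time_normalize()], or `raw_trial`
#'   objects already holding 200-point envelopes.
#' @param n_keep Number of trials to retain (default 5).
#' @return An `emg_matrix`: list with `values` (muscles x time,
#'   non-negative), `muscle_labels`, `n_trials`, `n_points`, `scale_max`,
#'   `scale_sd`.
#' @export
assemble_subject <- function(trials, n_keep = 5) {
  if (length(trials) < n_keep) {
    stop("insufficient trials: need ", n_keep, ", got ", length(trials))
  }
  trials <- trials[seq_len(n_keep)]
  mats <- lapply(trials, function(tr) {
    if (inherits(tr, "raw_trial")) tr$samples else as.matrix(tr)
  })
  labels <- colnames(mats[[1]])
  npt <- nrow(mats[[1]])
  for (m in mats) {
    if (nrow(m) != npt || ncol(m) != ncol(mats[[1]])) {
      stop("all trials must share dimensions")
    }
    if (!is.null(labels) && !identical(colnames(m), labels)) {
      stop("trials have inconsistent muscle labels")
    }
  }
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(mats[[1]])))
  values <- t(do.call(rbind, mats)) # muscles x (n_points * n_keep)
  rownames(values) <- labels
  if (any(values < 0)) stop("envelope trials must be non-negative")
  scale_max <- apply(values, 1, max)
  flat <- which(scale_max == 0)
  if (length(flat)) {
    stop("constant (all-zero) muscle channel cannot be scaled: ",
         paste(labels[flat], collapse = ", "))
  }
  values <- values / scale_max
  scale_sd <- apply(values, 1, sd)
  flat <- which(scale_sd == 0)
  if (length(flat)) {
    stop("constant muscle channel cannot be unit-variance scaled: ",
         paste(labels[flat], collapse = ", "))
  }
  values <- values / scale_sd
  structure(
    list(values = values, muscle_labels = labels,
         n_trials = n_keep, n_points = npt,
         scale_max = scale_max, scale_sd = scale_sd),
    class = "emg_matrix")
}

#' @export
print.emg_matrix <- function(x, ...) {
  cat(sprintf("<emg_matrix> %d muscles x %d samples (%d trials x %d points)\n",
              nrow(x$values), ncol(x$values), x$n_trials, x$n_points))
  invisible(x)
}
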
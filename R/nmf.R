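as_emg_values <- function(M) {
  if (inherits(M, "emg_matrix")) M$values else as.matrix(M)
}

#' Variance accounted for by a reconstruction
#'
#' VAF is 100 times the squared uncentered Pearson correlation between
#' the data matrix and its reconstruction, both treated as flattened
#' vectors: `100 * (sum(M * R) / (||M||_F * ||R||_F))^2`. It is 100 for
#' a perfect reconstruction and 0 when data and reconstruction have
#' disjoint support.
#'
#' @param M Data matrix (or `emg_matrix`).
#' @param W Muscle weighting matrix (muscles x n).
#' @param C Temporal pattern matrix (n x time). Alternatively pass the
#'   reconstruction directly as `W` and leave `C` `NULL`.
#' @return VAF in percent, in `[0, 100]`.
#' @export
vaf <- function(M, W, C = NULL) {
  M <- as_emg_values(M)
  R <- if (is.null(C)) as.matrix(W) else W %*% C
  nm <- sqrt(sum(M^2)); nr <- sqrt(sum(R^2))
  if (nm == 0 || nr == 0) {
    stop("VAF undefined: data or reconstruction is all zero")
  }
  100 * (sum(M * R) / (nm * nr))^2
}

#' Fit NMF by multiplicative updates
#'
#' Factorizes a non-negative matrix `M ~ W %*% C` (muscles x time into
#' muscle weighting components and temporal pattern components) by
#' multiplicative updates minimizing the squared Frobenius error. The
#' error is non-increasing across iterations; iteration stops at
#' `max_iter` or when the relative error decrease falls below `tol`.
#' Factors are initialized uniform on (0, 1] from `seed`.
#'
#' @param M Non-negative matrix or `emg_matrix`.
#' @param n Number of synergies, `1 <= n <= nrow(M)`.
#' @param max_iter Iteration cap (default 1000).
#' @param tol Relative error-decrease stopping tolerance (default 1e-6).
#' @param seed Integer seed for the random initialization.
#' @return List with `W`, `C`, `error` (final Frobenius residual norm),
#'   `error_trace`, `iterations`, `vaf`.
#' @export
nmf_fit <- function(M, n, max_iter = 1000, tol = 1e-6, seed = 1) {
  V <- as_emg_values(M)
  if (anyNA(V)) stop("data matrix contains NA/NaN")
  if (any(V < 0)) stop("data matrix must be non-negative")
  m <- nrow(V)
  if (n < 1 || n > m) {
    stop("synergy order n must be between 1 and ", m, ", got ", n)
  }
  set.seed(seed)
  W0 <- matrix(1 - runif(m * n), m, n)        # uniform on (0, 1]
  C0 <- matrix(1 - runif(n * ncol(V)), n, ncol(V))
  fit <- nmf_mu_cpp(V, W0, C0, as.integer(max_iter), tol, 1e-12)
  list(W = fit$W, C = fit$H, error = fit$error,
       error_trace = fit$error_trace, iterations = fit$iterations,
       vaf = vaf(V, fit$W, fit$H))
}

#' Multi-restart NMF keeping the highest-VAF solution
#'
#' Repeats [nmf_fit()] from `restarts` random initializations and keeps
#' the solution with the highest VAF, guarding against poor local
#' minima. Restart `r` uses the deterministic sub-seed derived from
#' (`seed`, `r`), so results are bitwise reproducible.
#'
#' @inheritParams nmf_fit
#' @param restarts Number of random restarts (default 50).
#' @return As [nmf_fit()], plus `restart` (index of the winning restart).
#' @export
nmf_best_of <- function(M, n, restarts = 50, seed = 1,
                        max_iter = 1000, tol = 1e-6) {
  if (restarts < 1) stop("restarts must be >= 1")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- nmf_fit(M, n, max_iter = max_iter, tol = tol,
                   seed = sub_seed(seed, r))
    if (is.null(best) || fit$vaf > best$vaf) {
      best <- fit
      best$restart <- r
    }
  }
  best
}

#' Extract synergies with VAF-based model-order selection
#'
#' Runs multi-restart NMF for candidate orders `n = 1..m` and selects
#' the smallest order whose VAF strictly exceeds `vaf_threshold`
#' (default 90, i.e. VAF > 0.9 on the 0-1 scale). The returned weight
#' columns are scaled to unit Euclidean norm with the inverse factor
#' absorbed into the temporal patterns, so downstream comparisons
#' operate on unit vectors without changing the reconstruction.
#'
#' @inheritParams nmf_best_of
#' @param vaf_threshold Selection threshold in percent (default 90).
#' @param max_order Highest candidate order to evaluate (default: the
#'   muscle count).
#' @param full_curve If `TRUE` (default) evaluate every candidate order
#'   up to `max_order` so the full VAF curve is reported; if `FALSE`
#'   stop scanning once the threshold is exceeded.
#' @return A `synergy_decomposition`: list with unit-norm `W`
#'   (muscles x n), `C` (n x time), `n`, `vaf_curve` (named by order),
#'   `vaf_selected`, `residual_norm`, `restarts`, `seed`,
#'   `threshold_reached`, `muscle_labels`, `n_trials`, `n_points`.
#' @export
select_order <- function(M, vaf_threshold = 90, restarts = 50, seed = 1,
                         max_iter = 1000, tol = 1e-6,
                         max_order = NULL, full_curve = TRUE) {
  V <- as_emg_values(M)
  m <- nrow(V)
  if (is.null(max_order)) max_order <- m
  max_order <- min(max_order, m)
  vaf_curve <- rep(NA_real_, max_order)
  names(vaf_curve) <- seq_len(max_order)
  fits <- vector("list", max_order)
  selected <- NA_integer_
  for (n in seq_len(max_order)) {
    fit <- nmf_best_of(V, n, restarts = restarts, seed = sub_seed(seed, n * 1000L),
                       max_iter = max_iter, tol = tol)
    vaf_curve[n] <- fit$vaf
    fits[[n]] <- fit
    if (is.na(selected) && fit$vaf > vaf_threshold) {
      selected <- n
      if (!full_curve) break
    }
  }
  reached <- !is.na(selected)
  if (!reached) {
    warning("VAF threshold ", vaf_threshold,
            " not reached by order ", max_order, "; returning the maximum order")
    selected <- max_order
  }
  fit <- fits[[selected]]
  nrm <- sqrt(colSums(fit$W^2))
  nrm[nrm == 0] <- 1
  W <- sweep(fit$W, 2, nrm, "/")
  C <- sweep(fit$C, 1, nrm, "*")
  if (inherits(M, "emg_matrix")) rownames(W) <- M$muscle_labels
  structure(
    list(W = W, C = C, n = selected,
         vaf_curve = vaf_curve[!is.na(vaf_curve)],
         vaf_selected = fit$vaf, residual_norm = fit$error,
         restarts = restarts, seed = seed,
         threshold = vaf_threshold, threshold_reached = reached,
         muscle_labels = if (inherits(M, "emg_matrix")) M$muscle_labels
                         else rownames(V),
         n_trials = if (inherits(M, "emg_matrix")) M$n_trials else NULL,
         n_points = if (inherits(M, "emg_matrix")) M$n_points else NULL),
    class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf("<synergy_decomposition> n = %d synergies (VAF %.2f%%, threshold %g%%%s)\n",
              x$n, x$vaf_selected, x$threshold,
              if (x$threshold_reached) "" else ", NOT reached"))
  invisible(x)
}

#' Average temporal patterns over concatenated trials
#'
#' Collapses the temporal pattern components of a concatenated
#' multi-trial fit into one averaged movement cycle per synergy by
#' averaging over the per-trial blocks.
#'
#' @param C Temporal pattern matrix (n x `n_points * n_trials`), or a
#'   `synergy_decomposition`.
#' @param n_trials Number of concatenated trial blocks.
#' @param n_points Points per trial block (default 200).
#' @return Matrix n x `n_points`: per-synergy mean cycle.
#' @export
average_temporal <- function(C, n_trials = NULL, n_points = 200) {
  if (inherits(C, "synergy_decomposition")) {
    if (is.null(n_trials)) n_trials <- C$n_trials
    if (!is.null(C$n_points)) n_points <- C$n_points
    C <- C$C
  }
  C <- as.matrix(C)
  if (is.null(n_trials)) stop("n_trials must be supplied")
  if (ncol(C) != n_points * n_trials) {
    stop("temporal pattern length (", ncol(C),
         ") is not n_points (", n_points, ") x n_trials (", n_trials, ")")
  }
  out <- matrix(0, nrow(C), n_points)
  for (b in seq_len(n_trials)) {
    out <- out + C[, ((b - 1) * n_points + 1):(b * n_points), drop = FALSE]
  }
  out / n_trials
}
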
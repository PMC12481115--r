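#' Hoyer sparseness of a synergy vector
#'
#' Normalized L1/L2 ratio measure of how selectively activity is
#' distributed over muscles:
#' `phi = (sqrt(n) - sum(w) / sqrt(sum(w^2))) / (sqrt(n) - 1)`.
#' A one-hot vector (a single active muscle) scores 1; a uniform vector
#' (all muscles equally active) scores 0. Invariant to positive scaling
#' and to permutation of the components.
#'
#' @param w Non-negative, non-zero numeric vector of muscle weights.
#' @param n Component count (default `length(w)`).
#' @return Sparseness in `[0, 1]`.
#' @export
sparseness <- function(w, n = length(w)) {
  if (n < 2) stop("sparseness requires at least 2 components")
  if (length(w) != n) stop("w has length ", length(w), ", expected ", n)
  if (any(w < 0)) stop("w must be non-negative")
  l2 <- sqrt(sum(w^2))
  if (l2 == 0) stop("sparseness undefined for the all-zero vector")
  (sqrt(n) - sum(abs(w)) / l2) / (sqrt(n) - 1)
}

#' Per-synergy and per-subject sparseness for a group
#'
#' Computes the sparseness of every synergy weight vector of every
#' subject in a group, plus each subject's mean over their synergies
#' (the subject-level quantity compared between groups).
#'
#' @param decompositions List of `synergy_decomposition` objects.
#' @param subject_ids Optional subject identifiers.
#' @param group Group label attached to the output (default `""`).
#' @return A list of class `sparseness_report`: `per_synergy`
#'   (data.frame `subject`, `synergy`, `phi`), `per_subject`
#'   (data.frame `subject`, `mean_phi`), `group`.
#' @export
group_sparseness <- function(decompositions, subject_ids = NULL, group = "") {
  if (length(decompositions) == 0) stop("empty decomposition set")
  if (is.null(subject_ids)) {
    subject_ids <- names(decompositions)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_along(decompositions))
  }
  per <- do.call(rbind, lapply(seq_along(decompositions), function(i) {
    W <- decompositions[[i]]$W
    data.frame(subject = subject_ids[i], synergy = seq_len(ncol(W)),
               phi = apply(W, 2, sparseness))
  }))
  subj <- aggregate(phi ~ subject, per, mean)
  names(subj)[2] <- "mean_phi"
  subj <- subj[match(subject_ids, subj$subject), ]
  rownames(subj) <- NULL
  structure(list(per_synergy = per, per_subject = subj, group = group),
            class = "sparseness_report")
}

#' Non-negative least-squares combination of basis synergies
#'
#' Finds the coefficients `m >= 0` minimizing
#' `||target - basis %*% m||_2` — the building block of the
#' fractionation and merging models.
#'
#' @param target Numeric vector (unit-normalized centroid).
#' @param basis Matrix whose columns are candidate contributing
#'   centroids (unit-normalized).
#' @return Non-negative coefficient vector, one entry per basis column.
#' @export
nnls_combination <- function(target, basis) {
  basis <- as.matrix(basis)
  if (ncol(basis) == 0) stop("empty basis")
  if (nrow(basis) != length(target)) stop("target/basis dimension mismatch")
  as.numeric(pracma::lsqnonneg(basis, as.numeric(target))$x)
}

# Shared subset-search engine behind detect_fractionation and
# detect_merging: explain each target centroid as a non-negative
# combination of >= 2 basis centroids. For every basis subset of size
# 2..N, fit NNLS; a candidate passes when the coefficients surviving
# `coef_threshold` number >= 2 and the reconstruction's scalar product
# with the target is >= sp_threshold. The passing candidate with the
# highest SP wins (ties toward fewer contributing centroids).
decompose_targets <- function(targets, basis, coef_threshold, sp_threshold,
                              target_prefix, basis_prefix) {
  targets <- unit_cols(as.matrix(targets), "centroid")
  basis <- unit_cols(as.matrix(basis), "centroid")
  nb <- ncol(basis)
  if (nb < 2) stop("need at least 2 basis centroids, got ", nb)
  subsets <- unlist(lapply(2:nb, function(s) {
    asplit(combn(nb, s), 2)
  }), recursive = FALSE)
  lapply(seq_len(ncol(targets)), function(i) {
    target <- targets[, i]
    diag_rows <- lapply(subsets, function(ss) {
      coef <- nnls_combination(target, basis[, ss, drop = FALSE])
      recon <- basis[, ss, drop = FALSE] %*% coef
      spv <- if (all(recon == 0)) 0 else scalar_product(recon, target)
      surviving <- ss[coef >= coef_threshold]
      data.frame(
        subset = paste(ss, collapse = "+"),
        size = length(ss),
        n_surviving = length(surviving),
        sp = spv,
        passed = length(surviving) >= 2 && spv >= sp_threshold,
        coefficients = I(list(stats::setNames(coef, paste0(basis_prefix, ss)))))
    })
    diagnostics <- do.call(rbind, diag_rows)
    passing <- which(diagnostics$passed)
    best <- NULL
    if (length(passing)) {
      ord <- passing[order(-diagnostics$sp[passing], diagnostics$size[passing])]
      best <- ord[1]
    }
    res <- list(
      target_id = paste0(target_prefix, i),
      passed = length(passing) > 0,
      diagnostics = diagnostics,
      coef_threshold = coef_threshold,
      sp_threshold = sp_threshold)
    if (!is.null(best)) {
      coef <- diagnostics$coefficients[[best]]
      keep <- coef >= coef_threshold
      res$basis_ids <- names(coef)[keep]
      res$coefficients <- coef[keep]
      res$reconstruction_sp <- diagnostics$sp[best]
    } else {
      # full-basis fit reported for diagnosis even when nothing passes
      full <- nrow(diagnostics)
      res$basis_ids <- character(0)
      res$coefficients <- diagnostics$coefficients[[full]]
      res$reconstruction_sp <- diagnostics$sp[full]
    }
    res
  })
}

#' Detect fractionated synergies
#'
#' Tests whether each parent centroid (typically from the younger
#' group) can be explained as a non-negative combination of two or more
#' fragment centroids (from the older group): fits NNLS over every
#' fragment subset of size >= 2, and flags fractionation when at least
#' two coefficients reach `coef_threshold` and the reconstruction
#' matches the parent at `sp_threshold` or better. For each parent the
#' best passing candidate (highest reconstruction SP, ties toward fewer
#' fragments) is reported; every candidate fit is retained in a
#' diagnostics table.
#'
#' @param parents Matrix of parent centroids (muscles x kA).
#' @param fragments Matrix of candidate fragment centroids
#'   (muscles x kB).
#' @param coef_threshold Minimum contributing coefficient (default
#'   0.2).
#' @param sp_threshold Minimum reconstruction scalar product (default
#'   0.75).
#' @return List of `fractionation_result` objects, one per parent, each
#'   with `target_id`, `passed`, `basis_ids`, `coefficients`,
#'   `reconstruction_sp`, `diagnostics`.
#' @export
detect_fractionation <- function(parents, fragments, coef_threshold = 0.2,
                                 sp_threshold = 0.75) {
  out <- decompose_targets(parents, fragments, coef_threshold, sp_threshold,
                           target_prefix = "parent", basis_prefix = "fragment")
  lapply(out, function(r) structure(r, class = "fractionation_result"))
}

#' Detect merged synergies
#'
#' Mirror image of [detect_fractionation()]: tests whether each merged
#' candidate centroid (typically from the older group) can be explained
#' as a non-negative combination of two or more source centroids from
#' the younger group, under the same coefficient and scalar-product
#' criteria.
#'
#' @param merged_candidates Matrix of candidate merged centroids.
#' @param sources Matrix of candidate source centroids.
#' @inheritParams detect_fractionation
#' @return List of `merging_result` objects, same fields as
#'   [detect_fractionation()].
#' @export
detect_merging <- function(merged_candidates, sources, coef_threshold = 0.2,
                           sp_threshold = 0.75) {
  out <- decompose_targets(merged_candidates, sources, coef_threshold,
                           sp_threshold,
                           target_prefix = "merged", basis_prefix = "source")
  lapply(out, function(r) structure(r, class = "merging_result"))
}

#' @export
print.fractionation_result <- function(x, ...) {
  cat(sprintf("<fractionation_result> %s: %s", x$target_id,
              if (x$passed) "fractionated" else "not fractionated"))
  if (x$passed) {
    cat(sprintf(" <- %s (m = %s, SP = %.3f)",
                paste(x$basis_ids, collapse = " + "),
                paste(sprintf("%.2f", x$coefficients), collapse = ", "),
                x$reconstruction_sp))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.merging_result <- function(x, ...) {
  cat(sprintf("<merging_result> %s: %s\n", x$target_id,
              if (x$passed) "merged" else "not merged"))
  invisible(x)
}

#' Decide the direction of the fractionation/merging analysis
#'
#' Compares per-subject mean sparseness between the younger group (A)
#' and older group (B) with a Mann-Whitney U test. If the older group
#' is significantly sparser, the pipeline is directed to the
#' fractionation analysis (synergies splitting into specialized parts);
#' if significantly less sparse, to the merging analysis; otherwise
#' both are run exploratorily.
#'
#' @param phi_A,phi_B Per-subject mean sparseness vectors (group A =
#'   younger, group B = older), or `sparseness_report` objects.
#' @param alpha Significance level (default 0.05).
#' @return List with `directive` (`"fractionation"`, `"merging"` or
#'   `"both"`), `test` (the [mann_whitney()] result), `median_A`,
#'   `median_B`.
#' @export
direction_gate <- function(phi_A, phi_B, alpha = 0.05) {
  if (inherits(phi_A, "sparseness_report")) phi_A <- phi_A$per_subject$mean_phi
  if (inherits(phi_B, "sparseness_report")) phi_B <- phi_B$per_subject$mean_phi
  mw <- mann_whitney(phi_A, phi_B)
  directive <- if (mw$p_value < alpha) {
    if (median(phi_B) > median(phi_A)) "fractionation" else "merging"
  } else {
    "both"
  }
  list(directive = directive, test = mw,
       median_A = median(phi_A), median_B = median(phi_B))
}
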
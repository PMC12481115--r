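#' Run the full two-group muscle-synergy pipeline
#'
#' End-to-end analysis on envelope-level trials for two groups:
#' per-subject assembly and scaling, multi-restart NMF with VAF order
#' selection, within-group pooling and gap-statistic Ward clustering,
#' subject-invariance filtering, between-group centroid matching,
#' sparseness comparison with the direction gate, and the directed
#' fractionation and/or merging analysis.
#'
#' @param subjects Named list: per subject, a list of time-normalized
#'   envelope trials (time x muscles matrices). A `synthetic_dataset`
#'   can be passed directly.
#' @param groups Named character vector mapping subject id to `"A"`
#'   (younger) or `"B"` (older); ignored when `subjects` is a
#'   `synthetic_dataset`.
#' @param n_keep Trials per subject (default 5).
#' @param vaf_threshold VAF selection threshold in percent (default
#'   90).
#' @param restarts NMF restarts per candidate order (default 50).
#' @param max_iter,tol NMF iteration controls.
#' @param max_order Highest candidate synergy order (default: muscle
#'   count).
#' @param full_curve Evaluate the full VAF curve (default `FALSE` in
#'   the pipeline: scanning stops once the threshold is reached).
#' @param h_range Candidate cluster counts (default `2:20`).
#' @param B Gap-statistic reference datasets (default 500).
#' @param fraction Subject-invariance fraction (default 1/3).
#' @param sp_threshold Matching / reconstruction SP threshold (default
#'   0.75).
#' @param coef_threshold Fractionation coefficient threshold (default
#'   0.2).
#' @param alpha Significance level for the direction gate (default
#'   0.05).
#' @param force Force `"fractionation"`, `"merging"` or `"both"`
#'   regardless of the direction gate (default `NULL`: follow the
#'   gate).
#' @param seed Master seed.
#' @return A `synergy_pipeline` list: `decompositions`, `orders`,
#'   `clusters` (per group `cluster_solution`), `invariant` (filtered
#'   centroids), `match`, `sparseness` (per-group reports), `gate`,
#'   `fractionation`, `merging`, `comparison` (synergy count and
#'   sparseness group tables).
#' @export
run_synergy_pipeline <- function(subjects, groups = NULL, n_keep = 5,
                                 vaf_threshold = 90, restarts = 50,
                                 max_iter = 1000, tol = 1e-6,
                                 max_order = NULL, full_curve = FALSE,
                                 h_range = 2:20, B = 500,
                                 fraction = 1 / 3, sp_threshold = 0.75,
                                 coef_threshold = 0.2, alpha = 0.05,
                                 force = NULL, seed = 1) {
  if (inherits(subjects, "synthetic_dataset")) {
    groups <- subjects$groups
    subjects <- lapply(subjects$subjects, `[[`, "trials")
  }
  if (is.null(groups)) stop("groups must be supplied")
  ids <- names(subjects)
  decomps <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    M <- assemble_subject(subjects[[id]], n_keep = n_keep)
    decomps[[id]] <- select_order(M, vaf_threshold = vaf_threshold,
                                  restarts = restarts, max_iter = max_iter,
                                  tol = tol, max_order = max_order,
                                  full_curve = full_curve,
                                  seed = sub_seed(seed, 5000 + i))
  }
  ids_A <- ids[groups[ids] == "A"]; ids_B <- ids[groups[ids] == "B"]
  if (length(ids_A) == 0 || length(ids_B) == 0) {
    stop("both groups must be non-empty")
  }
  clusters <- list(
    A = cluster_synergies(pool_group(decomps[ids_A]), h_range = h_range,
                          B = B, seed = sub_seed(seed, 11)),
    B = cluster_synergies(pool_group(decomps[ids_B]), h_range = h_range,
                          B = B, seed = sub_seed(seed, 12)))
  invariant <- list(
    A = subject_invariant(clusters$A, length(ids_A), fraction = fraction),
    B = subject_invariant(clusters$B, length(ids_B), fraction = fraction))
  match <- match_groups(invariant$A$centroids, invariant$B$centroids,
                        sp_threshold = sp_threshold)
  sparse <- list(
    A = group_sparseness(decomps[ids_A], group = "A"),
    B = group_sparseness(decomps[ids_B], group = "B"))
  gate <- direction_gate(sparse$A, sparse$B, alpha = alpha)
  directive <- if (is.null(force)) gate$directive else force
  fractionation <- NULL; merging <- NULL
  if (directive %in% c("fractionation", "both") &&
      ncol(invariant$B$centroids) >= 2) {
    fractionation <- detect_fractionation(invariant$A$centroids,
                                          invariant$B$centroids,
                                          coef_threshold = coef_threshold,
                                          sp_threshold = sp_threshold)
  }
  if (directive %in% c("merging", "both") &&
      ncol(invariant$A$centroids) >= 2) {
    merging <- detect_merging(invariant$B$centroids,
                              invariant$A$centroids,
                              coef_threshold = coef_threshold,
                              sp_threshold = sp_threshold)
  }
  orders <- vapply(decomps, `[[`, integer(1), "n")
  subj_phi <- c(sparse$A$per_subject$mean_phi, sparse$B$per_subject$mean_phi)
  grp <- c(rep("A", length(ids_A)), rep("B", length(ids_B)))
  safe_summarize <- function(variable, values, groups) {
    tryCatch(summarize_comparison(variable, values, groups),
             error = function(e) {
               # degenerate samples (e.g. every subject at the same order)
               mw <- mann_whitney(values[groups == "A"], values[groups == "B"])
               data.frame(variable = variable,
                          median_A = median(values[groups == "A"]),
                          min_A = min(values[groups == "A"]),
                          max_A = max(values[groups == "A"]),
                          median_B = median(values[groups == "B"]),
                          min_B = min(values[groups == "B"]),
                          max_B = max(values[groups == "B"]),
                          u_statistic = mw$U, p_value = mw$p_value,
                          effect_size_d = NA_real_)
             })
  }
  comparison <- rbind(
    safe_summarize("n_synergies", as.numeric(orders[c(ids_A, ids_B)]), grp),
    safe_summarize("sparseness", subj_phi, grp))
  structure(
    list(decompositions = decomps, orders = orders, clusters = clusters,
         invariant = invariant, match = match, sparseness = sparse,
         gate = gate, directive = directive,
         fractionation = fractionation, merging = merging,
         comparison = comparison),
    class = "synergy_pipeline")
}

#' @export
print.synergy_pipeline <- function(x, ...) {
  cat("<synergy_pipeline>\n")
  cat(sprintf("  subjects: %d A + %d B\n",
              nrow(x$sparseness$A$per_subject),
              nrow(x$sparseness$B$per_subject)))
  cat(sprintf("  clusters: h_A = %d, h_B = %d\n",
              x$clusters$A$h, x$clusters$B$h))
  cat(sprintf("  matched centroid pairs: %d of %d\n",
              sum(x$match$pairs$matched), nrow(x$match$pairs)))
  cat(sprintf("  sparseness medians: A = %.3f, B = %.3f (p = %.4g)\n",
              x$gate$median_A, x$gate$median_B, x$gate$test$p_value))
  cat(sprintf("  direction gate: %s\n", x$directive))
  if (!is.null(x$fractionation)) {
    cat(sprintf("  fractionated parents: %d of %d\n",
                sum(vapply(x$fractionation, `[[`, logical(1), "passed")),
                length(x$fractionation)))
  }
  invisible(x)
}
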
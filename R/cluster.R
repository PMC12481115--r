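#' Pool unit-normalized synergy vectors across a group's subjects
#'
#' Collects every muscle weighting component (column of W) from every
#' subject's decomposition into one set, unit-normalized and tagged with
#' its subject, ready for clustering.
#'
#' @param decompositions List of `synergy_decomposition` objects (one
#'   per subject).
#' @param subject_ids Optional character vector of subject identifiers
#'   (defaults to list names or `S1..Sk`).
#' @return A `synergy_pool`: list with `vectors` (muscles x N, unit
#'   columns), `subject` (length-N tag vector), `muscle_labels`.
#' @export
pool_group <- function(decompositions, subject_ids = NULL) {
  if (length(decompositions) == 0) stop("empty decomposition set")
  if (is.null(subject_ids)) {
    subject_ids <- names(decompositions)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_along(decompositions))
  }
  labels <- decompositions[[1]]$muscle_labels
  ws <- list(); tags <- character(0)
  for (i in seq_along(decompositions)) {
    d <- decompositions[[i]]
    if (!is.null(labels) && !is.null(d$muscle_labels) &&
        !identical(d$muscle_labels, labels)) {
      stop("inconsistent muscle labels across subjects")
    }
    ws[[i]] <- d$W
    tags <- c(tags, rep(subject_ids[i], ncol(d$W)))
  }
  vectors <- unit_cols(do.call(cbind, ws), "synergy vector")
  rownames(vectors) <- labels
  structure(list(vectors = vectors, subject = tags, muscle_labels = labels),
            class = "synergy_pool")
}

#' Ward hierarchical clustering of synergy vectors
#'
#' Agglomerative clustering with Ward's criterion on Euclidean
#' distances, cut at `h` clusters.
#'
#' @param vectors Matrix of column vectors (muscles x N) or a
#'   `synergy_pool`.
#' @param h Number of clusters.
#' @return Integer assignment vector of length N.
#' @export
ward_cluster <- function(vectors, h) {
  V <- if (inherits(vectors, "synergy_pool")) vectors$vectors else as.matrix(vectors)
  if (h < 1) stop("cluster count h must be >= 1")
  if (h > ncol(V)) stop("cluster count h exceeds number of vectors")
  hc <- hclust(dist(t(V)), method = "ward.D2")
  cutree(hc, k = h)
}

# Tibshirani within-cluster dispersion: sum over clusters of
# (sum of pairwise squared Euclidean distances) / (2 * cluster size).
within_dispersion <- function(V, assignments) {
  tot <- 0
  for (cl in unique(assignments)) {
    X <- V[, assignments == cl, drop = FALSE]
    nr <- ncol(X)
    if (nr < 2) next
    d2 <- as.matrix(dist(t(X)))^2
    tot <- tot + sum(d2) / (2 * nr) # sum(d2) counts each pair twice
  }
  tot
}

#' Gap statistic for selecting the number of synergy clusters
#'
#' Compares the compactness of the Ward clustering of the real synergy
#' vectors against `B` reference datasets drawn uniformly within the
#' per-dimension bounds of the data (no cluster structure). For each
#' candidate `h`, `Gap(h) = mean_b log W_b(h) - log W(h)` with `W` the
#' within-cluster dispersion; the chosen `h*` is the smallest `h` with
#' `Gap(h) >= Gap(h+1) - sd(h+1)`.
#'
#' @param vectors Matrix (features x N) or `synergy_pool`.
#' @param h_range Candidate cluster counts (default `2:20`).
#' @param B Number of reference datasets (default 500; small values are
#'   accepted with a warning).
#' @param seed Integer seed for the reference draws.
#' @param sd_correction Multiply the reference spread by
#'   `sqrt(1 + 1/B)` (the finite-B correction; default `TRUE`).
#' @param renormalize_ref Unit-normalize reference vectors before
#'   clustering (default `FALSE`: references live in the bounding box of
#'   the data).
#' @return List with `gap_curve` (data.frame `h`, `gap`, `sd`,
#'   `log_w`), `h_star`, `found`.
#' @export
gap_statistic <- function(vectors, h_range = 2:20, B = 500, seed = 1,
                          sd_correction = TRUE, renormalize_ref = FALSE) {
  V <- if (inherits(vectors, "synergy_pool")) vectors$vectors else as.matrix(vectors)
  N <- ncol(V)
  h_range <- sort(unique(as.integer(h_range)))
  if (max(h_range) + 1 > N) {
    stop("need at least max(h_range)+1 = ", max(h_range) + 1,
         " vectors, got ", N)
  }
  if (B < 2) stop("B must be >= 2")
  if (B < 10) warning("B = ", B, " reference datasets is very small")
  lo <- apply(V, 1, min); hi <- apply(V, 1, max)
  hc <- hclust(dist(t(V)), method = "ward.D2")
  log_w <- vapply(h_range, function(h) {
    log(within_dispersion(V, cutree(hc, k = h)))
  }, numeric(1))
  log_wb <- matrix(NA_real_, B, length(h_range))
  for (b in seq_len(B)) {
    set.seed(sub_seed(seed, b))
    R <- matrix(runif(length(V), min = rep(lo, N), max = rep(hi, N)),
                nrow = nrow(V))
    if (renormalize_ref) R <- unit_cols(R, "reference vector")
    hcb <- hclust(dist(t(R)), method = "ward.D2")
    log_wb[b, ] <- vapply(h_range, function(h) {
      log(within_dispersion(R, cutree(hcb, k = h)))
    }, numeric(1))
  }
  gap <- colMeans(log_wb) - log_w
  sdk <- apply(log_wb, 2, sd) * sqrt((B - 1) / B) # population sd over refs
  if (sd_correction) sdk <- sdk * sqrt(1 + 1 / B)
  h_star <- NA_integer_; found <- FALSE
  for (i in seq_len(length(h_range) - 1L)) {
    if (gap[i] >= gap[i + 1] - sdk[i + 1]) {
      h_star <- h_range[i]; found <- TRUE; break
    }
  }
  if (!found) h_star <- max(h_range)
  list(gap_curve = data.frame(h = h_range, gap = gap, sd = sdk, log_w = log_w),
       h_star = h_star, found = found)
}

#' Cluster a group's pooled synergy vectors into representative synergies
#'
#' Full representative-synergy workflow for one group: Ward clustering
#' of the pooled unit vectors, gap-statistic selection of the cluster
#' count, centroid computation and per-cluster subject support.
#'
#' @param pool A `synergy_pool` from [pool_group()].
#' @inheritParams gap_statistic
#' @return A `cluster_solution`: list with `vectors`, `subject`,
#'   `linkage` (the `hclust` tree), `h`, `gap_curve`, `gap_found`,
#'   `assignments`, `centroids` (muscles x h unit-normalized means),
#'   `centroids_raw` (unnormalized means), `support` (distinct subjects
#'   per cluster), `muscle_labels`.
#' @export
cluster_synergies <- function(pool, h_range = 2:20, B = 500, seed = 1,
                              sd_correction = TRUE, renormalize_ref = FALSE) {
  stopifnot(inherits(pool, "synergy_pool"))
  V <- pool$vectors
  h_range <- h_range[h_range + 1 <= ncol(V)]
  if (length(h_range) < 2) stop("too few vectors for the requested h_range")
  gs <- gap_statistic(V, h_range = h_range, B = B, seed = seed,
                      sd_correction = sd_correction,
                      renormalize_ref = renormalize_ref)
  hc <- hclust(dist(t(V)), method = "ward.D2")
  assign <- cutree(hc, k = gs$h_star)
  cent_raw <- vapply(seq_len(gs$h_star), function(cl) {
    rowMeans(V[, assign == cl, drop = FALSE])
  }, numeric(nrow(V)))
  centroids <- unit_cols(cent_raw, "centroid")
  support <- vapply(seq_len(gs$h_star), function(cl) {
    length(unique(pool$subject[assign == cl]))
  }, integer(1))
  structure(
    list(vectors = V, subject = pool$subject, linkage = hc,
         h = gs$h_star, gap_curve = gs$gap_curve, gap_found = gs$found,
         assignments = assign, centroids = centroids,
         centroids_raw = cent_raw, support = support,
         muscle_labels = pool$muscle_labels),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d vectors -> h = %d clusters (support: %s)\n",
              ncol(x$vectors), x$h, paste(x$support, collapse = ", ")))
  invisible(x)
}

#' Filter clusters by subject-invariance
#'
#' Retains only clusters whose members come from at least
#' `ceiling(fraction * group_size)` distinct subjects — clusters
#' representing a group-typical synergy rather than an idiosyncratic
#' one.
#'
#' @param solution A `cluster_solution`.
#' @param group_size Number of subjects in the group.
#' @param fraction Minimum fraction of subjects (default 1/3).
#' @return List with `centroids` (retained unit centroids), `ids`
#'   (retained cluster ids), `support`.
#' @export
subject_invariant <- function(solution, group_size, fraction = 1 / 3) {
  stopifnot(inherits(solution, "cluster_solution"))
  need <- ceiling(fraction * group_size)
  keep <- which(solution$support >= need)
  list(centroids = solution$centroids[, keep, drop = FALSE],
       ids = keep, support = solution$support[keep])
}

# Exact maximum-total-SP injective assignment of the smaller centroid
# set into the larger, by depth-first search with an upper-bound prune.
best_assignment <- function(sp) {
  nA <- nrow(sp); nB <- ncol(sp)
  transposed <- nA > nB
  if (transposed) sp <- t(sp)
  n_small <- nrow(sp); n_big <- ncol(sp)
  col_max <- apply(sp, 1, max)
  best <- list(total = -Inf, assign = NULL)
  search <- function(i, used, total, assign) {
    if (i > n_small) {
      if (total > best$total) best <<- list(total = total, assign = assign)
      return()
    }
    if (total + sum(col_max[i:n_small]) <= best$total) return()
    for (j in seq_len(n_big)) {
      if (!used[j]) {
        used[j] <- TRUE
        search(i + 1, used, total + sp[i, j], c(assign, j))
        used[j] <- FALSE
      }
    }
  }
  search(1L, rep(FALSE, n_big), 0, integer(0))
  if (transposed) {
    cbind(A = best$assign, B = seq_len(n_small))
  } else {
    cbind(A = seq_len(n_small), B = best$assign)
  }
}

#' Match synergy cluster centroids between two groups
#'
#' Pairs the centroids of two groups by the injective assignment that
#' maximizes the total scalar product (cosine similarity of the unit
#' vectors); the smaller set is fully considered. Pairs whose SP falls
#' below `sp_threshold` are demoted to unmatched.
#'
#' @param centroids_A,centroids_B Unit-normalized centroid matrices
#'   (muscles x k), e.g. from [subject_invariant()].
#' @param sp_threshold Minimum scalar product for a match (default
#'   0.75).
#' @return A `match_result`: list with `pairs` (data.frame `cluster_A`,
#'   `cluster_B`, `sp`, `matched`), `unmatched_A`, `unmatched_B`,
#'   `sp_threshold`, `total_sp`.
#' @export
match_groups <- function(centroids_A, centroids_B, sp_threshold = 0.75) {
  A <- as.matrix(centroids_A); B <- as.matrix(centroids_B)
  if (ncol(A) == 0 || ncol(B) == 0) {
    return(structure(list(
      pairs = data.frame(cluster_A = integer(0), cluster_B = integer(0),
                         sp = numeric(0), matched = logical(0)),
      unmatched_A = seq_len(ncol(A)), unmatched_B = seq_len(ncol(B)),
      sp_threshold = sp_threshold, total_sp = 0), class = "match_result"))
  }
  A <- unit_cols(A, "centroid"); B <- unit_cols(B, "centroid")
  sp <- crossprod(A, B) # nA x nB matrix of scalar products
  asg <- best_assignment(sp)
  asg <- asg[order(asg[, "A"]), , drop = FALSE]
  spv <- sp[asg]
  pairs <- data.frame(cluster_A = asg[, "A"], cluster_B = asg[, "B"],
                      sp = spv, matched = spv >= sp_threshold)
  structure(list(
    pairs = pairs,
    unmatched_A = sort(c(setdiff(seq_len(ncol(A)), pairs$cluster_A),
                         pairs$cluster_A[!pairs$matched])),
    unmatched_B = sort(c(setdiff(seq_len(ncol(B)), pairs$cluster_B),
                         pairs$cluster_B[!pairs$matched])),
    sp_threshold = sp_threshold, total_sp = sum(spv)),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (%d matched at SP >= %g)\n",
              nrow(x$pairs), sum(x$pairs$matched), x$sp_threshold))
  invisible(x)
}

#' Permutation-based pointwise comparison of temporal patterns
#'
#' Compares two groups' per-subject averaged temporal patterns point by
#' point with a two-sample t-statistic trajectory, controlling the
#' family-wise error over time points by the max-statistic permutation
#' method (group labels permuted). Returns the supra-threshold time
#' clusters.
#'
#' @param patterns_A,patterns_B Numeric matrices, subjects x time
#'   points, one row per subject, for the matched pair of synergies.
#' @param n_perm Number of label permutations (default 999).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Integer seed for the permutations.
#' @return List with `t_stat` (length-T trajectory), `threshold`
#'   (critical max-|t|), `significant` (logical length-T), `clusters`
#'   (data.frame `start`, `end`).
#' @export
compare_temporal <- function(patterns_A, patterns_B, n_perm = 999,
                             alpha = 0.05, seed = 1) {
  A <- as.matrix(patterns_A); B <- as.matrix(patterns_B)
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop("need at least 2 subjects per group")
  }
  if (ncol(A) != ncol(B)) stop("pattern lengths differ")
  X <- rbind(A, B)
  nA <- nrow(A); n <- nrow(X)
  tstat <- function(lab) {
    a <- X[lab, , drop = FALSE]; b <- X[!lab, , drop = FALSE]
    va <- apply(a, 2, var); vb <- apply(b, 2, var)
    sp2 <- ((nrow(a) - 1) * va + (nrow(b) - 1) * vb) / (n - 2)
    se <- sqrt(sp2 * (1 / nrow(a) + 1 / nrow(b)))
    d <- colMeans(a) - colMeans(b)
    ifelse(se == 0, 0, d / se)
  }
  lab0 <- c(rep(TRUE, nA), rep(FALSE, n - nA))
  t0 <- tstat(lab0)
  maxs <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(sub_seed(seed, p))
    maxs[p] <- max(abs(tstat(sample(lab0))))
  }
  thr <- quantile(c(maxs, max(abs(t0))), 1 - alpha, names = FALSE)
  sig <- abs(t0) > thr
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  clusters <- data.frame(start = starts[runs$values], end = ends[runs$values])
  list(t_stat = t0, threshold = thr, significant = sig, clusters = clusters)
}
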
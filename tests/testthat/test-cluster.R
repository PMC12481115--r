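make_pool <- function(k, subjects, jitter = 0.03, seed = 1,
                      sparsity = 0.6) {
  tpl <- make_templates(k, sparsity_target = sparsity, seed = seed)
  set.seed(seed + 1)
  V <- do.call(cbind, lapply(seq_len(subjects), function(s) {
    J <- pmax(tpl + matrix(rnorm(length(tpl), 0, jitter), nrow(tpl)), 0)
    sweep(J, 2, sqrt(colSums(J^2)), "/")
  }))
  list(templates = tpl, vectors = V,
       subject = rep(paste0("S", seq_len(subjects)), each = k))
}

test_that("pool_group collects unit-normalized tagged vectors", {
  d1 <- list(W = matrix(runif(16 * 3), 16, 3), muscle_labels = default_muscle_labels())
  d2 <- list(W = matrix(runif(16 * 4), 16, 4), muscle_labels = default_muscle_labels())
  pool <- pool_group(list(a = d1, b = d2))
  expect_equal(ncol(pool$vectors), 7L)
  expect_equal(unname(colSums(pool$vectors^2)), rep(1, 7), tolerance = 1e-12)
  expect_equal(pool$subject, c(rep("a", 3), rep("b", 4)))
  expect_error(pool_group(list()), "empty")
  d3 <- list(W = matrix(runif(16 * 2), 16, 2),
             muscle_labels = rev(default_muscle_labels()))
  expect_error(pool_group(list(a = d1, c = d3)), "labels")
})

test_that("ward clustering separates blobs and honors cut sizes", {
  set.seed(5)
  blob1 <- matrix(rnorm(5 * 10, mean = 0, sd = 0.01), 5)
  blob2 <- matrix(rnorm(5 * 10, mean = 3, sd = 0.01), 5)
  V <- cbind(blob1, blob2)
  cl <- ward_cluster(V, 2)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])
  expect_equal(sort(unique(ward_cluster(V, 20))), 1:20)
  expect_error(ward_cluster(V, 0), "h")
  expect_error(ward_cluster(V, 21), "exceeds")
})

test_that("ward linkage heights match a hand-rolled Lance-Williams oracle", {
  set.seed(8)
  V <- matrix(runif(4 * 10), 4, 10)
  got <- sort(hclust(dist(t(V)), method = "ward.D2")$height)
  # naive agglomeration: merge the pair minimizing the Ward distance,
  # updating distances with the Lance-Williams recurrence
  d <- as.matrix(dist(t(V)))^2
  sizes <- rep(1, 10)
  active <- 1:10
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in active) for (j in active) if (i < j && d[i, j] < bestv) {
      bestv <- d[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestv))
    for (k in setdiff(active, best)) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  expect_equal(got, sort(heights), tolerance = 1e-9)
})

test_that("gap statistic recovers planted cluster counts", {
  pool <- make_pool(3, subjects = 10, jitter = 0.01, seed = 31)
  gs <- gap_statistic(pool$vectors, h_range = 2:10, B = 50, seed = 4)
  expect_equal(gs$h_star, 3L)
  expect_true(gs$found)
  expect_equal(nrow(gs$gap_curve), 9L)
  for (k in c(5, 7)) {
    pool <- make_pool(k, subjects = 8, jitter = 0.04, seed = 31 + k)
    gs <- gap_statistic(pool$vectors, h_range = 2:12, B = 50, seed = 4)
    expect_equal(gs$h_star, k)
  }
})

test_that("gap statistic accepts tiny B with a warning and guards inputs", {
  pool <- make_pool(3, subjects = 4, seed = 77)
  expect_warning(gs <- gap_statistic(pool$vectors, h_range = 2:5, B = 2,
                                     seed = 1), "small")
  expect_true(gs$h_star >= 2)
  expect_error(gap_statistic(pool$vectors[, 1:5], h_range = 2:10, B = 10),
               "at least")
})

test_that("structureless data selects the smallest cluster count", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    V <- matrix(runif(8 * 40), 8, 40)
    gs <- gap_statistic(V, h_range = 2:8, B = 30, seed = s)
    if (gs$h_star == 2) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("cluster_synergies centroids are member means and support counts subjects", {
  pool <- make_pool(4, subjects = 6, jitter = 0.02, seed = 55)
  sp <- structure(list(vectors = pool$vectors, subject = pool$subject,
                       muscle_labels = NULL), class = "synergy_pool")
  sol <- cluster_synergies(sp, h_range = 2:8, B = 30, seed = 9)
  expect_equal(sol$h, 4L)
  expect_equal(length(sol$assignments), ncol(pool$vectors))
  for (cl in seq_len(sol$h)) {
    members <- pool$vectors[, sol$assignments == cl, drop = FALSE]
    expect_equal(sol$centroids_raw[, cl], rowMeans(members), tolerance = 1e-9)
  }
  expect_equal(unname(colSums(sol$centroids^2)), rep(1, sol$h),
               tolerance = 1e-12)
  expect_equal(sol$support, rep(6L, 4))
  # centroid recovery of the planted templates
  best <- apply(crossprod(sol$centroids, pool$templates), 1, max)
  expect_true(all(best > 0.98))
})

test_that("centroids are invariant to input vector order", {
  pool <- make_pool(3, subjects = 5, jitter = 0.02, seed = 91)
  sp1 <- structure(list(vectors = pool$vectors, subject = pool$subject,
                        muscle_labels = NULL), class = "synergy_pool")
  perm <- sample(ncol(pool$vectors))
  sp2 <- structure(list(vectors = pool$vectors[, perm],
                        subject = pool$subject[perm],
                        muscle_labels = NULL), class = "synergy_pool")
  s1 <- cluster_synergies(sp1, h_range = 2:6, B = 20, seed = 3)
  s2 <- cluster_synergies(sp2, h_range = 2:6, B = 20, seed = 3)
  m <- match_groups(s1$centroids, s2$centroids)
  expect_true(all(m$pairs$sp > 1 - 1e-9))
})

test_that("subject-invariance filter applies the ceiling rule", {
  sol <- structure(list(centroids = matrix(runif(16 * 3), 16, 3),
                        support = c(5L, 2L, 13L)), class = "cluster_solution")
  expect_equal(subject_invariant(sol, 13)$ids, c(1L, 3L))  # need >= 5
  sol$support <- c(2L, 3L, 8L)
  expect_equal(subject_invariant(sol, 8)$ids, c(2L, 3L))   # need >= 3
  expect_equal(subject_invariant(sol, 8, fraction = 0)$ids, 1:3)
})

test_that("match_groups pairs identical sets perfectly and rejects orthogonal ones", {
  A <- diag(4)[, 1:3]
  m <- match_groups(A, A)
  expect_equal(m$pairs$cluster_B, m$pairs$cluster_A)
  expect_equal(m$pairs$sp, rep(1, 3))
  expect_true(all(m$pairs$matched))

  B <- diag(8)
  m2 <- match_groups(B[, 1:3], B[, 4:8])
  expect_true(all(!m2$pairs$matched))
  expect_equal(m2$unmatched_A, 1:3)
  expect_equal(m2$unmatched_B, 1:5)

  empty <- match_groups(matrix(numeric(0), 4, 0), B[, 1:2])
  expect_equal(nrow(empty$pairs), 0L)
})

test_that("match_groups equals exhaustive assignment enumeration", {
  set.seed(17)
  for (rep in 1:6) {
    nA <- sample(3:5, 1); nB <- sample(3:6, 1)
    A <- matrix(runif(10 * nA), 10, nA)
    B <- matrix(runif(10 * nB), 10, nB)
    m <- match_groups(A, B, sp_threshold = 0)
    An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    oracle <- assignment_oracle(crossprod(An, Bn))
    expect_equal(m$total_sp, oracle$total, tolerance = 1e-12)
  }
})

test_that("temporal comparison flags planted group differences only", {
  set.seed(71)
  base <- sin(seq(0, pi, length.out = 100))
  A <- t(replicate(8, base + rnorm(100, 0, 0.05)))
  B0 <- t(replicate(8, base + rnorm(100, 0, 0.05)))
  null_res <- compare_temporal(A, B0, n_perm = 199, seed = 5)
  expect_equal(nrow(null_res$clusters), 0L)

  B1 <- B0
  B1[, 50:80] <- B1[, 50:80] + 1.5
  res <- compare_temporal(A, B1, n_perm = 199, seed = 5)
  expect_gt(nrow(res$clusters), 0)
  hit <- any(res$clusters$start <= 80 & res$clusters$end >= 50)
  expect_true(hit)
  expect_error(compare_temporal(A[1, , drop = FALSE], B1), "2 subjects")
})

test_that("max-statistic correction keeps the familywise error near alpha", {
  set.seed(404)
  fp <- 0
  nsim <- 60
  for (i in seq_len(nsim)) {
    A <- matrix(rnorm(6 * 40), 6, 40)
    B <- matrix(rnorm(6 * 40), 6, 40)
    res <- compare_temporal(A, B, n_perm = 99, alpha = 0.05, seed = i)
    if (nrow(res$clusters) > 0) fp <- fp + 1
  }
  # binomial(60, 0.05) upper tail: >9 false positives is < 1e-3 likely
  expect_lte(fp, 9)
})
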
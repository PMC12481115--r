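test_that("sparseness hits its boundary cases exactly", {
  one_hot <- c(5, rep(0, 15))
  expect_identical(sparseness(one_hot), 1)
  uniform <- rep(0.3, 16)
  expect_equal(sparseness(uniform), 0)
  expect_equal(sparseness(c(1, 1, 0, 0)), 2 - sqrt(2), tolerance = 1e-12)
})

test_that("sparseness validates input", {
  expect_error(sparseness(rep(0, 16)), "all-zero")
  expect_error(sparseness(c(1)), "at least 2")
  expect_error(sparseness(c(1, -1, 0)), "non-negative")
  expect_error(sparseness(c(1, 2), n = 3), "length")
})

test_that("sparseness is bounded, scale- and permutation-invariant", {
  set.seed(12)
  for (i in 1:200) {
    w <- runif(16)^sample(1:8, 1)
    phi <- sparseness(w)
    expect_gte(phi, 0)
    expect_lte(phi, 1)
    expect_equal(sparseness(3.7 * w), phi, tolerance = 1e-12)
    expect_equal(sparseness(sample(w)), phi, tolerance = 1e-12)
  }
})

test_that("group_sparseness reports per-synergy values and subject means", {
  W1 <- cbind(c(1, rep(0, 15)), rep(1, 16))  # phi = 1 and 0
  W2 <- cbind(c(1, 1, rep(0, 14)))
  rep_ <- group_sparseness(list(s1 = list(W = W1), s2 = list(W = W2)),
                           group = "A")
  expect_equal(rep_$group, "A")
  expect_equal(rep_$per_subject$mean_phi[1], 0.5)
  expect_equal(rep_$per_subject$mean_phi[2],
               (4 - sqrt(2)) / 3, tolerance = 1e-12)
  # scale invariance carries through
  rep3 <- group_sparseness(list(s1 = list(W = 3 * W1)))
  expect_equal(rep3$per_subject$mean_phi[1], 0.5)
  expect_error(group_sparseness(list()), "empty")
})

test_that("nnls_combination solves the constrained fit", {
  basis <- diag(6)[, 1:3]
  coef <- nnls_combination(basis[, 2], basis)
  expect_equal(coef, c(0, 1, 0), tolerance = 1e-10)
  ortho <- c(0, 0, 0, 1, 0, 0)
  expect_equal(nnls_combination(ortho, basis), rep(0, 3), tolerance = 1e-12)
  expect_error(nnls_combination(ortho, matrix(numeric(0), 6, 0)), "empty")
})

test_that("nnls matches an exhaustive active-set enumeration oracle", {
  set.seed(21)
  for (rep in 1:5) {
    basis <- matrix(runif(8 * 5), 8, 5)
    basis <- sweep(basis, 2, sqrt(colSums(basis^2)), "/")
    target <- runif(8)
    coef <- nnls_combination(target, basis)
    obj <- sum((target - basis %*% coef)^2)
    # oracle: best feasible unconstrained LS over every support subset
    best <- sum(target^2)
    for (sz in 1:5) {
      for (ss in asplit(combn(5, sz), 2)) {
        Bm <- basis[, ss, drop = FALSE]
        beta <- tryCatch(solve(crossprod(Bm), crossprod(Bm, target)),
                         error = function(e) NULL)
        if (is.null(beta) || any(beta < 0)) next
        best <- min(best, sum((target - Bm %*% beta)^2))
      }
    }
    expect_equal(obj, best, tolerance = 1e-8)
  }
})

test_that("nnls optimum beats hand-picked nonnegative coefficients", {
  set.seed(33)
  basis <- matrix(runif(10 * 4), 10, 4)
  target <- runif(10)
  coef <- nnls_combination(target, basis)
  obj <- sum((target - basis %*% coef)^2)
  for (i in 1:20) {
    rand_coef <- runif(4, 0, 1.5)
    expect_lte(obj, sum((target - basis %*% rand_coef)^2) + 1e-12)
  }
})

test_that("forward-constructed fractionation is detected with analytic coefficients", {
  f1 <- c(1, 1, 0, 0, 0, 0, 0, 0) / sqrt(2)
  f2 <- c(0, 0, 1, 1, 0, 0, 0, 0) / sqrt(2)
  extra <- c(0, 0, 0, 0, 1, 0, 0, 0)
  parent_raw <- 0.7 * f1 + 0.4 * f2
  parent <- parent_raw / sqrt(sum(parent_raw^2))
  res <- detect_fractionation(matrix(parent), cbind(f1, f2, extra))
  expect_true(res[[1]]$passed)
  expect_equal(sort(res[[1]]$basis_ids), c("fragment1", "fragment2"))
  nrm <- sqrt(0.7^2 + 0.4^2)
  expect_equal(unname(res[[1]]$coefficients[order(names(res[[1]]$coefficients))]),
               c(0.7, 0.4) / nrm, tolerance = 1e-8)
  expect_gte(res[[1]]$reconstruction_sp, 1 - 1e-9)
})

test_that("pure-share and unreconstructable parents are rejected", {
  basis <- diag(8)[, 1:4]
  # parent equal to one fragment: second coefficient cannot reach 0.2
  res <- detect_fractionation(matrix(basis[, 1]), basis)
  expect_false(res[[1]]$passed)
  # parent orthogonal to every fragment: SP below threshold
  ortho <- c(rep(0, 7), 1)
  res2 <- detect_fractionation(matrix(ortho), basis)
  expect_false(res2[[1]]$passed)
  expect_error(detect_fractionation(matrix(ortho), basis[, 1, drop = FALSE]),
               "at least 2")
})

test_that("merging detection mirrors fractionation on symmetric fixtures", {
  set.seed(55)
  tpl <- make_templates(5, sparsity_target = 0.7, seed = 3)
  merged_raw <- 0.6 * tpl[, 1] + 0.5 * tpl[, 2]
  merged <- merged_raw / sqrt(sum(merged_raw^2))
  fwd <- detect_merging(matrix(merged), tpl)
  expect_true(fwd[[1]]$passed)
  expect_equal(sort(fwd[[1]]$basis_ids), c("source1", "source2"))
  # the same geometry through detect_fractionation gives the same answer
  bwd <- detect_fractionation(matrix(merged), tpl)
  expect_equal(fwd[[1]]$passed, bwd[[1]]$passed)
  expect_equal(unname(fwd[[1]]$coefficients), unname(bwd[[1]]$coefficients))
  expect_equal(fwd[[1]]$reconstruction_sp, bwd[[1]]$reconstruction_sp)
})

test_that("subset search decisions equal a brute-force evaluation", {
  set.seed(91)
  tpl <- make_templates(6, sparsity_target = 0.7, seed = 12)
  parents <- tpl[, 1:2]
  basis <- cbind(tpl[, 3:6],
                 (0.5 * tpl[, 1] + 0.6 * tpl[, 3]) /
                   sqrt(sum((0.5 * tpl[, 1] + 0.6 * tpl[, 3])^2)))
  res <- detect_fractionation(parents, basis)
  for (i in seq_along(res)) {
    # independent re-evaluation of every subset
    any_pass <- FALSE
    nb <- ncol(basis)
    for (sz in 2:nb) for (ss in asplit(combn(nb, sz), 2)) {
      cf <- pracma::lsqnonneg(basis[, ss, drop = FALSE], parents[, i])$x
      rec <- basis[, ss, drop = FALSE] %*% cf
      if (sum(rec^2) == 0) next
      spv <- sum(rec * parents[, i]) / sqrt(sum(rec^2) * sum(parents[, i]^2))
      if (sum(cf >= 0.2) >= 2 && spv >= 0.75) any_pass <- TRUE
    }
    expect_equal(res[[i]]$passed, any_pass)
  }
})

test_that("planted splits are detected across noise and degrade with it", {
  detected_at <- function(sigma, seed) {
    tpl <- make_templates(6, sparsity_target = 0.6, seed = seed)
    frac <- make_group_b_by_fractionation(tpl, 1:2, coeffs = c(0.6, 0.5))
    set.seed(seed + 1)
    noisy <- pmax(frac$templates_B +
                    matrix(rnorm(length(frac$templates_B), 0, sigma),
                           nrow(frac$templates_B)), 0)
    noisy <- sweep(noisy, 2, sqrt(colSums(noisy^2)), "/")
    res <- detect_fractionation(tpl[, 1:2], noisy)
    mean(vapply(res, `[[`, logical(1), "passed"))
  }
  for (seed in c(7, 19, 63)) {
    expect_equal(detected_at(0.03, seed), 1)
  }
  # heavy corruption must not be detected more often than light
  rate_low <- mean(vapply(c(7, 19, 63), function(s) detected_at(0.02, s), numeric(1)))
  rate_high <- mean(vapply(c(7, 19, 63), function(s) detected_at(0.5, s), numeric(1)))
  expect_lte(rate_high, rate_low)
})

test_that("direction gate follows the sparseness comparison", {
  lo <- c(0.30, 0.32, 0.31, 0.29, 0.33, 0.31, 0.30, 0.32)
  hi <- lo + 0.2
  expect_equal(direction_gate(lo, hi)$directive, "fractionation")
  expect_equal(direction_gate(hi, lo)$directive, "merging")
  set.seed(2)
  same <- direction_gate(lo, lo + rnorm(8, 0, 0.001))
  expect_equal(same$directive, "both")
})
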
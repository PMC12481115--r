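# Shared fixture builders and independent oracles for the test suite.

# In-memory raw_trial over the full window.
new_trial <- function(samples, sample_rate) {
  structure(list(samples = samples, sample_rate = sample_rate,
                 muscle_labels = paste0("V", seq_len(ncol(samples))),
                 window = c(1L, nrow(samples))),
            class = "raw_trial")
}

# Write a trial matrix to a temporary delimited file.
write_trial_file <- function(text, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}

# Noiseless multi-trial subject built directly from ground truth:
# templates with near-disjoint dominant muscle groups and compact
# activation bursts, so each synergy carries distinct variance. The
# sparseness level is the block-structure level at which k disjoint
# groups fit into 16 muscles.
recovery_sparsity <- c("3" = 0.6, "4" = 0.67, "5" = 0.76,
                       "6" = 0.76, "7" = 0.86, "8" = 0.86)

make_noiseless_subject <- function(k, seed = 11) {
  tpl <- make_templates(k, sparsity_target = recovery_sparsity[as.character(k)],
                        seed = seed)
  pr <- make_activation_profiles(k, seed = seed + 1)
  sim <- simulate_subject(tpl, pr, trials = 5, noise_sd = 0,
                          subject_jitter = 0, timing_jitter = 5,
                          seed = seed + 2)
  list(templates = tpl, profiles = pr, trials = sim$trials,
       M = assemble_subject(sim$trials))
}

# Uncentered squared-correlation VAF evaluated from first principles
# (independent of the package's vaf()).
vaf_oracle <- function(M, R) {
  m <- as.numeric(M); r <- as.numeric(R)
  100 * (sum(m * r) / (sqrt(sum(m^2)) * sqrt(sum(r^2))))^2
}

# Alternating constrained least-squares NMF (independent algorithm from
# the package's multiplicative updates); columns/rows solved with
# pracma::lsqnonneg.
anls_nmf <- function(V, n, iters = 30, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(nrow(V) * n), nrow(V), n)
  for (it in seq_len(iters)) {
    H <- vapply(seq_len(ncol(V)), function(j) {
      pracma::lsqnonneg(W, V[, j])$x
    }, numeric(n))
    W <- t(vapply(seq_len(nrow(V)), function(i) {
      pracma::lsqnonneg(t(H), V[i, ])$x
    }, numeric(n)))
    if (n == 1) { H <- matrix(H, nrow = 1); W <- matrix(W, ncol = 1) }
  }
  list(W = W, H = H, error = norm(V - W %*% H, "F"))
}

# Exhaustive-enumeration oracle for the maximum-total-SP assignment:
# tries every injective mapping of the smaller side into the larger.
assignment_oracle <- function(sp) {
  nA <- nrow(sp); nB <- ncol(sp)
  if (nA <= nB) {
    perms <- all_permutations(nB, nA)
    totals <- apply(perms, 1, function(p) sum(sp[cbind(seq_len(nA), p)]))
    best <- perms[which.max(totals), ]
    list(total = max(totals), pairs = cbind(A = seq_len(nA), B = best))
  } else {
    res <- assignment_oracle(t(sp))
    list(total = res$total,
         pairs = cbind(A = res$pairs[, "B"], B = res$pairs[, "A"]))
  }
}

# All ordered arrangements of r items out of n (n small).
all_permutations <- function(n, r) {
  if (r == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1, r - 1)
    rest <- matrix(setdiff(seq_len(n), i)[rest], nrow = nrow(rest))
    out <- rbind(out, cbind(i, rest))
  }
  out
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every
# assignment of the pooled values to the two groups.
mann_whitney_enumeration <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nA * (nA + 1) / 2
  }
  u_obs <- u_of(seq_len(nA))
  combos <- combn(length(pooled), nA)
  us <- apply(combos, 2, u_of)
  mu <- nA * length(b) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu))
  list(U = u_obs, p_value = p)
}
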
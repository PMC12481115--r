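#' Generate ground-truth synergy weight templates
#'
#' Draws `k` non-negative unit vectors over `n_muscles` muscles with a
#' target sparseness level and a minimum pairwise angular separation.
#' Each template is built from a dominant muscle block (the blocks are
#' a random disjoint partition of the muscles, mirroring functional
#' muscle groupings) plus a diffuse leakage component over the
#' remaining muscles; the leakage scale is bisected per template until
#' its sparseness lands within +/- `sparsity_tol` of the target. Draws
#' violating the sparseness band or the pairwise-angle bound are
#' rejected and resampled.
#'
#' @param k Number of templates.
#' @param n_muscles Muscle count (default 16).
#' @param sparsity_target Desired sparseness level (default 0.5).
#' @param min_pairwise_angle Minimum pairwise angle in degrees (default
#'   60).
#' @param seed Integer seed.
#' @param sparsity_tol Acceptance half-width around the target
#'   (default 0.05).
#' @param max_attempts Rejection-sampling budget (default 500).
#' @return Matrix `n_muscles` x `k` of unit column vectors.
#' @export
make_templates <- function(k, n_muscles = 16, sparsity_target = 0.5,
                           min_pairwise_angle = 60, seed = 1,
                           sparsity_tol = 0.05, max_attempts = 500) {
  if (k > n_muscles) stop("k must not exceed n_muscles")
  set.seed(seed)
  max_sp <- cos(min_pairwise_angle * pi / 180)
  # dominant-support size implied by the target: a uniform vector over
  # m_eff muscles has sparseness (sqrt(n) - sqrt(m_eff)) / (sqrt(n) - 1)
  m_eff <- round((sqrt(n_muscles) - sparsity_target * (sqrt(n_muscles) - 1))^2)
  size <- max(1, min(floor(n_muscles / k), m_eff))
  # spread any leftover muscles over the blocks (one extra each) so no
  # muscle is driven by leakage alone, unless that would overshoot the
  # reachable sparseness range
  sizes <- rep(size, k)
  leftover <- n_muscles - size * k
  grow <- seq_len(min(leftover, k))
  if (size < m_eff && length(grow)) sizes[grow] <- sizes[grow] + 1L
  build_one <- function(block) {
    w <- numeric(n_muscles)
    w[block] <- runif(length(block), 0.6, 1)
    leak <- runif(n_muscles)
    leak[block] <- 0
    phi_at <- function(lam) sparseness(w + lam * leak)
    lo <- 0; hi <- 0
    if (phi_at(0) > sparsity_target + sparsity_tol / 2) {
      hi <- 0.05
      while (phi_at(hi) > sparsity_target && hi < 50) hi <- hi * 2
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (phi_at(mid) > sparsity_target) lo <- mid else hi <- mid
      }
    }
    v <- w + hi * leak
    # faint baseline keeps every channel alive (a real envelope never
    # flatlines); skipped only when an exactly one-hot vector is asked for
    if (sparsity_target < 0.95) {
      v <- v + 0.005 * runif(n_muscles)
    }
    v / sqrt(sum(v^2))
  }
  for (attempt in seq_len(max_attempts)) {
    ord <- sample.int(n_muscles)
    ends <- cumsum(sizes)
    blocks <- lapply(seq_len(k), function(i) {
      ord[(ends[i] - sizes[i] + 1):ends[i]]
    })
    out <- vapply(blocks, build_one, numeric(n_muscles))
    phi <- apply(out, 2, sparseness)
    if (any(abs(phi - sparsity_target) > sparsity_tol) &&
        !(size == 1 && sparsity_target >= 1)) next
    if (k > 1) {
      sp <- crossprod(out)
      if (max(sp[upper.tri(sp)]) > max_sp) next
    }
    dimnames(out) <- NULL
    return(out)
  }
  stop("could not generate ", k, " templates within ", max_attempts,
       " attempts; constraints may be infeasible")
}

#' Derive an older-group template set by fractionating parents
#'
#' Builds the second group's ground-truth synergies from the first
#' group's by splitting selected parent templates into two fragments:
#' the parent's dominant muscles are partitioned into two disjoint
#' supports (balanced by weight, plus a small shared leakage), and the
#' unselected templates are copied over as shared synergies. Each
#' fragment pair reconstructs its parent: the unit-normalized
#' combination `c1*f1 + c2*f2` has scalar product >= 0.9 with the
#' parent by construction.
#'
#' @param templates_A Matrix of group-A unit templates (muscles x kA).
#' @param which Indices of the parents to fractionate.
#' @param coeffs Length-2 positive mixing coefficients (both >= 0.3 so
#'   planted splits clear the 0.2 detection threshold with margin;
#'   default `c(0.7, 0.4)`).
#' @param leakage Fraction of the opposite-half weight shared by each
#'   fragment (default 0.1).
#' @return List with `templates_B` (muscles x kB, fragments appended
#'   after the shared synergies) and `fractionation_map` (list of
#'   `parent`, `fragments` (indices into B), `coeffs`).
#' @export
make_group_b_by_fractionation <- function(templates_A, which,
                                          coeffs = c(0.7, 0.4),
                                          leakage = 0.1) {
  A <- as.matrix(templates_A)
  if (any(which < 1 | which > ncol(A))) stop("parent index out of range")
  if (length(coeffs) != 2 || any(coeffs < 0.3)) {
    stop("coeffs must be two values >= 0.3")
  }
  shared <- setdiff(seq_len(ncol(A)), which)
  B <- A[, shared, drop = FALSE]
  map <- list()
  for (p in which) {
    parent <- A[, p]
    dominant <- which(parent >= 0.25 * max(parent))
    if (length(dominant) < 2) {
      stop("parent ", p, " support too small to split (",
           length(dominant), " dominant muscle)")
    }
    # alternate sorted dominant muscles between halves to balance mass
    ord <- dominant[order(parent[dominant], decreasing = TRUE)]
    half1 <- ord[seq(1, length(ord), by = 2)]
    half2 <- ord[seq(2, length(ord), by = 2)]
    f1 <- parent; f1[half2] <- leakage * parent[half2]
    f2 <- parent; f2[half1] <- leakage * parent[half1]
    minor <- setdiff(seq_along(parent), dominant)
    f1[minor] <- parent[minor] / 2
    f2[minor] <- parent[minor] / 2
    f1 <- f1 / sqrt(sum(f1^2)); f2 <- f2 / sqrt(sum(f2^2))
    recon <- coeffs[1] * f1 + coeffs[2] * f2
    spv <- scalar_product(recon, parent)
    if (spv < 0.9) {
      stop("fragment construction for parent ", p,
           " reconstructs at SP ", round(spv, 3), " < 0.9")
    }
    B <- cbind(B, f1, f2)
    map[[length(map) + 1]] <- list(parent = p,
                                   fragments = c(ncol(B) - 1L, ncol(B)),
                                   coeffs = coeffs)
  }
  dimnames(B) <- NULL
  list(templates_B = B, fractionation_map = map)
}

#' Gaussian-bump activation profiles
#'
#' Smooth non-negative temporal pattern templates: one Gaussian burst
#' per synergy with centers staggered across the movement cycle,
#' emulating the sequenced proximal-to-distal recruitment of a throw.
#'
#' @param k Number of synergies.
#' @param n_points Points per cycle (default 200).
#' @param seed Integer seed (jitters centers/widths).
#' @return List with `centers`, `widths`, `amplitudes` (length-k) and
#'   `curves` (k x `n_points`).
#' @export
make_activation_profiles <- function(k, n_points = 200, seed = 1) {
  set.seed(seed)
  centers <- seq(0.1, 0.9, length.out = k) * n_points +
    runif(k, -0.01, 0.01) * n_points
  widths <- runif(k, 0.025, 0.035) * n_points
  amplitudes <- runif(k, 0.9, 1.1)
  tt <- seq_len(n_points)
  curves <- t(vapply(seq_len(k), function(i) {
    amplitudes[i] * exp(-(tt - centers[i])^2 / (2 * widths[i]^2))
  }, numeric(n_points)))
  list(centers = centers, widths = widths, amplitudes = amplitudes,
       curves = curves)
}

profile_curves <- function(profiles, center_shift = 0, n_points = 200) {
  tt <- seq_len(n_points)
  k <- length(profiles$centers)
  shift <- rep_len(center_shift, k)
  t(vapply(seq_len(k), function(i) {
    profiles$amplitudes[i] *
      exp(-(tt - profiles$centers[i] - shift[i])^2 /
            (2 * profiles$widths[i]^2))
  }, numeric(n_points)))
}

#' Simulate one subject's envelope trials from ground truth
#'
#' Forward model `M = W %*% C + e`: the subject's weights are the group
#' templates plus non-negative-clipped Gaussian jitter (renormalized),
#' each trial's activation timings are jittered, and truncated-Gaussian
#' envelope noise (clipped at zero) is added. Trials are emitted as
#' 200-point envelope matrices (time x muscles), i.e. at the
#' post-filtering stage of the preprocessing chain.
#'
#' @param templates Ground-truth unit templates (muscles x k).
#' @param profiles Activation profiles from
#'   [make_activation_profiles()].
#' @param trials Trials to simulate (default 5).
#' @param noise_sd Envelope noise standard deviation before clipping
#'   (default 0.05).
#' @param subject_jitter Weight jitter standard deviation (default
#'   0.05).
#' @param timing_jitter Activation center jitter in points (default 5).
#' @param seed Integer seed.
#' @return List with `trials` (list of `n_points` x muscles matrices),
#'   `W_subject` (the subject's jittered unit weights).
#' @export
simulate_subject <- function(templates, profiles, trials = 5,
                             noise_sd = 0.05, subject_jitter = 0.05,
                             timing_jitter = 5, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  W <- as.matrix(templates)
  k <- ncol(W)
  n_points <- ncol(profiles$curves)
  set.seed(seed)
  Ws <- pmax(W + matrix(rnorm(length(W), 0, subject_jitter), nrow(W)), 0)
  Ws <- unit_cols(Ws, "subject weight")
  out <- vector("list", trials)
  for (tr in seq_len(trials)) {
    shift <- if (timing_jitter > 0) runif(k, -timing_jitter, timing_jitter) else 0
    C <- profile_curves(profiles, center_shift = shift, n_points = n_points)
    M <- Ws %*% C
    if (noise_sd > 0) {
      M <- M + matrix(rnorm(length(M), 0, noise_sd), nrow(M))
    }
    out[[tr]] <- t(pmax(M, 0))
  }
  list(trials = out, W_subject = Ws)
}

#' Simulate a two-group developmental EMG dataset
#'
#' Builds a complete synthetic study with known modular ground truth:
#' group A (younger) subjects draw from `k_A` templates; group B
#' (older) subjects draw from the same templates with `n_fractionate`
#' of them split into sparser fragment pairs, so group B has
#' `k_A + n_fractionate` synergies and a strictly higher ground-truth
#' sparseness. Defaults mirror a small developmental cohort: 13 vs 8
#' subjects, 16 muscles, 5 trials of 200 points each.
#'
#' @param subjects_A,subjects_B Group sizes (defaults 13 and 8).
#' @param k_A Group-A synergy count (default 6).
#' @param n_fractionate How many parents to split (default 2).
#' @param trials Trials per subject (default 5).
#' @param noise_sd Envelope noise sd (default 0.05).
#' @param subject_jitter Weight jitter sd (default 0.05).
#' @param sparsity_target Template sparseness level (default 0.5).
#' @param frac_coeffs Mixing coefficients for planted splits (default
#'   `c(0.7, 0.4)`).
#' @param seed Master seed; all subject/trial randomness derives from
#'   it.
#' @param n_muscles Muscle count (default 16).
#' @return A `synthetic_dataset`: list with `truth` (templates_A/B,
#'   fractionation_map, profiles_A/B, parameters), `subjects`
#'   (named list of per-subject trial lists), `groups` (named group
#'   vector), `muscle_labels`.
#' @export
simulate_dataset <- function(subjects_A = 13, subjects_B = 8, k_A = 6,
                             n_fractionate = 2, trials = 5,
                             noise_sd = 0.05, subject_jitter = 0.05,
                             sparsity_target = 0.5,
                             frac_coeffs = c(0.7, 0.4), seed = 1,
                             n_muscles = 16) {
  templates_A <- make_templates(k_A, n_muscles = n_muscles,
                                sparsity_target = sparsity_target,
                                seed = sub_seed(seed, 1))
  frac <- if (n_fractionate > 0) {
    make_group_b_by_fractionation(templates_A, seq_len(n_fractionate),
                                  coeffs = frac_coeffs)
  } else {
    list(templates_B = templates_A, fractionation_map = list())
  }
  k_B <- ncol(frac$templates_B)
  profiles_A <- make_activation_profiles(k_A, seed = sub_seed(seed, 2))
  profiles_B <- make_activation_profiles(k_B, seed = sub_seed(seed, 3))
  labels <- if (n_muscles == 16) default_muscle_labels()
            else paste0("M", seq_len(n_muscles))
  subjects <- list(); groups <- character(0)
  for (s in seq_len(subjects_A)) {
    id <- sprintf("A%02d", s)
    sim <- simulate_subject(templates_A, profiles_A, trials = trials,
                            noise_sd = noise_sd,
                            subject_jitter = subject_jitter,
                            seed = sub_seed(seed, 100 + s))
    sim$trials <- lapply(sim$trials, function(m) {
      colnames(m) <- labels; m
    })
    subjects[[id]] <- sim
    groups[id] <- "A"
  }
  for (s in seq_len(subjects_B)) {
    id <- sprintf("B%02d", s)
    sim <- simulate_subject(frac$templates_B, profiles_B, trials = trials,
                            noise_sd = noise_sd,
                            subject_jitter = subject_jitter,
                            seed = sub_seed(seed, 200 + s))
    sim$trials <- lapply(sim$trials, function(m) {
      colnames(m) <- labels; m
    })
    subjects[[id]] <- sim
    groups[id] <- "B"
  }
  structure(
    list(truth = list(templates_A = templates_A,
                      templates_B = frac$templates_B,
                      fractionation_map = frac$fractionation_map,
                      profiles_A = profiles_A, profiles_B = profiles_B,
                      parameters = list(subjects_A = subjects_A,
                                        subjects_B = subjects_B,
                                        k_A = k_A, k_B = k_B,
                                        n_fractionate = n_fractionate,
                                        trials = trials,
                                        noise_sd = noise_sd,
                                        subject_jitter = subject_jitter,
                                        seed = seed)),
         subjects = subjects, groups = groups, muscle_labels = labels),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$truth$parameters
  cat(sprintf(paste0("<synthetic_dataset> %d + %d subjects, k_A = %d, ",
                     "k_B = %d (%d planted splits), %d trials, noise sd %g\n"),
              p$subjects_A, p$subjects_B, p$k_A, p$k_B,
              p$n_fractionate, p$trials, p$noise_sd))
  invisible(x)
}

#' Write a synthetic dataset to the on-disk trial layout
#'
#' Emits the file layout the preprocessing module consumes: one CSV per
#' trial (header row of muscle labels, rows = time points), a manifest
#' JSON mapping subjects to trial files, group membership and sample
#' rate, and a ground-truth JSON for scoring recovery.
#'
#' @param dataset A `synthetic_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  manifest <- list(sample_rate = 2000, subjects = list())
  for (id in names(dataset$subjects)) {
    files <- character(0)
    for (tr in seq_along(dataset$subjects[[id]]$trials)) {
      fn <- sprintf("%s_trial%02d.csv", id, tr)
      m <- dataset$subjects[[id]]$trials[[tr]]
      write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                  file.path(out_dir, fn), sep = ",", quote = FALSE,
                  row.names = FALSE, col.names = colnames(m))
      files <- c(files, fn)
    }
    manifest$subjects[[id]] <- list(group = dataset$groups[[id]],
                                    trials = files)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  truth <- dataset$truth
  truth$profiles_A$curves <- NULL
  truth$profiles_B$curves <- NULL
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a written dataset back as per-subject trial lists
#'
#' @param manifest_path Path to the manifest JSON written by
#'   [write_dataset()].
#' @return List with `subjects` (named list of trial-matrix lists),
#'   `groups`, `sample_rate`.
#' @export
read_dataset <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  base <- dirname(manifest_path)
  subjects <- list(); groups <- character(0)
  for (id in names(man$subjects)) {
    entry <- man$subjects[[id]]
    subjects[[id]] <- lapply(entry$trials, function(fn) {
      tr <- read_trial(file.path(base, fn), sample_rate = man$sample_rate)
      m <- tr$samples
      colnames(m) <- tr$muscle_labels
      m
    })
    groups[id] <- entry$group
  }
  list(subjects = subjects, groups = groups, sample_rate = man$sample_rate)
}
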
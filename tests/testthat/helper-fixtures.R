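# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Default PBS ladder dataset (9 levels x 15 replicates).
pbs_dataset <- function(seed = 101) {
  memo(paste0("pbs_", seed), generate_dataset(seed = seed))
}

# Cross-validated GPR on the default PBS dataset (the expensive fixture).
pbs_gpr_cv <- function(seed = 101) {
  memo(paste0("gprcv_", seed),
       cross_validate(pbs_dataset(seed), "gpr", seed = seed))
}

# Noise-free assay parameters: deterministic RGB per level.
noiseless_params <- function(matrix = "PBS") {
  assay_params(matrix, blank_mean_conc = 0, blank_sd_conc = 0)
}

# Fundamental-mode water cavity at the default 700 kHz drive.
fundamental_field <- function(pressure_amplitude = 3e5) {
  m <- water_medium()
  standing_wave_field(pressure_amplitude,
                      cavity_length = m$sound_speed / 700e3 / 2,
                      sound_speed = m$sound_speed)
}

# Aggregate-scale particle that migrates on tens-of-seconds timescales.
cluster_particle <- function(radius = 2e-6) {
  gold_nanoparticle(effective_cluster_radius = radius)
}

# Independent O(n^2) brute-force KNN oracle implementing the documented
# vote and tie-break rules with plain loops (kept separate from the package
# implementation on purpose).
knn_oracle <- function(train_rgb, train_labels, k, q) {
  n <- nrow(train_rgb)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- sqrt(sum((train_rgb[i, ] - q)^2))
  nn <- order(d)[1:k]
  labs <- as.character(train_labels[nn])
  classes <- unique(labs)
  counts <- vapply(classes, function(cl) sum(labs == cl), numeric(1))
  tied <- classes[counts == max(counts)]
  if (length(tied) > 1) {
    sums <- vapply(tied, function(cl) sum(d[nn][labs == cl]), numeric(1))
    tied <- tied[sums == min(sums)]
    if (length(tied) > 1) {
      tied <- if (labs[1] %in% tied) labs[1] else sort(tied)[1]
    }
  }
  tied[1]
}

# Independent dense-linear-algebra log marginal likelihood oracle.
gpr_lml_oracle <- function(X, y, sf2, ell, sn2, jitter = 1e-10) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  yc <- y - mean(y)
  n <- length(y)
  K <- sf2 * exp(-as.matrix(dist(Xs))^2 / (2 * ell^2)) +
    (sn2 + jitter) * diag(n)
  -0.5 * drop(t(yc) %*% solve(K, yc)) -
    0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
    n / 2 * log(2 * pi)
}
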
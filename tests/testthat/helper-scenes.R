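# shared fixtures, built in code

# a small fast wedge scene for unit tests (96 x 96, radius 30, ramp 10)
tiny_spec <- function(seed = 1, ...) {
  args <- list(shape = c(96, 96),
               cells = list(list(center = c(48, 48), radius = 30)),
               ramp_width = 10, s2_plateau = 2000, a0 = 0.7,
               B1 = 120, B2 = 100, noise_sigma1 = 8, noise_sigma2 = 8,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scene_spec, args)
}

tiny_box <- function() bg_box(4, 4, 12, 12)

# disc mask helper
disc_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  m <- matrix(FALSE, n, n)
  (row(m) - center[1])^2 + (col(m) - center[2])^2 <= r^2
}

# random multi-disc blob mask for property tests (never touches border)
random_blob_mask <- function(n = 48, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  for (i in 1:3) {
    r <- sample(4:8, 1)
    ctr <- sample(seq(r + 2, n - r - 1), 2, replace = TRUE)
    m <- m | disc_mask(n, r, ctr)
  }
  m
}

# O(N^2) brute-force Euclidean distance to nearest background pixel
brute_force_distance <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}
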
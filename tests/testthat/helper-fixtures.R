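# Shared fixtures: compact slides keep unit tests fast; acceptance tests
# build their own full-size inputs.

small_params <- function(n_cells = 40, seed = 11, ...) {
  tissue_sim_params(image_height_px = 192, image_width_px = 192,
                    n_cells = n_cells, seed = seed, ...)
}

small_slide <- function(...) simulate_slide(small_params(...))

# A label map holding a single filled disk, for constructed-fixture tests.
disk_label_map <- function(h = 64, w = 64, center = c(32, 32), radius = 10) {
  lab <- matrix(0L, h, w)
  for (r in 1:h) for (cl in 1:w)
    if ((r - 1 - center[1])^2 + (cl - 1 - center[2])^2 <= radius^2)
      lab[r, cl] <- 1L
  ihcquant:::new_label_map(lab)
}

# Independent direct-formula evaluation of linearly weighted kappa via
# explicit double loops over the k x k confusion table; deliberately coded
# apart from the package implementation.
kappa_oracle <- function(a, b, k = 4) {
  n <- length(a)
  po <- 0; pe <- 0
  for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
    w <- 1 - abs(i - j) / (k - 1)
    pij <- sum(a == i & b == j) / n
    pi_ <- sum(a == i) / n
    p_j <- sum(b == j) / n
    po <- po + w * pij
    pe <- pe + w * pi_ * p_j
  }
  (po - pe) / (1 - pe)
}
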
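# Shared fixtures: everything is generated in code, seeded.

# Random unit quaternions, n x 4.
random_unit_quats <- function(n, seed = 1) {
  set.seed(seed)
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# Independent rotation-matrix oracle for the passive q* P q convention,
# built from the axis-angle (Rodrigues) form rather than quaternion algebra.
rotation_oracle <- function(q) {
  q <- q / sqrt(sum(q^2))
  theta <- 2 * acos(pmin(pmax(q[1], -1), 1))
  s <- sqrt(max(1 - q[1]^2, 0))
  axis <- if (s < 1e-12) c(1, 0, 0) else q[2:4] / s
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R_active <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
  t(R_active)  # passive sense
}

# A uniform 100 Hz quaternion stream rotating about `axis` by theta(t).
make_rotation_stream <- function(theta, axis = c(0, 0, 1), site = "hand") {
  q <- cbind(cos(theta / 2), outer(sin(theta / 2), axis))
  quat_stream((seq_along(theta) - 1) / 100, q, site = site)
}

# Toy feature dataset: class counts given as c(normal=, PD=, ET=) (zeros
# allowed); sequences are small seeded random matrices. Subjects contribute
# up to two recordings.
make_toy_dataset <- function(counts, frames = 12, feats = 6, seed = 1,
                             two_frac = 0.4) {
  set.seed(seed)
  meta <- NULL; seqs <- list()
  for (cl in names(counts)) {
    n <- counts[[cl]]
    if (n == 0) next
    made <- 0; si <- 0
    while (made < n) {
      si <- si + 1
      nr <- if (stats::runif(1) < two_frac) 2 else 1
      nr <- min(nr, n - made)
      for (r in seq_len(nr)) {
        made <- made + 1
        id <- sprintf("%s_r%02d", cl, made)
        m <- matrix(stats::rnorm(frames * feats), frames, feats)
        attr(m, "label") <- class_code(cl)
        seqs[[id]] <- m
        meta <- rbind(meta, data.frame(id = id,
                                       subject = sprintf("%s_s%02d", cl, si),
                                       label = class_code(cl),
                                       augmented = FALSE, source = id,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  feature_dataset(meta, seqs)
}

# The two worked-example confusion matrices used across the metric tests:
# two-class PD/ET test outcome and the reconstructed three-class outcome.
two_class_cm <- function() {
  confusion(c(rep("PD", 10), rep("ET", 10)),
            c(rep("PD", 10), "PD", rep("ET", 9)),
            classes = c("PD", "ET"))
}

three_class_cm <- function() {
  truth <- c(rep("normal", 10), rep("PD", 10), rep("ET", 10))
  pred <- c(rep("normal", 10), "normal", rep("PD", 9), "normal", rep("ET", 9))
  confusion(truth, pred, classes = c("normal", "PD", "ET"))
}
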
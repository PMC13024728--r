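# Independent oracles, deliberately written scalar / brute-force so they
# share no code path with the implementations they check.

# per-pixel polar sampler (same bilinear interpolation, scalar loops)
brute_unwrap <- function(img, g, hemisphere) {
  U <- matrix(NA_real_, g$H, g$W)
  for (i in 0:(g$H - 1)) {
    for (j in 0:(g$W - 1)) {
      r <- i / (g$H - 1) * g$Rmax
      th <- j / (g$W - 1) * pi
      x <- g$cx + r * cos(th)
      y <- g$cy + (if (hemisphere == "lower") 1 else -1) * r * sin(th)
      U[i + 1, j + 1] <- bilinear_sample(img, x, y)
    }
  }
  U
}

# Mann-Whitney pair counting with half credit for ties
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# brute-force min/max bounding box over points
brute_box <- function(px, py, w, h, m) {
  c(xmin = max(0, min(px) - m), xmax = min(w, max(px) + m),
    ymin = max(0, min(py) - m), ymax = min(h, max(py) + m))
}

# a small constant-radius eye phantom used by several tests
circular_phantom <- function(..., beta = 0) {
  make_eye_phantom(iris_radius = 20, eyelid_radii = c(50, 50, 50),
                   config = smue_config(beta = beta), ...)
}
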
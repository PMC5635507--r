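# shared fixtures and independent oracles, built in code

empty_truth_df <- function() {
  data.frame(net_id = character(), side = character(),
             cx_cm = numeric(), cy_cm = numeric(),
             a_cm = numeric(), b_cm = numeric(),
             orientation_deg = numeric(), area_cm2 = numeric(),
             stringsAsFactors = FALSE)
}

truth_df <- function(cx, cy, a, b, side = "long1", net_id = "net0001",
                     orientation = 0) {
  data.frame(net_id = net_id, side = side, cx_cm = cx, cy_cm = cy,
             a_cm = a, b_cm = b, orientation_deg = orientation,
             area_cm2 = pi * a * b, stringsAsFactors = FALSE)
}

# nearest-centroid assignment of detected holes to planted holes
match_to_truth <- function(holes, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    which.min((holes$cx_cm - truth$cx_cm[i])^2 +
              (holes$cy_cm - truth$cy_cm[i])^2), integer(1))
}

# binary mask of a disk/ellipse from the pixel-center-in-shape rule
ellipse_mask <- function(nr, nc, cr, cc, a_px, b_px) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((c - cc) / a_px)^2 + ((r - cr) / b_px)^2 <= 1
}

# brute-force exact Wilcoxon signed-rank p over all 2^n sign assignments
wilcoxon_enum_oracle <- function(x, y,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge, less = p_le)
}

# literal, unvectorized evaluation of the Gi* formula
gi_star_oracle <- function(x, radius_cm, cell_cm) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- matrix(NA_real_, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    num <- 0; wi <- 0
    for (i2 in seq_len(nrow(x))) for (j2 in seq_len(ncol(x))) {
      if (((i - i2)^2 + (j - j2)^2) * cell_cm^2 <= radius_cm^2) {
        num <- num + x[i2, j2]
        wi <- wi + 1
      }
    }
    z[i, j] <- (num - xbar * wi) / (s * sqrt((n * wi - wi^2) / (n - 1)))
  }
  z
}
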
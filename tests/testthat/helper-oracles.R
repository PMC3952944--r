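# Independent oracles and small fixture builders shared across tests.

# Brute-force lRMSD: centroid alignment plus Euler-angle rotation search
# (coarse grid refined by Nelder-Mead), deliberately independent of the
# package's closed-form Kabsch route.
brute_lrmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((Bc %*% t(rotmat(ang)) - Ac)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a1 in grid) for (a2 in grid[grid <= pi]) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# direct four-point torsion via the textbook atan2 expression, written
# independently of torsion_angle()
torsion_reference <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, x) * 180 / pi
}

rand_coords <- function(m, sd = 2) matrix(stats::rnorm(3 * m, sd = sd), m, 3)

rand_conformation <- function(n) {
  conformation(rep("A", n), stats::runif(n, -180, 180),
               stats::runif(n, -180, 180))
}

random_rigid_motion <- function(X) {
  ang <- stats::runif(3, 0, 2 * pi)
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
    matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  sweep(X %*% t(R), 2, stats::rnorm(3, sd = 5), `+`)
}

# measured bond lengths and angles of a backbone coordinate matrix
measure_geometry <- function(xyz) {
  n <- nrow(xyz) / 4
  at <- function(a, i) xyz[(i - 1) * 4 + match(a, c("N", "CA", "C", "O")), ]
  blen <- function(p, q) sqrt(sum((p - q)^2))
  bang <- function(p, q, r) {
    u <- p - q; v <- r - q
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }
  out <- list(n_ca = c(), ca_c = c(), c_n = c(), c_o = c(),
              n_ca_c = c(), ca_c_n = c(), c_n_ca = c(), ca_c_o = c())
  for (i in seq_len(n)) {
    out$n_ca <- c(out$n_ca, blen(at("N", i), at("CA", i)))
    out$ca_c <- c(out$ca_c, blen(at("CA", i), at("C", i)))
    out$c_o <- c(out$c_o, blen(at("C", i), at("O", i)))
    out$n_ca_c <- c(out$n_ca_c, bang(at("N", i), at("CA", i), at("C", i)))
    out$ca_c_o <- c(out$ca_c_o, bang(at("CA", i), at("C", i), at("O", i)))
    if (i < n) {
      out$c_n <- c(out$c_n, blen(at("C", i), at("N", i + 1)))
      out$ca_c_n <- c(out$ca_c_n, bang(at("CA", i), at("C", i), at("N", i + 1)))
      out$c_n_ca <- c(out$c_n_ca, bang(at("C", i), at("N", i + 1),
                                       at("CA", i + 1)))
    }
  }
  out
}

# chi-square goodness-of-fit p-value for observed counts vs probabilities
chisq_p <- function(counts, probs) {
  stats::chisq.test(counts, p = probs / sum(probs))$p.value
}
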
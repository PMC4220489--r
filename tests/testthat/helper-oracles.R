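# Independent oracles used by the tests. These deliberately share no code
# with the package implementations they check.

# bisection solution of the 1:1 competitor mass balance, solved for the
# free ligand F = L - C so the bracketing variable is the answer itself:
# g(F) = F * (I - L + F) - K * (L - F), increasing on [0, L], root at F*
free_ligand_bisection <- function(L_tot, I_tot, K_I) {
  g <- function(F) F * (I_tot - L_tot + F) - K_I * (L_tot - F)
  lo <- 0
  hi <- L_tot
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# latitude-band quadrature ASA: an independent numeric-grid estimate of
# solvent accessibility (different point construction from the package's
# Fibonacci lattice)
grid_asa <- function(atoms, radii = c(C = 1.70, N = 1.55, O = 1.52,
                                      S = 1.80, H = 1.20),
                     probe = 1.4, n_theta = 40, n_phi = 80) {
  r <- unname(radii[atoms$element]) + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  g <- expand.grid(theta = theta, phi = phi)
  dirs <- cbind(sin(g$theta) * cos(g$phi), sin(g$theta) * sin(g$phi),
                cos(g$theta))
  w <- sin(g$theta) * (pi / n_theta) * (2 * pi / n_phi) # solid-angle weights
  vapply(seq_len(nrow(xyz)), function(i) {
    p <- sweep(dirs * r[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, nrow(p))
    for (j in setdiff(seq_len(nrow(xyz)), i)) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > r[j]^2
    }
    sum(w[exposed]) * r[i]^2
  }, numeric(1))
}

# random rigid motion applied to the x/y/z columns of a tibble
apply_rigid_motion <- function(tbl, seed = 1) {
  set.seed(seed)
  ang <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  rot <- rx %*% ry %*% rz
  shift <- stats::runif(3, -20, 20)
  m <- as.matrix(tbl[, c("x", "y", "z")]) %*% t(rot)
  tbl$x <- m[, 1] + shift[1]
  tbl$y <- m[, 2] + shift[2]
  tbl$z <- m[, 3] + shift[3]
  tbl
}
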
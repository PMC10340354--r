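# Small fixtures shared across the suite; everything is generated in code.

tiny_probe <- function(K = 4L) probe_spec(K = K)

# rotate + translate a shape's centers (alpha updated consistently)
rigid_move_shape <- function(shape, theta = 0, shift = c(0, 0)) {
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  P <- cbind(shape$x, shape$z) %*% t(Rm)
  flexbeam:::new_array_shape(P[, 1] + shift[1], P[, 2] + shift[2],
                             shape$alpha + theta,
                             pitch = attr(shape, "pitch"))
}

# independent geometric circle fit (Gauss-Newton on center+radius) used as
# an oracle against the algebraic Pratt fit
geo_circle_fit <- function(x, z) {
  obj <- function(par) {
    r <- sqrt((x - par[1])^2 + (z - par[2])^2)
    sum((r - mean(r))^2)
  }
  ctr <- optim(c(mean(x), mean(z)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))$par
  list(center = ctr, r = mean(sqrt((x - ctr[1])^2 + (z - ctr[2])^2)))
}

# a small point-target RF set on a known arc, reused by several tests
point_rf <- function(K = 16L, R = 70, z_t = 25, seed = 2L) {
  sp <- probe_spec(K = K)
  sh <- arc_shape(R, sp)
  rf <- simulate_rf(sh, phantom_spec(
    point_targets = data.frame(x = 0, z = z_t, amplitude = 1)),
    sp, seed = seed)
  list(spec = sp, shape = sh, rf = rf)
}
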
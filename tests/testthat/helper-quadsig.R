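# shared fixtures built in code

# a flat-ratio table: R(lambda) = 1 everywhere, eps260 as given (missing
# doublets default to 0)
toy_flat_table <- function(eps260 = c(), grid = c(220, 260, 350)) {
  eps <- stats::setNames(rep(0, 24), nn_doublets())
  eps[names(eps260)] <- eps260
  ratios <- matrix(1, 24, length(grid),
                   dimnames = list(nn_doublets(), NULL))
  new_nn_table(eps, grid, ratios)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

flat_spectrum <- function(values, wl = 220:350, unit = "molar_extinction") {
  spectrum_tbl(wl, values, unit = unit)
}

# independent dihedral oracle: angle between plane normals with the sign of
# the triple product (a different construction than the implementation's
# atan2-on-b2 form)
dihedral_oracle <- function(a, b, c, d) {
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b - a, c - b)
  n2 <- cross(c - b, d - c)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cross(n1, n2) * (c - b)) < 0) ang <- -ang
  ang
}
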
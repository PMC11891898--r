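# shared test helpers: all fixtures are generated in code at test time

# fast low-resolution SESA parameters for tests that only need plumbing
quick_sesa <- function(n = 150) sesa_params(probe_radius = 0.15, n_points = n)

# write a minimal hand-rolled PDB file and return its path
write_raw_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, resid, x, y, z,
                          element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resid, x, y, z, element)
}

# independent union-of-spheres surface area oracle: fraction of points on
# each sphere lying outside all other spheres (no probe involved)
union_sphere_area <- function(x, r, n = 2000) {
  dirs <- ride:::fibonacci_sphere(n)
  total <- 0
  for (i in seq_len(nrow(x))) {
    pts <- dirs * r[i]
    pts[, 1] <- pts[, 1] + x[i, 1]
    pts[, 2] <- pts[, 2] + x[i, 2]
    pts[, 3] <- pts[, 3] + x[i, 3]
    outside <- rep(TRUE, n)
    for (j in seq_len(nrow(x))) {
      if (j == i) next
      d2 <- (pts[, 1] - x[j, 1])^2 + (pts[, 2] - x[j, 2])^2 +
        (pts[, 3] - x[j, 3])^2
      outside <- outside & (d2 >= r[j]^2)
    }
    total <- total + mean(outside) * 4 * pi * r[i]^2
  }
  total
}

# rigid rotation of a structure about an arbitrary axis
rotate_structure <- function(s, angle = 0.7, axis = c(1, 2, 2), shift = c(1, -2, 0.5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}
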
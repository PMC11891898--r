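# sesa: numerical solvent-excluded surface area (SESA) with a rolling-probe
# surface definition.
#
# The SES is the inner boundary of the union of all probe spheres whose
# centers do not overlap the molecule. It decomposes into contact patches
# (on the van der Waals spheres, where the probe touches an atom) and
# reentrant patches (on probe spheres wedged between atoms). Both are
# estimated here by deterministic Fibonacci-lattice sampling:
#
#   * contact: accessible probe-center directions on each atom's
#     probe-expanded sphere, mapped radially back to the vdW sphere;
#   * reentrant: points sampled on every accessible probe sphere that lie on
#     the boundary of the discrete probe-ball union, classified as facing the
#     molecule, excluding points that duplicate a contact patch.
#
# The scheme is deterministic (no RNG), converges to the SES definition as
# the sampling density grows, and self-convergence under resolution doubling
# is the correctness criterion.

# Quasi-uniform points on the unit sphere (golden-spiral lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Assign van der Waals radii to a structure
#'
#' Fills the `radius` column of the atom table from a radius set, with
#' per-atom-name overrides taking precedence over per-element values.
#' Idempotent.
#'
#' @param s A `ride_structure`.
#' @param radius_set A `ride_radius_set`, default [default_radius_set()].
#' @return The structure with all atom radii set (nm).
#' @export
assign_radii <- function(s, radius_set = default_radius_set()) {
  stopifnot(inherits(s, "ride_structure"))
  a <- s$atoms
  r <- rep(NA_real_, nrow(a))
  if (length(radius_set$by_atom_name) > 0) {
    hit <- match(toupper(a$name), names(radius_set$by_atom_name))
    r[!is.na(hit)] <- radius_set$by_atom_name[hit[!is.na(hit)]]
  }
  need <- is.na(r)
  hit <- match(toupper(a$element[need]), names(radius_set$by_element))
  r[need] <- unname(radius_set$by_element[hit])
  if (any(is.na(r))) {
    bad <- unique(a$element[is.na(r)])
    stop("radius set '", radius_set$name,
         "' cannot resolve element(s): ", paste(bad, collapse = ", "))
  }
  s$atoms$radius <- r
  s$radius_set_name <- radius_set$name
  s
}

#' SESA computation parameters
#'
#' @param probe_radius Probe (solvent) sphere radius in nm; default 0.15, the
#'   value used throughout the hydrodiffusivity-scale derivation.
#' @param n_points Sampling resolution: number of lattice points per
#'   probe-expanded atom sphere. Probe spheres are sampled with `n_points / 4`
#'   points (minimum 80). Doubling `n_points` refines both families.
#' @param seed Kept for interface stability; the Fibonacci sampling is fully
#'   deterministic so no randomness is consumed.
#' @return A `ride_sesa_params` list.
#' @export
sesa_params <- function(probe_radius = 0.15, n_points = 400, seed = 1L) {
  stopifnot(probe_radius > 0, n_points >= 16)
  p <- list(probe_radius = probe_radius, n_points = as.integer(n_points),
            seed = as.integer(seed))
  class(p) <- "ride_sesa_params"
  p
}

#' Compute per-atom solvent-excluded surface area
#'
#' Numerical SES area of a structure with assigned radii, for the probe
#' radius and resolution in `params`. Contact patches are attributed to
#' their atom; reentrant patches to the nearest contributing atom.
#' Deterministic for fixed parameters.
#'
#' @param s A `ride_structure` with radii assigned (see [assign_radii()]).
#' @param params A `ride_sesa_params`, default [sesa_params()].
#' @return A `ride_sesa_result`: list with `per_atom` (nm^2, one entry per
#'   atom in structure order), `total` (nm^2), `params`.
#' @export
compute_sesa <- function(s, params = sesa_params()) {
  stopifnot(inherits(s, "ride_structure"), inherits(params, "ride_sesa_params"))
  x <- as.matrix(s$atoms[, c("x", "y", "z")])
  r <- s$atoms$radius
  n <- nrow(x)
  if (n < 1) stop("structure has no atoms")
  if (any(is.na(r)) || any(r <= 0)) {
    stop("atom radii not assigned; call assign_radii() first")
  }
  rp <- params$probe_radius
  npt <- params$n_points

  # coincident identical atoms make the surface ill-defined
  if (n > 1) {
    dmat <- as.matrix(stats::dist(x))
    diag(dmat) <- Inf
    hit <- which(dmat < 1e-9, arr.ind = TRUE)
    if (nrow(hit) > 0 &&
        any(abs(r[hit[, 1]] - r[hit[, 2]]) < 1e-12)) {
      stop("coincident atoms with identical radii at zero separation")
    }
  }

  dirs <- fibonacci_sphere(npt)
  expand <- r + rp
  per_atom <- numeric(n)

  # ---- contact patches + accessible probe centers -----------------------
  centers <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- x[rep(i, npt), , drop = FALSE] + dirs * expand[i]
    acc <- rep(TRUE, npt)
    for (j in seq_len(n)) {
      if (j == i) next
      # prune atoms that cannot block any probe position of atom i
      if (sum((x[i, ] - x[j, ])^2) >= (expand[i] + expand[j])^2) next
      dx <- ci[, 1] - x[j, 1]; dy <- ci[, 2] - x[j, 2]; dz <- ci[, 3] - x[j, 3]
      acc <- acc & (dx * dx + dy * dy + dz * dz >= (expand[j] - 1e-12)^2)
    }
    per_atom[i] <- mean(acc) * 4 * pi * r[i]^2
    centers[[i]] <- ci[acc, , drop = FALSE]
  }
  cen <- do.call(rbind, centers)
  M <- nrow(cen)

  # ---- reentrant patches ------------------------------------------------
  # resolvable only when the probe-center spacing is fine relative to the
  # probe radius; below that the reentrant contribution (which vanishes like
  # the probe radius) is below sampling resolution and is omitted
  spacing <- sqrt(4 * pi * max(expand)^2 / npt)
  if (M > 0 && n > 1 && spacing < 0.75 * rp) {
    k2 <- max(80L, as.integer(round(npt / 4)))
    pdirs <- fibonacci_sphere(k2)
    w_pt <- 4 * pi * rp^2 / k2   # area carried by one probe-sphere point

    # spatial binning of probe centers; only centers within 2*rp of a point
    # can cover it
    cell <- 2 * rp
    key <- function(p) {
      floor(p[, 1] / cell) * 73856093 +
        floor(p[, 2] / cell) * 19349663 +
        floor(p[, 3] / cell) * 83492791
    }
    ckey <- key(cen)
    cell_index <- split(seq_len(M), ckey)
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    neighbor_keys <- function(p1) {
      gx <- floor(p1[1] / cell); gy <- floor(p1[2] / cell); gz <- floor(p1[3] / cell)
      (gx + offs[, 1]) * 73856093 + (gy + offs[, 2]) * 19349663 +
        (gz + offs[, 3]) * 83492791
    }

    scallop <- (pi * (max(expand))^2 / npt) / (2 * rp)  # lattice sagitta scale
    tol_c <- min(0.5 * rp, 8 * scallop)

    reentrant_owner <- integer(0)
    reentrant_count <- 0L
    owner_acc <- numeric(n)

    for (m in seq_len(M)) {
      q <- pdirs * rp
      q[, 1] <- q[, 1] + cen[m, 1]
      q[, 2] <- q[, 2] + cen[m, 2]
      q[, 3] <- q[, 3] + cen[m, 3]

      # inner classification: point faces the molecule if it lies inside some
      # probe-expanded atom sphere
      inner <- rep(FALSE, k2)
      for (j in seq_len(n)) {
        if (sum((cen[m, ] - x[j, ])^2) >= (rp + expand[j])^2) next
        dj2 <- (q[, 1] - x[j, 1])^2 + (q[, 2] - x[j, 2])^2 + (q[, 3] - x[j, 3])^2
        inner <- inner | (dj2 < expand[j]^2)
      }
      if (!any(inner)) next
      qi <- q[inner, , drop = FALSE]

      # boundary-of-union test against nearby probe centers
      nbk <- unique(neighbor_keys(cen[m, ]))
      nb <- unlist(cell_index[as.character(nbk)], use.names = FALSE)
      nb <- nb[nb != m]
      if (length(nb) > 0) {
        cn <- cen[nb, , drop = FALSE]
        d2 <- outer(rowSums(qi^2), rowSums(cn^2), "+") - 2 * tcrossprod(qi, cn)
        surv <- apply(d2 > (rp - 1e-9)^2, 1, all)
      } else {
        surv <- rep(TRUE, nrow(qi))
      }
      if (!any(surv)) next
      qs <- qi[surv, , drop = FALSE]

      # nearest atom (by gap to its vdW sphere) owns the point; drop points
      # that coincide with a contact patch (radial probe position accessible)
      for (t in seq_len(nrow(qs))) {
        p1 <- qs[t, ]
        gaps <- sqrt((p1[1] - x[, 1])^2 + (p1[2] - x[, 2])^2 +
                       (p1[3] - x[, 3])^2) - r
        jmin <- which.min(gaps)
        if (gaps[jmin] < tol_c) {
          u <- p1 - x[jmin, ]
          u <- u / sqrt(sum(u^2))
          pc <- x[jmin, ] + u * expand[jmin]
          dpc <- sqrt((pc[1] - x[, 1])^2 + (pc[2] - x[, 2])^2 +
                        (pc[3] - x[, 3])^2)
          if (all(dpc >= expand - 1e-9)) next  # duplicates contact area
        }
        owner_acc[jmin] <- owner_acc[jmin] + w_pt
        reentrant_count <- reentrant_count + 1L
      }
    }
    per_atom <- per_atom + owner_acc
  }

  res <- list(per_atom = per_atom, total = sum(per_atom), params = params)
  class(res) <- "ride_sesa_result"
  res
}

#' @export
print.ride_sesa_result <- function(x, ...) {
  cat(sprintf(
    "<ride_sesa_result> %d atoms, total SESA %.4f nm^2 (probe %.3f nm, n_points %d)\n",
    length(x$per_atom), x$total, x$params$probe_radius, x$params$n_points))
  invisible(x)
}

#' Difference of two SESA totals
#'
#' Subtracts a reference total area from a capped-solute total area, the
#' quantity entering the hydrodiffusivity-coefficient denominator. Both
#' results must have been computed with identical parameters.
#'
#' @param capped,reference `ride_sesa_result` objects.
#' @return Area difference in nm^2 (capped minus reference).
#' @export
sesa_difference <- function(capped, reference) {
  stopifnot(inherits(capped, "ride_sesa_result"),
            inherits(reference, "ride_sesa_result"))
  if (!isTRUE(all.equal(capped$params$probe_radius,
                        reference$params$probe_radius)) ||
      capped$params$n_points != reference$params$n_points) {
    stop("SESA results were computed with different parameters")
  }
  capped$total - reference$total
}
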
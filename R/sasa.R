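# Solvent-accessible surface area by deterministic sphere-point sampling
# (Shrake-Rupley style). Points are placed on a golden-spiral lattice so that
# results are exactly reproducible for a fixed point count.

# Bondi-type van der Waals radii (Angstrom)
DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                 P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)

#' SASA computation parameters
#'
#' @param probe_radius probe sphere radius in Angstrom (water: 1.4).
#' @param n_points sampling points per atom (>= 100; default 960).
#' @param radii named vector of van der Waals radii by element; unlisted
#'   elements fall back to `fallback_radius` with a warning at compute time.
#' @param fallback_radius radius for unknown elements (default 1.70).
#' @param ignore_h drop hydrogens before the calculation (united-atom
#'   convention; default `TRUE`).
#' @return list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960,
                        radii = DEFAULT_VDW, fallback_radius = 1.70,
                        ignore_h = TRUE) {
  stopifnot(probe_radius > 0, n_points >= 100)
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii = radii, fallback_radius = fallback_radius,
                 ignore_h = ignore_h), class = "sasa_params")
}

#' Deterministic unit-sphere point set (golden spiral)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Rolls a probe sphere over van der Waals spheres by testing, for every atom,
#' which points of an expanded-radius sphere lattice lie outside all
#' neighbouring expanded spheres. Deterministic for a fixed point count.
#'
#' @param x a `tie2ab_structure` (non-empty).
#' @param params a [sasa_params()].
#' @return list with `per_atom` (numeric vector, Angstrom^2, parallel to the
#'   atom table used), `per_residue` (data.frame chain/resno/ins/resid/area)
#'   and `total`; the atom table actually used (after hydrogen handling) is
#'   attached as `atoms`.
#' @export
compute_sasa <- function(x, params = sasa_params()) {
  stopifnot(inherits(x, "tie2ab_structure"), inherits(params, "sasa_params"))
  if (params$ignore_h && any(x$element == "H")) {
    x <- x[x$element != "H", , drop = FALSE]
    class(x) <- c("tie2ab_structure", "data.frame")
  }
  if (!nrow(x)) stop("zero atoms: nothing to compute")
  rad <- unname(params$radii[x$element])
  if (anyNA(rad)) {
    warning("unknown element(s) ",
            paste(unique(x$element[is.na(rad)]), collapse = ", "),
            ": using fallback radius ", params$fallback_radius)
    rad[is.na(rad)] <- params$fallback_radius
  }
  rr <- rad + params$probe_radius        # expanded radii
  xyz <- as.matrix(x[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(params$n_points)
  # neighbour lists: atoms whose expanded spheres can intersect
  d <- atom_distances(x, x)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rr[i] + rr & seq_len(n) != i)
    p <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, params$n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      # points exactly on a shared boundary belong to the earlier atom
      exposed <- exposed & if (j < i) dj > rr[j]^2 + 1e-9
      else dj >= rr[j]^2 - 1e-9
    }
    per_atom[i] <- 4 * pi * rr[i]^2 * sum(exposed) / params$n_points
  }
  key <- paste(x$chain, x$resno, x$ins)
  agg <- rowsum(per_atom, key)
  first <- !duplicated(key)
  per_res <- data.frame(chain = x$chain[first], resno = x$resno[first],
                        ins = x$ins[first], resid = x$resid[first],
                        area = agg[match(key[first], rownames(agg)), 1],
                        stringsAsFactors = FALSE)
  rownames(per_res) <- NULL
  list(per_atom = per_atom, per_residue = per_res, total = sum(per_atom),
       atoms = x)
}

#' Analytic SASA of two spheres (closed form)
#'
#' Exact accessible area of the union of two probe-expanded spheres, from the
#' spherical-cap formula. Serves as the independent oracle for the sampled
#' calculation.
#'
#' @param r1,r2 van der Waals radii (Angstrom).
#' @param separation centre-centre distance (>= 0).
#' @param probe_radius probe radius.
#' @return list with `per_atom` (length 2) and `total` (Angstrom^2).
#' @export
two_sphere_sasa <- function(r1, r2, separation, probe_radius = 1.4) {
  if (separation < 0) stop("separation must be non-negative")
  R1 <- r1 + probe_radius
  R2 <- r2 + probe_radius
  full <- function(R) 4 * pi * R^2
  if (separation >= R1 + R2)
    return(list(per_atom = c(full(R1), full(R2)),
                total = full(R1) + full(R2)))
  if (separation <= abs(R1 - R2)) {
    # one sphere engulfed: the union surface is the larger sphere
    # (ties: the first keeps the area)
    if (R1 >= R2) return(list(per_atom = c(full(R1), 0), total = full(R1)))
    return(list(per_atom = c(0, full(R2)), total = full(R2)))
  }
  d <- separation
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)   # cap height buried on sphere 1
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  a1 <- full(R1) - 2 * pi * R1 * h1
  a2 <- full(R2) - 2 * pi * R2 * h2
  list(per_atom = c(a1, a2), total = a1 + a2)
}
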
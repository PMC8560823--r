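# Geometry of closed polygonal IgG / receptor-dimer rings and shape
# classification of assembly graphs.
#
# An assembly is a bipartite graph of IgG hubs (each with two Fab arms) and
# receptor homodimers (each with two epitopes): degree <= 2 on both sides.
# Closed rings with k hubs are the polygonal categories; acyclic connected
# assemblies are linear.

ASSEMBLY_CATEGORIES <- c("linear", "lt_tetragonal", "tetragonal",
                         "pentagonal", "hexagonal", "gt_hexagonal")

#' Ring-geometry parameters
#'
#' @param fab_fab_angle_range attainable angle between the two Fab arms of one
#'   IgG, degrees (IgG1 hinge: 115-148).
#' @param edge_span receptor-dimer epitope-to-epitope span in Angstrom
#'   (~120 between adjacent cross-linked membrane-proximal domains).
#' @param paratope_reach optimal distance between the two paratopes of an IgG
#'   in Angstrom (~130).
#' @param vertex_tolerance degrees of slack absorbing Fab elbow flexibility,
#'   the ~15 degree epitope tilt, out-of-plane pucker and non-regular rings
#'   (default 25).
#' @param reach_slack admissible |edge_span - paratope_reach| in Angstrom
#'   (default 20).
#' @return list of class `geometry_params`.
#' @export
geometry_params <- function(fab_fab_angle_range = c(115, 148),
                            edge_span = 120, paratope_reach = 130,
                            vertex_tolerance = 25, reach_slack = 20) {
  stopifnot(length(fab_fab_angle_range) == 2,
            fab_fab_angle_range[1] <= fab_fab_angle_range[2],
            edge_span > 0, paratope_reach > 0, vertex_tolerance >= 0)
  structure(list(fab_fab_angle_range = fab_fab_angle_range,
                 edge_span = edge_span, paratope_reach = paratope_reach,
                 vertex_tolerance = vertex_tolerance,
                 reach_slack = reach_slack), class = "geometry_params")
}

#' Interior vertex angle of a regular polygon
#' @param n number of vertices (>= 3).
#' @return angle in degrees, `180 (n - 2) / n`.
#' @export
polygon_vertex_angle <- function(n) {
  if (any(n < 3)) stop("a polygon needs n >= 3 vertices")
  180 * (n - 2) / n
}

#' Feasibility of closed n-gon rings under the hinge-angle constraint
#'
#' An n-ring is feasible iff the regular n-gon vertex angle lies within the
#' Fab-Fab angle range widened by the vertex tolerance. The margin is the
#' distance to the nearest bound of the widened interval (positive inside,
#' negative outside). The edge-length condition
#' `|edge_span - paratope_reach| <= reach_slack` is reported alongside.
#'
#' @param params a [geometry_params()].
#' @param n_range integer vector of ring sizes (>= 3, non-empty).
#' @return data.frame with `n`, `vertex_angle`, `feasible`, `margin_deg`,
#'   `edge_admissible`.
#' @export
ring_feasibility <- function(params = geometry_params(), n_range = 3:12) {
  stopifnot(inherits(params, "geometry_params"))
  if (!length(n_range)) stop("empty n_range")
  ang <- polygon_vertex_angle(n_range)
  lo <- params$fab_fab_angle_range[1] - params$vertex_tolerance
  hi <- params$fab_fab_angle_range[2] + params$vertex_tolerance
  margin <- pmin(ang - lo, hi - ang)
  data.frame(n = n_range, vertex_angle = ang, feasible = margin >= 0,
             margin_deg = margin,
             edge_admissible = abs(params$edge_span - params$paratope_reach) <=
               params$reach_slack)
}

#' @keywords internal
as_assembly_edges <- function(edges) {
  if (!is.data.frame(edges) || !all(c("hub", "dimer") %in% names(edges)))
    stop("edges must be a data.frame with columns hub, dimer")
  edges$hub <- as.character(edges$hub)
  edges$dimer <- as.character(edges$dimer)
  if (length(intersect(edges$hub, edges$dimer)))
    stop("invariant violation: non-bipartite graph ",
         "(identifier used as both hub and dimer)")
  edges
}

#' Classify one assembly graph into a shape category
#'
#' A single cycle with k IgG hubs maps to k = 3 `lt_tetragonal`,
#' 4 `tetragonal`, 5 `pentagonal`, 6 `hexagonal`, >= 7 `gt_hexagonal`
#' (2-hub closed dimers also fall below tetragonal); any acyclic connected
#' assembly is `linear`.
#'
#' @param edges data.frame with columns `hub` (IgG identifiers) and `dimer`
#'   (receptor-dimer identifiers), one row per Fab-arm binding.
#' @return one of the six category labels.
#' @export
classify_assembly <- function(edges) {
  edges <- as_assembly_edges(edges)
  deg_h <- table(edges$hub); deg_d <- table(edges$dimer)
  if (any(deg_h > 2) || any(deg_d > 2))
    stop("invariant violation: degree > 2 (one Fab per epitope, two Fabs per ",
         "IgG, two epitopes per dimer)")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (igraph::components(g)$no > 1)
    stop("disconnected assembly graph: classify components separately")
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (ne == nv - 1) return("linear")
  if (ne != nv || any(igraph::degree(g) != 2))
    stop("invariant violation: graph is neither a tree nor a single cycle")
  k <- length(unique(edges$hub))
  if (k <= 3) "lt_tetragonal"
  else if (k == 4) "tetragonal"
  else if (k == 5) "pentagonal"
  else if (k == 6) "hexagonal"
  else "gt_hexagonal"
}

#' Category counts and proportions for a set of classified assemblies
#'
#' @param labels character vector of category labels.
#' @return list of class `category_counts`: `counts` (all six categories),
#'   `total`, `proportions_pct` (1 decimal) and `polygonal_fraction_pct`
#'   (tetragonal + pentagonal + hexagonal + >hexagonal).
#' @export
category_proportions <- function(labels) {
  if (!length(labels)) stop("empty label list")
  bad <- setdiff(unique(labels), ASSEMBLY_CATEGORIES)
  if (length(bad)) stop("unknown category label(s): ",
                        paste(bad, collapse = ", "))
  counts <- table(factor(labels, levels = ASSEMBLY_CATEGORIES))
  total <- length(labels)
  prop <- round(100 * as.numeric(counts) / total, 1)
  poly <- c("tetragonal", "pentagonal", "hexagonal", "gt_hexagonal")
  structure(list(
    counts = stats::setNames(as.integer(counts), ASSEMBLY_CATEGORIES),
    total = total,
    proportions_pct = stats::setNames(prop, ASSEMBLY_CATEGORIES),
    polygonal_fraction_pct =
      round(100 * sum(counts[poly]) / total, 1)),
    class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  df <- data.frame(category = names(x$counts), count = x$counts,
                   pct = x$proportions_pct, row.names = NULL)
  print(df)
  cat(sprintf("total %d; polygonal fraction %.1f%%\n", x$total,
              x$polygonal_fraction_pct))
  invisible(x)
}
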
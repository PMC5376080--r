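# Constructive solid geometry over quadric surfaces.
#
# A surface is the zero set of Ax^2+By^2+Cz^2+Dxy+Eyz+Fzx+Gx+Hy+Iz+J.
# A point has negative sense with respect to a surface when the quadric
# evaluates negative there (the interior for the canonical closed forms
# below). Cells are boolean expression trees over signed surface
# references; particle tracking advances a nudge of 1e-6 cm past each
# crossed surface before relocating.

GEOM_NUDGE_CM <- 1e-6

#' Define a quadric surface
#'
#' @param id Surface label (unique within a model).
#' @param coefficients Numeric length-10 vector (A..J) of
#'   Ax^2+By^2+Cz^2+Dxy+Eyz+Fzx+Gx+Hy+Iz+J = 0.
#' @param kind Informational tag (plane, sphere, cylinder, ellipsoid,
#'   cone, general).
#' @return A \code{quadric} object.
#' @export
quadric_surface <- function(id, coefficients, kind = "general") {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 10 || any(!is.finite(coefficients)))
    stop("coefficients must be 10 finite numbers")
  if (all(coefficients[1:9] == 0))
    stop("degenerate quadric: all of A..I are zero")
  structure(list(id = id, coefficients = coefficients, kind = kind),
            class = "quadric")
}

#' Evaluate a quadric at points
#' @param surface A \code{quadric}.
#' @param p Numeric length-3 position or 3-column matrix.
#' @return Quadric value(s); the sign is the sense of each point.
#' @export
quadric_eval <- function(surface, p) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  k <- surface$coefficients
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  k[1] * x^2 + k[2] * y^2 + k[3] * z^2 + k[4] * x * y + k[5] * y * z +
    k[6] * z * x + k[7] * x + k[8] * y + k[9] * z + k[10]
}

# -- convenience constructors -------------------------------------------------

#' Axis-aligned plane (x, y or z = at)
#' @param id Label. @param axis "x","y" or "z". @param at Coordinate (cm).
#' @export
surf_plane <- function(id, axis, at) {
  co <- numeric(10)
  co[6 + match(axis, c("x", "y", "z"))] <- 1
  co[10] <- -at
  quadric_surface(id, co, "plane")
}

#' Sphere
#' @param id Label. @param center Length-3 (cm). @param radius cm.
#' @export
surf_sphere <- function(id, center, radius) {
  co <- c(1, 1, 1, 0, 0, 0, -2 * center,
          sum(center^2) - radius^2)
  quadric_surface(id, co, "sphere")
}

#' Ellipsoid with axis-aligned semi-axes
#' @param id Label. @param center Length-3 (cm). @param semi Length-3 (cm).
#' @export
surf_ellipsoid <- function(id, center, semi) {
  a2 <- semi^2
  co <- c(1 / a2[1], 1 / a2[2], 1 / a2[3], 0, 0, 0,
          -2 * center / a2, sum(center^2 / a2) - 1)
  quadric_surface(id, co, "ellipsoid")
}

#' Elliptic cylinder along a coordinate axis
#'
#' @param id Label.
#' @param axis "x", "y" or "z" (the translation axis).
#' @param center Length-2 center in the transverse plane, coordinates in
#'   x,y,z order with the axis coordinate omitted.
#' @param semi Length-2 transverse semi-axes (cm); a scalar gives a
#'   circular cylinder.
#' @export
surf_cylinder <- function(id, axis, center, semi) {
  if (length(semi) == 1) semi <- c(semi, semi)
  tr <- setdiff(1:3, match(axis, c("x", "y", "z")))
  co <- numeric(10)
  co[tr] <- 1 / semi^2
  co[6 + tr] <- -2 * center / semi^2
  co[10] <- sum(center^2 / semi^2) - 1
  quadric_surface(id, co, "cylinder")
}

#' Circular cone around a coordinate axis
#'
#' One-sheet usage is up to the cell expression (combine with planes).
#' @param id Label. @param axis "x","y","z". @param apex Length-3 (cm).
#' @param tan_half Tangent of the half-opening angle.
#' @export
surf_cone <- function(id, axis, apex, tan_half) {
  ia <- match(axis, c("x", "y", "z"))
  tr <- setdiff(1:3, ia)
  co <- numeric(10)
  co[tr] <- 1
  co[ia] <- -tan_half^2
  co[6 + tr] <- -2 * apex[tr]
  co[6 + ia] <- 2 * tan_half^2 * apex[ia]
  co[10] <- sum(apex[tr]^2) - tan_half^2 * apex[ia]^2
  quadric_surface(id, co, "cone")
}

# -- region expressions -------------------------------------------------------

#' Signed surface reference (negative sense: quadric < 0)
#' @param surf Surface id. @export
inside <- function(surf) structure(list(type = "leaf", surf = surf,
                                        sense = -1L), class = "csg_region")

#' Signed surface reference (positive sense: quadric > 0)
#' @param surf Surface id. @export
outside <- function(surf) structure(list(type = "leaf", surf = surf,
                                         sense = 1L), class = "csg_region")

#' Region intersection
#' @param ... \code{csg_region} terms. @export
rg_and <- function(...) structure(list(type = "and", args = list(...)),
                                  class = "csg_region")

#' Region union
#' @param ... \code{csg_region} terms. @export
rg_or <- function(...) structure(list(type = "or", args = list(...)),
                                 class = "csg_region")

#' Region complement
#' @param x A \code{csg_region}. @export
rg_not <- function(x) structure(list(type = "not", args = list(x)),
                                class = "csg_region")

#' Axis-aligned box region from six planes
#'
#' Helper returning both the six plane surfaces and the box region.
#' @param id_prefix Prefix for generated surface ids.
#' @param lo,hi Length-3 lower/upper corners (cm).
#' @return list(surfaces, region).
#' @export
box_region <- function(id_prefix, lo, hi) {
  ax <- c("x", "y", "z")
  surfs <- list()
  terms <- list()
  for (i in 1:3) {
    slo <- surf_plane(paste0(id_prefix, ".", ax[i], "lo"), ax[i], lo[i])
    shi <- surf_plane(paste0(id_prefix, ".", ax[i], "hi"), ax[i], hi[i])
    surfs[[slo$id]] <- slo
    surfs[[shi$id]] <- shi
    terms[[2 * i - 1]] <- outside(slo$id)
    terms[[2 * i]] <- inside(shi$id)
  }
  list(surfaces = surfs, region = do.call(rg_and, terms))
}

region_surfaces <- function(region) {
  if (region$type == "leaf") return(region$surf)
  unique(unlist(lapply(region$args, region_surfaces)))
}

# Postfix-encode a region for the kernel: leaf token = 2*surf_idx0 + (sense>0) + 1,
# operators AND=-1, OR=-2, NOT=-3.
region_postfix <- function(region, surf_index) {
  if (region$type == "leaf") {
    i0 <- surf_index[[region$surf]]
    if (is.null(i0)) stop("region references unknown surface: ", region$surf)
    return(2L * i0 + as.integer(region$sense > 0) + 1L)
  }
  toks <- unlist(lapply(region$args, region_postfix, surf_index = surf_index))
  op <- switch(region$type, and = -1L, or = -2L, not = -3L)
  if (region$type == "not") c(toks, op)
  else c(toks, rep(op, length(region$args) - 1L))
}

# Evaluate a region at a point in R (reference implementation used by tests).
region_contains <- function(region, surfaces, p) {
  if (region$type == "leaf") {
    q <- quadric_eval(surfaces[[region$surf]], p)
    return(if (region$sense < 0) q < 0 else q >= 0)
  }
  vals <- vapply(region$args, region_contains, logical(1),
                 surfaces = surfaces, p = p)
  switch(region$type, and = all(vals), or = any(vals), not = !vals[1])
}

# -- cells and models ---------------------------------------------------------

#' Define a geometry cell
#'
#' @param id Cell label.
#' @param region A \code{csg_region}.
#' @param material Material name (resolved against the scenario material set).
#' @param density_override Optional density replacing the material default.
#' @param tally Flag: score energy deposition in this cell.
#' @param organ Optional tissue label for dose reports.
#' @param volume Analytic cell volume in cm^3 (NA when unknown; required
#'   for dose-per-mass tallies).
#' @param world Flag: this cell is the exterior world.
#' @return A \code{csg_cell}.
#' @export
csg_cell <- function(id, region, material, density_override = NULL,
                     tally = FALSE, organ = NULL, volume = NA_real_,
                     world = FALSE) {
  stopifnot(inherits(region, "csg_region"))
  structure(list(id = id, region = region, material = material,
                 density_override = density_override, tally = tally,
                 organ = organ, volume = volume, world = world),
            class = "csg_cell")
}

#' Assemble a geometry model
#'
#' Validates that every referenced surface exists and that exactly one
#' cell is flagged as the exterior world.
#'
#' @param surfaces List of \code{quadric} (names ignored; ids used).
#' @param cells List of \code{csg_cell}.
#' @param bounding_box list(lo=, hi=) axis-aligned extents (cm) enclosing
#'   all interior cells.
#' @return A \code{geometry_model}.
#' @export
geometry_model <- function(surfaces, cells, bounding_box) {
  names(surfaces) <- vapply(surfaces, `[[`, "", "id")
  names(cells) <- vapply(cells, `[[`, "", "id")
  if (anyDuplicated(names(surfaces))) stop("duplicate surface ids")
  if (anyDuplicated(names(cells))) stop("duplicate cell ids")
  for (cl in cells) {
    miss <- setdiff(region_surfaces(cl$region), names(surfaces))
    if (length(miss))
      stop("cell ", cl$id, " references unknown surfaces: ",
           paste(miss, collapse = ", "))
  }
  nw <- sum(vapply(cells, `[[`, FALSE, "world"))
  if (nw != 1) stop("exactly one world cell required (got ", nw, ")")
  m <- structure(list(surfaces = surfaces, cells = cells,
                      bounding_box = bounding_box),
                 class = "geometry_model")
  m$compiled <- compile_geometry(m)
  m
}

#' @export
print.geometry_model <- function(x, ...) {
  cat(sprintf("<geometry_model> %d surfaces, %d cells\n",
              length(x$surfaces), length(x$cells)))
  invisible(x)
}

# Flatten a model into the plain-vector bundle consumed by the C++ kernel.
compile_geometry <- function(model) {
  surf_ids <- names(model$surfaces)
  surf_index <- as.list(seq_along(surf_ids) - 1L)
  names(surf_index) <- surf_ids
  coef <- t(vapply(model$surfaces, `[[`, numeric(10), "coefficients"))
  toks <- lapply(model$cells, function(cl)
    region_postfix(cl$region, surf_index))
  lens <- vapply(toks, length, 0L)
  list(
    surf_coef = coef,
    tokens = as.integer(unlist(toks)),
    tok_offset = as.integer(cumsum(c(0L, lens[-length(lens)]))),
    tok_len = as.integer(lens),
    world = which(vapply(model$cells, `[[`, FALSE, "world")) - 1L,
    cell_ids = names(model$cells),
    surf_ids = surf_ids
  )
}

#' Locate a point in a geometry model
#'
#' Full-audit location: every cell is tested; two cells claiming the point
#' is a geometry-definition error naming the cells.
#'
#' @param p Length-3 position (cm) or 3-column matrix of positions.
#' @param model A \code{geometry_model}.
#' @return Cell id(s).
#' @export
locate_point <- function(p, model) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  if (any(!is.finite(p))) stop("positions must be finite")
  g <- model$compiled
  res <- cpp_locate_points(g$surf_coef, g$tokens, g$tok_offset, g$tok_len,
                           p, TRUE)
  if (any(res$n_matches > 1)) {
    i <- which(res$n_matches > 1)[1]
    stop(sprintf("ambiguous location at (%g, %g, %g): cells %s and %s",
                 p[i, 1], p[i, 2], p[i, 3],
                 g$cell_ids[res$first[i] + 1L],
                 g$cell_ids[res$second[i] + 1L]))
  }
  if (any(res$n_matches == 0)) {
    i <- which(res$n_matches == 0)[1]
    stop(sprintf("point (%g, %g, %g) matched no cell (world must be a complement)",
                 p[i, 1], p[i, 2], p[i, 3]))
  }
  g$cell_ids[res$first + 1L]
}

#' Distance to the current cell boundary along a direction
#'
#' Smallest positive quadric root along p + t u among the cell's bounding
#' surfaces; +Inf when the cell is unbounded in that direction.
#'
#' @param p Length-3 position inside \code{cell}.
#' @param u Unit direction (|u| = 1 within 1e-12).
#' @param cell Cell id.
#' @param model A \code{geometry_model}.
#' @return list(distance, surface) — crossed surface id (NA at +Inf).
#' @export
distance_to_boundary <- function(p, u, cell, model) {
  if (abs(sqrt(sum(u^2)) - 1) > 1e-12) stop("direction must be unit length")
  g <- model$compiled
  ci <- match(cell, g$cell_ids) - 1L
  if (is.na(ci)) stop("unknown cell: ", cell)
  r <- cpp_distance_to_boundary(g$surf_coef, g$tokens, g$tok_offset,
                                g$tok_len, ci, as.numeric(p), as.numeric(u))
  list(distance = r$distance,
       surface = if (r$surface < 0) NA_character_
                 else g$surf_ids[r$surface + 1L])
}

#' Trace a ray through a geometry model
#'
#' Returns the ordered chords (cell, length) from p to escape into the
#' world cell. Consecutive identical cells (internal surface crossings)
#' are merged; more than \code{max_segments} raw segments is an
#' infinite-loop guard error.
#'
#' @param p Length-3 start position (cm).
#' @param u Unit direction.
#' @param model A \code{geometry_model}.
#' @param max_segments Guard limit (default 1e4).
#' @return data.frame(cell, length).
#' @export
ray_trace <- function(p, u, model, max_segments = 10000L) {
  if (abs(sqrt(sum(u^2)) - 1) > 1e-12) stop("direction must be unit length")
  g <- model$compiled
  r <- cpp_ray_trace(g$surf_coef, g$tokens, g$tok_offset, g$tok_len,
                     g$world, as.numeric(p), as.numeric(u),
                     as.integer(max_segments))
  if (r$status == 1L) stop("ray_trace: segment limit exceeded (loop guard)")
  if (r$status == 2L) stop("ray_trace: particle lost (bounded cell with no exit root)")
  cells <- g$cell_ids[r$cell + 1L]
  len <- r$length
  if (length(cells) > 1) {   # merge consecutive duplicates
    grp <- cumsum(c(TRUE, cells[-1] != cells[-length(cells)]))
    len <- as.numeric(tapply(len, grp, sum))
    cells <- cells[!duplicated(grp)]
  }
  data.frame(cell = cells, length = len, stringsAsFactors = FALSE)
}

#' Monte Carlo space-filling audit
#'
#' Samples points uniformly in the bounding box and verifies each locates
#' to exactly one cell; returns the per-cell hit fractions (a volume
#' estimate when multiplied by the box volume).
#'
#' @param model A \code{geometry_model}.
#' @param n Number of points (default 1e5).
#' @param seed RNG seed.
#' @return data.frame(cell, hits, fraction).
#' @export
audit_space_filling <- function(model, n = 1e5, seed = 1L) {
  set.seed(seed)
  lo <- model$bounding_box$lo; hi <- model$bounding_box$hi
  p <- cbind(stats::runif(n, lo[1], hi[1]),
             stats::runif(n, lo[2], hi[2]),
             stats::runif(n, lo[3], hi[3]))
  cells <- locate_point(p, model)   # errors on any ambiguous/unmatched point
  tab <- table(factor(cells, levels = names(model$cells)))
  data.frame(cell = names(tab), hits = as.integer(tab),
             fraction = as.integer(tab) / n, stringsAsFactors = FALSE)
}
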
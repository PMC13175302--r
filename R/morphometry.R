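# Geometric quantification of imaging-derived objects: puncta density near
# traced filament surfaces, neurite-length summaries, live/dead viability.
# The filament surface is modeled as a capsule union: each parent-child
# segment is a cone frustum with linearly interpolated radius and spherical
# end caps (the endpoint clamp of the point-segment distance).

#' Traced filament model
#'
#' A neuron skeleton as an SWC-style node table: `id`, `type`, `x`, `y`, `z`
#' (micrometres), `radius` (micrometres, >= 0), `parent` (`-1` for roots).
#' The parent links must form an acyclic forest and every non-root parent id
#' must resolve.
#'
#' @param nodes Data frame with the seven SWC columns.
#' @return A tibble of class `filament_model`.
#' @export
filament_model <- function(nodes) {
  nodes <- as_tibble(nodes)
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  missing_cols <- setdiff(need, names(nodes))
  if (length(missing_cols)) {
    nq_abort(sprintf("missing SWC column(s): %s", paste(missing_cols, collapse = ", ")),
             field = paste(missing_cols, collapse = ","))
  }
  if (any(!is.finite(nodes$x) | !is.finite(nodes$y) | !is.finite(nodes$z))) {
    nq_abort("non-finite coordinates", field = "x/y/z")
  }
  bad_r <- which(nodes$radius < 0)
  if (length(bad_r)) nq_abort("negative radius", field = "radius", row = bad_r[1])
  if (anyDuplicated(nodes$id)) nq_abort("duplicate node ids", field = "id")
  non_root <- nodes$parent != -1
  dangling <- which(non_root & !(nodes$parent %in% nodes$id))
  if (length(dangling)) {
    nq_abort(sprintf("dangling parent id %s", nodes$parent[dangling[1]]),
             field = "parent", row = dangling[1])
  }
  # forest check: following parent links must terminate at a root
  parent_of <- setNames(nodes$parent, nodes$id)
  for (start in nodes$id) {
    seen <- character(0)
    cur <- start
    while (parent_of[[as.character(cur)]] != -1) {
      if (as.character(cur) %in% seen) nq_abort("cycle in parent links", field = "parent")
      seen <- c(seen, as.character(cur))
      cur <- parent_of[[as.character(cur)]]
    }
  }
  structure(nodes, class = c("filament_model", class(nodes)))
}

#' @export
print.filament_model <- function(x, ...) {
  cat(sprintf("<filament_model> %d nodes, %d segment(s), length %.2f um, volume %.2f um^3\n",
              nrow(x), nrow(filament_segments(x)), filament_total_length(x),
              filament_volume(x)))
  invisible(x)
}

#' Segment table of a filament model
#'
#' One row per parent-child edge with endpoint coordinates, endpoint radii
#' and Euclidean length.
#'
#' @param filament A [filament_model()].
#' @return Tibble with columns `ax,ay,az,r0,bx,by,bz,r1,length`.
#' @export
filament_segments <- function(filament) {
  stopifnot(inherits(filament, "filament_model"))
  nodes <- as_tibble(filament)
  child <- nodes[nodes$parent != -1, , drop = FALSE]
  if (!nrow(child)) {
    return(tibble(ax = numeric(0), ay = numeric(0), az = numeric(0), r0 = numeric(0),
                  bx = numeric(0), by = numeric(0), bz = numeric(0), r1 = numeric(0),
                  length = numeric(0)))
  }
  pidx <- match(child$parent, nodes$id)
  tibble(ax = nodes$x[pidx], ay = nodes$y[pidx], az = nodes$z[pidx],
         r0 = nodes$radius[pidx],
         bx = child$x, by = child$y, bz = child$z, r1 = child$radius,
         length = sqrt((child$x - nodes$x[pidx])^2 +
                         (child$y - nodes$y[pidx])^2 +
                         (child$z - nodes$z[pidx])^2))
}

#' Total skeleton length of a filament model
#'
#' @param filament A [filament_model()].
#' @return Length in micrometres.
#' @export
filament_total_length <- function(filament) {
  sum(filament_segments(filament)$length)
}

#' Filament volume as summed conical frusta
#'
#' Each segment contributes `pi/3 * L * (r0^2 + r0*r1 + r1^2)`; no overlap
#' correction is applied at branch points.
#'
#' @param filament A [filament_model()].
#' @return Volume in cubic micrometres.
#' @export
filament_volume <- function(filament) {
  s <- filament_segments(filament)
  sum(pi / 3 * s$length * (s$r0^2 + s$r0 * s$r1 + s$r1^2))
}

#' 3D puncta set
#'
#' @param points Data frame with finite `x`, `y`, `z` (micrometres) and
#'   optional `intensity`.
#' @return A tibble of class `puncta_set`.
#' @export
puncta_set <- function(points) {
  points <- as_tibble(points)
  need <- c("x", "y", "z")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols)) {
    nq_abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
             field = paste(missing_cols, collapse = ","))
  }
  bad <- which(!is.finite(points$x) | !is.finite(points$y) | !is.finite(points$z))
  if (length(bad)) nq_abort("non-finite puncta coordinates", field = "x/y/z", row = bad[1])
  structure(points, class = c("puncta_set", class(points)))
}

#' Distance from points to the filament surface
#'
#' For each query point, the minimum over segments of the point-to-segment
#' distance minus the linearly interpolated local radius, clamped at zero
#' (points inside the capsule surface report 0). This is the capsule-union
#' surface distance used for the "puncta within 2.5 um of the filament
#' surface" inclusion rule.
#'
#' @param points A [puncta_set()] or data frame with `x,y,z` in micrometres.
#' @param filament A [filament_model()] with at least one segment.
#' @return Numeric vector of surface distances in micrometres.
#' @export
distance_to_filament_surface <- function(points, filament) {
  segs <- filament_segments(filament)
  if (!nrow(segs)) nq_abort("filament has no segments", field = "filament")
  px <- points$x; py <- points$y; pz <- points$z
  dx <- segs$bx - segs$ax; dy <- segs$by - segs$ay; dz <- segs$bz - segs$az
  len2 <- dx^2 + dy^2 + dz^2
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    tt <- ((px[i] - segs$ax) * dx + (py[i] - segs$ay) * dy +
             (pz[i] - segs$az) * dz) / len2
    tt[len2 == 0] <- 0
    tt <- pmin(pmax(tt, 0), 1)
    cx <- segs$ax + tt * dx; cy <- segs$ay + tt * dy; cz <- segs$az + tt * dz
    d <- sqrt((px[i] - cx)^2 + (py[i] - cy)^2 + (pz[i] - cz)^2) -
      (segs$r0 + tt * (segs$r1 - segs$r0))
    out[i] <- min(pmax(d, 0))
  }
  out
}

#' Count puncta within a distance of the filament surface
#'
#' Inclusive rule: a punctum at exactly the threshold distance counts.
#'
#' @param puncta A [puncta_set()].
#' @param filament A [filament_model()].
#' @param threshold Surface distance threshold in micrometres (> 0,
#'   default 2.5, the axial step of a typical confocal stack).
#' @return Integer count.
#' @export
count_puncta_near_filament <- function(puncta, filament, threshold = 2.5) {
  check_number(threshold, "threshold", positive = TRUE)
  if (!nrow(puncta)) return(0L)
  sum(distance_to_filament_surface(puncta, filament) <= threshold)
}

#' Synapse density normalized to neuronal volume and length
#'
#' Density is reported both per 100 um^3 of filament volume and per 100 um of
#' filament length; neither normalization is privileged.
#'
#' @param included Number of puncta passing the surface-distance filter.
#' @param filament A [filament_model()] with positive volume and length.
#' @return Tibble with `included`, `volume_um3`, `length_um`,
#'   `density_per_100um3`, `density_per_100um`.
#' @export
synapse_density <- function(included, filament) {
  vol <- filament_volume(filament)
  len <- filament_total_length(filament)
  if (vol <= 0) nq_abort("filament volume must be > 0", field = "volume")
  if (len <= 0) nq_abort("filament length must be > 0", field = "length")
  if (included < 0) nq_abort("negative count", field = "included")
  tibble(included = as.integer(included), volume_um3 = vol, length_um = len,
         density_per_100um3 = included / vol * 100,
         density_per_100um = included / len * 100)
}

#' Mean neurite length over filament models
#'
#' @param filaments A list of [filament_model()] objects (>= 1).
#' @return Mean of per-filament total lengths, micrometres.
#' @export
neurite_mean_length <- function(filaments) {
  if (!length(filaments)) nq_abort("empty filament list", field = "filaments")
  mean(map_dbl(filaments, filament_total_length))
}

#' Live/dead viability percentage
#'
#' @param live,dead Object counts (live + dead > 0).
#' @return Tibble with `live`, `dead`, `percent_viable`.
#' @export
viability_percent <- function(live, dead) {
  if (live < 0 || dead < 0) nq_abort("counts must be non-negative", field = "live/dead")
  if (live + dead == 0) nq_abort("live + dead must be > 0", field = "live/dead")
  tibble(live = as.integer(live), dead = as.integer(dead),
         percent_viable = 100 * live / (live + dead))
}
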
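#' Subject time series
#'
#' Container for one participant's stimulus-locked cortical response matrix.
#' The data matrix is always oriented time x vertex: rows are acquisition
#' time points (TRs), columns are cortical surface vertices.  All model
#' stages assume the columns have been z-scored (see
#' [normalize_timeseries()]); vertices with zero variance (e.g. medial-wall
#' or masked vertices) are zeroed out and flagged rather than dropped, so
#' that vertex indices stay aligned with the surface geometry.
#'
#' @param data numeric matrix, time x vertex.
#' @param subject_id character scalar identifying the participant.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param run_boundaries integer vector of 0-based time indices at which
#'   scanner runs start; strictly increasing, first element 0.
#' @return An object of class `subject_timeseries`: a list with elements
#'   `subject_id`, `data`, `tr_seconds`, `run_boundaries`, and
#'   `zero_variance` (logical per-vertex flag, set by normalization).
#' @export
subject_timeseries <- function(data, subject_id = "subj", tr_seconds = 1,
                               run_boundaries = 0L) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(colSums(!is.finite(data)) > 0)
    stop("non-finite values in vertices: ", paste(bad, collapse = ", "))
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("`tr_seconds` must be a positive scalar")
  run_boundaries <- as.integer(run_boundaries)
  t_time <- nrow(data)
  if (length(run_boundaries) == 0 || run_boundaries[1] != 0L ||
      is.unsorted(run_boundaries, strictly = TRUE) ||
      any(run_boundaries >= t_time))
    stop("`run_boundaries` must be strictly increasing, start at 0, and be < t")
  structure(list(subject_id = as.character(subject_id),
                 data = data,
                 tr_seconds = tr_seconds,
                 run_boundaries = run_boundaries,
                 zero_variance = rep(FALSE, ncol(data))),
            class = "subject_timeseries")
}

#' @export
print.subject_timeseries <- function(x, ...) {
  cat(sprintf("<subject_timeseries '%s': %d time points x %d vertices, TR = %gs, %d run(s)>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              length(x$run_boundaries)))
  if (any(x$zero_variance))
    cat(sprintf("  %d zero-variance vertices flagged\n", sum(x$zero_variance)))
  invisible(x)
}

#' Run labels for each time point
#' @noRd
run_labels <- function(t_time, run_boundaries) {
  findInterval(seq_len(t_time) - 1L, run_boundaries)
}

#' Z-score each vertex time series
#'
#' Normalizes every vertex (column) to zero mean and unit variance, the
#' final preprocessing step assumed by all model stages.  The standard
#' deviation uses the population convention (denominator `t`).  Columns
#' with zero variance are set to all zeros and flagged in the
#' `zero_variance` field instead of producing NaNs; such vertices carry no
#' signal and are excluded from regression targets downstream.  The
#' operation is idempotent.
#'
#' @param ts a [subject_timeseries()] object.
#' @return The normalized `subject_timeseries`.
#' @export
normalize_timeseries <- function(ts) {
  stopifnot(inherits(ts, "subject_timeseries"))
  x <- ts$data
  if (nrow(x) < 2) stop("need at least 2 time points to normalize")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sd_pop <- sqrt(colMeans(xc^2))
  zero <- sd_pop < .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  sd_pop[zero] <- 1
  xz <- sweep(xc, 2, sd_pop, "/")
  xz[, zero] <- 0
  ts$data <- xz
  ts$zero_variance <- ts$zero_variance | zero
  ts
}

#' Surface geometry
#'
#' Vertex coordinates of a cortical surface mesh (or any point cloud) used
#' to define searchlights.  Distances are euclidean on the supplied 3-D
#' coordinates by default; geodesic (graph shortest-path) distances along
#' mesh edges are available when `edges` is supplied.
#'
#' @param coordinates numeric matrix, vertex x 3, positions in mm.
#' @param distance_mode `"euclidean"` or `"geodesic"`.
#' @param edges optional integer matrix (n_edge x 2, 1-based vertex
#'   indices) giving mesh edges; required for geodesic distances.
#' @return An object of class `surface_geometry`.
#' @export
surface_geometry <- function(coordinates,
                             distance_mode = c("euclidean", "geodesic"),
                             edges = NULL) {
  coordinates <- as.matrix(coordinates)
  distance_mode <- match.arg(distance_mode)
  if (nrow(coordinates) < 1) stop("geometry must contain at least one vertex")
  if (ncol(coordinates) != 3) stop("`coordinates` must be vertex x 3")
  if (any(!is.finite(coordinates))) stop("coordinates must be finite")
  if (distance_mode == "geodesic" && is.null(edges))
    stop("geodesic distances require mesh `edges`")
  structure(list(coordinates = coordinates, distance_mode = distance_mode,
                 edges = edges),
            class = "surface_geometry")
}

#' @export
print.surface_geometry <- function(x, ...) {
  cat(sprintf("<surface_geometry: %d vertices, %s distances>\n",
              nrow(x$coordinates), x$distance_mode))
  invisible(x)
}

n_vertices <- function(geom) nrow(geom$coordinates)

geodesic_distances_from <- function(geom, center) {
  co <- geom$coordinates
  ne <- nrow(geom$edges)
  w <- sqrt(rowSums((co[geom$edges[, 1], , drop = FALSE] -
                     co[geom$edges[, 2], , drop = FALSE])^2))
  # Dijkstra on the undirected weighted mesh graph
  v <- nrow(co)
  adj <- vector("list", v)
  for (e in seq_len(ne)) {
    a <- geom$edges[e, 1]; b <- geom$edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, w[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, w[e]))
  }
  dist <- rep(Inf, v)
  dist[center] <- 0
  done <- rep(FALSE, v)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (length(u) == 0 || !is.finite(dist[u])) break
    done[u] <- TRUE
    if (all(done)) break
    for (k in seq_len(NROW(adj[[u]]))) {
      nb <- adj[[u]][k, 1]; d2 <- dist[u] + adj[[u]][k, 2]
      if (d2 < dist[nb]) dist[nb] <- d2
    }
  }
  dist
}

#' Build searchlights around every vertex
#'
#' For each vertex, collects all vertices within `radius_mm` under the
#' geometry's distance mode.  Every vertex is the center of exactly one
#' searchlight and is always a member of its own searchlight (distance 0).
#'
#' @param geom a [surface_geometry()].
#' @param radius_mm searchlight radius in mm (default 20, the radius used
#'   throughout the model).
#' @return A list of `searchlight` objects, one per vertex, each a list
#'   with `center_vertex`, `members` (1-based indices), `distances` (mm),
#'   and `radius`.
#' @export
build_searchlights <- function(geom, radius_mm = 20) {
  stopifnot(inherits(geom, "surface_geometry"))
  if (!is.numeric(radius_mm) || radius_mm <= 0) stop("radius must be positive")
  v <- n_vertices(geom)
  co <- geom$coordinates
  out <- vector("list", v)
  if (geom$distance_mode == "euclidean") {
    # block over centers to keep memory bounded on large meshes
    block <- max(1L, floor(2^22 / v))
    for (start in seq(1L, v, by = block)) {
      idx <- start:min(start + block - 1L, v)
      d2 <- outer(rowSums(co[idx, , drop = FALSE]^2), rowSums(co^2), "+") -
        2 * co[idx, , drop = FALSE] %*% t(co)
      d2[d2 < 0] <- 0
      for (k in seq_along(idx)) {
        d <- sqrt(d2[k, ])
        mem <- which(d <= radius_mm)
        out[[idx[k]]] <- structure(list(center_vertex = idx[k],
                                        members = mem,
                                        distances = d[mem],
                                        radius = radius_mm),
                                   class = "searchlight")
      }
    }
  } else {
    for (i in seq_len(v)) {
      d <- geodesic_distances_from(geom, i)
      mem <- which(d <= radius_mm)
      out[[i]] <- structure(list(center_vertex = i, members = mem,
                                 distances = d[mem], radius = radius_mm),
                            class = "searchlight")
    }
  }
  out
}

#' Distance-based aggregation weight
#'
#' Weight used when combining overlapping searchlight estimates into a
#' whole-brain quantity: `(r - d) / r`, i.e. 1 at the searchlight center
#' and falling off linearly to 0 at the searchlight boundary.
#'
#' @param d_mm distance from the searchlight center to the vertex (mm).
#' @param r_mm searchlight radius (mm).
#' @return Weight(s) in `[0, 1]`.
#' @export
aggregation_weight <- function(d_mm, r_mm) {
  if (any(r_mm <= 0)) stop("radius must be positive")
  if (any(d_mm < 0) || any(d_mm > r_mm)) stop("need 0 <= d <= r")
  (r_mm - d_mm) / r_mm
}

#' Region mask
#'
#' A named set of vertex indices, e.g. an early-visual-cortex mask used to
#' evaluate retinotopic predictions.
#'
#' @param members integer vector of 1-based vertex indices.
#' @param name character label.
#' @param n_vertex optional total vertex count for bounds checking.
#' @export
region_mask <- function(members, name = "mask", n_vertex = NULL) {
  members <- sort(unique(as.integer(members)))
  if (length(members) && members[1] < 1) stop("mask indices must be >= 1")
  if (!is.null(n_vertex) && length(members) && max(members) > n_vertex)
    stop("mask indices exceed vertex count")
  structure(list(name = as.character(name), members = members),
            class = "region_mask")
}

#' Regular grid geometry
#'
#' A flat rectangular grid of vertices embedded in 3-D (z = 0), the default
#' geometry of the synthetic cohort generator.  Searchlights on this grid
#' behave like cortical-surface searchlights on a locally flat patch.
#'
#' @param nx,ny grid dimensions (vertices).
#' @param spacing_mm distance between neighboring vertices (default 3 mm).
#' @export
grid_geometry <- function(nx, ny = nx, spacing_mm = 3) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  co <- cbind((g$x - 1) * spacing_mm, (g$y - 1) * spacing_mm, 0)
  surface_geometry(co)
}
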
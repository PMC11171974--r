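#' Areal unit geometry
#'
#' Lightweight container for one areal unit: an identifier, one or more
#' closed polygon rings in a common projected coordinate system (km), and a
#' centroid.  If no centroid is given it is computed from the first ring by
#' the standard polygon (shoelace) centroid formula.
#'
#' @param area_id unique identifier for the area.
#' @param rings list of numeric matrices (two columns, x and y); each ring
#'   must be closed (first vertex equal to last).
#' @param centroid optional numeric length-2 centroid; computed if `NULL`.
#' @return an object of class `area_geometry`.
#' @export
area_geometry <- function(area_id, rings, centroid = NULL) {
  if (is.matrix(rings)) rings <- list(rings)
  stopifnot(length(rings) >= 1L)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2L || nrow(r) < 4L)
      stop("area ", area_id, ": each ring needs >= 4 vertices in 2 columns")
    if (any(r[1L, ] != r[nrow(r), ]))
      stop("area ", area_id, ": ring is not closed (first vertex != last)")
    if (any(!is.finite(r))) stop("area ", area_id, ": nonfinite coordinates")
    r
  })
  if (is.null(centroid)) centroid <- polygon_centroid(rings[[1L]])
  if (length(centroid) != 2L || any(!is.finite(centroid)))
    stop("area ", area_id, ": centroid must be two finite coordinates")
  structure(list(area_id = area_id, rings = rings,
                 centroid = as.numeric(centroid)),
            class = "area_geometry")
}

polygon_centroid <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- length(x)
  cr <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x[-n]), mean(y[-n])))
  c(sum((x[-n] + x[-1L]) * cr), sum((y[-n] + y[-1L]) * cr)) / (6 * a)
}

area_ids <- function(areas) vapply(areas, `[[`, "", "area_id")

area_centroids <- function(areas) {
  if (is.data.frame(areas)) {
    cols <- intersect(c("x_km", "y_km"), names(areas))
    if (length(cols) != 2L) cols <- c("x", "y")
    m <- as.matrix(areas[, cols])
    rownames(m) <- as.character(areas$area_id)
    return(m)
  }
  m <- t(vapply(areas, `[[`, numeric(2L), "centroid"))
  rownames(m) <- area_ids(areas)
  m
}

#' Spatial weight matrix over areal units
#'
#' Sparse, symmetric neighbour structure: per-area neighbour index lists and
#' aligned positive weights.  Validates symmetry (`w_jk = w_kj`), absence of
#' self-neighbours and positivity of all weights.
#'
#' @param ids character vector of unique area identifiers.
#' @param neighbours list of integer vectors of neighbour indices (1-based).
#' @param weights list of numeric vectors aligned with `neighbours`; defaults
#'   to binary weights.
#' @param kind `"queen"` or `"distance_band"`.
#' @param band_km distance band, for `kind = "distance_band"`.
#' @return an object of class `weight_matrix`.
#' @export
weight_matrix <- function(ids, neighbours, weights = NULL,
                          kind = c("queen", "distance_band"), band_km = NULL) {
  kind <- match.arg(kind)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate area_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(neighbours) != n) stop("neighbour list length must equal n")
  neighbours <- lapply(neighbours, as.integer)
  if (is.null(weights))
    weights <- lapply(neighbours, function(x) rep(1, length(x)))
  for (j in seq_len(n)) {
    nb <- neighbours[[j]]; w <- weights[[j]]
    if (length(nb) != length(w)) stop("weights misaligned with neighbours for area ", ids[j])
    if (any(nb == j)) stop("self-neighbour for area ", ids[j])
    if (any(nb < 1L | nb > n)) stop("neighbour index out of range for area ", ids[j])
    if (any(w <= 0)) stop("nonpositive weight for area ", ids[j])
    if (anyDuplicated(nb)) stop("duplicate neighbour for area ", ids[j])
  }
  for (j in seq_len(n)) {
    for (m in seq_along(neighbours[[j]])) {
      k <- neighbours[[j]][m]
      pos <- match(j, neighbours[[k]])
      if (is.na(pos) || weights[[k]][pos] != weights[[j]][m])
        stop("weight matrix is not symmetric: areas ", ids[j], " and ", ids[k])
    }
  }
  structure(list(n = n, ids = as.character(ids), neighbours = neighbours,
                 weights = weights, kind = kind, band_km = band_km),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cnt <- lengths(x$neighbours)
  cat("Spatial weight matrix (", x$kind,
      if (!is.null(x$band_km)) paste0(", band ", signif(x$band_km, 4), " km"),
      "): ", x$n, " areas, neighbour counts ", min(cnt), "-", max(cnt),
      if (any(cnt == 0L)) paste0(" [", sum(cnt == 0L), " isolated]"), "\n",
      sep = "")
  invisible(x)
}

#' Convert a weight matrix to a dense matrix
#' @param W a `weight_matrix`.
#' @return dense n-by-n numeric matrix with area ids as dimnames.
#' @export
as_dense_matrix <- function(W) {
  m <- matrix(0, W$n, W$n, dimnames = list(W$ids, W$ids))
  for (j in seq_len(W$n))
    m[j, W$neighbours[[j]]] <- W$weights[[j]]
  m
}

#' Queen contiguity weight matrix
#'
#' Two areas are neighbours if their polygons share at least one boundary
#' point or vertex.  Vertices are snapped to a tolerance before comparison,
#' so exact lattices and imperfect real-world coordinates both work.
#'
#' @param areas list of [area_geometry()] objects.
#' @param snap_tol coordinate snapping tolerance (same units as the
#'   coordinates).
#' @return a binary `weight_matrix` of kind `"queen"`.
#' @export
queen_contiguity <- function(areas, snap_tol = 1e-9) {
  if (length(areas) < 2L) stop("at least 2 areas are required")
  ids <- area_ids(areas)
  if (anyDuplicated(ids)) stop("duplicate area_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n <- length(areas)
  # map snapped vertex -> areas touching it
  vert <- new.env(parent = emptyenv(), hash = TRUE)
  for (j in seq_len(n)) {
    keys <- character(0)
    for (r in areas[[j]]$rings) {
      r <- r[-nrow(r), , drop = FALSE]                 # drop closing vertex
      keys <- c(keys, sprintf("%.0f_%.0f", round(r[, 1L] / snap_tol) + 0,
                              round(r[, 2L] / snap_tol) + 0))
    }
    keys <- unique(keys)
    if (length(keys) < 3L)
      stop("degenerate polygon for area ", ids[j], " (<3 distinct vertices)")
    for (k in keys) vert[[k]] <- c(vert[[k]], j)
  }
  nb <- vector("list", n)
  for (k in ls(vert)) {
    touching <- unique(vert[[k]])
    if (length(touching) > 1L)
      for (j in touching) nb[[j]] <- c(nb[[j]], setdiff(touching, j))
  }
  nb <- lapply(nb, function(x) sort(unique(as.integer(x))))
  weight_matrix(ids, nb, kind = "queen")
}

#' Distance-band weight matrix
#'
#' Two areas are neighbours if their centroids lie within `band_km` of each
#' other (planar Euclidean distance on projected coordinates).  Areas with no
#' neighbour are permitted but reported with a warning; the model fitter
#' refuses them unless explicitly overridden.
#'
#' @param areas list of [area_geometry()] objects, or a data.frame with
#'   columns `area_id`, `x_km`, `y_km`.
#' @param band_km positive distance band in km.
#' @return a binary `weight_matrix` of kind `"distance_band"`.
#' @export
distance_band <- function(areas, band_km) {
  stopifnot(is.numeric(band_km), length(band_km) == 1L, band_km > 0)
  cen <- area_centroids(areas)
  if (any(!is.finite(cen))) stop("nonfinite centroid coordinates")
  if (nrow(cen) < 2L) stop("at least 2 areas are required")
  d <- as.matrix(stats::dist(cen))
  nb <- lapply(seq_len(nrow(cen)), function(j)
    which(d[j, ] > 0 & d[j, ] <= band_km & seq_len(ncol(d)) != j))
  W <- weight_matrix(rownames(cen), nb, kind = "distance_band",
                     band_km = band_km)
  iso <- which(lengths(W$neighbours) == 0L)
  if (length(iso) > 0L)
    warning("distance band ", band_km, " km leaves ", length(iso),
            " isolated area(s): ", paste(W$ids[iso], collapse = ", "))
  W
}

#' Smallest distance band connecting every area
#'
#' Returns the maximum over areas of the nearest-neighbour centroid distance.
#' Any band at least this wide gives every area at least one neighbour; any
#' smaller band leaves at least one area isolated.
#'
#' @inheritParams distance_band
#' @return numeric length-1, in km.
#' @export
min_connecting_band <- function(areas) {
  cen <- area_centroids(areas)
  if (nrow(cen) < 2L) stop("at least 2 areas are required")
  d <- as.matrix(stats::dist(cen))
  diag(d) <- Inf
  max(apply(d, 1L, min))
}

#' Summarize neighbour counts of a weight matrix
#'
#' @param W a `weight_matrix`.
#' @return data.frame with mean, median, min, max and (sample) sd of the
#'   per-area neighbour counts.
#' @export
neighbour_summary <- function(W) {
  stopifnot(inherits(W, "weight_matrix"))
  cnt <- lengths(W$neighbours)
  data.frame(kind = W$kind, mean = mean(cnt), median = stats::median(cnt),
             min = min(cnt), max = max(cnt), sd = stats::sd(cnt))
}

#' Connected components of a weight matrix
#'
#' @param W a `weight_matrix`.
#' @return integer vector of component labels, one per area.
#' @export
connected_components <- function(W) {
  comp <- integer(W$n)
  cur <- 0L
  for (start in seq_len(W$n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0L) {
      j <- queue[[1L]]; queue <- queue[-1L]
      for (k in W$neighbours[[j]]) {
        if (comp[k] == 0L) { comp[k] <- cur; queue <- c(queue, k) }
      }
    }
  }
  comp
}
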
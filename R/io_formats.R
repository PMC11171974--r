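#' Read a GAL neighbour-list file
#'
#' Parses the GeoDa GAL exchange dialect: a header line that is either a bare
#' area count `n` or `0 n <name> <id-field>`, then for each area a line
#' `id k` followed by a line of `k` neighbour ids.  The file must describe a
#' symmetric structure (CAR priors require symmetry); asymmetry is an error.
#'
#' @param path path to the GAL file.
#' @return a binary `weight_matrix` of kind `"queen"` provenance unknown
#'   (GAL carries no kind; `"queen"` is recorded as the conventional default
#'   unless overridden via `kind`).
#' @param kind provenance to record, `"queen"` or `"distance_band"`.
#' @export
read_gal <- function(path, kind = "queen") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 1L) stop("GAL parse failure at line 1: empty file")
  hdr <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  n <- if (length(hdr) == 1L) suppressWarnings(as.integer(hdr[1L]))
       else suppressWarnings(as.integer(hdr[2L]))
  if (is.na(n) || n < 1L)
    stop("GAL parse failure at line 1: cannot read area count from header")
  ids <- character(n)
  nb_ids <- vector("list", n)
  ln <- 1L
  for (j in seq_len(n)) {
    ln <- ln + 1L
    if (ln > length(lines)) stop("GAL parse failure at line ", ln,
                                 ": unexpected end of file")
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1L]]
    if (length(tok) != 2L)
      stop("GAL parse failure at line ", ln, ": expected 'id count'")
    ids[j] <- tok[1L]
    k <- suppressWarnings(as.integer(tok[2L]))
    if (is.na(k) || k < 0L)
      stop("GAL parse failure at line ", ln, ": bad neighbour count")
    if (k > 0L) {
      ln <- ln + 1L
      if (ln > length(lines)) stop("GAL parse failure at line ", ln,
                                   ": unexpected end of file")
      nb_ids[[j]] <- strsplit(trimws(lines[[ln]]), "\\s+")[[1L]]
      if (length(nb_ids[[j]]) != k)
        stop("GAL parse failure at line ", ln, ": expected ", k,
             " neighbour ids, found ", length(nb_ids[[j]]))
    } else nb_ids[[j]] <- character(0)
  }
  if (anyDuplicated(ids)) stop("duplicate area ids in GAL file")
  nb <- lapply(nb_ids, function(x) {
    idx <- match(x, ids)
    if (anyNA(idx)) stop("unknown area id referenced in GAL file: ",
                         paste(x[is.na(idx)], collapse = ", "))
    sort(idx)
  })
  # weight_matrix() validates symmetry and raises the CAR-required error
  weight_matrix(ids, nb, kind = kind)
}

#' Write a weight matrix as a GAL file
#'
#' @param W a binary `weight_matrix` (all weights 1; GAL carries none).
#' @param path output path.
#' @export
write_gal <- function(W, path) {
  stopifnot(inherits(W, "weight_matrix"))
  if (any(unlist(W$weights) != 1))
    stop("GAL files carry binary weights only")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("0 %d bymlogit area_id", W$n), con)
  for (j in seq_len(W$n)) {
    writeLines(sprintf("%s %d", W$ids[j], length(W$neighbours[[j]])), con)
    if (length(W$neighbours[[j]]) > 0L)
      writeLines(paste(W$ids[W$neighbours[[j]]], collapse = " "), con)
  }
  invisible(path)
}

#' Read areal polygons from a GeoJSON FeatureCollection
#'
#' Accepts `Polygon` and `MultiPolygon` features; coordinates are taken as
#' already-projected planar km.
#'
#' @param path path to the GeoJSON file.
#' @param id_property feature property holding the area identifier.
#' @return list of [area_geometry()] objects.
#' @export
read_geojson_areas <- function(path, id_property = "area_id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(gj$features, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature without property '", id_property, "'")
    g <- f$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(g$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type '", g$type, "' for area ", id))
    area_geometry(id, rings)
  })
}

#' Write areal polygons as a GeoJSON FeatureCollection
#'
#' @param areas list of [area_geometry()] objects.
#' @param path output path.
#' @param properties optional data.frame of extra feature properties, one row
#'   per area (joined by position).
#' @export
write_geojson_areas <- function(areas, path, properties = NULL) {
  feats <- lapply(seq_along(areas), function(j) {
    a <- areas[[j]]
    props <- list(area_id = a$area_id)
    if (!is.null(properties))
      props <- c(props, as.list(properties[j, , drop = FALSE]))
    list(type = "Feature",
         properties = props,
         geometry = list(
           type = "Polygon",
           coordinates = lapply(a$rings, function(r)
             lapply(seq_len(nrow(r)), function(i) c(r[i, 1L], r[i, 2L])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read area centroids from CSV
#'
#' @param path CSV with columns `area_id`, `x_km`, `y_km`.
#' @return data.frame usable wherever centroid-only geometry suffices
#'   (e.g. [distance_band()], [min_connecting_band()]).
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "x_km", "y_km")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("centroid CSV missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$x_km)) || any(!is.finite(df$y_km)))
    stop("nonfinite centroid coordinates in ", path)
  df
}
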
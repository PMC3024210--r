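#' Construct an area map
#'
#' An `area_map` holds the spatial frame of an aggregated-area disease map:
#' one record per area with a unique id, a planar centroid and a population
#' at risk, plus an optional first-order adjacency structure. All other
#' objects in the package (case vectors, scan results, intensity results)
#' are index-aligned to the area order given here.
#'
#' Centroid coordinates are treated as planar; distances between centroids
#' are Euclidean. Users with longitude/latitude coordinates must project
#' them first.
#'
#' @param id character vector of unique area identifiers.
#' @param x,y numeric centroid coordinates (planar units).
#' @param population nonnegative integer population at risk per area.
#' @param adjacency optional named list mapping each area id to a character
#'   vector of neighbouring ids. Symmetrised and checked; self-edges are an
#'   error.
#' @return An object of class `area_map`: a list with elements `areas`
#'   (data.frame with columns `id`, `x`, `y`, `population`), `adjacency`
#'   (named list or `NULL`) and `total_population`.
#' @examples
#' m <- area_map(c("a", "b"), x = c(0, 1), y = c(0, 0), population = c(10, 20))
#' m$total_population
#' @export
area_map <- function(id, x, y, population, adjacency = NULL) {
  id <- as.character(id)
  K <- length(id)
  if (K < 1) stop("an area map needs at least one area")
  if (anyDuplicated(id)) {
    stop("duplicate area id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(x) != K || length(y) != K || length(population) != K) {
    stop("id, x, y and population must have equal length")
  }
  population <- check_count(population, "population")
  if (sum(population) <= 0) stop("total population must be positive")
  if (anyDuplicated(cbind(x, y))) {
    warning("coincident centroids detected; circular-window ordering will break ties by area index")
  }
  map <- structure(
    list(
      areas = data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                         population = population, stringsAsFactors = FALSE),
      adjacency = NULL,
      total_population = sum(population)
    ),
    class = "area_map"
  )
  if (!is.null(adjacency)) map$adjacency <- validate_adjacency(adjacency, id)
  map
}

#' @export
print.area_map <- function(x, ...) {
  cat("area_map:", nrow(x$areas), "areas, total population",
      format(x$total_population, big.mark = ","), "\n")
  cat("adjacency:", if (is.null(x$adjacency)) "absent" else "present", "\n")
  invisible(x)
}

#' Construct a case vector
#'
#' Per-area observed (or simulated) case counts, index-aligned with a
#' companion [area_map()].
#'
#' @param counts nonnegative integer vector of case counts, one per area in
#'   map order.
#' @param map optional `area_map`; when supplied the length is checked
#'   against the number of areas.
#' @return An object of class `case_vector`: a list with elements `counts`
#'   and `total`.
#' @export
case_vector <- function(counts, map = NULL) {
  counts <- check_count(counts, "cases")
  if (!is.null(map) && length(counts) != nrow(map$areas)) {
    stop("case vector length (", length(counts), ") does not match number of areas (",
         nrow(map$areas), ")")
  }
  structure(list(counts = counts, total = sum(counts)), class = "case_vector")
}

#' @export
print.case_vector <- function(x, ...) {
  cat("case_vector:", length(x$counts), "areas,", x$total, "total cases\n")
  invisible(x)
}

check_count <- function(v, what) {
  v <- as.numeric(v)
  if (anyNA(v)) stop(what, " contains missing values")
  bad <- which(v < 0 | v != floor(v))
  if (length(bad)) {
    stop(what, " must be a nonnegative integer (row ", bad[1], ": ", v[bad[1]], ")")
  }
  as.integer(round(v))
}

validate_adjacency <- function(adjacency, ids) {
  if (!is.list(adjacency)) stop("adjacency must be a named list")
  unknown <- setdiff(names(adjacency), ids)
  if (length(unknown)) stop("adjacency references unknown area id(s): ",
                            paste(unknown, collapse = ", "))
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) out[[i]] <- character(0)
  for (a in names(adjacency)) {
    nb <- as.character(adjacency[[a]])
    unknown <- setdiff(nb, ids)
    if (length(unknown)) stop("adjacency references unknown area id(s): ",
                              paste(unknown, collapse = ", "))
    if (a %in% nb) stop("self-adjacency for area ", a)
    out[[a]] <- union(out[[a]], nb)
    for (b in nb) out[[b]] <- union(out[[b]], a)  # symmetrise
  }
  lapply(out, sort)
}

#' Read an area table
#'
#' Reads a CSV with one row per area and columns `id`, `x`, `y`,
#' `population`, `cases` (extra columns are ignored). Row order becomes the
#' area order. Lines starting with `#` are treated as comments.
#'
#' @param path path to the CSV file.
#' @return A list with elements `map` (an [area_map()]) and `cases`
#'   (a [case_vector()]).
#' @export
read_area_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("id", "x", "y", "population", "cases")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("area table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  map <- area_map(tab$id, tab$x, tab$y, tab$population)
  list(map = map, cases = case_vector(tab$cases, map))
}

#' Write an area table
#'
#' Inverse of [read_area_table()]: writes `id,x,y,population,cases` so that
#' reading the file back reproduces the map and cases exactly.
#'
#' @param map an [area_map()].
#' @param cases a [case_vector()] aligned with `map`.
#' @param path output CSV path.
#' @param header optional character vector written as leading `#` comment
#'   lines (e.g. the generating seed).
#' @return `path`, invisibly.
#' @export
write_area_table <- function(map, cases, path, header = NULL) {
  tab <- map$areas
  tab$cases <- cases$counts
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach first-order adjacency to a map
#'
#' First-order neighbourhoods are required by the local empirical-Bayes
#' smoother. They can come from an edge-list file (two columns of area ids;
#' orientation is ignored and edges are symmetrised) or, when no polygon or
#' edge information exists, from a Delaunay triangulation of the centroids —
#' the standard fallback for deriving contiguity from points.
#'
#' @param map an [area_map()].
#' @param method `"file"` (requires `edges`) or `"delaunay"`.
#' @param edges for `method = "file"`: either a path to a two-column CSV
#'   (header `id_a,id_b`) or a two-column data.frame/matrix of ids.
#' @return `map` with its `adjacency` field populated.
#' @export
build_adjacency <- function(map, method = c("file", "delaunay"), edges = NULL) {
  method <- match.arg(method)
  ids <- map$areas$id
  if (method == "file") {
    if (is.null(edges)) stop("method = \"file\" requires `edges`")
    if (is.character(edges) && length(edges) == 1) {
      edges <- utils::read.csv(edges, stringsAsFactors = FALSE, comment.char = "#")
    }
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2) stop("edge list must have two id columns")
    adj <- split(as.character(edges[[2]]), as.character(edges[[1]]))
  } else {
    if (nrow(map$areas) < 3) stop("Delaunay adjacency needs at least 3 areas")
    if (!requireNamespace("deldir", quietly = TRUE)) {
      stop("package 'deldir' is required for method = \"delaunay\"")
    }
    tri <- deldir::deldir(map$areas$x, map$areas$y, suppressMsge = TRUE)
    adj <- split(ids[tri$delsgs$ind2], ids[tri$delsgs$ind1])
  }
  map$adjacency <- validate_adjacency(adj, ids)
  map
}

#' Neighbour index sets
#'
#' @param map an `area_map` with adjacency attached.
#' @param include_self include the area itself in its neighbourhood
#'   (the convention used by the local smoother).
#' @return list of integer index vectors, one per area.
#' @keywords internal
neighbour_indices <- function(map, include_self = TRUE) {
  if (is.null(map$adjacency)) stop("map has no adjacency; call build_adjacency() first")
  ids <- map$areas$id
  lapply(seq_along(ids), function(i) {
    nb <- match(map$adjacency[[ids[i]]], ids)
    if (include_self) nb <- c(i, nb)
    sort(nb)
  })
}

#' Write a per-area intensity table
#'
#' Writes `id,q,quantile_class` for every area. `q` is printed with six
#' fixed decimals (its exact values are multiples of 1/m, so this is lossless
#' for any practical replicate count when compared after identical rounding).
#'
#' @param result an `intensity_result` from [intensity_bounds()].
#' @param map the companion [area_map()].
#' @param path output CSV path.
#' @param levels shading breakpoints passed to [quantile_shading()].
#' @param header optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(result, map, path,
                                  levels = c(0.90, 0.95, 0.99, 1.0),
                                  header = NULL) {
  cls <- quantile_shading(result$q, levels)
  tab <- data.frame(id = map$areas$id,
                    q = sprintf("%.6f", result$q),
                    quantile_class = cls)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write intensity results as GeoJSON
#'
#' Emits a FeatureCollection with one feature per area carrying `id`, `q`
#' and `quantile_class` properties. When `polygons` supplies a coordinate
#' ring per area id the features are Polygons; otherwise each feature is a
#' Point at the area centroid.
#'
#' @param result an `intensity_result`.
#' @param map the companion [area_map()].
#' @param path output path.
#' @param levels shading breakpoints passed to [quantile_shading()].
#' @param polygons optional named list: for each area id a two-column
#'   matrix of ring coordinates (closed or open; closed automatically).
#' @return `path`, invisibly.
#' @export
write_intensity_geojson <- function(result, map, path,
                                    levels = c(0.90, 0.95, 0.99, 1.0),
                                    polygons = NULL) {
  cls <- quantile_shading(result$q, levels)
  feats <- lapply(seq_len(nrow(map$areas)), function(i) {
    id <- map$areas$id[i]
    if (!is.null(polygons) && !is.null(polygons[[id]])) {
      ring <- as.matrix(polygons[[id]])
      if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      geom <- list(type = "Polygon",
                   coordinates = list(lapply(seq_len(nrow(ring)),
                                             function(r) unname(ring[r, ]))))
    } else {
      geom <- list(type = "Point",
                   coordinates = c(map$areas$x[i], map$areas$y[i]))
    }
    list(type = "Feature",
         geometry = geom,
         properties = list(id = id, q = result$q[i], quantile_class = cls[i]))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
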
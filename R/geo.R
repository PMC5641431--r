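EARTH_RADIUS_KM <- 6371.0088 # mean Earth radius

#' Locality records
#'
#' Validates a table of species occurrence points (decimal degrees, WGS84).
#' @param df data frame with columns `species`, `latitude`, `longitude`
#'   (aliases `decimal_latitude`/`decimal_longitude` accepted).
#' @return a tibble of validated records.
#' @export
locality_records <- function(df) {
  nm <- names(df)
  lat <- df[[intersect(c("latitude", "decimal_latitude", "lat"), nm)[1]]]
  lon <- df[[intersect(c("longitude", "decimal_longitude", "lon"), nm)[1]]]
  out <- tibble::tibble(species = as.character(df$species),
                        latitude = as.numeric(lat),
                        longitude = as.numeric(lon))
  if (any(is.na(out$latitude)) || any(is.na(out$longitude))) {
    stop("missing coordinates")
  }
  if (any(abs(out$latitude) > 90) || any(abs(out$longitude) > 180)) {
    stop("coordinates outside WGS84 bounds")
  }
  out
}

#' @rdname locality_records
#' @param path CSV file with the same columns.
#' @export
read_localities <- function(path) {
  locality_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Spherical centroid of a set of localities
#'
#' Normalized mean of the unit vectors of the points on the sphere,
#' converted back to latitude/longitude — robust near the antimeridian,
#' unlike a naive mean of coordinates.
#'
#' @param lat,lon decimal-degree coordinates.
#' @return named numeric `c(latitude, longitude)`.
#' @export
sphere_centroid <- function(lat, lon) {
  stopifnot(length(lat) >= 1, length(lat) == length(lon))
  la <- lat * pi / 180; lo <- lon * pi / 180
  v <- c(mean(cos(la) * cos(lo)), mean(cos(la) * sin(lo)), mean(sin(la)))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate (antipodal) centroid")
  v <- v / nv
  c(latitude = asin(v[3]) * 180 / pi,
    longitude = atan2(v[2], v[1]) * 180 / pi)
}

#' Species centroids from locality records
#' @param records a [locality_records] tibble.
#' @return tibble of species, latitude, longitude.
#' @export
species_centroids <- function(records) {
  records <- locality_records(records)
  dplyr::bind_rows(lapply(split(records, records$species), function(d) {
    ct <- sphere_centroid(d$latitude, d$longitude)
    tibble::tibble(species = d$species[1], latitude = ct[[1]],
                   longitude = ct[[2]])
  }))
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km.
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectorized).
#' @return distance in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Pairwise great-circle distance matrix
#' @param centroids tibble with `species` (or other label), `latitude`,
#'   `longitude`.
#' @param label column used for row/col names.
#' @return symmetric matrix of km distances, zero diagonal.
#' @export
distance_matrix_km <- function(centroids, label = 1) {
  labs <- as.character(centroids[[label]])
  n <- nrow(centroids)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    D[i, ] <- great_circle_km(centroids$latitude[i], centroids$longitude[i],
                              centroids$latitude, centroids$longitude)
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Region maps
#'
#' A named list of simple polygons in lon/lat used to group species by the
#' ecoregion containing their centroid. Polygons are data frames with
#' columns `longitude`, `latitude` (closed implicitly).
#'
#' @param polygons named list of polygon data frames.
#' @return an object of class `region_map`.
#' @export
region_map <- function(polygons) {
  if (is.null(names(polygons)) || anyDuplicated(names(polygons))) {
    stop("region polygons must have unique names")
  }
  polygons <- lapply(polygons, function(p) {
    p <- as.data.frame(p)
    if (!all(c("longitude", "latitude") %in% names(p))) {
      names(p)[1:2] <- c("longitude", "latitude")
    }
    p
  })
  structure(polygons, class = "region_map")
}

#' Read a region map from GeoJSON
#'
#' Supports FeatureCollections of simple (single-ring) Polygon features;
#' the feature property `name` labels each region.
#' @param path GeoJSON file.
#' @return a [region_map].
#' @export
read_regions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  polys <- list()
  for (f in feats) {
    nm <- f$properties$name
    ring <- f$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    polys[[nm]] <- data.frame(longitude = xy[, 1], latitude = xy[, 2])
  }
  region_map(polys)
}

#' Assign a point to a region
#'
#' Returns the name of the containing polygon; points on a shared boundary
#' go to the lexicographically first matching region (a deterministic
#' tie-break), and points outside every polygon fall back to the region
#' with the nearest boundary vertex, flagged via the `fallback` attribute
#' and a message.
#'
#' @param lat,lon point coordinates.
#' @param regions a [region_map].
#' @param quiet suppress the fallback message.
#' @return region name (attribute `fallback` = TRUE when outside all).
#' @export
assign_region <- function(lat, lon, regions, quiet = FALSE) {
  if (!length(regions)) stop("empty region map")
  hits <- character(0)
  for (nm in sort(names(regions))) {
    p <- regions[[nm]]
    inside <- sp::point.in.polygon(lon, lat, p$longitude, p$latitude)
    if (inside > 0) hits <- c(hits, nm)
  }
  if (length(hits)) return(hits[1])
  # nearest boundary vertex fallback
  dmin <- vapply(names(regions), function(nm) {
    p <- regions[[nm]]
    min(great_circle_km(lat, lon, p$latitude, p$longitude))
  }, numeric(1))
  nm <- names(regions)[which.min(dmin)]
  if (!quiet) message(sprintf("point (%.3f, %.3f) outside all regions; assigned to nearest '%s'", lat, lon, nm))
  structure(nm, fallback = TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with the Q criterion
#' `Q_ij = (n-2) d_ij - sum_k d_ik - sum_k d_jk`; ties broken by the lowest
#' index pair. Negative branch-length estimates are clamped to zero with
#' the deficit transferred to the sibling edge, preserving path lengths.
#'
#' @param D symmetric distance matrix with labelled rows (or a `dist`).
#' @return an unrooted [ape::phylo] tree (a star for 3 labels).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 labels")
  if (max(abs(D - t(D))) > 1e-6) stop("distance matrix is not symmetric")
  labs <- rownames(D)
  n0 <- nrow(D)
  # active nodes: newick fragments + current distance matrix
  frag <- labs
  act <- seq_len(n0)
  while (length(act) > 3) {
    n <- length(act)
    Dm <- D[act, act]
    rs <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(rs, rs, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    ij <- best[1, ]; i <- min(ij); j <- max(ij)
    dij <- Dm[i, j]
    li <- dij / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[act[i]], li,
                       frag[act[j]], lj)
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    u <- act[i]
    D[u, act] <- dnew; D[act, u] <- dnew; D[u, u] <- 0
    frag[u] <- newfrag
    act <- act[-j]
  }
  Dm <- D[act, act]
  l1 <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  l2 <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  l3 <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  l <- pmax(c(l1, l2, l3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[act[1]], l[1], frag[act[2]], l[2], frag[act[3]], l[3])
  ape::read.tree(text = nwk)
}

#' Ecoregion distance tree and constraints
#'
#' The geographic hypothesis pipeline: species centroids are assigned to
#' regions; a great-circle distance matrix between region centroids (the
#' spherical centroid of member-species centroids) is built and summarized
#' by neighbor joining; and each region occupied by two or more species
#' becomes a monophyly constraint (regions are disjoint, so the constraints
#' are always compatible).
#'
#' @param records a [locality_records] tibble.
#' @param regions a [region_map].
#' @param name constraint-set name (default `"EDT"`).
#' @return list with `tree` (NJ tree over regions), `constraints`
#'   (a [constraint_set] over species), `assignments` (tibble of species,
#'   region, fallback flag) and `region_centroids`.
#' @export
ecoregion_distance_tree <- function(records, regions, name = "EDT") {
  cen <- species_centroids(records)
  asg <- vapply(seq_len(nrow(cen)), function(i) {
    as.character(assign_region(cen$latitude[i], cen$longitude[i], regions,
                               quiet = TRUE))
  }, character(1))
  fb <- vapply(seq_len(nrow(cen)), function(i) {
    isTRUE(attr(assign_region(cen$latitude[i], cen$longitude[i], regions,
                              quiet = TRUE), "fallback"))
  }, logical(1))
  assignments <- tibble::tibble(species = cen$species, region = asg,
                                fallback = fb)
  occ <- unique(asg)
  if (length(occ) < 3) stop("fewer than 3 occupied regions: NJ undefined")
  rc <- dplyr::bind_rows(lapply(occ, function(r) {
    sub <- cen[asg == r, ]
    ct <- sphere_centroid(sub$latitude, sub$longitude)
    tibble::tibble(region = r, latitude = ct[1], longitude = ct[2])
  }))
  D <- distance_matrix_km(rc, label = "region")
  tree <- nj_tree(D)
  sets <- lapply(occ, function(r) cen$species[asg == r])
  sets <- sets[lengths(sets) >= 2]
  cs <- constraint_set(sets, name = name, taxa = cen$species)
  list(tree = tree, constraints = cs, assignments = assignments,
       region_centroids = rc)
}

#' Range area of a species from its localities
#'
#' Area of the convex hull of the collection sites, measured after an
#' azimuthal equal-area projection about the species centroid (so the value
#' is faithful to areas on the sphere); fewer than three distinct points
#' give 0.
#'
#' @param lat,lon locality coordinates of one species.
#' @return area in square kilometres.
#' @export
range_area_km2 <- function(lat, lon) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3) return(0)
  ct <- sphere_centroid(pts[, 2], pts[, 1])
  # Lambert azimuthal equal-area about the centroid
  la0 <- ct[1] * pi / 180; lo0 <- ct[2] * pi / 180
  la <- pts[, 2] * pi / 180; lo <- pts[, 1] * pi / 180
  denom <- 1 + sin(la0) * sin(la) + cos(la0) * cos(la) * cos(lo - lo0)
  kk <- sqrt(2 / denom)
  x <- EARTH_RADIUS_KM * kk * cos(la) * sin(lo - lo0)
  y <- EARTH_RADIUS_KM * kk * (cos(la0) * sin(la) -
                                 sin(la0) * cos(la) * cos(lo - lo0))
  h <- grDevices::chull(x, y)
  xs <- x[h]; ys <- y[h]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

#' Short-range endemism class of a range area
#'
#' Micro-range endemic (MRE) below 1,000 km2; short-range endemic (SRE)
#' below 10,000 km2 (strict "less than"); otherwise widespread. MREs also
#' qualify as SREs in summary counts (the classes nest).
#'
#' @param area_km2 range area (>= 0), vectorized.
#' @return character vector in `{"MRE", "SRE", "widespread"}`.
#' @export
endemism_class <- function(area_km2) {
  stopifnot(all(area_km2 >= 0))
  ifelse(area_km2 < 1000, "MRE",
         ifelse(area_km2 < 10000, "SRE", "widespread"))
}

#' Endemism table over species
#'
#' @param records a [locality_records] tibble.
#' @return tibble of species, range area, class, and `sre_qualifying`
#'   (TRUE for both SRE and MRE, since MREs nest within SREs).
#' @export
endemism_table <- function(records) {
  records <- locality_records(records)
  dplyr::mutate(
    dplyr::summarise(dplyr::group_by(records, .data$species),
                     area_km2 = range_area_km2(.data$latitude, .data$longitude),
                     .groups = "drop"),
    class = endemism_class(.data$area_km2),
    sre_qualifying = .data$area_km2 < 10000)
}
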
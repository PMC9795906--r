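#' The nine default biogeographic area codes
#'
#' Andes (And), Central America/Caribbean (CAm), Patagonia (Pat), tropical
#' South America (TSA), Afrotropics (Afr), Australasia with Oceania (Aus),
#' Indomalaya (Ind), Nearctic (Nea), Palaearctic (Pal). The first four are
#' the neotropical focal areas.
#' @export
default_area_codes <- function() {
  c("And", "CAm", "Pat", "TSA", "Afr", "Aus", "Ind", "Nea", "Pal")
}

#' Focal areas of the default scheme
#' @export
default_focal_areas <- function() c("And", "CAm", "Pat", "TSA")

#' Build an area scheme
#'
#' An area scheme couples the area codes, one (multi)polygon per area, and a
#' country -> area-set lookup table. Countries mapping to more than one area
#' are deliberately ambiguous and never resolve by the country route.
#'
#' @param codes character vector of unique area codes.
#' @param polygons named list (by code): each a multipolygon, i.e. a list of
#'   polygons, each a list of rings, each ring an n x 2 matrix of (lon, lat)
#'   with first ring the outer boundary. May be `NULL` for code-only schemes.
#' @param country_table named list: country -> character vector of codes.
#' @export
area_scheme <- function(codes, polygons = NULL, country_table = list()) {
  if (anyDuplicated(codes)) stop("area codes must be unique", call. = FALSE)
  if (!is.null(polygons)) {
    bad <- setdiff(names(polygons), codes)
    if (length(bad)) stop("polygons for unknown codes: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (code in names(polygons)) {
      for (poly in polygons[[code]]) for (ring in poly) {
        if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4 ||
            any(ring[1, ] != ring[nrow(ring), ])) {
          stop("invalid (unclosed) ring in polygon for area ", code, call. = FALSE)
        }
      }
    }
  }
  bad <- setdiff(unique(unlist(country_table)), codes)
  if (length(bad)) stop("country table refers to unknown codes: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(codes = codes, polygons = polygons,
                 country_table = country_table),
            class = "area_scheme")
}

#' Read an area scheme from GeoJSON (+ optional country table YAML)
#'
#' The GeoJSON must be a FeatureCollection of Polygon/MultiPolygon features
#' with an `area` property holding the code. The country table YAML maps
#' country names to one code or a list of codes.
#'
#' @param geojson_path path to the FeatureCollection.
#' @param country_yaml optional YAML path.
#' @export
read_area_scheme <- function(geojson_path, country_yaml = NULL) {
  gj <- jsonlite::read_json(geojson_path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  polys <- list()
  for (f in gj$features) {
    code <- f$properties$area
    if (is.null(code)) stop("feature without an 'area' property", call. = FALSE)
    g <- f$geometry
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    mp <- switch(g$type,
      Polygon = list(lapply(g$coordinates, ring_mat)),
      MultiPolygon = lapply(g$coordinates, function(p) lapply(p, ring_mat)),
      stop("unsupported geometry type: ", g$type, call. = FALSE))
    polys[[code]] <- c(polys[[code]], mp)
  }
  ctab <- list()
  if (!is.null(country_yaml)) {
    ctab <- lapply(yaml::read_yaml(country_yaml), function(x) as.character(unlist(x)))
  }
  area_scheme(names(polys), polys, ctab)
}

#' The default (synthetic) area scheme shipped with the package
#'
#' Nine rectangles standing in for the real merged-ecoregion polygons, which
#' are not redistributable here; suitable for tests and as a format example,
#' not for real-world assignment. The country table covers the countries
#' used in the package's examples.
#' @export
default_area_scheme <- function() {
  read_area_scheme(
    system.file("extdata", "areas_synthetic.geojson", package = "mkareas"),
    system.file("extdata", "countries.yaml", package = "mkareas"))
}

# even-odd ray casting; points exactly on a boundary count as inside
point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring) - 1   # last vertex repeats the first
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    # on-segment check (closed contains)
    if (on_segment(lon, lat, x1, y1, x2, y2)) return(NA)  # boundary marker
    if ((y1 > lat) != (y2 > lat)) {
      xint <- x1 + (lat - y1) / (y2 - y1) * (x2 - x1)
      if (lon < xint) inside <- !inside
    }
  }
  inside
}

on_segment <- function(px, py, x1, y1, x2, y2, tol = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > tol * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  px >= min(x1, x2) - tol && px <= max(x1, x2) + tol &&
    py >= min(y1, y2) - tol && py <= max(y1, y2) + tol
}

#' Point-in-area test
#'
#' Even--odd rule over all rings of the area's multipolygon; points exactly
#' on any boundary belong to the polygon (closed contains).
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param multipolygon an area's polygon list as in [area_scheme()].
#' @export
point_in_area <- function(lon, lat, multipolygon) {
  for (poly in multipolygon) {
    parity <- FALSE
    boundary <- FALSE
    for (ring in poly) {
      r <- point_in_ring(lon, lat, ring)
      if (is.na(r)) { boundary <- TRUE; break }
      parity <- xor(parity, r)
    }
    if (boundary || parity) return(TRUE)
  }
  FALSE
}

#' Assign one sequence record to an area
#'
#' The assignment cascade: (1) if the record's country maps to exactly one
#' area, that area (provenance `"country"`); (2) else if coordinates are
#' present and fall in exactly one area polygon, that area
#' (`"coordinates"`); (3) else if a manual area code is present, that area
#' (`"manual"`); (4) else no assignment (`"none"`). Coordinates inside more
#' than one polygon (overlapping scheme) are an error naming the areas;
#' coordinates in no polygon fall through to (3).
#'
#' @param record one metadata row (list or single-row data.frame).
#' @param scheme an [area_scheme()].
#' @return `list(area = code or NA, provenance = one of
#'   "country","coordinates","manual","none")`.
#' @export
assign_sequence <- function(record, scheme) {
  country <- record$country
  if (!is.null(country) && length(country) && !is.na(country)) {
    areas <- scheme$country_table[[country]]
    if (length(areas) == 1) {
      return(list(area = areas, provenance = "country"))
    }
  }
  lat <- record$lat; lon <- record$lon
  if (!is.null(lat) && length(lat) && !is.na(lat) && !is.na(lon) &&
      !is.null(scheme$polygons)) {
    hits <- names(scheme$polygons)[vapply(scheme$polygons, function(mp)
      point_in_area(lon, lat, mp), logical(1))]
    if (length(hits) == 1) {
      return(list(area = hits, provenance = "coordinates"))
    }
    if (length(hits) > 1) {
      stop("coordinates (", lon, ", ", lat, ") fall in overlapping areas: ",
           paste(hits, collapse = ", "), call. = FALSE)
    }
  }
  manual <- record$manual_area
  if (!is.null(manual) && length(manual) && !is.na(manual)) {
    if (!manual %in% scheme$codes) {
      stop("manual area code not in scheme: ", manual, call. = FALSE)
    }
    return(list(area = manual, provenance = "manual"))
  }
  list(area = NA_character_, provenance = "none")
}

#' Assign all metadata records
#'
#' @param metadata data.frame from [read_metadata()].
#' @param scheme an [area_scheme()].
#' @return the metadata with `area` and `provenance` columns appended.
#' @export
assign_sequences <- function(metadata, scheme) {
  res <- lapply(seq_len(nrow(metadata)), function(i)
    assign_sequence(metadata[i, ], scheme))
  metadata$area <- vapply(res, function(x) x$area, "")
  metadata$provenance <- vapply(res, function(x) x$provenance, "")
  metadata
}

#' Union member-sequence areas into OTU area sets, honouring overrides
#'
#' The OTU's area set is the union of its member sequences' assigned areas.
#' Introduced occurrences are removed via `overrides`, a data.frame of
#' `(otu_id, area)` rows; overriding an area absent from the union warns
#' (and does nothing). Removed areas are reported in `ignored`.
#'
#' @param assigned metadata with `otu_id` and `area` (from [assign_sequences()]).
#' @param overrides optional data.frame with `otu_id`, `area`.
#' @return named list by OTU: `list(areas = character set, ignored = character)`.
#' @export
assign_otu <- function(assigned, overrides = NULL) {
  sp <- split(assigned$area, assigned$otu_id)
  out <- lapply(sp, function(a) {
    list(areas = sort(unique(a[!is.na(a)])), ignored = character(0))
  })
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      otu <- as.character(overrides$otu_id[i]); ar <- overrides$area[i]
      if (!otu %in% names(out)) { warning("override for unknown OTU ", otu); next }
      if (!ar %in% out[[otu]]$areas) {
        warning("override area ", ar, " not present in OTU ", otu)
        next
      }
      out[[otu]]$areas <- setdiff(out[[otu]]$areas, ar)
      out[[otu]]$ignored <- c(out[[otu]]$ignored, ar)
    }
  }
  out
}

#' Per-area counts of sequences and OTUs
#'
#' Percentages are computed over the total number of sequences/OTUs
#' (including unassigned), so OTU percentages may sum to more than 100%
#' because one OTU can occur in several areas.
#'
#' @param assigned metadata with `area` (sequence level).
#' @param otus output of [assign_otu()].
#' @param codes area codes to tabulate (default: those present).
#' @return data.frame `area`, `n_sequences`, `pct_sequences`, `n_otus`, `pct_otus`
#'   with an `Unassigned` row.
#' @export
area_summary <- function(assigned, otus, codes = NULL) {
  if (is.null(codes)) {
    codes <- sort(unique(c(assigned$area[!is.na(assigned$area)],
                           unlist(lapply(otus, `[[`, "areas")))))
  }
  n_seq_tot <- nrow(assigned); n_otu_tot <- length(otus)
  rows <- lapply(codes, function(a) {
    ns <- sum(!is.na(assigned$area) & assigned$area == a)
    no <- sum(vapply(otus, function(o) a %in% o$areas, logical(1)))
    data.frame(area = a, n_sequences = ns,
               pct_sequences = if (n_seq_tot) 100 * ns / n_seq_tot else 0,
               n_otus = no,
               pct_otus = if (n_otu_tot) 100 * no / n_otu_tot else 0)
  })
  ns_un <- sum(is.na(assigned$area))
  no_un <- sum(vapply(otus, function(o) length(o$areas) == 0, logical(1)))
  rows <- c(rows, list(data.frame(
    area = "Unassigned", n_sequences = ns_un,
    pct_sequences = if (n_seq_tot) 100 * ns_un / n_seq_tot else 0,
    n_otus = no_un, pct_otus = if (n_otu_tot) 100 * no_un / n_otu_tot else 0)))
  do.call(rbind, rows)
}

#' Shared-OTU counts between areas
#'
#' Cell (i, j) counts OTUs whose area set contains both i and j; the
#' diagonal counts OTUs containing i. Symmetric by construction.
#'
#' @param otus output of [assign_otu()].
#' @param codes area codes for the matrix axes.
#' @export
otu_overlap <- function(otus, codes = NULL) {
  if (is.null(codes)) codes <- sort(unique(unlist(lapply(otus, `[[`, "areas"))))
  m <- matrix(0L, length(codes), length(codes), dimnames = list(codes, codes))
  for (o in otus) {
    a <- intersect(o$areas, codes)
    if (length(a)) m[a, a] <- m[a, a] + 1L
  }
  m
}
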
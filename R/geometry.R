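# Spatial geometry: hexagon layout, cross-modality region masks, mm/degree
# conversion and ganglion-cell displacement.
#
# Coordinate convention: visual-field degrees, fovea at the origin, right-eye
# orientation. Left eyes are mirrored about the vertical axis on ingest.

#' Build the hexagonal stimulus layout
#'
#' Constructs the stimulus hexagon layout covering the central retina. The
#' shipped preset \code{"veris103"} is a 103-hexagon array: the full
#' hexagonal rings 0-5 (91 elements) plus the 12 ring-6 elements closest to
#' fixation, scaled to a 47-degree overall diameter. Hexagon areas grow with
#' eccentricity by \code{eccentricityScaling} per ring, emulating
#' eccentricity-scaled stimuli that roughly equalize per-hexagon response
#' amplitude.
#'
#' This is a generic scaled array, not a replication of any device's
#' proprietary hexagon geometry.
#'
#' @param preset layout name; only \code{"veris103"} is shipped. Alternatively
#'   pass a data.frame with columns \code{x_deg, y_deg, ring} (and optionally
#'   \code{area_scale}) to define a custom grid.
#' @param eccentricityScaling per-ring area growth factor (> 0; 1 = uniform).
#' @param diameterDeg overall layout diameter in degrees (default 47).
#' @return a \linkS4class{HexLayout}
#' @examples
#' layout <- buildHexLayout()
#' nHexagons(layout)  # 103
#' @export
buildHexLayout <- function(preset = "veris103", eccentricityScaling = 1.6,
                           diameterDeg = 47) {
  if (is.data.frame(preset)) {
    req <- c("x_deg", "y_deg", "ring")
    if (!all(req %in% names(preset)))
      stop("custom grid needs columns x_deg, y_deg, ring")
    centers <- as.matrix(preset[, c("x_deg", "y_deg")])
    colnames(centers) <- c("x_deg", "y_deg")
    ring <- as.integer(preset$ring)
    areas <- if ("area_scale" %in% names(preset)) preset$area_scale
             else eccentricityScaling^ring
    return(new("HexLayout", centers = centers, areas = areas, ring = ring,
               preset = "custom"))
  }
  if (!identical(preset, "veris103"))
    stop("unknown layout preset: ", preset)
  if (eccentricityScaling <= 0) stop("eccentricityScaling must be positive")

  grid <- hexGrid(6L)
  keep5 <- grid$ring <= 5L
  ring6 <- grid[grid$ring == 6L, ]
  # 12 ring-6 hexagons closest to fixation; ties resolved toward the
  # horizontal meridian, then by angle (deterministic).
  ord <- order(round(ring6$radius, 9), round(abs(ring6$y), 9),
               atan2(ring6$y, ring6$x))
  sel <- rbind(grid[keep5, ], ring6[ord[1:12], ])

  scale <- (diameterDeg / 2) / max(sel$radius)
  centers <- cbind(x_deg = sel$x * scale, y_deg = sel$y * scale)
  new("HexLayout", centers = centers,
      areas = eccentricityScaling^sel$ring / 1,
      ring = as.integer(sel$ring), preset = "veris103")
}

# Hexagonal grid in axial coordinates out to maxRing, on a unit lattice.
hexGrid <- function(maxRing) {
  q <- r <- integer()
  for (qq in -maxRing:maxRing) for (rr in -maxRing:maxRing) {
    if (abs(qq + rr) <= maxRing) { q <- c(q, qq); r <- c(r, rr) }
  }
  ring <- pmax(abs(q), abs(r), abs(q + r))
  keep <- ring <= maxRing
  q <- q[keep]; r <- r[keep]; ring <- ring[keep]
  x <- q + r / 2
  y <- r * sqrt(3) / 2
  data.frame(q = q, r = r, ring = ring, x = x, y = y,
             radius = sqrt(x^2 + y^2))
}

#' Central-hexagon region mask
#'
#' Selects the hexagons with ring index at most \code{nRings}: the central 7
#' hexagons for \code{nRings = 1} (the 10-degree analysis region) and the
#' central 19 hexagons for \code{nRings = 2} (the 15-degree region).
#'
#' @param layout a \linkS4class{HexLayout}
#' @param nRings integer, 0 to the layout's maximum ring
#' @return a \linkS4class{RegionMask} of modality \code{"mfERG"}
#' @examples
#' layout <- buildHexLayout()
#' length(memberIds(centralHexagons(layout, 1)))  # 7
#' length(memberIds(centralHexagons(layout, 2)))  # 19
#' @export
centralHexagons <- function(layout, nRings) {
  stopifnot(is(layout, "HexLayout"))
  nRings <- as.integer(nRings)
  if (nRings < 0L || nRings > max(layout@ring))
    stop("nRings out of range [0, ", max(layout@ring), "]")
  ids <- which(layout@ring <= nRings)
  label <- if (nRings == 1L) "central10"
           else if (nRings == 2L) "central15"
           else sprintf("rings0-%d", nRings)
  new("RegionMask", modality = "mfERG", memberIds = as.integer(ids),
      label = label)
}

#' Convert a retinal length to visual angle
#'
#' Linear small-angle conversion from mm on the retina to degrees of visual
#' field. The default factor of 3.3 deg/mm maps the 4.0 x 4.8 mm GCIPL
#' annulus diameters to 13.2 and 15.8 degrees.
#'
#' @param lengthMm length on the retina, mm (>= 0)
#' @param factor degrees per mm (> 0)
#' @return degrees
#' @examples
#' mmToDegrees(4.0)  # 13.2
#' mmToDegrees(4.8)  # 15.84
#' @export
mmToDegrees <- function(lengthMm, factor = 3.3) {
  if (factor <= 0) stop("conversion factor must be positive")
  if (any(lengthMm < 0)) stop("length must be >= 0")
  lengthMm * factor
}

#' Foveal ganglion-cell displacement
#'
#' Centrifugal displacement of retinal ganglion cell bodies relative to their
#' receptive fields, as a function of receptive-field eccentricity. The curve
#' is piecewise linear through the anchors (1 mm, 0.62 mm) and
#' (4 mm, 0.12 mm), held constant at 0.62 mm inside 1 mm and at 0.12 mm
#' beyond 4 mm.
#'
#' @param eccentricityMm eccentricity from the foveola, mm (>= 0); vectorized
#' @return displacement in mm (non-negative, non-increasing on [1, 4] mm)
#' @examples
#' drasdoDisplacement(c(1, 2.5, 4))  # 0.62 0.37 0.12
#' @export
drasdoDisplacement <- function(eccentricityMm) {
  if (any(eccentricityMm < 0)) stop("eccentricity must be >= 0")
  d <- 0.62 + (pmin(pmax(eccentricityMm, 1), 4) - 1) / (4 - 1) * (0.12 - 0.62)
  d
}

#' Default perimetry point table
#'
#' A symmetric test-point grid for the central visual field: nine points per
#' quadrant inside ~11 degrees plus one point per quadrant near 13.4 degrees.
#' The four outer points are the shipped "additional points" that extend the
#' central-10-degree set to the 15-degree set matched to the GCIPL annulus;
#' their ids are carried in the \code{"additional15"} attribute and can be
#' overridden in \code{\link{selectSapPoints}}.
#'
#' @return data.frame with columns \code{point_id, x_deg, y_deg} and
#'   attribute \code{additional15}
#' @export
sapPointTable <- function() {
  base <- rbind(c(1.5, 1.5), c(4.5, 1.5), c(1.5, 4.5), c(4.5, 4.5),
                c(7.5, 1.5), c(1.5, 7.5), c(7.5, 4.5), c(4.5, 7.5),
                c(7.5, 7.5))
  quad <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  pts <- do.call(rbind, lapply(seq_len(4), function(qi)
    cbind(base[, 1] * quad[qi, 1], base[, 2] * quad[qi, 2])))
  extra <- cbind(9.5 * quad[, 1], 9.5 * quad[, 2])
  all <- rbind(pts, extra)
  tab <- data.frame(point_id = seq_len(nrow(all)),
                    x_deg = all[, 1], y_deg = all[, 2])
  attr(tab, "additional15") <- seq_len(nrow(all))[-(1:nrow(pts))]
  tab
}

#' Select perimetry points for a central analysis region
#'
#' \code{central10}: points whose eccentricity, after ganglion-cell
#' displacement correction, is at most 10 degrees. \code{central15}: the
#' central-10 set plus exactly four configured additional points, matching
#' the slightly larger GCIPL annulus. The displacement correction moves each
#' test point outward to the retinal location of the ganglion cells it
#' stimulates (\code{\link{drasdoDisplacement}}).
#'
#' @param pointTable data.frame with \code{point_id, x_deg, y_deg}
#' @param region \code{"central10"} or \code{"central15"}
#' @param additionalIds ids of the four added points for central15; default
#'   taken from the table's \code{"additional15"} attribute
#' @param displacement logical, apply the ganglion-cell displacement
#'   correction (default TRUE)
#' @param degPerMm degrees-per-mm conversion factor
#' @return a \linkS4class{RegionMask} of modality \code{"SAP"}
#' @export
selectSapPoints <- function(pointTable, region = c("central10", "central15"),
                            additionalIds = attr(pointTable, "additional15"),
                            displacement = TRUE, degPerMm = 3.3) {
  region <- match.arg(region)
  stopifnot(all(c("point_id", "x_deg", "y_deg") %in% names(pointTable)))
  ecc <- sqrt(pointTable$x_deg^2 + pointTable$y_deg^2)
  if (displacement) {
    eccMm <- ecc / degPerMm
    ecc <- ecc + mmToDegrees(drasdoDisplacement(eccMm), degPerMm)
  }
  inner <- pointTable$point_id[ecc <= 10]
  if (region == "central10") {
    if (length(inner) == 0L)
      warning("no points within the central 10 degrees")
    return(new("RegionMask", modality = "SAP",
               memberIds = as.integer(inner), label = "central10"))
  }
  if (is.null(additionalIds) || length(additionalIds) != 4L)
    stop("central15 requires exactly 4 configured additional point ids")
  if (!all(additionalIds %in% pointTable$point_id))
    stop("additional point ids not present in the point table")
  if (any(additionalIds %in% inner))
    stop("central15 configuration must extend central10 ",
         "(an additional point already lies inside 10 degrees)")
  new("RegionMask", modality = "SAP",
      memberIds = as.integer(c(inner, additionalIds)), label = "central15")
}
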
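#' A calibrated grayscale image frame
#'
#' Thin container pairing a pixel matrix (rows = y, columns = x, 0-based
#' pixel coordinates in reports) with its spatial calibration. Intensities
#' are expected in [0, 1].
#'
#' @param pixels numeric matrix of intensities
#' @param pixel_size micrometres per pixel; `NA` marks an uncalibrated
#'   frame
#' @param timestamp acquisition time (s) for high-speed frames, or a day
#'   index for culture images
#' @return an object of class `espray_frame`
#' @export
image_frame <- function(pixels, pixel_size = NA_real_, timestamp = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    .stopf("pixels must be a numeric matrix")
  if (any(!is.finite(pixels))) .stopf("pixel intensities must be finite")
  if (!is.na(pixel_size) && pixel_size <= 0)
    .stopf("pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 timestamp = timestamp),
            class = "espray_frame")
}

#' @export
print.espray_frame <- function(x, ...) {
  cat(sprintf("<espray image frame> %d x %d px, %s um/px\n",
              nrow(x$pixels), ncol(x$pixels),
              if (is.na(x$pixel_size)) "uncalibrated" else
                format(x$pixel_size)))
  invisible(x)
}

#' Write / read a frame as a greyscale image file
#'
#' @param frame an [image_frame()]
#' @param path output file; format from the extension (tiff or png)
#' @return `path`, invisibly
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "espray_frame"))
  img <- EBImage::Image(t(frame$pixels))
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @param path image file to read
#' @param pixel_size calibration to attach (um/px)
#' @param timestamp timestamp to attach
#' @rdname write_frame
#' @export
read_frame <- function(path, pixel_size = NA_real_, timestamp = NA_real_) {
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) > 2) px <- px[, , 1]
  image_frame(t(px), pixel_size = pixel_size, timestamp = timestamp)
}

#' High-speed acquisition arithmetic
#'
#' @param frame_rate frames per second (the study records at 7000 fps)
#' @param duration recording length (s; the study records 5 s)
#' @return an object of class `espray_acquisition` with the frame interval
#'   (s) and frame count
#' @examples
#' acquisition_params(7000, 5)  # 35,000 frames, 142.86 us apart
#' @export
acquisition_params <- function(frame_rate, duration) {
  if (!is.finite(frame_rate) || frame_rate <= 0)
    .stopf("frame_rate must be > 0")
  if (!is.finite(duration) || duration <= 0)
    .stopf("duration must be > 0")
  structure(list(frame_rate = frame_rate, duration = duration,
                 frame_interval = 1 / frame_rate,
                 n_frames = round(frame_rate * duration)),
            class = "espray_acquisition")
}

#' @export
print.espray_acquisition <- function(x, ...) {
  cat(sprintf("<espray acquisition> %g fps x %g s: %d frames, %.2f us apart\n",
              x$frame_rate, x$duration, x$n_frames,
              x$frame_interval * 1e6))
  invisible(x)
}

#' Pixel size from a scale bar
#'
#' @param bar_length_px scale-bar length in pixels
#' @param bar_length_um physical scale-bar length (um); culture images
#'   carry a 500 um bar
#' @return pixel size in um/px
#' @examples
#' scale_from_bar(250, 500)  # 2 um/px
#' @export
scale_from_bar <- function(bar_length_px, bar_length_um = 500) {
  if (!is.finite(bar_length_px) || bar_length_px <= 0)
    .stopf("bar_length_px must be > 0")
  if (!is.finite(bar_length_um) || bar_length_um <= 0)
    .stopf("bar_length_um must be > 0")
  bar_length_um / bar_length_px
}

#' Locate a rendered scale bar in a frame
#'
#' Finds the longest horizontal run of near-black pixels, the convention
#' used for superimposed scale bars, and returns its pixel length.
#'
#' @param frame an [image_frame()]
#' @param intensity_max intensity below which a pixel counts as bar ink
#' @return bar length in pixels
#' @export
locate_scale_bar <- function(frame, intensity_max = 0.2) {
  stopifnot(inherits(frame, "espray_frame"))
  ink <- frame$pixels < intensity_max
  run_len <- apply(ink, 1, function(row) {
    r <- rle(row)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  len <- max(run_len)
  if (len < 20L) .stopf("no scale bar found (longest dark run %d px)", len)
  as.integer(len)
}

# threshold + label + per-object shape features shared by both detectors;
# returns one row per object with px and calibrated measurements
.segment_objects <- function(frame, threshold = "auto",
                             closing_radius = 0, drop_border = TRUE) {
  px <- frame$pixels
  rng <- range(px)
  if (diff(rng) < 1e-9) return(NULL)  # featureless frame
  thr <- if (identical(threshold, "auto")) {
    # Otsu on the normalised image, mapped back to intensity units
    norm <- (px - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(t(norm))) * diff(rng) + rng[1]
  } else threshold
  mask <- EBImage::Image(t(px < thr))  # dark objects on bright background
  if (closing_radius > 0) {
    brush_size <- 2 * closing_radius + 1
    mask <- EBImage::closing(mask, EBImage::makeBrush(brush_size, "disc"))
  }
  labels <- EBImage::bwlabel(mask)
  n <- max(labels)
  if (n == 0) return(NULL)
  lab <- EBImage::imageData(labels)  # dims: x (cols of px), y (rows of px)
  if (drop_border) {
    border <- unique(c(lab[1, ], lab[dim(lab)[1], ], lab[, 1],
                       lab[, dim(lab)[2]]))
    border <- border[border > 0]
  } else border <- integer(0)
  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  keep <- setdiff(seq_len(n), border)
  if (!length(keep)) return(NULL)
  data.frame(label = keep,
             cx_px = mom[keep, "m.cx"] - 1,  # 0-based, x = column
             cy_px = mom[keep, "m.cy"] - 1,  # 0-based, y = row
             area_px = shp[keep, "s.area"],
             perimeter_px = shp[keep, "s.perimeter"],
             row.names = NULL)
}

#' Detect droplets in a high-speed frame
#'
#' Dark-object segmentation of a calibrated frame: automatic (Otsu) or
#' fixed thresholding, connected components, removal of border-touching
#' objects, and a physical diameter floor. Diameters are equivalent-circle
#' diameters, `2 sqrt(area / pi)`.
#'
#' @param frame a calibrated [image_frame()]
#' @param threshold `"auto"` (Otsu) or a fixed intensity threshold
#' @param min_diameter smallest droplet diameter kept (um); the default
#'   120 um floor separates droplets from the small satellite outliers
#' @param frame_index frame number recorded in the output
#' @return a data.frame with one row per droplet: centroid (px, 0-based),
#'   area (um^2) and equivalent diameter (um). A featureless frame yields
#'   zero rows.
#' @export
detect_droplets <- function(frame, threshold = "auto", min_diameter = 120,
                            frame_index = NA_integer_) {
  stopifnot(inherits(frame, "espray_frame"))
  if (is.na(frame$pixel_size))
    .stopf("frame is uncalibrated: set pixel_size before detection")
  empty <- data.frame(frame = integer(0), label = integer(0),
                      cx_px = numeric(0), cy_px = numeric(0),
                      area_um2 = numeric(0), diameter_um = numeric(0))
  obj <- .segment_objects(frame, threshold = threshold)
  if (is.null(obj)) return(empty)
  ps <- frame$pixel_size
  obj$area_um2 <- obj$area_px * ps^2
  obj$diameter_um <- 2 * sqrt(obj$area_um2 / pi)
  obj <- obj[obj$diameter_um >= min_diameter, ]
  if (!nrow(obj)) return(empty)
  data.frame(frame = frame_index, label = obj$label, cx_px = obj$cx_px,
             cy_px = obj$cy_px, area_um2 = obj$area_um2,
             diameter_um = obj$diameter_um, row.names = NULL)
}

#' Summary statistics of detected droplet diameters
#'
#' @param detections a data.frame from [detect_droplets()] (rows from
#'   several frames may be concatenated)
#' @return a one-row data.frame: n, mean, sd, min, max (um) and
#'   polydispersity (sd/mean). A single detection reports sd 0 with
#'   `sd_defined = FALSE`; an empty input reports an all-`NA` summary.
#' @export
droplet_diameter_stats <- function(detections) {
  d <- detections$diameter_um
  n <- length(d)
  if (n == 0)
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                      min = NA_real_, max = NA_real_,
                      polydispersity = NA_real_, sd_defined = FALSE))
  s <- if (n > 1) sd(d) else 0
  data.frame(n = n, mean = mean(d), sd = s, min = min(d), max = max(d),
             polydispersity = s / mean(d), sd_defined = n > 1)
}

#' Segment spheroids in a brightfield image
#'
#' Otsu thresholding, morphological closing and connected components on a
#' calibrated brightfield image, followed by the study's inclusion rule: a
#' mass counts as a spheroid when its area reaches `min_area`, or when it
#' falls in the borderline band `[borderline_min, min_area)` and is round
#' enough (circularity `4 pi A / P^2` at least `circularity_min` — the
#' automated stand-in for the observer judgement applied to borderline
#' masses). All candidate objects are returned with their raw
#' measurements and inclusion flags so the rule can be re-applied.
#'
#' @param image a calibrated [image_frame()]
#' @param min_area unconditional inclusion threshold (um^2)
#' @param borderline_min lower edge of the borderline band (um^2)
#' @param circularity_min circularity floor for borderline masses
#' @param closing_radius radius (px) of the morphological closing brush
#' @param threshold `"auto"` (Otsu) or a fixed intensity threshold
#' @return a data.frame of class `espray_spheroids`: label, centroid (px),
#'   area (um^2), perimeter (um), circularity, and `included`
#' @export
segment_spheroids <- function(image, min_area = 3000, borderline_min = 2500,
                              circularity_min = 0.4, closing_radius = 2,
                              threshold = "auto") {
  stopifnot(inherits(image, "espray_frame"))
  if (is.na(image$pixel_size))
    .stopf("image is uncalibrated: set pixel_size (e.g. from the scale bar)")
  if (borderline_min > min_area)
    .stopf("borderline_min must not exceed min_area")
  empty <- data.frame(label = integer(0), cx_px = numeric(0),
                      cy_px = numeric(0), area_um2 = numeric(0),
                      perimeter_um = numeric(0), circularity = numeric(0),
                      included = logical(0))
  obj <- .segment_objects(image, threshold = threshold,
                          closing_radius = closing_radius)
  if (is.null(obj)) return(structure(empty, class = c("espray_spheroids",
                                                      "data.frame")))
  ps <- image$pixel_size
  area <- obj$area_px * ps^2
  perim <- pmax(obj$perimeter_px, 1) * ps
  circ <- 4 * pi * area / perim^2
  included <- area >= min_area |
    (area >= borderline_min & circ >= circularity_min)
  structure(data.frame(label = obj$label, cx_px = obj$cx_px,
                       cy_px = obj$cy_px, area_um2 = area,
                       perimeter_um = perim, circularity = circ,
                       included = included, row.names = NULL),
            class = c("espray_spheroids", "data.frame"))
}

#' Spheroid-area summaries per dish and day
#'
#' Aggregates included spheroids the way the culture time course is
#' reported: per dish and day the total covered area, mean area per
#' spheroid and count; per day the mean total area per dish (the study's
#' headline quantity) across dishes.
#'
#' @param records a data.frame of spheroid records (for example row-bound
#'   outputs of [segment_spheroids()]) with columns `area_um2`,
#'   `included`, `dish` and `day`
#' @return a list with data.frames `per_dish` (dish x day totals) and
#'   `per_day` (mean total area per dish, overall mean spheroid area,
#'   counts)
#' @export
spheroid_area_summary <- function(records) {
  need <- c("area_um2", "included", "dish", "day")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    .stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  if (!nrow(records))
    .stopf("no spheroid records to summarise")
  inc <- records[records$included, , drop = FALSE]
  groups <- unique(records[c("dish", "day")])
  per_dish <- do.call(rbind, lapply(seq_len(nrow(groups)), function(j) {
    g <- inc[inc$dish == groups$dish[j] & inc$day == groups$day[j], ,
             drop = FALSE]
    data.frame(dish = groups$dish[j], day = groups$day[j],
               n_spheroids = nrow(g),
               total_area_um2 = sum(g$area_um2),
               mean_area_um2 = if (nrow(g)) mean(g$area_um2) else NA_real_)
  }))
  per_dish <- per_dish[order(per_dish$day, per_dish$dish), ]
  rownames(per_dish) <- NULL
  per_day <- do.call(rbind, lapply(split(per_dish, per_dish$day), function(g) {
    day_inc <- inc[inc$day == g$day[1], , drop = FALSE]
    data.frame(day = g$day[1], n_dishes = nrow(g),
               mean_total_area_per_dish = mean(g$total_area_um2),
               mean_area_per_spheroid = if (nrow(day_inc))
                 mean(day_inc$area_um2) else NA_real_,
               n_spheroids = sum(g$n_spheroids))
  }))
  rownames(per_day) <- NULL
  list(per_dish = per_dish, per_day = per_day)
}
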
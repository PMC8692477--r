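## Synthetic-data generators. Every generator is deterministic under a
## fixed seed, emits its ground truth beside the data, and produces output
## that passes the schema checks of the stage that consumes it.

# stamp a (possibly wobbled) filled disc into a pixel matrix
.draw_disc <- function(px, cy, cx, r_px, value, wobble = 0) {
  h <- nrow(px); w <- ncol(px)
  rmax <- r_px * (1 + 3 * wobble) + 1
  rows <- max(1, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  cols <- max(1, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  rr <- sqrt(dy^2 + dx^2)
  if (wobble > 0) {
    theta <- atan2(dy, dx)
    amp <- rnorm(3, 0, wobble / (1:3))
    phs <- runif(3, 0, 2 * pi)
    mod <- 1 + amp[1] * cos(theta + phs[1]) + amp[2] * cos(2 * theta + phs[2]) +
      amp[3] * cos(3 * theta + phs[3])
    rlim <- r_px * mod
  } else rlim <- r_px
  inside <- rr <= rlim
  px[rows, cols][inside] <- value
  px
}

# rejection-sample non-overlapping centres inside a margin
.place_centres <- function(n, h, w, radii_px, margin = 4, max_retries = 200) {
  cy <- numeric(0); cx <- numeric(0); rs <- numeric(0)
  for (j in seq_len(n)) {
    r <- radii_px[j]
    ok <- FALSE
    for (t in seq_len(max_retries)) {
      y <- runif(1, r + margin + 1, h - r - margin)
      x <- runif(1, r + margin + 1, w - r - margin)
      if (!length(cy) || all(sqrt((cy - y)^2 + (cx - x)^2) >
                               rs + r + margin)) {
        ok <- TRUE; break
      }
    }
    if (!ok) .stopf("could not place object %d without overlap after %d tries",
                    j, max_retries)
    cy <- c(cy, y); cx <- c(cx, x); rs <- c(rs, r)
  }
  data.frame(cy = cy, cx = cx, r_px = rs)
}

#' Generate synthetic high-speed droplet frames
#'
#' Renders stacks of frames mimicking the high-speed recordings of the
#' spray: dark circular droplets falling on a bright background, diameters
#' drawn uniformly from `diameter_range` (the observed 200-300 um band by
#' default), optionally with sub-120 um satellite outliers and one small
#' secondary daughter droplet trailing each mother, plus additive Gaussian
#' pixel noise. The planted ground truth is returned alongside.
#'
#' @param n_frames number of frames
#' @param droplets_per_frame mother droplets per frame
#' @param diameter_range mother diameter range (um)
#' @param include_outliers also plant small satellite droplets?
#' @param outlier_range satellite diameter range (um), below the 120 um
#'   detection floor
#' @param include_daughters plant one secondary daughter droplet per mother?
#' @param daughter_ratio daughter/mother diameter ratio
#' @param width,height frame size (px); the recordings are 512 x 1024
#' @param pixel_size um per pixel
#' @param background,droplet_intensity background and droplet grey levels
#' @param noise_sd additive Gaussian pixel-noise sd
#' @param frame_rate frames per second, used for frame timestamps
#' @param seed RNG seed; identical seed and parameters give identical output
#' @return a list with `frames` (list of [image_frame()]), `truth`
#'   (data.frame: frame, kind, centroid, planted diameter and area) and
#'   `params`
#' @export
synth_droplet_frames <- function(n_frames = 10, droplets_per_frame = 6,
                                 diameter_range = c(200, 300),
                                 include_outliers = FALSE,
                                 outlier_range = c(60, 110),
                                 include_daughters = FALSE,
                                 daughter_ratio = 0.3,
                                 width = 512, height = 1024,
                                 pixel_size = 4,
                                 background = 0.85, droplet_intensity = 0.2,
                                 noise_sd = 0.02, frame_rate = 7000,
                                 seed = NULL) {
  if (max(diameter_range) / pixel_size >= min(width, height))
    .stopf("droplets larger than the frame: max diameter %g um at %g um/px",
           max(diameter_range), pixel_size)
  .with_seed(seed, {
    frames <- vector("list", n_frames)
    truth <- list()
    for (f in seq_len(n_frames)) {
      d_um <- runif(droplets_per_frame, diameter_range[1], diameter_range[2])
      kind <- rep("mother", droplets_per_frame)
      if (include_outliers) {
        n_out <- max(1L, rbinom(1, droplets_per_frame, 0.3))
        d_um <- c(d_um, runif(n_out, outlier_range[1], outlier_range[2]))
        kind <- c(kind, rep("outlier", n_out))
      }
      r_px <- d_um / 2 / pixel_size
      pos <- .place_centres(length(d_um), height, width, r_px)
      if (include_daughters) {
        mothers <- which(kind == "mother")
        dd <- d_um[mothers] * daughter_ratio
        # daughters trail just above their mother along the fall axis
        dy <- -(r_px[mothers] + dd / 2 / pixel_size + 6)
        pos <- rbind(pos, data.frame(cy = pos$cy[mothers] + dy,
                                     cx = pos$cx[mothers],
                                     r_px = dd / 2 / pixel_size))
        d_um <- c(d_um, dd)
        kind <- c(kind, rep("daughter", length(mothers)))
      }
      px <- matrix(background, height, width)
      for (j in seq_along(d_um))
        px <- .draw_disc(px, pos$cy[j], pos$cx[j], pos$r_px[j],
                         droplet_intensity)
      px <- px + rnorm(length(px), 0, noise_sd)
      px <- pmin(pmax(px, 0), 1)
      frames[[f]] <- image_frame(px, pixel_size = pixel_size,
                                 timestamp = (f - 1) / frame_rate)
      truth[[f]] <- data.frame(frame = f, kind = kind,
                               cy_px = pos$cy - 1, cx_px = pos$cx - 1,
                               diameter_um = d_um,
                               area_um2 = pi * (d_um / 2)^2)
    }
    list(frames = frames, truth = do.call(rbind, truth),
         params = list(n_frames = n_frames,
                       droplets_per_frame = droplets_per_frame,
                       diameter_range = diameter_range,
                       pixel_size = pixel_size, seed = seed))
  })
}

#' Generate a synthetic brightfield spheroid image
#'
#' Renders a culture image the way the spheroid time course is quantified:
#' darker quasi-circular spheroids on a bright background, scattered
#' sub-borderline cell debris, and a superimposed 500 um scale bar flush
#' with the lower image edge. Spheroid areas are drawn log-normally
#' (median about 5000 um^2 by default) or can be given explicitly.
#'
#' @param n_spheroids number of spheroids (ignored when `areas` is given)
#' @param areas explicit spheroid areas (um^2), optional
#' @param area_meanlog,area_sdlog log-normal area parameters (log um^2)
#' @param n_debris number of small debris objects below the borderline band
#' @param debris_area_range debris area range (um^2)
#' @param width,height image size (px)
#' @param pixel_size um per pixel
#' @param background,spheroid_intensity,debris_intensity grey levels
#' @param noise_sd additive Gaussian pixel-noise sd
#' @param wobble radial irregularity of spheroid outlines (0 = circles)
#' @param scale_bar_um physical scale-bar length
#' @param day day index stored on the frame timestamp
#' @param seed RNG seed
#' @return a list with `frame` (a calibrated [image_frame()]), `truth`
#'   (planted objects), `bar_length_px` and `params`
#' @export
synth_spheroid_image <- function(n_spheroids = 8, areas = NULL,
                                 area_meanlog = log(5000),
                                 area_sdlog = 0.35,
                                 n_debris = 12,
                                 debris_area_range = c(100, 1500),
                                 width = 512, height = 512, pixel_size = 2,
                                 background = 0.85,
                                 spheroid_intensity = 0.45,
                                 debris_intensity = 0.5,
                                 noise_sd = 0.02, wobble = 0.05,
                                 scale_bar_um = 500, day = NA_real_,
                                 seed = NULL) {
  .with_seed(seed, {
    if (is.null(areas)) areas <- rlnorm(n_spheroids, area_meanlog, area_sdlog)
    deb <- if (n_debris > 0)
      runif(n_debris, debris_area_range[1], debris_area_range[2])
    else numeric(0)
    all_areas <- c(areas, deb)
    kind <- c(rep("spheroid", length(areas)), rep("debris", length(deb)))
    r_px <- sqrt(all_areas / pi) / pixel_size
    if (any(2 * r_px >= min(width, height) - 20))
      .stopf("an object of area %.0f um^2 does not fit the image",
             max(all_areas))
    bar_px <- round(scale_bar_um / pixel_size)
    if (bar_px >= width - 10)
      .stopf("scale bar (%d px) does not fit the image width", bar_px)
    pos <- .place_centres(length(all_areas), height - 14, width, r_px)
    px <- matrix(background, height, width)
    for (j in seq_along(all_areas))
      px <- .draw_disc(px, pos$cy[j], pos$cx[j], r_px[j],
                       if (kind[j] == "spheroid") spheroid_intensity
                       else debris_intensity,
                       wobble = if (kind[j] == "spheroid") wobble else 0)
    # scale bar: flush with the lower edge so quantification can discard it
    px[(height - 4):height, 1:bar_px] <- 0.05
    px <- pmin(pmax(px + rnorm(length(px), 0, noise_sd), 0), 1)
    list(frame = image_frame(px, pixel_size = pixel_size, timestamp = day),
         truth = data.frame(kind = kind, cy_px = pos$cy - 1,
                            cx_px = pos$cx - 1, area_um2 = all_areas),
         bar_length_px = bar_px,
         params = list(n_spheroids = length(areas), n_debris = n_debris,
                       pixel_size = pixel_size, seed = seed))
  })
}

#' Generate a spheroid growth time course
#'
#' Produces one brightfield image per dish, day and replicate with planted
#' spheroid areas growing geometrically over days, emulating the culture
#' time course (spheroids enlarging from the first week to day 14).
#'
#' @param days day indices to image
#' @param dishes dish labels
#' @param images_per_day images per dish per day (the study takes 10)
#' @param n_spheroids spheroids per image
#' @param base_meanlog log-normal mean of day-one areas (log um^2)
#' @param area_sdlog log-normal sd
#' @param growth_per_day multiplicative daily area growth factor
#' @param seed RNG seed
#' @param ... further arguments passed to [synth_spheroid_image()]
#' @return a list with `images` (data.frame index + list of frames) and
#'   `truth` (planted objects with dish/day columns)
#' @export
synth_spheroid_study <- function(days = c(6, 14), dishes = c("dish1", "dish2"),
                                 images_per_day = 3, n_spheroids = 6,
                                 base_meanlog = log(3500), area_sdlog = 0.3,
                                 growth_per_day = 1.08, seed = NULL, ...) {
  .with_seed(seed, {
    frames <- list(); truth <- list(); meta <- list()
    i <- 0L
    for (day in days) for (dish in dishes) for (rep in seq_len(images_per_day)) {
      i <- i + 1L
      scale <- growth_per_day^(day - min(days))
      img <- synth_spheroid_image(
        n_spheroids = n_spheroids,
        area_meanlog = base_meanlog + log(scale),
        area_sdlog = area_sdlog, day = day, seed = NULL, ...)
      frames[[i]] <- img$frame
      tr <- img$truth
      tr$dish <- dish; tr$day <- day; tr$image <- i
      truth[[i]] <- tr
      meta[[i]] <- data.frame(image = i, dish = dish, day = day,
                              replicate = rep)
    }
    list(images = list(index = do.call(rbind, meta), frames = frames),
         truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic optical-density table
#'
#' Emulates the LDH plate read: per-group replicate ODs with the planted
#' group viabilities (relative to control) recovered by
#' [viability_percent()]. Defaults plant the study's observed 90% (10 kV)
#' and 70% (15 kV) viabilities.
#'
#' @param groups group labels; first is the control
#' @param viability planted viability fraction per group
#' @param control_mean_od mean OD of the control group
#' @param replicates replicates per group
#' @param noise_sd Gaussian OD noise sd
#' @param wavelength_nm metadata wavelength
#' @param seed RNG seed
#' @return a data.frame (group, replicate, od, wavelength_nm) with the
#'   planted viabilities as attribute `truth`
#' @export
synth_od_table <- function(groups = c("control", "10 kV", "15 kV"),
                           viability = c(1, 0.9, 0.7),
                           control_mean_od = 0.6, replicates = 3,
                           noise_sd = 0.01, wavelength_nm = 605,
                           seed = NULL) {
  stopifnot(length(groups) == length(viability))
  .with_seed(seed, {
    od <- unlist(lapply(viability, function(v)
      pmax(rnorm(replicates, control_mean_od * v, noise_sd), 0)))
    out <- data.frame(group = rep(groups, each = replicates),
                      replicate = rep(seq_len(replicates), length(groups)),
                      od = od, wavelength_nm = wavelength_nm)
    attr(out, "truth") <- setNames(viability, groups)
    out
  })
}

#' Generate a synthetic quantification-cycle (Ct) table
#'
#' Emulates the qPCR layout: a reference gene (GAPDH) in every sample and
#' target genes whose treated-vs-calibrator fold changes are planted so
#' that [delta_delta_ct()] recovers them exactly at zero noise. Defaults
#' plant the chondrogenesis markers ACAN (8.7-fold) and SOX9 (6-fold).
#'
#' @param fold_changes named vector of planted fold changes per target gene
#' @param treated,calibrator sample labels
#' @param reference_gene endogenous control gene
#' @param base_ct calibrator Ct of the target genes
#' @param reference_ct Ct of the reference gene
#' @param noise_sd Gaussian Ct noise sd (0 gives exact recovery)
#' @param seed RNG seed
#' @return a data.frame (sample, gene, ct) with planted fold changes as
#'   attribute `truth`
#' @export
synth_ct_table <- function(fold_changes = c(ACAN = 8.7, SOX9 = 6),
                           treated = "treated", calibrator = "control",
                           reference_gene = "GAPDH",
                           base_ct = 24, reference_ct = 16,
                           noise_sd = 0, seed = NULL) {
  .with_seed(seed, {
    genes <- names(fold_changes)
    rows <- rbind(
      data.frame(sample = calibrator, gene = reference_gene,
                 ct = reference_ct),
      data.frame(sample = treated, gene = reference_gene, ct = reference_ct),
      data.frame(sample = calibrator, gene = genes, ct = base_ct),
      data.frame(sample = treated, gene = genes,
                 ct = base_ct - log2(unname(fold_changes))))
    if (noise_sd > 0) rows$ct <- rows$ct + rnorm(nrow(rows), 0, noise_sd)
    rownames(rows) <- NULL
    attr(rows, "truth") <- fold_changes
    rows
  })
}

# the chondrogenesis panel planted by default: ACAN/SOX9 at the reported
# fold changes for each voltage, the upregulated and downregulated
# collagen sets, and the 20-gene chondrocyte-development ontology term
# tallying 17 up / 3 down
.chondro_panel <- function(voltage = c("15kV", "10kV")) {
  voltage <- match.arg(voltage)
  up_coll <- c("COL23A1", "COL21A1", "COL4A1", "COL6A5", "COL4A4", "COL7A1",
               "COL4A6", "COL4A5", "COL24A1", "COL9A2", "COL4A2", "COL8A1",
               "COL9A3", "COL11A2", "COL18A1")
  down_coll <- c("COL17A1", "COL19A1", "COL13A1", "COL15A1", "COL8A2",
                 "COL1A1")
  marker_fc <- if (voltage == "15kV") c(ACAN = 8.7, SOX9 = 6)
               else c(ACAN = 4.4, SOX9 = 3)
  planted <- data.frame(
    gene = c(names(marker_fc), up_coll, down_coll),
    fold_change = c(unname(marker_fc), rep(2.5, length(up_coll)),
                    rep(0.4, length(down_coll))))
  go_terms <- list(CHONDROCYTE_DEVELOPMENT =
                     c(names(marker_fc), up_coll, down_coll[1:3]))
  list(planted = planted, go_terms = go_terms)
}

#' Generate a synthetic differential-expression table
#'
#' Emulates the per-gene fold-change / p-value table that enters DEG
#' filtering: planted effect genes (by default the chondrogenesis panel —
#' ACAN, SOX9 and the up/down collagen sets at their reported fold
#' changes) on a background of null genes. Effect-gene log2 fold changes
#' get Gaussian noise; their p-values fall below the significance
#' threshold with probability `power`. Null genes draw fold changes around
#' 1 and uniform p-values.
#'
#' @param n_null number of null background genes
#' @param voltage which planted panel to use (`"15kV"` or `"10kV"`)
#' @param planted optional data.frame (gene, fold_change) overriding the
#'   default panel
#' @param go_terms named list of ontology terms to gene vectors; defaults
#'   to the panel's 20-gene chondrocyte-development term
#' @param lfc_noise_sd Gaussian noise sd on planted log2 fold changes
#' @param null_lfc_sd sd of null-gene log2 fold changes
#' @param power probability that an effect gene's p-value falls below
#'   `p_threshold`
#' @param p_threshold significance threshold used to draw effect p-values
#' @param seed RNG seed
#' @return a data.frame (gene, fold_change, p_value) with attributes
#'   `truth` (the planted table) and `go_terms`
#' @export
synth_deg_table <- function(n_null = 2000, voltage = c("15kV", "10kV"),
                            planted = NULL, go_terms = NULL,
                            lfc_noise_sd = 0.1, null_lfc_sd = 0.2,
                            power = 1, p_threshold = 0.05, seed = NULL) {
  voltage <- match.arg(voltage)
  panel <- .chondro_panel(voltage)
  if (is.null(planted)) planted <- panel$planted
  if (is.null(go_terms)) go_terms <- panel$go_terms
  .with_seed(seed, {
    eff_lfc <- log2(planted$fold_change) +
      rnorm(nrow(planted), 0, lfc_noise_sd)
    eff_p <- ifelse(runif(nrow(planted)) < power,
                    runif(nrow(planted), 0, p_threshold),
                    runif(nrow(planted), p_threshold, 1))
    null_genes <- if (n_null > 0) sprintf("NULL%04d", seq_len(n_null))
                  else character(0)
    out <- data.frame(
      gene = c(planted$gene, null_genes),
      fold_change = c(2^eff_lfc, 2^rnorm(n_null, 0, null_lfc_sd)),
      p_value = c(eff_p, runif(n_null)))
    rownames(out) <- NULL
    attr(out, "truth") <- planted
    attr(out, "go_terms") <- go_terms
    out
  })
}
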
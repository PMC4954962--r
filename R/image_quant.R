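#' Construct a fluorescence image object
#'
#' @param pixels Integer/numeric matrix of grayscale intensities.
#' @param plate,well,field,strain_id,construct Acquisition metadata.
#' @return Object of class `fluor_image`.
#' @export
fluor_image <- function(pixels, plate = NA_character_, well = NA_character_,
                        field = 1L, strain_id = NA_character_,
                        construct = NA_character_) {
  stopifnot(is.matrix(pixels), all(pixels >= 0, na.rm = TRUE))
  structure(list(pixels = pixels, plate = plate, well = well,
                 field = as.integer(field), strain_id = strain_id,
                 construct = construct),
            class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image %s %s s%d: %d x %d, range [%d, %d]>\n",
              x$plate, x$well, x$field, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Segmentation parameters
#'
#' The two intensity thresholds are the screen's printed settings: a pixel
#' belongs to a cell when it sits at least `cell_delta` (default 300)
#' grayscale units above the local background, and to an inclusion when it
#' sits at least `inclusion_delta` (default 400) units above the cell's
#' diffuse level.
#'
#' @param cell_delta Cell-isolation threshold (grayscale units above
#'   background).
#' @param inclusion_delta Inclusion-isolation threshold (grayscale units above
#'   the cell's diffuse mean).
#' @param min_cell_area_px,max_cell_area_px Area gate for cell regions.
#' @param min_inclusion_area_px Minimum inclusion region area (suppresses
#'   single-pixel noise).
#' @param border_policy `"exclude"` drops cells touching the image edge.
#' @param background_method `"median"` (tiled median, interpolated) or
#'   `"rolling_ball"` (grayscale opening).
#' @param background_radius_px Half-window of the background estimator.
#' @param min_cells_for_scoring QC floor on cells per well (default 300, the
#'   screen's manual-confirmation count).
#' @param intensity_mode `"mean_of_means"` (per-cell means averaged; default)
#'   or `"pooled"` (area-weighted over all cellular pixels).
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(cell_delta = 300, inclusion_delta = 400,
                                min_cell_area_px = 20, max_cell_area_px = 2000,
                                min_inclusion_area_px = 2,
                                border_policy = c("exclude", "include"),
                                background_method = c("median", "rolling_ball"),
                                background_radius_px = 24L,
                                min_cells_for_scoring = 300L,
                                intensity_mode = c("mean_of_means", "pooled")) {
  stopifnot(cell_delta > 0, inclusion_delta > 0, min_cell_area_px >= 1,
            max_cell_area_px >= min_cell_area_px, min_inclusion_area_px >= 1,
            background_radius_px >= 1)
  structure(list(cell_delta = cell_delta, inclusion_delta = inclusion_delta,
                 min_cell_area_px = min_cell_area_px,
                 max_cell_area_px = max_cell_area_px,
                 min_inclusion_area_px = min_inclusion_area_px,
                 border_policy = match.arg(border_policy),
                 background_method = match.arg(background_method),
                 background_radius_px = as.integer(background_radius_px),
                 min_cells_for_scoring = as.integer(min_cells_for_scoring),
                 intensity_mode = match.arg(intensity_mode)),
            class = "segmentation_params")
}

#' Remove large-scale illumination shading
#'
#' `poly2` fits a second-order polynomial surface to the dimmer (background
#' dominated) half of the pixels and subtracts it, adding back its mean, so
#' the image mean is preserved and intensity *differences* — which both
#' thresholds are — are untouched by the re-centering.
#' `flatfield_reference` divides by a supplied flat-field image and rescales
#' to its mean.
#'
#' @param img A `fluor_image`.
#' @param model `"poly2"` or `"flatfield_reference"`.
#' @param reference Flat-field `fluor_image` or matrix (required for
#'   `flatfield_reference`).
#' @return Corrected `fluor_image`.
#' @export
shade_correct <- function(img, model = c("poly2", "flatfield_reference"),
                          reference = NULL) {
  model <- match.arg(model)
  px <- img$pixels
  if (model == "flatfield_reference") {
    if (is.null(reference)) stop("flatfield_reference requires a reference image")
    ref <- if (inherits(reference, "fluor_image")) reference$pixels else reference
    stopifnot(identical(dim(ref), dim(px)), all(ref > 0))
    out <- px / ref * mean(ref)
  } else {
    if (stats::sd(px) == 0) {
      message("shade_correct: constant image, returned unchanged")
      return(img)
    }
    nr <- nrow(px); nc <- ncol(px)
    r <- (row(px) - (nr + 1) / 2) / nr
    c <- (col(px) - (nc + 1) / 2) / nc
    # background-dominated pixels only: cells would bias the surface
    sel <- px <= stats::quantile(px, 0.5)
    df <- data.frame(y = px[sel], r = r[sel], c = c[sel])
    fit <- stats::lm(y ~ r + c + I(r^2) + I(c^2) + I(r * c), data = df)
    surf <- matrix(stats::predict(fit, newdata = data.frame(r = as.vector(r),
                                                            c = as.vector(c))),
                   nr, nc)
    out <- px - surf + mean(surf)
  }
  img$pixels <- out
  img
}

interp_grid <- function(vals, centers, n) {
  # 1-D linear interpolation of tile summaries to pixel positions, constant
  # beyond the outer tile centers
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Estimate the image background
#'
#' `"median"` computes per-tile medians on a grid of side
#' `2 * background_radius_px` and bilinearly interpolates them to a full
#' background map — robust while cells cover a minority of each tile.
#' `"rolling_ball"` uses a grayscale opening (erosion then dilation) with a
#' square structuring element of the same radius.
#'
#' @param img A `fluor_image`.
#' @param params [segmentation_params()].
#' @return List with `level` (scalar, median of the map) and `map` (matrix).
#' @export
estimate_background <- function(img, params = segmentation_params()) {
  px <- img$pixels
  if (all(px >= 65535)) stop("image saturated everywhere: unusable acquisition")
  if (params$background_method == "rolling_ball") {
    map <- .max_filter(.min_filter(px * 1.0, params$background_radius_px),
                       params$background_radius_px)
  } else {
    tile <- 2L * params$background_radius_px
    nr <- nrow(px); nc <- ncol(px)
    rb <- unique(c(seq(1L, nr, by = tile), nr + 1L))
    cb <- unique(c(seq(1L, nc, by = tile), nc + 1L))
    meds <- matrix(0, length(rb) - 1L, length(cb) - 1L)
    rcent <- numeric(length(rb) - 1L); ccent <- numeric(length(cb) - 1L)
    for (i in seq_len(length(rb) - 1L)) {
      for (j in seq_len(length(cb) - 1L)) {
        meds[i, j] <- stats::median(px[rb[i]:(rb[i + 1L] - 1L),
                                       cb[j]:(cb[j + 1L] - 1L)])
      }
    }
    rcent <- (rb[-length(rb)] + rb[-1] - 1) / 2
    ccent <- (cb[-length(cb)] + cb[-1] - 1) / 2
    # separable bilinear interpolation
    tmp <- apply(meds, 2, interp_grid, centers = rcent, n = nr)
    if (is.null(dim(tmp))) tmp <- matrix(tmp, nrow = nr)
    map <- t(apply(tmp, 1, interp_grid, centers = ccent, n = nc))
    if (nc == 1) map <- t(map)
  }
  list(level = stats::median(map), map = map)
}

drop_border_labels <- function(lab) {
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) lab[lab %in% border] <- 0L
  lab
}

relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(lab)
  lut <- integer(max(ids)); lut[ids] <- seq_along(ids)
  lab[lab > 0] <- lut[lab[lab > 0]]
  lab
}

#' Segment cells by intensity difference over background
#'
#' Foreground pixels are those at least `cell_delta` grayscale units above the
#' local background map; 4-connected regions are labelled, gated by area, and
#' (by default) dropped when touching the image border.
#'
#' @param img A `fluor_image`.
#' @param background Result of [estimate_background()] (or a matrix/scalar).
#' @param params [segmentation_params()].
#' @return Integer label matrix (0 = background, 1..n = cells).
#' @export
segment_cells <- function(img, background, params = segmentation_params()) {
  px <- img$pixels
  bg <- if (is.list(background)) background$map else background
  if (length(bg) == 1) bg <- matrix(bg, nrow(px), ncol(px))
  fg <- (px - bg) >= params$cell_delta
  lab <- .label_components(fg)
  if (params$border_policy == "exclude") lab <- drop_border_labels(lab)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    bad <- which(areas < params$min_cell_area_px |
                 areas > params$max_cell_area_px)
    if (length(bad)) lab[lab %in% bad] <- 0L
  }
  relabel(lab)
}

#' Segment inclusions within segmented cells
#'
#' For each cell the diffuse (non-inclusion) reference level is estimated
#' iteratively: starting from the median of the cell's pixels, pixels at least
#' `inclusion_delta` above the current reference are flagged as inclusion
#' candidates and the reference is re-estimated as the mean over the
#' remaining pixels (2 refinement iterations). Candidate regions smaller than
#' `min_inclusion_area_px` are discarded. The result is always a subset of
#' the cell mask.
#'
#' @param img A `fluor_image`.
#' @param cell_mask Label matrix from [segment_cells()].
#' @param params [segmentation_params()].
#' @return Logical inclusion mask.
#' @export
segment_inclusions <- function(img, cell_mask, params = segmentation_params()) {
  px <- img$pixels
  out <- matrix(FALSE, nrow(px), ncol(px))
  n <- max(cell_mask)
  if (n == 0) return(out)
  cell_idx <- which(cell_mask > 0)
  groups <- split(cell_idx, cell_mask[cell_idx])
  nr <- nrow(px)
  for (g in names(groups)) {
    idx <- groups[[g]]
    vals <- px[idx]
    ref <- stats::median(vals)
    cand <- (vals - ref) >= params$inclusion_delta
    for (it in 1:2) {
      keep <- !cand
      if (!any(keep)) break
      ref <- mean(vals[keep])
      cand <- (vals - ref) >= params$inclusion_delta
    }
    if (!any(cand)) next
    # area-gate candidate regions inside the cell's bounding box
    rr <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    r0 <- min(rr); c0 <- min(cc)
    sub <- matrix(FALSE, max(rr) - r0 + 1L, max(cc) - c0 + 1L)
    sub[cbind(rr - r0 + 1L, cc - c0 + 1L)[cand, , drop = FALSE]] <- TRUE
    sl <- .label_components(sub)
    if (max(sl) > 0) {
      areas <- tabulate(sl[sl > 0], nbins = max(sl))
      small <- which(areas < params$min_inclusion_area_px)
      if (length(small)) sl[sl %in% small] <- 0L
    }
    keep_px <- which(sl > 0, arr.ind = TRUE)
    if (nrow(keep_px)) {
      out[cbind(keep_px[, 1] + r0 - 1L, keep_px[, 2] + c0 - 1L)] <- TRUE
    }
  }
  out & (cell_mask > 0)
}

#' Score cells by combining the cell and inclusion masks
#'
#' @param img A `fluor_image` (intensities are averaged from it).
#' @param cell_mask Label matrix from [segment_cells()].
#' @param inclusion_mask Logical matrix from [segment_inclusions()].
#' @return data.frame with one row per cell: image, label, area_px,
#'   mean_intensity, inclusion_count, inclusion_area_px, has_inclusion.
#' @export
score_cells <- function(img, cell_mask, inclusion_mask) {
  stopifnot(identical(dim(cell_mask), dim(img$pixels)),
            identical(dim(inclusion_mask), dim(img$pixels)))
  img_id <- sprintf("%s_%s_s%d", img$plate, img$well, img$field)
  n <- max(cell_mask)
  if (n == 0)
    return(data.frame(image = character(0), label = integer(0),
                      area_px = integer(0), mean_intensity = numeric(0),
                      diffuse_mean_intensity = numeric(0),
                      inclusion_count = integer(0),
                      inclusion_area_px = integer(0),
                      has_inclusion = logical(0), stringsAsFactors = FALSE))
  nr <- nrow(img$pixels)
  cell_idx <- which(cell_mask > 0)
  groups <- split(cell_idx, cell_mask[cell_idx])
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    inc <- inclusion_mask[idx]
    n_regions <- 0L
    if (any(inc)) {
      rr <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
      r0 <- min(rr); c0 <- min(cc)
      sub <- matrix(FALSE, max(rr) - r0 + 1L, max(cc) - c0 + 1L)
      sub[cbind(rr - r0 + 1L, cc - c0 + 1L)[inc, , drop = FALSE]] <- TRUE
      n_regions <- max(.label_components(sub))
    }
    # diffuse mean excludes inclusion pixels: the whole-cell mean is coupled
    # to inclusion content (puncta concentrate signal), so the diffuse mean
    # is the cleaner expression proxy
    diffuse <- if (all(inc)) mean(img$pixels[idx]) else mean(img$pixels[idx][!inc])
    data.frame(image = img_id, label = as.integer(g),
               area_px = length(idx),
               mean_intensity = mean(img$pixels[idx]),
               diffuse_mean_intensity = diffuse,
               inclusion_count = n_regions,
               inclusion_area_px = sum(inc),
               has_inclusion = any(inc), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize a well from its pooled cell records
#'
#' The screen phenotype: percentage of cells carrying an inclusion among all
#' cells showing fluorescent signal, plus the mean cellular intensity used by
#' the expression-level control. Wells with fewer than
#' `min_cells_for_scoring` cells fail QC.
#'
#' @param records Cell records pooled over the well's fields
#'   ([score_cells()] output).
#' @param min_cells_for_scoring QC floor on cell count.
#' @param intensity_mode `"mean_of_means"` or `"pooled"` (area-weighted).
#' @param well,strain_id,construct Metadata carried into the phenotype row.
#' @return One-row data.frame: well, strain_id, construct, n_cells,
#'   pct_inclusion, mean_cell_intensity, diffuse_mean_cell_intensity (the
#'   punctum-excluded expression proxy; the whole-cell mean is mechanically
#'   coupled to inclusion content because puncta concentrate signal),
#'   qc_pass.
#' @export
score_well <- function(records, min_cells_for_scoring = 300L,
                       intensity_mode = c("mean_of_means", "pooled"),
                       well = NA_character_, strain_id = NA_character_,
                       construct = NA_character_) {
  intensity_mode <- match.arg(intensity_mode)
  n <- nrow(records)
  if (n == 0) {
    return(data.frame(well = well, strain_id = strain_id, construct = construct,
                      n_cells = 0L, pct_inclusion = NA_real_,
                      mean_cell_intensity = NA_real_,
                      diffuse_mean_cell_intensity = NA_real_, qc_pass = FALSE,
                      stringsAsFactors = FALSE))
  }
  pct <- 100 * sum(records$has_inclusion) / n
  mci <- if (intensity_mode == "pooled")
    sum(records$mean_intensity * records$area_px) / sum(records$area_px)
  else mean(records$mean_intensity)
  dmci <- if ("diffuse_mean_intensity" %in% names(records))
    mean(records$diffuse_mean_intensity) else NA_real_
  data.frame(well = well, strain_id = strain_id, construct = construct,
             n_cells = n, pct_inclusion = pct, mean_cell_intensity = mci,
             diffuse_mean_cell_intensity = dmci,
             qc_pass = n >= min_cells_for_scoring, stringsAsFactors = FALSE)
}

#' Quantify one image through the full scoring chain
#'
#' Shade correction, background estimation, cell segmentation, inclusion
#' segmentation, per-cell scoring.
#'
#' @param img A `fluor_image`.
#' @param params [segmentation_params()].
#' @param shade_model Shading model passed to [shade_correct()], or `"none"`.
#' @return data.frame of cell records.
#' @export
quantify_image <- function(img, params = segmentation_params(),
                           shade_model = "poly2") {
  if (!identical(shade_model, "none")) img <- shade_correct(img, shade_model)
  bg <- estimate_background(img, params)
  cells <- segment_cells(img, bg, params)
  incl <- segment_inclusions(img, cells, params)
  score_cells(img, cells, incl)
}

#' Quantify a plate of images into per-cell and per-well tables
#'
#' @param images Either a directory of `plate_well_field.tif` files or a list
#'   of `fluor_image` objects.
#' @param platemap Plate map data.frame (plate, well, strain_id, construct,
#'   replicate; `field` optional).
#' @param params [segmentation_params()].
#' @param shade_model Passed to [quantify_image()].
#' @return List with `cells` (CellRecord rows) and `wells` (WellPhenotype
#'   rows, one per plate x well, replicate carried through).
#' @export
quantify_plate <- function(images, platemap, params = segmentation_params(),
                           shade_model = "poly2") {
  if (is.character(images)) {
    dir <- images
    images <- lapply(seq_len(nrow(platemap)), function(i) {
      pm <- platemap[i, ]
      f <- if ("field" %in% names(pm)) pm$field else 1L
      fn <- file.path(dir, sprintf("%s_%s_s%d.tif", pm$plate, pm$well, f))
      px <- read_tiff_gray(fn)
      fluor_image(px, plate = pm$plate, well = pm$well, field = f,
                  strain_id = pm$strain_id, construct = pm$construct)
    })
  }
  cells <- do.call(rbind, lapply(images, quantify_image, params = params,
                                 shade_model = shade_model))
  wells <- list()
  key_img <- vapply(images, function(im) paste(im$plate, im$well), "")
  for (k in unique(key_img)) {
    ims <- images[key_img == k]
    ids <- vapply(ims, function(im) sprintf("%s_%s_s%d", im$plate, im$well,
                                            im$field), "")
    recs <- cells[cells$image %in% ids, , drop = FALSE]
    pm_rows <- platemap[paste(platemap$plate, platemap$well) == k, , drop = FALSE]
    wp <- score_well(recs, params$min_cells_for_scoring,
                     params$intensity_mode,
                     well = paste(ims[[1]]$plate, ims[[1]]$well, sep = "_"),
                     strain_id = ims[[1]]$strain_id,
                     construct = ims[[1]]$construct)
    wp$replicate <- if (nrow(pm_rows)) pm_rows$replicate[1] else NA_integer_
    wells[[k]] <- wp
  }
  list(cells = cells, wells = do.call(rbind, c(wells, list(make.row.names = FALSE))))
}
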
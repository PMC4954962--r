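# Shared fixtures: analytic disc images and truth-matching utilities.

# Flat-background image with discs of given delta above background; optional
# punctum (radius 1) at each disc center with punctum_delta above the disc.
disc_image <- function(shape = c(96L, 96L), background = 200,
                       centers = matrix(c(30, 30), ncol = 2),
                       radii = 6, deltas = 400,
                       punctum_delta = rep(0, nrow(centers))) {
  px <- matrix(background, shape[1], shape[2])
  deltas <- rep_len(deltas, nrow(centers))
  radii <- rep_len(radii, nrow(centers))
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(shape[1]) - centers[i, 1])^2,
                (seq_len(shape[2]) - centers[i, 2])^2, "+")
    px[d2 <= radii[i]^2] <- background + deltas[i]
    if (punctum_delta[i] > 0) {
      px[d2 <= 1.5^2] <- background + deltas[i] + punctum_delta[i]
    }
  }
  fluor_image(px, plate = "P01", well = "A01", field = 1L)
}

# Run the scoring chain on a generated plate and compare per-cell inclusion
# calls against ground truth (cells matched by truth centre pixel).
truth_confusion <- function(plate, params = segmentation_params(),
                            shade_model = "poly2") {
  matched <- 0L; agree <- 0L; unmatched <- 0L
  well_rows <- list()
  for (img in plate$images) {
    id <- sprintf("%s_%s_s%d", img$plate, img$well, img$field)
    tc <- plate$truth_cells[plate$truth_cells$image == id, , drop = FALSE]
    im2 <- if (identical(shade_model, "none")) img else shade_correct(img, shade_model)
    bg <- estimate_background(im2, params)
    cm <- segment_cells(im2, bg, params)
    incl <- segment_inclusions(im2, cm, params)
    recs <- score_cells(im2, cm, incl)
    det <- logical(nrow(tc))
    ok <- logical(nrow(tc))
    for (i in seq_len(nrow(tc))) {
      lab <- cm[round(tc$center_row[i]), round(tc$center_col[i])]
      if (lab == 0) { unmatched <- unmatched + 1L; next }
      matched <- matched + 1L
      det[i] <- TRUE
      ok[i] <- recs$has_inclusion[recs$label == lab] == tc$has_inclusion[i]
    }
    agree <- agree + sum(ok)
    well_rows[[id]] <- data.frame(
      plate = img$plate, well = img$well,
      measured_pct = if (nrow(recs)) 100 * mean(recs$has_inclusion) else NA_real_,
      stringsAsFactors = FALSE)
  }
  wells <- do.call(rbind, well_rows)
  wells <- stats::aggregate(measured_pct ~ plate + well, wells, mean)
  truth <- plate$truth_wells
  truth$true_pct <- 100 * truth$true_fraction
  wells <- merge(wells, truth[, c("plate", "well", "true_pct")],
                 by = c("plate", "well"))
  list(matched = matched, agree = agree, unmatched = unmatched,
       accuracy = agree / matched, wells = wells)
}

# Minimal union-find used as an independent connected-components oracle.
uf_components <- function(nodes, edge_a, edge_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(edge_a)) {
    ra <- find(edge_a[i]); rb <- find(edge_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}
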
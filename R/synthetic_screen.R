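#' Describe a screened strain
#'
#' A strain is one arrayed mutant (or the wild-type reference) carrying either
#' the dsRed-synphilin-1 fusion or the dsRed-only expression control. The
#' `true_*` fields are the planted ground truth the generators render and the
#' downstream estimators are benchmarked against.
#'
#' @param strain_id Unique strain identifier (e.g. `"yfg1d"`).
#' @param gene_id Gene identifier; several ts alleles may share one gene.
#' @param essential Logical; `TRUE` for ts-allele (essential-gene) arm,
#'   `FALSE` for the deletion arm.
#' @param construct `"dsRed_SY1"` (fusion) or `"dsRed_only"` (control).
#' @param true_inclusion_prob Probability in `[0, 1]` that a cell of this
#'   strain carries at least one inclusion. Must be 0 for `dsRed_only`
#'   controls (the bare tag never aggregates).
#' @param true_expression_scale Positive multiplier on the cellular
#'   fluorescence signal (expression level).
#' @param true_generation_time_h Exponential-phase doubling time in hours.
#' @return A one-row `data.frame`; rows from several calls can be `rbind`ed
#'   into a strain table.
#' @export
strain_spec <- function(strain_id, gene_id, essential = FALSE,
                        construct = c("dsRed_SY1", "dsRed_only"),
                        true_inclusion_prob = 0.4,
                        true_expression_scale = 1,
                        true_generation_time_h = 2.5) {
  construct <- match.arg(construct)
  stopifnot(length(strain_id) == 1, length(gene_id) == 1,
            is.logical(essential), length(essential) == 1)
  if (!is.numeric(true_inclusion_prob) || true_inclusion_prob < 0 ||
      true_inclusion_prob > 1)
    stop("true_inclusion_prob must be in [0, 1]")
  if (construct == "dsRed_only" && true_inclusion_prob != 0)
    stop("dsRed_only controls must have true_inclusion_prob = 0")
  if (!is.numeric(true_expression_scale) || true_expression_scale <= 0)
    stop("true_expression_scale must be > 0")
  if (!is.numeric(true_generation_time_h) || true_generation_time_h <= 0)
    stop("true_generation_time_h must be > 0")
  data.frame(strain_id = as.character(strain_id),
             gene_id = as.character(gene_id),
             essential = essential, construct = construct,
             true_inclusion_prob = true_inclusion_prob,
             true_expression_scale = true_expression_scale,
             true_generation_time_h = true_generation_time_h,
             stringsAsFactors = FALSE)
}

#' Imaging configuration for the synthetic plate generator
#'
#' Defaults emulate 16-bit widefield acquisitions of fixed yeast cells: a
#' shaded (vignetted) background, 40-80 cells per field, diffuse cytoplasmic
#' dsRed signal well above the 300-unit cell-isolation threshold, and bright
#' puncta well above the 400-unit inclusion threshold.
#'
#' @param image_shape Integer `(rows, cols)` of each field.
#' @param bit_depth Camera bit depth; pixel values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param background_level Mean background in grayscale units.
#' @param vignette_amplitude Peak-to-edge amplitude of the radial quadratic
#'   illumination falloff (grayscale units); 0 disables shading.
#' @param cells_per_image Integer range `(min, max)` of cells per field.
#' @param cell_radius_px Integer range of cell disc radii in pixels.
#' @param diffuse_signal_delta Diffuse cellular signal above local background
#'   (grayscale units), multiplied by each strain's `true_expression_scale`.
#' @param inclusion_delta Inclusion punctum intensity above the cell's diffuse
#'   level (grayscale units).
#' @param inclusion_radius_px Integer range of punctum radii in pixels.
#' @param noise_sd Additive Gaussian read-noise SD (grayscale units).
#' @param fields_per_well Fields imaged per well.
#' @return A list of class `imaging_config`.
#' @export
imaging_config <- function(image_shape = c(192L, 192L), bit_depth = 16L,
                           background_level = 200, vignette_amplitude = 60,
                           cells_per_image = c(40L, 80L),
                           cell_radius_px = c(4L, 7L),
                           diffuse_signal_delta = 800,
                           inclusion_delta = 800,
                           inclusion_radius_px = c(1L, 2L),
                           noise_sd = 10, fields_per_well = 1L) {
  cfg <- list(image_shape = as.integer(image_shape), bit_depth = as.integer(bit_depth),
              background_level = background_level,
              vignette_amplitude = vignette_amplitude,
              cells_per_image = as.integer(cells_per_image),
              cell_radius_px = as.integer(cell_radius_px),
              diffuse_signal_delta = diffuse_signal_delta,
              inclusion_delta = inclusion_delta,
              inclusion_radius_px = as.integer(inclusion_radius_px),
              noise_sd = noise_sd, fields_per_well = as.integer(fields_per_well))
  with(cfg, {
    stopifnot(length(image_shape) == 2, all(image_shape >= 32),
              bit_depth %in% c(8L, 16L),
              background_level >= 0, vignette_amplitude >= 0,
              diffuse_signal_delta >= 0, inclusion_delta >= 0,
              noise_sd >= 0, fields_per_well >= 1,
              cells_per_image[1] >= 1, cells_per_image[2] >= cells_per_image[1],
              cell_radius_px[1] >= 2, cell_radius_px[2] >= cell_radius_px[1],
              inclusion_radius_px[1] >= 1,
              inclusion_radius_px[2] <= cell_radius_px[1] - 1)
  })
  structure(cfg, class = "imaging_config")
}

vignette_surface <- function(shape, amplitude) {
  r <- seq_len(shape[1]) - (shape[1] + 1) / 2
  c <- seq_len(shape[2]) - (shape[2] + 1) / 2
  d2 <- outer(r^2, c^2, "+")
  amplitude * (1 - d2 / max(d2))
}

# Place n non-overlapping discs; drops down to fewer cells after bounded
# retries so degenerate configs still return an image.
place_cells <- function(n, shape, radius_range, max_tries = 40L) {
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      rad <- if (radius_range[1] == radius_range[2]) radius_range[1]
             else sample(radius_range[1]:radius_range[2], 1)
      row <- stats::runif(1, rad + 2, shape[1] - rad - 1)
      col <- stats::runif(1, rad + 2, shape[2] - rad - 1)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - row)^2 + (centers[, 2] - col)^2) >
              radii + rad + 1)) {
        centers <- rbind(centers, c(row, col))
        radii <- c(radii, rad)
        placed <- TRUE
        break
      }
    }
    if (!placed) break  # field is full: render fewer cells
  }
  list(centers = centers, radii = radii)
}

disc_pixels <- function(center, radius, shape) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(shape[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(shape[2], ceiling(center[2] + radius))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, "+")
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  cbind(rows[inside[, 1]], cols[inside[, 2]])
}

well_ids <- function(n) {
  rows <- LETTERS[1:8]; cols <- sprintf("%02d", 1:12)
  per_plate <- as.vector(t(outer(rows, cols, paste0)))
  plate <- (seq_len(n) - 1) %/% 96 + 1
  data.frame(plate = sprintf("P%02d", plate),
             well = per_plate[(seq_len(n) - 1) %% 96 + 1],
             stringsAsFactors = FALSE)
}

#' Generate synthetic fluorescence plates with planted ground truth
#'
#' Renders one well per strain x replicate: yeast-cell-sized discs of diffuse
#' dsRed signal over a vignetted background; each cell is flagged aggregated
#' with probability `true_inclusion_prob` and then carries 1-3 bright puncta.
#' Ground truth records every per-cell decision, so segmentation accuracy can
#' be measured exactly.
#'
#' @param strains Strain table (rows from [strain_spec()]).
#' @param cfg An [imaging_config()].
#' @param replicates Replicate wells per strain (>= 1).
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A list with `images` (list of `fluor_image`), `platemap`
#'   (plate, well, field, strain_id, gene_id, construct, replicate),
#'   `truth_cells` (per-cell table: image, label, center_row, center_col,
#'   radius, has_inclusion) and `truth_wells` (per-well true inclusion
#'   fraction, exactly flagged/total).
#' @export
generate_plate_images <- function(strains, cfg = imaging_config(),
                                  replicates = 3L, seed = 1L) {
  stopifnot(inherits(cfg, "imaging_config"), replicates >= 1,
            nrow(strains) >= 1)
  set.seed(as.integer(seed))
  shape <- cfg$image_shape
  vig <- vignette_surface(shape, cfg$vignette_amplitude)
  n_wells <- nrow(strains) * replicates
  wid <- well_ids(n_wells)
  images <- vector("list", n_wells * cfg$fields_per_well)
  platemap <- vector("list", n_wells * cfg$fields_per_well)
  truth_cells <- vector("list", n_wells * cfg$fields_per_well)
  truth_wells <- vector("list", n_wells)
  k <- 0L; wrow <- 0L
  for (si in seq_len(nrow(strains))) {
    st <- strains[si, ]
    for (rep in seq_len(replicates)) {
      wrow <- wrow + 1L
      well_flags <- logical(0)
      for (f in seq_len(cfg$fields_per_well)) {
        k <- k + 1L
        n_cells <- sample(cfg$cells_per_image[1]:cfg$cells_per_image[2], 1)
        pl <- place_cells(n_cells, shape, cfg$cell_radius_px)
        n <- length(pl$radii)
        img <- matrix(cfg$background_level, shape[1], shape[2]) + vig
        delta <- cfg$diffuse_signal_delta * st$true_expression_scale
        flags <- if (n > 0) stats::runif(n) < st$true_inclusion_prob else logical(0)
        img_id <- sprintf("%s_%s_s%d", wid$plate[wrow], wid$well[wrow], f)
        for (i in seq_len(n)) {
          cpx <- disc_pixels(pl$centers[i, ], pl$radii[i], shape)
          img[cpx] <- img[cpx] + delta
          if (flags[i]) {
            # puncta: total area capped below 40% of the cell disc so the
            # diffuse level stays the within-cell majority signal
            n_inc <- sample(1:3, 1)
            budget <- 0.4 * nrow(cpx)
            used <- 0
            for (j in seq_len(n_inc)) {
              irad <- if (cfg$inclusion_radius_px[1] == cfg$inclusion_radius_px[2])
                cfg$inclusion_radius_px[1]
              else sample(cfg$inclusion_radius_px[1]:cfg$inclusion_radius_px[2], 1)
              maxoff <- pl$radii[i] - irad
              ang <- stats::runif(1, 0, 2 * pi); off <- stats::runif(1, 0, maxoff)
              ic <- pl$centers[i, ] + off * c(cos(ang), sin(ang))
              ipx <- disc_pixels(ic, irad, shape)
              if (used + nrow(ipx) > budget && j > 1) break
              img[ipx] <- cfg$background_level + vig[ipx] + delta + cfg$inclusion_delta
              used <- used + nrow(ipx)
            }
          }
        }
        if (cfg$noise_sd > 0)
          img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
        img <- matrix(pmin(pmax(round(img), 0), 2^cfg$bit_depth - 1),
                      shape[1], shape[2])
        images[[k]] <- fluor_image(img, plate = wid$plate[wrow],
                                   well = wid$well[wrow], field = f,
                                   strain_id = st$strain_id,
                                   construct = st$construct)
        platemap[[k]] <- data.frame(plate = wid$plate[wrow], well = wid$well[wrow],
                                    field = f, strain_id = st$strain_id,
                                    gene_id = st$gene_id, construct = st$construct,
                                    replicate = rep, stringsAsFactors = FALSE)
        truth_cells[[k]] <- if (n > 0) data.frame(
          image = img_id, label = seq_len(n),
          center_row = pl$centers[, 1], center_col = pl$centers[, 2],
          radius = pl$radii, has_inclusion = flags,
          stringsAsFactors = FALSE) else NULL
        well_flags <- c(well_flags, flags)
      }
      truth_wells[[wrow]] <- data.frame(
        plate = wid$plate[wrow], well = wid$well[wrow],
        strain_id = st$strain_id, replicate = rep,
        n_cells = length(well_flags),
        n_inclusion = sum(well_flags),
        true_fraction = if (length(well_flags)) mean(well_flags) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(images = images,
       platemap = do.call(rbind, platemap),
       truth_cells = do.call(rbind, truth_cells),
       truth_wells = do.call(rbind, truth_wells))
}

#' Write a generated plate to disk
#'
#' Writes one 16-bit grayscale TIFF per field (`plate_well_field.tif`), the
#' plate map as `plate_map.csv`, per-cell truth as `truth_cells.tsv` and
#' per-well truth as `truth_wells.json`.
#'
#' @param plate Result of [generate_plate_images()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (im in plate$images) {
    fn <- sprintf("%s_%s_s%d.tif", im$plate, im$well, im$field)
    write_tiff_gray(im$pixels, file.path(dir, fn))
  }
  utils::write.csv(plate$platemap, file.path(dir, "plate_map.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(plate$truth_cells))
    utils::write.table(plate$truth_cells, file.path(dir, "truth_cells.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(plate$truth_wells, file.path(dir, "truth_wells.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Generate synthetic growth curves
#'
#' Optical density every `sampling_interval_h` hours for `duration_h` hours
#' (145 points at the default 0.5 h / 72 h). Curves are lag + exact
#' exponential (doubling time `true_generation_time_h`) + saturation toward
#' the carrying capacity, with additive Gaussian noise; OD is blank-corrected
#' (a shared optical offset can be added via `blank_od` to exercise blank
#' estimation).
#'
#' @param strains Strain table; one curve set per row (construct included).
#' @param sampling_interval_h Sampling interval in hours.
#' @param duration_h Total duration in hours; must be a multiple of the
#'   interval.
#' @param lag_h Lag-phase length in hours.
#' @param carrying_capacity Stationary-phase OD.
#' @param noise_sd Additive OD noise SD.
#' @param od0 Inoculation density (OD); default well below detection, as in
#'   Bioscreen micro-cultivation.
#' @param blank_od Optical blank added to every reading (default 0 =
#'   pre-corrected export).
#' @param replicates Replicate wells per strain row.
#' @param seed Integer seed.
#' @return List with `od` (data.frame: `time_h` then one column per well) and
#'   `map` (well, strain_id, gene_id, construct, replicate).
#' @export
generate_growth_curves <- function(strains, sampling_interval_h = 0.5,
                                   duration_h = 72, lag_h = 2,
                                   carrying_capacity = 1.5,
                                   noise_sd = 0.005, od0 = 0.005,
                                   blank_od = 0, replicates = 3L, seed = 1L) {
  stopifnot(nrow(strains) >= 1, replicates >= 1, od0 > 0,
            carrying_capacity > od0, noise_sd >= 0)
  n_steps <- duration_h / sampling_interval_h
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration_h must be an integer multiple of sampling_interval_h")
  if (any(strains$true_generation_time_h <= 0))
    stop("non-positive generation time")
  set.seed(as.integer(seed))
  t <- seq(0, duration_h, by = sampling_interval_h)
  od <- data.frame(time_h = t)
  map <- NULL
  half_k <- carrying_capacity / 2
  for (si in seq_len(nrow(strains))) {
    st <- strains[si, ]
    g <- st$true_generation_time_h
    # exact log2-linear exponential phase, then exponential approach to K
    t_switch <- lag_h + g * log2(half_k / od0)
    n_t <- ifelse(t <= lag_h, od0,
           ifelse(t <= t_switch, od0 * 2^((t - lag_h) / g),
                  carrying_capacity - half_k * 2^(-(t - t_switch) / g)))
    for (rep in seq_len(replicates)) {
      y <- n_t + blank_od
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
      y <- pmax(y, 0)
      wname <- sprintf("%s_%s_r%d", st$strain_id, st$construct, rep)
      od[[wname]] <- y
      map <- rbind(map, data.frame(well = wname, strain_id = st$strain_id,
                                   gene_id = st$gene_id,
                                   construct = st$construct, replicate = rep,
                                   stringsAsFactors = FALSE))
    }
  }
  list(od = od, map = map)
}

#' Generate a synthetic gene-to-term annotation set
#'
#' Genes are assigned to terms uniformly at random, except an optional
#' planted term that is forced to contain a requested number of designated
#' hit genes — the positive control for enrichment.
#'
#' @param universe Character vector of background gene ids.
#' @param term_sizes Named integer vector: term id -> number of annotated
#'   universe genes.
#' @param planted Optional list `(term =, hits =, overlap =)`: force `overlap`
#'   genes of `hits` into `term`.
#' @param seed Integer seed.
#' @return List with `mapping` (data.frame gene, term) and `universe`.
#' @export
generate_annotation <- function(universe, term_sizes, planted = NULL, seed = 1L) {
  stopifnot(length(universe) >= 1, !anyDuplicated(universe),
            all(term_sizes >= 1), all(term_sizes <= length(universe)),
            !is.null(names(term_sizes)))
  set.seed(as.integer(seed))
  rows <- list()
  for (term in names(term_sizes)) {
    size <- term_sizes[[term]]
    if (!is.null(planted) && identical(term, planted$term)) {
      ov <- planted$overlap
      if (ov > size) stop("planted overlap exceeds term size")
      if (ov > length(planted$hits)) stop("planted overlap exceeds hit-list size")
      members <- sample(planted$hits, ov)
      rest <- setdiff(universe, members)
      members <- c(members, sample(rest, size - ov))
    } else {
      members <- sample(universe, size)
    }
    rows[[term]] <- data.frame(gene = members, term = term,
                               stringsAsFactors = FALSE)
  }
  list(mapping = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       universe = universe)
}

#' Generate a synthetic interaction edge list
#'
#' Each planted module becomes a connected set of physical edges (a random
#' spanning tree plus extra within-module edges); decoy genetic-type edges
#' are added between random hit pairs. Downstream physical-only filtering
#' must recover the modules exactly as connected components.
#'
#' @param hits Character vector of hit gene ids.
#' @param modules List of character vectors, each a subset of `hits`.
#' @param extra_genetic_edges Number of genetic decoy edges.
#' @param seed Integer seed.
#' @return data.frame with columns gene_a, gene_b, kind, source.
#' @export
generate_interactions <- function(hits, modules = list(),
                                  extra_genetic_edges = 0L, seed = 1L) {
  stopifnot(is.list(modules))
  for (m in modules)
    if (!all(m %in% hits)) stop("module genes must be a subset of hits")
  set.seed(as.integer(seed))
  edges <- list()
  for (mi in seq_along(modules)) {
    m <- modules[[mi]]
    if (length(m) < 2) next
    perm <- sample(m)
    # random spanning tree: attach each node to a random earlier node
    for (i in 2:length(perm)) {
      j <- if (i == 2) 1L else sample(i - 1L, 1)
      edges[[length(edges) + 1]] <- c(perm[j], perm[i], "physical")
    }
    if (length(m) >= 3) {  # a few redundant in-module edges
      n_extra <- sample(0:(length(m) - 2), 1)
      for (e in seq_len(n_extra)) {
        pair <- sample(m, 2)
        edges[[length(edges) + 1]] <- c(pair[1], pair[2], "physical")
      }
    }
  }
  if (extra_genetic_edges > 0) {
    if (length(hits) < 2) stop("need >= 2 hits for genetic edges")
    for (e in seq_len(extra_genetic_edges)) {
      pair <- sample(hits, 2)
      edges[[length(edges) + 1]] <- c(pair[1], pair[2], "genetic")
    }
  }
  if (length(edges) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      kind = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, edges)
  data.frame(gene_a = m[, 1], gene_b = m[, 2], kind = m[, 3],
             source = "synthetic", stringsAsFactors = FALSE)
}

#' Generate replicate phenotype tables directly (no imaging)
#'
#' Emulates the per-strain replicate wells the hit caller consumes: the
#' percentage of inclusion-carrying cells is the planted probability (scaled
#' down when expression is reduced, since low expression lowers both signal
#' and inclusion formation) plus Gaussian replicate noise; the mean cellular
#' intensity is the expression scale times a baseline plus noise.
#'
#' @param strains Strain table (dsRed_SY1 rows; `true_inclusion_prob` is the
#'   planted inclusion fraction).
#' @param replicates Replicate wells per strain.
#' @param pct_noise_sd Replicate SD of the inclusion percentage (points).
#' @param intensity_mean Baseline mean cellular intensity (grayscale units)
#'   at expression scale 1.
#' @param intensity_sd Replicate SD of mean intensity.
#' @param seed Integer seed.
#' @return Long data.frame: strain_id, gene_id, construct, replicate,
#'   pct_inclusion, mean_cell_intensity.
#' @export
generate_phenotypes <- function(strains, replicates = 3L, pct_noise_sd = 3,
                                intensity_mean = 1000, intensity_sd = 50,
                                seed = 1L) {
  stopifnot(replicates >= 2)
  set.seed(as.integer(seed))
  out <- list()
  for (si in seq_len(nrow(strains))) {
    st <- strains[si, ]
    true_pct <- 100 * st$true_inclusion_prob * min(1, st$true_expression_scale)
    pct <- pmin(pmax(stats::rnorm(replicates, true_pct, pct_noise_sd), 0), 100)
    intens <- pmax(stats::rnorm(replicates,
                                intensity_mean * st$true_expression_scale,
                                intensity_sd), 0)
    out[[si]] <- data.frame(strain_id = st$strain_id, gene_id = st$gene_id,
                            construct = st$construct,
                            replicate = seq_len(replicates),
                            pct_inclusion = pct, mean_cell_intensity = intens,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
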
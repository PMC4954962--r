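#' Run the screen pipeline end to end
#'
#' Executes (optionally) simulate, then quantify, call-hits, enrich, network
#' and growth from a single configuration, writing each stage's tables plus a
#' machine-readable `summary.json` with stage provenance (input hashes,
#' parameters, category counts, significant terms, module sizes, significant
#' toxicity strains). A stage failure aborts with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config Nested list (see [read_config()]) or path to a config file.
#'   Recognized sections: `simulate` (seed, n_strains, replicates, noise_sd,
#'   fields_per_well, wt_inclusion_prob, mutant settings...), `quantify`
#'   (segmentation parameter overrides, shade_model), `hits` (wt_strain,
#'   alpha, min_effect, effect_mode), `enrich` (annotation path or
#'   `use_simulated`, correction), `network` (edges path or `use_simulated`),
#'   `growth` (od path or `use_simulated`, window_points, blank), and
#'   top-level `out_dir`.
#' @return The summary list, invisibly; `summary.json` and per-stage TSVs are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf("stage %s: done", name)
    res
  }
  summary <- list(stages = list(), parameters = config)
  hash_file <- function(p) unname(tools::md5sum(p))

  ## ---- simulate -------------------------------------------------------
  sim <- config$simulate %||% list()
  seed <- as.integer(sim$seed %||% 1L)
  sim_out <- stage("simulate", {
    n_mut <- as.integer(sim$n_strains %||% 6L)
    wt_p <- sim$wt_inclusion_prob %||% 0.4
    strains <- strain_spec("WT_his3", "HIS3", construct = "dsRed_SY1",
                           true_inclusion_prob = wt_p,
                           true_generation_time_h = sim$wt_generation_time_h %||% 2.5)
    set.seed(seed)
    probs <- stats::runif(n_mut, 0, wt_p)
    scales <- rep(1, n_mut)
    n_conf <- as.integer(sim$n_confounded %||% max(1L, n_mut %/% 3L))
    scales[seq_len(n_conf)] <- sim$confounded_scale %||% 0.5
    for (i in seq_len(n_mut)) {
      strains <- rbind(strains, strain_spec(
        sprintf("mut%02d", i), sprintf("GENE%02d", i),
        construct = "dsRed_SY1", true_inclusion_prob = probs[i],
        true_expression_scale = scales[i],
        true_generation_time_h = (sim$wt_generation_time_h %||% 2.5) +
          stats::runif(1, 0.3, 0.8)))
    }
    cfg <- imaging_config(noise_sd = sim$noise_sd %||% 10,
                          fields_per_well = as.integer(sim$fields_per_well %||% 1L))
    plate <- generate_plate_images(strains, cfg,
                                   replicates = as.integer(sim$replicates %||% 3L),
                                   seed = seed)
    img_dir <- file.path(out_dir, "images")
    write_plate(plate, img_dir)
    ctrl <- strains
    ctrl$construct <- "dsRed_only"; ctrl$true_inclusion_prob <- 0
    ctrl$true_generation_time_h <- sim$wt_generation_time_h %||% 2.5
    ctrl$strain_id <- strains$strain_id  # same strain, control plasmid
    growth <- generate_growth_curves(rbind(strains, ctrl), seed = seed + 1L,
                                     noise_sd = sim$growth_noise_sd %||% 0.005)
    utils::write.csv(growth$od, file.path(out_dir, "growth.csv"),
                     row.names = FALSE)
    list(strains = strains, plate = plate, img_dir = img_dir, growth = growth)
  })
  summary$stages$simulate <- list(
    seed = seed, n_strains = nrow(sim_out$strains),
    n_images = length(sim_out$plate$images),
    platemap_hash = hash_file(file.path(sim_out$img_dir, "plate_map.csv")))

  ## ---- quantify -------------------------------------------------------
  q <- config$quantify %||% list()
  params <- segmentation_params(
    cell_delta = q$cell_delta %||% 300,
    inclusion_delta = q$inclusion_delta %||% 400,
    min_cells_for_scoring = as.integer(q$min_cells_for_scoring %||% 30L))
  quant <- stage("quantify", quantify_plate(sim_out$plate$images,
                                            sim_out$plate$platemap, params,
                                            shade_model = q$shade_model %||% "poly2"))
  utils::write.table(quant$cells, file.path(out_dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(quant$wells, file.path(out_dir, "wells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary$stages$quantify <- list(
    n_cells = nrow(quant$cells), n_wells = nrow(quant$wells),
    cell_delta = params$cell_delta, inclusion_delta = params$inclusion_delta,
    wells_hash = hash_file(file.path(out_dir, "wells.tsv")))

  ## ---- call-hits ------------------------------------------------------
  h <- config$hits %||% list()
  hits_tab <- stage("call-hits", {
    wells <- quant$wells[quant$wells$qc_pass, , drop = FALSE]
    # intensity = "diffuse" uses the punctum-excluded expression proxy,
    # decoupling the intensity control from the inclusion phenotype
    int_col <- if (identical(h$intensity %||% "mean", "diffuse"))
      "diffuse_mean_cell_intensity" else "mean_cell_intensity"
    ph <- data.frame(strain_id = wells$strain_id, replicate = wells$replicate,
                     pct_inclusion = wells$pct_inclusion,
                     mean_cell_intensity = wells[[int_col]],
                     stringsAsFactors = FALSE)
    call_hits(ph, wt_strain = h$wt_strain %||% "WT_his3",
              criteria = hit_criteria(
                alpha_inclusion = h$alpha %||% 0.05,
                min_effect = h$min_effect %||% 25,
                effect_mode = h$effect_mode %||% "relative_to_wt"))
  })
  utils::write.table(hits_tab, file.path(out_dir, "hits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(hits_tab[hits_tab$category == "expression_confounded", ],
                     file.path(out_dir, "confounded.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cat_counts <- table(factor(hits_tab$category,
                             levels = c("decreased", "increased",
                                        "expression_confounded", "not_hit")))
  summary$stages$call_hits <- list(category_counts = as.list(cat_counts),
                                   n_strains = nrow(hits_tab))

  ## ---- enrich ---------------------------------------------------------
  en <- config$enrich %||% list()
  hit_genes <- sim_out$strains$gene_id[match(
    hits_tab$strain_id[hits_tab$category %in% c("decreased", "increased")],
    sim_out$strains$strain_id)]
  enr <- stage("enrich", {
    ann <- if (!is.null(en$annotation)) {
      if (!file.exists(en$annotation))
        stop("annotation file not found: ", en$annotation)
      universe <- unique(sim_out$strains$gene_id)
      read_annotation(en$annotation, universe)
    } else {
      universe <- unique(sim_out$strains$gene_id)
      planted <- if (length(hit_genes) >= 2)
        list(term = "T_planted", hits = hit_genes,
             overlap = min(length(hit_genes),
                           max(2L, length(hit_genes) - 1L)))
      else NULL
      sizes <- c(T_planted = max(3L, length(hit_genes) + 1L),
                 T_null1 = max(2L, length(universe) %/% 3L),
                 T_null2 = max(2L, length(universe) %/% 4L))
      generate_annotation(universe, sizes, planted = planted, seed = seed + 2L)
    }
    if (length(hit_genes) == 0) NULL
    else enrich(hit_genes, ann,
                correction = en$correction %||% "bonferroni")
  })
  if (!is.null(enr))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  summary$stages$enrich <- list(
    n_terms = if (is.null(enr)) 0L else nrow(enr),
    significant_terms = if (is.null(enr)) character(0)
                        else enr$term[enr$significant])

  ## ---- network --------------------------------------------------------
  nw <- config$network %||% list()
  net <- stage("network", {
    if (length(hit_genes) == 0) NULL
    else {
      edges <- if (!is.null(nw$edges)) load_edges(nw$edges)
      else generate_interactions(
        hit_genes,
        modules = if (length(hit_genes) >= 2) list(hit_genes[1:min(3, length(hit_genes))])
                  else list(),
        extra_genetic_edges = if (length(hit_genes) >= 2) 2L else 0L,
        seed = seed + 3L)
      build_hit_network(hit_genes, edges)
    }
  })
  if (!is.null(net)) export_network(net, out_dir)
  summary$stages$network <- list(
    module_sizes = if (is.null(net)) integer(0) else net$modules$size)

  ## ---- growth ---------------------------------------------------------
  gr <- config$growth %||% list()
  tox <- stage("growth", {
    growth <- if (!is.null(gr$od)) {
      list(od = read_growth_csv(gr$od), map = utils::read.csv(gr$platemap))
    } else sim_out$growth
    gt <- generation_times(growth$od, growth$map,
                           window_points = as.integer(gr$window_points %||% 9L),
                           blank = gr$blank %||% 0)
    utils::write.table(gt, file.path(out_dir, "generation_times.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    wt <- h$wt_strain %||% "WT_his3"
    muts <- setdiff(unique(gt$strain_id), wt)
    do.call(rbind, lapply(muts, toxicity_test, gtimes = gt, wt_strain = wt))
  })
  utils::write.table(tox, file.path(out_dir, "toxicity.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  summary$stages$growth <- list(
    significant_toxicity = tox$strain_id[tox$significant])

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete: %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}

#' Command-line entry point
#'
#' `inclusion-screen <simulate|quantify|call-hits|enrich|network|growth|run>`
#' — see `exec/inclusion-screen` in the installed package. `run` drives
#' [run_pipeline()] from `--config FILE`; the single-stage verbs operate on
#' files produced by earlier stages.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
inclusion_screen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: inclusion-screen <command> [flags]",
    "  run       --config FILE",
    "  quantify  --images DIR --platemap FILE --out DIR",
    "            [--cell-delta 300] [--inclusion-delta 400] [--min-cells 300]",
    "  call-hits --wells FILE --wt-strain ID --out FILE",
    "            [--alpha 0.05] [--min-effect 25] [--effect-mode relative_to_wt]",
    "  enrich    --hits FILE --annotation FILE --universe FILE --out FILE",
    "            [--correction bonferroni]",
    "  network   --hits FILE --edges FILE --out DIR",
    "  growth    --od FILE --platemap FILE --out DIR [--window 9]",
    sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  flags <- list()
  i <- 2
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    flags[[sub("^--", "", args[i])]] <- args[i + 1]
    i <- i + 2
  }
  getf <- function(name, default = NULL) {
    v <- flags[[name]]
    if (is.null(v)) {
      if (is.null(default)) stop("missing required flag --", name)
      default
    } else v
  }
  status <- tryCatch({
    switch(cmd,
      run = {
        run_pipeline(getf("config"))
      },
      quantify = {
        pm <- utils::read.csv(getf("platemap"), stringsAsFactors = FALSE)
        params <- segmentation_params(
          cell_delta = as.numeric(getf("cell-delta", "300")),
          inclusion_delta = as.numeric(getf("inclusion-delta", "400")),
          min_cells_for_scoring = as.integer(getf("min-cells", "300")))
        res <- quantify_plate(getf("images"), pm, params)
        out <- getf("out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(res$cells, file.path(out, "cells.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        utils::write.table(res$wells, file.path(out, "wells.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
      },
      `call-hits` = {
        wells <- utils::read.delim(getf("wells"), stringsAsFactors = FALSE)
        wells <- wells[wells$qc_pass, , drop = FALSE]
        hits <- call_hits(wells, getf("wt-strain"),
                          hit_criteria(
                            alpha_inclusion = as.numeric(getf("alpha", "0.05")),
                            min_effect = as.numeric(getf("min-effect", "25")),
                            effect_mode = getf("effect-mode", "relative_to_wt")))
        utils::write.table(hits, getf("out"), sep = "\t", row.names = FALSE,
                           quote = FALSE)
      },
      enrich = {
        hits <- readLines(getf("hits"))
        universe <- readLines(getf("universe"))
        ann <- read_annotation(getf("annotation"), universe)
        res <- enrich(hits, ann, correction = getf("correction", "bonferroni"))
        utils::write.table(res, getf("out"), sep = "\t", row.names = FALSE,
                           quote = FALSE)
      },
      network = {
        hits <- readLines(getf("hits"))
        edges <- load_edges(getf("edges"))
        net <- build_hit_network(hits, edges)
        export_network(net, getf("out"))
      },
      growth = {
        od <- read_growth_csv(getf("od"))
        map <- utils::read.csv(getf("platemap"), stringsAsFactors = FALSE)
        gt <- generation_times(od, map,
                               window_points = as.integer(getf("window", "9")))
        out <- getf("out")
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(gt, file.path(out, "generation_times.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      },
      { cat(usage, "\n"); stop("unknown command: ", cmd) })
    0L
  }, error = function(e) {
    message("inclusion-screen: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
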
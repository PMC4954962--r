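#' Two-sample Student's t-test (pooled variance)
#'
#' The classical equal-variance two-sample t with `n_a + n_b - 2` degrees of
#' freedom and a two-sided p-value — the screen's named test. Degenerate
#' inputs are resolved by contract: zero pooled variance with equal means
#' gives `t = 0, p = 1`; zero pooled variance with unequal means gives
#' `p = 0` flagged `degenerate`.
#'
#' @param a,b Numeric samples, each with >= 2 values.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
students_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Hit-calling criteria
#'
#' The screen's three published rules: (1) the inclusion-percentage difference
#' from wild type is significant at `alpha_inclusion` by Student's t-test,
#' (2) the effect is at least `min_effect` (interpreted per `effect_mode`),
#' and (3) the fluorescence intensity shows no significant change at
#' `alpha_intensity`. Strains passing (1) but failing (3) are routed to the
#' expression-confounded category.
#'
#' `effect_mode = "relative_to_wt"` (default) reads "at least 25%" as a
#' fraction of the wild-type percentage, matching the screen's WT-relative
#' normalized reporting; `"absolute_points"` reads it as percentage points.
#'
#' @param alpha_inclusion Significance cutoff for the inclusion phenotype.
#' @param min_effect Minimum effect size (percent).
#' @param effect_mode `"relative_to_wt"` or `"absolute_points"`.
#' @param alpha_intensity Significance cutoff for the intensity control
#'   (two-sided: it catches both reduced and elevated expression).
#' @return List of class `hit_criteria`.
#' @export
hit_criteria <- function(alpha_inclusion = 0.05, min_effect = 25,
                         effect_mode = c("relative_to_wt", "absolute_points"),
                         alpha_intensity = 0.05) {
  stopifnot(alpha_inclusion > 0, alpha_inclusion <= 1, min_effect > 0,
            alpha_intensity > 0, alpha_intensity <= 1)
  structure(list(alpha_inclusion = alpha_inclusion, min_effect = min_effect,
                 effect_mode = match.arg(effect_mode),
                 alpha_intensity = alpha_intensity),
            class = "hit_criteria")
}

#' Call screen hits against the wild-type reference
#'
#' Per strain: `p_inclusion` from [students_t()] on the replicate inclusion
#' percentages vs WT, `p_intensity` on the replicate mean intensities vs WT,
#' effect from the mean difference. Categories: `decreased`/`increased` when
#' criteria 1+2 hold and intensity is unchanged; `expression_confounded` when
#' the inclusion change is significant but intensity also changed
#' significantly; `not_hit` otherwise. Every strain receives exactly one
#' category.
#'
#' @param phenotypes Long data.frame of replicate phenotypes (columns
#'   strain_id, replicate, pct_inclusion, mean_cell_intensity), QC-failed
#'   wells already excluded.
#' @param wt_strain Strain id of the wild-type reference in `phenotypes`.
#' @param criteria [hit_criteria()].
#' @return data.frame of hit calls: strain_id, category, p_inclusion,
#'   p_intensity, effect (signed percent, per `effect_mode`),
#'   normalized_pct (WT anchored at 50), n_replicates.
#' @export
call_hits <- function(phenotypes, wt_strain, criteria = hit_criteria()) {
  stopifnot(inherits(criteria, "hit_criteria"))
  wt <- phenotypes[phenotypes$strain_id == wt_strain, , drop = FALSE]
  if (nrow(wt) < 2) stop("wild-type reference '", wt_strain,
                         "' missing or has < 2 replicates")
  wt_pct <- wt$pct_inclusion
  wt_int <- wt$mean_cell_intensity
  mut_ids <- setdiff(unique(phenotypes$strain_id), wt_strain)
  out <- list()
  for (id in mut_ids) {
    m <- phenotypes[phenotypes$strain_id == id, , drop = FALSE]
    if (nrow(m) < 2) {
      message("call_hits: strain ", id, " has < 2 replicates, skipped")
      next
    }
    t_inc <- students_t(m$pct_inclusion, wt_pct)
    t_int <- students_t(m$mean_cell_intensity, wt_int)
    diff_pts <- mean(m$pct_inclusion) - mean(wt_pct)
    effect <- if (criteria$effect_mode == "relative_to_wt") {
      if (mean(wt_pct) <= 0) stop("wild-type inclusion percentage is zero")
      100 * diff_pts / mean(wt_pct)
    } else diff_pts
    sig_inc <- t_inc$p <= criteria$alpha_inclusion
    big <- abs(effect) >= criteria$min_effect
    sig_int <- t_int$p <= criteria$alpha_intensity
    category <- if (sig_inc && sig_int) "expression_confounded"
    else if (sig_inc && big) { if (diff_pts < 0) "decreased" else "increased" }
    else "not_hit"
    out[[id]] <- data.frame(
      strain_id = id, category = category,
      p_inclusion = t_inc$p, p_intensity = t_int$p, effect = effect,
      normalized_pct = normalize_to_wt(mean(m$pct_inclusion), mean(wt_pct)),
      n_replicates = nrow(m), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Normalize an inclusion percentage to the wild-type anchor
#'
#' Reporting scale in which the wild-type percentage is set to 50%; values
#' are not capped, so increased-inclusion strains exceed 50.
#'
#' @param pct_mut Mutant percentage of inclusion-carrying cells.
#' @param pct_wt Wild-type percentage (> 0).
#' @return `50 * pct_mut / pct_wt`.
#' @export
normalize_to_wt <- function(pct_mut, pct_wt) {
  if (any(pct_wt <= 0)) stop("wild-type percentage must be > 0 to normalize")
  50 * pct_mut / pct_wt
}

#' Confirmation rate of automated hits against manual microscopy
#'
#' @param automated_hits Character set of automated hit strains.
#' @param manually_confirmed Character set of manually confirmed strains
#'   (must be a subset of `automated_hits`).
#' @return List with `confirmation_pct` and `false_positive_pct`
#'   (their sum is 100).
#' @export
confirmation_rate <- function(automated_hits, manually_confirmed) {
  automated_hits <- unique(automated_hits)
  manually_confirmed <- unique(manually_confirmed)
  if (length(automated_hits) == 0) stop("empty automated hit set")
  if (!all(manually_confirmed %in% automated_hits))
    stop("manually confirmed strains must be a subset of automated hits")
  conf <- 100 * length(manually_confirmed) / length(automated_hits)
  list(confirmation_pct = conf, false_positive_pct = 100 - conf)
}

#' Build the screen background registry
#'
#' Combines the deletion-collection and ts-allele manifests into the strain
#' count and the deduplicated gene universe used as the enrichment
#' background. Several ts alleles of one essential gene collapse to a single
#' gene.
#'
#' @param deletion_manifest data.frame with `strain_id`, `gene_id` (deletion
#'   arm).
#' @param ts_manifest data.frame with `strain_id`, `gene_id` (ts-allele arm);
#'   may be empty.
#' @return List: `strain_count`, `gene_universe` (character), `n_deletion`,
#'   `n_ts`, `essential_genes` (unique ts-covered genes).
#' @export
build_background_registry <- function(deletion_manifest, ts_manifest) {
  need <- c("strain_id", "gene_id")
  stopifnot(all(need %in% names(deletion_manifest)))
  if (nrow(ts_manifest) > 0) stopifnot(all(need %in% names(ts_manifest)))
  all_ids <- c(deletion_manifest$strain_id, ts_manifest$strain_id)
  if (anyDuplicated(all_ids))
    stop("duplicate strain_id across manifests: ",
         paste(unique(all_ids[duplicated(all_ids)])[1:3], collapse = ", "))
  essential <- unique(ts_manifest$gene_id)
  list(strain_count = nrow(deletion_manifest) + nrow(ts_manifest),
       gene_universe = union(deletion_manifest$gene_id, essential),
       n_deletion = nrow(deletion_manifest),
       n_ts = nrow(ts_manifest),
       essential_genes = essential)
}
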
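#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the number of term-annotated genes in a hit list of size
#' `n` drawn without replacement from a universe of `N` genes of which `K`
#' are annotated. Terms are summed in log space (via `lchoose`) with the
#' largest term factored out, so tiny tails keep full relative precision.
#'
#' @param k Observed overlap (hits annotated to the term).
#' @param n Hit-list size.
#' @param K Universe genes annotated to the term.
#' @param N Universe size.
#' @return The tail probability; exactly 1 when `k <= 0`, exactly 0 when
#'   `k > min(n, K)`.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (!(k >= 0 && n <= N && K <= N && k <= n && n >= 0 && K >= 0))
    stop("hypergeometric bounds violated: need 0 <= k <= n <= N, K <= N")
  hi <- min(n, K)
  if (k <= 0) return(1)
  if (k > hi) return(0)
  i <- k:hi
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

#' Multiple-hypothesis correction for enrichment p-values
#'
#' `"bonferroni"`: `min(1, m * p)` with `m` the number of tested terms.
#' `"resampling"`: simulation-based correction — the corrected p of a term is
#' the fraction of random same-size hit lists whose *best* raw p over all
#' terms is at most the observed p (supply `null_best_p` from
#' [enrichment_null_best_p()] or your own simulation).
#'
#' @param p_raws Numeric vector of raw p-values in (0, 1].
#' @param method `"bonferroni"` or `"resampling"`.
#' @param null_best_p For `"resampling"`: vector of best raw p-values from
#'   random hit lists.
#' @return Corrected p-values, always `>= p_raws` element-wise and `<= 1`.
#' @export
correct_pvalues <- function(p_raws, method = c("bonferroni", "resampling"),
                            null_best_p = NULL) {
  method <- match.arg(method)
  stopifnot(all(p_raws > 0), all(p_raws <= 1))
  if (method == "bonferroni") {
    pmin(1, length(p_raws) * p_raws)
  } else {
    if (is.null(null_best_p)) stop("resampling correction needs null_best_p")
    if (length(null_best_p) < 100)
      warning("fewer than 100 resamples: corrected p-values are coarse")
    vapply(p_raws, function(p) max(mean(null_best_p <= p), 1 / (length(null_best_p) + 1)),
           0)
  }
}

#' Simulate the null distribution of best raw enrichment p-values
#'
#' Draws random hit lists of size `n` from the universe and records the best
#' (smallest) raw hypergeometric p over all terms — the Boyle-style
#' simulation reference for the resampling correction.
#'
#' @param annotation Annotation set (list with `mapping`, `universe`).
#' @param n Hit-list size.
#' @param n_resamples Number of random lists.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_resamples`.
#' @export
enrichment_null_best_p <- function(annotation, n, n_resamples = 1000L,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  uni <- annotation$universe
  term_genes <- split(annotation$mapping$gene, annotation$mapping$term)
  term_genes <- lapply(term_genes, function(g) intersect(unique(g), uni))
  Ks <- lengths(term_genes)
  term_genes <- term_genes[Ks >= 1]
  Ks <- Ks[Ks >= 1]
  N <- length(uni)
  vapply(seq_len(n_resamples), function(i) {
    draw <- sample(uni, n)
    ps <- vapply(seq_along(term_genes), function(j) {
      hypergeom_tail(length(intersect(draw, term_genes[[j]])), n, Ks[j], N)
    }, 0)
    min(ps)
  }, 0)
}

#' Term enrichment of a hit list against the screen universe
#'
#' One result row per term with at least one universe member, reporting the
#' contingency counts, relative (`100 k/n`) and background (`100 K/N`)
#' frequencies, their ratio as fold enrichment, the raw hypergeometric tail p
#' and the corrected p. Terms with fewer than `min_term_hits` hit members are
#' kept in the full table but never flagged significant.
#'
#' @param hits Character vector of hit genes; genes outside the universe are
#'   dropped with a warning.
#' @param annotation Annotation set: list with `mapping` (data.frame gene,
#'   term) and `universe` (character), e.g. from [generate_annotation()] or
#'   [read_annotation()].
#' @param min_term_hits Minimum hit overlap for significance eligibility.
#' @param correction `"bonferroni"` or `"resampling"`.
#' @param alpha Significance cutoff on the corrected p.
#' @param n_resamples,seed Resampling-correction controls.
#' @return data.frame sorted by corrected then raw p: term, k, n, K, N,
#'   relative_freq, background_freq, fold, p_raw, p_corrected, significant.
#' @export
enrich <- function(hits, annotation, min_term_hits = 2L,
                   correction = c("bonferroni", "resampling"), alpha = 0.05,
                   n_resamples = 1000L, seed = 1L) {
  correction <- match.arg(correction)
  if (length(hits) == 0) stop("empty hit list")
  uni <- annotation$universe
  hits <- unique(hits)
  outside <- setdiff(hits, uni)
  if (length(outside)) {
    warning(length(outside), " hit gene(s) outside the universe dropped")
    hits <- intersect(hits, uni)
  }
  if (length(hits) == 0) stop("no hit genes inside the universe")
  n <- length(hits); N <- length(uni)
  term_genes <- split(annotation$mapping$gene, annotation$mapping$term)
  term_genes <- lapply(term_genes, function(g) intersect(unique(g), uni))
  term_genes <- term_genes[lengths(term_genes) >= 1]
  res <- lapply(names(term_genes), function(term) {
    tg <- term_genes[[term]]
    K <- length(tg)
    k <- length(intersect(hits, tg))
    rel <- 100 * k / n; bgf <- 100 * K / N
    data.frame(term = term, k = k, n = n, K = K, N = N,
               relative_freq = rel, background_freq = bgf,
               fold = rel / bgf,
               p_raw = hypergeom_tail(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (correction == "resampling") {
    nb <- enrichment_null_best_p(annotation, n, n_resamples, seed)
    res$p_corrected <- correct_pvalues(res$p_raw, "resampling", null_best_p = nb)
  } else {
    res$p_corrected <- correct_pvalues(res$p_raw, "bonferroni")
  }
  res$significant <- res$p_corrected <= alpha & res$k >= min_term_hits
  res[order(res$p_corrected, res$p_raw, res$term), , drop = FALSE]
}

#' Read a gene-to-term annotation file
#'
#' Accepts a flat two-column TSV (`gene`, `term`; header optional) or a
#' GAF 2.x subset (comment lines starting with `!`; gene symbol from column
#' 2, term id from column 5).
#'
#' @param path Annotation file.
#' @param universe Character vector defining the background gene universe.
#' @param format `"tsv"` or `"gaf"`.
#' @return Annotation set list (`mapping`, `universe`).
#' @export
read_annotation <- function(path, universe, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    mapping <- data.frame(gene = vapply(parts, `[`, "", 2),
                          term = vapply(parts, `[`, "", 5),
                          stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (identical(tolower(as.character(tab[1, 1])), "gene"))
      tab <- tab[-1, , drop = FALSE]
    mapping <- data.frame(gene = as.character(tab[[1]]),
                          term = as.character(tab[[2]]),
                          stringsAsFactors = FALSE)
  }
  list(mapping = mapping, universe = universe)
}
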
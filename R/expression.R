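# Post-processing of per-gene differential-expression tables: DEG calling,
# sporulation-gene enrichment, and cross-strain profile correlation.
# Upstream read processing and model fitting are consumed, not reproduced:
# the input is one table per strain with a log2 fold change and a
# multiple-testing-adjusted p value per gene.

#' Call differentially expressed genes
#'
#' A gene is `up` when p < alpha and log2 fold change > log2(fold_change_min),
#' `down` symmetrically, else `unchanged`. By default the adjusted p column is
#' thresholded; set `use_raw_p = TRUE` to threshold a raw `p` column instead.
#'
#' @param table Data frame with `gene_id`, `log2fc`, `p_adj` (and `p` when
#'   `use_raw_p = TRUE`).
#' @param alpha Significance threshold (default 0.05).
#' @param fold_change_min Fold-change threshold on the linear scale
#'   (default 2; boundary excluded).
#' @param use_raw_p Threshold the raw p value instead of the adjusted one.
#' @param na_as_unchanged Count genes with missing values as unchanged
#'   (with a warning) instead of erroring.
#' @return List with `calls` (data frame `gene_id`, `status`) and `counts`
#'   (named vector up/down/unchanged).
#' @export
call_degs <- function(table, alpha = 0.05, fold_change_min = 2,
                      use_raw_p = FALSE, na_as_unchanged = FALSE) {
  if (!all(c("gene_id", "log2fc") %in% names(table)))
    stop("call_degs: table needs gene_id and log2fc")
  if (alpha <= 0 || alpha >= 1) stop("call_degs: alpha must be in (0,1)")
  if (fold_change_min <= 1) stop("call_degs: fold_change_min must be > 1")
  pcol <- if (use_raw_p) "p" else "p_adj"
  if (!pcol %in% names(table)) stop("call_degs: missing column ", pcol)
  if (anyDuplicated(table$gene_id)) stop("call_degs: duplicate gene ids")
  p <- table[[pcol]]; lfc <- table$log2fc
  bad <- is.na(p) | is.na(lfc)
  if (any(bad)) {
    if (!na_as_unchanged)
      stop("call_degs: missing values for ", sum(bad), " gene(s)")
    warning("call_degs: ", sum(bad), " gene(s) with missing values counted as unchanged")
  }
  thr <- log2(fold_change_min)
  status <- rep("unchanged", nrow(table))
  status[!bad & p < alpha & lfc > thr] <- "up"
  status[!bad & p < alpha & lfc < -thr] <- "down"
  calls <- data.frame(gene_id = table$gene_id, status = status,
                      stringsAsFactors = FALSE)
  counts <- c(up = sum(status == "up"), down = sum(status == "down"),
              unchanged = sum(status == "unchanged"))
  list(calls = calls, counts = counts)
}

#' Hypergeometric enrichment of annotated genes in a DEG set
#'
#' Upper-tail probability P(X >= k) of drawing at least the observed number
#' of annotated (e.g. sporulation) genes in a DEG set of size n from a
#' universe of N genes containing K annotated ones. Exact
#' ([stats::phyper()]), no normal approximation. The universe is the set of
#' genes present in the strain's table.
#'
#' @param deg_genes Character vector of DEG gene ids (subset of universe).
#' @param annotated_genes Character vector of annotated gene ids.
#' @param universe Character vector of all gene ids in the strain's table.
#' @return List with `N`, `K`, `n`, `k`, `p`.
#' @export
hypergeom_enrichment <- function(deg_genes, annotated_genes, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("hypergeom_enrichment: empty universe")
  deg_genes <- unique(as.character(deg_genes))
  if (!all(deg_genes %in% universe))
    stop("hypergeom_enrichment: DEG set not contained in universe")
  annotated <- intersect(unique(as.character(annotated_genes)), universe)
  N <- length(universe); K <- length(annotated); n <- length(deg_genes)
  k <- length(intersect(deg_genes, annotated))
  p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(N = N, K = K, n = n, k = k, p = min(1, p))
}

#' Enrichment of sporulation genes among up-regulated genes, per strain
#'
#' Convenience wrapper: calls DEGs per strain table, tests the chosen DEG set
#' against the sporulation annotation with the hypergeometric test, and
#' adjusts p values across strains.
#'
#' @param tables Named list of per-strain DE tables (must carry an
#'   `is_sporulation` logical column or be paired with `annotation`).
#' @param annotation Optional data frame `gene_id`, `is_sporulation` used for
#'   tables without their own flag.
#' @param direction DEG set to test: `"up"` (default), `"down"`, `"both"`.
#' @param adjust Cross-strain adjustment method (default Holm).
#' @param ... Passed to [call_degs()].
#' @return Data frame with one row per strain: N, K, n, k, p, p_adj and the
#'   DEG counts.
#' @export
enrichment_by_strain <- function(tables, annotation = NULL,
                                 direction = c("up", "down", "both"),
                                 adjust = c("holm", "bh", "by"), ...) {
  direction <- match.arg(direction)
  adjust <- match.arg(adjust)
  rows <- lapply(names(tables), function(s) {
    tab <- tables[[s]]
    if (!"is_sporulation" %in% names(tab)) {
      if (is.null(annotation))
        stop("enrichment_by_strain: no is_sporulation column and no annotation")
      tab$is_sporulation <- annotation$is_sporulation[
        match(tab$gene_id, annotation$gene_id)]
      tab$is_sporulation[is.na(tab$is_sporulation)] <- FALSE
    }
    degs <- call_degs(tab, ...)
    sel <- switch(direction,
                  up = degs$calls$status == "up",
                  down = degs$calls$status == "down",
                  both = degs$calls$status != "unchanged")
    enr <- hypergeom_enrichment(degs$calls$gene_id[sel],
                                tab$gene_id[tab$is_sporulation],
                                tab$gene_id)
    data.frame(strain = s, N = enr$N, K = enr$K, n = enr$n, k = enr$k,
               p = enr$p, n_up = degs$counts["up"],
               n_down = degs$counts["down"],
               n_unchanged = degs$counts["unchanged"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Correlation of differential-expression profiles between two strains
#'
#' Spearman rank correlation of log2 fold changes over the genes shared by
#' both tables.
#'
#' @param table_a,table_b DE tables with `gene_id` and `log2fc`.
#' @return List with `rho`, `p`, `n_shared`.
#' @export
profile_correlation <- function(table_a, table_b) {
  shared <- intersect(table_a$gene_id, table_b$gene_id)
  if (length(shared) < 3)
    stop("profile_correlation: fewer than 3 shared genes")
  a <- table_a$log2fc[match(shared, table_a$gene_id)]
  b <- table_b$log2fc[match(shared, table_b$gene_id)]
  sp <- spearman_correlation(a, b, exact_n_max = 0L)
  list(rho = sp$rho, p = sp$p, n_shared = length(shared))
}
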
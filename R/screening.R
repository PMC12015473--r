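#' Screening settings for trait-linked gene discovery
#'
#' @param alpha p-value cut on the per-gene Pearson test (default 0.01;
#'   raw, uncorrected — this is a screen, not inference).
#' @param fc_min minimum `|log2 fold change|` between the large- and
#'   small-bud groups (default 1, i.e. two-fold).
#' @param epsilon pseudocount added to group-mean TPM before the ratio so
#'   unexpressed genes get a finite fold change (default 0.1).
#' @param log correlate on `log2(TPM + 1)` instead of raw TPM.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(alpha = 0.01, fc_min = 1, epsilon = 0.1,
                             log = FALSE) {
  stopifnot(alpha > 0, alpha < 1, epsilon > 0, fc_min >= 0)
  structure(list(alpha = alpha, fc_min = fc_min, epsilon = epsilon,
                 log = isTRUE(log)),
            class = "screening_config")
}

#' Per-gene Pearson correlation with a trait
#'
#' Correlates each gene's expression across samples with a per-sample
#' trait value; the two-sided p-value uses the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom.
#' Genes with zero expression variance get `r = NA, p = NA`.
#'
#' @param tpm numeric gene x sample matrix with dimnames.
#' @param trait named numeric vector, one value per sample (names must
#'   match `colnames(tpm)`).
#' @return `data.frame` with `gene_id`, `r`, `p`.
#' @export
correlate_gene_trait <- function(tpm, trait) {
  tpm <- as.matrix(tpm)
  n <- ncol(tpm)
  if (n < 3) stop("need at least 3 samples")
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), colnames(tpm)))
      stop("sample names of `trait` do not match `tpm` columns")
    trait <- trait[colnames(tpm)]
  } else stopifnot(length(trait) == n)
  if (stats::sd(trait) == 0) stop("trait has zero variance")
  tc <- trait - mean(trait)
  xc <- tpm - rowMeans(tpm)
  ssx <- rowSums(xc^2)
  r <- as.vector(xc %*% tc) / sqrt(ssx * sum(tc^2))
  r[ssx == 0] <- NA
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(gene_id = rownames(tpm), r = r, p = p)
}

#' Log2 fold change between sample groups
#'
#' `log2((mean TPM in large group + epsilon) / (mean TPM in small group +
#' epsilon))`, fixed large-over-small so candidates expressed higher in
#' large buds carry a positive sign.
#'
#' @param tpm gene x sample matrix.
#' @param groups character vector per sample, `"small"` or `"large"`.
#' @param epsilon pseudocount (default 0.1).
#' @return Named numeric vector of log2 fold changes per gene.
#' @export
fold_change <- function(tpm, groups, epsilon = 0.1) {
  tpm <- as.matrix(tpm)
  stopifnot(length(groups) == ncol(tpm),
            all(groups %in% c("small", "large")))
  if (!any(groups == "small") || !any(groups == "large"))
    stop("both groups must be non-empty")
  ml <- rowMeans(tpm[, groups == "large", drop = FALSE])
  ms <- rowMeans(tpm[, groups == "small", drop = FALSE])
  stats::setNames(log2((ml + epsilon) / (ms + epsilon)), rownames(tpm))
}

#' Screen genes linked to one trait
#'
#' Combines the Pearson screen and the fold-change filter: a gene passes
#' if `p < alpha` and `|log2FC| > fc_min`. Zero-variance genes auto-fail.
#'
#' @param tpm gene x sample TPM matrix.
#' @param trait per-sample trait values (named by sample).
#' @param groups per-sample `"small"`/`"large"` labels.
#' @param cfg a [screening_config()].
#' @return A list with `table` (`gene_id`, `r`, `p`, `log2fc`, `passes`)
#'   and `genes` (sorted character vector of passing gene ids).
#' @export
screen_trait <- function(tpm, trait, groups, cfg = screening_config()) {
  stopifnot(inherits(cfg, "screening_config"))
  x <- if (cfg$log) log2(as.matrix(tpm) + 1) else as.matrix(tpm)
  ct <- correlate_gene_trait(x, trait)
  ct$log2fc <- unname(fold_change(tpm, groups, cfg$epsilon))
  ct$passes <- !is.na(ct$p) & ct$p < cfg$alpha &
    abs(ct$log2fc) > cfg$fc_min
  list(table = ct, genes = sort(ct$gene_id[ct$passes]))
}

#' Intersect per-trait gene sets
#'
#' @param sets named list of 2-4 character vectors of gene ids.
#' @return A list with `common` (sorted intersection of all sets) and
#'   `venn` (`data.frame` of all `2^k - 1` membership regions with their
#'   exclusive counts).
#' @export
intersect_traits <- function(sets) {
  k <- length(sets)
  stopifnot(k >= 2, k <= 4)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  regions <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(regions) <- names(sets)
  regions <- regions[rowSums(regions) > 0, , drop = FALSE]
  counts <- apply(regions, 1, function(rg)
    sum(apply(member, 1, function(mb) all(mb == rg))))
  venn <- cbind(regions, count = as.vector(counts))
  rownames(venn) <- NULL
  common <- universe[rowSums(member) == k]
  list(common = common, venn = venn)
}

#' Row z-score matrix for heatmap export
#'
#' @param tpm gene x sample matrix.
#' @param genes genes (rownames) to keep, in order.
#' @return Matrix with each row transformed to
#'   `(x - row mean) / row SD` (sample SD); a zero-variance row becomes
#'   all zeros with a warning.
#' @export
zscore_matrix <- function(tpm, genes = rownames(tpm)) {
  tpm <- as.matrix(tpm)
  missing <- setdiff(genes, rownames(tpm))
  if (length(missing))
    stop("genes not in matrix: ", paste(missing, collapse = ", "))
  x <- tpm[genes, , drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance row(s) set to zeros")
    sdv[flat] <- 1
  }
  z <- (x - mu) / sdv
  z[flat, ] <- 0
  z
}
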
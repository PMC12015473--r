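#' Hierarchical clustering of accessions on trait means
#'
#' Agglomerative clustering of accessions on Euclidean distances over the
#' trait means, by default after z-score standardization of each trait so
#' that no trait dominates the metric. The default linkage is Ward
#' (`hclust` method `"ward.D2"`, the Euclidean-distance form of Ward's
#' criterion), which on a few-hundred-accession standardized panel yields
#' merge heights of the magnitude at which germplasm panels are typically
#' cut into a handful of size groups.
#'
#' @param trait_means `data.frame` with `accession_id`, optional `region`,
#'   and one numeric column per trait (see [accession_means()]), or a
#'   numeric matrix with rownames.
#' @param linkage `"ward"` (default), `"complete"` or `"average"`.
#' @param standardize z-score each trait before computing distances
#'   (default `TRUE`).
#' @return An object of class `bud_clust`: list with `hclust` (the merge
#'   history), `accession_id`, `trait_means` (matrix as clustered, before
#'   standardization), `region` (or NULL), `linkage`, `standardize`.
#' @export
cluster_accessions <- function(trait_means,
                               linkage = c("ward", "complete", "average"),
                               standardize = TRUE) {
  linkage <- match.arg(linkage)
  if (is.data.frame(trait_means)) {
    acc <- as.character(trait_means$accession_id)
    region <- if ("region" %in% names(trait_means))
      as.character(trait_means$region) else NULL
    num <- trait_means[, setdiff(names(trait_means),
                                 c("accession_id", "region", "group")),
                       drop = FALSE]
    x <- as.matrix(num)
    rownames(x) <- acc
  } else {
    x <- as.matrix(trait_means)
    acc <- rownames(x)
    if (is.null(acc)) acc <- as.character(seq_len(nrow(x)))
    region <- NULL
  }
  if (nrow(x) < 2) stop("need at least 2 accessions")
  if (anyNA(x)) {
    bad <- acc[apply(x, 1, anyNA)]
    stop("missing trait values for accession(s): ",
         paste(bad, collapse = ", "))
  }
  z <- if (standardize) scale(x) else x
  hc <- stats::hclust(stats::dist(z),
                      method = c(ward = "ward.D2", complete = "complete",
                                 average = "average")[[linkage]])
  structure(list(hclust = hc, accession_id = acc, trait_means = x,
                 region = region, linkage = linkage,
                 standardize = standardize),
            class = "bud_clust")
}

#' @export
print.bud_clust <- function(x, ...) {
  cat(sprintf("<bud_clust> %d accessions, %d traits, %s linkage%s\n",
              nrow(x$trait_means), ncol(x$trait_means), x$linkage,
              if (x$standardize) " (standardized)" else ""))
  cat(sprintf("  merge heights: %.3g .. %.3g\n",
              min(x$hclust$height), max(x$hclust$height)))
  invisible(x)
}

#' Cut a cluster tree into groups
#'
#' Cuts by height (groups are the subtrees whose merges all occur at or
#' below `h`) or by a requested number of groups `k`. Groups are labelled
#' with Roman numerals `I, II, ...` by descending size, ties broken by
#' first-accession order, so Group I is always the largest.
#'
#' @param result a `bud_clust` from [cluster_accessions()].
#' @param h cut height (Euclidean/Ward distance), or
#' @param k number of groups (exactly one of `h`, `k`).
#' @return Character vector of group labels, named by accession id.
#' @export
cut_tree <- function(result, h = NULL, k = NULL) {
  stopifnot(inherits(result, "bud_clust"))
  if (is.null(h) == is.null(k)) stop("give exactly one of `h` or `k`")
  raw <- if (!is.null(h)) stats::cutree(result$hclust, h = h)
         else stats::cutree(result$hclust, k = k)
  sizes <- table(raw)
  first <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.vector(sizes), as.vector(first))
  lab <- as.character(utils::as.roman(seq_along(ord)))
  mapping <- stats::setNames(lab, names(sizes)[ord])
  out <- mapping[as.character(raw)]
  names(out) <- result$accession_id
  out
}

#' Summarize cluster groups
#'
#' @param assignment group labels named by accession id (see [cut_tree()]).
#' @param trait_means as passed to [cluster_accessions()].
#' @param regions optional character vector of regions per accession (in
#'   `trait_means` order); defaults to the `region` column if present.
#' @param top_n restrict the region x group table to the `top_n` regions
#'   by total accession count (default 15).
#' @return A list with `groups` (`data.frame`: `group`, `n`, one mean
#'   column per trait) and `region_table` (region x group count matrix,
#'   top regions only; accessions with no region counted as "unknown").
#' @export
summarize_groups <- function(assignment, trait_means, regions = NULL,
                             top_n = 15) {
  if (is.data.frame(trait_means)) {
    acc <- as.character(trait_means$accession_id)
    if (is.null(regions) && "region" %in% names(trait_means))
      regions <- trait_means$region
    x <- as.matrix(trait_means[, setdiff(names(trait_means),
                                         c("accession_id", "region",
                                           "group")), drop = FALSE])
  } else {
    x <- as.matrix(trait_means)
    acc <- rownames(x)
  }
  g <- assignment[acc]
  if (anyNA(g)) stop("assignment does not cover all accessions")
  lev <- unique(g[order(match(g, as.character(utils::as.roman(1:50))))])
  groups <- data.frame(group = lev,
                       n = as.vector(table(g)[lev]))
  for (j in colnames(x))
    groups[[paste0("mean_", j)]] <-
      as.vector(tapply(x[, j], g, mean)[lev])
  if (is.null(regions)) regions <- rep("unknown", length(acc))
  regions <- as.character(regions)
  regions[is.na(regions) | regions == ""] <- "unknown"
  totals <- sort(table(regions), decreasing = TRUE)
  keep <- names(totals)[seq_len(min(top_n, length(totals)))]
  rt <- table(factor(regions[regions %in% keep], levels = keep),
              factor(g[regions %in% keep], levels = lev))
  list(groups = groups, region_table = unclass(rt))
}
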
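#' Interval construction settings
#'
#' @param alpha per-trait significance threshold on the association
#'   p-value. Default `1e-6`, i.e. the `-log10 P = 6` genome-wide line
#'   commonly drawn on the Manhattan plot (a slightly stricter cut than
#'   the `P < 6e-6` sometimes quoted for the same analyses; override via
#'   this argument if needed).
#' @param min_traits minimum number of traits a SNP must be significant in
#'   to be a candidate (default 2).
#' @param flank bp added on each side of a candidate SNP (default 1e5,
#'   the 100-kb candidate window).
#' @param merge_bookended merge intervals that touch end-to-start with no
#'   gap (the behaviour of the standard BED merge tool; default `TRUE`).
#' @return An object of class `interval_config`.
#' @export
interval_config <- function(alpha = 1e-6, min_traits = 2, flank = 1e5,
                            merge_bookended = TRUE) {
  stopifnot(alpha > 0, alpha < 1, min_traits >= 1, flank >= 0)
  structure(list(alpha = alpha, min_traits = as.integer(min_traits),
                 flank = flank, merge_bookended = isTRUE(merge_bookended)),
            class = "interval_config")
}

#' Combine per-trait association scans into one wide table
#'
#' @param assoc named list of `data.frame`s with columns `chrom`, `pos`,
#'   `p` (one per trait).
#' @return `data.frame` with `chrom`, `pos` and one `p_<trait>` column per
#'   trait; SNPs absent from a scan get `NA`.
#' @export
merge_assoc <- function(assoc) {
  stopifnot(is.list(assoc), length(assoc) >= 1, !is.null(names(assoc)))
  keys <- unique(do.call(rbind, lapply(assoc, function(d)
    data.frame(chrom = as.character(d$chrom), pos = as.numeric(d$pos)))))
  keys <- keys[order(keys$chrom, keys$pos), ]
  rownames(keys) <- NULL
  for (tr in names(assoc)) {
    d <- assoc[[tr]]
    i <- match(paste(keys$chrom, keys$pos),
               paste(as.character(d$chrom), as.numeric(d$pos)))
    keys[[paste0("p_", tr)]] <- d$p[i]
  }
  keys
}

#' Candidate SNPs significant in multiple traits
#'
#' A SNP is a candidate if its p-value is below `cfg$alpha` in at least
#' `cfg$min_traits` traits. Missing p-values are treated as
#' non-significant (with a warning).
#'
#' @param assoc wide table from [merge_assoc()], or a named list of
#'   per-trait scans (passed through [merge_assoc()]).
#' @param cfg an [interval_config()].
#' @return `data.frame` with `chrom`, `pos`, `traits` (comma-separated
#'   supporting traits) and `n_traits`.
#' @export
candidate_snps <- function(assoc, cfg = interval_config()) {
  stopifnot(inherits(cfg, "interval_config"))
  if (is.list(assoc) && !is.data.frame(assoc)) assoc <- merge_assoc(assoc)
  pcols <- grep("^p_", names(assoc), value = TRUE)
  if (!length(pcols)) stop("no p_<trait> columns found")
  pm <- as.matrix(assoc[, pcols, drop = FALSE])
  if (anyNA(pm))
    warning(sum(is.na(pm)), " missing p-value(s) treated as non-significant")
  sig <- !is.na(pm) & pm < cfg$alpha
  keep <- rowSums(sig) >= cfg$min_traits
  traits <- sub("^p_", "", pcols)
  out <- data.frame(chrom = assoc$chrom[keep], pos = assoc$pos[keep])
  out$traits <- apply(sig[keep, , drop = FALSE], 1,
                      function(z) paste(traits[z], collapse = ","))
  out$n_traits <- rowSums(sig)[keep]
  rownames(out) <- NULL
  out
}

#' Build merged candidate intervals around candidate SNPs
#'
#' Flanks each candidate SNP by `cfg$flank` bp on each side (clipped to
#' the chromosome), then merges overlapping — and, by default,
#' book-ended — intervals per chromosome, unioning the source SNPs and
#' supporting traits into each merged record. Coordinates are 1-based
#' inclusive throughout (GFF/VCF convention).
#'
#' @param snps `data.frame` from [candidate_snps()] (columns `chrom`,
#'   `pos`, optional `traits`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param cfg an [interval_config()].
#' @return `data.frame` with `chrom`, `start`, `end`, `n_snps`,
#'   `snp_pos` (comma-separated source positions), `traits`
#'   (comma-separated union of supporting traits).
#' @export
build_intervals <- function(snps, chrom_lengths, cfg = interval_config()) {
  stopifnot(inherits(cfg, "interval_config"),
            !is.null(names(chrom_lengths)))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      snp_pos = character(), traits = character())
  if (!nrow(snps)) return(empty)
  if (!all(snps$chrom %in% names(chrom_lengths)))
    stop("SNP chromosome(s) missing from `chrom_lengths`")
  if (any(snps$pos < 1 | snps$pos > chrom_lengths[as.character(snps$chrom)]))
    stop("SNP position beyond chromosome length")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(
      start = pmax(1, snps$pos - cfg$flank),
      end = pmin(chrom_lengths[as.character(snps$chrom)],
                 snps$pos + cfg$flank)))
  merged <- GenomicRanges::reduce(
    gr, min.gapwidth = if (cfg$merge_bookended) 1L else 0L)
  ov <- GenomicRanges::findOverlaps(gr, merged)
  idx <- S4Vectors::subjectHits(ov)
  src <- split(S4Vectors::queryHits(ov), idx)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged))
  out$n_snps <- as.integer(lengths(src)[as.character(seq_len(nrow(out)))])
  out$snp_pos <- vapply(seq_len(nrow(out)), function(i)
    paste(sort(snps$pos[src[[as.character(i)]]]), collapse = ","), "")
  out$traits <- vapply(seq_len(nrow(out)), function(i) {
    tr <- snps$traits[src[[as.character(i)]]]
    if (is.null(tr)) return("")
    paste(sort(unique(unlist(strsplit(tr, ",")))), collapse = ",")
  }, "")
  ord <- order(out$chrom, out$start)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Re-merge a set of intervals
#'
#' Applies the same overlap/book-ended merge rule to an existing interval
#' table; running it on already-merged intervals returns them unchanged.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @param merge_bookended merge touching intervals (default `TRUE`).
#' @return `data.frame` with `chrom`, `start`, `end`.
#' @export
merge_intervals <- function(intervals, merge_bookended = TRUE) {
  if (!nrow(intervals))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  gr <- GenomicRanges::GRanges(as.character(intervals$chrom),
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  m <- GenomicRanges::reduce(gr, min.gapwidth = if (merge_bookended) 1L
                                                else 0L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(m)),
                    start = GenomicRanges::start(m),
                    end = GenomicRanges::end(m))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Annotate intervals with overlapping genes
#'
#' A gene overlaps an interval if their 1-based inclusive spans share at
#' least one bp. Genes are counted once in the summary even if they fall
#' in several intervals.
#'
#' @param intervals `data.frame` from [build_intervals()].
#' @param genes gene annotation: either a `data.frame` with `gene_id`,
#'   `chrom`, `start`, `end`, or a path to a GFF3 file (features of type
#'   `gene` are used; the `ID` attribute is the gene id).
#' @return A list with `intervals` (input plus `n_genes` and `genes`
#'   columns) and `summary` (`n_intervals`, `total_span_bp`, `n_genes`).
#' @export
annotate_genes <- function(intervals, genes) {
  if (is.character(genes)) genes <- read_gff3_genes(genes)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  out <- intervals
  out$n_genes <- rep(0L, nrow(out))
  out$genes <- rep("", nrow(out))
  if (nrow(intervals)) {
    gi <- GenomicRanges::GRanges(as.character(intervals$chrom),
                                 IRanges::IRanges(intervals$start,
                                                  intervals$end))
    gg <- GenomicRanges::GRanges(as.character(genes$chrom),
                                 IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(gi, gg)
    hits <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
    for (i in names(hits)) {
      ids <- sort(genes$gene_id[hits[[i]]])
      out$n_genes[as.integer(i)] <- length(ids)
      out$genes[as.integer(i)] <- paste(ids, collapse = ",")
    }
  }
  all_genes <- unique(unlist(strsplit(out$genes[out$genes != ""], ",")))
  list(intervals = out,
       summary = list(n_intervals = nrow(out),
                      total_span_bp = sum(out$end - out$start + 1),
                      n_genes = length(all_genes)))
}

#' Stratify phenotypes by genotype at a lead SNP
#'
#' Groups accessions by their unphased genotype class at one SNP
#' (hom-ref / het / hom-alt; missing genotypes excluded), then runs a
#' one-way ANOVA per trait with all-pairs Tukey HSD (Tukey-Kramer for
#' unbalanced groups) and a compact letter display at the 0.05 level:
#' genotype classes sharing a letter are not significantly different.
#'
#' @param genotypes either a path to a VCF file (the record at
#'   `chrom:pos` is used) or a `data.frame` with `sample_id` and `gt`
#'   (strings like "0/0", "0|1"; "." for missing).
#' @param snp for VCF input, the target SNP as `"chrom:pos"` or
#'   `c(chrom, pos)`.
#' @param phenotypes `data.frame` with `accession_id` and one numeric
#'   column per trait (accession trait means).
#' @param alpha level of the letter display (default 0.05).
#' @return An object of class `genotype_strata`: list with `snp`,
#'   `classes` (`data.frame`: `gt`, `n`), and per-trait results in
#'   `traits` (each: `anova_p`, `tukey` data.frame of pairwise adjusted
#'   p-values, `letters` named by genotype class, `means`).
#' @export
stratify_by_genotype <- function(genotypes, snp = NULL, phenotypes,
                                 alpha = 0.05) {
  if (is.character(genotypes) && length(genotypes) == 1L)
    genotypes <- read_vcf_genotypes(genotypes, snp)
  stopifnot(all(c("sample_id", "gt") %in% names(genotypes)))
  gt <- gsub("\\|", "/", genotypes$gt)
  gt[gt == "1/0"] <- "0/1"
  keep <- gt %in% c("0/0", "0/1", "1/1")
  gt <- gt[keep]
  ids <- genotypes$sample_id[keep]
  if (length(unique(gt)) < 2)
    stop("SNP is monomorphic across the genotyped samples")
  miss <- setdiff(ids, phenotypes$accession_id)
  if (length(miss))
    stop("samples absent from phenotype table: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ...")
  tab <- table(gt)
  if (sum(tab >= 2) < 2)
    stop("need at least 2 genotype classes with >= 2 samples")
  ph <- phenotypes[match(ids, phenotypes$accession_id), , drop = FALSE]
  traits <- setdiff(names(ph), c("accession_id", "region", "group"))
  fgt <- factor(gt, levels = c("0/0", "0/1", "1/1")[c("0/0", "0/1", "1/1")
                                                    %in% gt])
  res <- lapply(traits, function(tr) {
    y <- ph[[tr]]
    fit <- stats::aov(y ~ fgt)
    pa <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$fgt
    pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL)
    sig <- stats::setNames(pairs$p_adj < alpha, pairs$pair)
    lt <- compact_letters(levels(fgt), sig)
    list(anova_p = pa, tukey = pairs, letters = lt,
         means = tapply(y, fgt, mean))
  })
  names(res) <- traits
  structure(list(snp = snp,
                 classes = data.frame(gt = levels(fgt),
                                      n = as.vector(table(fgt))),
                 traits = res, alpha = alpha),
            class = "genotype_strata")
}

#' @export
print.genotype_strata <- function(x, ...) {
  cat("<genotype_strata>",
      if (!is.null(x$snp)) paste(unlist(x$snp), collapse = ":"), "\n")
  print(x$classes)
  for (tr in names(x$traits)) {
    t <- x$traits[[tr]]
    cat(sprintf("%s: ANOVA p = %.3g; means [%s]; letters [%s]\n", tr,
                t$anova_p,
                paste(sprintf("%s=%.3g", names(t$means), t$means),
                      collapse = ", "),
                paste(sprintf("%s=%s", names(t$letters), t$letters),
                      collapse = ", ")))
  }
  invisible(x)
}

# Compact letter display by insert-and-absorb: start with one column (all
# groups share a letter); for each significantly different pair split every
# column containing both; absorb columns that are subsets of another.
# `sig` is a logical vector named "B-A" over group pairs.
compact_letters <- function(groups, sig) {
  cols <- list(groups)
  pairs <- names(sig)[sig]
  for (pr in pairs) {
    ab <- strsplit(pr, "-")[[1]]
    new_cols <- list()
    for (col in cols) {
      if (all(ab %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, ab[1])),
                      list(setdiff(col, ab[2])))
      } else new_cols <- c(new_cols, list(col))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) for (j in seq_along(new_cols)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_cols[[i]] %in% new_cols[[j]]) &&
          !(all(new_cols[[j]] %in% new_cols[[i]]) && i < j))
        keep[i] <- FALSE
    }
    cols <- unique(new_cols[keep])
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cols))
    for (g in cols[[k]]) out[g] <- paste0(out[g], letters[k])
  out
}
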
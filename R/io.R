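#' @name budmetrics-io
#' @title File formats used by the pipeline
#' @description
#' Plain-text readers and writers for the pipeline's interchange formats:
#' feature/phenotype CSVs and TPM/association TSVs (with `#` provenance
#' header lines), GFF3 gene annotation, minimal VCF 4.2, and BED
#' (0-based half-open) for merged intervals. All genomic coordinates are
#' 1-based inclusive in memory; BED conversion happens only at the file
#' boundary.
NULL

provenance_header <- function(seed = NULL, config = NULL) {
  h <- sprintf("# budmetrics %s",
               as.character(utils::packageVersion("budmetrics")))
  if (!is.null(seed)) h <- c(h, sprintf("# seed=%s", seed))
  if (!is.null(config))
    h <- c(h, sprintf("# config_hash=%s", config_hash(config)))
  h
}

#' Hash of a configuration object
#'
#' Deterministic short hash of any R configuration (via its deparsed
#' form), written into output headers so downstream stages can detect
#' mixed-provenance inputs.
#'
#' @param config any R object.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  # 31-polynomial rolling hash mod the Mersenne prime 2^31 - 1
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a table with provenance header lines
#'
#' @param df data.frame.
#' @param path output file.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @param seed,config recorded in `#` header lines.
#' @export
write_table_prov <- function(df, path, sep = ",", seed = NULL,
                             config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_table_prov()]
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame (header `#` lines skipped).
#' @export
read_table_prov <- function(path, sep = ",") {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a rendered scene to PNG
#'
#' @param scene output of [render_scene()], or a [scan_image].
#' @param path output PNG path.
#' @export
write_scene_png <- function(scene, path) {
  img <- if (inherits(scene, "scan_image")) scene else scene$image
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' Read GFF3 gene features
#'
#' Validates the 9-column layout line by line (reporting the first
#' malformed line), then imports via `rtracklayer` and keeps features of
#' type `gene`, using the `ID` attribute as the gene id.
#'
#' @param path GFF3 file.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9))
    stop("malformed GFF3 line ", body[which(nf != 9)[1]], " in ", path,
         ": expected 9 tab-separated fields")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Write gene features as GFF3
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `start`, `end`,
#'   optional `strand`.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\tbudmetrics\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, as.integer(genes$start),
                     as.integer(genes$end), strand, genes$gene_id), con)
  invisible(path)
}

#' Write a minimal single-site VCF 4.2
#'
#' @param genotypes `data.frame` with `sample_id`, `gt` ("0/0", "0/1",
#'   "1/1" or ".").
#' @param chrom,pos site coordinates (1-based).
#' @param ref,alt alleles.
#' @param id variant id (default `chrom:pos`).
#' @param path output file.
#' @export
write_vcf <- function(genotypes, chrom, pos, ref = "A", alt = "G",
                      id = NULL, path) {
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", genotypes$sample_id),
                     collapse = "\t")), con)
  writeLines(paste(c(chrom, as.integer(pos), id, ref, alt, ".", "PASS",
                     ".", "GT", genotypes$gt), collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes at one site from a VCF
#'
#' @param path VCF file.
#' @param snp `"chrom:pos"` or `c(chrom, pos)`; if `NULL` and the VCF has
#'   a single record, that record is used.
#' @return `data.frame` with `sample_id`, `gt`.
#' @export
read_vcf_genotypes <- function(path, snp = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(snp)) {
    if (nrow(fix) != 1) stop("VCF has ", nrow(fix),
                             " records; specify `snp` as chrom:pos")
    row <- 1L
  } else {
    if (length(snp) == 1L) snp <- strsplit(snp, ":")[[1]]
    row <- which(fix[, "CHROM"] == snp[1] &
                 as.numeric(fix[, "POS"]) == as.numeric(snp[2]))
    if (!length(row)) stop("SNP ", paste(snp, collapse = ":"),
                           " not found in ", path)
    row <- row[1]
  }
  gt <- vcfR::extract.gt(v)[row, ]
  data.frame(sample_id = names(gt), gt = unname(gt))
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  writeLines(sprintf("%s\t%d\t%d", intervals$chrom,
                     as.integer(intervals$start) - 1L,
                     as.integer(intervals$end)), path)
  invisible(path)
}

#' Read a BED file back to 1-based inclusive intervals
#'
#' @param path BED file.
#' @return `data.frame` with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  data.frame(chrom = d[[1]], start = d[[2]] + 1L, end = d[[3]])
}

#' Write per-trait association scans as TSVs
#'
#' @param assoc named list of `data.frame`s (`chrom`, `pos`, `p`).
#' @param dir output directory; each trait goes to `assoc_<trait>.tsv`.
#' @return Named character vector of written paths.
#' @export
write_assoc <- function(assoc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(assoc), function(tr) {
    p <- file.path(dir, paste0("assoc_", tr, ".tsv"))
    utils::write.table(assoc[[tr]], p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    p
  }, "")
  paths
}

#' Read per-trait association scans
#'
#' @param paths named character vector (names = traits) of TSV files with
#'   columns `chrom`, `pos`, `p`.
#' @return Named list of `data.frame`s.
#' @export
read_assoc <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("^assoc_", "",
                        tools::file_path_sans_ext(basename(paths)))
  lapply(paths, function(p)
    utils::read.table(p, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))
}

#' Read a TPM matrix TSV
#'
#' @param path TSV whose first column is the gene id and remaining columns
#'   are samples.
#' @return Numeric matrix with gene rownames.
#' @export
read_tpm <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a TPM matrix TSV
#'
#' @param tpm gene x sample matrix.
#' @param path output file.
#' @export
write_tpm <- function(tpm, path) {
  d <- data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
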
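# Candidate-interval construction and lead-SNP genotype stratification.

test_that("the multi-trait rule keeps 2-of-4 SNPs and drops 1-of-4", {
  assoc <- data.frame(chrom = "Chr1", pos = c(100, 200, 300),
                      p_length = c(1e-8, 1e-8, 0.5),
                      p_width = c(1e-8, 0.5, 0.5),
                      p_perimeter = c(0.5, 0.5, 1e-8),
                      p_area = c(0.5, 0.5, 0.5))
  out <- candidate_snps(assoc)
  expect_equal(out$pos, 100)
  expect_equal(out$traits, "length,width")
  # min_traits = 1 keeps all three
  out1 <- candidate_snps(assoc, interval_config(min_traits = 1))
  expect_equal(nrow(out1), 3)
  # missing p treated as non-significant, with warning
  assoc$p_width[1] <- NA
  expect_warning(out2 <- candidate_snps(assoc), "missing")
  expect_equal(nrow(out2), 0)
})

test_that("the 100-kb flank around the lead SNP gives the published window", {
  snps <- data.frame(chrom = "Chr10", pos = 14322573,
                     traits = "length,width")
  iv <- build_intervals(snps, c(Chr10 = 2.5e7))
  expect_equal(iv$start, 14222573)
  expect_equal(iv$end, 14422573)
  # i.e. the 14.22-14.42 Mb window
  expect_equal(round(iv$start / 1e6, 2), 14.22)
  expect_equal(round(iv$end / 1e6, 2), 14.42)
})

test_that("flanks are clipped at chromosome boundaries", {
  snps <- data.frame(chrom = "Chr1", pos = c(50000, 9.99e6))
  iv <- build_intervals(snps, c(Chr1 = 1e7))
  expect_equal(iv$start[1], 1)
  expect_equal(iv$end[2], 1e7)
  expect_error(build_intervals(data.frame(chrom = "Chr1", pos = 2e7),
                               c(Chr1 = 1e7)), "beyond")
})

test_that("merged intervals equal a brute-force per-bp oracle on random fixtures", {
  set.seed(42)
  chrom_lengths <- c(c1 = 50000, c2 = 30000)
  cfg <- interval_config(flank = 1500)
  for (rep in 1:100) {
    n <- sample(1:12, 1)
    snps <- data.frame(
      chrom = sample(names(chrom_lengths), n, replace = TRUE),
      pos = NA_real_)
    snps$pos <- vapply(snps$chrom, function(ch)
      sample(chrom_lengths[[ch]], 1), 1)
    iv <- build_intervals(snps, chrom_lengths, cfg)
    bf <- bruteforce_intervals(snps, chrom_lengths, cfg$flank)
    expect_equal(iv[, c("chrom", "start", "end")], bf)
  }
})

test_that("merging is idempotent and monotone in flank and min_traits", {
  set.seed(7)
  snps <- data.frame(chrom = "Chr1",
                     pos = sort(sample(1e6, 20)))
  lens <- c(Chr1 = 1e6)
  iv <- build_intervals(snps, lens, interval_config(flank = 2e4))
  again <- merge_intervals(iv)
  expect_equal(iv[, c("chrom", "start", "end")], again)

  # larger flank never shrinks the covered span
  span <- function(flank) {
    v <- build_intervals(snps, lens, interval_config(flank = flank))
    sum(v$end - v$start + 1)
  }
  spans <- vapply(c(1e3, 5e3, 2e4, 1e5), span, 1)
  expect_false(is.unsorted(spans))

  # higher min_traits never admits more SNPs
  assoc <- data.frame(chrom = "Chr1", pos = snps$pos,
                      p_a = runif(20, 0, 2e-6),
                      p_b = runif(20, 0, 2e-6),
                      p_c = runif(20))
  n_cand <- vapply(1:3, function(mt)
    nrow(candidate_snps(assoc, interval_config(min_traits = mt))), 1L)
  expect_false(is.unsorted(rev(n_cand)))
})

test_that("book-ended merging is on by default and strict overlap available", {
  iv <- data.frame(chrom = "c", start = c(1, 101), end = c(100, 200))
  expect_equal(nrow(merge_intervals(iv)), 1)
  expect_equal(nrow(merge_intervals(iv, merge_bookended = FALSE)), 2)
})

test_that("BED round-trip preserves 1-based inclusive coordinates", {
  iv <- data.frame(chrom = c("Chr1", "Chr2"), start = c(1, 14222573),
                   end = c(500, 14422573))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, tmp)
  back <- read_bed(tmp)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  raw <- read.table(tmp)
  expect_equal(raw$V2, iv$start - 1)      # BED is 0-based half-open
})

test_that("gene overlap uses inclusive coordinates and counts genes once", {
  genes <- data.frame(gene_id = sprintf("G%02d", 1:10), chrom = "Chr1",
                      start = seq(1, 901, by = 100),
                      end = seq(50, 950, by = 100))
  iv <- data.frame(chrom = "Chr1", start = 150, end = 420)
  ann <- annotate_genes(iv, genes)
  # genes 101-150 (abuts at 150), 201-250, 301-350, 401-450
  expect_equal(ann$intervals$n_genes, 4)
  expect_equal(ann$summary$n_genes, 4)

  # abutting: gene starting exactly at interval end overlaps
  iv2 <- data.frame(chrom = "Chr1", start = 90, end = 101)
  expect_equal(annotate_genes(iv2, genes)$intervals$n_genes, 1)
  # one bp past: no overlap
  iv3 <- data.frame(chrom = "Chr1", start = 51, end = 100)
  expect_equal(annotate_genes(iv3, genes)$intervals$n_genes, 0)

  # a gene spanning two intervals counts once in the summary
  iv4 <- data.frame(chrom = "Chr1", start = c(1, 30), end = c(20, 60))
  expect_equal(annotate_genes(iv4, genes)$summary$n_genes, 1)
})

test_that("GFF3 round trip feeds annotation; malformed lines are rejected", {
  genes <- data.frame(gene_id = c("GA", "GB"), chrom = "Chr1",
                      start = c(100, 5000), end = c(900, 6000),
                      strand = c("+", "-"))
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, tmp)
  back <- read_gff3_genes(tmp)
  expect_equal(back[, c("gene_id", "chrom", "start", "end")],
               genes[, c("gene_id", "chrom", "start", "end")])

  writeLines(c("##gff-version 3", "Chr1\tonly\tthree"), tmp)
  expect_error(read_gff3_genes(tmp), "line 2")
})

test_that("genotype stratification separates an additive lead SNP", {
  sim <- simulate_association(chrom_lengths = c(Chr10 = 2.5e7),
                              spacing = 1e6,
                              lead_snp = c("Chr10", 14322573),
                              n_samples = 90, effect_sd = 1, seed = 11)
  st <- stratify_by_genotype(sim$genotypes, snp = c("Chr10", 14322573),
                             phenotypes = sim$phenotypes)
  expect_s3_class(st, "genotype_strata")
  expect_equal(sum(st$classes$n), 90)
  for (tr in names(st$traits)) {
    t <- st$traits[[tr]]
    expect_lt(t$anova_p, 0.05)
    # additive effect: monotone class means, three distinct letters
    expect_false(is.unsorted(t$means))
    expect_equal(length(unique(t$letters)), 3)
  }
})

test_that("stratification via a VCF file reproduces the in-memory result", {
  sim <- simulate_association(chrom_lengths = c(Chr10 = 2.5e7),
                              spacing = 1e6,
                              lead_snp = c("Chr10", 14322573),
                              n_samples = 60, seed = 12)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, "Chr10", 14322573, path = tmp)
  st1 <- stratify_by_genotype(tmp, snp = "Chr10:14322573",
                              phenotypes = sim$phenotypes)
  st2 <- stratify_by_genotype(sim$genotypes,
                              phenotypes = sim$phenotypes)
  expect_equal(st1$classes, st2$classes)
  expect_equal(st1$traits$length$letters, st2$traits$length$letters)
})

test_that("stratification degenerate cases behave", {
  # three identical groups: one shared letter everywhere
  set.seed(13)
  geno <- data.frame(sample_id = sprintf("A%03d", 1:30),
                     gt = rep(c("0/0", "0/1", "1/1"), each = 10))
  ph <- data.frame(accession_id = geno$sample_id, y = rnorm(30, 5, 0.1))
  st <- stratify_by_genotype(geno, phenotypes = ph)
  expect_equal(length(unique(st$traits$y$letters)), 1)

  # two classes with a strong shift: letters {a, b}
  geno2 <- geno[geno$gt != "1/1", ]
  ph2 <- data.frame(accession_id = geno2$sample_id,
                    y = rnorm(20, 5, 0.1) +
                      ifelse(geno2$gt == "0/1", 3, 0))
  st2 <- stratify_by_genotype(geno2, phenotypes = ph2)
  expect_setequal(unname(st2$traits$y$letters), c("a", "b"))

  # monomorphic SNP rejected; absent samples named
  mono <- data.frame(sample_id = geno$sample_id, gt = "0/0")
  expect_error(stratify_by_genotype(mono, phenotypes = ph),
               "monomorphic")
  expect_error(stratify_by_genotype(geno, phenotypes = ph[1:5, ]),
               "absent")
})

test_that("compact letter display encodes exactly the significant pairs", {
  g <- c("0/0", "0/1", "1/1")
  # only the extremes differ: het shares letters with both
  sig <- c("0/1-0/0" = FALSE, "1/1-0/0" = TRUE, "1/1-0/1" = FALSE)
  lt <- budmetrics:::compact_letters(g, sig)
  expect_true(lt["0/0"] != lt["1/1"])
  expect_true(any(strsplit(lt["0/1"], "")[[1]] %in%
                  strsplit(lt["0/0"], "")[[1]]))
  expect_true(any(strsplit(lt["0/1"], "")[[1]] %in%
                  strsplit(lt["1/1"], "")[[1]]))
  # all different: three distinct letters
  lt2 <- budmetrics:::compact_letters(g, setNames(rep(TRUE, 3),
                                                  names(sig)))
  expect_equal(length(unique(lt2)), 3)
  # none different: one shared letter
  lt3 <- budmetrics:::compact_letters(g, setNames(rep(FALSE, 3),
                                                  names(sig)))
  expect_equal(length(unique(lt3)), 1)
})
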
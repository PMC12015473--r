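# Synthetic-data generators: determinism, planted truth, moment match.

test_that("rendered scenes are deterministic given a seed and vary only in noise", {
  sp <- list(shape_spec("stadium", 1.2, 0.3, center_px = c(100, 100),
                        angle_deg = 40))
  a <- render_scene(sp, dpi = 300, size_px = c(200, 200), seed = 5)
  b <- render_scene(sp, dpi = 300, size_px = c(200, 200), seed = 5)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  # different seed: same geometry (same masks), different noise field
  c_ <- render_scene(sp, dpi = 300, size_px = c(200, 200), seed = 6)
  expect_identical(c_$truth, a$truth)
  expect_false(identical(c_$image$pixels, a$image$pixels))
  ma <- segment_buds(a$image)[[1]]
  mc <- segment_buds(c_$image)[[1]]
  expect_identical(ma$mask, mc$mask)
})

test_that("empty scene renders pure background with empty truth", {
  sc <- render_scene(list(), dpi = 300, size_px = c(50, 50), seed = 1)
  expect_equal(nrow(sc$truth), 0)
  expect_lt(max(sc$image$pixels), 50)
})

test_that("overlapping or out-of-canvas shapes are rejected with offenders named", {
  sp1 <- shape_spec("circle", 0.5, 0.5, center_px = c(60, 60))
  sp2 <- shape_spec("circle", 0.5, 0.5, center_px = c(62, 62))
  expect_error(render_scene(list(sp1, sp2), dpi = 300,
                            size_px = c(120, 120)), "overlap")
  sp3 <- shape_spec("circle", 0.5, 0.5, center_px = c(5, 60))
  expect_error(render_scene(list(sp3), dpi = 300, size_px = c(120, 120)),
               "margin")
})

test_that("phenotype simulator hits its moments and respects sd_e = 0", {
  tr <- data.frame(trait = "length", mean = 2.65, sd_g = 0.38, sd_e = 0)
  ph <- simulate_phenotypes(n_accessions = 280, replicates = 3,
                            traits = tr, seed = 1)
  # all replicates identical within accession when sd_e = 0
  spread <- tapply(ph$value, ph$accession_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
  am <- tapply(ph$value, ph$accession_id, mean)
  expect_lt(abs(mean(am) - 2.65), 3 * 0.38 / sqrt(280))
  expect_lt(abs(sd(am) - 0.38), 0.05)

  # moment match at n = 2000 within 3 SE
  ph2 <- simulate_phenotypes(n_accessions = 2000, replicates = 2,
                             traits = data.frame(trait = "x", mean = 10,
                                                 sd_g = 1, sd_e = 0.5),
                             seed = 2)
  am2 <- tapply(ph2$value, ph2$accession_id, mean)
  # accession means carry sd_g^2 + sd_e^2/r variance
  sd_am <- sqrt(1 + 0.25 / 2)
  expect_lt(abs(mean(am2) - 10), 3 * sd_am / sqrt(2000))
  expect_lt(abs(sd(am2) - sd_am), 3 * sd_am / sqrt(2 * 1999))
})

test_that("phenotype simulator is deterministic and long-format complete", {
  a <- simulate_phenotypes(n_accessions = 10, replicates = 4, seed = 3)
  b <- simulate_phenotypes(n_accessions = 10, replicates = 4, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 10 * 4 * 4)  # 4 default traits
  expect_setequal(unique(a$trait),
                  c("length", "width", "perimeter", "area"))
})

test_that("expression simulator plants exact correlations at zero noise", {
  sim <- simulate_expression(n_genes = 6, n_linked = 6, noise_sd = 0,
                             slope_sign = c(1, 1, 1, -1, -1, -1),
                             seed = 4)
  ct <- correlate_gene_trait(log2(sim$tpm + 1),
                             setNames(sim$meta$trait,
                                      sim$meta$sample_id))
  expect_equal(ct$r, c(1, 1, 1, -1, -1, -1), tolerance = 1e-10)
  # sign propagation into the screen
  sc <- screen_trait(sim$tpm, setNames(sim$meta$trait,
                                       sim$meta$sample_id),
                     sim$meta$group)
  expect_true(all(sc$table$log2fc[1:3] > 0))
  expect_true(all(sc$table$log2fc[4:6] < 0))
})

test_that("null expression simulation is calibrated at the 1% level", {
  sim <- simulate_expression(n_genes = 1000, n_linked = 0, seed = 8)
  ct <- correlate_gene_trait(sim$tpm,
                             setNames(sim$meta$trait,
                                      sim$meta$sample_id))
  fp <- mean(ct$p < 0.01, na.rm = TRUE)
  se <- sqrt(0.01 * 0.99 / 1000)
  expect_lt(abs(fp - 0.01), 3 * se)
})

test_that("association simulator output drives interval construction end to end", {
  peaks <- data.frame(chrom = "Chr10", pos = 14322573,
                      traits = "length,width", neglog10p = 8)
  sim <- simulate_association(chrom_lengths = c(Chr10 = 2.5e7),
                              spacing = 1e5, peaks = peaks, seed = 9)
  cands <- candidate_snps(sim$assoc)
  expect_equal(nrow(cands), 1)
  iv <- build_intervals(cands, c(Chr10 = 2.5e7))
  expect_equal(nrow(iv), 1)
  expect_true(iv$start <= 14322573 && iv$end >= 14322573)

  # single-trait peak excluded by the >= 2-trait rule
  peaks1 <- data.frame(chrom = "Chr10", pos = 5e6, traits = "length",
                       neglog10p = 8)
  sim1 <- simulate_association(chrom_lengths = c(Chr10 = 2.5e7),
                               spacing = 1e5, peaks = peaks1, seed = 9)
  expect_equal(nrow(candidate_snps(sim1$assoc)), 0)

  # no peaks: no candidates at the default threshold
  sim0 <- simulate_association(chrom_lengths = c(Chr10 = 2.5e7),
                               spacing = 1e5, seed = 10)
  expect_equal(nrow(candidate_snps(sim0$assoc)), 0)
})
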
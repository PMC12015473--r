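#' Render a synthetic scanner scene with closed-form ground truth
#'
#' Rasterizes analytic shapes ([shape_spec()]) onto a near-black canvas the
#' way a flatbed scan of buds on light-absorbing cloth looks: bright
#' green-brown foreground, dark noisy background, crisp edges. Each shape
#' is rasterized by 4x4 supersampling of its analytic inside test and
#' thresholding pixel coverage at 0.5, so the binary silhouette tracks the
#' true boundary to within a fraction of a pixel and the closed-form area,
#' perimeter, length and width are valid ground truth for the measured
#' features.
#'
#' @param shapes list of [shape_spec()] objects. Shapes must fit inside the
#'   canvas with at least 10 px margin and must not overlap.
#' @param dpi rendering resolution (default 600, the scan setting the
#'   pipeline is calibrated for).
#' @param size_px canvas size `c(rows, cols)` in pixels.
#' @param noise_sd Gaussian background noise SD on the 0-1 intensity scale.
#' @param seed RNG seed for the noise field; shape geometry is
#'   deterministic and unaffected by the seed.
#' @param bg_level mean background brightness (0-1).
#' @param fg_rgb foreground colour (length-3, 0-1).
#' @param accession_id accession label attached to the scene.
#' @param supersample linear supersampling factor per pixel.
#' @return A list with `image` (a [scan_image]) and `truth` (a `data.frame`
#'   of one row per shape: `shape`, `kind`, `length_cm`, `width_cm`,
#'   `perimeter_cm`, `area_cm2`, `center_row`, `center_col`, `angle_deg`).
#' @export
render_scene <- function(shapes, dpi = 600, size_px = c(600, 600),
                         noise_sd = 0.02, seed = 1, bg_level = 0.05,
                         fg_rgb = c(0.45, 0.52, 0.30),
                         accession_id = "SYN", supersample = 4L) {
  stopifnot(length(size_px) == 2L, all(size_px >= 1), noise_sd >= 0)
  s <- 2.54 / dpi
  nr <- as.integer(size_px[1]); nc <- as.integer(size_px[2])

  half_px <- function(sh) sh$length_cm / 2 / s + 2
  bad <- character()
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    h <- half_px(sh)
    if (sh$center_px[1] - h < 10 || sh$center_px[2] - h < 10 ||
        sh$center_px[1] + h > nr - 10 || sh$center_px[2] + h > nc - 10)
      bad <- c(bad, sprintf("shape %d outside canvas margin", i))
  }
  if (length(shapes) > 1) {
    for (i in seq_len(length(shapes) - 1)) for (j in (i + 1):length(shapes)) {
      a <- shapes[[i]]; b <- shapes[[j]]
      d <- sqrt(sum((a$center_px - b$center_px)^2)) * s
      if (d < (a$length_cm + b$length_cm) / 2)  # conservative circumradius test
        bad <- c(bad, sprintf("shapes %d and %d may overlap", i, j))
    }
  }
  if (length(bad)) stop("invalid scene: ", paste(bad, collapse = "; "))

  fg <- matrix(FALSE, nr, nc)
  truth <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    h <- ceiling(half_px(sh)) + 2L
    r0 <- max(1L, floor(sh$center_px[1] - h)); r1 <- min(nr, ceiling(sh$center_px[1] + h))
    c0 <- max(1L, floor(sh$center_px[2] - h)); c1 <- min(nc, ceiling(sh$center_px[2] + h))
    rows <- r0:r1; cols <- c0:c1
    th <- sh$angle_deg * pi / 180
    co <- cos(th); si <- sin(th)
    cover <- matrix(0, length(rows), length(cols))
    off <- (seq_len(supersample) - 0.5) / supersample - 0.5
    x <- (rows - sh$center_px[1]) * s   # along image rows
    y <- (cols - sh$center_px[2]) * s   # along image cols
    # long axis at angle th from the column axis; the pixel-grid
    # transform is affine, so subsample offsets are scalar shifts
    u0 <- outer(x, y, function(xx, yy) -si * xx + co * yy)
    v0 <- outer(x, y, function(xx, yy) co * xx + si * yy)
    for (dr in off) for (dc in off) {
      du <- s * (-si * dr + co * dc)
      dv <- s * (co * dr + si * dc)
      cover <- cover + shape_inside(sh, u0 + du, v0 + dv)
    }
    fg[rows, cols] <- fg[rows, cols] | (cover / supersample^2 >= 0.5)
    truth[[i]] <- data.frame(shape = i, kind = sh$kind,
                             length_cm = sh$length_cm, width_cm = sh$width_cm,
                             perimeter_cm = sh$perimeter_cm,
                             area_cm2 = sh$area_cm2,
                             center_row = sh$center_px[1],
                             center_col = sh$center_px[2],
                             angle_deg = sh$angle_deg)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(shape = integer(), kind = character(), length_cm = numeric(),
               width_cm = numeric(), perimeter_cm = numeric(),
               area_cm2 = numeric(), center_row = numeric(),
               center_col = numeric(), angle_deg = numeric())

  set.seed(seed)
  bg <- matrix(pmin(pmax(stats::rnorm(nr * nc, bg_level, noise_sd), 0), 1),
               nr, nc)
  px <- array(0L, c(nr, nc, 3L))
  for (ch in 1:3) {
    plane <- bg
    plane[fg] <- fg_rgb[ch]
    px[, , ch] <- as.integer(round(plane * 255))
  }
  list(image = scan_image(px, dpi, source_id = sprintf("scene_seed%d", seed),
                          accession_id = accession_id),
       truth = truth)
}

#' Default trait panel for the phenotype simulator
#'
#' Reference scale of the four bud size traits in a diverse tea germplasm
#' panel: trait means and between-accession SDs on the published Table-1
#' scale, with broad-sense heritability targets used to set the
#' within-accession (replicate) SD.
#'
#' @return `data.frame` with columns `trait`, `mean`, `sd_g`
#'   (between-accession genetic SD), `h2` (target broad-sense
#'   heritability), `sd_e` (within-accession SD implied by `h2`).
#' @export
default_trait_panel <- function() {
  d <- data.frame(
    trait = c("length", "width", "perimeter", "area"),
    mean  = c(2.65, 0.35, 5.75, 0.58),
    sd_g  = c(0.38, 0.05, 0.83, 0.14),
    h2    = c(0.72, 0.90, 0.71, 0.60))
  d$sd_e <- d$sd_g * sqrt(1 / d$h2 - 1)
  d
}

#' Simulate a replicate bud phenotype table
#'
#' Draws `value(accession i, replicate j, trait t) = mu_t + g_it + e_ijt`
#' with `g ~ N(0, sd_g^2)` (accession effect) and `e ~ N(0, sd_e^2)`
#' (bud-to-bud noise), emulating a germplasm panel in which each accession
#' contributes several clonal replicate buds. Optional group centres shift
#' accession effects to plant a blocky (clusterable) population structure.
#'
#' @param n_accessions number of accessions (default 280).
#' @param replicates replicate buds per accession (default 15).
#' @param traits `data.frame` with columns `trait`, `mean`, `sd_g`, `sd_e`
#'   (default [default_trait_panel()]).
#' @param regions character pool of geographic origins sampled per
#'   accession (default a set of Chinese tea-growing provinces).
#' @param blob_centers optional numeric matrix (`k x n_traits`, columns in
#'   `traits$trait` order) of additive group offsets; accessions are
#'   assigned to groups cyclically unless `blob_sizes` is given.
#' @param blob_sizes optional integer vector of group sizes summing to
#'   `n_accessions`.
#' @param seed RNG seed.
#' @return Long-format `data.frame`: `accession_id`, `region`, `group`
#'   (planted group or NA), `replicate`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(n_accessions = 280, replicates = 15,
                                traits = default_trait_panel(),
                                regions = c("Fujian", "Yunnan", "Zhejiang",
                                            "Guangxi", "Anhui", "Guizhou",
                                            "Sichuan", "Hunan", "Hubei",
                                            "Guangdong", "Jiangxi", "Henan",
                                            "Shaanxi", "Jiangsu", "Hainan",
                                            "Chongqing", "Taiwan"),
                                blob_centers = NULL, blob_sizes = NULL,
                                seed = 1) {
  stopifnot(n_accessions >= 1, replicates >= 1,
            all(c("trait", "mean", "sd_g", "sd_e") %in% names(traits)),
            all(traits$sd_g >= 0), all(traits$sd_e >= 0))
  set.seed(seed)
  acc <- sprintf("A%03d", seq_len(n_accessions))
  reg <- sample(regions, n_accessions, replace = TRUE)
  grp <- rep(NA_integer_, n_accessions)
  if (!is.null(blob_centers)) {
    blob_centers <- as.matrix(blob_centers)
    stopifnot(ncol(blob_centers) == nrow(traits))
    k <- nrow(blob_centers)
    grp <- if (is.null(blob_sizes)) rep_len(seq_len(k), n_accessions)
           else { stopifnot(sum(blob_sizes) == n_accessions)
                  rep(seq_len(k), times = blob_sizes) }
  }
  out <- vector("list", nrow(traits))
  for (t in seq_len(nrow(traits))) {
    g <- stats::rnorm(n_accessions, 0, traits$sd_g[t])
    if (!is.null(blob_centers)) g <- g + blob_centers[grp, t]
    e <- matrix(stats::rnorm(n_accessions * replicates, 0, traits$sd_e[t]),
                n_accessions, replicates)
    val <- traits$mean[t] + g + e           # recycles g down columns
    out[[t]] <- data.frame(
      accession_id = rep(acc, times = replicates),
      region = rep(reg, times = replicates),
      group = rep(grp, times = replicates),
      replicate = rep(seq_len(replicates), each = n_accessions),
      trait = traits$trait[t],
      value = as.vector(val))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$trait, res$accession_id, res$replicate), ]
  rownames(res) <- NULL
  res
}

#' Simulate a TPM expression matrix with planted trait-linked genes
#'
#' Emulates the 4-small-bud vs 4-large-bud extreme-accession design: for
#' linked genes, `log2(TPM + 1) = b0 + slope * z(trait) + N(0, noise_sd)`;
#' null genes get a trait-independent log-normal baseline. Truth flags mark
#' the planted genes and the sign of their slope.
#'
#' @param n_genes total genes.
#' @param n_linked number of trait-linked genes (first `n_linked` rows).
#' @param slope absolute slope on the log2 scale per SD of trait; signs
#'   alternate +/- across linked genes unless `slope_sign` is given.
#' @param slope_sign optional vector of +/-1 per linked gene.
#' @param noise_sd residual SD on the log2 scale for linked genes.
#' @param baseline_mean,baseline_sd gene-level mean log2(TPM+1) distribution.
#' @param null_sd sample-to-sample SD of null genes (log2 scale).
#' @param trait_small,trait_large group means of the per-sample trait
#'   (bud length, cm); the large:small ratio defaults near the observed
#'   ~1.7-fold contrast between extreme groups.
#' @param trait_sd within-group SD of the per-sample trait.
#' @param seed RNG seed.
#' @return A list: `tpm` (genes x 8 matrix), `meta` (`sample_id`, `group`,
#'   `trait`), `truth` (`gene_id`, `linked`, `sign`).
#' @export
simulate_expression <- function(n_genes = 1000, n_linked = 0, slope = 1.5,
                                slope_sign = NULL, noise_sd = 0.25,
                                baseline_mean = 3.5, baseline_sd = 1.2,
                                null_sd = 0.5,
                                trait_small = 2.0, trait_large = 3.4,
                                trait_sd = 0.15, seed = 1) {
  stopifnot(n_linked <= n_genes, n_genes >= 1)
  set.seed(seed)
  samples <- c(paste0("S", 1:4), paste0("L", 1:4))
  group <- rep(c("small", "large"), each = 4)
  trait <- c(stats::rnorm(4, trait_small, trait_sd),
             stats::rnorm(4, trait_large, trait_sd))
  zt <- as.vector(scale(trait))
  if (is.null(slope_sign) && n_linked > 0)
    slope_sign <- rep_len(c(1, -1), n_linked)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  b0 <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  logx <- matrix(0, n_genes, 8)
  if (n_linked > 0)
    logx[seq_len(n_linked), ] <-
      b0[seq_len(n_linked)] +
      outer(slope * slope_sign, zt) +
      matrix(stats::rnorm(n_linked * 8, 0, noise_sd), n_linked, 8)
  if (n_linked < n_genes) {
    idx <- (n_linked + 1):n_genes
    logx[idx, ] <- b0[idx] +
      matrix(stats::rnorm(length(idx) * 8, 0, null_sd), length(idx), 8)
  }
  tpm <- pmax(2^logx - 1, 0)
  dimnames(tpm) <- list(gene_id, samples)
  list(tpm = tpm,
       meta = data.frame(sample_id = samples, group = group, trait = trait),
       truth = data.frame(gene_id = gene_id,
                          linked = seq_len(n_genes) <= n_linked,
                          sign = c(slope_sign, rep(NA, n_genes - n_linked))))
}

#' Simulate per-trait association scans with planted peaks
#'
#' Lays a regular SNP grid over the chromosomes with background
#' p ~ Uniform(0, 1), then overwrites p at planted peak positions for the
#' peak's member traits (adding the position to the grid if absent). Also
#' emits a tiled gene annotation, a one-record genotype table at a
#' designated lead SNP, and accession phenotypes shifted additively by
#' genotype class, so the downstream interval construction and genotype
#' stratification can be exercised end to end.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param spacing SNP grid spacing (bp).
#' @param traits trait names (one scan per trait).
#' @param peaks `data.frame` with columns `chrom`, `pos`, `traits`
#'   (comma-separated member traits) and `neglog10p`; may be empty.
#' @param gene_every,gene_width gene tiling: one gene every `gene_every`
#'   bp, of `gene_width` bp.
#' @param lead_snp optional `c(chrom, pos)` (pos coercible to numeric) at
#'   which genotypes are simulated.
#' @param n_samples accessions genotyped at the lead SNP.
#' @param maf alternate-allele frequency at the lead SNP.
#' @param effect_sd additive phenotype shift per alternate allele, in
#'   trait-SD units (monotone 0/0 < 0/1 < 1/1 when positive).
#' @param seed RNG seed.
#' @return A list: `assoc` (named list of per-trait `data.frame`s
#'   `chrom,pos,p`), `genes` (`gene_id,chrom,start,end,strand`), and, if
#'   `lead_snp` is given, `genotypes` (`sample_id`, `gt` as "0/0" etc.)
#'   and `phenotypes` (accession trait means shifted by genotype).
#' @export
simulate_association <- function(chrom_lengths = c(Chr1 = 2e7, Chr2 = 2e7,
                                                   Chr3 = 2e7),
                                 spacing = 5e4,
                                 traits = c("length", "width",
                                            "perimeter", "area"),
                                 peaks = NULL,
                                 gene_every = 5e4, gene_width = 2e4,
                                 lead_snp = NULL, n_samples = 90,
                                 maf = 0.4, effect_sd = 1,
                                 seed = 1) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  set.seed(seed)
  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch)
    data.frame(chrom = ch,
               pos = seq(spacing, chrom_lengths[[ch]], by = spacing))))
  if (!is.null(peaks) && nrow(peaks)) {
    stopifnot(all(peaks$chrom %in% names(chrom_lengths)),
              all(peaks$pos >= 1),
              all(peaks$pos <= chrom_lengths[peaks$chrom]))
    extra <- unique(peaks[, c("chrom", "pos")])
    grid <- unique(rbind(grid, extra))
  }
  grid <- grid[order(grid$chrom, grid$pos), ]
  assoc <- lapply(traits, function(tr) {
    d <- grid
    d$p <- stats::runif(nrow(d))
    if (!is.null(peaks) && nrow(peaks)) {
      for (k in seq_len(nrow(peaks))) {
        members <- trimws(strsplit(peaks$traits[k], ",")[[1]])
        if (tr %in% members) {
          i <- which(d$chrom == peaks$chrom[k] & d$pos == peaks$pos[k])
          d$p[i] <- 10^(-peaks$neglog10p[k])
        }
      }
    }
    rownames(d) <- NULL
    d
  })
  names(assoc) <- traits

  genes <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]] - gene_width, by = gene_every)
    data.frame(chrom = ch, start = starts, end = starts + gene_width - 1,
               strand = "+")
  }))
  genes <- cbind(gene_id = sprintf("GENE%05d", seq_len(nrow(genes))), genes)

  out <- list(assoc = assoc, genes = genes)
  if (!is.null(lead_snp)) {
    alleles <- stats::rbinom(n_samples, 2, maf)
    gt <- c("0/0", "0/1", "1/1")[alleles + 1]
    sample_id <- sprintf("A%03d", seq_len(n_samples))
    panel <- default_trait_panel()
    ph <- data.frame(accession_id = sample_id)
    for (t in seq_len(nrow(panel)))
      ph[[panel$trait[t]]] <- panel$mean[t] +
        effect_sd * panel$sd_g[t] * (alleles - 2 * maf) +
        stats::rnorm(n_samples, 0, panel$sd_g[t])
    out$genotypes <- data.frame(sample_id = sample_id, gt = gt)
    out$lead_snp <- list(chrom = as.character(lead_snp[1]),
                         pos = as.numeric(lead_snp[2]))
    out$phenotypes <- ph
  }
  out
}
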
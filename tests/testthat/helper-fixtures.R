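# Shared fixture builders. Everything is generated in code at test time.

# Render a single shape in a canvas just large enough for it and return
# the scene plus the measured features of its (single) segmented mask.
render_and_measure <- function(kind, length_cm, width_cm, angle_deg = 0,
                               dpi = 600, seed = 1, noise_sd = 0.02) {
  s <- 2.54 / dpi
  half <- ceiling(length_cm / 2 / s) + 16L
  ctr <- half + 1L
  sp <- shape_spec(kind, length_cm, width_cm, center_px = c(ctr, ctr),
                   angle_deg = angle_deg)
  sc <- render_scene(list(sp), dpi = dpi, size_px = c(2L * half + 2L,
                                                      2L * half + 2L),
                     seed = seed, noise_sd = noise_sd)
  masks <- segment_buds(sc$image)
  stopifnot(length(masks) == 1L)
  list(shape = sp, scene = sc,
       features = measure_bud(masks[[1]], px_scale(sc$image)))
}

# Small three-bud scene with well-separated shapes. `scale` grows or
# shrinks all buds, emulating accessions of different bud size.
three_bud_scene <- function(dpi = 300, seed = 2, scale = 1) {
  s <- 2.54 / dpi
  shapes <- list(
    shape_spec("stadium", 2.0 * scale, 0.35 * scale,
               center_px = c(150, 160), angle_deg = 15),
    shape_spec("ellipse", 1.8 * scale, 0.40 * scale,
               center_px = c(150, 430), angle_deg = 80),
    shape_spec("stadium", 2.4 * scale, 0.30 * scale,
               center_px = c(430, 290), angle_deg = 120))
  render_scene(shapes, dpi = dpi, size_px = c(620, 580), seed = seed)
}

# Brute-force interval merge oracle: paint flanked SNPs onto a per-bp
# logical vector and read off maximal runs. Only usable for small
# chromosomes.
bruteforce_intervals <- function(snps, chrom_lengths, flank,
                                 merge_bookended = TRUE) {
  out <- list()
  for (ch in sort(unique(as.character(snps$chrom)))) {
    len <- chrom_lengths[[ch]]
    covered <- logical(len)
    for (pos in snps$pos[snps$chrom == ch])
      covered[max(1, pos - flank):min(len, pos + flank)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    iv <- data.frame(chrom = ch, start = starts[r$values],
                     end = ends[r$values])
    if (!merge_bookended || nrow(iv) < 2) { out[[ch]] <- iv; next }
    # merge book-ended runs (cannot occur from a painted vector, but keep
    # the oracle honest about the rule it implements)
    keep <- iv[1, ]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= keep$end[nrow(keep)] + 1)
        keep$end[nrow(keep)] <- max(keep$end[nrow(keep)], iv$end[i])
      else keep <- rbind(keep, iv[i, ])
    }
    out[[ch]] <- keep
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
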
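#' Run the phenotyping chain: images -> features -> stats -> clusters
#'
#' Reads every scan listed in the manifest, extracts per-bud features,
#' aggregates them into a long-format phenotype table, computes the
#' per-trait diversity statistics and clusters the accessions. Per-file
#' failures are logged as warnings and the run continues; stage outputs
#' are written with provenance headers (package version, seed, config
#' hash).
#'
#' @param manifest `data.frame` (or CSV path) with columns `path`,
#'   `accession_id` and optionally `dpi` (default 600) and `region`.
#' @param out_dir output directory (created if needed).
#' @param cfg list of stage settings: `segmentation`
#'   (a [segmentation_config()]), `cut_height` and/or `cut_k` for the
#'   cluster cut, `linkage`, `standardize`.
#' @param seed recorded in output headers (the chain itself is
#'   deterministic).
#' @return (invisibly) a list with `features`, `phenotypes`, `stats`,
#'   `clusters` (`bud_clust`), `assignment`, `summary`, and `n_failed`.
#' @export
run_phenotyping <- function(manifest, out_dir = ".",
                            cfg = list(), seed = 1) {
  if (is.character(manifest)) manifest <- read_table_prov(manifest)
  stopifnot(all(c("path", "accession_id") %in% names(manifest)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seg <- cfg$segmentation %||% segmentation_config()
  dpi <- if ("dpi" %in% names(manifest)) manifest$dpi else
    rep(600, nrow(manifest))

  n_failed <- 0L
  images <- list()
  for (i in seq_len(nrow(manifest))) {
    img <- tryCatch(read_scan(manifest$path[i], dpi = dpi[i],
                              accession_id = manifest$accession_id[i]),
                    error = function(e) {
                      warning("manifest row ", i, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(img)) n_failed <- n_failed + 1L else
      images[[length(images) + 1L]] <- img
  }
  features <- extract_features(images, seg)
  write_table_prov(features, file.path(out_dir, "features.csv"),
                   seed = seed, config = cfg)

  phen <- features
  if (!nrow(phen)) {
    warning("no buds extracted from any image")
    return(invisible(list(features = features, phenotypes = NULL,
                          stats = NULL, clusters = NULL,
                          assignment = NULL, summary = NULL,
                          n_failed = n_failed)))
  }
  long <- stats::reshape(
    phen[, c("accession_id", "bud_index", "length_cm", "width_cm",
             "perimeter_cm", "area_cm2")],
    direction = "long",
    varying = c("length_cm", "width_cm", "perimeter_cm", "area_cm2"),
    v.names = "value", timevar = "trait",
    times = c("length", "width", "perimeter", "area"),
    idvar = c("accession_id", "bud_index"))
  names(long)[names(long) == "bud_index"] <- "replicate"
  rownames(long) <- NULL
  if ("region" %in% names(manifest))
    long$region <- manifest$region[match(long$accession_id,
                                         manifest$accession_id)]
  write_table_prov(long, file.path(out_dir, "phenotypes.csv"),
                   seed = seed, config = cfg)

  st <- stats_table(long)
  write_table_prov(st, file.path(out_dir, "stats_table.csv"),
                   seed = seed, config = cfg)

  am <- accession_means(long)
  cl <- NULL; assignment <- NULL; summ <- NULL
  if (nrow(am) >= 2) {
    cl <- cluster_accessions(am, linkage = cfg$linkage %||% "ward",
                             standardize = cfg$standardize %||% TRUE)
    assignment <- if (!is.null(cfg$cut_height))
      cut_tree(cl, h = cfg$cut_height)
    else cut_tree(cl, k = cfg$cut_k %||% min(4, nrow(am)))
    summ <- summarize_groups(assignment, am)
    write_table_prov(data.frame(accession_id = names(assignment),
                                group = assignment),
                     file.path(out_dir, "cluster_assignment.csv"),
                     seed = seed, config = cfg)
    write_table_prov(summ$groups,
                     file.path(out_dir, "cluster_groups.csv"),
                     seed = seed, config = cfg)
    hm <- cl$hclust$merge
    write_table_prov(data.frame(left = hm[, 1], right = hm[, 2],
                                height = cl$hclust$height),
                     file.path(out_dir, "cluster_merges.csv"),
                     seed = seed, config = cfg)
  }
  invisible(list(features = features, phenotypes = long, stats = st,
                 clusters = cl, assignment = assignment, summary = summ,
                 n_failed = n_failed))
}

#' Run the genetics chain: screening + intervals + convergence report
#'
#' Screens trait-linked genes from the expression matrix, builds merged
#' candidate intervals from the association scans, and writes a joint
#' report of screened genes whose annotated coordinates fall inside a
#' candidate interval — the convergence step that elevates a screened
#' gene to a positional candidate.
#'
#' @param tpm gene x sample TPM matrix (or TSV path, see [read_tpm()]).
#' @param meta `data.frame` with `sample_id`, `group` ("small"/"large")
#'   and one column per trait holding the per-sample trait value.
#' @param assoc named list of per-trait association `data.frame`s
#'   (`chrom`, `pos`, `p`) or TSV paths (see [read_assoc()]).
#' @param genes gene annotation `data.frame` or GFF3 path (see
#'   [annotate_genes()]); genes missing from the annotation are excluded
#'   from the joint report with a warning.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param out_dir output directory.
#' @param screening a [screening_config()].
#' @param intervals_cfg an [interval_config()].
#' @param seed recorded in output headers.
#' @return (invisibly) a list with `screens` (per-trait [screen_trait()]
#'   results), `venn`, `common_genes`, `intervals` (annotated),
#'   `interval_summary`, and `joint_report` (`data.frame` of screened
#'   genes inside intervals).
#' @export
run_genetics <- function(tpm, meta, assoc, genes, chrom_lengths,
                         out_dir = ".",
                         screening = screening_config(),
                         intervals_cfg = interval_config(), seed = 1) {
  if (is.character(tpm)) tpm <- read_tpm(tpm)
  if (is.character(assoc) ||
      (is.list(assoc) && all(vapply(assoc, is.character, TRUE))))
    assoc <- read_assoc(unlist(assoc))
  if (is.character(genes)) genes <- read_gff3_genes(genes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  traits <- intersect(names(assoc),
                      setdiff(names(meta), c("sample_id", "group")))
  if (!length(traits))
    traits <- setdiff(names(meta), c("sample_id", "group"))
  tpm <- tpm[, meta$sample_id, drop = FALSE]
  screens <- lapply(traits, function(tr) {
    screen_trait(tpm, stats::setNames(meta[[tr]], meta$sample_id),
                 meta$group, screening)
  })
  names(screens) <- traits
  for (tr in traits)
    write_table_prov(screens[[tr]]$table,
                     file.path(out_dir, paste0("screen_", tr, ".tsv")),
                     sep = "\t", seed = seed, config = screening)
  sets <- lapply(screens, `[[`, "genes")
  iv_genes <- NULL; venn <- NULL; common <- unique(unlist(sets))
  if (length(sets) >= 2) {
    it <- intersect_traits(sets)
    common <- it$common
    venn <- it$venn
    write_table_prov(venn, file.path(out_dir, "venn_counts.csv"),
                     seed = seed, config = screening)
  }
  writeLines(common, file.path(out_dir, "common_genes.txt"))
  if (length(common)) {
    z <- suppressWarnings(zscore_matrix(tpm, common))
    write_table_prov(data.frame(gene_id = rownames(z), z,
                                check.names = FALSE),
                     file.path(out_dir, "zscore_matrix.tsv"), sep = "\t",
                     seed = seed, config = screening)
  }

  cands <- candidate_snps(assoc, intervals_cfg)
  iv <- build_intervals(cands, chrom_lengths, intervals_cfg)
  ann <- annotate_genes(iv, genes)
  write_bed(ann$intervals, file.path(out_dir, "intervals.bed"))
  write_table_prov(ann$intervals,
                   file.path(out_dir, "intervals_annotated.tsv"),
                   sep = "\t", seed = seed, config = intervals_cfg)

  known <- common %in% genes$gene_id
  if (any(!known) && length(common))
    warning(sum(!known), " screened gene(s) absent from the annotation; ",
            "excluded from the joint report")
  in_iv <- unique(unlist(strsplit(
    ann$intervals$genes[ann$intervals$genes != ""], ",")))
  joint <- common[known & common %in% in_iv]
  jr <- data.frame(gene_id = joint)
  if (nrow(jr)) {
    jr <- cbind(jr, genes[match(joint, genes$gene_id),
                          c("chrom", "start", "end")])
    rownames(jr) <- NULL
  }
  write_table_prov(jr, file.path(out_dir, "joint_report.tsv"), sep = "\t",
                   seed = seed, config = intervals_cfg)
  invisible(list(screens = screens, venn = venn, common_genes = common,
                 intervals = ann$intervals,
                 interval_summary = ann$summary, joint_report = jr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
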
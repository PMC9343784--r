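# Orchestration: fixture generation and the end-to-end analysis over the
# four contrasts of the factorial design. Everything downstream of the
# simulator is deterministic, so reruns on the same inputs are
# byte-identical.

.default_contrast_names <- function() {
  c("SAL_SAL-vs-METH_SAL", "SAL_SAL-vs-SAL_METH",
    "METH_SAL-vs-METH_METH", "SAL_METH-vs-METH_METH")
}

.default_pairs <- function() {
  list(
    list(name = "prenatal_vs_postnatal",
         contrast_A = "SAL_SAL-vs-METH_SAL",
         contrast_B = "SAL_SAL-vs-SAL_METH"),
    list(name = "postnatal_vs_prepostnatal",
         contrast_A = "SAL_SAL-vs-SAL_METH",
         contrast_B = "SAL_METH-vs-METH_METH")
  )
}

.default_thresholds <- function() {
  list(min_cov = 10L, dmc_q = 0.05, dmr_sig_q = 0.01, dmr_alpha = 0.05,
       window_size = 1000L, window_step = 200L, min_cpg = 3L,
       min_delta_pp = 20, max_gene_distance = 10000L)
}

#' Write a synthetic fixture directory
#'
#' Generates a genome model, truth set and 12 per-sample cytosine reports
#' and writes them, together with annotation (gene BED12, island BED,
#' chromosome sizes), a gene-set GMT (truth-linked sets plus decoys), a
#' truth BED and a ready-to-run pipeline config, into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param factors truth factors to spike, see
#'   [spike_differential_regions()].
#' @return invisibly, a list with the config path, the model and the truth
#'   set.
#' @export
make_fixture <- function(dir, config = sim_config(),
                         factors = c("pre", "post", "interaction")) {
  dir.create(file.path(dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  model <- build_genome_model(config)
  truth <- spike_differential_regions(model, config, factors = factors)
  counts <- simulate_counts(model, truth, config)

  for (sid in names(counts)) {
    write_cytosine_report(counts[[sid]],
                          file.path(dir, "reports", paste0(sid, ".cov.tsv")))
  }
  tb <- copy(as.data.table(truth))
  if (nrow(tb)) {
    tb[, `:=`(name = paste(factor_id, direction, sep = ":"),
              score = delta_pp, strand = ".")]
  }
  write_bed(tb, file.path(dir, "truth.bed"))
  write_gene_bed12(model$genes, model$exons, file.path(dir, "genes.bed12"))
  write_bed(model$islands, file.path(dir, "islands.bed"))
  write_tsv(data.table(chrom = names(model$chrom_lengths),
                       length = unname(model$chrom_lengths)),
            file.path(dir, "chrom_sizes.tsv"))

  # gene sets: genes assigned to each factor's truth regions, plus decoys
  ann <- annotation_set(model$genes, model$exons, model$islands,
                        model$chrom_lengths)
  sets <- list()
  if (nrow(tb)) {
    ag <- assign_gene(tb, ann)
    for (f in unique(tb$factor_id)) {
      g <- sort(unique(stats::na.omit(ag$gene_id[tb$factor_id == f])))
      if (length(g) >= 2L) sets[[paste0("truth_", f)]] <- g
    }
  }
  set.seed(config$seed + 3L)
  all_genes <- model$genes$gene_id
  for (i in 1:3) {
    sets[[paste0("random_", i)]] <-
      sort(sample(all_genes, min(10L, length(all_genes))))
  }
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))

  manifest <- data.table(
    id = names(counts),
    group = sub("_r[0-9]+$", "", names(counts)),
    path = file.path("reports", paste0(names(counts), ".cov.tsv")))
  cfg <- list(
    samples = lapply(seq_len(nrow(manifest)), function(i) {
      as.list(manifest[i])
    }),
    contrasts = .default_contrast_names(),
    pairs = .default_pairs(),
    thresholds = .default_thresholds(),
    annotation = list(genes_bed12 = "genes.bed12", islands_bed = "islands.bed",
                      chrom_sizes = "chrom_sizes.tsv"),
    gene_sets = "gene_sets.gmt",
    metagene = list(flank = 5000L, n_flank_bins = 50L, n_body_bins = 60L),
    out_dir = "output",
    seed = config$seed
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(config_path = cfg_path, model = model, truth = truth,
                 counts = counts))
}

#' Read and validate a pipeline config
#'
#' Relative paths in the config are resolved against the config file's
#' directory.
#'
#' @param path YAML config path (as written by [make_fixture()]).
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(root, p))
  }
  for (i in seq_along(cfg$samples)) {
    cfg$samples[[i]]$path <- resolve(cfg$samples[[i]]$path)
  }
  cfg$annotation <- lapply(cfg$annotation, resolve)
  cfg$gene_sets <- resolve(cfg$gene_sets)
  if (!grepl("^/", cfg$out_dir)) cfg$out_dir <- file.path(root, cfg$out_dir)
  th <- .default_thresholds()
  th[names(cfg$thresholds)] <- cfg$thresholds
  cfg$thresholds <- th
  if (is.null(cfg$contrasts)) cfg$contrasts <- .default_contrast_names()
  if (is.null(cfg$pairs)) cfg$pairs <- .default_pairs()
  groups <- vapply(cfg$samples, `[[`, character(1), "group")
  for (cn in cfg$contrasts) {
    parts <- strsplit(cn, "-vs-", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% groups)) {
      stop("contrast ", cn, " refers to groups missing from the manifest")
    }
  }
  stopifnot(all(unlist(cfg$thresholds[c("min_cov", "window_size",
                                        "window_step", "min_cpg")]) > 0))
  structure(cfg, class = "pipeline_config")
}

.contrast_from_name <- function(name, samples) {
  parts <- strsplit(name, "-vs-", fixed = TRUE)[[1]]
  ids <- vapply(samples, `[[`, character(1), "id")
  grp <- vapply(samples, `[[`, character(1), "group")
  contrast(name, ids[grp == parts[1]], ids[grp == parts[2]])
}

#' Run the full analysis pipeline
#'
#' From a config (path or [read_pipeline_config()] result): reads all
#' cytosine reports and annotation, then per contrast calls DMCs and DMRs,
#' classifies them and writes a genomic-distribution summary; per
#' cross-contrast pair computes the Venn/hypergeometric overlap, Pearson
#' correlations on both site scopes, a z-scored clustering matrix and
#' gene-set enrichment of the common sites' genes; writes per-group
#' meta-gene profiles over all DMC sites and a per-sample context summary.
#' All outputs are TSV/BED under the config's `out_dir`; reruns on the same
#' inputs are byte-identical.
#'
#' @param config config path or `pipeline_config` object.
#' @return invisibly, a named list with the in-memory results (dmc tables,
#'   dmr tables, overlaps, correlations, enrichments, profiles).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  out <- config$out_dir
  for (d in c("dmc", "dmr", "compare", "metagene")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  log_lines <- c(
    paste("methslide", as.character(packageVersion("methslide"))),
    paste("seed", config$seed),
    paste("thresholds:", paste(names(th), unlist(th), sep = "=",
                               collapse = " ")))

  counts <- list()
  for (s in config$samples) {
    counts[[s$id]] <- read_cytosine_report(s$path)
  }
  log_lines <- c(log_lines, paste("samples read:", length(counts)))

  gm <- read_gene_bed12(config$annotation$genes_bed12)
  islands <- read_bed(config$annotation$islands_bed)
  sizes <- data.table::fread(config$annotation$chrom_sizes, sep = "\t")
  chrom_lengths <- setNames(as.integer(sizes$length), sizes$chrom)
  ann <- annotation_set(gm$genes, gm$exons, islands, chrom_lengths)
  gmt <- read_gmt(config$gene_sets)

  # context summary per sample
  ctx <- context_methylation_summary(counts)
  write_tsv(ctx, file.path(out, "context_summary.tsv"))

  dmc_tables <- list(); dmr_tables <- list()
  for (cn in config$contrasts) {
    ct <- .contrast_from_name(cn, config$samples)
    dmc <- call_dmcs(counts, ct, min_cov = th$min_cov, q_max = th$dmc_q)
    write_dmc_table(dmc, file.path(out, "dmc", paste0(cn, ".dmc.tsv")))
    dmr <- call_dmrs(dmc, chrom_lengths, size = th$window_size,
                     step = th$window_step, alpha = th$dmr_alpha,
                     min_cpg = th$min_cpg, sig_q = th$dmr_sig_q,
                     min_delta_pp = th$min_delta_pp)
    if (nrow(dmr)) {
      cls <- classify_region(dmr, ann)
      dmr[, `:=`(primary = cls$primary, cpg_island = cls$cpg_island)]
    } else {
      dmr[, `:=`(primary = character(0), cpg_island = logical(0))]
    }
    write_dmr_bed(dmr, file.path(out, "dmr", paste0(cn, ".dmr.bed")))
    rej <- attr(dmr, "rejections")
    if (!is.null(rej) && nrow(rej)) {
      write_tsv(rej[order(reason)],
                file.path(out, "dmr", paste0(cn, ".rejections.tsv")))
    }
    dist <- summarize_dmr_distribution(dmr)
    write_tsv(dist, file.path(out, "dmr", paste0(cn, ".distribution.tsv")))
    tiles <- rbindlist(lapply(seq_len(nrow(dmr)), function(i) {
      tl <- refine_subregions(dmr[i], dmc, q_max = th$dmc_q)
      if (nrow(tl)) tl[, dmr_id := i]
      tl
    }), fill = TRUE)
    if (nrow(tiles)) {
      write_tsv(tiles, file.path(out, "dmr", paste0(cn, ".tiles.tsv")))
    }
    log_lines <- c(log_lines, paste0(
      cn, ": ", nrow(dmc), " CpGs tested, ", sum(dmc$sig), " DMCs (q<=",
      th$dmc_q, "), ", nrow(dmr), " DMRs"))
    dmc_tables[[cn]] <- dmc
    dmr_tables[[cn]] <- dmr
  }

  overlaps <- list(); correlations <- list(); enrichments <- list()
  for (pr in config$pairs) {
    ta <- dmc_tables[[pr$contrast_A]]
    tb <- dmc_tables[[pr$contrast_B]]
    if (is.null(ta) || is.null(tb)) {
      stop("pair ", pr$name, " refers to a contrast not in the config")
    }
    universe_keys <- intersect(.site_keys(ta, significant = FALSE),
                               .site_keys(tb, significant = FALSE))
    ov <- dmc_set_overlap(ta, tb, universe = length(universe_keys))
    write_tsv(data.table(pair = pr$name, n_A_only = ov$n_A_only,
                         n_common = ov$n_common, n_B_only = ov$n_B_only,
                         universe = ov$universe, p_overlap = ov$p_overlap),
              file.path(out, "compare", paste0(pr$name, ".overlap.tsv")))
    cors <- lapply(c("union", "common"), function(sc) {
      cr <- correlate_deltas(ta, tb, site_scope = sc)
      data.table(pair = pr$name, scope = sc, r = cr$r, p = cr$p,
                 n_sites = cr$n_sites)
    })
    write_tsv(rbindlist(cors),
              file.path(out, "compare", paste0(pr$name, ".correlation.tsv")))

    # z-scored per-sample levels at common DMC sites, clustered
    common_keys <- intersect(.site_keys(ta), .site_keys(tb))
    if (length(common_keys) >= 2L) {
      m <- methylation_matrix(counts, common_keys)
      z <- suppressWarnings(zscore_matrix(
        m[stats::complete.cases(m), , drop = FALSE]))
      if (nrow(z) >= 1L) {
        ord <- hclust_order(z)
        zt <- data.table(site = rownames(z))
        for (cc in ord$labels[ord$order]) zt[[cc]] <- z[, cc]
        write_tsv(zt, file.path(out, "compare",
                                paste0(pr$name, ".zmatrix.tsv")))
        write_tsv(data.table(leaf = seq_along(ord$order),
                             sample = ord$labels[ord$order]),
                  file.path(out, "compare", paste0(pr$name, ".hclust.tsv")))
      }
    }

    # enrichment of genes carrying common DMCs; universe = genes with any
    # tested-in-both site within the assignment distance
    if (length(common_keys)) {
      ck <- data.table(key_ = common_keys)
      ck[, c("chrom", "start") := {
        sp <- strsplit(key_, ":", fixed = TRUE)
        .(vapply(sp, `[`, character(1), 1L),
          as.integer(vapply(sp, `[`, character(1), 2L)))
      }]
      ck[, end := start + 1L]
      qg <- stats::na.omit(unique(assign_gene(ck, ann,
                                              th$max_gene_distance)$gene_id))
      uk <- data.table(key_ = universe_keys)
      uk[, c("chrom", "start") := {
        sp <- strsplit(key_, ":", fixed = TRUE)
        .(vapply(sp, `[`, character(1), 1L),
          as.integer(vapply(sp, `[`, character(1), 2L)))
      }]
      ug <- vapply(seq_len(nrow(gm$genes)), function(i) {
        any(uk$chrom == gm$genes$chrom[i] &
              uk$start >= gm$genes$start[i] - th$max_gene_distance &
              uk$start < gm$genes$end[i] + th$max_gene_distance)
      }, logical(1))
      universe_genes <- gm$genes$gene_id[ug]
      qg <- intersect(qg, universe_genes)
      if (length(qg) && length(universe_genes)) {
        enr <- enrich_gene_sets(qg, gmt, universe_genes)
        write_tsv(enr, file.path(out, "compare",
                                 paste0(pr$name, ".enrichment.tsv")))
        enrichments[[pr$name]] <- enr
      }
    }
    overlaps[[pr$name]] <- ov
    correlations[[pr$name]] <- rbindlist(cors)
    log_lines <- c(log_lines, paste0(
      "pair ", pr$name, ": common ", ov$n_common, ", p_overlap ",
      format(ov$p_overlap, digits = 4)))
  }

  # meta-gene profiles per group over the union of all contrasts' DMC sites
  dmc_keys_all <- unique(unlist(lapply(dmc_tables, .site_keys)))
  profiles <- list()
  if (length(dmc_keys_all)) {
    groups <- unique(vapply(config$samples, `[[`, character(1), "group"))
    ids <- vapply(config$samples, `[[`, character(1), "id")
    grp_of <- vapply(config$samples, `[[`, character(1), "group")
    for (g in groups) {
      pooled <- pool_group_counts(counts, ids[grp_of == g])
      pooled[, key_ := paste(chrom, start, strand, sep = ":")]
      st <- pooled[key_ %in% dmc_keys_all & count_m + count_u > 0]
      st[, `:=`(value = count_m / (count_m + count_u),
                weight = count_m + count_u)]
      prof <- suppressWarnings(average_profile(
        st, gm$genes, chrom_lengths,
        flank = config$metagene$flank,
        n_flank_bins = config$metagene$n_flank_bins,
        n_body_bins = config$metagene$n_body_bins))
      write_tsv(cbind(data.table(group = g), prof),
                file.path(out, "metagene", paste0(g, ".profile.tsv")))
      profiles[[g]] <- prof
    }
  }

  yaml::write_yaml(unclass(config), file.path(out, "effective_config.yaml"))
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(list(dmc = dmc_tables, dmr = dmr_tables, overlaps = overlaps,
                 correlations = correlations, enrichments = enrichments,
                 profiles = profiles, context_summary = ctx,
                 out_dir = out))
}
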
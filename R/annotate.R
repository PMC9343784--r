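#' Build an annotation set
#'
#' Wraps gene models, exons, CpG islands and chromosome lengths into the
#' GRanges objects the classifiers use. Promoters are defined strand-aware
#' as `[TSS - upstream, TSS + downstream)` (a common convention; the study
#' never defines "promoter", so both extents are parameters).
#'
#' @param genes data.table gene_id, chrom, start, end, strand (0-based
#'   half-open).
#' @param exons data.table gene_id, chrom, start, end.
#' @param islands data.table chrom, start, end.
#' @param chrom_lengths named integer vector.
#' @param promoter_upstream,promoter_downstream promoter extent around the
#'   TSS in bp.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(genes, exons, islands, chrom_lengths,
                           promoter_upstream = 2000L,
                           promoter_downstream = 200L) {
  mk <- function(dt, strand = NULL) {
    if (!nrow(dt)) {
      gr <- GenomicRanges::GRanges()
      return(gr)
    }
    GenomicRanges::GRanges(
      seqnames = dt$chrom,
      ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
      strand = if (is.null(strand)) "*" else strand
    )
  }
  genes_gr <- mk(genes, strand = if (nrow(genes)) genes$strand)
  if (length(genes_gr)) names(genes_gr) <- genes$gene_id
  exons_gr <- mk(exons)
  islands_gr <- mk(islands)
  promoters_gr <- if (length(genes_gr)) {
    prom <- suppressWarnings(GenomicRanges::promoters(
      genes_gr, upstream = promoter_upstream,
      downstream = promoter_downstream))
    # clip to chromosome bounds (seqlengths are not attached to the GRanges)
    lims <- unname(chrom_lengths[as.character(GenomicRanges::seqnames(prom))])
    IRanges::ranges(prom) <- IRanges::IRanges(
      start = pmax(GenomicRanges::start(prom), 1L),
      end = pmin(GenomicRanges::end(prom), lims))
    prom
  } else GenomicRanges::GRanges()
  structure(list(genes = genes, exons = exons, islands = islands,
                 chrom_lengths = chrom_lengths,
                 genes_gr = genes_gr, exons_gr = exons_gr,
                 islands_gr = islands_gr, promoters_gr = promoters_gr),
            class = "annotation_set")
}

.regions_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
}

#' Classify regions into genomic features
#'
#' Assigns exactly one primary label with precedence
#' Promoter > Exons > Introns > Intergenic. By default the label is decided
#' by the region midpoint (deterministic for windows straddling features);
#' `rule = "any"` uses any-overlap with the same precedence. The CpG-island
#' flag is an independent overlay: true iff the full region overlaps an
#' island by at least 1 bp.
#'
#' @param regions data.table chrom, start, end (0-based half-open).
#' @param annotation an [annotation_set()].
#' @param rule `"midpoint"` (default) or `"any"`.
#' @return data.table with columns primary, cpg_island.
#' @export
classify_region <- function(regions, annotation, rule = c("midpoint", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(annotation, "annotation_set"))
  regions <- as.data.table(regions)
  bad <- !(regions$chrom %in% names(annotation$chrom_lengths)) |
    regions$end > annotation$chrom_lengths[regions$chrom] |
    regions$start < 0
  if (any(bad)) {
    stop("region outside chromosome bounds: ",
         regions$chrom[which(bad)[1]], ":", regions$start[which(bad)[1]],
         "-", regions$end[which(bad)[1]])
  }
  query <- if (rule == "midpoint") {
    mid <- regions$start + floor((regions$end - regions$start) / 2)
    GenomicRanges::GRanges(regions$chrom,
                           IRanges::IRanges(start = mid + 1L, width = 1L))
  } else {
    .regions_gr(regions)
  }
  hit <- function(subject) {
    if (!length(subject)) rep(FALSE, length(query))
    else IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
  }
  in_prom <- hit(annotation$promoters_gr)
  in_exon <- hit(annotation$exons_gr)
  in_gene <- hit(annotation$genes_gr)
  primary <- ifelse(in_prom, "Promoter",
                    ifelse(in_exon, "Exons",
                           ifelse(in_gene, "Introns", "Intergenic")))
  full_gr <- .regions_gr(regions)
  isl <- if (length(annotation$islands_gr)) {
    IRanges::overlapsAny(full_gr, annotation$islands_gr, ignore.strand = TRUE)
  } else rep(FALSE, length(full_gr))
  data.table(primary = primary, cpg_island = isl)
}

#' Genomic-distribution summary of called DMRs
#'
#' Reproduces the published table layout: one total row, one row per
#' primary feature (Exons, Intergenic, Introns, Promoter; mutually
#' exclusive and exhaustive) and a separate CpG-island overlay row. Percent
#' of total is rounded to 2 decimals; hyper/hypo percentages (of the row
#' count) to 4 decimals.
#'
#' @param dmrs data.table with columns direction, primary, cpg_island (see
#'   [classify_region()]).
#' @return data.table: category, n, pct_total, n_hyper, pct_hyper, n_hypo,
#'   pct_hypo.
#' @export
summarize_dmr_distribution <- function(dmrs) {
  dt <- as.data.table(dmrs)
  total <- nrow(dt)
  row_for <- function(label, sub) {
    n <- nrow(sub)
    nh <- sum(sub$direction == "hyper")
    nl <- sum(sub$direction == "hypo")
    data.table(
      category = label, n = n,
      pct_total = if (total > 0) round(100 * n / total, 2) else 0,
      n_hyper = nh,
      pct_hyper = if (n > 0) round(100 * nh / n, 4) else 0,
      n_hypo = nl,
      pct_hypo = if (n > 0) round(100 * nl / n, 4) else 0)
  }
  cats <- c("Exons", "Intergenic", "Introns", "Promoter")
  rbindlist(c(
    list(row_for("DMR", dt)),
    lapply(cats, function(cc) row_for(cc, dt[primary == cc])),
    list(row_for("CpG islands", dt[cpg_island == TRUE]))
  ))
}

#' Assign a gene to each region
#'
#' A gene overlapping the region is preferred (several overlaps: the
#' lexicographically first gene id, flagged as a tie); otherwise the gene
#' with the nearest TSS within `max_distance` bp (ties broken by smaller
#' distance, then lexicographic gene id, flagged).
#'
#' @param regions data.table chrom, start, end.
#' @param annotation an [annotation_set()].
#' @param max_distance maximum TSS distance in bp for non-overlapping
#'   assignment.
#' @return data.table gene_id (NA when unassigned), distance (0 for
#'   overlaps), tie (logical).
#' @export
assign_gene <- function(regions, annotation, max_distance = 10000L) {
  stopifnot(inherits(annotation, "annotation_set"))
  regions <- as.data.table(regions)
  genes <- annotation$genes
  out <- data.table(gene_id = rep(NA_character_, nrow(regions)),
                    distance = rep(NA_integer_, nrow(regions)),
                    tie = rep(FALSE, nrow(regions)))
  if (!nrow(genes) || !nrow(regions)) return(out)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  for (i in seq_len(nrow(regions))) {
    g <- which(genes$chrom == regions$chrom[i])
    if (!length(g)) next
    ov <- g[genes$start[g] < regions$end[i] & genes$end[g] > regions$start[i]]
    if (length(ov)) {
      ids <- sort(genes$gene_id[ov])
      out$gene_id[i] <- ids[1]
      out$distance[i] <- 0L
      out$tie[i] <- length(ov) > 1L
      next
    }
    d <- pmax(0L, pmax(regions$start[i] - tss[g], tss[g] - (regions$end[i] - 1L)))
    ok <- which(d <= max_distance)
    if (!length(ok)) next
    dmin <- min(d[ok])
    best <- g[ok][d[ok] == dmin]
    ids <- sort(genes$gene_id[best])
    out$gene_id[i] <- ids[1]
    out$distance[i] <- as.integer(dmin)
    out$tie[i] <- length(best) > 1L
  }
  out
}

#' Expand per-category direction counts into region rows
#'
#' Utility for reproducing a published genomic-distribution table from its
#' printed counts: given hyper/hypo counts per primary feature plus a
#' CpG-island overlay row, builds one row per region so that
#' [summarize_dmr_distribution()] recomputes the table (counts and
#' percentages) from scratch.
#'
#' @param counts data.table with columns category, n_hyper, n_hypo; the
#'   four primary categories are mutually exclusive and exhaustive, the
#'   `"CpG islands"` row is an overlay whose regions are a subset of the
#'   primary rows.
#' @return data.table with columns direction, primary, cpg_island.
#' @export
expand_distribution_counts <- function(counts) {
  dt <- as.data.table(counts)
  prim <- dt[category != "CpG islands"]
  rows <- rbindlist(lapply(seq_len(nrow(prim)), function(i) {
    data.table(
      direction = rep(c("hyper", "hypo"),
                      c(prim$n_hyper[i], prim$n_hypo[i])),
      primary = prim$category[i])
  }))
  rows[, cpg_island := FALSE]
  isl <- dt[category == "CpG islands"]
  if (nrow(isl)) {
    for (d in c("hyper", "hypo")) {
      k <- if (d == "hyper") isl$n_hyper[1] else isl$n_hypo[1]
      if (k > 0) {
        idx <- which(rows$direction == d)[seq_len(k)]
        rows[idx, cpg_island := TRUE]
      }
    }
  }
  rows[]
}
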
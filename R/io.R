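# Readers and writers for the plain-text formats the pipeline touches.
# Cytosine reports are 1-based; BED files are 0-based half-open; internal
# tables are 0-based half-open throughout, so conversion happens only here.

.msl_conn <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

.msl_read_lines <- function(path) {
  con <- .msl_conn(path, "r")
  on.exit(close(con))
  readLines(con)
}

.msl_write_lines <- function(lines, path) {
  con <- .msl_conn(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
}

.msl_normalize_context <- function(x, path, lineno) {
  out <- ifelse(x %in% c("CG", "CpG"), "CpG", x)
  bad <- which(!out %in% c("CpG", "CHG", "CHH"))
  if (length(bad)) {
    stop("unknown context '", x[bad[1]], "' in ", path, " at line ",
         lineno[bad[1]])
  }
  out
}

#' Read a Bismark-style cytosine report
#'
#' Expects seven tab-separated columns: chrom, position (1-based), strand,
#' methylated count, unmethylated count, context, trinucleotide. Context
#' `CG` is accepted as an alias for `CpG`. Malformed lines are reported with
#' their line numbers. Gzipped files are read transparently.
#'
#' @param path file path (optionally `.gz`).
#' @return data.table with columns chrom, start (0-based), strand, context,
#'   count_m, count_u.
#' @export
read_cytosine_report <- function(path) {
  lines <- .msl_read_lines(path)
  empty <- data.table(chrom = character(0), start = integer(0),
                      strand = character(0), context = character(0),
                      count_m = integer(0), count_u = integer(0))
  if (!length(lines)) {
    warning("empty cytosine report: ", path)
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)
    stop("malformed cytosine report ", path, ": expected 7 fields, got ",
         nf[bad[1]], " at line ", bad[1],
         if (length(bad) > 1L) paste0(" (and ", length(bad) - 1L, " more)"))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 7L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  cm <- suppressWarnings(as.integer(m[, 4]))
  cu <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos) | is.na(cm) | is.na(cu) | pos < 1L | cm < 0L | cu < 0L)
  if (length(bad)) {
    stop("invalid position or negative/non-numeric count in ", path,
         " at line ", bad[1], ": '", lines[bad[1]], "'")
  }
  bad <- which(!m[, 3] %in% c("+", "-"))
  if (length(bad)) {
    stop("unknown strand '", m[bad[1], 3], "' in ", path, " at line ", bad[1])
  }
  ctx <- .msl_normalize_context(m[, 6], path, seq_len(nrow(m)))
  data.table(chrom = m[, 1], start = pos - 1L, strand = m[, 3],
             context = ctx, count_m = cm, count_u = cu)
}

#' Write a Bismark-style cytosine report
#'
#' Inverse of [read_cytosine_report()]: records are sorted by chromosome,
#' position and strand and written 1-based with a context-typical
#' trinucleotide placeholder. An empty table produces an empty file.
#'
#' @param counts data.table as returned by [read_cytosine_report()].
#' @param path output path (optionally `.gz`).
#' @export
write_cytosine_report <- function(counts, path) {
  if (!nrow(counts)) {
    .msl_write_lines(character(0), path)
    return(invisible(path))
  }
  dt <- as.data.table(counts)[order(chrom, start, strand)]
  tri <- c(CpG = "CGG", CHG = "CAG", CHH = "CTT")[dt$context]
  .msl_write_lines(
    paste(dt$chrom, dt$start + 1L, dt$strand, dt$count_m, dt$count_u,
          dt$context, tri, sep = "\t"),
    path
  )
  invisible(path)
}

#' Read a BED file (BED3/BED6)
#'
#' @param path file path; 0-based half-open intervals.
#' @param n_fields minimum number of fields to require (3 or 6).
#' @return data.table with chrom, start, end and, when present, name,
#'   score, strand (plus any extra columns as character).
#' @export
read_bed <- function(path, n_fields = 3L) {
  lines <- .msl_read_lines(path)
  base <- data.table(chrom = character(0), start = integer(0),
                     end = integer(0))
  if (!length(lines)) return(base)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < n_fields)) {
    bad <- which(nf < n_fields)[1]
    stop("BED line ", bad, " in ", path, " has ", nf[bad],
         " fields, expected >= ", n_fields)
  }
  k <- min(nf)
  m <- t(vapply(fields, function(f) f[seq_len(k)], character(k)))
  if (k == 1L) m <- t(m)
  dt <- data.table(chrom = m[, 1],
                   start = suppressWarnings(as.integer(m[, 2])),
                   end = suppressWarnings(as.integer(m[, 3])))
  bad <- which(is.na(dt$start) | is.na(dt$end) | dt$end <= dt$start |
                 dt$start < 0L)
  if (length(bad)) {
    stop("invalid BED interval (end <= start or non-numeric) in ", path,
         " at line ", bad[1])
  }
  if (k >= 4L) dt[, name := m[, 4]]
  if (k >= 5L) dt[, score := suppressWarnings(as.numeric(m[, 5]))]
  if (k >= 6L) dt[, strand := m[, 6]]
  if (k > 6L) for (j in 7:k) set(dt, j = paste0("extra", j - 6L), value = m[, j])
  dt
}

#' Write intervals as BED
#'
#' @param dt data.table with chrom, start, end and optional name, score,
#'   strand columns (written in BED order).
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(dt))
  dt2 <- as.data.table(dt)[order(chrom, start, end)]
  lines <- do.call(paste, c(unname(as.list(dt2[, cols, with = FALSE])),
                            list(sep = "\t")))
  .msl_write_lines(if (nrow(dt2)) lines else character(0), path)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Blocks define exons; block consistency is validated (first block starts
#' at 0, last block ends at the interval end, blocks within bounds).
#'
#' @param path BED12 file path.
#' @return list with `genes` (gene_id, chrom, start, end, strand) and
#'   `exons` (gene_id, chrom, start, end) data.tables.
#' @export
read_gene_bed12 <- function(path) {
  lines <- .msl_read_lines(path)
  genes <- data.table(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0))
  exons <- data.table(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0))
  if (!length(lines)) return(list(genes = genes, exons = exons))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("BED12 line ", which(nf < 12L)[1], " in ", path, " has fewer than 12 fields")
  }
  g_l <- vector("list", length(fields))
  e_l <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    start <- as.integer(f[2]); end <- as.integer(f[3])
    if (is.na(start) || is.na(end) || end <= start) {
      stop("invalid BED12 interval at line ", i, " in ", path)
    }
    nb <- as.integer(f[10])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    if (length(sizes) != nb || length(starts) != nb) {
      stop("BED12 block count mismatch at line ", i, " in ", path)
    }
    if (starts[1] != 0L || starts[nb] + sizes[nb] != end - start ||
        any(starts + sizes > end - start) || any(diff(starts) <= 0)) {
      stop("inconsistent BED12 blocks at line ", i, " in ", path)
    }
    g_l[[i]] <- data.table(gene_id = f[4], chrom = f[1], start = start,
                           end = end, strand = f[6])
    e_l[[i]] <- data.table(gene_id = f[4], chrom = f[1],
                           start = start + starts, end = start + starts + sizes)
  }
  list(genes = rbindlist(g_l), exons = rbindlist(e_l))
}

#' Write gene models as BED12
#'
#' @param genes data.table gene_id, chrom, start, end, strand.
#' @param exons data.table gene_id, chrom, start, end.
#' @param path output path.
#' @export
write_gene_bed12 <- function(genes, exons, path) {
  ex <- as.data.table(exons)[order(gene_id, start)]
  g <- as.data.table(genes)[order(chrom, start)]
  lines <- vapply(seq_len(nrow(g)), function(i) {
    e <- ex[gene_id == g$gene_id[i]]
    paste(g$chrom[i], g$start[i], g$end[i], g$gene_id[i], 0, g$strand[i],
          g$start[i], g$end[i], "0", nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - g$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  .msl_write_lines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path: set name, description, then member genes,
#'   tab-separated.
#' @return named list of character vectors; descriptions kept as the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- .msl_read_lines(path)
  if (!length(lines)) return(structure(list(), descriptions = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("GMT line ", which(lengths(fields) < 3L)[1], " in ", path,
         " has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  structure(sets, descriptions = setNames(
    vapply(fields, `[`, character(1), 2L), names(sets)))
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  .msl_write_lines(
    vapply(seq_along(sets), function(i) {
      paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1)),
    path
  )
  invisible(path)
}

# fixed DMC table header (positions written 1-based)
.dmc_cols <- c("chrom", "pos", "strand", "m_A", "m_B", "delta_pp",
               "cov_A", "cov_B", "p", "q")

#' Write a DMC table as TSV
#'
#' Fixed header `chrom pos strand m_A m_B delta_pp cov_A cov_B p q`;
#' positions are written 1-based. An empty table yields a header-only file.
#'
#' @param dmcs a [call_dmcs()] table.
#' @param path output path.
#' @export
write_dmc_table <- function(dmcs, path) {
  dt <- as.data.table(dmcs)
  out <- data.table(chrom = dt$chrom, pos = dt$start + 1L, strand = dt$strand,
                    m_A = dt$m_A, m_B = dt$m_B, delta_pp = dt$delta_pp,
                    cov_A = dt$cov_A, cov_B = dt$cov_B, p = dt$p, q = dt$q)
  setorder(out, chrom, pos, strand)
  lines <- c(paste(.dmc_cols, collapse = "\t"),
             if (nrow(out)) do.call(paste, c(unname(as.list(out)),
                                             list(sep = "\t"))))
  .msl_write_lines(lines, path)
  invisible(path)
}

#' Read a DMC table written by [write_dmc_table()]
#'
#' @param path TSV path.
#' @return data.table with internal 0-based `start` coordinates.
#' @export
read_dmc_table <- function(path) {
  lines <- .msl_read_lines(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]], .dmc_cols)) {
    stop("not a DMC table (bad header): ", path)
  }
  if (length(lines) == 1L) {
    return(data.table(chrom = character(0), start = integer(0),
                      strand = character(0), m_A = numeric(0),
                      m_B = numeric(0), delta_pp = numeric(0),
                      cov_A = integer(0), cov_B = integer(0),
                      p = numeric(0), q = numeric(0)))
  }
  m <- matrix(unlist(strsplit(lines[-1], "\t", fixed = TRUE)),
              ncol = 10L, byrow = TRUE)
  data.table(chrom = m[, 1], start = as.integer(m[, 2]) - 1L, strand = m[, 3],
             m_A = as.numeric(m[, 4]), m_B = as.numeric(m[, 5]),
             delta_pp = as.numeric(m[, 6]), cov_A = as.integer(m[, 7]),
             cov_B = as.integer(m[, 8]), p = as.numeric(m[, 9]),
             q = as.numeric(m[, 10]))
}

#' Write called DMRs as BED6+
#'
#' Name column carries the direction; score is `-10*log10(q_region)` capped
#' at 1000 (q = 1 gives 0). Extra columns: n_cpg, mean_delta_pp, n_sig_cpg,
#' p_combined, q_region, feature label (`.` when unannotated).
#'
#' @param dmrs a [call_dmrs()] table.
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dt <- as.data.table(dmrs)
  if (!nrow(dt)) {
    .msl_write_lines(character(0), path)
    return(invisible(path))
  }
  score <- ifelse(dt$q_region <= 0, 1000,
                  pmin(1000, round(-10 * log10(dt$q_region), 2)))
  feat <- if ("primary" %in% names(dt)) dt$primary else rep(".", nrow(dt))
  out <- data.table(dt$chrom, dt$start, dt$end, dt$direction, score, ".",
                    dt$n_cpg, round(dt$mean_delta_pp, 4), dt$n_sig_cpg,
                    signif(dt$p_combined, 6), signif(dt$q_region, 6), feat)
  setorder(out, V1, V2, V3)
  .msl_write_lines(do.call(paste, c(unname(as.list(out)), list(sep = "\t"))),
                   path)
  invisible(path)
}

#' Read a DMR BED written by [write_dmr_bed()]
#'
#' @param path BED6+ path.
#' @return data.table with chrom, start, end, direction, n_cpg,
#'   mean_delta_pp, n_sig_cpg, p_combined, q_region, primary.
#' @export
read_dmr_bed <- function(path) {
  lines <- .msl_read_lines(path)
  if (!length(lines)) {
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      n_cpg = integer(0), mean_delta_pp = numeric(0),
                      n_sig_cpg = integer(0), p_combined = numeric(0),
                      q_region = numeric(0), primary = character(0)))
  }
  m <- matrix(unlist(strsplit(lines, "\t", fixed = TRUE)), ncol = 12L,
              byrow = TRUE)
  data.table(chrom = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), direction = m[, 4],
             n_cpg = as.integer(m[, 7]), mean_delta_pp = as.numeric(m[, 8]),
             n_sig_cpg = as.integer(m[, 9]), p_combined = as.numeric(m[, 10]),
             q_region = as.numeric(m[, 11]), primary = m[, 12])
}

#' Write any data.table as TSV with header
#'
#' @param dt a data.frame/data.table.
#' @param path output path.
#' @export
write_tsv <- function(dt, path) {
  data.table::fwrite(as.data.table(dt), path, sep = "\t", quote = FALSE)
  invisible(path)
}
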
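#' Read a TF-to-cluster map
#'
#' Motif enrichment is computed at the level of motif clusters (groups of
#' transcription factors with similar binding matrices, in the style of
#' RSAT matrix clustering); the map assigns every TF to a cluster and each
#' cluster a display label (conventionally the most common TF family in
#' the cluster).
#'
#' @param path TSV with columns `tf_name`, `cluster_id`, `cluster_label`.
#' @return data frame of class `ClusterMap` with those three columns.
#' @export
read_cluster_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  cluster_map(x$tf_name, x$cluster_id, x$cluster_label)
}

#' @rdname read_cluster_map
#' @param tf_name,cluster_id,cluster_label vectors defining the map.
#' @export
cluster_map <- function(tf_name, cluster_id, cluster_label = cluster_id) {
  if (anyDuplicated(tf_name)) stop("each TF may map to one cluster only")
  m <- data.frame(tf_name = as.character(tf_name),
                  cluster_id = as.character(cluster_id),
                  cluster_label = as.character(cluster_label),
                  stringsAsFactors = FALSE)
  class(m) <- c("ClusterMap", "data.frame")
  m
}

#' Load motif occurrences from a BED-like file
#'
#' Expects tab-separated columns chrom, start, end, tf_name, confidence,
#' strand.  Occurrences with confidence <= 0 are dropped (the confidence
#' filter); TFs absent from the cluster map are rejected and reported via
#' the `rejected_tfs` attribute.
#'
#' @param path file path.
#' @param cmap a [cluster_map()].
#' @return data frame: `chrom`, `start`, `end`, `tf_name`, `confidence`,
#'   `cluster_id`; attributes `n_dropped_confidence` and `rejected_tfs`.
#' @export
load_motif_bed <- function(path, cmap) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 6L)
  if (length(bad) > 0L)
    stop(sprintf("malformed motif record at line %d (need 6 columns)",
                 bad[1]))
  x <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                  start = as.integer(vapply(parts, `[`, character(1), 2)),
                  end = as.integer(vapply(parts, `[`, character(1), 3)),
                  tf_name = vapply(parts, `[`, character(1), 4),
                  confidence = as.numeric(vapply(parts, `[`, character(1), 5)),
                  stringsAsFactors = FALSE)
  if (any(is.na(x$start) | is.na(x$end) | is.na(x$confidence)))
    stop(sprintf("malformed motif record at line %d (non-numeric field)",
                 which(is.na(x$start) | is.na(x$end) | is.na(x$confidence))[1]))
  annotate_clusters(x, cmap)
}

#' Filter and cluster-annotate in-memory motif occurrences
#'
#' The in-memory counterpart of [load_motif_bed()]: drops occurrences with
#' confidence <= 0, rejects TFs absent from the cluster map (reported via
#' the `rejected_tfs` attribute and a warning) and adds the `cluster_id`
#' column.
#'
#' @param occurrences data frame with columns `chrom`, `start`, `end`,
#'   `tf_name`, `confidence`.
#' @param cmap a [cluster_map()].
#' @return the filtered data frame with a `cluster_id` column; attributes
#'   `n_dropped_confidence` and `rejected_tfs`.
#' @export
annotate_clusters <- function(occurrences, cmap) {
  x <- occurrences
  n0 <- nrow(x)
  x <- x[x$confidence > 0, , drop = FALSE]
  n_dropped <- n0 - nrow(x)
  idx <- match(x$tf_name, cmap$tf_name)
  rejected <- sort(unique(x$tf_name[is.na(idx)]))
  if (length(rejected) > 0L)
    warning("TFs absent from the cluster map rejected: ",
            paste(rejected, collapse = ", "), call. = FALSE)
  x <- x[!is.na(idx), , drop = FALSE]
  x$cluster_id <- cmap$cluster_id[idx[!is.na(idx)]]
  rownames(x) <- NULL
  attr(x, "n_dropped_confidence") <- n_dropped
  attr(x, "rejected_tfs") <- rejected
  x
}

#' Unique motif clusters under each peak
#'
#' A cluster is recorded for a peak when at least one occurrence of any
#' member TF overlaps the peak by >= 1 bp.
#'
#' @param peaks a [peak_set()].
#' @param occurrences data frame from [load_motif_bed()] (needs `chrom`,
#'   `start`, `end`, `cluster_id`).
#' @return named list: peak id -> character vector of cluster ids (every
#'   peak present, possibly empty).
#' @export
clusters_per_peak <- function(peaks, occurrences) {
  stop_not_peakset(peaks, "peaks")
  if (nrow(occurrences) > 0L && !"cluster_id" %in% names(occurrences))
    stop("occurrences need a cluster_id column; see annotate_clusters()")
  out <- stats::setNames(rep(list(character(0)), nrow(peaks)), peaks$name)
  if (nrow(occurrences) == 0L) return(out)
  occ_gr <- GenomicRanges::GRanges(
    occurrences$chrom,
    IRanges::IRanges(occurrences$start + 1L, occurrences$end))
  hits <- GenomicRanges::findOverlaps(ps_granges(peaks), occ_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh))
    out[[peaks$name[i]]] <- sort(unique(occurrences$cluster_id[sh[qh == i]]))
  out
}

#' Concordant regulatory regions for motif enrichment
#'
#' Foreground selection: peaks significantly differential
#' (`padj < alpha`) whose accessibility change matches `direction`, and
#' which are linked — as an enhancer via `gene_links` or as a promoter via
#' `prom_gene_map` — to at least one significantly differential gene
#' changing in the same direction.
#'
#' @param da `DifferentialResult` over peaks.
#' @param de `DifferentialResult` over genes (peak_id column holds gene
#'   ids).
#' @param gene_links data frame from [enhancer_gene_links()].
#' @param prom_gene_map named list from [promoter_gene_map()].
#' @param alpha significance cutoff on both results (default 0.05).
#' @param direction `"up"` or `"down"`.
#' @return character vector of foreground peak ids.
#' @export
select_regulatory_regions <- function(da, de, gene_links, prom_gene_map,
                                      alpha = 0.05,
                                      direction = c("up", "down")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "up") 1 else -1
  sig_genes <- de$peak_id[de$padj < alpha & sign(de$log2fc) == sgn]
  sig_peaks <- da$peak_id[da$padj < alpha & sign(da$log2fc) == sgn]
  enh_ok <- gene_links$enhancer_peak_id[gene_links$gene_id %in% sig_genes]
  prom_ok <- names(prom_gene_map)[vapply(prom_gene_map, function(g)
    any(g %in% sig_genes), logical(1))]
  intersect(sig_peaks, union(enh_ok, prom_ok))
}

#' Hypergeometric motif-cluster enrichment
#'
#' For each cluster, tests over-representation of cluster-containing peaks
#' in the foreground against the background universe with an upper-tail
#' hypergeometric test; p-values are BH-adjusted across all tested
#' clusters.
#'
#' @param foreground,background character vectors of peak ids; the
#'   foreground must be a subset of the background.
#' @param cluster_sets named list from [clusters_per_peak()], covering the
#'   background.
#' @param direction label stored with the results (e.g. `"gained"` /
#'   `"lost"`).
#' @return data frame of class `EnrichmentResult`, sorted by p: columns
#'   `cluster_id`, `k`, `n`, `K`, `N`, `p`, `padj`, `direction`.
#' @export
hypergeom_enrichment <- function(foreground, background, cluster_sets,
                                 direction = "gained") {
  if (length(background) < 2L) stop("background needs >= 2 peaks")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background")
  missing_bg <- setdiff(background, names(cluster_sets))
  if (length(missing_bg) > 0L)
    stop("cluster_sets missing background peaks: ",
         paste(utils::head(missing_bg, 5), collapse = ", "))
  N <- length(background)
  n <- length(foreground)
  bg_sets <- cluster_sets[background]
  clusters <- sort(unique(unlist(bg_sets, use.names = FALSE)))
  in_fg <- names(bg_sets) %in% foreground
  rows <- lapply(clusters, function(cl) {
    has <- vapply(bg_sets, function(s) cl %in% s, logical(1))
    K <- sum(has)
    k <- sum(has & in_fg)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cluster_id = cl, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(cluster_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  res$padj <- if (nrow(res) > 0L) bh_adjust(res$p) else numeric(0)
  res$direction <- rep(direction, nrow(res))
  res <- res[order(res$p, res$cluster_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Re-assign significant clusters to member TFs and compare contrasts
#'
#' Expands each significant cluster to its member TFs, labelled by
#' direction; when two contrasts are given, also reports the shared and
#' contrast-specific TF sets (the Venn logic for gained/lost motifs).
#'
#' @param significant an `EnrichmentResult` (or a list of two, named by
#'   contrast) already filtered to significant clusters, or filtered here
#'   with `alpha`.
#' @param cmap a [cluster_map()].
#' @param alpha padj cutoff applied to each result (default 0.05).
#' @return for one result: data frame `tf_name`, `cluster_id`,
#'   `direction`.  For two: list with per-contrast data frames plus
#'   `shared`, and `only_<contrast>` TF vectors computed within each
#'   direction.
#' @export
clusters_to_tfs <- function(significant, cmap, alpha = 0.05) {
  expand1 <- function(res) {
    res <- res[res$padj < alpha, , drop = FALSE]
    if (nrow(res) == 0L)
      return(data.frame(tf_name = character(0), cluster_id = character(0),
                        direction = character(0), stringsAsFactors = FALSE))
    rows <- lapply(seq_len(nrow(res)), function(i) {
      tfs <- cmap$tf_name[cmap$cluster_id == res$cluster_id[i]]
      data.frame(tf_name = tfs, cluster_id = res$cluster_id[i],
                 direction = res$direction[i], stringsAsFactors = FALSE)
    })
    unique(do.call(rbind, rows))
  }
  if (inherits(significant, "data.frame")) return(expand1(significant))
  if (!is.list(significant) || length(significant) != 2L)
    stop("`significant` must be one EnrichmentResult or a list of two")
  ctr <- names(significant)
  if (is.null(ctr)) ctr <- c("contrast1", "contrast2")
  e1 <- expand1(significant[[1]]); e2 <- expand1(significant[[2]])
  per_dir <- function(d) {
    t1 <- e1$tf_name[e1$direction == d]
    t2 <- e2$tf_name[e2$direction == d]
    out <- list(intersect(t1, t2), setdiff(t1, t2), setdiff(t2, t1))
    names(out) <- c("shared", paste0("only_", ctr[1]), paste0("only_", ctr[2]))
    out
  }
  dirs <- union(unique(e1$direction), unique(e2$direction))
  res <- list(per_contrast = stats::setNames(list(e1, e2), ctr))
  for (d in dirs) res[[d]] <- per_dir(d)
  res
}
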
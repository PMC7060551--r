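#' Read BEDPE anchor pairs
#'
#' Parses one replicate's interaction file (first six columns: chromA,
#' startA, endA, chromB, startB, endB; BED coordinates).  Pair order is
#' canonicalized so the lexicographically smaller anchor comes first.
#'
#' @param path BEDPE file path.
#' @param replicate_id identifier stored with the set.
#' @return list of class `AnchorPairSet`: `replicate_id` and `pairs`, a
#'   data frame with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`.
#' @export
read_bedpe <- function(path, replicate_id = basename(path)) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(x) < 6L) stop("BEDPE file needs at least 6 columns")
  anchor_pair_set(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]],
                  replicate_id = replicate_id)
}

#' @rdname read_bedpe
#' @param chromA,startA,endA,chromB,startB,endB anchor coordinates.
#' @export
anchor_pair_set <- function(chromA, startA, endA, chromB, startB, endB,
                            replicate_id = "rep") {
  p <- data.frame(chromA = as.character(chromA), startA = as.integer(startA),
                  endA = as.integer(endA), chromB = as.character(chromB),
                  startB = as.integer(startB), endB = as.integer(endB),
                  stringsAsFactors = FALSE)
  if (any(p$startA < 0 | p$startB < 0 | p$startA >= p$endA |
          p$startB >= p$endB))
    stop("anchors must satisfy 0 <= start < end")
  keyA <- sprintf("%s:%012d-%012d", p$chromA, p$startA, p$endA)
  keyB <- sprintf("%s:%012d-%012d", p$chromB, p$startB, p$endB)
  swap <- keyB < keyA
  if (any(swap)) {
    tmp <- p[swap, 1:3]
    p[swap, 1:3] <- p[swap, 4:6]
    p[swap, 4:6] <- tmp
  }
  structure(list(replicate_id = replicate_id, pairs = p),
            class = "AnchorPairSet")
}

# gap between two half-open intervals (0 when overlapping or adjacent)
interval_gap <- function(s1, e1, s2, e2) pmax(0L, pmax(s2 - e1, s1 - e2))

#' Assign anchors to their nearest peak
#'
#' Each anchor is assigned to the nearest peak by edge gap (0 when
#' overlapping), or to no peak when the gap exceeds `max_dist`.  Ties are
#' broken by the smaller peak start coordinate.
#'
#' @param chrom,start,end anchor coordinates (vectors).
#' @param peaks a [peak_set()].
#' @param max_dist maximum allowed gap in bp (default 2000).
#' @return character vector of peak ids (`NA` where unassigned).
#' @export
assign_anchor <- function(chrom, start, end, peaks, max_dist = 2000) {
  stop_not_peakset(peaks, "peaks")
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (nrow(pk) == 0L) next
    for (i in which(chrom == ch)) {
      gaps <- interval_gap(start[i], end[i], pk$start, pk$end)
      j <- which.min(gaps)            # first minimum = smallest start (sorted)
      if (gaps[j] <= max_dist) out[i] <- pk$name[j]
    }
  }
  out
}

#' Replicate-reproducible peak-peak links from anchor pairs
#'
#' Maps every anchor pair of every replicate to its nearest consensus
#' peaks ([assign_anchor()]), drops pairs with any unassigned anchor and
#' self-links (both anchors on the same peak), deduplicates unordered
#' pairs, and keeps only links present in *all* replicates.
#'
#' @param reps list of `AnchorPairSet`s (length >= 2).
#' @param peaks a [peak_set()].
#' @param max_dist anchor assignment distance (default 2000 bp).
#' @return data frame of class `LinkageSet` with columns `peakA`, `peakB`
#'   (unordered pairs stored with `peakA <= peakB`, each once).
#' @export
pairs_to_peak_links <- function(reps, peaks, max_dist = 2000) {
  if (length(reps) < 2L) stop("need >= 2 replicates")
  rep_links <- lapply(reps, function(r) {
    if (!inherits(r, "AnchorPairSet")) stop("reps must be AnchorPairSets")
    p <- r$pairs
    a <- assign_anchor(p$chromA, p$startA, p$endA, peaks, max_dist)
    b <- assign_anchor(p$chromB, p$startB, p$endB, peaks, max_dist)
    ok <- !is.na(a) & !is.na(b) & a != b
    a <- a[ok]; b <- b[ok]
    unique(paste(pmin(a, b), pmax(a, b), sep = "\r"))
  })
  kept <- Reduce(intersect, rep_links)
  kept <- sort(kept)
  parts <- strsplit(kept, "\r", fixed = TRUE)
  res <- data.frame(
    peakA = vapply(parts, `[`, character(1), 1),
    peakB = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  class(res) <- c("LinkageSet", "data.frame")
  res
}

#' Enhancer-gene links from classified peak-peak links
#'
#' Emits `(gene_id, enhancer_peak_id)` for every link that joins an
#' enhancer-class peak to a promoter-class peak, once per gene behind the
#' promoter peak.  Promoter-promoter and unknown-containing links are kept
#' in the `LinkageSet` but contribute nothing here.
#'
#' @param links a `LinkageSet` from [pairs_to_peak_links()].
#' @param classes data frame from [classify_peaks()].
#' @param prom_gene_map named list from [promoter_gene_map()].
#' @return data frame: `gene_id`, `enhancer_peak_id`.
#' @export
enhancer_gene_links <- function(links, classes, prom_gene_map) {
  cls <- stats::setNames(as.character(classes$cls), classes$peak_id)
  out_gene <- character(0); out_enh <- character(0)
  for (i in seq_len(nrow(links))) {
    a <- links$peakA[i]; b <- links$peakB[i]
    ca <- cls[[a]]; cb <- cls[[b]]
    if (is.null(ca) || is.null(cb)) next
    enh <- prom <- NULL
    if (ca == "enhancer" && cb == "promoter") { enh <- a; prom <- b }
    else if (cb == "enhancer" && ca == "promoter") { enh <- b; prom <- a }
    else next
    genes <- prom_gene_map[[prom]]
    if (length(genes) == 0L) next
    out_gene <- c(out_gene, genes)
    out_enh <- c(out_enh, rep(enh, length(genes)))
  }
  unique(data.frame(gene_id = out_gene, enhancer_peak_id = out_enh,
                    stringsAsFactors = FALSE))
}

#' Shuffle the gene side of enhancer-gene links
#'
#' The null diagnostic for linkage relevance: the gene column is permuted
#' uniformly at random among the links, preserving the enhancer multiset
#' and per-enhancer link counts.  Deterministic given `seed`.
#'
#' @param gene_links data frame from [enhancer_gene_links()].
#' @param seed integer seed.
#' @return data frame of the same shape with `gene_id` permuted.
#' @export
shuffle_links <- function(gene_links, seed) {
  if (nrow(gene_links) < 2L) stop("need >= 2 links to shuffle")
  perm <- with_seed(seed, sample.int(nrow(gene_links)))
  out <- gene_links
  out$gene_id <- gene_links$gene_id[perm]
  out
}

#' Correlation between enhancer and linked-gene fold changes
#'
#' One pair per link: the enhancer's signal log2 fold change against the
#' linked gene's expression log2 fold change; Pearson r with a two-sided
#' test.
#'
#' @param enhancer_fc named numeric vector, peak id -> log2FC.
#' @param gene_fc named numeric vector, gene id -> log2FC.
#' @param gene_links data frame from [enhancer_gene_links()].
#' @return list with elements `r`, `p`, `n` (complete pairs used).
#' @export
link_fc_correlation <- function(enhancer_fc, gene_fc, gene_links) {
  x <- enhancer_fc[gene_links$enhancer_peak_id]
  y <- gene_fc[gene_links$gene_id]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need >= 3 links with both fold changes present")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant fold changes; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
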
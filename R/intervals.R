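#' Construct a peak set
#'
#' A `PeakSet` is the universal coordinate currency of the pipeline: a
#' data frame of genomic intervals in BED convention (0-based, half-open
#' `[start, end)`), with optional per-peak summit positions.  On
#' construction intervals are validated and normalized (sorted by
#' chromosome, start, end).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`, end exclusive.
#' @param name unique peak identifiers; auto-generated (`peak_1`, ...) when
#'   `NULL`.
#' @param score optional numeric score (`NA` allowed).
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param summits optional list of integer vectors: absolute 0-based
#'   positions, each within its interval and strictly increasing.
#' @return a data frame of class `PeakSet` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand` and a list column `summits`.
#' @examples
#' peak_set(c("chr1", "chr1"), c(0L, 500L), c(100L, 900L))
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NA_real_,
                     strand = ".", summits = NULL) {
  n <- length(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (any(start < 0L)) stop("start must be >= 0")
  if (any(start >= end)) stop("start must be < end")
  if (is.null(name)) name <- sprintf("peak_%d", seq_len(n))
  name <- as.character(name)
  if (anyDuplicated(name)) stop("peak names must be unique")
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  score <- rep_len(as.numeric(score), n)
  if (is.null(summits)) {
    summits <- rep(list(NULL), n)
  } else {
    if (length(summits) != n) stop("summits must have one entry per interval")
    summits <- lapply(summits, function(s) if (is.null(s)) NULL else as.integer(s))
    for (i in seq_len(n)) {
      s <- summits[[i]]
      if (is.null(s) || length(s) == 0L) next
      if (any(s < start[i] | s >= end[i]))
        stop("summit outside its interval [start, end)")
      if (is.unsorted(s, strictly = TRUE))
        stop("summits must be strictly increasing")
    }
  }
  ps <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = name, score = score, strand = strand,
                   stringsAsFactors = FALSE)
  ps$summits <- summits
  ord <- order(ps$chrom, ps$start, ps$end)
  ps <- ps[ord, , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("PeakSet", "data.frame")
  ps
}

is_peak_set <- function(x) inherits(x, "PeakSet")

stop_not_peakset <- function(x, arg) {
  if (!is_peak_set(x)) stop(sprintf("`%s` must be a PeakSet", arg))
}

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
ps_granges <- function(ps) {
  # BED half-open [start, end) -> 1-based closed [start + 1, end]
  GenomicRanges::GRanges(ps$chrom, IRanges::IRanges(ps$start + 1L, ps$end))
}

#' Read / write BED-family peak files
#'
#' `read_bed()` parses BED3/BED6; `read_narrowpeak()` parses 10-column
#' narrowPeak (column 10 = summit offset from `start`, `-1` = absent);
#' `write_bed()` and `write_narrowpeak()` are the inverses.  All use BED
#' 0-based half-open coordinates.
#'
#' @param path file path.
#' @return a [peak_set()].
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(x) < 3L) stop("BED file needs at least 3 columns")
  peak_set(chrom = x[[1]], start = x[[2]], end = x[[3]],
           name = if (ncol(x) >= 4L) x[[4]] else NULL,
           score = if (ncol(x) >= 5L) x[[5]] else NA_real_,
           strand = if (ncol(x) >= 6L) x[[6]] else ".")
}

#' @rdname read_bed
#' @export
read_narrowpeak <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(x) != 10L) stop("narrowPeak files have 10 columns")
  summits <- lapply(seq_len(nrow(x)), function(i) {
    off <- x[[10]][i]
    if (off < 0) NULL else as.integer(x[[2]][i] + off)
  })
  peak_set(chrom = x[[1]], start = x[[2]], end = x[[3]], name = x[[4]],
           score = x[[5]], strand = x[[6]], summits = summits)
}

#' @rdname read_bed
#' @param ps a [peak_set()].
#' @export
write_bed <- function(ps, path) {
  stop_not_peakset(ps, "ps")
  out <- data.frame(ps$chrom, ps$start, ps$end, ps$name,
                    ifelse(is.na(ps$score), 0, ps$score), ps$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @export
write_narrowpeak <- function(ps, path) {
  stop_not_peakset(ps, "ps")
  summit_off <- vapply(seq_len(nrow(ps)), function(i) {
    s <- ps$summits[[i]]
    if (is.null(s) || length(s) == 0L) -1L else as.integer(s[1] - ps$start[i])
  }, integer(1))
  out <- data.frame(ps$chrom, ps$start, ps$end, ps$name,
                    ifelse(is.na(ps$score), 0, ps$score), ps$strand,
                    0, -1, -1, summit_off)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tn5 cut sites from aligned reads
#'
#' Converts strand-aware read intervals to single-bp transposase insertion
#' sites: forward-strand reads are shifted +5 bp from their 5' end, reverse
#' strand reads -4 bp (i.e. the cut position is `end - 4`).  The resulting
#' point occupies `[c, c + 1)` and may fall outside the read span for very
#' short reads.
#'
#' @param reads a [peak_set()] whose strands are all `+` or `-`.
#' @return a `PeakSet` of width-1 cut sites (same names, same order after
#'   normalization).
#' @export
shift_tn5 <- function(reads) {
  stop_not_peakset(reads, "reads")
  if (any(reads$strand == "."))
    stop("cut site undefined for unstranded reads")
  pos <- ifelse(reads$strand == "+", reads$start + 5L, reads$end - 4L)
  peak_set(reads$chrom, pos, pos + 1L, name = reads$name,
           score = reads$score, strand = reads$strand)
}

#' Split multi-summit peaks at summit midpoints
#'
#' A peak with k summits is split into k contiguous sub-peaks that exactly
#' tile `[start, end)`.  The boundary between adjacent summits `s_i`,
#' `s_{i+1}` is `floor((s_i + s_{i+1}) / 2)`, taken as the exclusive end of
#' the left sub-peak.  Sub-peaks are renamed `<name>_1 ... <name>_k`; a
#' single-summit peak keeps its span but is renamed `<name>_1` for
#' consistency.
#'
#' @param ps a [peak_set()]; every interval must carry at least one summit.
#' @return a `PeakSet` of sub-peaks, each containing exactly one original
#'   summit.
#' @export
split_at_summits <- function(ps) {
  stop_not_peakset(ps, "ps")
  nsum <- vapply(ps$summits, length, integer(1))
  if (any(nsum == 0L)) stop("every peak must have at least one summit")
  chrom <- character(0); start <- integer(0); end <- integer(0)
  name <- character(0); summ <- list()
  for (i in seq_len(nrow(ps))) {
    s <- ps$summits[[i]]
    k <- length(s)
    cuts <- if (k > 1L) as.integer(floor((s[-k] + s[-1]) / 2)) else integer(0)
    st <- c(ps$start[i], cuts)
    en <- c(cuts, ps$end[i])
    chrom <- c(chrom, rep(ps$chrom[i], k))
    start <- c(start, st)
    end <- c(end, en)
    name <- c(name, sprintf("%s_%d", ps$name[i], seq_len(k)))
    summ <- c(summ, as.list(s))
  }
  peak_set(chrom, start, end, name = name, summits = summ)
}

#' Overlapping interval pairs between two peak sets
#'
#' Reports every pair sharing at least 1 bp on the same chromosome under
#' half-open semantics (`[0,10)` and `[10,20)` do not overlap).
#'
#' @param a,b [peak_set()]s.
#' @return data frame with columns `a_id`, `b_id`, one row per overlapping
#'   pair.
#' @importFrom S4Vectors queryHits subjectHits
#' @export
overlap_pairs <- function(a, b) {
  stop_not_peakset(a, "a"); stop_not_peakset(b, "b")
  hits <- GenomicRanges::findOverlaps(ps_granges(a), ps_granges(b))
  data.frame(a_id = a$name[S4Vectors::queryHits(hits)],
             b_id = b$name[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

# edge-gap distance between a point p and [s, e): 0 when s <= p <= e,
# else the gap to the nearer half-open boundary coordinate.  Symmetric under
# coordinate mirroring x -> M - x applied to s, e and p jointly.
point_gap <- function(p, s, e) pmax(0L, pmax(s - p, p - e))

#' Nearest transcription start site per peak
#'
#' Distance is measured from the peak's half-open boundary coordinates to
#' the TSS point: 0 when the TSS lies within the peak, otherwise the gap to
#' the nearer edge.  Ties are broken in favor of the smaller TSS
#' coordinate.  TSS sets should be restricted to expressed genes upstream
#' of this call.
#'
#' @param peaks a [peak_set()].
#' @param tss a [peak_set()] of width-1 TSS points whose `name` column holds
#'   gene identifiers (non-unique gene names allowed via suffixing at read
#'   time; the `name` is reported as-is).
#' @return data frame with columns `peak_id`, `gene_id`, `distance`.  Peaks
#'   on chromosomes with no TSS get `gene_id = NA` and `distance = Inf`.
#' @export
nearest_tss <- function(peaks, tss) {
  stop_not_peakset(peaks, "peaks"); stop_not_peakset(tss, "tss")
  if (nrow(tss) == 0L) stop("tss set is empty")
  if (any(tss$end - tss$start != 1L)) stop("tss must be width-1 points")
  res_gene <- rep(NA_character_, nrow(peaks))
  res_dist <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    ti <- which(tss$chrom == ch)
    if (length(ti) == 0L) next
    pos <- tss$start[ti]            # already sorted: PeakSet is normalized
    genes <- tss$name[ti]
    pi <- which(peaks$chrom == ch)
    for (i in pi) {
      s <- peaks$start[i]; e <- peaks$end[i]
      lo <- findInterval(s - 0.5, pos) + 1L   # first pos >= s
      if (lo <= length(pos) && pos[lo] <= e) {
        res_gene[i] <- genes[lo]; res_dist[i] <- 0
        next
      }
      dl <- if (lo > 1L) s - pos[lo - 1L] else Inf
      dr <- if (lo <= length(pos)) pos[lo] - e else Inf
      if (dl <= dr) {                          # tie -> smaller coordinate
        res_gene[i] <- genes[lo - 1L]; res_dist[i] <- dl
      } else {
        res_gene[i] <- genes[lo]; res_dist[i] <- dr
      }
    }
  }
  data.frame(peak_id = peaks$name, gene_id = res_gene, distance = res_dist,
             stringsAsFactors = FALSE)
}

#' Classify peaks as promoter, enhancer or unknown
#'
#' A peak is a *promoter* if it overlaps an H3K4me3 peak that itself
#' overlaps a TSS; failing that it is an *enhancer* if it overlaps an
#' H3K27ac peak and its nearest expressed-gene TSS lies more than
#' `radius_bp` away; otherwise *unknown*.  The promoter rule takes
#' precedence when both hold.
#'
#' @param peaks,h3k27ac,h3k4me3 [peak_set()]s.
#' @param tss width-1 TSS points of expressed genes.
#' @param radius_bp promoter-exclusion radius for the enhancer rule
#'   (default 2000 bp).
#' @return data frame with columns `peak_id`, `cls` (factor with levels
#'   `promoter`, `enhancer`, `unknown`), `nearest_tss_gene`, `tss_distance`.
#' @export
classify_peaks <- function(peaks, h3k27ac, h3k4me3, tss, radius_bp = 2000) {
  stop_not_peakset(peaks, "peaks")
  stop_not_peakset(h3k27ac, "h3k27ac")
  stop_not_peakset(h3k4me3, "h3k4me3")
  stop_not_peakset(tss, "tss")
  gr_peaks <- ps_granges(peaks)
  # H3K4me3 peaks that themselves cover a TSS
  k4_with_tss <- GenomicRanges::countOverlaps(ps_granges(h3k4me3),
                                              ps_granges(tss)) > 0
  has_prom_mark <- GenomicRanges::countOverlaps(
    gr_peaks, ps_granges(h3k4me3[k4_with_tss, , drop = FALSE])) > 0
  has_k27 <- GenomicRanges::countOverlaps(gr_peaks, ps_granges(h3k27ac)) > 0
  nt <- nearest_tss(peaks, tss)
  cls <- ifelse(has_prom_mark, "promoter",
                ifelse(has_k27 & nt$distance > radius_bp, "enhancer",
                       "unknown"))
  data.frame(peak_id = peaks$name,
             cls = factor(cls, levels = c("promoter", "enhancer", "unknown")),
             nearest_tss_gene = nt$gene_id,
             tss_distance = nt$distance,
             stringsAsFactors = FALSE)
}

#' Genes behind promoter-class peaks
#'
#' For each peak, collects the genes whose TSSs are covered by the H3K4me3
#' peaks that the peak overlaps — the gene assignment underlying the
#' promoter classification.  Used to resolve promoter anchors of
#' enhancer-promoter links to genes.
#'
#' @inheritParams classify_peaks
#' @return named list: `peak_id` -> character vector of gene ids (only
#'   peaks with at least one gene appear).
#' @export
promoter_gene_map <- function(peaks, h3k4me3, tss) {
  stop_not_peakset(peaks, "peaks")
  stop_not_peakset(h3k4me3, "h3k4me3")
  stop_not_peakset(tss, "tss")
  k4_tss <- GenomicRanges::findOverlaps(ps_granges(h3k4me3), ps_granges(tss))
  pk_k4 <- GenomicRanges::findOverlaps(ps_granges(peaks), ps_granges(h3k4me3))
  k4_genes <- split(tss$name[S4Vectors::subjectHits(k4_tss)],
                    S4Vectors::queryHits(k4_tss))
  out <- list()
  if (length(pk_k4) > 0L) {
    qh <- S4Vectors::queryHits(pk_k4); sh <- S4Vectors::subjectHits(pk_k4)
    for (i in unique(qh)) {
      genes <- unique(unlist(k4_genes[as.character(sh[qh == i])],
                             use.names = FALSE))
      if (length(genes) > 0L) out[[peaks$name[i]]] <- sort(genes)
    }
  }
  out
}
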
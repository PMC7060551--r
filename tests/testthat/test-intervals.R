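test_that("peak_set enforces interval and summit invariants", {
  expect_error(peak_set("chr1", 10, 10), "start must be < end")
  expect_error(peak_set("chr1", -1, 10), "start must be >= 0")
  expect_error(peak_set(c("chr1", "chr1"), c(0, 5), c(10, 20),
                        name = c("a", "a")), "unique")
  expect_error(peak_set("chr1", 0, 100, summits = list(c(150L))),
               "outside")
  expect_error(peak_set("chr1", 0, 100, summits = list(c(50L, 20L))),
               "strictly increasing")
  ps <- peak_set(c("chr2", "chr1"), c(5L, 0L), c(15L, 10L))
  expect_equal(ps$chrom, c("chr1", "chr2"))  # normalized ordering
})

test_that("Tn5 cut sites are +5 on forward and end-4 on reverse strands", {
  reads <- peak_set(c("chr1", "chr1", "chr1"), c(100L, 100L, 0L),
                    c(150L, 150L, 3L), name = c("f", "r", "short"),
                    strand = c("+", "-", "+"))
  cs <- shift_tn5(reads)
  expect_equal(cs$start[cs$name == "f"], 105L)
  expect_equal(cs$start[cs$name == "r"], 146L)
  # the +5 offset applies to the 5' end even past a short read's end
  expect_equal(cs$start[cs$name == "short"], 5L)
  expect_true(all(cs$end - cs$start == 1L))
  expect_error(shift_tn5(peak_set("chr1", 0, 10, strand = ".")),
               "undefined")
})

test_that("summit splitting uses floor-midpoint boundaries and tiles exactly", {
  p <- peak_set("chr1", 0L, 1000L, name = "pk",
                summits = list(c(200L, 700L)))
  sp <- split_at_summits(p)
  expect_equal(sp$start, c(0L, 450L))
  expect_equal(sp$end, c(450L, 1000L))
  expect_equal(sp$name, c("pk_1", "pk_2"))

  p3 <- peak_set("chr1", 10L, 100L, name = "pk",
                 summits = list(c(20L, 40L, 80L)))
  sp3 <- split_at_summits(p3)
  expect_equal(sp3$start, c(10L, 30L, 60L))
  expect_equal(sp3$end, c(30L, 60L, 100L))

  one <- split_at_summits(peak_set("chr1", 0L, 1000L, name = "pk",
                                   summits = list(500L)))
  expect_equal(c(one$start, one$end), c(0L, 1000L))
  expect_error(split_at_summits(peak_set("chr1", 0L, 10L)), "summit")
})

test_that("summit splitting tiles the parent peak for random inputs", {
  set.seed(41)
  for (i in 1:20) {
    w <- sample(100:2000, 1)
    k <- sample(1:5, 1)
    s <- sort(sample.int(w, k)) - 1L
    p <- peak_set("chr1", 0L, w, name = "pk", summits = list(s))
    sp <- split_at_summits(p)
    expect_equal(nrow(sp), k)
    expect_equal(sp$start[1], 0L)
    expect_equal(sp$end[k], w)
    if (k > 1) expect_equal(sp$start[-1], sp$end[-k])  # contiguous
    expect_equal(sum(sp$end - sp$start), w)
    # each sub-peak contains exactly its own summit
    for (j in seq_len(k))
      expect_true(sp$start[j] <= s[j] && s[j] < sp$end[j])
  }
})

test_that("overlap_pairs matches brute force and half-open boundaries", {
  a <- peak_set("chr1", 0L, 10L, name = "a1")
  expect_equal(nrow(overlap_pairs(a, peak_set("chr1", 5L, 15L, name = "b1"))), 1)
  expect_equal(nrow(overlap_pairs(a, peak_set("chr1", 10L, 20L, name = "b1"))), 0)
  set.seed(42)
  for (i in 1:5) {
    x <- random_peaks(40, prefix = "x")
    y <- random_peaks(40, prefix = "y")
    got <- overlap_pairs(x, y)
    want <- brute_overlap(x, y)
    key <- function(d) sort(paste(d$a_id, d$b_id))
    expect_equal(key(got), key(want))
  }
})

test_that("nearest_tss measures edge gaps with smaller-coordinate ties", {
  tss <- peak_set(c("chr1", "chr1"), c(5000L, 6100L), c(5001L, 6101L),
                  name = c("gA", "gB"))
  pk <- peak_set("chr1", 6000L, 6500L, name = "p1")
  # TSS inside the peak wins with distance 0
  expect_equal(nearest_tss(pk, tss)$distance, 0)
  expect_equal(nearest_tss(pk, tss)$gene_id, "gB")
  # gap arithmetic
  far <- peak_set("chr1", 6000L, 6500L, name = "p1")
  only_left <- peak_set("chr1", 5000L, 5001L, name = "gA")
  expect_equal(nearest_tss(far, only_left)$distance, 1000)
  # 1-bp tie on both sides resolves to the smaller coordinate
  tie <- peak_set(c("chr1", "chr1"), c(5999L, 6501L), c(6000L, 6502L),
                  name = c("gL", "gR"))
  nt <- nearest_tss(pk, tie)
  expect_equal(nt$distance, 1)
  expect_equal(nt$gene_id, "gL")
  # no TSS on the chromosome
  other <- nearest_tss(peak_set("chr9", 0L, 10L, name = "px"), tss)
  expect_equal(other$distance, Inf)
  expect_true(is.na(other$gene_id))
})

test_that("nearest_tss distance is invariant under coordinate mirroring", {
  set.seed(43)
  M <- 200000L
  pk <- random_peaks(30, prefix = "p")
  pos <- sample.int(M - 1L, 15)
  tss <- peak_set(rep("chrT", 15), pos, pos + 1L,
                  name = sprintf("g%02d", seq_len(15)))
  d1 <- nearest_tss(pk, tss)
  # mirror x -> M - x applied to interval boundaries and point coordinates
  pk_m <- peak_set(pk$chrom, M - pk$end, M - pk$start, name = pk$name)
  tss_m <- peak_set(tss$chrom, M - tss$start, M - tss$start + 1L,
                    name = tss$name)
  d2 <- nearest_tss(pk_m, tss_m)
  expect_equal(d1$distance[order(d1$peak_id)], d2$distance[order(d2$peak_id)])
})

test_that("peak classification follows the promoter/enhancer rules", {
  tss <- peak_set("chr1", 1000L, 1001L, name = "gene1")
  k4 <- peak_set("chr1", 900L, 1100L, name = "k4_1")
  k27 <- peak_set("chr1", 5000L, 5600L, name = "k27_1")
  peaks <- peak_set(c("chr1", "chr1", "chr1"),
                    c(950L, 5100L, 20000L), c(1050L, 5500L, 20500L),
                    name = c("pkP", "pkE", "pkU"))
  cl <- classify_peaks(peaks, k27, k4, tss)
  got <- setNames(as.character(cl$cls), cl$peak_id)
  expect_equal(got[["pkP"]], "promoter")
  expect_equal(got[["pkE"]], "enhancer")   # K27ac overlap, TSS ~4 kb away
  expect_equal(got[["pkU"]], "unknown")
  # every peak gets exactly one class
  expect_false(any(is.na(cl$cls)))

  # enhancer rule fails within the exclusion radius
  near <- peak_set("chr1", 2400L, 2900L, name = "pkN")
  k27b <- peak_set("chr1", 2300L, 3000L, name = "k27_b")
  cln <- classify_peaks(near, k27b, k4, tss)   # TSS at 1000, gap 1400 < 2000
  expect_equal(as.character(cln$cls), "unknown")

  # promoter precedence when both rules hold
  both <- peak_set("chr1", 950L, 1050L, name = "pkB")
  k27c <- peak_set("chr1", 900L, 1100L, name = "k27_c")
  expect_equal(as.character(classify_peaks(both, k27c, k4, tss)$cls),
               "promoter")
})

test_that("BED and narrowPeak round-trip preserves coordinates and summits", {
  ps <- peak_set(c("chr1", "chr2"), c(0L, 500L), c(100L, 900L),
                 name = c("a", "b"), score = c(5, 7), strand = c("+", "-"),
                 summits = list(50L, 700L))
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".narrowPeak")
  write_bed(ps, f1); write_narrowpeak(ps, f2)
  r1 <- read_bed(f1); r2 <- read_narrowpeak(f2)
  expect_equal(r1$start, ps$start)
  expect_equal(r1$end, ps$end)
  expect_equal(r2$summits, ps$summits)
  expect_equal(r2$name, ps$name)
})
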
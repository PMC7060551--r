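toy_cmap <- function() {
  cluster_map(c("TFA", "TFB", "TFC"), c("c1", "c1", "c2"),
              c("famAB", "famAB", "famC"))
}

test_that("motif loading filters zero confidence and unmapped TFs", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tTFA\t0.5\t+",
               "chr1\t30\t40\tTFB\t0\t+",          # confidence 0 -> dropped
               "chr1\t50\t60\tTFX\t0.9\t+",        # unmapped -> rejected
               "chr1\t70\t80\tTFC\t0.3\t-"), f)
  expect_warning(occ <- load_motif_bed(f, toy_cmap()), "TFX")
  expect_equal(nrow(occ), 2)
  expect_equal(occ$cluster_id, c("c1", "c2"))
  expect_equal(attr(occ, "n_dropped_confidence"), 1)
  expect_equal(attr(occ, "rejected_tfs"), "TFX")
  # malformed line reported with its number
  writeLines(c("chr1\t10\t20\tTFA\t0.5\t+", "chr1\t10"), f)
  expect_error(load_motif_bed(f, toy_cmap()), "line 2")
})

test_that("clusters per peak are deduplicated and match brute force", {
  pk <- peak_set(c("chr1", "chr1"), c(0L, 1000L), c(100L, 1100L),
                 name = c("pk1", "pk2"))
  occ <- data.frame(chrom = rep("chr1", 3), start = c(10L, 50L, 5000L),
                    end = c(20L, 60L, 5010L),
                    tf_name = c("TFA", "TFB", "TFC"),
                    confidence = c(0.5, 0.5, 0.5),
                    cluster_id = c("c1", "c1", "c2"),
                    stringsAsFactors = FALSE)
  cps <- clusters_per_peak(pk, occ)
  expect_equal(cps$pk1, "c1")           # two members of c1 -> one entry
  expect_equal(cps$pk2, character(0))   # occurrence outside all peaks
  set.seed(51)
  pk2 <- random_peaks(30)
  pos <- sample.int(100000L, 200, replace = TRUE)
  occ2 <- data.frame(chrom = "chrT", start = pos, end = pos + 15L,
                     tf_name = "t", confidence = 1,
                     cluster_id = sample(c("c1", "c2", "c3"), 200, TRUE),
                     stringsAsFactors = FALSE)
  cps2 <- clusters_per_peak(pk2, occ2)
  for (i in seq_len(nrow(pk2))) {
    ov <- occ2$start < pk2$end[i] & pk2$start[i] < occ2$end &
      occ2$chrom == pk2$chrom[i]
    expect_equal(cps2[[pk2$name[i]]], sort(unique(occ2$cluster_id[ov])))
  }
})

test_that("regulatory-region selection demands concordant linked genes", {
  da <- data.frame(peak_id = c("pk1", "pk2", "pk3", "pk4"),
                   log2fc = c(2, 2, 2, 2), padj = c(0.01, 0.01, 0.2, 0.01))
  de <- data.frame(peak_id = c("gUp", "gDown"),
                   log2fc = c(1.5, -1.5), padj = c(0.02, 0.02))
  gl <- data.frame(gene_id = c("gUp", "gDown", "gUp"),
                   enhancer_peak_id = c("pk1", "pk2", "pk3"),
                   stringsAsFactors = FALSE)
  fg <- select_regulatory_regions(da, de, gl, list(), direction = "up")
  expect_equal(fg, "pk1")   # pk2 linked only to a discordant gene,
                            # pk3 not significant, pk4 unlinked
  # promoter-side linkage counts too
  fg2 <- select_regulatory_regions(da, de, gl[0, ], list(pk4 = "gUp"),
                                   direction = "up")
  expect_equal(fg2, "pk4")
})

test_that("hypergeometric p-values match closed forms and edge cases", {
  cs <- list(a = "c1", b = "c1", c = "c1", d = "c1", e = "c1",
             f = character(0), g = character(0), h = character(0),
             i = character(0), j = character(0))
  # N=10, K=5, n=4, k=4: p = C(5,4)/C(10,4) = 5/210
  en <- hypergeom_enrichment(c("a", "b", "c", "d"), letters[1:10], cs)
  expect_equal(en$p[en$cluster_id == "c1"], 5 / 210, tolerance = 1e-12)
  # foreground = background -> p = 1 for every cluster
  all_fg <- hypergeom_enrichment(letters[1:10], letters[1:10], cs)
  expect_true(all(all_fg$p == 1))
  # k = 0 -> p = 1
  zero <- hypergeom_enrichment(c("f", "g"), letters[1:10], cs)
  expect_equal(zero$p[zero$cluster_id == "c1"], 1)
  expect_error(hypergeom_enrichment(c("zz"), letters[1:10], cs), "subset")
})

test_that("enrichment is invariant to peak relabeling and input order", {
  set.seed(52)
  ids <- sprintf("pk%02d", 1:30)
  cs <- setNames(lapply(1:30, function(i)
    sort(sample(c("c1", "c2", "c3"), sample(0:2, 1)))), ids)
  fg <- sample(ids, 8)
  e1 <- hypergeom_enrichment(fg, ids, cs)
  e2 <- hypergeom_enrichment(rev(fg), sample(ids), cs)
  expect_equal(e1, e2)
  relab <- setNames(cs, sprintf("X%02d", 1:30))
  fg_r <- sprintf("X%02d", match(fg, ids))
  e3 <- hypergeom_enrichment(fg_r, names(relab), relab)
  expect_equal(e1[, c("cluster_id", "k", "K", "p")],
               e3[, c("cluster_id", "k", "K", "p")])
})

test_that("significant clusters expand to member TFs with Venn logic", {
  cmap <- toy_cmap()
  res1 <- structure(data.frame(cluster_id = c("c1", "c2"),
                               padj = c(0.01, 0.5),
                               direction = "gained"),
                    class = c("EnrichmentResult", "data.frame"))
  one <- clusters_to_tfs(res1, cmap)
  expect_setequal(one$tf_name, c("TFA", "TFB"))  # only c1 significant
  res2 <- structure(data.frame(cluster_id = c("c1", "c2"),
                               padj = c(0.01, 0.01),
                               direction = "gained"),
                    class = c("EnrichmentResult", "data.frame"))
  venn <- clusters_to_tfs(list(lung = res1, brain = res2), cmap)
  expect_setequal(venn$gained$shared, c("TFA", "TFB"))
  expect_equal(venn$gained$only_brain, "TFC")
  expect_equal(venn$gained$only_lung, character(0))
  # no significant clusters -> empty
  none <- structure(data.frame(cluster_id = "c1", padj = 0.9,
                               direction = "lost"),
                    class = c("EnrichmentResult", "data.frame"))
  expect_equal(nrow(clusters_to_tfs(none, cmap)), 0)
})
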
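test_that("lifting gene annotations to families takes the union over members", {
  genes <- AnnotationMap(data.frame(el = c("g1"), tm = c("GO:1")),
                         background = c("g1", "g2"))
  mem <- data.frame(gene_id = c("g1", "g2"), family_id = c("F", "F"))
  fam <- liftGoToFamilies(genes, mem)
  expect_identical(as.character(fam@map[["F"]]), "GO:1")

  none <- AnnotationMap(data.frame(el = character(), tm = character()),
                        background = c("g1", "g2"))
  expect_length(liftGoToFamilies(none, mem)@map, 0L)

  orphan <- AnnotationMap(data.frame(el = "gX", tm = "GO:9"))
  expect_warning(liftGoToFamilies(orphan, mem), "missing from membership")
})

test_that("lifting matches a brute-force set-union oracle", {
  set.seed(13)
  mem <- data.frame(gene_id = sprintf("g%03d", 1:500),
                    family_id = sample(sprintf("F%02d", 1:50), 500, TRUE))
  pairs <- data.frame(el = sample(mem$gene_id, 800, TRUE),
                      tm = sample(sprintf("GO:%04d", 1:30), 800, TRUE))
  genes <- AnnotationMap(pairs, background = mem$gene_id)
  fam <- liftGoToFamilies(genes, mem)
  g2f <- setNames(mem$family_id, mem$gene_id)
  for (f in names(fam@map)) {
    members <- mem$gene_id[mem$family_id == f]
    oracle <- sort(unique(unlist(lapply(members, function(g) {
      if (g %in% names(genes@map)) as.character(genes@map[[g]]) else character()
    }))))
    expect_identical(sort(as.character(fam@map[[f]])), oracle)
  }
})

test_that("term filtering keeps terms at the threshold and matches counting", {
  pairs <- data.frame(el = c(sprintf("F%02d", 1:49), sprintf("F%02d", 1:50)),
                      tm = c(rep("rare", 49), rep("common", 50)))
  ann <- AnnotationMap(pairs)
  kept <- filterTerms(ann, 50L)
  expect_identical(termUniverse(kept), "common")
  expect_identical(termUniverse(filterTerms(ann, 1L)), termUniverse(ann))

  set.seed(14)
  rnd <- AnnotationMap(data.frame(el = sample(sprintf("e%03d", 1:200), 2000, TRUE),
                                  tm = sample(sprintf("T%02d", 1:40), 2000, TRUE)))
  got <- termUniverse(filterTerms(rnd, 8L))
  counts <- table(unlist(rnd@map, use.names = FALSE))
  expect_setequal(got, names(counts)[counts >= 8])
})

test_that("lifting must precede family-level term filtering", {
  # one term on 60 genes spread over 40 families: survives a gene-level >= 50
  # filter but must be dropped by the family-level >= 50 filter after lifting
  mem <- data.frame(gene_id = sprintf("g%03d", 1:80),
                    family_id = rep(sprintf("F%02d", 1:40), 2))
  pairs <- data.frame(el = sprintf("g%03d", 1:60), tm = "GO:X")
  genes <- AnnotationMap(pairs, background = mem$gene_id)
  expect_identical(termUniverse(filterTerms(genes, 50L)), "GO:X")
  lifted <- liftGoToFamilies(genes, mem)
  expect_length(termUniverse(filterTerms(lifted, 50L)), 0L)
})

test_that("resampling enrichment flags degenerate terms and is reproducible", {
  bg <- sprintf("F%03d", 1:100)
  pairs <- data.frame(el = bg, tm = "everywhere")
  ann <- AnnotationMap(pairs, background = bg)
  res <- samplingEnrichment(bg[1:20], ann, nSamples = 50, seed = 1)
  tab <- enrichmentTable(res)
  expect_true(tab$degenerate[tab$term == "everywhere"])
  expect_equal(tab$p[tab$term == "everywhere"], 1)
  expect_equal(tab$observed_proportion, tab$null_mean)

  # focal = background: every draw is the background itself
  resAll <- samplingEnrichment(bg, ann, nSamples = 20, seed = 2)
  expect_true(all(enrichmentTable(resAll)$degenerate))

  set.seed(15)
  pairs2 <- data.frame(el = sample(bg, 300, TRUE),
                       tm = sample(sprintf("T%02d", 1:10), 300, TRUE))
  ann2 <- AnnotationMap(pairs2, background = bg)
  r1 <- samplingEnrichment(bg[1:30], ann2, nSamples = 200, seed = 7)
  r2 <- samplingEnrichment(bg[1:30], ann2, nSamples = 200, seed = 7)
  expect_identical(enrichmentTable(r1), enrichmentTable(r2))
  expect_error(samplingEnrichment(c(bg[1], "zzz"), ann2), "outside")
})

test_that("a strongly planted term attains the smallest q-value", {
  set.seed(16)
  bg <- sprintf("F%03d", 1:400)
  focal <- bg[1:40]
  rows <- list(data.frame(el = c(sample(focal, 32), sample(setdiff(bg, focal), 36)),
                          tm = "planted"))
  for (t in sprintf("T%02d", 1:50))
    rows[[t]] <- data.frame(el = sample(bg, 60), tm = t)
  ann <- AnnotationMap(do.call(rbind, rows), background = bg)
  res <- samplingEnrichment(focal, ann, nSamples = 1000, seed = 99)
  tab <- enrichmentTable(res)
  expect_identical(tab$term[1L], "planted")   # table is sorted by q then p
  expect_lt(tab$q[1L], 0.05)
  expect_identical(tab$direction[tab$term == "planted"], "over")
})

test_that("chi-square overlap reproduces exact and hand-formula results", {
  # proportional table: statistic 0, p 1, fold 0
  bg <- sprintf("g%03d", 1:90)
  lst <- bg[1:30]              # 30 in list
  foc <- bg[c(1:10, 31:50)]    # 10 of them focal, 20 focal outside
  res <- chiSquareOverlap(lst, NULL, foc, bg)
  expect_equal(unname(res$table[1, 1]), 10)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$log2_fold, 0)

  # perfect association
  bg2 <- sprintf("h%03d", 1:40)
  half <- bg2[1:20]
  res2 <- chiSquareOverlap(half, NULL, half, bg2)
  expect_identical(res2$direction, "over")
  expect_equal(res2$statistic, 40)  # n * phi^2 with phi = 1
  expect_lt(res2$p, 1e-9)

  # fixed table [[30,70],[20,180]] against the hand formula
  bg3 <- sprintf("k%03d", 1:300)
  lst3 <- bg3[1:100]
  foc3 <- bg3[c(1:30, 101:120)]
  res3 <- chiSquareOverlap(lst3, NULL, foc3, bg3)
  O <- matrix(c(30, 20, 70, 180), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res3$statistic, sum((O - E)^2 / E), tolerance = 1e-12)
  expect_identical(res3$direction, "over")
  expect_equal(res3$log2_fold, log2(30 / E[1, 1]))

  # statistic is invariant to swapping the roles of the two sets
  res4 <- chiSquareOverlap(foc3, NULL, intersect(lst3, bg3), bg3)
  expect_equal(res4$statistic, res3$statistic, tolerance = 1e-12)
})

test_that("list backgrounds are harmonized by intersection", {
  bg <- sprintf("g%03d", 1:100)
  listBg <- bg[1:60]
  lst <- bg[1:20]
  foc <- bg[seq(2, 100, by = 2)]
  res <- chiSquareOverlap(lst, listBg, foc, bg)
  expect_equal(res$n_background, 60)
  expect_equal(sum(res$table), 60)
  # small expected cells flagged but still reported
  tiny <- chiSquareOverlap(bg[1:2], NULL, bg[1:3], bg[1:20])
  expect_true(tiny$unreliable)
  expect_true(is.finite(tiny$statistic))
})
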
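test_that("GRAVY follows the Kyte-Doolittle scale", {
  expect_equal(gravy("AAA"), 1.8)
  expect_equal(gravy("AG"), 0.7)  # (1.8 - 0.4) / 2
  expect_equal(gravy("aag"), gravy("AAG"))  # case-insensitive
  expect_warning(g <- gravy("AXA"), "skipped")
  expect_equal(g, 1.8)
  expect_error(gravy(""), "empty")
  expect_error(suppressWarnings(gravy("XXX")), "no standard residue")
})

test_that("protein mass sums residue masses plus one water", {
  expect_equal(proteinMw("G"), 75.07, tolerance = 1e-4)
  expect_equal(proteinMw("GG"), 132.12, tolerance = 1e-4)
  expect_lt(proteinMw("G", type = "monoisotopic"), proteinMw("G"))
  expect_error(proteinMw("AB-junk"), "B")
  expect_warning(mw <- proteinMw("ABG", skipUnknown = TRUE), "skipped")
  expect_equal(mw, proteinMw("AG"))
})

test_that("composition statistics are permutation invariant", {
  set.seed(71)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:5) {
    s <- paste(sample(aa, 40, replace = TRUE), collapse = "")
    shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(gravy(s), gravy(shuffled))
    expect_equal(proteinMw(s), proteinMw(shuffled))
  }
})

test_that("sequenceFeatures computes per-protein biophysics", {
  f <- sequenceFeatures(c(P1 = "AAAA", P2 = "FWYG"))
  expect_equal(f$gravy[f$protein == "P1"], 1.8)
  expect_equal(f$aromaticity[f$protein == "P2"], 0.75)
  expect_equal(f$aliphatic_index[f$protein == "P1"], 100)
  expect_equal(f$length, c(4L, 4L))
})

test_that("keyword enrichment matches hypergeometric enumeration", {
  bg <- sprintf("P%02d", 1:10)
  ann <- data.frame(protein = bg[1:5], keyword = "kw")
  fg <- bg[1:4]  # all four annotated
  r <- keywordEnrichment(fg, bg, ann, alternative = "greater")
  # one-sided hypergeometric: C(5,4) C(5,0) / C(10,4) = 5/210
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  expect_equal(r$fg_count, 4L)
  expect_equal(r$bg_count, 5L)
  expect_equal(r$q, r$p)  # single keyword: BH is the identity
  expect_error(keywordEnrichment(c("ZZ"), bg, ann), "subset")
})

test_that("Fisher p equals brute-force enumeration for small tables", {
  set.seed(73)
  for (i in 1:30) {
    N <- sample(6:12, 1)
    nFg <- sample(2:(N - 2), 1)
    nKw <- sample(1:(N - 1), 1)
    bg <- sprintf("P%02d", 1:N)
    withKw <- sample(bg, nKw)
    fg <- sample(bg, nFg)
    a <- sum(fg %in% withKw)
    if (a == 0) next
    ann <- data.frame(protein = withKw, keyword = "kw")
    r <- keywordEnrichment(fg, bg, ann)
    expect_equal(r$p,
                 enumFisherP(a, nFg - a, nKw - a, N - nFg - (nKw - a)),
                 tolerance = 1e-9,
                 label = sprintf("table N=%d fg=%d kw=%d a=%d", N, nFg,
                                 nKw, a))
  }
})

test_that("null-frequency foregrounds give odds ratios near one", {
  set.seed(79)
  bg <- sprintf("P%03d", 1:200)
  withKw <- bg[seq(1, 200, by = 2)]  # every other protein
  ann <- data.frame(protein = withKw, keyword = "kw")
  fg <- bg[sort(c(seq(1, 200, by = 8), seq(2, 200, by = 8)))]  # 50% kw
  r <- keywordEnrichment(fg, bg, ann)
  expect_gt(r$p, 0.05)
  expect_lt(abs(log(r$odds_ratio)), 0.5)
})

test_that("BH q-values are monotone in rank and bounded below by p", {
  set.seed(83)
  bg <- sprintf("P%03d", 1:60)
  ann <- do.call(rbind, lapply(1:8, function(k)
    data.frame(protein = sample(bg, sample(10:40, 1)),
               keyword = paste0("kw", k))))
  fg <- sample(bg, 15)
  r <- keywordEnrichment(fg, bg, ann)
  expect_true(all(r$q >= r$p - 1e-12))
  expect_true(all(diff(r$q) >= -1e-12))  # sorted by p: q nondecreasing
  expect_true(all(r$q <= 1))
})

test_that("property comparisons between stability classes", {
  vals <- setNames(c(10, 11, 12, 30, 31, 32, 20, 21, 22),
                   sprintf("P%d", 1:9))
  r <- compareSetsProperty(sprintf("P%d", 4:6), sprintf("P%d", 1:3),
                           sprintf("P%d", 7:9), vals)
  de <- r[r$comparison == "destabilized_vs_null", ]
  expect_lt(de$median_diff, 0)
  expect_lt(de$p, 0.2)  # exact two-sided floor at n=3 vs 3
  st <- r[r$comparison == "stabilized_vs_destabilized", ]
  expect_equal(st$median_diff, 20)
  same <- compareSetsProperty(c("P1", "P2"), c("P1", "P2"),
                              c("P7"), vals)
  expect_equal(same$median_diff[1], 0)
  w <- capture_warnings(
    compareSetsProperty(character(0), c("P1"), c("P7"), vals))
  expect_true(all(grepl("empty set", w)))
  expect_length(w, 2)  # both comparisons involving the empty set skipped
})
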
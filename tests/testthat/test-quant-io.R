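writeToyTable <- function(path, ids = c("P2", "P1"), reverse = NULL,
                          contaminant = NULL) {
  n <- length(ids)
  d <- data.frame(`Protein IDs` = ids, check.names = FALSE)
  for (i in 1:10)
    d[[sprintf("Reporter intensity corrected %d", i)]] <-
      round(seq(1e6, 1e5, length.out = 10)[i] * seq_len(n), 1)
  d[["LFQ intensity"]] <- 1e7 * seq_len(n)
  if (!is.null(reverse)) d[["Reverse"]] <- reverse
  if (!is.null(contaminant)) d[["Potential contaminant"]] <- contaminant
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toyMap <- setNames(defaultTemperatures,
                   sprintf("Reporter intensity corrected %d", 1:10))

test_that("quantification tables map channels to the thermal gradient", {
  f <- writeToyTable(tempfile(fileext = ".tsv"))
  pq <- readQuantTable(f, toyMap, "control",
                       abundanceColumn = "LFQ intensity")
  expect_s4_class(pq, "ProteomeQuant")
  expect_equal(temperatures(pq), c(30, 34, 38, 43, 47, 52, 56, 60, 66, 70))
  expect_equal(rownames(pq), c("P1", "P2"))  # sorted, not file order
  expect_equal(condition(pq), "control")
  expect_equal(unname(abundance(pq)), c(2e7, 1e7))
  expect_equal(attr(pq, "dropped"), 0L)
})

test_that("unmapped reporter columns are ignored with a warning", {
  f <- writeToyTable(tempfile(fileext = ".tsv"))
  partial <- toyMap[1:9]
  expect_warning(pq <- readQuantTable(f, partial, "control"), "ignored")
  expect_equal(ncol(pq), 9L)
})

test_that("reverse/contaminant rows are dropped and counted", {
  f <- writeToyTable(tempfile(fileext = ".tsv"), ids = c("P1", "P2", "P3"),
                     reverse = c("", "+", ""),
                     contaminant = c("", "", "+"))
  pq <- readQuantTable(f, toyMap, "control")
  expect_equal(rownames(pq), "P1")
  expect_equal(attr(pq, "dropped"), 2L)
})

test_that("format errors name the offending column or accession", {
  f <- writeToyTable(tempfile(fileext = ".tsv"))
  badMap <- c(toyMap, `Reporter intensity corrected 99` = 75)
  expect_error(readQuantTable(f, badMap, "x"),
               "Reporter intensity corrected 99")
  fdup <- writeToyTable(tempfile(fileext = ".tsv"), ids = c("P1", "P1"))
  expect_error(readQuantTable(fdup, toyMap, "x"), "duplicate.*P1")
})

test_that("channel maps load from YAML and TSV", {
  fy <- tempfile(fileext = ".yaml")
  writeLines(c("ch1: 30", "ch2: 40", "ch3: 50"), fy)
  expect_equal(readChannelMap(fy), c(ch1 = 30, ch2 = 40, ch3 = 50))
  ft <- tempfile(fileext = ".tsv")
  write.table(data.frame(channel = c("a", "b"), temperature = c(30, 40)),
              ft, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(readChannelMap(ft), c(a = 30, b = 40))
  fdup <- tempfile(fileext = ".yaml")
  writeLines(c("ch1: 30", "ch2: 30"), fdup)
  expect_error(readChannelMap(fdup), "distinct")
})

test_that("crowder property tables validate on read", {
  d <- data.frame(
    reagent = c("ficoll70", "ficoll400", "dextran40", "dextran86",
                "peg1", "peg8"),
    molecular_weight = c(70, 400, 40, 86, 1, 8),
    intrinsic_viscosity = c(13, 20, 18, 24, 5, 12),
    polar_atom_fraction = c(0.55, 0.55, 0.6, 0.6, 0.33, 0.33),
    hydrophobicity_index = c(0.2, 0.2, 0.15, 0.15, 0.5, 0.5),
    topology = c("branched", "branched", "linear", "linear",
                 "linear", "linear"),
    mass_concentration = rep(150, 6))
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- readCrowderProperties(f)
  expect_s4_class(tab, "CrowderPropertyTable")
  expect_equal(nrow(tab), 6L)
  expect_true("mass_concentration" %in% colnames(tab))  # extras preserved
  d2 <- d; d2$polar_atom_fraction[1] <- 1.3
  f2 <- tempfile(fileext = ".tsv")
  write.table(d2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCrowderProperties(f2), "polar_atom_fraction")
  f3 <- tempfile(fileext = ".tsv")
  file.create(f3)
  expect_error(readCrowderProperties(f3), "empty")
})

test_that("result round trips preserve values and restrict call classes", {
  sim <- smallSim(n = 3, seed = 3)
  fits <- fitProteome(sim$quants$control)
  calls <- data.frame(protein = c("A", "B"), crowder = "ficoll70",
                      delta_tm = c(2.5, -3.1), z = c(2.2, -2.6),
                      call = c("stabilized", "destabilized"),
                      qc_reason = NA_character_)
  dir <- tempfile()
  writeResults(fits, calls, dir)
  fits2 <- read.delim(file.path(dir, "fits.tsv"))
  expect_equal(sort(fits2$tm), sort(fits$tm), tolerance = 1e-6)
  calls2 <- read.delim(file.path(dir, "calls.tsv"))
  expect_true(all(calls2$call %in% c("stabilized", "destabilized", "null")))
  # invalid class rejected
  bad <- calls; bad$call[1] <- "wobbly"
  expect_error(writeResults(fits, bad, tempfile()), "classes")
  # empty collections give headers-only files
  dir2 <- tempfile()
  writeResults(fits[0, ], calls[0, ], dir2)
  expect_equal(nrow(read.delim(file.path(dir2, "calls.tsv"))), 0L)
  expect_equal(nrow(read.delim(file.path(dir2, "fits.tsv"))), 0L)
})
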
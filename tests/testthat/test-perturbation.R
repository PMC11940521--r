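make_reps <- function(ids, doses, units, up, down) {
  df <- data.frame(perturbagen_id = ids, dose_value = doses,
                   dose_unit = units, stringsAsFactors = FALSE)
  df$up_genes <- up
  df$down_genes <- down
  df
}

test_that("dose filtering keeps the target dose across unit spellings", {
  lm <- default_landmarks()
  reps <- make_reps(c("a", "a", "a", "b"),
                    c(10, 1, 10000, 10), c("uM", "uM", "nM", "µM"),
                    up = list("G0001", "G0002", "G0003", "G0004"),
                    down = list("G0010", "G0020", "G0030", "G0040"))
  out <- filter_by_dose(reps, "10uM")
  # 10 uM, 10000 nM and 10 µM all match; 1 uM is dropped
  expect_identical(nrow(out), 3L)
  expect_identical(attr(out, "dropped_dose"), 1L)
  expect_identical(out$up_genes[[2]], "G0003")
  expect_identical(nrow(filter_by_dose(reps[0, ], "10uM")), 0L)
})

test_that("unparseable doses are dropped with a warning", {
  reps <- make_reps(c("a", "a"), c("10", "soon"), c("uM", "uM"),
                    list("G0001", "G0002"), list("G0003", "G0004"))
  reps$dose_value <- suppressWarnings(as.numeric(reps$dose_value))
  expect_warning(out <- filter_by_dose(reps, "10uM"), "unparseable")
  expect_identical(nrow(out), 1L)
  expect_identical(attr(out, "dropped_unparseable"), 1L)
})

test_that("regulatory vector arithmetic matches the counting definition", {
  lm <- default_landmarks()
  reps <- make_reps(rep("a", 3), rep(10, 3), rep("uM", 3),
                    up = list(c("G0001", "G0002"), c("G0001"), c("G0001", "G0003")),
                    down = list(c("G0005"), c("G0005", "G0002"), character(0)))
  v <- compute_regulatory_vector(reps, lm)
  expect_identical(dim(v), c(978L, 2L))
  expect_identical(unname(v["G0001", "up"]), 1)        # 3 of 3
  expect_identical(unname(v["G0002", "up"]), 1 / 3)
  expect_identical(unname(v["G0005", "down"]), 2 / 3)
  expect_identical(unname(v["G0002", "down"]), 1 / 3)  # up and down both count
  expect_identical(unname(v["G0900", "up"]), 0)        # never mentioned
  expect_true(all(v >= 0 & v <= 1))
  expect_error(compute_regulatory_vector(reps[0, ], lm), "at least one")
})

test_that("genes outside the landmark panel are dropped and tallied", {
  lm <- default_landmarks()
  reps <- make_reps("a", 10, "uM", list(c("G0001", "NOT_A_GENE")), list("G0002"))
  v <- compute_regulatory_vector(reps, lm)
  expect_identical(attr(v, "dropped_genes"), 1L)
  expect_identical(sum(v), 2)
})

test_that("the full matrix equals the brute-force nested-loop count", {
  lm <- default_landmarks()
  set.seed(99)
  n <- 12
  reps <- make_reps(sample(c("p1", "p2", "p3"), n, replace = TRUE),
                    rep(10, n), rep("uM", n),
                    up = replicate(n, sample(as.character(lm), 8), simplify = FALSE),
                    down = replicate(n, sample(as.character(lm), 8), simplify = FALSE))
  mapping <- data.frame(perturbagen_id = c("p1", "p2", "p3"),
                        smiles = c("CCO", "CC", "CO"))
  got <- build_regulatory_matrix(reps, mapping, lm)
  want <- brute_regulatory(reps, lm)
  expect_identical(unclass(got)[, , ], want[, , ])
  # values are multiples of 1 / replicate_count
  for (i in seq_len(dim(got)[1])) {
    k <- attr(got, "replicate_counts")[i]
    expect_true(all(abs(got[i, , ] * k - round(got[i, , ] * k)) < 1e-12))
  }
})

test_that("replicate order never changes the matrix", {
  lm <- default_landmarks()
  set.seed(5)
  reps <- make_reps(rep(c("x", "y"), each = 3), rep(10, 6), rep("uM", 6),
                    up = replicate(6, sample(as.character(lm), 5), simplify = FALSE),
                    down = replicate(6, sample(as.character(lm), 5), simplify = FALSE))
  mapping <- data.frame(perturbagen_id = c("x", "y"), smiles = c("CCO", "CC"))
  a <- build_regulatory_matrix(reps, mapping, lm)
  b <- build_regulatory_matrix(reps[sample(6), ], mapping, lm)
  expect_equal(unclass(a)[, , ], unclass(b)[, , ])
})

test_that("perturbagens drop to k survivors through dose and mapping", {
  lm <- default_landmarks()
  reps <- make_reps(c("p1", "p2", "p3", "p4", "p5"),
                    c(10, 10, 1, 10, 10), rep("uM", 5),
                    up = as.list(sprintf("G%04d", 1:5)),
                    down = as.list(sprintf("G%04d", 11:15)))
  # p3 fails the dose filter; p4, p5 are unmapped
  mapping <- data.frame(perturbagen_id = c("p1", "p2", "p3"),
                        smiles = c("CCO", "CC", "CO"))
  got <- suppressWarnings(build_regulatory_matrix(reps, mapping, lm))
  expect_identical(dim(got)[1], 2L)
  expect_identical(dimnames(got)[[1]], c("p1", "p2"))
  expect_identical(dim(got)[2], 978L)
  t <- attr(got, "tallies")
  expect_identical(unname(t["dropped_dose"] + t["dropped_unmapped"]), 3L)
})

test_that("ids sharing a molecule pool into one row per unique SMILES", {
  lm <- default_landmarks()
  reps <- make_reps(c("p1", "p1", "p2"), rep(10, 3), rep("uM", 3),
                    up = list("G0001", "G0002", "G0001"),
                    down = list("G0009", "G0009", "G0008"))
  mapping <- data.frame(perturbagen_id = c("p1", "p2"),
                        smiles = c("OCC", "CCO"))   # same molecule
  got <- build_regulatory_matrix(reps, mapping, lm)
  expect_identical(dim(got)[1], 2L)   # one entry per perturbagen
  pooled <- regulatory_by_smiles(got)
  expect_identical(dim(pooled)[1], 1L)
  # replicate-weighted pooling == recounting over the union of replicates
  expect_equal(unname(pooled[1, "G0001", "up"]), 2 / 3)
  expect_equal(unname(pooled[1, "G0009", "down"]), 2 / 3)
  expect_identical(unname(attr(pooled, "replicate_counts")), 3L)
})

test_that("replicate files round-trip and enforce disjointness", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("perturbagen_id\tdose_value\tdose_unit\tup_genes\tdown_genes",
               "p1\t10\tuM\tG0001|G0002\tG0003"), f)
  reps <- read_replicates(f)
  expect_identical(reps$up_genes[[1]], c("G0001", "G0002"))
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("perturbagen_id\tdose_value\tdose_unit\tup_genes\tdown_genes",
               "p1\t10\tuM\tG0001\tG0001"), bad)
  expect_error(read_replicates(bad), "disjoint")
  expect_error(map_to_smiles(reps, "/nonexistent/mapping.tsv"),
               "configuration error")
})

test_that("landmark lists enforce the 978-gene panel", {
  lm <- default_landmarks()
  expect_length(lm, 978L)
  f <- tempfile()
  writeLines(as.character(lm), f)
  expect_identical(as.character(read_landmarks(f)), as.character(lm))
  writeLines(as.character(lm)[1:100], f)
  expect_error(read_landmarks(f), "978")
})
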
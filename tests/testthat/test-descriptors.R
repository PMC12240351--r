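test_that("edge weights follow the index formulas", {
  expect_equal(edge_weight("F", 2, 3), 13)
  expect_equal(edge_weight("GA", 2, 2), 1)
  expect_equal(edge_weight("M1", 2, 4), 6)
  expect_equal(edge_weight("M2", 2, 4), 8)
  expect_equal(edge_weight("ABC", 1, 3), sqrt(2 / 3))
  expect_equal(edge_weight("SO", 3, 4), 5)
  expect_equal(edge_weight("H", 1, 3), 0.5)
  expect_error(edge_weight("W", 2, 2))
  expect_warning(w <- edge_weight("ABC", 1, 1), "degenerate")
  expect_equal(w, 0)
  # symmetry across a grid of degree pairs
  for (nm in index_names()) {
    for (i in 1:4) for (j in i:4) {
      if (nm == "ABC" && i == 1 && j == 1) next
      expect_equal(edge_weight(nm, i, j), edge_weight(nm, j, i))
      expect_gt(edge_weight(nm, i, j), 0)
    }
  }
})

test_that("Oxaliplatin worked example reproduces the printed index values", {
  oxa <- oxaliplatin_partition()
  expect_equal(topological_index(oxa, "F"), 238)
  expect_equal(round(topological_index(oxa, "ABC"), 4), 12.1587)
  # the printed GA sum (16.3826) is a typesetting slip; the formula gives 16.3821
  expect_equal(round(topological_index(oxa, "GA"), 4), 16.3821)
  expect_equal(topological_index(oxa, "M1"), 86)
  expect_equal(topological_index(oxa, "M2"), 104)

  expect_equal(round(entropy_index(oxa, "F"), 4), 2.7843)
  # true EntABC is 2.831759; the published 2.8317 is a truncation of it
  expect_lt(abs(entropy_index(oxa, "ABC") - 2.8317), 1e-4)
  expect_equal(round(entropy_index(oxa, "GA"), 4), 2.8323)
})

test_that("uniform edge weights attain the ln(m) entropy bound", {
  for (m in c(1, 6, 17)) {
    p <- partition_from_counts(data.frame(du = 2, dv = 2, count = m))
    for (nm in index_names()) {
      expect_equal(entropy_index(p, nm), log(m), tolerance = 1e-12)
    }
  }
  # a single-edge graph has one-outcome entropy 0 for every well-defined index
  k2 <- partition_from_counts(data.frame(du = 1, dv = 1, count = 1))
  for (nm in setdiff(index_names(), "ABC")) {
    expect_equal(entropy_index(k2, nm), 0)
  }
  suppressWarnings(
    expect_error(entropy_index(k2, "ABC"), "zero total weight")
  )
})

test_that("entropy equals the per-edge Shannon oracle and respects its bounds", {
  graphs <- random_graphs(100)
  for (g in graphs) {
    p <- edge_partition(g)
    m <- nrow(g$edges)
    for (nm in index_names()) {
      expect_equal(entropy_index(p, nm), oracle_entropy(g, nm),
                   tolerance = 1e-12)
      e <- entropy_index(p, nm)
      expect_gte(e, -1e-12)
      expect_lte(e, log(m) + 1e-12)
    }
  }
})

test_that("partition-based indices equal the per-edge summation oracle", {
  graphs <- random_graphs(100)
  for (g in graphs) {
    p <- edge_partition(g)
    for (nm in index_names()) {
      expect_equal(topological_index(p, nm), oracle_topological(g, nm),
                   tolerance = 1e-12)
    }
  }
})

test_that("scaling every cell count by k adds exactly ln k to the entropy", {
  oxa <- oxaliplatin_partition()
  for (k in c(2, 5, 10)) {
    scaled <- dplyr::mutate(oxa, count = count * k)
    for (nm in index_names()) {
      expect_equal(entropy_index(scaled, nm), entropy_index(oxa, nm) + log(k),
                   tolerance = 1e-10)
    }
  }
})

test_that("descriptor_table lays out one labeled row per compound", {
  tbl <- descriptor_table(list(Oxaliplatin = oxaliplatin_partition()))
  expect_equal(tbl$compound, "Oxaliplatin")
  expect_named(tbl, c("compound", paste0("Ent_", index_names())))
  # the row agrees with the published drug table at printed precision
  printed <- dplyr::filter(crc_descriptors(), compound == "Oxaliplatin")
  expect_equal(unlist(tbl[-1]), unlist(printed[-1]), tolerance = 2e-4)

  two <- descriptor_table(list(a = oxaliplatin_partition(),
                               b = oxaliplatin_partition()))
  expect_equal(unlist(two[1, -1]), unlist(two[2, -1]))

  expect_error(descriptor_table(list(a = oxaliplatin_partition()),
                                indices = character(0)), "empty index")
  one <- descriptor_table(list(a = oxaliplatin_partition()), indices = "F")
  expect_named(one, c("compound", "Ent_F"))
  both <- descriptor_table(list(a = oxaliplatin_partition()), indices = "F",
                           type = "both")
  expect_named(both, c("compound", "Ent_F", "F"))
})

test_that("descriptor CSV round-trips at serialized precision", {
  tbl <- descriptor_table(list(Oxaliplatin = oxaliplatin_partition()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(tbl, f)
  back <- read_descriptor_csv(f)
  expect_equal(back$compound, tbl$compound)
  expect_equal(unlist(back[-1]), round(unlist(tbl[-1]), 4))
  # writing the round-tripped table again is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_csv(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("packaged fixture CSVs agree with the in-code tables", {
  ext <- function(x) system.file("extdata", x, package = "entroqspr")
  expect_equal(as.data.frame(read_descriptor_csv(ext("crc_descriptors.csv"))),
               as.data.frame(crc_descriptors()))
  expect_equal(as.data.frame(read_descriptor_csv(ext("crc_properties.csv"))),
               as.data.frame(crc_properties()))
  expect_equal(read_partition_csv(ext("oxaliplatin_partition.csv")),
               oxaliplatin_partition())
})
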
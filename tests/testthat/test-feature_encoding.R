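test_that("chemical-property triples are the four fixed codes", {
  expect_equal(encode_ncp("A"), c(x = 1, y = 1, z = 1))
  expect_equal(encode_ncp("C"), c(x = 0, y = 0, z = 1))
  expect_equal(encode_ncp("G"), c(x = 1, y = 0, z = 0))
  expect_equal(encode_ncp("U"), c(x = 0, y = 1, z = 0))
  expect_error(encode_ncp("N"), "alphabet error")
  expect_error(encode_ncp("T"), "alphabet error")
})

test_that("density is the prefix frequency of the resident base", {
  expect_equal(encode_density("A"), 1)
  expect_equal(encode_density("AACG"), c(1, 1, 1 / 3, 1 / 4))
  expect_equal(encode_density("ACGU"), c(1, 1 / 2, 1 / 3, 1 / 4))
  expect_equal(encode_density(strrep("G", 7)), rep(1, 7))
  expect_error(encode_density(""), "nonempty")
  expect_error(encode_density("ACGT"), "alphabet error")
})

test_that("density matches a brute-force prefix-count oracle", {
  oracle <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    vapply(seq_along(ch), function(i) sum(ch[1:i] == ch[i]) / i, numeric(1))
  }
  withr::with_seed(19, {
    for (rep in 1:200) {
      l <- sample(1:50, 1)
      seq <- paste(sample(c("A", "C", "G", "U"), l, TRUE), collapse = "")
      expect_identical(encode_density(seq), oracle(seq))
    }
  })
})

test_that("window encoding is position-major with fixed channel order", {
  w41 <- random_windows(1, seed = 3)$seq
  expect_length(encode_window(w41), 164L)
  ring <- encode_window(w41, "ring")
  expect_length(ring, 41L)
  expect_true(all(ring %in% c(0, 1)))

  expect_equal(unname(encode_window("AAA")), rep(1, 12))

  # "AC": pos 1 = A -> (1,1,1,d=1); pos 2 = C -> (0,0,1,d=1/2)
  v <- encode_window("AC")
  expect_equal(unname(v), c(1, 1, 1, 1, 0, 0, 1, 0.5))
  expect_equal(names(v), c("p01_x", "p01_y", "p01_z", "p01_d",
                           "p02_x", "p02_y", "p02_z", "p02_d"))

  # mask order given by the user is canonicalized
  expect_identical(encode_window("ACGU", c("density", "ring")),
                   encode_window("ACGU", c("ring", "density")))
  expect_error(encode_window("ACGU", "purine"), "invalid feature mask")
})

test_that("feature matrices have one row per window and scale with the mask", {
  rec <- random_windows(7, seed = 8)
  X <- encode_windows(rec)
  expect_equal(dim(X), c(7L, 164L))
  expect_equal(rownames(X), rec$id)
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(ncol(encode_windows(rec, c("ring", "density"))), 82L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(X, path)
  expect_match(readLines(path, n = 1), "mask=ring\\+hbond\\+functionality\\+density l=41")
  expect_equal(nrow(utils::read.delim(path, skip = 1)), 7L)
})

test_that("PseDNC reduces to dinucleotide frequencies at lambda 0", {
  props <- read_psednc_properties(
    system.file("extdata", "psednc_properties_example.tsv",
                package = "m1Apred"))
  cfg0 <- psednc_config(lambda = 0, w = 0.5, property_table = props)

  v <- encode_psednc("ACGUACGAU", cfg0)
  expect_length(v, 16L)
  expect_equal(sum(v), 1)
  expect_equal(unname(v["AC"]), 2 / 8)

  only_ac <- encode_psednc(strrep("AC", 6), cfg0)
  expect_equal(sum(only_ac > 0), 2L)  # only AC and CA occur
})

test_that("PseDNC vectors are normalized for any lambda and input", {
  props <- read_psednc_properties(
    system.file("extdata", "psednc_properties_example.tsv",
                package = "m1Apred"))
  # standardized per property across the 16 dinucleotides
  expect_equal(unname(colMeans(props)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(props, 2, sd)), rep(1, 3), tolerance = 1e-12)

  cfg <- psednc_config(lambda = 3, w = 0.4, property_table = props)
  withr::with_seed(23, {
    for (rep in 1:20) {
      seq <- paste(sample(c("A", "C", "G", "U"), sample(8:40, 1), TRUE),
                   collapse = "")
      v <- encode_psednc(seq, cfg)
      expect_length(v, 19L)
      expect_equal(sum(v), 1, tolerance = 1e-9)
      expect_true(all(v >= 0))
    }
  })

  expect_error(encode_psednc("ACGU", cfg), "parameter error")
})

test_that("incomplete property tables are rejected", {
  tab <- utils::read.delim(
    system.file("extdata", "psednc_properties_example.tsv",
                package = "m1Apred"))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab[-5, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_psednc_properties(path), "configuration error.*missing")
})
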
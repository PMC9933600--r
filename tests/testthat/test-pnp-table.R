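# Golden copy of the packaged 20-PNP benchmark table, written out
# independently of the CSV fixture.
golden_pnp20 <- function() {
  txt <- "
id   amw  ncsp cc1 aai kin  obs pred split
5   6.06    1   0   0   1  -70  -59 T
4   6.06    1   0   0   0  -60  -59 T
18  6.35    3   0   1   0  -50  -35 V
2   6.06    1   0   1   0  -30  -34 T
11  6.06    0   0   0   0  -30  -26 T
15  5.96    1   0   1   0  -20  -16 V
19  5.34    0   0   1   0  -20  -10 T
17  6.35    1   0   1   0  -15  -19 T
3   6.06    1   0   1   0  -10  -22 T
14  5.96    0   0   1   0  -10    2 V
16  5.96    1   0   1   0   -5  -16 T
1   6.06    1   0   1   0   -4  -22 V
6   6.06    0   0   1   0    5   20 T
9   6.06    0   0   1   0    5    8 T
8   6.06    0   0   1   0   10    8 V
10  6.06    0   0   1   0   10    8 T
13  8.23    0   0   0   0   15    7 T
20  6.98    0   0   1   0   20   15 V
12  8.23    0   0   1   0   45   45 T
7   6.06    0   1   0   0   50   49 T"
  read.table(text = txt, header = TRUE, colClasses = c(id = "character"))
}

test_that("packaged benchmark table matches the published values cell for cell", {
  tab <- pnp20()
  g <- golden_pnp20()
  expect_equal(dim(tab), c(20L, 5L))
  expect_identical(tab$ids, g$id)
  expect_equal(unname(tab$X[, "AMW-P"]), g$amw)
  expect_equal(unname(tab$X[, "nCsp2-C"]), g$ncsp)
  expect_equal(unname(tab$X[, "CC1rs"]), g$cc1)
  expect_equal(unname(tab$X[, "ApoA-I"]), g$aai)
  expect_equal(unname(tab$X[, "kininogen-1"]), g$kin)
  expect_equal(tab$zeta, g$obs)
  expect_equal(tab$reference_pred, g$pred)
  expect_identical(tab$split, g$split)
  expect_equal(sum(tab$split == "T"), 14L)
  expect_equal(sum(tab$split == "V"), 6L)
  expect_identical(tab$schema$block,
                   c("core", "coating", "corona", "corona", "corona"))
  # spot rows quoted in the study
  s7 <- which(tab$ids == "7")
  expect_equal(unname(tab$X[s7, ]), c(6.06, 0, 1, 0, 0))
  expect_equal(tab$zeta[s7], 50)
  expect_identical(tab$split[s7], "T")
  s5 <- which(tab$ids == "5")
  expect_equal(tab$zeta[s5], -70)
  expect_equal(unname(tab$X[s5, "kininogen-1"]), 1)
})

test_that("CSV round trip reproduces a table exactly", {
  tab <- pnp20()
  csv <- withr::local_tempfile(fileext = ".csv")
  sch <- withr::local_tempfile(fileext = ".json")
  write_pnp_table(tab, csv, sch)
  back <- read_pnp_table(csv, sch)
  expect_identical(as.data.frame(back), as.data.frame(tab))
  # values survive as decimal text
  expect_identical(format(back$X, digits = 15), format(tab$X, digits = 15))
})

test_that("malformed CSV input is rejected with coordinates", {
  tab <- pnp20()
  csv <- withr::local_tempfile(fileext = ".csv")
  sch <- withr::local_tempfile(fileext = ".json")
  write_pnp_table(tab, csv, sch)
  d <- read.csv(csv, check.names = FALSE, colClasses = "character")

  d2 <- d; d2[3, "AMW-P"] <- "NA"
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d2, f2, row.names = FALSE)
  expect_error(read_pnp_table(f2, sch), "row '18', column 'AMW-P'")

  d3 <- d; d3[4, "CC1rs"] <- "2"
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d3, f3, row.names = FALSE)
  expect_error(read_pnp_table(f3, sch), "binary column 'CC1rs'")

  d4 <- d; d4$zeta_mV <- NULL
  f4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d4, f4, row.names = FALSE)
  expect_error(read_pnp_table(f4, sch), "missing column")
})

test_that("table invariants reject duplicate ids and bad labels", {
  sch <- data.frame(name = "d1", block = "core", kind = "continuous")
  expect_error(pnp_table(cbind(d1 = 1:3), 1:3, sch, ids = c("a", "a", "b")),
               "duplicate structure_id")
  expect_error(pnp_table(cbind(d1 = 1:3), 1:3, sch,
                         split = c("T", "X", "V")), "split labels")
  expect_error(pnp_table(cbind(d1 = 1:3), c(1, NA, 3), sch), "endpoint")
})

test_that("every-third splitter assigns floor(n/3) validation samples at sorted positions", {
  sch <- data.frame(name = "d1", block = "core", kind = "continuous")
  t6 <- pnp_table(cbind(d1 = rnorm(6)), zeta = c(30, -10, 0, 20, -25, 5),
                  schema = sch, ids = letters[1:6])
  out <- split_every_third(t6)
  # sorted order: e(-25) b(-10) c(0) f(5) d(20) a(30); V at positions 3, 6
  expect_identical(out$ids[out$split == "V"], c("a", "c"))
  for (n in c(3, 5, 8, 14, 20)) {
    tt <- pnp_table(cbind(d1 = rnorm(n)), zeta = rnorm(n), schema = sch)
    ss <- split_every_third(tt)
    expect_equal(sum(ss$split == "V"), floor(n / 3))
    expect_equal(sum(ss$split == "T"), n - floor(n / 3))
  }
  expect_error(split_every_third(
    pnp_table(cbind(d1 = 1:2), 1:2, sch)), "at least 3")
})

test_that("splitter with tied endpoints is invariant to input row order", {
  sch <- data.frame(name = "d1", block = "core", kind = "continuous")
  ids <- c("a", "b", "c")
  # brute force over all 6 input permutations; tie break by id
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  labels <- lapply(perms, function(p) {
    tt <- pnp_table(cbind(d1 = c(1, 2, 3)[p]), zeta = c(5, 5, 5),
                    schema = sch, ids = ids[p])
    out <- split_every_third(tt, tie_break = ids)
    out$split[match(ids, out$ids)]
  })
  for (l in labels) expect_identical(l, labels[[1]])
  expect_identical(labels[[1]], c("T", "T", "V"))
})

test_that("a tie-break priority exists that reproduces the published split", {
  tab <- pnp20()
  # priority: published row order except kininogen-free PCL-PEG (14) ahead
  # of its -10 mV tie partner (3)
  prio <- c("5", "4", "18", "2", "11", "15", "19", "17", "14", "3",
            "16", "1", "6", "9", "8", "10", "13", "20", "12", "7")
  out <- split_every_third(tab, tie_break = prio)
  expect_setequal(out$ids[out$split == "V"],
                  c("18", "15", "14", "1", "8", "20"))
})

test_that("subset_descriptors restricts matrix and schema consistently", {
  tab <- pnp20()
  sub <- subset_descriptors(tab, c("CC1rs", "AMW-P"))
  expect_identical(colnames(sub$X), c("CC1rs", "AMW-P"))
  expect_identical(sub$schema$block, c("corona", "core"))
  expect_error(subset_descriptors(tab, "nope"), "unknown descriptor")
})
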
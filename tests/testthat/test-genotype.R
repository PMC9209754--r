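test_that("packaged genotype table parses to the published panel", {
  panel <- ser_study_panel()
  expect_s3_class(panel, "genotype_panel")
  expect_equal(ncol(panel$presence), 11L)
  expect_equal(sum(!panel$lines$is_control), 31L)
  sizes <- vapply(lines_by_group(panel), length, 1L)
  expect_equal(sizes, c(`2QL` = 7L, `3QL` = 10L, `4QL` = 7L,
                        `5QL` = 5L, `6QL` = 2L))
  # every row's segment count equals its group number
  ln <- panel$lines[!panel$lines$is_control, ]
  expect_equal(rowSums(panel$presence)[ln$line_id],
               stats::setNames(as.numeric(ln$qtl_count), ln$line_id))
  expect_setequal(
    colnames(panel$presence)[panel$presence["6QL-1", ]],
    c("qSER2a-sat", "qSER2b-sat", "qSER3a-sat", "qSER3b-sat",
      "qSER5-glu", "qSER8b-gla"))
})

test_that("genotype reading validates structure and tokens", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("line_id,qA-sat,qB-gla", "L1,+,-", "L2,+,+"), tmp)
  panel <- read_genotype_table(tmp, control = character())
  expect_equal(panel$lines$qtl_count, c(1L, 2L))

  writeLines(c("line_id,qA-sat,qB-gla", "L1,+,-", "L1,+,+"), tmp)
  expect_error(read_genotype_table(tmp), "duplicate line_id")

  writeLines(c("line_id,qA-sat,qB-gla", "L1,+,?"), tmp)
  expect_error(read_genotype_table(tmp), "unknown presence/absence token")

  writeLines("line_id,qA-sat,qB-gla", tmp)
  expect_error(read_genotype_table(tmp), "no data rows")

  writeLines(c("line_id,group,qA-sat,qB-gla", "L1,2QL,+,-"), tmp)
  expect_error(read_genotype_table(tmp), "group label disagrees")

  # alternative token dialects normalise identically
  writeLines(c("line_id,qA-sat,qB-gla", "L1,1,0", "L2,TRUE,FALSE"), tmp)
  p2 <- read_genotype_table(tmp, control = character())
  expect_equal(unname(p2$presence[, "qA-sat"]), c(TRUE, TRUE))
  expect_equal(unname(p2$presence[, "qB-gla"]), c(FALSE, FALSE))
})

test_that("writing and re-reading a genotype table is lossless", {
  panel <- ser_study_panel()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(panel, tmp)
  back <- read_genotype_table(tmp, control = "HJX74",
                              loci = ser_study_metadata())
  expect_identical(back$presence, panel$presence)
  expect_identical(back$lines, panel$lines)
})

test_that("focal split partitions each group and reports published counts", {
  panel <- ser_study_panel()
  s <- split_by_focal_locus(panel, "qSER3a-sat", c("2QL", "3QL", "4QL"))
  counts <- vapply(s, function(x) c(length(x$with), length(x$without)),
                   integer(2))
  expect_equal(unname(counts), matrix(c(3L, 4L, 6L, 4L, 4L, 3L), nrow = 2))
  s6 <- split_by_focal_locus(panel, "qSER8b-gla", "6QL")
  expect_equal(length(s6$`6QL`$with), 2L)
  expect_equal(length(s6$`6QL`$without), 0L)
  # partition property over all loci and groups
  sizes <- vapply(lines_by_group(panel), length, 1L)
  for (locus in colnames(panel$presence)) {
    sp <- split_by_focal_locus(panel, locus)
    expect_equal(vapply(sp, function(x) length(x$with) + length(x$without), 1L),
                 sizes)
  }
  expect_error(split_by_focal_locus(panel, "nope"), "unknown locus")
})

test_that("panel construction enforces invariants", {
  pres <- matrix(c(TRUE, FALSE), 1, 2,
                 dimnames = list("L1", c("qA-sat", "qB-gla")))
  expect_silent(genotype_panel(pres))
  bad <- rbind(pres, L2 = c(FALSE, FALSE))
  expect_error(genotype_panel(bad), "1-6 QTLs")
  expect_equal(lines_by_group(genotype_panel(pres, control = "CTL")),
               list(`1QL` = "L1"))
  only_ctl <- genotype_panel(
    matrix(FALSE, 1, 1, dimnames = list("CTL", "qA-sat")), control = "CTL")
  expect_length(lines_by_group(only_ctl), 0L)
  md <- data.frame(name = c("qA-sat", "qB-gla"),
                   donor_species = c("glaberrima", "glaberrima"))
  expect_error(genotype_panel(pres, loci = md), "disagrees with name suffix")
})

test_that("donor species is inferred from the name suffix", {
  expect_equal(donor_from_name(c("qSER3a-sat", "qSER8b-gla", "qSER5-glu", "x")),
               c("sativa", "glaberrima", "glumaepatula", NA))
})
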
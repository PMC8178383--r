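test_that("QTL tables round-trip through write and read", {
  qtl <- dplyr::bind_rows(
    make_qtl("q1"),
    make_qtl("q2", trait = "FHB", peak_cm = 18, pve = 0.25, pop_type = "DH"),
    make_qtl("q3", chromosome = "2B", left_marker = "n1",
             right_marker = "n2", peak_cm = 20))
  path <- write_tsv_tmp(qtl)
  back <- read_qtl_table(path)
  expect_equal(nrow(back), 3)
  expect_equal(nrow(attr(back, "rejected")), 0)
  attr(back, "rejected") <- NULL
  expect_equal(dplyr::select(back, -trait_category), qtl)
})

test_that("rows violating invariants are rejected with row diagnostics", {
  qtl <- dplyr::bind_rows(
    make_qtl("q1"),
    make_qtl("q2", pve = 1.5),
    make_qtl("q3", left_marker = "m2", right_marker = "m2"),
    make_qtl("q4", pop_size = 1))
  path <- write_tsv_tmp(qtl)
  expect_warning(back <- read_qtl_table(path), "rejected")
  expect_equal(back$qtl_id, "q1")
  rej <- attr(back, "rejected")
  expect_equal(rej$row, c(2L, 3L, 4L))
  expect_match(rej$reason[1], "pve")
  expect_match(rej$reason[2], "flanking")
  expect_match(rej$reason[3], "pop_size")
})

test_that("schema remaps file columns and missing columns error", {
  qtl <- make_qtl()
  names(qtl)[names(qtl) == "pve"] <- "R2"
  path <- write_tsv_tmp(qtl)
  back <- read_qtl_table(path, schema = qtl_schema(pve = "R2"))
  expect_equal(back$pve, 0.10)

  no_peak <- dplyr::select(make_qtl(), -peak_cm)
  expect_error(read_qtl_table(write_tsv_tmp(no_peak)), "peak_cm")
})

test_that("non-numeric fields raise a parse error naming the row", {
  qtl <- make_qtl(pve = 0.1)
  qtl$pve <- "abc"
  expect_error(read_qtl_table(write_tsv_tmp(qtl)), "non-numeric pve.*row")
})

test_that("unknown trait codes are kept with a warning", {
  qtl <- make_qtl(trait = "XYZ")
  expect_warning(back <- read_qtl_table(write_tsv_tmp(qtl)),
                 "unknown trait")
  expect_true(is.na(back$trait_category))
})

test_that("consensus maps read, sort and reject duplicates", {
  map <- tiny_consensus_map()[c(3, 1, 2, 6, 7, 8, 4, 5), ]  # shuffled
  back <- read_consensus_map(write_tsv_tmp(map))
  expect_equal(back, dplyr::arrange(map, chromosome, cm))
  expect_equal(length(unique(back$chromosome)), 2)

  dup <- dplyr::bind_rows(tiny_consensus_map(), tiny_consensus_map()[1, ])
  expect_error(read_consensus_map(write_tsv_tmp(dup)), "duplicate")
})

test_that("chromosome aliases normalize to the 1A..7B scheme", {
  expect_equal(normalize_chromosome(c("chr1A", "Chr_2b", "7B", "weird")),
               c("1A", "2B", "7B", "weird"))
})

test_that("GFF3 round-trips and TE features are flagged", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chromosome = "1A",
    start = c(100, 5000, 9000), end = c(1500, 6200, 9500),
    is_te = c(FALSE, TRUE, FALSE),
    description = c("kinase", "retrotransposon protein", "unknown"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, path)
  back <- read_gff3(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  # flagged via feature type (g2) and via description keyword (g2 only here)
  expect_equal(back$is_te, c(FALSE, TRUE, FALSE))

  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(read_gff3(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "1A\tonly\tthree"), bad)
  expect_error(read_gff3(bad), "malformed.*line 1")
})

test_that("expression matrices validate tpm and key uniqueness", {
  ok <- tiny_expression()
  back <- read_expression_matrix(write_tsv_tmp(ok))
  expect_equal(nrow(back), nrow(ok))

  neg <- ok; neg$tpm[2] <- -1
  expect_error(read_expression_matrix(write_tsv_tmp(neg)), "negative tpm")

  dup <- dplyr::bind_rows(ok, ok[1, ])
  expect_error(read_expression_matrix(write_tsv_tmp(dup)),
               "duplicated expression key.*g1")
})

test_that("gzip-compressed inputs are read transparently", {
  qtl <- make_qtl()
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  readr::write_tsv(qtl, gz)  # readr compresses by extension
  back <- read_qtl_table(gz)
  expect_equal(back$qtl_id, "q1")
})

test_that("the packaged population table carries the study spectrum", {
  pops <- reference_populations()
  ks <- dplyr::filter(pops, cross == "Kristal x Sebatel")
  expect_equal(ks$pop_type, "RIL")
  expect_equal(ks$pop_size, 85)
  expect_equal(ks$trait, "SR")
  expect_equal(ks$n_qtl, 7)
  expect_true(all(pops$pop_type %in% c("RIL", "DH", "BC", "BIL", "BP")))
  expect_equal(range(pops$pop_size), c(85, 249))
})

test_that("the packaged MQTL catalogue loads with bp anchors intact", {
  mq <- reference_mqtl()
  expect_equal(nrow(mq), 85)
  expect_equal(sort(unique(mq$chromosome)),
               sort(paste0(rep(1:7, each = 2), c("A", "B"))))
  row1 <- mq[mq$mqtl_id == "durumMQTL1A.1", ]
  expect_equal(row1$left_marker, "BS00064204_51")
  expect_equal(row1$left_bp, 3574024)
  expect_true(all(mq$ci_left <= mq$peak & mq$peak <= mq$ci_right))
})
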
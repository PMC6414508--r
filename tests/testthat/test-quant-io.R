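test_that("protein table TSV parsing maps empty cells to missing and validates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tgene_symbol\tscore\ts1\ts2",
               "P1\tG1\t10\t1.5\t2",
               "P2\tG2\t7\t\t4",
               "P3\tG3\t5\t0\t3.25"), tmp)
  pt <- read_protein_table(tmp)
  expect_equal(n_proteins(pt), 3L)
  expect_equal(sum(is.na(pt$signal)), 1L)
  expect_true(is.na(pt$signal["P2", "s1"]))
  expect_equal(pt$signal["P3", "s1"], 0)  # zero is present, not missing

  writeLines(c("accession\tscore\ts1", "P00325\t10\t1", "P00325\t9\t2"), tmp)
  expect_error(read_protein_table(tmp), "P00325")

  writeLines(c("accession\tscore\ts1", "P1\t10\tabc"), tmp)
  expect_error(read_protein_table(tmp), "non-numeric")

  writeLines(c("accession\tscore\ts1", "P1\t10\t-4"), tmp)
  expect_error(read_protein_table(tmp), "negative")
})

test_that("protein table write/read round trip is the identity", {
  fx <- make_table(n_proteins = 12L, missing = 0.15, seed = 8L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(fx$table, tmp)
  back <- read_protein_table(tmp)
  expect_identical(back$accession, fx$table$accession)
  expect_identical(back$sample_id, fx$table$sample_id)
  expect_equal(back$signal, fx$table$signal)
  expect_equal(back$score, fx$table$score)
  expect_identical(is.na(back$signal), is.na(fx$table$signal))
})

test_that("writing an empty table yields a header-only file that reads back", {
  pt <- protein_table(matrix(numeric(0), 0, 2), accession = character(0),
                      score = numeric(0), sample_id = c("s1", "s2"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_protein_table(pt, tmp)
  expect_length(readLines(tmp), 1L)
  back <- read_protein_table(tmp)
  expect_equal(n_proteins(back), 0L)
  expect_equal(back$sample_id, c("s1", "s2"))
})

test_that("design validation enforces the paired-within-run two-run layout", {
  des <- make_design(8L)
  expect_s3_class(des, "sample_design")
  expect_equal(nrow(des), 18L)  # 8 subjects x 2 depots + 2 controls

  # subject with only one depot
  bad <- as.data.frame(des)[-1L, ]
  expect_error(sample_design(bad), "exactly twice")

  # subject split across runs
  bad <- as.data.frame(des)
  bad$run_id[bad$sample_id == "S01-A"] <- "R2"
  expect_error(sample_design(bad), "split across runs")

  # run without control
  bad <- as.data.frame(des)[des$sample_id != "C-R1", ]
  expect_error(sample_design(bad), "control")

  # duplicated control in a run
  bad <- as.data.frame(des)
  extra <- bad[bad$sample_id == "C-R1", ]
  extra$sample_id <- "C-R1b"
  expect_error(sample_design(rbind(bad, extra)), "control")
})

test_that("design, blood list and morphology round trip through their files", {
  des <- make_design(4L)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_design(des, tmp)
  expect_equal(as.data.frame(read_design(tmp)), as.data.frame(des))

  bl <- blood_list(c("P00738", "P02768"))
  tmp2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# plasma proteins", "P00738", "", "P02768  # albumin-ish"), tmp2)
  expect_equal(sort(as.character(read_blood_list(tmp2))), sort(as.character(bl)))

  mo <- morphology_table(data.frame(subject_id = c("S01", "S02"),
                                    abdominal_fcs = c(55, 60),
                                    femoral_fcs = c(62, 68)))
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  write_morphology(mo, tmp3)
  expect_equal(as.data.frame(read_morphology(tmp3)), as.data.frame(mo))

  expect_error(morphology_table(data.frame(subject_id = c("S01", "S01"),
                                           abdominal_fcs = c(55, 60),
                                           femoral_fcs = c(62, 68))),
               "duplicate subject")
  expect_error(morphology_table(data.frame(subject_id = "S01",
                                           abdominal_fcs = -1,
                                           femoral_fcs = 62)),
               "positive")
})

test_that("table/design consistency check names absent samples", {
  fx <- make_table()
  des <- fx$design[fx$design$sample_id != "S01-A", ]
  expect_error(check_table_design(fx$table, des), "S01-A")
})
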
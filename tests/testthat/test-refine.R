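test_that("SV types and lengths resolve from INFO, symbolic ALTs and sequences", {
  path <- write_test_vcf(c(
    "chr1\t100\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=250",
    paste0("chr1\t300\tb\tA\tA", strrep("T", 60), "\t.\tPASS\t."),
    "chr1\t600\tc\tN\t<DUP:TANDEM>\t.\tPASS\tEND=900",
    "chr1\t2000\td\tN\t<INS>\t.\tPASS\tSVTYPE=INS"
  ))
  ann <- annotate_sv(read_caller_vcf(path))
  expect_equal(ann$svtype, c("DEL", "INS", "DUP", "INS"))
  expect_equal(ann$svlen, c(150L, 60L, 300L, NA))
})

test_that("breakend orientations classify DEL, DUP, INV and CTX junctions", {
  # All four orientation combinations for a same-contig pair at 1000 < 4000,
  # plus an inter-contig breakend.
  path <- write_test_vcf(c(
    "chr1\t1000\tdel_1\tN\tN[chr1:4000[\t.\tPASS\tSVTYPE=BND;MATEID=del_2",
    "chr1\t4000\tdel_2\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=del_1",
    "chr1\t1000\tdup_1\tN\t]chr1:4000]N\t.\tPASS\tSVTYPE=BND;MATEID=dup_2",
    "chr1\t4000\tdup_2\tN\tN[chr1:1000[\t.\tPASS\tSVTYPE=BND;MATEID=dup_1",
    "chr1\t1000\tinv_1\tN\tN]chr1:4000]\t.\tPASS\tSVTYPE=BND;MATEID=inv_2",
    "chr1\t1000\tinv_3\tN\t[chr1:4000[N\t.\tPASS\tSVTYPE=BND;MATEID=inv_4",
    "chr1\t1000\tctx_1\tN\tN[chr5:2000[\t.\tPASS\tSVTYPE=BND;MATEID=ctx_2"
  ))
  ann <- annotate_sv(read_caller_vcf(path))
  expect_equal(ann$svtype[ann$record_id == "del_1"], "DEL")
  expect_equal(ann$svtype[ann$record_id == "del_2"], "DEL")  # mate agrees
  expect_equal(ann$svtype[ann$record_id == "dup_1"], "DUP")
  expect_equal(ann$svtype[ann$record_id == "dup_2"], "DUP")
  expect_equal(ann$svtype[ann$record_id == "inv_1"], "INV")
  expect_equal(ann$svtype[ann$record_id == "inv_3"], "INV")
  expect_equal(ann$svlen[ann$record_id == "del_1"], 3000L)
  expect_equal(ann$svtype[ann$record_id == "ctx_1"], "CTX")
  expect_true(is.na(ann$svlen[ann$record_id == "ctx_1"]))
})

test_that("unclassifiable records are dropped with a warning, not an error", {
  path <- write_test_vcf(c(
    "chr1\t100\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=250",
    "chr1\t300\tb\tACGT\tTGCA\t.\tPASS\t."  # same length, no SVTYPE, no mate
  ))
  expect_warning(ann <- annotate_sv(read_caller_vcf(path)), "1 unclassifiable")
  expect_equal(nrow(ann), 1)
  expect_equal(attr(ann, "n_dropped"), 1L)
})

test_that("the size filter excludes sub-50 bp calls but keeps unknown lengths", {
  recs <- dplyr::bind_rows(
    make_sv(100L, svlen = 49L),
    make_sv(200L, svlen = 50L),
    make_sv(300L, svtype = "CTX", svlen = NA_integer_),
    make_sv(400L, svtype = "INS", svlen = NA_integer_)
  )
  kept <- filter_min_size(recs, 50)
  expect_equal(kept$pos, c(200L, 300L, 400L))
  expect_equal(attr(kept, "n_removed"), 1L)
})

test_that("paired-record dedup keeps the smaller position of each linked pair", {
  path <- write_test_vcf(c(
    "chr1\t1000\tp_1\tN\tN[chr1:5000[\t.\tPASS\tSVTYPE=BND;MATEID=p_2",
    "chr1\t5000\tp_2\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=p_1",
    "chr1\t7000\tlone\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=7400"
  ))
  ann <- annotate_sv(read_caller_vcf(path))
  deduped <- deduplicate_paired(ann)
  expect_equal(deduped$pos, c(1000L, 7000L))
  expect_equal(attr(deduped, "n_removed"), 1L)
})

test_that("inter-contig pairs keep the record on the earlier contig", {
  path <- write_test_vcf(c(
    "chr1\t1000\tq_1\tN\tN[chr5:2000[\t.\tPASS\tSVTYPE=BND;MATEID=q_2",
    "chr5\t2000\tq_2\tN\tN[chr1:1000[\t.\tPASS\tSVTYPE=BND;MATEID=q_1"
  ))
  ann <- annotate_sv(read_caller_vcf(path))
  deduped <- deduplicate_paired(ann)
  expect_equal(nrow(deduped), 1)
  expect_equal(deduped$contig, "chr1")
})

test_that("records are linked by MATEID, shared EVENT, or _1/_2 ID stems", {
  path <- write_test_vcf(c(
    "chr1\t1000\tev_a\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1500;EVENT=E9",
    "chr1\t1500\tev_b\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1500;EVENT=E9",
    "chr1\t3000\tstem_1\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=3600",
    "chr1\t3600\tstem_2\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=3600"
  ))
  ann <- annotate_sv(read_caller_vcf(path))
  deduped <- deduplicate_paired(ann)
  expect_equal(deduped$pos, c(1000L, 3000L))
})

test_that("a mate ID pointing nowhere keeps the survivor with a warning", {
  path <- write_test_vcf(
    "chr1\t1000\torphan_1\tN\tN[chr1:4000[\t.\tPASS\tSVTYPE=BND;MATEID=orphan_2"
  )
  ann <- annotate_sv(read_caller_vcf(path))
  expect_warning(deduped <- deduplicate_paired(ann), "missing")
  expect_equal(nrow(deduped), 1)
})

test_that("PASS filtering keeps exactly PASS and rejects missing filters", {
  recs <- make_sv(c(100L, 200L, 300L), filter = c("PASS", "LowQual", "."))
  kept <- filter_pass(recs)
  expect_equal(kept$pos, 100L)
  expect_equal(attr(kept, "n_removed"), 2L)
  expect_equal(nrow(filter_pass(recs, pass_only = FALSE)), 3)
})

test_that("caller tagging sets every record and rejects empty labels", {
  recs <- make_sv(c(100L, 200L, 300L), caller = NA_character_)
  tagged <- tag_caller(recs, "DELLY")
  expect_equal(unique(tagged$caller), "DELLY")
  retagged <- tag_caller(tagged, "Manta")  # last write wins
  expect_equal(unique(retagged$caller), "Manta")
  expect_equal(nrow(tag_caller(recs[0, ], "DELLY")), 0)
  expect_error(tag_caller(recs, ""), "non-empty")
})

test_that("length summaries follow the type-7 quartile convention", {
  recs <- dplyr::bind_rows(
    make_sv(c(100L, 200L, 300L), svlen = c(50L, 100L, 150L)),
    make_sv(400L, svlen = 1000L),
    make_sv(500L, svtype = "CTX", svlen = NA_integer_)
  )
  s <- summarize_lengths(recs)
  del <- s[s$svtype == "DEL", ]
  # lengths {50,100,150,1000}: quartiles by hand under type 7 are
  # Q1 = 50 + 0.75*50 = 87.5 and Q3 = 150 + 0.25*850 = 362.5
  expect_equal(del$median, 125)
  expect_equal(del$min, 50)
  expect_equal(del$max, 1000)
  expect_equal(del$iqr, 275)
  expect_equal(s$count[s$svtype == "CTX"], 1L)
  expect_true(is.na(s$median[s$svtype == "CTX"]))
  expect_false("INS" %in% s$svtype)

  s3 <- summarize_lengths(make_sv(1:3 * 100L, svlen = c(50L, 100L, 150L)))
  expect_equal(s3$median, 100)
})

test_that("refinement is idempotent and its counters are conserved", {
  path <- write_test_vcf(c(
    "chr1\t100\tsmall\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;SVLEN=-30",
    "chr1\t500\tlow\tN\t<DEL>\t.\tq5\tSVTYPE=DEL;END=900",
    "chr1\t1000\tmate_1\tN\tN[chr1:4000[\t.\tPASS\tSVTYPE=BND;MATEID=mate_2",
    "chr1\t4000\tmate_2\tN\t]chr1:1000]N\t.\tPASS\tSVTYPE=BND;MATEID=mate_1",
    "chr1\t9000\tok\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=120"
  ))
  refined <- refine_calls(read_caller_vcf(path), "Manta")
  expect_equal(nrow(refined), 2)
  expect_equal(refined$record_id, c("mate_1", "ok"))

  stats <- attr(refined, "stats")
  expect_equal(stats$n_in - stats$n_out, stats$n_removed)
  expect_equal(sum(stats$n_removed), 5 - nrow(refined))

  # Round-trip the refined set and refine again: nothing changes.
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(refined, path2, contigs = c(chr1 = 1e6))
  again <- refine_calls(read_caller_vcf(path2), "Manta")
  expect_equal(
    again[, c("contig", "pos", "svtype", "svlen", "filter", "caller")],
    refined[, c("contig", "pos", "svtype", "svlen", "filter", "caller")],
    ignore_attr = TRUE
  )
  expect_equal(sum(attr(again, "stats")$n_removed), 0)
})
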
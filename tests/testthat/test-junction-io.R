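test_that("SJ.out.tab rows convert to 0-based half-open introns", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t101\t200\t1\t0\t1\t42\t7\t30",
               "chr2\t51\t300\t2\t0\t1\t5\t0\t20"), path)
  jc <- parse_star_sj(path, "s1")
  expect_equal(jc$intron_start, c(100L, 50L))
  expect_equal(jc$intron_end, c(200L, 300L))
  expect_equal(jc$strand, c("+", "-"))
  expect_equal(jc$count, c(42L, 5L))
  expect_equal(jc$sample, c("s1", "s1"))
})

test_that("duplicate SJ rows for one junction are summed (vs naive groupby)", {
  set.seed(11)
  rows <- data.frame(chrom = sample(c("c1", "c2"), 40, replace = TRUE),
                     start1 = sample(c(101, 201, 301), 40, replace = TRUE),
                     len = sample(c(100, 150), 40, replace = TRUE),
                     code = sample(1:2, 40, replace = TRUE),
                     count = sample(0:30, 40, replace = TRUE))
  path <- withr::local_tempfile()
  writeLines(sprintf("%s\t%d\t%d\t%d\t0\t1\t%d\t0\t30", rows$chrom,
                     rows$start1, rows$start1 + rows$len - 1, rows$code,
                     rows$count), path)
  jc <- parse_star_sj(path, "s")
  naive <- aggregate(count ~ chrom + start1 + len + code, rows, sum)
  got <- jc$count[match(
    paste(naive$chrom, naive$start1 - 1, naive$start1 + naive$len - 1,
          c("+", "-")[naive$code]),
    paste(jc$chrom, jc$intron_start, jc$intron_end, jc$strand))]
  expect_equal(got, naive$count)
  expect_equal(sum(jc$count), sum(rows$count))
})

test_that("strand-code-0 junctions are dropped, or resolved by annotation", {
  path <- withr::local_tempfile()
  writeLines(c("c1\t101\t200\t0\t0\t0\t9\t0\t30",
               "c1\t301\t400\t1\t0\t1\t4\t0\t30"), path)
  expect_message(jc <- parse_star_sj(path, "s"), "dropped")
  expect_equal(nrow(jc), 1L)
  # an exon ending exactly at the intron start resolves the strand
  ex <- data.frame(chrom = "c1", start = 0L, end = 100L, strand = "-",
                   type = "exon", transcript_id = "t", gene_id = "g",
                   stringsAsFactors = FALSE)
  jc2 <- parse_star_sj(path, "s", exon_index = exon_index(ex))
  expect_equal(nrow(jc2), 2L)
  expect_equal(jc2$strand[jc2$intron_start == 100], "-")
})

test_that("malformed and negative SJ rows raise informative errors", {
  path <- withr::local_tempfile()
  writeLines(c("c1\t101\t200\t1\t0\t1\t5\t0\t30", "c1\t101"), path)
  expect_error(parse_star_sj(path, "s"), "line 2")
  writeLines("c1\t101\t200\t1\t0\t1\t-5\t0\t30", path)
  expect_error(parse_star_sj(path, "s"), "negative")
})

test_that("BED12 junction records decode block arithmetic", {
  path <- withr::local_tempfile()
  # chromStart=100, blockSizes 50,60, blockStarts 0,150 -> intron [150, 250)
  writeLines(paste0("c1\t100\t310\tj1\t10\t+\t100\t310\t0\t2\t50,60\t0,150"),
             path)
  jc <- parse_junction_bed(path, "s")
  expect_equal(jc$intron_start, 150L)
  expect_equal(jc$intron_end, 250L)
  expect_equal(jc$count, 10L)
  # score 0 retained; minus strand gives the same intron interval
  writeLines(c("c1\t100\t310\tj1\t0\t+\t100\t310\t0\t2\t50,60\t0,150",
               "c1\t100\t310\tj2\t7\t-\t100\t310\t0\t2\t50,60\t0,150"), path)
  jc <- parse_junction_bed(path, "s")
  expect_equal(jc$count[jc$strand == "+"], 0L)
  expect_equal(jc$intron_start, c(150L, 150L))
  # a 3-block record is rejected
  writeLines("c1\t100\t400\tj1\t5\t+\t100\t400\t0\t3\t50,50,50\t0,100,250",
             path)
  expect_error(parse_junction_bed(path, "s"), "2 blocks")
})

test_that("generic junction TSV round-trips bit-exactly", {
  cfg <- synth_config(n_class1 = 3, n_class2 = 0, n_null = 3, n_cassette = 2,
                      seed = 5)
  sim <- simulate_counts(generate_reference(cfg))
  path <- withr::local_tempfile()
  write_junction_tsv(sim$counts, path)
  back <- read_junction_tsv(path)
  expect_identical(as.data.frame(back), as.data.frame(sim$counts))
})

test_that("SJ.out.tab and BED12 dialects parse to identical junction sets", {
  cfg <- synth_config(n_class1 = 4, n_class2 = 0, n_null = 4, n_cassette = 2,
                      seed = 7)
  sim <- simulate_counts(generate_reference(cfg))
  one <- sim$counts[sim$counts$sample == sim$samples[1], , drop = FALSE]
  sj_path <- withr::local_tempfile()
  bed_path <- withr::local_tempfile()
  write_sj_tab(one, sj_path)
  # serialize the same junctions as BED12 with 50-nt flanks
  writeLines(sprintf("%s\t%d\t%d\tj%d\t%d\t%s\t0\t0\t0\t2\t50,50\t0,%d",
                     one$chrom, one$intron_start - 50L, one$intron_end + 50L,
                     seq_len(nrow(one)), one$count, one$strand,
                     one$intron_end - one$intron_start + 50L), bed_path)
  a <- parse_star_sj(sj_path, "s")
  b <- parse_junction_bed(bed_path, "s")
  key <- function(j) sort(paste(j$chrom, j$intron_start, j$intron_end,
                                j$strand, j$count))
  expect_identical(key(a), key(b))
})

test_that("GTF exons convert to 0-based half-open spans and answer containment", {
  ex <- data.frame(chrom = "c1", start = 100L, end = 200L, strand = "+",
                   type = "exon", transcript_id = "t1", gene_id = "g1",
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile()
  write_gtf(ex, path)
  # written as 1-based [101, 200]; read back identically
  line <- readLines(path)
  expect_match(line, "\t101\t200\t")
  back <- read_exon_annotation(path, "gtf")
  expect_equal(back$start, 100L)
  expect_equal(back$end, 200L)
  idx <- exon_index(back)
  expect_true(exon_contains(idx, "c1", 150L, 160L, "+"))
  expect_false(exon_contains(idx, "c1", 150L, 260L, "+"))
  expect_false(exon_contains(idx, "c1", 150L, 160L, "-"))
})

test_that("genome accessor returns transcript-orientation sequence", {
  g <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTAC"))
  expect_equal(genome_subseq(g, "c1", 2, 6, "+"), "GTAC")
  expect_equal(genome_subseq(g, "c1", 0, 3, "-"), "CGT")
  expect_equal(genome_subseq(g, "c1", 1, 6, "-"), "GTACG")
  expect_error(genome_subseq(g, "c1", 5, 12, "+"), "outside")
  expect_error(genome_subseq(g, "c9", 0, 2, "+"), "unknown")
})
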
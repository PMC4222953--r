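# The standard toy: 100-nt exons, CDS starting at mRNA position 11
# (10-nt 5'UTR + ATG in exon 1), stop-free Ala codons through exons 1-2,
# and a planted TAA near the start of exon 3. mRNA frame: codon starts sit
# at positions 11 + 3k, so the first codon start inside the extension
# (which begins at mRNA position 201 of the long isoform) is 203.

base_exons <- function() {
  list(e1 = paste0(strrep("C", 10), "ATG", codons(29)),   # 100 nt
       e2 = substr(codons(34), 1, 100))                   # 100 nt
}

ref_e3 <- function() {
  # exon 3: continue the frame (mRNA 201.. for the short isoform); place the
  # reference stop at codon start 221 (mRNA), i.e. exon-3 offset 20
  paste0(substr(codons(7), 1, 20), "TAA", strrep("C", 77))  # 100 nt
}

test_that("an in-frame stop deep inside the extension is PTC_NMD", {
  ex <- base_exons()
  # extension of 100 nt with TAA at offset 2 -> codon start at mRNA 203,
  # stop end 205; last junction of the long mRNA at 300; distance 95 > 50
  ext <- paste0("CC", "TAA", strrep("C", 95))
  toy <- toy_a5c(ex$e1, ex$e2, ext, ref_e3(), cds_span = c(10, 143))
  models <- transcript_models(toy$exons, toy$genome)
  cc <- call_consequences(toy$event, models, toy$genome)
  expect_equal(cc$category, "PTC_NMD")
  expect_equal(cc$host_transcript, "toy.t1")
  # the altered (long) isoform's stop agrees with a naive codon walk on the
  # hand-spliced mRNA
  mrna_long <- paste0(ex$e1, ex$e2, ext, ref_e3())
  expect_equal(cc$stop_alt, oracle_codon_walk(mrna_long, 11))
  expect_equal(cc$dist_alt, 300 - oracle_codon_walk(mrna_long, 11))
  # reference stop also verified against the oracle on the short mRNA
  mrna_short <- paste0(ex$e1, ex$e2, ref_e3())
  expect_equal(cc$stop_ref, oracle_codon_walk(mrna_short, 11))
})

test_that("a stop just before the last junction escapes NMD", {
  ex <- base_exons()
  # codon start at mRNA 251 -> extension offset 50; stop end 253;
  # distance to the last junction (300) is 47 <= 50
  ext <- paste0(strrep("C", 50), "TAA", strrep("C", 47))
  toy <- toy_a5c(ex$e1, ex$e2, ext, ref_e3(), cds_span = c(10, 143))
  cc <- call_consequences(toy$event, transcript_models(toy$exons, toy$genome),
                          toy$genome)
  expect_equal(cc$category, "PTC_escape")
  expect_equal(cc$dist_alt, 47)
  # with a smaller NMD rule distance the same event is predicted NMD;
  # increasing the rule distance never converts escape into NMD
  cc40 <- call_consequences(toy$event,
                            transcript_models(toy$exons, toy$genome),
                            toy$genome, nmd_rule_nt = 40)
  expect_equal(cc40$category, "PTC_NMD")
  cc80 <- call_consequences(toy$event,
                            transcript_models(toy$exons, toy$genome),
                            toy$genome, nmd_rule_nt = 80)
  expect_equal(cc80$category, "PTC_escape")
})

test_that("a frame-preserving stop-free extension changes the ORF without PTC", {
  ex <- base_exons()
  ext <- strrep("C", 33)
  toy <- toy_a5c(ex$e1, ex$e2, ext, ref_e3(), cds_span = c(10, 143))
  cc <- call_consequences(toy$event, transcript_models(toy$exons, toy$genome),
                          toy$genome)
  expect_equal(cc$category, "ORF_change_noPTC")
  # both isoforms terminate at the same genomic stop: the long (altered)
  # isoform's stop sits exactly one extension length further in its mRNA
  mrna_long <- paste0(ex$e1, ex$e2, ext, ref_e3())
  mrna_short <- paste0(ex$e1, ex$e2, ref_e3())
  expect_equal(cc$stop_ref, oracle_codon_walk(mrna_short, 11))
  expect_equal(cc$stop_alt, oracle_codon_walk(mrna_long, 11))
  expect_equal(cc$stop_alt, cc$stop_ref + 33)
})

test_that("an extension upstream of the CDS start is a 5'UTR change", {
  # CDS entirely in exon 3: exons 1-2 are untranslated
  e1 <- strrep("C", 100)
  e2 <- strrep("C", 100)
  e3 <- paste0(strrep("C", 10), "ATG", codons(10), "TAA", strrep("C", 54))
  toy <- toy_a5c(e1, e2, strrep("C", 60), e3, cds_span = NULL)
  # attach the CDS span genomically: exon 3 starts at coords$s3
  s3 <- toy$coords$s3
  cds <- data.frame(chrom = "toy", start = s3 + 10L, end = s3 + 10L + 36L,
                    strand = "+", type = "CDS", transcript_id = "toy.t1",
                    gene_id = "toygene", stringsAsFactors = FALSE)
  exons <- rbind(toy$exons, cds)
  cc <- call_consequences(toy$event, transcript_models(exons, toy$genome),
                          toy$genome)
  expect_equal(cc$category, "UTR5_change")
})

test_that("an extension downstream of the stop is a 3'UTR change", {
  # CDS entirely in exon 1
  e1 <- paste0(strrep("C", 10), "ATG", codons(10), "TAA", strrep("C", 54))
  toy <- toy_a5c(e1, strrep("C", 100), strrep("C", 60), strrep("C", 100),
                 cds_span = c(10, 56))
  cc <- call_consequences(toy$event, transcript_models(toy$exons, toy$genome),
                          toy$genome)
  expect_equal(cc$category, "UTR3_change")
})

test_that("grafting conserves exon structure and spliced lengths", {
  ex <- base_exons()
  ext <- strrep("C", 90)
  toy <- toy_a5c(ex$e1, ex$e2, ext, ref_e3(), cds_span = c(10, 143))
  models <- transcript_models(toy$exons, toy$genome)
  pair <- graft_event(toy$event, models[["toy.t1"]])
  expect_false(pair$host_is_long)
  long_len <- sum(pair$long$exons[, 2] - pair$long$exons[, 1])
  short_len <- sum(pair$short$exons[, 2] - pair$short$exons[, 1])
  expect_equal(long_len - short_len, 90)
  # all non-event exons unchanged
  expect_equal(pair$long$exons[c(1, 3), ], pair$short$exons[c(1, 3), ])
})

test_that("events without a compatible transcript boundary are unresolved", {
  ex <- base_exons()
  toy <- toy_a5c(ex$e1, ex$e2, strrep("C", 60), ref_e3(),
                 cds_span = c(10, 143))
  orphan <- toy$event
  orphan$u_site <- orphan$u_site + 7L  # interior to every annotated exon
  orphan$d_site <- orphan$d_site + 7L
  orphan$common_site <- orphan$common_site + 7L
  cc <- call_consequences(orphan, transcript_models(toy$exons, toy$genome),
                          toy$genome)
  expect_equal(cc$category, "unresolved")
  expect_equal(cc$reason, "no_host_transcript")
})

test_that("noncoding hosts are unresolved with reason", {
  e1 <- strrep("C", 100)
  toy <- toy_a5c(e1, strrep("C", 100), strrep("C", 60), strrep("C", 100),
                 cds_span = NULL)
  cc <- call_consequences(toy$event, transcript_models(toy$exons, toy$genome),
                          toy$genome)
  expect_equal(cc$category, "unresolved")
  expect_equal(cc$reason, "noncoding_host")
})

test_that("translate_to_stop agrees with the codon-walk oracle", {
  expect_equal(translate_to_stop("CCATGAAATGACCC", 3), 11)
  expect_true(is.na(translate_to_stop(paste0("ATG", codons(5)), 1)))
  set.seed(61)
  for (i in 1:40) {
    mrna <- random_dna(sample(30:300, 1))
    cds <- sample(1:10, 1)
    expect_identical(translate_to_stop(mrna, cds),
                     oracle_codon_walk(mrna, cds))
  }
})

test_that("each resolved event gets exactly one category and the partition sums", {
  cfg <- synth_config(n_class1 = 8, n_class2 = 8, n_null = 8, n_cassette = 0,
                      n_a3c_class1 = 4, seed = 17)
  ref <- generate_reference(cfg)
  ev <- deplete_cassette(rbind(enumerate_a5c(ref$junctions),
                               enumerate_a3c(ref$junctions)),
                         exon_index(ref$exons))
  models <- transcript_models(ref$exons, ref$genome)
  cc <- call_consequences(ev, models, ref$genome)
  expect_equal(nrow(cc), sum(ev$retained))
  cats <- c("UTR5_change", "ORF_change_noPTC", "PTC_NMD", "PTC_escape",
            "UTR3_change", "unresolved")
  expect_true(all(cc$category %in% cats))
  expect_equal(sum(table(cc$category)), nrow(cc))
  # frame-preserving stop-free extensions are never PTC_NMD
  tr <- ref$truth[ref$truth$class != "decoy", ]
  ids <- sprintf("%s:%s:%s:%d:%d:%d", tr$event_type, tr$chrom, tr$strand,
                 tr$common_site, tr$u_site, tr$d_site)
  mod3 <- tr$ext_len %% 3 == 0
  no_stop <- vapply(seq_len(nrow(tr)), function(i) {
    s <- genome_subseq(ref$genome, tr$chrom[i], tr$ext_start[i],
                       tr$ext_end[i], tr$strand[i])
    !grepl("TAA|TAG|TGA", s)
  }, logical(1))
  safe <- ids[mod3 & no_stop]
  if (length(safe))
    expect_false(any(cc$category[match(safe, cc$event_id)] == "PTC_NMD"))
  # NMD monotonicity across the fixture
  cc_strict <- call_consequences(ev, models, ref$genome, nmd_rule_nt = 100)
  moved <- cc$category == "PTC_escape" & cc_strict$category == "PTC_NMD"
  expect_false(any(moved))
})
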
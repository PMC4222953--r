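# Hand-built toy genes for consequence tests. The toy mimics the classic
# three-exon topology with an alternate donor at the middle exon: the short
# isoform splices at the middle exon's annotated end, the long isoform
# extends it by `ext_seq`.
#
# Layout (plus strand, coordinates 0-based):
#   exon1 [0, n1) | intron1 | exon2 [s2, s2+n2) | ext | intron2 | exon3
#
# e1/e2/e3 are the exonic sequences of the SHORT isoform; cds_span is the
# genomic CDS span of the short (reference) isoform.

toy_a5c <- function(e1, e2, ext_seq, e3, cds_span,
                    intron1 = paste0("GT", strrep("C", 76), "AG"),
                    intron2 = paste0("GT", strrep("C", 76), "AG"),
                    chrom = "toy") {
  n1 <- nchar(e1); n2 <- nchar(e2); L <- nchar(ext_seq); n3 <- nchar(e3)
  i1 <- nchar(intron1); i2 <- nchar(intron2)
  s2 <- n1 + i1
  u_site <- s2 + n2
  d_site <- u_site + L
  s3 <- d_site + i2
  seqs <- paste0(e1, intron1, e2, ext_seq, intron2, e3)
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chrom
  mk <- function(tx, mid_end, cds = NULL) {
    spans <- rbind(c(0, n1), c(s2, mid_end), c(s3, s3 + n3))
    rows <- data.frame(chrom = chrom, start = spans[, 1], end = spans[, 2],
                       strand = "+", type = "exon", transcript_id = tx,
                       gene_id = "toygene", stringsAsFactors = FALSE)
    if (!is.null(cds)) {
      for (i in seq_len(nrow(spans))) {
        cs <- max(spans[i, 1], cds[1]); ce <- min(spans[i, 2], cds[2])
        if (ce > cs)
          rows <- rbind(rows,
                        data.frame(chrom = chrom, start = cs, end = ce,
                                   strand = "+", type = "CDS",
                                   transcript_id = tx, gene_id = "toygene",
                                   stringsAsFactors = FALSE))
      }
    }
    rows
  }
  exons <- rbind(mk("toy.t1", u_site, cds_span), mk("toy.t2", d_site))
  event <- data.frame(
    event_id = "A5C:toy", type = "A5C", chrom = chrom, strand = "+",
    common_site = s3, u_site = u_site, d_site = d_site,
    ext_start = u_site, ext_end = d_site,
    long_intron_start = d_site, long_intron_end = s3,
    short_intron_start = u_site, short_intron_end = s3,
    retained = TRUE, stringsAsFactors = FALSE)
  list(genome = genome, exons = exons, event = event,
       coords = list(s2 = s2, u_site = u_site, d_site = d_site, s3 = s3))
}

# stop-free codon filler (Ala repeats)
codons <- function(n) strrep("GCT", n)

# a small single-gene annotation + genome for donor-PWM and IO tests
toy_annotation <- function(donor_9mers, chrom = "t") {
  # one two-exon transcript per donor; exon1 ends at position 50
  n <- length(donor_9mers)
  width <- 200L
  seqs <- vapply(donor_9mers, function(d9) {
    s <- strsplit(random_dna(width), "")[[1]]
    s[48:56] <- strsplit(d9, "")[[1]]  # donor boundary at 0-based pos 50
    s[99:100] <- c("A", "G")
    paste(s, collapse = "")
  }, character(1))
  chroms <- paste0(chrom, seq_len(n))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  exons <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(chrom = chroms[i], start = c(0L, 100L), end = c(50L, 180L),
               strand = "+", type = "exon",
               transcript_id = paste0("tx", i), gene_id = paste0("gn", i),
               stringsAsFactors = FALSE)))
  list(genome = genome, exons = exons)
}
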
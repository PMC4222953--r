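## Junction, annotation and genome input.
##
## Internal coordinate convention, used everywhere in the package:
## 0-based, half-open, genomic. A splice junction is represented by its
## intron interval [intron_start, intron_end); the donor is the intron
## boundary adjacent to the upstream exon (intron_start on "+",
## intron_end on "-") and the acceptor the opposite boundary.

#' Construct a junction-count table
#'
#' The atomic observation of the package: an intron interval with strand and
#' a per-sample unique-read count. Stored as a plain data.frame in long
#' format with columns `chrom`, `intron_start`, `intron_end`, `strand`,
#' `sample`, `count`.
#'
#' @param chrom,intron_start,intron_end,strand junction coordinates
#'   (0-based half-open intron interval; strand `"+"` or `"-"`).
#' @param sample sample identifier.
#' @param count non-negative integer unique-read count.
#' @return a `data.frame` of class `junction_counts`.
#' @export
junction_counts <- function(chrom, intron_start, intron_end, strand, sample, count) {
  df <- data.frame(
    chrom = as.character(chrom),
    intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end),
    strand = as.character(strand),
    sample = as.character(sample),
    count = as.integer(count),
    stringsAsFactors = FALSE
  )
  validate_junction_counts(df)
}

validate_junction_counts <- function(df) {
  need <- c("chrom", "intron_start", "intron_end", "strand", "sample", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("junction counts missing columns: ", paste(missing, collapse = ", "))
  if (any(df$count < 0)) stop("negative junction read counts")
  if (any(df$intron_end <= df$intron_start))
    stop("intron_end must exceed intron_start")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  class(df) <- unique(c("junction_counts", class(df)))
  df
}

#' Sample design with reference and knockdown contrasts
#'
#' @param condition_of named character vector mapping sample id -> condition
#'   label.
#' @param reference the reference (control) condition label.
#' @param contrasts list of `c(treatment, reference)` pairs; defaults to every
#'   non-reference condition against the reference, in order of appearance.
#' @return list of class `sample_design` with elements `condition_of`,
#'   `reference`, `treatments`, `contrasts` (named list).
#' @export
sample_design <- function(condition_of, reference, contrasts = NULL) {
  stopifnot(is.character(condition_of), !is.null(names(condition_of)))
  conds <- unique(unname(condition_of))
  if (!reference %in% conds)
    stop("reference condition '", reference, "' has no samples")
  treatments <- setdiff(conds, reference)
  if (is.null(contrasts))
    contrasts <- lapply(treatments, function(t) c(t, reference))
  if (!length(contrasts)) stop("design needs at least one contrast")
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% conds))
      stop("each contrast must be c(treatment, reference) over known conditions")
  }
  names(contrasts) <- vapply(contrasts, function(ct)
    paste0(ct[1], "_vs_", ct[2]), character(1))
  structure(
    list(condition_of = condition_of, reference = reference,
         treatments = treatments, contrasts = contrasts),
    class = "sample_design"
  )
}

#' Parse a STAR-style SJ.out.tab junction file (one sample)
#'
#' Columns: chrom, 1-based first intronic base, 1-based last intronic base,
#' strand code (0 undefined / 1 "+" / 2 "-"), intron motif, annotated flag,
#' unique reads, multi-mapped reads, maximum overhang. Only the unique-read
#' column is counted by default. Rows with strand code 0 are dropped unless
#' `exon_index` resolves the strand unambiguously (all annotated exons
#' adjacent to either intron boundary agree on one strand). Duplicate rows
#' for one junction are summed.
#'
#' @param path file path.
#' @param sample sample id to assign to the counts.
#' @param exon_index optional [exon_index()] used to resolve strand-code-0
#'   rows.
#' @param min_intron minimum intron length retained (nt).
#' @param use_multimapped also add the multi-mapped read column to the count.
#' @return a `junction_counts` data.frame.
#' @export
parse_star_sj <- function(path, sample, exon_index = NULL, min_intron = 20,
                          use_multimapped = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(junction_counts(character(), integer(), integer(), character(),
                           character(), integer()))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 7)) {
    stop("malformed SJ.out.tab row at line ", which(nf < 7)[1],
         " of ", path, " (expected >= 7 fields)")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  start1 <- suppressWarnings(as.integer(m[, 2]))
  end1 <- suppressWarnings(as.integer(m[, 3]))
  code <- suppressWarnings(as.integer(m[, 4]))
  uniq <- suppressWarnings(as.integer(m[, 7]))
  multi <- suppressWarnings(as.integer(m[, 8]))
  bad <- which(is.na(start1) | is.na(end1) | is.na(code) | is.na(uniq))
  if (length(bad))
    stop("malformed SJ.out.tab row at line ", bad[1], " of ", path)
  if (any(uniq < 0) || (use_multimapped && any(multi < 0, na.rm = TRUE)))
    stop("negative read count in ", path)
  count <- uniq + if (use_multimapped) ifelse(is.na(multi), 0L, multi) else 0L
  intron_start <- start1 - 1L
  intron_end <- end1
  strand <- c("0", "+", "-")[code + 1L]
  unresolved <- strand == "0"
  if (any(unresolved) && !is.null(exon_index)) {
    res <- resolve_strand(exon_index, intron_start[unresolved],
                          intron_end[unresolved])
    strand[unresolved][!is.na(res)] <- res[!is.na(res)]
  }
  keep <- strand %in% c("+", "-")
  if (any(!keep))
    message(sum(!keep), " junction(s) with unresolved strand dropped from ",
            basename(path))
  df <- data.frame(chrom = m[keep, 1], intron_start = intron_start[keep],
                   intron_end = intron_end[keep], strand = strand[keep],
                   sample = sample, count = count[keep],
                   stringsAsFactors = FALSE)
  df <- df[df$intron_end - df$intron_start >= min_intron, , drop = FALSE]
  df <- sum_duplicate_junctions(df)
  validate_junction_counts(df)
}

## collapse duplicate (chrom, start, end, strand, sample) rows by summing
sum_duplicate_junctions <- function(df) {
  if (!nrow(df)) return(df)
  key <- paste(df$chrom, df$intron_start, df$intron_end, df$strand, df$sample,
               sep = "\r")
  if (!anyDuplicated(key)) return(df)
  agg <- rowsum(df$count, key)
  first <- df[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(agg[match(
    paste(first$chrom, first$intron_start, first$intron_end, first$strand,
          first$sample, sep = "\r"), rownames(agg)), 1])
  rownames(first) <- NULL
  first
}

## strand of all annotated exons abutting either intron boundary, or NA
resolve_strand <- function(exon_index, intron_start, intron_end) {
  ex <- exon_index$exons
  vapply(seq_along(intron_start), function(i) {
    hit <- (ex$end == intron_start[i] | ex$start == intron_end[i])
    s <- unique(ex$strand[hit])
    if (length(s) == 1) s else NA_character_
  }, character(1))
}

#' Parse a BED12 junction file (one sample)
#'
#' Each record must have exactly two blocks flanking the intron; the score
#' field carries the read count. The intron is
#' `[chromStart + blockSizes[1], chromStart + blockStarts[2])`.
#'
#' @inheritParams parse_star_sj
#' @return a `junction_counts` data.frame.
#' @export
parse_junction_bed <- function(path, sample, min_intron = 20) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!length(gr)) {
    return(junction_counts(character(), integer(), integer(), character(),
                           character(), integer()))
  }
  blocks <- mcols(gr)$blocks
  if (is.null(blocks)) stop("BED junction file must be BED12 (blocks required)")
  nb <- lengths(blocks)
  if (any(nb != 2))
    stop("BED12 junction records must have exactly 2 blocks (record ",
         which(nb != 2)[1], ")")
  chrom_start <- GenomicRanges::start(gr) - 1L  # back to 0-based
  bl <- unlist(blocks)
  b1_end <- GenomicRanges::end(bl)[seq(1, length(bl), by = 2)]      # block1 size
  b2_start <- GenomicRanges::start(bl)[seq(2, length(bl), by = 2)]  # 1-based offset+1
  intron_start <- chrom_start + b1_end
  intron_end <- chrom_start + b2_start - 1L
  if (any(intron_end <= intron_start))
    stop("BED12 junction with non-positive intron length (record ",
         which(intron_end <= intron_start)[1], ")")
  strand <- as.character(strand(gr))
  if (any(strand == "*")) stop("BED12 junction records must be stranded")
  score <- mcols(gr)$score
  if (any(is.na(score) | score < 0)) stop("negative or missing junction score")
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   intron_start = as.integer(intron_start),
                   intron_end = as.integer(intron_end),
                   strand = strand, sample = sample,
                   count = as.integer(score), stringsAsFactors = FALSE)
  df <- df[df$intron_end - df$intron_start >= min_intron, , drop = FALSE]
  df <- sum_duplicate_junctions(df)
  validate_junction_counts(df)
}

#' Read / write the generic junction TSV dialect
#'
#' The package's canonical exchange format: a header line then columns
#' `chrom`, `intron_start` (0-based), `intron_end` (exclusive), `strand`,
#' `sample`, `count`. Round-trips bit-exactly.
#'
#' @param path file path.
#' @return `read_junction_tsv`: a `junction_counts` data.frame.
#' @export
read_junction_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "integer"))
  validate_junction_counts(df)
}

#' @rdname read_junction_tsv
#' @param counts a `junction_counts` data.frame.
#' @export
write_junction_tsv <- function(counts, path) {
  validate_junction_counts(as.data.frame(counts))
  write.table(counts[, c("chrom", "intron_start", "intron_end", "strand",
                         "sample", "count")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an exon annotation into a flat exon table
#'
#' GTF `exon` and `CDS` features (1-based inclusive, converted to 0-based
#' half-open) or BED12 transcripts (blocks become exons). The result is a
#' data.frame with columns `chrom`, `start`, `end`, `strand`, `type`
#' (`"exon"` or `"CDS"`), `transcript_id`, `gene_id`.
#'
#' @param path annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @return exon table data.frame.
#' @export
read_exon_annotation <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[mcols(gr)$type %in% c("exon", "CDS")]
    tx <- mcols(gr)$transcript_id
    if (is.null(tx) || anyNA(tx))
      stop("GTF exon/CDS feature without transcript_id")
    gene <- mcols(gr)$gene_id
    if (is.null(gene)) gene <- tx
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(strand(gr)),
                     type = as.character(mcols(gr)$type),
                     transcript_id = tx, gene_id = gene,
                     stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    name <- mcols(gr)$name
    if (is.null(name)) name <- paste0("tx", seq_along(gr))
    blocks <- mcols(gr)$blocks
    if (is.null(blocks)) {  # plain BED: whole record is one exon
      df <- data.frame(chrom = as.character(seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       strand = as.character(strand(gr)), type = "exon",
                       transcript_id = name, gene_id = name,
                       stringsAsFactors = FALSE)
    } else {
      rep_i <- rep(seq_along(gr), lengths(blocks))
      bl <- unlist(blocks)
      df <- data.frame(chrom = as.character(seqnames(gr))[rep_i],
                       start = GenomicRanges::start(gr)[rep_i] - 1L +
                         GenomicRanges::start(bl) - 1L,
                       end = GenomicRanges::start(gr)[rep_i] - 1L +
                         GenomicRanges::end(bl),
                       strand = as.character(strand(gr))[rep_i],
                       type = "exon", transcript_id = name[rep_i],
                       gene_id = name[rep_i], stringsAsFactors = FALSE)
    }
  }
  if (any(df$end <= df$start))
    stop("annotation exon with end <= start after coordinate conversion")
  ## deduplicate identical spans within one transcript
  df <- df[!duplicated(df[c("chrom", "start", "end", "strand", "type",
                            "transcript_id")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build an interval-queryable exon index
#'
#' Wraps the flat exon table in a `GRanges` (exon features only) for strand-
#' aware containment and overlap queries.
#'
#' @param exons exon table from [read_exon_annotation()] or
#'   [generate_reference()].
#' @return list of class `exon_index` with elements `exons` (the exon-feature
#'   subset of the table) and `gr` (its `GRanges`).
#' @export
exon_index <- function(exons) {
  ex <- exons[exons$type == "exon", , drop = FALSE]
  gr <- GRanges(ex$chrom, IRanges(ex$start + 1L, ex$end), strand = ex$strand)
  mcols(gr)$transcript_id <- ex$transcript_id
  mcols(gr)$gene_id <- ex$gene_id
  structure(list(exons = ex, gr = gr), class = "exon_index")
}

#' Containment query against an exon index
#'
#' Returns whether each query interval (0-based half-open, stranded) lies
#' entirely within a single annotated exon on the same chromosome and strand.
#'
#' @param idx an [exon_index()].
#' @param chrom,start,end,strand query intervals.
#' @return logical vector.
#' @export
exon_contains <- function(idx, chrom, start, end, strand) {
  if (!length(chrom)) return(logical(0))
  q <- GRanges(chrom, IRanges(start + 1L, end), strand = strand)
  hits <- findOverlaps(q, idx$gr, type = "within")
  out <- logical(length(q))
  out[unique(queryHits(hits))] <- TRUE
  out
}

#' Load a genome FASTA
#'
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet` named by the first word of each
#'   header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a genomic subsequence in transcript orientation
#'
#' @param genome a `DNAStringSet`.
#' @param chrom,start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"`; minus-strand sequences are
#'   reverse-complemented.
#' @return uppercase character string of length `end - start`.
#' @export
genome_subseq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- Biostrings::width(genome[chrom])
  if (start < 0 || end > L || end < start)
    stop("interval [", start, ", ", end, ") outside chromosome ", chrom,
         " (length ", L, ")")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}
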
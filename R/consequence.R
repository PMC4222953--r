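## mRNA-consequence classification: graft an event onto a host transcript,
## translate both isoforms, and classify the change as a 5'UTR change, an
## ORF change without a PTC, a PTC predicted to trigger NMD, a PTC escaping
## NMD, or a 3'UTR change.
##
## The NMD prediction uses the canonical boundary rule: a stop codon ending
## more than `nmd_rule_nt` (default 50) nucleotides upstream of the last
## exon-exon junction of its mRNA is predicted to trigger NMD.

#' Build transcript models from an exon table
#'
#' Groups exon and CDS features by transcript and records, per transcript,
#' its ordered genomic exon spans and the genomic position of the first CDS
#' base (transcript orientation). Transcripts whose CDS does not start with
#' ATG in the supplied genome raise a warning at load.
#'
#' @param exons exon table (see [read_exon_annotation()]).
#' @param genome optional `DNAStringSet` used to check the start codon.
#' @return named list of transcript models; each model is a list with
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `exons` (2-column matrix
#'   of 0-based half-open spans, ascending), `cds_start` / `cds_end`
#'   (genomic 0-based half-open CDS span, or NA for non-coding), and
#'   `cds_len` (spliced CDS length).
#' @export
transcript_models <- function(exons, genome = NULL) {
  sp <- split(exons, exons$transcript_id)
  models <- lapply(sp, function(df) {
    ex <- df[df$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- df[df$type == "CDS", , drop = FALSE]
    model <- list(
      transcript_id = df$transcript_id[1], gene_id = df$gene_id[1],
      chrom = df$chrom[1], strand = df$strand[1],
      exons = cbind(start = ex$start, end = ex$end),
      cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_integer_,
      cds_len = if (nrow(cds)) sum(cds$end - cds$start) else 0L
    )
    if (!is.null(genome) && nrow(cds)) {
      p5 <- cds5p_genomic(model)
      codon <- if (model$strand == "+")
        genome_subseq(genome, model$chrom, p5, p5 + 3L, "+")
      else genome_subseq(genome, model$chrom, p5 - 2L, p5 + 1L, "-")
      if (codon != "ATG")
        warning("transcript ", model$transcript_id,
                ": CDS does not start with ATG (", codon, ")")
    }
    model
  })
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  models
}

## genomic 0-based position of the first CDS base in transcript orientation
cds5p_genomic <- function(model) {
  if (is.na(model$cds_start)) return(NA_integer_)
  if (model$strand == "+") model$cds_start else model$cds_end - 1L
}

## map a genomic 0-based position (of a base) to 1-based mRNA coordinate
genomic_to_mrna <- function(exons, strand, gpos) {
  n <- nrow(exons)
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  offset <- 0L
  for (i in ord) {
    s <- exons[i, 1]; e <- exons[i, 2]
    if (gpos >= s && gpos < e) {
      within <- if (strand == "+") gpos - s else e - 1L - gpos
      return(offset + within + 1L)
    }
    offset <- offset + (e - s)
  }
  NA_integer_
}

## map a 1-based mRNA coordinate back to the genomic 0-based base position
mrna_to_genomic <- function(exons, strand, mpos) {
  n <- nrow(exons)
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  offset <- 0L
  for (i in ord) {
    len <- exons[i, 2] - exons[i, 1]
    if (mpos <= offset + len) {
      within <- mpos - offset - 1L
      return(if (strand == "+") exons[i, 1] + within
             else exons[i, 2] - 1L - within)
    }
    offset <- offset + len
  }
  NA_integer_
}

spliced_sequence <- function(model, genome) {
  ex <- model$exons
  ord <- if (model$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  paste(vapply(ord, function(i)
    genome_subseq(genome, model$chrom, ex[i, 1], ex[i, 2], model$strand),
    character(1)), collapse = "")
}

## 1-based mRNA coordinate of the last base before the final exon-exon
## junction (NA for single-exon transcripts)
last_junction_mrna <- function(model) {
  n <- nrow(model$exons)
  if (n < 2) return(NA_integer_)
  lens <- model$exons[, 2] - model$exons[, 1]
  ord <- if (model$strand == "+") seq_len(n) else rev(seq_len(n))
  sum(lens[ord[-n]])
}

#' Realize an event's two isoforms on a host transcript
#'
#' Finds the exon boundary of `transcript` that coincides with one of the
#' event's alternative sites (with the adjacent exon matching the shared
#' boundary) and builds the two transcript variants that use the upstream
#' and downstream alternative site respectively. All other exons are
#' unchanged.
#'
#' @param event one row of an event table.
#' @param transcript a transcript model from [transcript_models()].
#' @return list with `long`, `short` (transcript-model variants; the long
#'   isoform contains the extension region), `host_is_long` (whether the
#'   unmodified host equals the long variant), or `NULL` when no exon
#'   boundary of the transcript is compatible with the event.
#' @export
graft_event <- function(event, transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  if (n < 2 || transcript$chrom != event$chrom ||
      transcript$strand != event$strand) return(NULL)
  alt <- c(event$u_site, event$d_site)
  plus <- transcript$strand == "+"
  donor_side_varies <- xor(event$type == "A5C", !plus)
  ## on "+": A5C varies an exon end (next exon starts at the acceptor);
  ## A3C varies an exon start. On "-" genomic roles swap.
  hit <- NA_integer_
  if (donor_side_varies) {
    for (i in seq_len(n - 1)) {
      if (ex[i, 2] %in% alt && ex[i + 1, 1] == event$common_site) {
        hit <- i; break
      }
    }
  } else {
    for (i in 2:n) {
      if (ex[i, 1] %in% alt && ex[i - 1, 2] == event$common_site) {
        hit <- i; break
      }
    }
  }
  if (is.na(hit)) return(NULL)
  make_variant <- function(site) {
    v <- transcript
    if (donor_side_varies) v$exons[hit, 2] <- site else v$exons[hit, 1] <- site
    if (any(v$exons[, 2] <= v$exons[, 1])) return(NULL)
    v
  }
  long_site <- if (event$type == "A5C") event$d_site else event$u_site
  short_site <- if (event$type == "A5C") event$u_site else event$d_site
  long <- make_variant(long_site)
  short <- make_variant(short_site)
  if (is.null(long) || is.null(short)) return(NULL)
  host_site <- if (donor_side_varies) ex[hit, 2] else ex[hit, 1]
  list(long = long, short = short, host_is_long = host_site == long_site)
}

#' Position of the first in-frame stop codon
#'
#' Scans codons from the CDS start in the spliced mRNA sequence using the
#' standard genetic code and returns the 1-based mRNA coordinate of the last
#' base of the first stop codon (TAA/TAG/TGA), or `NA` when no in-frame stop
#' occurs before the mRNA end.
#'
#' @param mrna spliced mRNA sequence (character, DNA alphabet).
#' @param cds_start 1-based mRNA coordinate of the first CDS base.
#' @return integer mRNA coordinate or `NA`.
#' @export
translate_to_stop <- function(mrna, cds_start) {
  n <- nchar(mrna)
  if (is.na(cds_start) || cds_start < 1 || cds_start > n) return(NA_integer_)
  len <- n - cds_start + 1L
  len <- len - len %% 3L
  if (len < 3L) return(NA_integer_)
  orf <- Biostrings::DNAString(substr(mrna, cds_start, cds_start + len - 1L))
  aa <- as.character(Biostrings::translate(orf, if.fuzzy.codon = "X"))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0) return(NA_integer_)
  cds_start + 3L * as.integer(hit) - 1L
}

#' Classify the mRNA consequence of an isoform pair
#'
#' Compares the grafted long and short isoforms of an event against the host
#' (reference) isoform. If the extension region lies entirely 5' of the CDS
#' start the event changes the 5'UTR; entirely 3' of the reference stop, the
#' 3'UTR. Otherwise the altered isoform's stop is compared to the reference
#' stop: an earlier stop ending more than `nmd_rule_nt` nt upstream of the
#' altered mRNA's last exon-exon junction is `PTC_NMD`, an earlier stop
#' within that window (or in the last exon) is `PTC_escape`, and an
#' unchanged stop with preserved reading frame is `ORF_change_noPTC`.
#'
#' @param pair output of [graft_event()].
#' @param event the event row the pair was grafted from.
#' @param genome a `DNAStringSet`.
#' @param nmd_rule_nt NMD boundary-rule distance in nucleotides.
#' @return list with `category` (one of `UTR5_change`, `ORF_change_noPTC`,
#'   `PTC_NMD`, `PTC_escape`, `UTR3_change`, `unresolved`), `reason`,
#'   per-isoform stop positions (mRNA coordinates), the altered isoform's
#'   stop distance to its last exon-exon junction, and `nmd_rule_nt`.
#' @export
classify_consequence <- function(pair, event, genome, nmd_rule_nt = 50) {
  unresolved <- function(reason)
    list(category = "unresolved", reason = reason, stop_ref = NA_integer_,
         stop_alt = NA_integer_, dist_alt = NA_integer_,
         nmd_rule_nt = nmd_rule_nt)
  long <- pair$long; short <- pair$short
  if (is.na(long$cds_start)) return(unresolved("noncoding_host"))
  ref <- if (pair$host_is_long) long else short
  alt <- if (pair$host_is_long) short else long
  cds5 <- cds5p_genomic(ref)
  mrna_long <- spliced_sequence(long, genome)
  mrna_short <- spliced_sequence(short, genome)
  cds_long <- genomic_to_mrna(long$exons, long$strand, cds5)
  cds_short <- genomic_to_mrna(short$exons, short$strand, cds5)
  if (is.na(cds_long) || is.na(cds_short))
    return(unresolved("cds_start_outside_mrna"))
  ## extension span in the long isoform's mRNA (transcript orientation)
  ext_lo <- genomic_to_mrna(long$exons, long$strand, event$ext_start)
  ext_hi <- genomic_to_mrna(long$exons, long$strand, event$ext_end - 1L)
  ext_m <- sort(c(ext_lo, ext_hi))
  if (anyNA(ext_m)) return(unresolved("extension_outside_mrna"))
  if (ext_m[2] < cds_long) {
    return(list(category = "UTR5_change", reason = "",
                stop_ref = NA_integer_, stop_alt = NA_integer_,
                dist_alt = NA_integer_, nmd_rule_nt = nmd_rule_nt))
  }
  stop_long <- translate_to_stop(mrna_long, cds_long)
  stop_short <- translate_to_stop(mrna_short, cds_short)
  stop_ref <- if (pair$host_is_long) stop_long else stop_short
  stop_alt <- if (pair$host_is_long) stop_short else stop_long
  if (is.na(stop_ref)) return(unresolved("nonstop_reference"))
  ## extension entirely 3' of the reference stop (compared in the long mRNA)
  stop_ref_g <- mrna_to_genomic(ref$exons, ref$strand, stop_ref)
  stop_ref_in_long <- genomic_to_mrna(long$exons, long$strand, stop_ref_g)
  if (!is.na(stop_ref_in_long) && ext_m[1] > stop_ref_in_long) {
    return(list(category = "UTR3_change", reason = "",
                stop_ref = stop_ref, stop_alt = stop_alt,
                dist_alt = NA_integer_, nmd_rule_nt = nmd_rule_nt))
  }
  if (is.na(stop_alt)) return(unresolved("nonstop_isoform"))
  stop_alt_g <- mrna_to_genomic(alt$exons, alt$strand, stop_alt)
  ext_len <- event$ext_end - event$ext_start
  lj_alt <- last_junction_mrna(alt)
  dist_alt <- if (is.na(lj_alt)) NA_integer_ else lj_alt - stop_alt
  if (stop_alt_g == stop_ref_g) {
    if (ext_len %% 3L == 0L)
      return(list(category = "ORF_change_noPTC", reason = "",
                  stop_ref = stop_ref, stop_alt = stop_alt,
                  dist_alt = dist_alt, nmd_rule_nt = nmd_rule_nt))
    return(unresolved("frameshift_same_stop"))
  }
  ## is the altered stop earlier in transcript orientation than the
  ## reference stop? compare both in the altered mRNA's coordinates
  stop_ref_in_alt <- genomic_to_mrna(alt$exons, alt$strand, stop_ref_g)
  earlier <- if (!is.na(stop_ref_in_alt)) stop_alt < stop_ref_in_alt else {
    ## reference stop position is not part of the altered mRNA (it lies in
    ## the extension): compare genomically in transcript orientation
    if (alt$strand == "+") stop_alt_g < stop_ref_g else stop_alt_g > stop_ref_g
  }
  if (!earlier) return(unresolved("stop_downstream_of_reference"))
  category <- if (!is.na(dist_alt) && dist_alt > nmd_rule_nt) "PTC_NMD"
              else "PTC_escape"
  list(category = category, reason = "", stop_ref = stop_ref,
       stop_alt = stop_alt, dist_alt = dist_alt, nmd_rule_nt = nmd_rule_nt)
}

## host transcript: CDS-bearing, compatible with the event, longest spliced
## CDS, ties broken lexicographically by transcript id
select_host <- function(event, models) {
  best <- NULL; best_pair <- NULL; saw_compatible <- FALSE
  ids <- sort(names(models))
  for (id in ids) {
    m <- models[[id]]
    pair <- graft_event(event, m)
    if (is.null(pair)) next
    saw_compatible <- TRUE
    if (m$cds_len == 0L) next
    if (is.null(best) || m$cds_len > best$cds_len) {
      best <- m; best_pair <- pair
    }
  }
  list(model = best, pair = best_pair, saw_compatible = saw_compatible)
}

#' Classify consequences for a table of events
#'
#' For each retained event, selects the host transcript (longest annotated
#' CDS among compatible transcripts, ties broken lexicographically), grafts
#' the two isoforms and classifies the consequence.
#'
#' @param events event table (rows with `retained == FALSE` are skipped).
#' @param models transcript models from [transcript_models()].
#' @param genome a `DNAStringSet`.
#' @param nmd_rule_nt NMD boundary-rule distance.
#' @return data.frame with `event_id`, `host_transcript`, `category`,
#'   `reason`, `stop_ref`, `stop_alt`, `dist_alt`, `nmd_rule_nt`.
#' @export
call_consequences <- function(events, models, genome, nmd_rule_nt = 50) {
  use <- if ("retained" %in% names(events)) which(events$retained)
         else seq_len(nrow(events))
  rows <- lapply(use, function(i) {
    ev <- events[i, ]
    sel <- select_host(ev, models)
    if (is.null(sel$model)) {
      reason <- if (sel$saw_compatible) "noncoding_host" else
        "no_host_transcript"
      return(data.frame(event_id = ev$event_id, host_transcript = NA_character_,
                        category = "unresolved", reason = reason,
                        stop_ref = NA_integer_, stop_alt = NA_integer_,
                        dist_alt = NA_integer_, nmd_rule_nt = nmd_rule_nt,
                        stringsAsFactors = FALSE))
    }
    cc <- classify_consequence(sel$pair, ev, genome, nmd_rule_nt)
    data.frame(event_id = ev$event_id,
               host_transcript = sel$model$transcript_id,
               category = cc$category, reason = cc$reason,
               stop_ref = cc$stop_ref, stop_alt = cc$stop_alt,
               dist_alt = cc$dist_alt, nmd_rule_nt = nmd_rule_nt,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(event_id = character(), host_transcript = character(),
                      category = character(), reason = character(),
                      stop_ref = integer(), stop_alt = integer(),
                      dist_alt = integer(), nmd_rule_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
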
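## Candidate A5C/A3C event enumeration and cassette depletion.
##
## An A5C event is a pair of junctions sharing (chrom, strand, acceptor) with
## distinct donors; an A3C event shares the donor and differs at the
## acceptor. The upstream/downstream labels follow transcript orientation:
## for A5C the u5'ss is intron-distal (longer intron), for A3C the u3'ss is
## intron-proximal (shorter intron). The extension region between the two
## alternative sites is exonic only in the long isoform, which is always the
## junction with the shorter intron.

junction_boundaries <- function(j) {
  donor <- ifelse(j$strand == "+", j$intron_start, j$intron_end)
  acceptor <- ifelse(j$strand == "+", j$intron_end, j$intron_start)
  list(donor = donor, acceptor = acceptor)
}

enumerate_pairs <- function(junctions, type) {
  j <- unique(as.data.frame(junctions)[c("chrom", "intron_start",
                                         "intron_end", "strand")])
  if (!nrow(j)) return(empty_events())
  rownames(j) <- NULL
  b <- junction_boundaries(j)
  if (type == "A5C") {
    shared <- b$acceptor; alt <- b$donor
  } else {
    shared <- b$donor; alt <- b$acceptor
  }
  key <- paste(j$chrom, j$strand, shared, sep = "\r")
  groups <- split(seq_len(nrow(j)), key)
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) return(empty_events())
  rows <- lapply(groups, function(ix) {
    pr <- combn(ix[order(alt[ix])], 2)
    i1 <- pr[1, ]; i2 <- pr[2, ]
    strand <- j$strand[i1]
    common <- shared[i1]
    a1 <- alt[i1]; a2 <- alt[i2]   # a1 < a2 genomically
    ## transcript-orientation u/d assignment:
    ## A5C: u = intron-distal donor (longer intron); A3C: u = intron-proximal
    ## acceptor (shorter intron). On "+" both reduce to u = lower coordinate
    ## for A5C / lower for A3C; on "-" the roles mirror.
    if (type == "A5C") {
      u <- ifelse(strand == "+", a1, a2)
      d <- ifelse(strand == "+", a2, a1)
    } else {
      u <- ifelse(strand == "+", a1, a2)
      d <- ifelse(strand == "+", a2, a1)
    }
    data.frame(chrom = j$chrom[i1], strand = strand, common_site = common,
               u_site = u, d_site = d, stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ## long isoform = shorter intron: site d for A5C, site u for A3C
  long_site <- if (type == "A5C") ev$d_site else ev$u_site
  short_site <- if (type == "A5C") ev$u_site else ev$d_site
  ev$type <- type
  ev$ext_start <- pmin(ev$u_site, ev$d_site)
  ev$ext_end <- pmax(ev$u_site, ev$d_site)
  ev$long_intron_start <- pmin(ev$common_site, long_site)
  ev$long_intron_end <- pmax(ev$common_site, long_site)
  ev$short_intron_start <- pmin(ev$common_site, short_site)
  ev$short_intron_end <- pmax(ev$common_site, short_site)
  ev$event_id <- sprintf("%s:%s:%s:%d:%d:%d", ev$type, ev$chrom, ev$strand,
                         ev$common_site, ev$u_site, ev$d_site)
  ev <- ev[order(ev$chrom, ev$ext_start, ev$ext_end, ev$common_site), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev[, event_columns()]
}

event_columns <- function() {
  c("event_id", "type", "chrom", "strand", "common_site", "u_site", "d_site",
    "ext_start", "ext_end", "long_intron_start", "long_intron_end",
    "short_intron_start", "short_intron_end")
}

empty_events <- function() {
  ev <- data.frame(event_id = character(), type = character(),
                   chrom = character(), strand = character(),
                   common_site = integer(), u_site = integer(),
                   d_site = integer(), ext_start = integer(),
                   ext_end = integer(), long_intron_start = integer(),
                   long_intron_end = integer(),
                   short_intron_start = integer(),
                   short_intron_end = integer(), stringsAsFactors = FALSE)
  ev
}

#' Enumerate candidate alternate splice-site events
#'
#' All unordered pairs of junctions sharing one boundary on the same
#' chromosome and strand: the acceptor for A5C events (distinct donors), the
#' donor for A3C events (distinct acceptors). With k alternative sites at a
#' shared boundary, all k(k-1)/2 pairs are emitted.
#'
#' @param junctions a junction table (e.g. a `junction_counts` data.frame;
#'   only `chrom`, `intron_start`, `intron_end`, `strand` are used and
#'   duplicates are ignored).
#' @return event data.frame with one row per candidate pair. `u_site` /
#'   `d_site` are the upstream/downstream alternative boundaries in
#'   transcript orientation; `ext_start`/`ext_end` the genomic extension
#'   region between them; `long_intron_*` the intron of the long (extension-
#'   containing) isoform.
#' @export
enumerate_a5c <- function(junctions) enumerate_pairs(junctions, "A5C")

#' @rdname enumerate_a5c
#' @export
enumerate_a3c <- function(junctions) enumerate_pairs(junctions, "A3C")

#' Deplete cassette-exon look-alike events
#'
#' A cassette exon's skipping junction pairs with an inclusion junction at a
#' shared boundary and mimics an A5C/A3C event, but its inter-site region
#' spans an intron. The default rule retains an event only when the full
#' extension region is contained in a single annotated exon on the same
#' strand (so the inter-site region is annotated-exonic). The looser
#' `"boundary"` rule only requires the intron-distal alternative site to fall
#' inside an annotated exon.
#'
#' @param events event table from [enumerate_a5c()] / [enumerate_a3c()].
#' @param idx an [exon_index()].
#' @param rule `"containment"` (default) or `"boundary"`.
#' @return the event table with logical `retained` and character `reason`
#'   columns added (`reason == "cassette_like"` for discarded events).
#' @export
deplete_cassette <- function(events, idx, rule = c("containment", "boundary")) {
  rule <- match.arg(rule)
  if (!nrow(events)) {
    events$retained <- logical(0); events$reason <- character(0)
    return(events)
  }
  if (rule == "containment") {
    ok <- exon_contains(idx, events$chrom, events$ext_start, events$ext_end,
                        events$strand)
  } else {
    ## intron-distal site: u for A5C, d for A3C; test the 1-nt exonic base
    ## adjacent to the boundary on the extension side
    distal <- ifelse(events$type == "A5C", events$u_site, events$d_site)
    inner <- ifelse(distal == events$ext_start, distal, distal - 1L)
    ok <- exon_contains(idx, events$chrom, inner, inner + 1L, events$strand)
  }
  events$retained <- ok
  events$reason <- ifelse(ok, "", "cassette_like")
  events
}

#' Attach gene ids to events
#'
#' Gene ids of all annotated exons touching the event's shared boundary,
#' lexicographically sorted and comma-joined; events with no annotation get
#' an empty string and `unassigned = TRUE`.
#'
#' @inheritParams deplete_cassette
#' @return event table with `gene_ids` and `unassigned` columns.
#' @export
annotate_event_gene <- function(events, idx) {
  if (!nrow(events)) {
    events$gene_ids <- character(0); events$unassigned <- logical(0)
    return(events)
  }
  q <- GRanges(events$chrom,
               IRanges(pmax(events$common_site, 1L), events$common_site + 1L),
               strand = events$strand)
  ## events on chromosomes absent from the annotation simply get no hits
  hits <- suppressWarnings(findOverlaps(q, idx$gr))
  ids <- rep("", nrow(events))
  if (length(hits)) {
    by_ev <- split(mcols(idx$gr)$gene_id[subjectHits(hits)], queryHits(hits))
    ids[as.integer(names(by_ev))] <-
      vapply(by_ev, function(g) paste(sort(unique(g)), collapse = ","),
             character(1))
  }
  events$gene_ids <- ids
  events$unassigned <- !nzchar(ids)
  events
}
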
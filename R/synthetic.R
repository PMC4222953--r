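## Synthetic reference and junction-count generator.
##
## Emulates the statistical structure of a knockdown RNA-seq study of
## alternate splice-site choice: three-exon genes whose middle exon carries
## an A5C (or whose third exon carries an A3C), a control condition plus two
## knockdown conditions with condition-dependent psi for regulated classes,
## cassette-exon decoy genes whose skipping junction mimics an A5C/A3C pair,
## pyrimidine-motif-enriched extensions for class-1 genes, and donor 9-mers
## planted from the bundled frequency matrix with a positive strength
## asymmetry (delta_S > 0) for class 1. One gene per synthetic chromosome,
## strands alternating, everything deterministic under the config seed.

#' Synthetic-study configuration
#'
#' Defaults encode the emulated study design: conditions `control`, `kd1`,
#' `kd2` with one replicate each and the contrasts kd1-vs-control and
#' kd2-vs-control; class-1 genes switch psi(long) from 10% in control to 40%
#' in both knockdowns, class-2 genes mirror (40% to 10%), null genes draw a
#' constant psi from U[10, 90]; 200 reads per event per condition; class-1
#' extensions carry the pyrimidine motif set at an expected 0.08 per-nt
#' density versus a 0.01 background.
#'
#' @param n_class1,n_class2,n_null numbers of A5C genes per regulatory class.
#' @param n_cassette number of cassette-exon decoy genes.
#' @param n_a3c_class1,n_a3c_null numbers of A3C genes (regulated like class
#'   1 / unregulated).
#' @param exon_len,intron_len,ext_len min/max lengths (nt) for exons,
#'   introns and the extension region.
#' @param motif_rate_class1,motif_rate_background expected per-nt motif
#'   density of class-1 versus other extensions.
#' @param psi_class1,psi_class2 named psi(long) percentages per condition.
#' @param psi_null_range range of the per-gene constant null psi.
#' @param depth reads per event per condition per replicate.
#' @param replicates replicates per condition.
#' @param seed mandatory integer seed; reference generation uses `seed` and
#'   count simulation `seed + 1`, so counts can be re-simulated on a fixed
#'   reference.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_class1 = 50, n_class2 = 50, n_null = 100,
                         n_cassette = 50, n_a3c_class1 = 0, n_a3c_null = 0,
                         exon_len = c(100, 160), intron_len = c(120, 200),
                         ext_len = c(60, 300),
                         motif_rate_class1 = 0.08,
                         motif_rate_background = 0.01,
                         psi_class1 = c(control = 10, kd1 = 40, kd2 = 40),
                         psi_class2 = c(control = 40, kd1 = 10, kd2 = 10),
                         psi_null_range = c(10, 90),
                         depth = 200, replicates = 1, seed = 1) {
  cfg <- list(n_class1 = n_class1, n_class2 = n_class2, n_null = n_null,
              n_cassette = n_cassette, n_a3c_class1 = n_a3c_class1,
              n_a3c_null = n_a3c_null, exon_len = exon_len,
              intron_len = intron_len, ext_len = ext_len,
              motif_rate_class1 = motif_rate_class1,
              motif_rate_background = motif_rate_background,
              psi_class1 = psi_class1, psi_class2 = psi_class2,
              psi_null_range = psi_null_range, depth = depth,
              replicates = replicates, seed = seed,
              conditions = c("control", "kd1", "kd2"), reference = "control")
  counts <- unlist(cfg[c("n_class1", "n_class2", "n_null", "n_cassette",
                         "n_a3c_class1", "n_a3c_null")])
  if (any(counts < 0)) stop("gene counts must be >= 0")
  if (cfg$ext_len[1] < 4) stop("extension length must be >= 4 nt")
  if (cfg$depth < 1) stop("depth must be >= 1")
  if (cfg$replicates < 1) stop("replicates must be >= 1")
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  psis <- c(cfg$psi_class1, cfg$psi_class2, cfg$psi_null_range)
  if (any(psis < 0 | psis > 100)) stop("psi values must lie in [0, 100]")
  structure(cfg, class = "synth_config")
}

## base composition achieving an expected per-nt density `rate` of the
## 4-motif pyrimidine set: each motif is a fixed C/T word, so
## rate = 4 * p^4 with p = P(C) = P(T)
pyrimidine_composition <- function(rate) {
  p <- (rate / 4)^(1 / 4)
  c(A = (1 - 2 * p) / 2, C = p, G = (1 - 2 * p) / 2, T = p)
}

random_bases <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## draw a donor 9-mer from the matrix; +1/+2 forced to GT and the exonic
## triplet may not be a stop codon (keeps ORF scrubbing conflict-free)
sample_donor_9mer <- function(pwm) {
  repeat {
    b <- vapply(1:9, function(i)
      sample(colnames(pwm), 1, prob = pwm[i, ]), character(1))
    b[4] <- "G"; b[5] <- "T"
    if (!paste(b[1:3], collapse = "") %in% STOP_CODONS)
      return(paste(b, collapse = ""))
  }
}

mirror_interval <- function(L, s, e) c(L - e, L - s)

flip_strand <- function(s) ifelse(s == "+", "-", "+")

## --- per-gene builders (all on a "+" template; flipped afterwards) -------

## Recode in-frame stop codons of the short-isoform ORF and plant ATG and a
## terminal TAA. `exons` are the short isoform's spans; `protected` are
## genomic positions that must not change (planted donor triplets).
scrub_orf <- function(seq_chars, exons, protected, cds_offset = 10L,
                      stop_into_last = 30L) {
  g2m <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, 1], exons[i, 2] - 1L)))  # mRNA index -> genomic 0-based
  mlen <- length(g2m)
  lens <- exons[, 2] - exons[, 1]
  last_junction <- sum(lens[-length(lens)])
  cds1 <- cds_offset + 1L                     # 1-based mRNA coord of the A
  ## terminal stop: first in-frame codon start >= last_junction + stop_into_last
  target <- last_junction + stop_into_last
  stop1 <- cds1 + 3L * ceiling((target - cds1) / 3)
  if (stop1 + 2L > mlen) stop("synthetic exon 3 too short for the ORF layout")
  set_base <- function(mpos, base) seq_chars[g2m[mpos] + 1L] <<- base
  set_base(cds1, "A"); set_base(cds1 + 1L, "T"); set_base(cds1 + 2L, "G")
  i <- cds1 + 3L
  while (i < stop1) {
    cod <- paste(seq_chars[g2m[c(i, i + 1L, i + 2L)] + 1L], collapse = "")
    if (cod %in% STOP_CODONS) {
      free <- which(!(g2m[c(i, i + 1L, i + 2L)] %in% protected))
      if (length(free)) set_base(i + free[1] - 1L, "C")
      ## a fully protected stop codon cannot occur: planted exonic triplets
      ## are rejected when they form a stop
    }
    i <- i + 3L
  }
  set_base(stop1, "T"); set_base(stop1 + 1L, "A"); set_base(stop1 + 2L, "A")
  list(seq_chars = seq_chars,
       cds_start_g = g2m[cds1], cds_end_g = g2m[stop1 + 2L] + 1L)
}

rand_len <- function(range) sample(range[1]:range[2], 1)

build_alt_gene <- function(gene_id, chrom, class, event_type, cfg, pwm) {
  e1 <- rand_len(cfg$exon_len); e2 <- rand_len(cfg$exon_len)
  e3 <- rand_len(cfg$exon_len)
  i1 <- rand_len(cfg$intron_len); i2 <- rand_len(cfg$intron_len)
  L <- rand_len(cfg$ext_len)
  pad <- 50L
  motif_rate <- if (class == "class1") cfg$motif_rate_class1
                else cfg$motif_rate_background
  ext_comp <- pyrimidine_composition(motif_rate)
  if (event_type == "A5C") {
    s1 <- pad; e1e <- s1 + e1
    s2 <- e1e + i1
    u_site <- s2 + e2          # short middle-exon donor
    d_site <- u_site + L       # long middle-exon donor
    s3 <- d_site + i2
    e3e <- s3 + e3
    clen <- e3e + pad
    ext <- c(u_site, d_site)
    short_mid <- c(s2, u_site); long_mid <- c(s2, d_site)
    exons_short <- rbind(c(s1, e1e), short_mid, c(s3, e3e))
    exons_long <- rbind(c(s1, e1e), long_mid, c(s3, e3e))
    common <- s3
    short_intron <- c(u_site, s3); long_intron <- c(d_site, s3)
  } else {  # A3C: third exon's acceptor varies
    s1 <- pad; e1e <- s1 + e1
    s2 <- e1e + i1; e2e <- s2 + e2
    u_site <- e2e + i2         # long third-exon acceptor (intron-proximal)
    d_site <- u_site + L       # short third-exon acceptor (intron-distal)
    e3e <- d_site + e3
    clen <- e3e + pad
    ext <- c(u_site, d_site)
    exons_short <- rbind(c(s1, e1e), c(s2, e2e), c(d_site, e3e))
    exons_long <- rbind(c(s1, e1e), c(s2, e2e), c(u_site, e3e))
    common <- e2e
    short_intron <- c(e2e, d_site); long_intron <- c(e2e, u_site)
  }
  seq_chars <- random_bases(clen)
  ## extension composition (class-dependent)
  seq_chars[(ext[1] + 1L):ext[2]] <- random_bases(L, ext_comp)
  ## splice signals of the constitutive intron(s)
  plant <- function(pos0, word)
    seq_chars[(pos0 + 1L):(pos0 + nchar(word))] <<-
      strsplit(word, "")[[1]]
  plant(e1e, "GT"); plant(s2 - 2L, "AG")
  protected <- integer(0)
  if (event_type == "A5C") {
    u9 <- sample_donor_9mer(pwm)
    if (class == "class1") {
      d9 <- sample_donor_9mer(pwm)
      ## class 1: the downstream donor is the stronger site by construction
      su <- score_donor(u9, pwm); sd <- score_donor(d9, pwm)
      while (su == sd) { d9 <- sample_donor_9mer(pwm); sd <- score_donor(d9, pwm) }
      if (su > sd) { tmp <- u9; u9 <- d9; d9 <- tmp }
    } else {
      d9 <- sample_donor_9mer(pwm)
    }
    plant(u_site - 3L, u9)
    plant(d_site - 3L, d9)
    plant(s3 - 2L, "AG")
    protected <- (u_site - 3L):(u_site - 1L)   # exonic triplet of the u donor
  } else {
    d9mer <- sample_donor_9mer(pwm)  # single (shared) donor of intron 2
    plant(e2e - 3L, d9mer)
    plant(u_site - 2L, "AG")
    plant(d_site - 2L, "AG")
    protected <- (e2e - 3L):(e2e - 1L)
    u9 <- NA_character_; d9 <- NA_character_
  }
  ## reference ORF on the short isoform
  sc <- scrub_orf(seq_chars, exons_short, protected)
  seq_chars <- sc$seq_chars
  ## psi per condition
  psi <- switch(class,
    class1 = cfg$psi_class1,
    class2 = cfg$psi_class2,
    null = setNames(rep(runif(1, cfg$psi_null_range[1],
                              cfg$psi_null_range[2]), 3), cfg$conditions))
  ## annotation rows: t1 = short isoform (CDS-bearing reference), t2 = long
  mk_exons <- function(tx, spans, cds = NULL) {
    rows <- data.frame(chrom = chrom, start = spans[, 1], end = spans[, 2],
                       strand = "+", type = "exon",
                       transcript_id = tx, gene_id = gene_id,
                       stringsAsFactors = FALSE)
    if (!is.null(cds)) {
      for (i in seq_len(nrow(spans))) {
        cs <- max(spans[i, 1], cds[1]); ce <- min(spans[i, 2], cds[2])
        if (ce > cs)
          rows <- rbind(rows, data.frame(chrom = chrom, start = cs, end = ce,
                                         strand = "+", type = "CDS",
                                         transcript_id = tx,
                                         gene_id = gene_id,
                                         stringsAsFactors = FALSE))
      }
    }
    rows
  }
  exons <- rbind(
    mk_exons(paste0(gene_id, ".t1"), exons_short,
             c(sc$cds_start_g, sc$cds_end_g)),
    mk_exons(paste0(gene_id, ".t2"), exons_long)
  )
  junctions <- data.frame(
    chrom = chrom,
    intron_start = c(e1e, long_intron[1], short_intron[1]),
    intron_end = c(s2, long_intron[2], short_intron[2]),
    strand = "+", role = c("constitutive", "long", "short"),
    gene_id = gene_id, stringsAsFactors = FALSE)
  ext_seq <- paste(seq_chars[(ext[1] + 1L):ext[2]], collapse = "")
  truth <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = "+", event_type = event_type,
    class = class, psi_control = unname(psi["control"]),
    psi_kd1 = unname(psi["kd1"]), psi_kd2 = unname(psi["kd2"]),
    common_site = common, u_site = u_site, d_site = d_site,
    ext_start = ext[1], ext_end = ext[2], ext_len = L,
    motif_count = count_motifs(ext_seq),
    u_9mer = u9, d_9mer = d9,
    S_u = if (is.na(u9)) NA_real_ else score_donor(u9, pwm),
    S_d = if (is.na(d9)) NA_real_ else score_donor(d9, pwm),
    stringsAsFactors = FALSE)
  truth$delta_S <- truth$S_d - truth$S_u
  list(seq = seq_chars, exons = exons, junctions = junctions, truth = truth)
}

build_decoy_gene <- function(gene_id, chrom, cfg, pwm) {
  e1 <- rand_len(cfg$exon_len); e2 <- rand_len(cfg$exon_len)
  e3 <- rand_len(cfg$exon_len)
  i1 <- rand_len(cfg$intron_len); i2 <- rand_len(cfg$intron_len)
  pad <- 50L
  s1 <- pad; e1e <- s1 + e1
  s2 <- e1e + i1; e2e <- s2 + e2
  s3 <- e2e + i2; e3e <- s3 + e3
  clen <- e3e + pad
  seq_chars <- random_bases(clen)
  plant <- function(pos0, word)
    seq_chars[(pos0 + 1L):(pos0 + nchar(word))] <<- strsplit(word, "")[[1]]
  plant(e1e - 3L, sample_donor_9mer(pwm)); plant(s2 - 2L, "AG")
  plant(e2e - 3L, sample_donor_9mer(pwm)); plant(s3 - 2L, "AG")
  spans <- rbind(c(s1, e1e), c(s2, e2e), c(s3, e3e))
  exons <- data.frame(chrom = chrom, start = spans[, 1], end = spans[, 2],
                      strand = "+", type = "exon",
                      transcript_id = paste0(gene_id, ".t1"),
                      gene_id = gene_id, stringsAsFactors = FALSE)
  junctions <- data.frame(
    chrom = chrom, intron_start = c(e1e, e2e, e1e),
    intron_end = c(s2, s3, s3), strand = "+",
    role = c("incl1", "incl2", "skip"), gene_id = gene_id,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = "+", event_type = "cassette",
    class = "decoy", psi_control = 50, psi_kd1 = 50, psi_kd2 = 50,
    common_site = NA_integer_, u_site = NA_integer_, d_site = NA_integer_,
    ext_start = NA_integer_, ext_end = NA_integer_, ext_len = NA_integer_,
    motif_count = NA_integer_, u_9mer = NA_character_,
    d_9mer = NA_character_, S_u = NA_real_, S_d = NA_real_,
    delta_S = NA_real_, stringsAsFactors = FALSE)
  list(seq = seq_chars, exons = exons, junctions = junctions, truth = truth)
}

## mirror one built gene onto the "-" strand of its chromosome
flip_gene <- function(g) {
  L <- length(g$seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  g$seq <- unname(comp[rev(g$seq)])
  flip_cols <- function(df, scol, ecol) {
    new_s <- L - df[[ecol]]; new_e <- L - df[[scol]]
    df[[scol]] <- new_s; df[[ecol]] <- new_e
    df
  }
  g$exons <- flip_cols(g$exons, "start", "end")
  g$exons$strand <- "-"
  g$junctions <- flip_cols(g$junctions, "intron_start", "intron_end")
  g$junctions$strand <- "-"
  tr <- g$truth
  tr$strand <- "-"
  for (col in c("common_site", "u_site", "d_site"))
    tr[[col]] <- ifelse(is.na(tr[[col]]), tr[[col]], L - tr[[col]])
  if (!is.na(tr$ext_start)) {
    new <- mirror_interval(L, tr$ext_start, tr$ext_end)
    tr$ext_start <- new[1]; tr$ext_end <- new[2]
  }
  g$truth <- tr
  g
}

#' Generate a synthetic reference (genome, annotation, truth)
#'
#' One gene per chromosome; strands alternate. Regulated and null A5C/A3C
#' genes are annotated with both isoform variants of the alternative exon
#' (so cassette depletion retains them); decoy genes carry a skippable
#' internal exon whose skipping junction shares a boundary with an
#' inclusion junction. Deterministic under `config$seed`.
#'
#' @param config a [synth_config()].
#' @param pwm donor frequency matrix used for planting (and scoring the
#'   truth records).
#' @return list of class `synth_reference`: `genome` (`DNAStringSet`),
#'   `exons` (annotation table), `junctions` (true junction table with
#'   roles), `truth` (one row per gene), `config`.
#' @export
generate_reference <- function(config, pwm = donor_pwm_default()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  plan <- data.frame(
    class = rep(c("class1", "class2", "null", "decoy", "class1", "null"),
                c(config$n_class1, config$n_class2, config$n_null,
                  config$n_cassette, config$n_a3c_class1, config$n_a3c_null)),
    event_type = rep(c("A5C", "A5C", "A5C", "cassette", "A3C", "A3C"),
                     c(config$n_class1, config$n_class2, config$n_null,
                       config$n_cassette, config$n_a3c_class1,
                       config$n_a3c_null)),
    stringsAsFactors = FALSE)
  if (!nrow(plan)) stop("config generates no genes")
  plan$gene_id <- sprintf("g%04d", seq_len(nrow(plan)))
  plan$chrom <- paste0("chr_", plan$gene_id)
  plan$strand <- rep(c("+", "-"), length.out = nrow(plan))
  genes <- lapply(seq_len(nrow(plan)), function(i) {
    g <- if (plan$event_type[i] == "cassette")
      build_decoy_gene(plan$gene_id[i], plan$chrom[i], config, pwm)
    else build_alt_gene(plan$gene_id[i], plan$chrom[i], plan$class[i],
                        plan$event_type[i], config, pwm)
    if (plan$strand[i] == "-") g <- flip_gene(g)
    g
  })
  genome <- Biostrings::DNAStringSet(
    vapply(genes, function(g) paste(g$seq, collapse = ""), character(1)))
  names(genome) <- plan$chrom
  out <- list(
    genome = genome,
    exons = do.call(rbind, lapply(genes, `[[`, "exons")),
    junctions = do.call(rbind, lapply(genes, `[[`, "junctions")),
    truth = do.call(rbind, lapply(genes, `[[`, "truth")),
    config = config)
  rownames(out$exons) <- rownames(out$junctions) <- rownames(out$truth) <- NULL
  class(out) <- "synth_reference"
  out
}

#' Simulate junction read counts over a synthetic reference
#'
#' Per event, condition and replicate, the long-isoform count is drawn as
#' Binomial(depth, psi/100) and the short isoform takes the remainder, so
#' `n_long + n_short = depth` exactly. Decoy genes emit inclusion and
#' skipping junction counts the same way at constant 50% inclusion.
#' Constitutive junctions receive the full depth. Uses `config$seed + 1` so
#' counts can be re-simulated on a fixed reference.
#'
#' @param ref a [generate_reference()] result.
#' @param config optionally override the reference's config (e.g. depth).
#' @return list of class `synth_counts`: `counts` (a `junction_counts`
#'   data.frame over all samples), `design` (a [sample_design()]), `samples`.
#' @export
simulate_counts <- function(ref, config = ref$config) {
  set.seed(config$seed + 1L)
  conds <- config$conditions
  samples <- as.vector(t(outer(conds, seq_len(config$replicates),
                               function(c, r) paste0(c, "_r", r))))
  cond_of <- setNames(rep(conds, each = config$replicates), samples)
  depth <- config$depth
  rows <- vector("list", nrow(ref$truth))
  jx <- ref$junctions
  for (i in seq_len(nrow(ref$truth))) {
    tr <- ref$truth[i, ]
    gj <- jx[jx$gene_id == tr$gene_id, , drop = FALSE]
    psi <- c(control = tr$psi_control, kd1 = tr$psi_kd1, kd2 = tr$psi_kd2)
    gene_rows <- list()
    for (s in samples) {
      p <- psi[[cond_of[[s]]]] / 100
      n_long <- rbinom(1, depth, p)
      n_short <- depth - n_long
      if (tr$event_type == "cassette") {
        counts <- setNames(c(n_short, n_short, n_long),
                           c("incl1", "incl2", "skip"))
      } else {
        counts <- setNames(c(depth, n_long, n_short),
                           c("constitutive", "long", "short"))
      }
      gene_rows[[s]] <- data.frame(
        chrom = gj$chrom, intron_start = gj$intron_start,
        intron_end = gj$intron_end, strand = gj$strand, sample = s,
        count = as.integer(counts[gj$role]), stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, gene_rows)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  structure(list(counts = validate_junction_counts(counts),
                 design = sample_design(cond_of, config$reference),
                 samples = samples),
            class = "synth_counts")
}

#' Mirror a synthetic dataset (reverse-complement every chromosome)
#'
#' Coordinates are mirrored (`x -> L - x` per chromosome), strands flipped
#' and sequences reverse-complemented. A strand-correct pipeline yields
#' identical event-level results on the mirrored dataset.
#'
#' @param ref a `synth_reference`.
#' @param sim optional `synth_counts` to mirror alongside.
#' @return list with mirrored `ref` and (if given) `sim`.
#' @export
mirror_dataset <- function(ref, sim = NULL) {
  lens <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  out <- ref
  out$genome <- Biostrings::reverseComplement(ref$genome)
  mirror_df <- function(df, scol, ecol) {
    L <- lens[df$chrom]
    new_s <- L - df[[ecol]]; new_e <- L - df[[scol]]
    df[[scol]] <- unname(new_s); df[[ecol]] <- unname(new_e)
    df$strand <- flip_strand(df$strand)
    df
  }
  out$exons <- mirror_df(ref$exons, "start", "end")
  out$junctions <- mirror_df(ref$junctions, "intron_start", "intron_end")
  tr <- ref$truth
  L <- lens[tr$chrom]
  for (col in c("common_site", "u_site", "d_site"))
    tr[[col]] <- ifelse(is.na(tr[[col]]), tr[[col]],
                        as.integer(L - tr[[col]]))
  es <- tr$ext_start; ee <- tr$ext_end
  tr$ext_start <- ifelse(is.na(es), es, as.integer(L - ee))
  tr$ext_end <- ifelse(is.na(ee), ee, as.integer(L - es))
  tr$strand <- flip_strand(tr$strand)
  out$truth <- tr
  result <- list(ref = out)
  if (!is.null(sim)) {
    sim2 <- sim
    sim2$counts <- validate_junction_counts(
      mirror_df(as.data.frame(sim$counts), "intron_start", "intron_end"))
    result$sim <- sim2
  }
  result
}
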
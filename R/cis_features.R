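## Cis-feature analysis of A5C events: density of polypyrimidine-tract
## binding motifs (UCUC/UCUU/UUCU/CUCU, T == U) in the extension region
## between the two alternative donors, and percent-scaled donor-strength
## scores from a 9-mer position frequency matrix (3 exonic + 6 intronic
## positions), with class-level ECDF/KS and Wilcoxon comparisons.

PTB_MOTIFS <- c("TCTC", "TCTT", "TTCT", "CTCT")

#' Extension-region sequence of an event
#'
#' @param event one row of an event table.
#' @param genome a `DNAStringSet`.
#' @return the extension sequence in transcript orientation (DNA alphabet;
#'   matching elsewhere treats T and U as identical).
#' @export
extension_sequence <- function(event, genome) {
  genome_subseq(genome, event$chrom, event$ext_start, event$ext_end,
                event$strand)
}

#' Count polypyrimidine-tract motif matches
#'
#' Overlapping occurrences of any motif in the set; matching is
#' case-insensitive and T is treated as U. Sequences shorter than the motif
#' length count 0.
#'
#' @param seq nucleotide string.
#' @param motifs motif set (DNA or RNA alphabet).
#' @param overlapping count overlapping occurrences (default) or
#'   non-overlapping left-to-right occurrences.
#' @return integer match count.
#' @export
count_motifs <- function(seq, motifs = PTB_MOTIFS, overlapping = TRUE) {
  seq <- chartr("u", "t", tolower(seq))
  motifs <- chartr("u", "t", tolower(motifs))
  if (nchar(seq) < min(nchar(motifs))) return(0L)
  s <- Biostrings::DNAString(toupper(seq))
  if (overlapping) {
    return(sum(vapply(toupper(motifs), function(m)
      Biostrings::countPattern(m, s), integer(1))))
  }
  ## non-overlapping: greedy left-to-right scan over the motif set
  n <- nchar(seq); w <- nchar(motifs[1]); i <- 1L; hits <- 0L
  seq <- toupper(seq); motifs <- toupper(motifs)
  while (i + w - 1L <= n) {
    if (substr(seq, i, i + w - 1L) %in% motifs) {
      hits <- hits + 1L; i <- i + w
    } else i <- i + 1L
  }
  hits
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled data points of the absolute ECDF
#' difference; the p-value uses the asymptotic Kolmogorov distribution with
#' effective sample size `nx * ny / (nx + ny)`.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  if (anyNA(x) || anyNA(y)) stop("NA in KS input")
  pts <- sort(unique(c(x, y)))
  D <- max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(n_eff) * D
  p <- if (lambda < 1e-12) 1 else {
    k <- 1:100
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))))
  }
  list(statistic = D, p.value = p)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks for ties; exact p for small tie-free samples, otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction (the convention of `stats::wilcox.test`). Two samples with all
#' values identical carry no information and return p = 1.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with `statistic` (Mann-Whitney W for `x`) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = min(1, p))
}

#' Bundled donor-site position frequency matrix
#'
#' A synthetic consensus-style frequency matrix for the 9-mer donor window
#' (positions -3..-1 exonic, +1..+6 intronic, transcript orientation),
#' modeled on the familiar mammalian 5' splice-site consensus
#' (C/A)AG | GTAAGT. It drives donor planting in the synthetic generator and
#' is the default scorer of the pipeline; it is not the matrix of any
#' external scoring service.
#'
#' @return 9 x 4 row-stochastic matrix (rows -3..+6, columns A, C, G, T).
#' @export
donor_pwm_default <- function() {
  m <- rbind(
    c(0.33, 0.37, 0.18, 0.12),  # -3
    c(0.60, 0.13, 0.14, 0.13),  # -2
    c(0.08, 0.04, 0.81, 0.07),  # -1
    c(0.002, 0.002, 0.994, 0.002),  # +1 (G)
    c(0.002, 0.002, 0.002, 0.994),  # +2 (T)
    c(0.60, 0.03, 0.34, 0.03),  # +3
    c(0.70, 0.08, 0.12, 0.10),  # +4
    c(0.06, 0.04, 0.84, 0.06),  # +5
    c(0.16, 0.16, 0.21, 0.47)   # +6
  )
  dimnames(m) <- list(c("-3", "-2", "-1", "+1", "+2", "+3", "+4", "+5", "+6"),
                      c("A", "C", "G", "T"))
  m
}

#' Build a donor position frequency matrix from an annotation
#'
#' Collects the 9-mer (3 exonic + 6 intronic nt) at every distinct annotated
#' internal donor site (the 3' boundary of every non-terminal exon, in
#' transcript orientation) and tabulates per-position nucleotide frequencies
#' with a pseudocount.
#'
#' @param exons exon table.
#' @param genome a `DNAStringSet`.
#' @param pseudocount added to every cell before normalization.
#' @param min_donors minimum number of distinct donors required.
#' @return 9 x 4 row-stochastic matrix as in [donor_pwm_default()].
#' @export
build_donor_pwm <- function(exons, genome, pseudocount = 0.5,
                            min_donors = 50) {
  ex <- exons[exons$type == "exon", , drop = FALSE]
  donors <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    n <- nrow(df)
    if (n < 2) return(NULL)
    if (df$strand[1] == "+") {
      data.frame(chrom = df$chrom[-n], pos = df$end[-n],
                 strand = "+", stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = df$chrom[-1], pos = df$start[-1],
                 strand = "-", stringsAsFactors = FALSE)
    }
  }))
  donors <- unique(donors)
  if (is.null(donors) || nrow(donors) < min_donors)
    stop("only ", if (is.null(donors)) 0 else nrow(donors),
         " annotated internal donors (need >= ", min_donors,
         "); consider donor_pwm_default()")
  nines <- vapply(seq_len(nrow(donors)), function(i)
    donor_9mer(genome, donors$chrom[i], donors$pos[i], donors$strand[i]),
    character(1))
  nines <- nines[!is.na(nines)]
  counts <- matrix(pseudocount, nrow = 9, ncol = 4,
                   dimnames = dimnames(donor_pwm_default()))
  chars <- do.call(rbind, strsplit(nines, ""))
  for (p in 1:9) {
    tab <- table(factor(chars[, p], levels = c("A", "C", "G", "T")))
    counts[p, ] <- counts[p, ] + as.integer(tab)
  }
  counts / rowSums(counts)
}

#' Donor 9-mer at a splice boundary
#'
#' @param genome a `DNAStringSet`.
#' @param chrom chromosome.
#' @param pos donor boundary coordinate (half-open boundary between the
#'   exon's last base and the intron's first base, in genomic coordinates).
#' @param strand `"+"` or `"-"`.
#' @return 9-character string (positions -3..+6 in transcript orientation),
#'   or `NA` if the window falls outside the chromosome.
#' @export
donor_9mer <- function(genome, chrom, pos, strand) {
  L <- Biostrings::width(genome[chrom])
  if (strand == "+") {
    if (pos - 3 < 0 || pos + 6 > L) return(NA_character_)
    genome_subseq(genome, chrom, pos - 3L, pos + 6L, "+")
  } else {
    if (pos - 6 < 0 || pos + 3 > L) return(NA_character_)
    genome_subseq(genome, chrom, pos - 6L, pos + 3L, "-")
  }
}

#' Percent-scaled donor strength
#'
#' `S = 100 * (sum_i f_i(x_i) - sum_i min_b f_i(b)) /
#'            (sum_i max_b f_i(b) - sum_i min_b f_i(b))`,
#' so the per-position argmax 9-mer scores 100 and the argmin 9-mer 0.
#'
#' @param nine_mer 9-character string over A/C/G/T (vectorized).
#' @param pwm 9 x 4 frequency matrix.
#' @return numeric score(s) in `[0, 100]`.
#' @export
score_donor <- function(nine_mer, pwm) {
  lo <- sum(apply(pwm, 1, min))
  hi <- sum(apply(pwm, 1, max))
  vapply(nine_mer, function(s) {
    if (is.na(s)) return(NA_real_)
    b <- strsplit(toupper(s), "")[[1]]
    if (length(b) != 9 || !all(b %in% colnames(pwm)))
      stop("donor 9-mer must be 9 characters over ",
           paste(colnames(pwm), collapse = ""))
    100 * (sum(pwm[cbind(1:9, match(b, colnames(pwm)))]) - lo) / (hi - lo)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-event cis features
#'
#' Extension length, motif count and per-nt density for every event;
#' donor 9-mers and percent-scaled strengths (S_u, S_d and
#' `delta_S = S_d - S_u`) for A5C events (A3C events share their donor, so
#' strength columns are `NA`).
#'
#' @param events event table.
#' @param genome a `DNAStringSet`.
#' @param pwm donor frequency matrix.
#' @param overlapping passed to [count_motifs()].
#' @return data.frame keyed by `event_id`.
#' @export
event_cis_features <- function(events, genome, pwm = donor_pwm_default(),
                               overlapping = TRUE) {
  n <- nrow(events)
  ext_len <- events$ext_end - events$ext_start
  motif_count <- integer(n)
  u9 <- d9 <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    motif_count[i] <- count_motifs(extension_sequence(events[i, ], genome),
                                   overlapping = overlapping)
    if (events$type[i] == "A5C") {
      u9[i] <- donor_9mer(genome, events$chrom[i], events$u_site[i],
                          events$strand[i])
      d9[i] <- donor_9mer(genome, events$chrom[i], events$d_site[i],
                          events$strand[i])
    }
  }
  S_u <- ifelse(is.na(u9), NA_real_, score_donor(u9, pwm))
  S_d <- ifelse(is.na(d9), NA_real_, score_donor(d9, pwm))
  data.frame(event_id = events$event_id, type = events$type,
             ext_len = ext_len, motif_count = motif_count,
             density = motif_count / ext_len, u_9mer = u9, d_9mer = d9,
             S_u = S_u, S_d = S_d, delta_S = S_d - S_u,
             stringsAsFactors = FALSE)
}

#' Assemble regulatory class sets from differential-usage results
#'
#' Class 1: regulated A5C events biased toward the u5'ss by the factor
#' (knockdown increases psi of the long isoform); class 2: biased toward the
#' d5'ss; class 3: a random control sample of insensitive A5C events (every
#' contrast `p >= alpha` and `|dpsi| <= min_dpsi`).
#'
#' @param results output of [call_regulated()].
#' @param alpha,min_dpsi thresholds defining insensitivity (match the
#'   calling thresholds).
#' @param class3_size target control-sample size.
#' @param seed seed for the class-3 draw (recorded in the report; the global
#'   RNG state is restored afterwards).
#' @return list of class `class_sets` with character vectors `class1`,
#'   `class2`, `class3` of event ids, plus `class3_seed`.
#' @export
build_class_sets <- function(results, alpha = 0.05, min_dpsi = 5,
                             class3_size = 100, seed = 1) {
  a5c <- results[results$type == "A5C", , drop = FALSE]
  class1 <- a5c$event_id[a5c$regulated &
                           a5c$direction_class == "class1_u_bias"]
  class2 <- a5c$event_id[a5c$regulated &
                           a5c$direction_class == "class2_d_bias"]
  pcols <- grep("^p_", names(a5c), value = TRUE)
  dcols <- grep("^dpsi_", names(a5c), value = TRUE)
  pm <- as.matrix(a5c[pcols]); dm <- as.matrix(a5c[dcols])
  insensitive <- a5c$tested &
    apply(pm >= alpha, 1, all) & apply(abs(dm) <= min_dpsi, 1, all)
  insensitive[is.na(insensitive)] <- FALSE
  pool <- a5c$event_id[insensitive]
  size <- min(class3_size, length(pool))
  if (size < class3_size)
    warning("only ", size, " insensitive A5C events available for class 3 ",
            "(requested ", class3_size, ")")
  class3 <- with_local_seed(seed, sample(pool, size))
  structure(list(class1 = class1, class2 = class2, class3 = sort(class3),
                 class3_seed = seed),
            class = "class_sets")
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Compare regulatory classes by motif density and donor strength
#'
#' Computes per-class motif densities and delta-S values, their medians and
#' ECDF tables, and tests class 1 and class 2 against the class 3 control:
#' Kolmogorov-Smirnov on motif densities, Wilcoxon rank-sum on delta-S.
#'
#' @param class_sets a [build_class_sets()] result (or any list with
#'   `class1`/`class2`/`class3` event-id vectors).
#' @param events event table covering the class members.
#' @param genome a `DNAStringSet`.
#' @param pwm donor frequency matrix.
#' @return list of class `class_report`: `features` (per-event features with
#'   a `class` column), `ecdf` (long-format ECDF table of densities),
#'   `stats` (D/W statistics, p-values, medians, class sizes, seed).
#' @export
compare_classes <- function(class_sets, events, genome,
                            pwm = donor_pwm_default()) {
  ids <- unlist(class_sets[c("class1", "class2", "class3")])
  if (!length(ids)) stop("empty class sets")
  ev <- events[match(ids, events$event_id), , drop = FALSE]
  if (anyNA(ev$event_id)) stop("class member events missing from event table")
  feat <- event_cis_features(ev, genome, pwm)
  feat$class <- rep(c("class1", "class2", "class3"),
                    lengths(class_sets[c("class1", "class2", "class3")]))
  dens <- split(feat$density, feat$class)
  ds <- split(feat$delta_S, feat$class)
  test_pair <- function(f, a, b) {
    if (is.null(a) || is.null(b) || length(a) < 2 || length(b) < 2)
      return(list(statistic = NA_real_, p.value = NA_real_))
    f(a, b)
  }
  ks1 <- test_pair(ks_two_sample, dens$class1, dens$class3)
  ks2 <- test_pair(ks_two_sample, dens$class2, dens$class3)
  w1 <- test_pair(wilcoxon_rank_sum, ds$class1, ds$class3)
  w2 <- test_pair(wilcoxon_rank_sum, ds$class2, ds$class3)
  ecdf_tab <- do.call(rbind, lapply(names(dens), function(cl) {
    x <- sort(dens[[cl]])
    if (!length(x)) return(NULL)
    data.frame(class = cl, density = x, ecdf = seq_along(x) / length(x),
               stringsAsFactors = FALSE)
  }))
  stats <- list(
    n_class1 = length(class_sets$class1), n_class2 = length(class_sets$class2),
    n_class3 = length(class_sets$class3),
    class3_seed = class_sets$class3_seed,
    ks_D_class1_vs_class3 = ks1$statistic, ks_p_class1_vs_class3 = ks1$p.value,
    ks_D_class2_vs_class3 = ks2$statistic, ks_p_class2_vs_class3 = ks2$p.value,
    wilcox_W_class1_vs_class3 = w1$statistic,
    wilcox_p_class1_vs_class3 = w1$p.value,
    wilcox_W_class2_vs_class3 = w2$statistic,
    wilcox_p_class2_vs_class3 = w2$p.value,
    median_density = lapply(dens, median),
    median_delta_S = lapply(ds, function(x) median(x, na.rm = TRUE))
  )
  structure(list(features = feat, ecdf = ecdf_tab, stats = stats),
            class = "class_report")
}
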
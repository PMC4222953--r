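# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: brute-force scans, explicit enumeration, naive
# codon walks.

# all-pairs classification of junctions by shared boundary (O(n^2) scan
# over every unordered pair, vectorized over the pair list). Pair keys use
# fixed-width coordinates so lexicographic order equals numeric order.
junction_label <- function(s, e) sprintf("%09d:%09d", s, e)

oracle_enumerate <- function(j) {
  j <- unique(j[c("chrom", "intron_start", "intron_end", "strand")])
  n <- nrow(j)
  if (n < 2) return(list(a5c = character(0), a3c = character(0)))
  donor <- ifelse(j$strand == "+", j$intron_start, j$intron_end)
  acceptor <- ifelse(j$strand == "+", j$intron_end, j$intron_start)
  pr <- combn(n, 2)
  i <- pr[1, ]; k <- pr[2, ]
  same <- j$chrom[i] == j$chrom[k] & j$strand[i] == j$strand[k]
  is_a5 <- same & acceptor[i] == acceptor[k] & donor[i] != donor[k]
  is_a3 <- same & donor[i] == donor[k] & acceptor[i] != acceptor[k]
  lab <- junction_label(j$intron_start, j$intron_end)
  pair_key <- paste(j$chrom[i], j$strand[i],
                    ifelse(lab[i] < lab[k], paste(lab[i], lab[k]),
                           paste(lab[k], lab[i])))
  list(a5c = sort(pair_key[is_a5]), a3c = sort(pair_key[is_a3]))
}

# package event rows -> the same pair keys as oracle_enumerate
event_pair_keys <- function(ev) {
  if (!nrow(ev)) return(character(0))
  l1 <- junction_label(ev$long_intron_start, ev$long_intron_end)
  l2 <- junction_label(ev$short_intron_start, ev$short_intron_end)
  sort(paste(ev$chrom, ev$strand,
             ifelse(l1 < l2, paste(l1, l2), paste(l2, l1))))
}

random_junction_set <- function(n, n_chrom = 3, boundary_pool = 60) {
  bounds <- sort(sample(seq(100, 5000, by = 10), boundary_pool))
  rows <- t(replicate(n, {
    b <- sort(sample(bounds, 2))
    c(b[1], b[2])
  }))
  data.frame(chrom = sample(paste0("c", seq_len(n_chrom)), n, replace = TRUE),
             intron_start = rows[, 1], intron_end = rows[, 2],
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# two-sided Fisher p by explicit enumeration over the hypergeometric support
# using binomial coefficients only
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  prob <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  p_obs <- prob(a)
  sum(vapply(lo:hi, function(x) {
    px <- prob(x)
    if (px <= p_obs * (1 + 1e-7)) px else 0
  }, numeric(1)))
}

# naive codon walk: 1-based mRNA coordinate of the last base of the first
# in-frame stop codon
oracle_codon_walk <- function(mrna, cds_start) {
  i <- cds_start
  n <- nchar(mrna)
  while (i + 2 <= n) {
    if (substr(mrna, i, i + 2) %in% c("TAA", "TAG", "TGA")) return(i + 2L)
    i <- i + 3L
  }
  NA_integer_
}

# exhaustive sliding-window motif count
oracle_count_motifs <- function(seq, motifs = c("TCTC", "TCTT", "TTCT", "CTCT")) {
  seq <- toupper(chartr("uU", "tT", seq))
  n <- nchar(seq)
  if (n < 4) return(0L)
  sum(vapply(seq_len(n - 3), function(i)
    substr(seq, i, i + 3) %in% motifs, logical(1)))
}

# explicit pooled-ECDF table maximum
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all rank assignments
oracle_wilcox_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(combn(n1 + n2, n1), 2, function(ix)
    sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs)))
}

random_dna <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}
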
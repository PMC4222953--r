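## psi, Fisher's exact test, and consistent-regulation calling across
## knockdown contrasts.

#' Percent spliced in of the long isoform
#'
#' `psi = 100 * n_long / (n_long + n_short)`; `NA` when both counts are zero
#' (undefined).
#'
#' @param n_long,n_short non-negative junction read counts of the long and
#'   short isoform (vectorized).
#' @return numeric vector of psi percentages in `[0, 100]` (or `NA`).
#' @export
compute_psi <- function(n_long, n_short) {
  if (any(n_long < 0) || any(n_short < 0)) stop("negative counts")
  total <- n_long + n_short
  ifelse(total > 0, 100 * n_long / total, NA_real_)
}

fisher_p_one <- function(a, b, c, d) {
  m <- a + b          # row 1 margin (reference)
  n <- c + d          # row 2 margin (treatment)
  k <- a + c          # column 1 margin (long isoform)
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  ## point-probability two-sided rule with relative slack against floating-
  ## point noise (the convention of fisher.test in R)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact test for a 2x2 count table
#'
#' Rows are reference/treatment, columns long-/short-isoform reads. The
#' two-sided p-value sums the hypergeometric point probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed table. A zero row or column margin carries no information and
#' returns p = 1.
#'
#' @param a,b reference long / short counts (vectorized).
#' @param c,d treatment long / short counts.
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("negative counts in 2x2 table")
  mapply(fisher_p_one, a, b, c, d)
}

pool_by_condition <- function(counts, design) {
  cond <- design$condition_of[counts$sample]
  if (anyNA(cond))
    stop("samples absent from design: ",
         paste(unique(counts$sample[is.na(cond)]), collapse = ", "))
  key <- paste(counts$chrom, counts$intron_start, counts$intron_end,
               counts$strand, cond, sep = "\r")
  tot <- rowsum(counts$count, key)
  parts <- do.call(rbind, strsplit(rownames(tot), "\r", fixed = TRUE))
  data.frame(jkey = paste(parts[, 1], parts[, 2], parts[, 3], parts[, 4],
                          sep = "\r"),
             condition = parts[, 5], count = as.integer(tot[, 1]),
             stringsAsFactors = FALSE)
}

## junction-key x condition count matrix lookup (0 for absent pairs)
condition_count_matrix <- function(pooled, jkeys, conditions) {
  pk <- paste(pooled$jkey, pooled$condition, sep = "\r")
  cols <- vapply(conditions, function(cn) {
    ix <- match(paste(jkeys, cn, sep = "\r"), pk)
    ifelse(is.na(ix), 0L, pooled$count[ix])
  }, integer(length(jkeys)))
  matrix(cols, nrow = length(jkeys), ncol = length(conditions),
         dimnames = list(NULL, conditions))
}

#' Call consistently regulated events across contrasts
#'
#' Replicate counts are pooled per condition. For each contrast the 2x2
#' table (reference vs treatment x long vs short) is tested with
#' [fisher_exact_2x2()] and the psi difference
#' `dpsi = psi(treatment) - psi(reference)` computed. An event is `regulated`
#' when every contrast has `p < alpha`, `|dpsi| > min_dpsi`, and all dpsi
#' values share one sign. The direction class keys on the intron-distal
#' site: knockdown contrasts that increase psi of the long isoform indicate
#' the factor promoted the intron-distal alternative (`class1_u_bias`),
#' decreases indicate `class2_d_bias`.
#'
#' Events where any contrast condition has fewer than `min_reads` total reads
#' across both isoforms are reported untested (reason `"low_counts"`, or
#' `"insufficient_reads"` when a condition has zero reads so psi is
#' undefined).
#'
#' @param events event table (from [deplete_cassette()]; only retained rows
#'   are tested, all are reported).
#' @param counts a `junction_counts` data.frame covering all samples.
#' @param design a [sample_design()].
#' @param alpha per-contrast significance threshold on the raw Fisher p.
#' @param min_dpsi minimum absolute psi difference (percent).
#' @param min_reads minimum pooled reads (both isoforms) per contrast
#'   condition; set 0 to disable the floor.
#' @param use_fdr gate the regulated flag on the Benjamini-Hochberg q-value
#'   instead of the raw p (a `q_*` column is reported either way).
#' @return the event table augmented with per-condition `n_long_*`,
#'   `n_short_*`, `psi_*` columns, per-contrast `dpsi_*`, `p_*`, `q_*`
#'   columns, and `tested`, `regulated`, `direction_class`, `reason`.
#' @export
call_regulated <- function(events, counts, design, alpha = 0.05,
                           min_dpsi = 5, min_reads = 10, use_fdr = FALSE) {
  conds <- unique(unname(design$condition_of))
  out <- events
  if (!nrow(events)) {
    out$tested <- logical(0); out$regulated <- logical(0)
    out$direction_class <- character(0); out$reason <- character(0)
    return(out)
  }
  pooled <- pool_by_condition(as.data.frame(counts), design)
  long_key <- paste(events$chrom, events$long_intron_start,
                    events$long_intron_end, events$strand, sep = "\r")
  short_key <- paste(events$chrom, events$short_intron_start,
                     events$short_intron_end, events$strand, sep = "\r")
  n_long <- condition_count_matrix(pooled, long_key, conds)
  n_short <- condition_count_matrix(pooled, short_key, conds)
  for (cn in conds) {
    out[[paste0("n_long_", cn)]] <- n_long[, cn]
    out[[paste0("n_short_", cn)]] <- n_short[, cn]
    out[[paste0("psi_", cn)]] <- compute_psi(n_long[, cn], n_short[, cn])
  }
  eligible <- if ("retained" %in% names(out)) out$retained else
    rep(TRUE, nrow(out))
  total <- n_long + n_short
  sig <- matrix(FALSE, nrow(out), length(design$contrasts))
  pos <- matrix(NA, nrow(out), length(design$contrasts))
  tested_all <- rep(TRUE, nrow(out))
  zero_cond <- rep(FALSE, nrow(out))
  for (ci in seq_along(design$contrasts)) {
    ct <- design$contrasts[[ci]]
    nm <- names(design$contrasts)[ci]
    trt <- ct[1]; ref <- ct[2]
    ok <- eligible & total[, ref] >= max(min_reads, 1L) &
      total[, trt] >= max(min_reads, 1L)
    zero_cond <- zero_cond | total[, ref] == 0 | total[, trt] == 0
    p <- rep(NA_real_, nrow(out))
    p[ok] <- fisher_exact_2x2(n_long[ok, ref], n_short[ok, ref],
                              n_long[ok, trt], n_short[ok, trt])
    dpsi <- out[[paste0("psi_", trt)]] - out[[paste0("psi_", ref)]]
    dpsi[!ok] <- NA_real_
    q <- rep(NA_real_, nrow(out))
    q[ok] <- p.adjust(p[ok], method = "BH")
    out[[paste0("dpsi_", nm)]] <- dpsi
    out[[paste0("p_", nm)]] <- p
    out[[paste0("q_", nm)]] <- q
    p_used <- if (use_fdr) q else p
    sig[, ci] <- ok & !is.na(p_used) & p_used < alpha &
      !is.na(dpsi) & abs(dpsi) > min_dpsi
    pos[, ci] <- dpsi > 0
    tested_all <- tested_all & ok
  }
  consistent <- apply(pos, 1, function(x) all(!is.na(x)) &&
                        (all(x) || all(!x)))
  out$tested <- tested_all
  out$regulated <- tested_all & apply(sig, 1, all) & consistent
  out$direction_class <- ifelse(!out$regulated, "unclassified",
                                ifelse(pos[, 1], "class1_u_bias",
                                       "class2_d_bias"))
  out$reason <- ifelse(out$regulated, "",
                ifelse(!eligible, "cassette_like",
                ifelse(zero_cond, "insufficient_reads",
                ifelse(!tested_all, "low_counts", "not_significant"))))
  out
}

#' Summary counts of regulated events
#'
#' @param results output of [call_regulated()].
#' @return named list of counts by event type and direction class.
#' @export
summarize_calls <- function(results) {
  reg <- results[results$regulated, , drop = FALSE]
  list(
    n_events = nrow(results),
    n_tested = sum(results$tested),
    n_regulated = nrow(reg),
    n_regulated_a5c = sum(reg$type == "A5C"),
    n_regulated_a3c = sum(reg$type == "A3C"),
    n_class1 = sum(reg$direction_class == "class1_u_bias"),
    n_class2 = sum(reg$direction_class == "class2_d_bias")
  )
}
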
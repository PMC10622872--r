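#' JC69 transition probability matrix
#'
#' `P(t)` for the Jukes-Cantor model: `p_same = 1/4 + 3/4 exp(-4t/3)` on the
#' diagonal and `p_diff = 1/4 - 1/4 exp(-4t/3)` off it, with `t` in expected
#' substitutions per site.
#'
#' @param t branch length, `t >= 0`.
#' @return 4x4 stochastic matrix (rows sum to 1), states T, C, A, G.
#' @examples
#' jc69_transition(0.1)[1, 1]  # about 0.90638
#' @export
jc69_transition <- function(t) {
  if (t < 0) stop("branch length must be >= 0")
  x <- exp(-4 * t / 3)
  ps <- 0.25 + 0.75 * x
  pd <- 0.25 - 0.25 * x
  m <- matrix(pd, 4L, 4L, dimnames = list(c("T", "C", "A", "G"),
                                          c("T", "C", "A", "G")))
  diag(m) <- ps
  m
}

#' Compress an alignment into unique site patterns
#'
#' @param locus an `mscm_locus` (integer codes 0..3; negative = missing).
#' @return list with `patterns` (tips x n_patterns integer matrix) and
#'   `counts` (multiplicities summing to the number of sites).
#' @export
site_patterns <- function(locus) {
  key <- apply(locus$seqs, 2L, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(patterns = locus$seqs[, first, drop = FALSE],
       counts = as.numeric(tab))
}

#' Phylogenetic log-likelihood of a locus given a gene tree
#'
#' Felsenstein pruning under JC69 over compressed site patterns with uniform
#' (1/4) root frequencies and per-node numerical rescaling.  Sequences are
#' matched to gene-tree tips by label.  The migration history does not enter:
#' branch lengths depend only on the coalescent times, so migration events
#' leave the likelihood unchanged.  Gaps and ambiguity codes (negative codes)
#' are treated as missing data.
#'
#' @param locus an `mscm_locus`.
#' @param gt an `mscm_gene_tree` whose tip labels match the sequence labels.
#' @return log-likelihood.
#' @export
log_likelihood <- function(locus, gt) {
  idx <- match(gt$labels, locus$labels)
  if (anyNA(idx))
    stop("sequence labels do not match gene-tree tips: ",
         paste(gt$labels[is.na(idx)], collapse = ", "))
  sp <- site_patterns(structure(list(seqs = locus$seqs[idx, , drop = FALSE],
                                     labels = gt$labels, h = locus$h),
                                class = "mscm_locus"))
  parent0 <- ifelse(is.na(gt$parent), -1L, gt$parent - 1L)
  cpp_prune_jc69(parent0, gt$time, sp$patterns, sp$counts)
}
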
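#' Age profile for a synthetic repeat-family expansion
#'
#' Divergence (a proxy for element age) is specified as mixture weights
#' over 1%-wide Kimura-divergence bins. The default profile decays
#' geometrically from bin 0, emulating a genome dominated by a recent
#' repeat expansion.
#'
#' @param family_classes repeat classes to simulate.
#' @param copies_per_family copies generated per class.
#' @param divergence_weights numeric vector of mixture weights; element `i`
#'   is the weight of divergence bin `i - 1` (i.e. `[i-1, i)` percent).
#'   Normalised to sum to 1.
#' @return a list of class `"repeat_age_profile"`.
#' @export
repeat_age_profile <- function(family_classes = c("DNA", "LINE", "SINE",
                                                  "LTR", "Unclassified"),
                               copies_per_family = 2000,
                               divergence_weights = exp(-(0:24) / 5)) {
  stopifnot(length(divergence_weights) >= 1, all(divergence_weights >= 0),
            sum(divergence_weights) > 0, is_count(copies_per_family))
  structure(list(family_classes = family_classes,
                 copies_per_family = copies_per_family,
                 divergence_weights =
                   divergence_weights / sum(divergence_weights)),
            class = "repeat_age_profile")
}

#' Generate aligned repeat copies around per-family consensus sequences
#'
#' Each copy is created by substituting bases of the family consensus so
#' that its Kimura 2-parameter distance to the consensus falls inside a
#' divergence bin drawn from the profile. Substitutions use a 2:1
#' transition:transversion ratio; the target K is converted to an observed
#' difference proportion by inverting the K2P correction, so the landscape
#' module recovers the planted bin. No indels are introduced, so copy and
#' consensus are emitted as equal-length gapless alignment strings.
#'
#' @param consensus_length consensus length in bp (>= 50).
#' @param profile a [repeat_age_profile()].
#' @param seed integer seed.
#' @return data.frame with columns `copy_id`, `class_label`, `planted_bin`,
#'   `aligned_copy`, `aligned_consensus`.
#' @export
generate_repeat_copies <- function(consensus_length = 600,
                                   profile = repeat_age_profile(),
                                   seed = 1) {
  stopifnot(inherits(profile, "repeat_age_profile"), consensus_length >= 50)
  set.seed(seed)
  bins <- seq_along(profile$divergence_weights) - 1L
  out <- vector("list", length(profile$family_classes))
  for (ci in seq_along(profile$family_classes)) {
    cls <- profile$family_classes[ci]
    consensus <- random_dna(consensus_length)
    cvec <- strsplit(consensus, "", fixed = TRUE)[[1]]
    ncop <- profile$copies_per_family
    bin <- sample(bins, ncop, replace = TRUE, prob = profile$divergence_weights)
    # target K drawn away from bin edges so site-count discreteness cannot
    # spill a copy into a neighbouring bin; bin 0 means exact consensus
    # copies (zero divergence)
    targK <- ifelse(bin == 0, 0, (bin + stats::runif(ncop, 0.15, 0.85)) / 100)
    copies <- vapply(seq_len(ncop), function(j) {
      mutate_to_divergence(cvec, targK[j])
    }, character(1))
    out[[ci]] <- data.frame(
      copy_id = sprintf("%s_copy_%04d", cls, seq_len(ncop)),
      class_label = cls, planted_bin = bin,
      aligned_copy = copies, aligned_consensus = consensus,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Observed difference proportion d (with ts:tv 2:1) giving K2P distance K.
k2p_inverse_proportion <- function(K) {
  if (K <= 0) return(0)
  f <- function(d) -0.5 * log((1 - 2 * (2 * d / 3) - d / 3) *
                                sqrt(1 - 2 * d / 3)) - K
  stats::uniroot(f, c(1e-9, 0.55), tol = 1e-10)$root
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

mutate_to_divergence <- function(cvec, targK) {
  n <- length(cvec)
  m <- round(k2p_inverse_proportion(targK) * n)
  if (m == 0) return(paste(cvec, collapse = ""))
  nts <- round(2 * m / 3)
  sites <- sample.int(n, m)
  v <- cvec
  ts_sites <- sites[seq_len(nts)]
  v[ts_sites] <- TRANSITION[v[ts_sites]]
  tv_sites <- sites[setdiff(seq_len(m), seq_len(nts))]
  for (s in tv_sites) {
    v[s] <- sample(switch(cvec[s],
                          A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G")), 1)
  }
  paste(v, collapse = "")
}

#' Write repeat copy-vs-consensus alignments as a TSV
#'
#' @param copies data.frame from [generate_repeat_copies()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_copies <- function(copies, path) {
  utils::write.table(copies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a repeat copy-vs-consensus alignment TSV
#'
#' @param path path written by [write_repeat_copies()].
#' @return data.frame in the layout of [generate_repeat_copies()].
#' @export
read_repeat_copies <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
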
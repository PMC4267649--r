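# Motif similarity by sliding Fisher-Irwin exact tests, decoy-calibrated
# Z-scores, distance transform, UPGMA clustering and benchmark success.

#' Motif comparison parameters
#'
#' @param min_overlap minimum aligned columns for a sliding comparison
#'   (default 3; informative motifs can be as short as 3 bp).
#' @param z_cap maximum similarity Z-score reported (default 10).
#' @param z_range observed Z-score range used by the distance transform
#'   (default 11.1), so `D = |Z - z_cap| / z_range` maps Z in
#'   \[z_cap - z_range, z_cap\] onto \[0, 1\].
#' @param z_success Z-score above which two motifs are called similar at 95
#'   percent confidence (default 2.0).
#' @param decoy_redundancy_p Fisher-Irwin p-value under which two decoy
#'   motifs are considered redundant (default 0.05).
#' @return An object of class `comparison_params`.
#' @export
comparison_params <- function(min_overlap = 3, z_cap = 10, z_range = 11.1,
                              z_success = 2.0, decoy_redundancy_p = 0.05) {
  stopifnot(min_overlap >= 1, z_cap > z_success, z_range > 0,
            decoy_redundancy_p > 0, decoy_redundancy_p < 1)
  structure(list(min_overlap = as.integer(min_overlap), z_cap = z_cap,
                 z_range = z_range, z_success = z_success,
                 decoy_redundancy_p = decoy_redundancy_p),
            class = "comparison_params")
}

#' Reverse complement of a PWM
#'
#' Reverses the column order and swaps the A/T and C/G frequencies in every
#' column. Applying it twice is the identity.
#'
#' @param m a `pwm`.
#' @return The reverse-complement `pwm`.
#' @export
reverse_complement_pwm <- function(m) {
  stopifnot(inherits(m, "pwm"))
  rc <- unclass(m)[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  new_pwm(rc, name = attr(m, "name") %||% "motif")
}

#' One-sided Fisher-Irwin exact p-value for consensus matches
#'
#' Probability of observing at least `matches` matching columns out of
#' `overlap` aligned columns, relative to the random expectation of
#' `round(overlap / 4)` matches: the one-sided hypergeometric tail of the
#' 2x2 table `[m, L - m; r, L - r]` with `r = round(L / 4)`.
#'
#' @param matches observed matching columns (m).
#' @param overlap aligned columns (L), `matches <= overlap`.
#' @return The one-sided exact p-value.
#' @export
#' @examples
#' fisher_irwin_p(6, 8)  # 849/12870
fisher_irwin_p <- function(matches, overlap) {
  stopifnot(all(matches >= 0), all(matches <= overlap))
  r <- round(overlap / 4)
  stats::phyper(matches - 1, matches + r, 2 * overlap - matches - r, overlap,
                lower.tail = FALSE)
}

fisher_match_p <- fisher_irwin_p

consensus_codes <- function(m) {
  apply(unclass(m), 2, which.max)   # ties -> first row = lexicographic base
}

# All sliding alignments of b (columns shifted by `offset` relative to a)
# with overlap >= min_overlap.
slide_offsets <- function(la, lb, min_overlap) {
  seq.int(-(lb - min_overlap), la - min_overlap)
}

#' Best sliding Fisher-Irwin comparison of two motifs
#'
#' Slides motif `b` (forward and reverse complement) over motif `a`. For
#' each alignment with at least `min_overlap` overlapping columns, the
#' per-column consensus strings are compared over the overlap and the number
#' of matching columns `m` out of `L` is tested against the random
#' expectation of `round(L/4)` matches with a one-sided Fisher-Irwin exact
#' test. The alignment with the smallest p-value wins (ties: forward strand
#' first, then smallest offset).
#'
#' @param a,b `pwm` objects, both at least `min_overlap` columns wide.
#' @param p a [comparison_params()] object.
#' @return A `comparison_result` list: `offset` (of b's first column
#'   relative to a's first), `strand` (`"+"` or `"-"` for the reverse
#'   complement of b), `overlap` (L), `matches` (m) and `p_value`.
#' @export
fisher_slide_compare <- function(a, b, p = comparison_params()) {
  stopifnot(inherits(a, "pwm"), inherits(b, "pwm"))
  if (ncol(a) < p$min_overlap || ncol(b) < p$min_overlap)
    stopf("motifs must have at least %d columns", p$min_overlap)
  ca <- consensus_codes(a)
  best <- NULL
  for (strand in c("+", "-")) {
    cb <- if (strand == "+") consensus_codes(b)
          else consensus_codes(reverse_complement_pwm(b))
    for (off in slide_offsets(length(ca), length(cb), p$min_overlap)) {
      ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
      L <- min(length(ca) - ia, length(cb) - ib) + 1L
      m <- sum(ca[ia:(ia + L - 1L)] == cb[ib:(ib + L - 1L)])
      pv <- fisher_match_p(m, L)
      if (is.null(best) || pv < best$p_value)
        best <- list(offset = off, strand = strand, overlap = L,
                     matches = m, p_value = pv)
    }
  }
  structure(best, class = "comparison_result")
}

# Best p-value between two motifs restricted to alignments with overlap
# exactly L (falling back to the largest achievable overlap below L).
best_p_at_overlap <- function(a, b, L, p) {
  ca <- consensus_codes(a)
  Luse <- min(L, length(ca), ncol(b))
  best <- Inf
  for (strand in c("+", "-")) {
    cb <- if (strand == "+") consensus_codes(b)
          else consensus_codes(reverse_complement_pwm(b))
    for (off in slide_offsets(length(ca), length(cb), p$min_overlap)) {
      ia <- max(1L, 1L + off); ib <- max(1L, 1L - off)
      ov <- min(length(ca) - ia, length(cb) - ib) + 1L
      if (ov != Luse) next
      m <- sum(ca[ia:(ia + ov - 1L)] == cb[ib:(ib + ov - 1L)])
      pv <- fisher_match_p(m, ov)
      if (pv < best) best <- pv
    }
  }
  best
}

#' Build a non-redundant decoy motif set
#'
#' Greedy selection in input order: a candidate motif is rejected when its
#' best sliding Fisher-Irwin p-value against any already-retained decoy
#' falls below `decoy_redundancy_p`.
#'
#' @param motifs list of `pwm` objects (at least 2).
#' @param p a [comparison_params()] object.
#' @return A `decoy_set`: list of retained `pwm`s.
#' @export
build_decoy_set <- function(motifs, p = comparison_params()) {
  if (length(motifs) < 2L) stopf("need at least 2 candidate motifs")
  kept <- list()
  for (m in motifs) {
    redundant <- FALSE
    for (d in kept) {
      if (fisher_slide_compare(m, d, p)$p_value < p$decoy_redundancy_p) {
        redundant <- TRUE; break
      }
    }
    if (!redundant) kept[[length(kept) + 1L]] <- m
  }
  if (length(kept) < 2L)
    warnf("fewer than 2 non-redundant decoys: Z calibration will be unstable")
  structure(kept, class = "decoy_set")
}

#' Decoy-calibrated similarity Z-score
#'
#' Sliding p-values depend on the alignment length and on the best-alignment
#' selection, so raw p-values are not comparable across motif pairs. The
#' query-target p-value is therefore standardized against the distribution
#' of the query's best sliding p-values over a set of decoy motifs of
#' matching width, computed with exactly the same search (all offsets, both
#' strands) so that the selection effect cancels:
#' `z = (x - mean) / sd` on `x = -log10(p)`, capped at `z_cap`. With
#' `overlap` set, decoy alignments are instead restricted to that overlap
#' length.
#'
#' @param query_vs_target a `comparison_result` from
#'   [fisher_slide_compare()].
#' @param query the query `pwm`.
#' @param decoys a `decoy_set`.
#' @param p a [comparison_params()] object.
#' @param overlap optional fixed overlap length for the decoy comparisons
#'   (default NULL: full sliding search, mirroring the query-target
#'   comparison).
#' @return The calibrated Z-score (a single number, at most `z_cap`).
#' @export
similarity_zscore <- function(query_vs_target, query, decoys,
                              p = comparison_params(), overlap = NULL) {
  stopifnot(inherits(query_vs_target, "comparison_result"),
            length(decoys) >= 1L)
  x_dec <- vapply(decoys, function(d) {
    pv <- if (is.null(overlap)) fisher_slide_compare(query, d, p)$p_value
          else best_p_at_overlap(query, d, overlap, p)
    -log10(pv)
  }, numeric(1))
  mu <- mean(x_dec); sdev <- stats::sd(x_dec)
  if (!is.finite(sdev) || sdev == 0)
    stopf("degenerate decoy calibration: zero variance of decoy p-values")
  min((-log10(query_vs_target$p_value) - mu) / sdev, p$z_cap)
}

#' Transform a similarity Z-score into a tree distance
#'
#' `D = |Z - z_cap| / z_range`: the most similar motifs (Z at the cap) get
#' distance 0, and Z spanning `[z_cap - z_range, z_cap]` maps onto
#' `[0, 1]`.
#'
#' @param z numeric vector of Z-scores (each at most `z_cap`).
#' @param p a [comparison_params()] object.
#' @return Distances on the same shape as `z`.
#' @export
z_to_distance <- function(z, p = comparison_params()) {
  if (any(z > p$z_cap + 1e-9)) stopf("Z-scores above the cap %g", p$z_cap)
  abs(z - p$z_cap) / p$z_range
}

#' UPGMA tree from a motif distance matrix
#'
#' Agglomerates by unweighted arithmetic-mean linkage, producing an
#' ultrametric rooted tree whose node heights are half the cluster distance
#' at each merge.
#'
#' @param D symmetric distance matrix with zero diagonal (n >= 2).
#' @param labels leaf labels (defaults to `rownames(D)`).
#' @return A `motif_tree` list: `phylo` (an [ape::as.phylo()] tree, Newick-
#'   writable via [ape::write.tree()]), `hclust` (merge heights on the
#'   cluster-distance scale) and `labels`.
#' @export
upgma_tree <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  if (nrow(D) < 2L) stopf("need at least 2 leaves")
  if (any(!is.finite(D))) stopf("distance matrix contains non-finite values")
  if (any(abs(D - t(D)) > 1e-9)) stopf("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-9)) stopf("distance matrix diagonal must be zero")
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  structure(list(phylo = ape::as.phylo(hc), hclust = hc, labels = labels),
            class = "motif_tree")
}

#' Cut a UPGMA motif tree into similarity clusters
#'
#' Cuts at the tree height corresponding to the success Z-score: two motifs
#' end up in one cluster exactly when they merged at a cluster distance of
#' at most `z_to_distance(z_success)` (node height convention: height =
#' cluster distance / 2).
#'
#' @param tree a `motif_tree` from [upgma_tree()].
#' @param p a [comparison_params()] object.
#' @return Named integer vector of cluster memberships, one per leaf.
#' @export
cut_clusters <- function(tree, p = comparison_params()) {
  stopifnot(inherits(tree, "motif_tree"))
  stats::cutree(tree$hclust, h = z_to_distance(p$z_success, p))
}

#' Benchmark success rate of predicted motifs
#'
#' For each (predicted, experimental) motif pair, computes the best sliding
#' comparison and its decoy-calibrated Z-score; a prediction counts as
#' correct when `z >= z_success` (similarity at 95 percent confidence).
#'
#' @param pairs list of two-element lists/pairs `(predicted, experimental)`.
#' @param decoys a `decoy_set` used for calibration.
#' @param p a [comparison_params()] object.
#' @return The success fraction in \[0, 1\]. The per-pair Z-scores are
#'   attached as attribute `z`.
#' @export
benchmark_success <- function(pairs, decoys, p = comparison_params()) {
  if (length(pairs) == 0L) stopf("no motif pairs supplied")
  z <- vapply(pairs, function(pr) {
    cmp <- fisher_slide_compare(pr[[1]], pr[[2]], p)
    similarity_zscore(cmp, pr[[1]], decoys, p)
  }, numeric(1))
  structure(mean(z >= p$z_success), z = z)
}
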
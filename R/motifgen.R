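# From raw interface scores to normalized scores, relative affinities,
# a selected binding-site set, and a position weight matrix.

#' Affinity-transform parameters
#'
#' Parameters of the score-to-affinity mapping and site selection: the
#' exponential slope constant `A` (kcal/mol) at temperature `T` (K), the
#' Boltzmann constant `k_B` (kcal/(mol K), fixed so that `A/(k_B T)` is
#' reproducible), the relative-affinity selection cutoff `gamma`, and the cap
#' on the number of selected binding sites.
#'
#' @param A slope constant in kcal/mol (default 4.74).
#' @param T temperature in Kelvin (default 298).
#' @param k_B Boltzmann constant in kcal/(mol K) (default 1.9872041e-3).
#' @param gamma relative-affinity cutoff in (0, 1) (default 0.25; sites with
#'   `K_a >= gamma` are selected -- the boundary is inclusive).
#' @param max_sites maximum number of selected sites (default 300).
#' @return An object of class `affinity_params`.
#' @export
affinity_params <- function(A = 4.74, T = 298, k_B = 1.9872041e-3,
                            gamma = 0.25, max_sites = 300) {
  stopifnot(A > 0, T > 0, k_B > 0, gamma > 0, gamma < 1, max_sites >= 1)
  structure(list(A = A, T = T, k_B = k_B, gamma = gamma,
                 max_sites = as.integer(max_sites)),
            class = "affinity_params")
}

#' Min-max normalize raw interface scores
#'
#' `S_norm = (S_RV - min S_RV) / (max S_RV - min S_RV)`: 0 marks the
#' strongest predicted binder (lowest raw score), 1 the weakest. The mapping
#' is invariant under affine rescaling of the raw scores. A table in which
#' all scores are equal carries no specificity signal and is rejected.
#'
#' @param t a `score_table` from [score_all_kmers()] (or any data.frame with
#'   `kmer` and `s_rv` columns).
#' @return An `affinity_table`: the input with an `s_norm` column added.
#' @export
normalize_scores <- function(t) {
  stopifnot(is.data.frame(t), all(c("kmer", "s_rv") %in% names(t)))
  lo <- min(t$s_rv); hi <- max(t$s_rv)
  if (hi - lo <= 0)
    stopf("degenerate score table: all %d scores are equal (no specificity)",
          nrow(t))
  t$s_norm <- (t$s_rv - lo) / (hi - lo)
  class(t) <- c("affinity_table", "data.frame")
  t
}

#' Transform a normalized score into a relative binding affinity
#'
#' `K_a = exp(-A / (k_B T) * S_norm)`, mapping `S_norm = 0` (strongest
#' binder) to `K_a = 1` and decaying exponentially; at the default
#' parameters the exponent slope `A/(k_B T)` is about 8.004, so the weakest
#' binder gets `K_a` of about 3.3e-4.
#'
#' @param s_norm numeric vector of normalized scores in \[0, 1\].
#' @param p an [affinity_params()] object.
#' @return Relative affinities in (0, 1\].
#' @export
affinity_transform <- function(s_norm, p = affinity_params()) {
  if (any(s_norm < 0 | s_norm > 1))
    stopf("normalized scores must lie in [0, 1]")
  exp(-p$A / (p$k_B * p$T) * s_norm)
}

#' Select the binding-site set
#'
#' Computes `K_a` for every k-mer (if not already present), keeps those with
#' `K_a >= gamma`, sorts by `K_a` descending (ties broken lexicographically
#' by k-mer for determinism) and truncates to `max_sites`.
#'
#' @param t an `affinity_table` from [normalize_scores()].
#' @param p an [affinity_params()] object.
#' @return A `binding_sites` data.frame with columns `kmer`, `s_rv`,
#'   `s_norm`, `k_a`, sorted by decreasing `k_a`. Empty (with a warning)
#'   when no site passes the cutoff.
#' @export
select_sites <- function(t, p = affinity_params()) {
  stopifnot(is.data.frame(t), all(c("kmer", "s_norm") %in% names(t)))
  if (is.null(t$k_a)) t$k_a <- affinity_transform(t$s_norm, p)
  keep <- t[t$k_a >= p$gamma, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warnf("no sequence reaches the affinity cutoff %g; motif cannot be built",
          p$gamma)
  }
  keep <- keep[order(-keep$k_a, keep$kmer), , drop = FALSE]
  keep <- utils::head(keep, p$max_sites)
  rownames(keep) <- NULL
  class(keep) <- c("binding_sites", "data.frame")
  keep
}

#' Build a position weight matrix from affinity-weighted binding sites
#'
#' Each selected k-mer contributes its relative affinity as weight:
#' `f(pos, b) = sum of K_a over sites with base b at pos / sum of K_a`.
#' All sites are in register (threading enumerates fixed-position k-mers),
#' so no alignment step is needed.
#'
#' @param sites a `binding_sites` data.frame (columns `kmer`, `k_a`), or any
#'   data.frame with those columns; k-mers must share one length.
#' @param name motif name stored on the PWM.
#' @return A `pwm`: 4 x k numeric matrix (rows A, C, G, T; columns summing
#'   to 1).
#' @export
build_pwm <- function(sites, name = "motif") {
  stopifnot(is.data.frame(sites), all(c("kmer", "k_a") %in% names(sites)))
  if (nrow(sites) == 0L) stopf("no binding sites to build a PWM from")
  k <- unique(nchar(sites$kmer))
  if (length(k) != 1L) stopf("binding sites have mismatched lengths")
  mat <- matrix(0, nrow = 4, ncol = k, dimnames = list(c("A", "C", "G", "T")))
  chars <- do.call(rbind, strsplit(sites$kmer, ""))
  for (j in seq_len(k)) {
    w <- tapply(sites$k_a, chars[, j], sum)
    mat[names(w), j] <- w
  }
  mat <- sweep(mat, 2, colSums(mat), `/`)
  new_pwm(mat, name = name)
}

new_pwm <- function(mat, name = "motif") {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4L)
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(mat < 0)) stopf("negative PWM frequencies")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9))
    stopf("PWM columns must sum to 1 (max deviation %.3g)", max(abs(cs - 1)))
  structure(mat, class = c("pwm", "matrix"), name = name)
}

#' Construct / validate a position weight matrix
#'
#' @param mat 4 x k matrix of base frequencies (rows A, C, G, T in that
#'   order); every column must sum to 1.
#' @param name motif name.
#' @return A `pwm` object.
#' @export
pwm <- function(mat, name = "motif") new_pwm(mat, name)

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%d columns), consensus %s\n",
              attr(x, "name") %||% "motif", ncol(x), pwm_consensus(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' Per-column argmax base; ties resolved to the lexicographically first base.
#'
#' @param m a `pwm`.
#' @return Character consensus string.
#' @export
pwm_consensus <- function(m) {
  paste(rownames(m)[apply(unclass(m), 2, which.max)], collapse = "")
}
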
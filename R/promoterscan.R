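# Promoter extraction around TSSs, exact match-score null distributions,
# PWM scanning and target-gene ranking.

#' Promoter scanning parameters
#'
#' @param upstream bases upstream of the TSS included in a promoter
#'   (default 1500).
#' @param downstream bases downstream of the TSS included (default 500).
#' @param p_cutoff per-window match p-value cutoff for reporting a hit
#'   (default 1e-4; no multiple-testing correction is applied).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param background base composition of the null model; `NULL` (default)
#'   estimates it from the scanned promoter set.
#' @param score_grid resolution of the discretized score grid for the exact
#'   null distribution (default 1e-4).
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(upstream = 1500, downstream = 500, p_cutoff = 1e-4,
                        both_strands = TRUE, background = NULL,
                        score_grid = 1e-4) {
  stopifnot(upstream >= 0, downstream >= 0, p_cutoff > 0, p_cutoff <= 1,
            score_grid > 0)
  if (!is.null(background)) {
    stopifnot(length(background) == 4L, all(background >= 0))
    background <- background / sum(background)
    names(background) <- c("A", "C", "G", "T")
  }
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 p_cutoff = p_cutoff, both_strands = isTRUE(both_strands),
                 background = background, score_grid = score_grid),
            class = "scan_params")
}

read_tss_annotation <- function(tss) {
  if (inherits(tss, "GRanges")) return(tss)
  ext <- tolower(tools::file_ext(tss))
  gr <- if (ext %in% c("gff", "gff3", "gtf")) {
    rtracklayer::import(tss)
  } else {
    tryCatch(rtracklayer::import(tss, format = "BED"),
             error = function(e) stopf("malformed BED file '%s': %s",
                                       tss, conditionMessage(e)))
  }
  if (is.null(gr$name) && !is.null(gr$ID)) gr$name <- gr$ID
  if (is.null(gr$name) && !is.null(gr$gene_id)) gr$name <- gr$gene_id
  if (is.null(gr$name)) gr$name <- paste0("feature", seq_along(gr))
  gr
}

#' Extract promoter sequences around transcription start sites
#'
#' The promoter of a feature is the window from `upstream` bases before to
#' `downstream` bases after its TSS (the feature's 5' end), oriented so the
#' returned sequence reads 5'->3' relative to the gene: minus-strand
#' promoters are reverse-complemented. Windows running off a contig edge are
#' clipped and flagged.
#'
#' @param genome a FASTA path or named `DNAStringSet`/character vector of
#'   contig sequences.
#' @param tss a BED/GFF path or `GRanges` of TSS-anchored features (the
#'   feature's strand-aware start is used as the TSS; the BED `name` column
#'   gives the gene id).
#' @param p a [scan_params()] object.
#' @return A `promoter_set` data.frame: `promoter_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open genomic window), `clipped`,
#'   `seq`.
#' @export
extract_promoters <- function(genome, tss, p = scan_params()) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- read_tss_annotation(tss)

  missing <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))),
                     names(genome))
  if (length(missing))
    stopf("chromosome(s) %s absent from the genome FASTA",
          paste(missing, collapse = ", "))

  prom <- GenomicRanges::promoters(gr, upstream = p$upstream,
                                   downstream = p$downstream)
  st <- GenomicRanges::start(prom); en <- GenomicRanges::end(prom)
  chrom <- as.character(GenomeInfoDb::seqnames(prom))
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  cl_st <- pmax(st, 1L); cl_en <- pmin(en, clen)
  clipped <- cl_st != st | cl_en != en
  strand <- as.character(BiocGenerics::strand(prom))
  strand[strand == "*"] <- "+"

  seqs <- vapply(seq_along(prom), function(i) {
    s <- Biostrings::subseq(genome[[chrom[i]]], cl_st[i], cl_en[i])
    if (strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))

  gene <- gr$name
  structure(data.frame(
    promoter_id = paste0(gene, "_p", stats::ave(seq_along(gene), gene,
                                                FUN = seq_along)),
    gene_id = gene, chrom = chrom, strand = strand,
    start = cl_st - 1L, end = cl_en, clipped = clipped, seq = seqs,
    stringsAsFactors = FALSE), class = c("promoter_set", "data.frame"))
}

#' Exact null distribution of PWM match scores
#'
#' The match score of a k-mer against a PWM is the sum over positions of the
#' PWM frequency of the letter at that position. Under an iid background,
#' the exact score distribution is obtained by position-wise convolution of
#' the per-column score distributions on a discretized score grid.
#'
#' @param m a `pwm`.
#' @param background base frequencies of the null model (default uniform).
#' @param grid score grid resolution (default 1e-4; scores are rounded to
#'   the grid before convolution, and scanned scores use the same rounding).
#' @return A `score_distribution` list: `grid`, `support` (integer grid
#'   scores), `pmf` and `tail` (`P(score >= s)` aligned with `support`).
#' @export
score_distribution <- function(m, background = rep(0.25, 4), grid = 1e-4) {
  stopifnot(inherits(m, "pwm"), length(background) == 4L)
  background <- background / sum(background)
  ints <- round(unclass(m) / grid)              # 4 x k integer scores
  pmf <- 1; offset <- 0L                        # pmf over support offset+0:n
  for (j in seq_len(ncol(ints))) {
    col <- ints[, j]
    lo <- min(col)
    shift <- col - lo
    width <- length(pmf) + max(shift)
    new <- numeric(width)
    for (b in 1:4) {
      if (background[b] == 0) next
      idx <- seq_along(pmf) + shift[b]
      new[idx] <- new[idx] + background[b] * pmf
    }
    pmf <- new; offset <- offset + lo
  }
  support <- offset + seq_along(pmf) - 1L
  keep <- pmf > 0 | seq_along(pmf) %in% c(1L, length(pmf))
  structure(list(grid = grid, support = support[keep], pmf = pmf[keep],
                 tail = rev(cumsum(rev(pmf[keep])))),
            class = "score_distribution")
}

# P(score >= s) for integer grid scores s (vectorized).
tail_probability <- function(dist, s_int) {
  idx <- findInterval(s_int - 0.5, dist$support) + 1L
  out <- ifelse(idx > length(dist$support), 0, dist$tail[pmin(idx,
                                                      length(dist$support))])
  out[s_int <= dist$support[1]] <- 1
  out
}

encode_dna <- function(seq) {
  x <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  x  # NA marks ambiguous letters
}

scan_one_strand <- function(codes, ints, dist) {
  k <- ncol(ints)
  n <- length(codes) - k + 1L
  if (n < 1L) return(NULL)
  total <- rep(0L, n)
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    cj <- codes[j:(j + n - 1L)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 1L
    total <- total + ints[cbind(cj, j)]
  }
  list(score_int = total, ok = ok,
       p = tail_probability(dist, total))
}

#' Scan promoters with a PWM
#'
#' Scores every window of width `ncol(m)` on the promoter (and, by default,
#' its reverse complement) by summing the PWM frequencies of the matching
#' letters; windows whose exact match p-value (from [score_distribution()])
#' is at most `p$p_cutoff` are reported. Windows containing ambiguous bases
#' are skipped. Hit positions are 0-based offsets of the window start on the
#' promoter's forward (5'->3') sequence for both strands; minus-strand hits
#' report the reverse-complement word actually matched.
#'
#' @param m a `pwm`.
#' @param promoters a `promoter_set` from [extract_promoters()], or a named
#'   character vector of sequences.
#' @param p a [scan_params()] object.
#' @return A `hit_table` data.frame: `promoter_id`, `gene_id`, `position`,
#'   `strand`, `word`, `score`, `p_value`, sorted by p-value then position.
#' @export
scan_pwm <- function(m, promoters, p = scan_params()) {
  stopifnot(inherits(m, "pwm"))
  if (is.character(promoters))
    promoters <- data.frame(
      promoter_id = names(promoters) %||% paste0("seq", seq_along(promoters)),
      gene_id = names(promoters) %||% paste0("seq", seq_along(promoters)),
      seq = unname(promoters), stringsAsFactors = FALSE)
  k <- ncol(m)
  if (any(nchar(promoters$seq) < k))
    stopf("promoter shorter than the motif width %d", k)

  background <- p$background
  if (is.null(background)) {
    pooled <- paste(promoters$seq, collapse = "")
    cnt <- vapply(c("A", "C", "G", "T"), function(b)
      sum(strsplit(toupper(pooled), "")[[1]] == b), numeric(1))
    if (sum(cnt) == 0) cnt <- rep(1, 4)
    background <- cnt / sum(cnt)
  }
  dist <- score_distribution(m, background, grid = p$score_grid)
  ints <- round(unclass(m) / p$score_grid)
  ints_rc <- round(unclass(reverse_complement_pwm(m)) / p$score_grid)

  res <- list()
  for (i in seq_len(nrow(promoters))) {
    codes <- encode_dna(promoters$seq[i])
    for (strand in c("+", if (p$both_strands) "-")) {
      sc <- scan_one_strand(codes, if (strand == "+") ints else ints_rc, dist)
      if (is.null(sc)) next
      hit <- which(sc$ok & sc$p <= p$p_cutoff)
      if (!length(hit)) next
      words <- vapply(hit, function(h)
        substr(promoters$seq[i], h, h + k - 1L), character(1))
      if (strand == "-")
        words <- vapply(words, function(w) as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(w))),
          character(1))
      res[[length(res) + 1L]] <- data.frame(
        promoter_id = promoters$promoter_id[i],
        gene_id = promoters$gene_id[i],
        position = hit - 1L, strand = strand, word = unname(words),
        score = sc$score_int[hit] * p$score_grid, p_value = sc$p[hit],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(promoter_id = character(0), gene_id = character(0),
               position = integer(0), strand = character(0),
               word = character(0), score = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Rank putative target genes from scan hits
#'
#' Collapses hits per gene over all of its promoters and both strands by the
#' best (highest) match score; genes are sorted by best score descending,
#' ties broken by p-value then gene id. Genes without hits are omitted.
#'
#' @param hits a `hit_table` from [scan_pwm()].
#' @param promoters optional `promoter_set` (unused columns tolerated);
#'   retained for interface symmetry.
#' @return A data.frame: `gene_id`, `best_score`, `best_p`, `n_hits`,
#'   ranked best first.
#' @export
rank_targets <- function(hits, promoters = NULL) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L)
    return(data.frame(gene_id = character(0), best_score = numeric(0),
                      best_p = numeric(0), n_hits = integer(0)))
  sp <- split(hits, hits$gene_id)
  out <- do.call(rbind, lapply(sp, function(h) {
    i <- which.max(h$score)
    data.frame(gene_id = h$gene_id[1], best_score = h$score[i],
               best_p = h$p_value[i], n_hits = nrow(h),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$best_score, out$best_p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
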
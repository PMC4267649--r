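# Distance-dependent, residue-specific knowledge-based potential for
# protein-DNA interfaces.

#' Distance binning scheme of the pair potential
#'
#' Distances between protein and DNA heavy atoms are mapped to bins: a wide
#' first bin followed by uniform bins up to the cutoff, beyond which pairs
#' are not scored. Defaults give 8 bins: \[0,3), \[3,4), ..., \[9,10).
#'
#' @param cutoff maximum scored distance in Angstrom (default 10).
#' @param first_bin_width width of the first bin in Angstrom (default 3).
#' @param other_bin_width width of the remaining bins in Angstrom (default 1).
#' @param n_bins total number of bins (default 8). The widths must tile the
#'   cutoff exactly: `first_bin_width + (n_bins - 1) * other_bin_width ==
#'   cutoff`.
#' @return An object of class `distance_binning`.
#' @export
distance_binning <- function(cutoff = 10, first_bin_width = 3,
                             other_bin_width = 1, n_bins = 8) {
  stopifnot(cutoff > 0, first_bin_width > 0, other_bin_width > 0, n_bins >= 1)
  if (abs(first_bin_width + (n_bins - 1) * other_bin_width - cutoff) > 1e-9)
    stopf("bin widths do not tile the cutoff: %g + %d*%g != %g",
          first_bin_width, n_bins - 1, other_bin_width, cutoff)
  structure(list(cutoff = cutoff, first_bin_width = first_bin_width,
                 other_bin_width = other_bin_width, n_bins = as.integer(n_bins)),
            class = "distance_binning")
}

#' Map a distance to its potential bin
#'
#' @param d numeric vector of distances in Angstrom (>= 0).
#' @param b a [distance_binning()] scheme.
#' @return Integer vector of 0-based bin indices; `NA` for distances at or
#'   beyond the cutoff.
#' @export
#' @examples
#' bin_index(c(2, 3.5, 12))  # 0 1 NA
bin_index <- function(d, b = distance_binning()) {
  if (any(d < 0)) stopf("negative distance")
  idx <- ifelse(d < b$first_bin_width, 0L,
                1L + floor((d - b$first_bin_width) / b$other_bin_width))
  idx <- as.integer(idx)
  idx[d >= b$cutoff] <- NA_integer_
  idx
}

# Extract the protein-DNA heavy-atom pair table of one complex: one row per
# pair within the cutoff, typed as (residue type, protein atom name) x
# (base letter, base atom name) with the distance bin. Waters are excluded.
interface_pairs <- function(protein, dna, b) {
  if (nrow(protein) == 0L || nrow(dna) == 0L)
    return(data.table::data.table(ptype = character(0), patom = character(0),
                                  btype = character(0), batom = character(0),
                                  bin = integer(0)))
  d <- cross_dist(protein[, c("x", "y", "z")], dna[, c("x", "y", "z")])
  hit <- which(d < b$cutoff, arr.ind = TRUE)
  data.table::data.table(
    ptype = protein$residue_name[hit[, 1]],
    patom = protein$name[hit[, 1]],
    btype = residue_base_letter(dna$residue_name[hit[, 2]]),
    batom = dna$name[hit[, 2]],
    bin = bin_index(d[hit], b))
}

new_pair_potential <- function(table, sigma, binning, meta = list()) {
  stopifnot(data.table::is.data.table(table),
            all(c("ptype", "patom", "btype", "batom", "bin", "energy") %in%
                  names(table)))
  if (any(!is.finite(table$energy))) stopf("non-finite potential energies")
  data.table::setkeyv(table, c("ptype", "patom", "btype", "batom", "bin"))
  structure(list(table = table, sigma = sigma, binning = binning, meta = meta),
            class = "pair_potential")
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf(
    "<pair_potential> %d energy cells, sigma=%g, %d bins to %g A%s\n",
    nrow(x$table), x$sigma, x$binning$n_bins, x$binning$cutoff,
    if (length(x$meta$n_complexes))
      sprintf(", trained on %d complexes", x$meta$n_complexes) else ""))
  invisible(x)
}

#' Train the knowledge-based pair potential
#'
#' Counts protein-DNA heavy-atom pairs within the distance cutoff over a set
#' of curated complexes, typed by (protein residue, protein atom name) and
#' (base, base atom name), binned by distance. Energies are log-odds against
#' a reference state that factorizes pair-type and distance preferences:
#' `e = -ln((N + sigma) / (N_exp + sigma))` with
#' `N_exp(tp, td, bin) = N(tp, td, .) * N(., ., bin) / N(., ., .)`.
#' Cells whose pair type was never observed keep energy 0 (the pseudocount
#' limit). With `self_swapped = TRUE` each complex is first rethreaded with
#' its own native sequence via [swap_bases()], so training sees the same
#' idealized base geometry that scoring of threaded models sees.
#'
#' @param complexes list of `curated_complex` objects.
#' @param b a [distance_binning()] scheme.
#' @param sigma pseudocount (default 1).
#' @param self_swapped logical; train on native-sequence rethreaded models
#'   (default FALSE).
#' @return A `pair_potential`.
#' @export
train_potential <- function(complexes, b = distance_binning(), sigma = 1,
                            self_swapped = FALSE) {
  if (length(complexes) == 0L) stopf("no complexes supplied")
  stopifnot(all(vapply(complexes, inherits, logical(1), "curated_complex")))
  pair_tabs <- lapply(complexes, function(cc) {
    if (self_swapped) {
      m <- swap_bases(cc, cc$native_sequence)
      prot <- m$atoms[m$atoms$record_class == "protein", , drop = FALSE]
      dna <- m$atoms[m$atoms$record_class == "dna", , drop = FALSE]
    } else {
      prot <- cc$protein; dna <- cc$dna
    }
    interface_pairs(prot, dna, b)
  })
  pairs <- data.table::rbindlist(pair_tabs)
  if (nrow(pairs) == 0L) stopf("no protein-DNA pairs within the cutoff")

  bin <- ptype <- patom <- btype <- batom <- N <- NULL  # NSE guards
  counts <- pairs[, list(N = .N), by = c("ptype", "patom", "btype", "batom",
                                         "bin")]
  total <- sum(counts$N)
  bin_marg <- counts[, list(Nbin = sum(N)), by = "bin"]
  type_marg <- counts[, list(Ntype = sum(N)),
                      by = c("ptype", "patom", "btype", "batom")]

  grid <- data.table::CJ(row = seq_len(nrow(type_marg)),
                         bin = 0:(b$n_bins - 1L))
  tab <- type_marg[grid$row]
  tab$bin <- grid$bin
  tab <- merge(tab, counts,
               by = c("ptype", "patom", "btype", "batom", "bin"),
               all.x = TRUE)
  tab$N[is.na(tab$N)] <- 0L
  tab <- merge(tab, bin_marg, by = "bin", all.x = TRUE)
  tab$Nbin[is.na(tab$Nbin)] <- 0L
  n_exp <- tab$Ntype * tab$Nbin / total
  tab$energy <- -log((tab$N + sigma) / (n_exp + sigma))
  tab <- tab[, c("ptype", "patom", "btype", "batom", "bin", "energy")]
  new_pair_potential(tab, sigma = sigma, binning = b,
                     meta = list(n_complexes = length(complexes),
                                 reference_state = "pairtype x distance marginals",
                                 self_swapped = self_swapped))
}

#' Score a TF-DNA interface with a pair potential
#'
#' Sums the potential energy over every protein-DNA heavy-atom pair within
#' the distance cutoff. Waters are never scored. Pair-type/bin combinations
#' absent from the potential table contribute 0 (the pseudocount limit).
#' Atoms whose residue is neither a canonical amino acid nor a canonical
#' DNA nucleotide are skipped with a warning, or raise an error in strict
#' mode.
#'
#' @param m a `structure_model` containing protein and DNA atoms.
#' @param pot a `pair_potential`.
#' @param b a [distance_binning()] scheme (defaults to the potential's own).
#' @param strict error (rather than warn and skip) on unclassifiable atoms.
#' @return The raw interface score S_RV (a single number; lower is more
#'   favorable).
#' @export
score_interface <- function(m, pot, b = pot$binning, strict = FALSE) {
  stopifnot(inherits(m, "structure_model"), inherits(pot, "pair_potential"))
  atoms <- m$atoms
  unknown <- atoms$record_class == "other"
  if (any(unknown)) {
    msg <- sprintf("%d atoms with unknown residue type (%s)", sum(unknown),
                   paste(unique(atoms$residue_name[unknown]), collapse = ","))
    if (strict) stopf("%s", msg) else warnf("%s skipped", msg)
    atoms <- atoms[!unknown, , drop = FALSE]
  }
  prot <- atoms[atoms$record_class == "protein", , drop = FALSE]
  dna <- atoms[atoms$record_class == "dna", , drop = FALSE]
  pairs <- interface_pairs(prot, dna, b)
  if (nrow(pairs) == 0L) return(0)
  e <- pot$table[pairs, on = c("ptype", "patom", "btype", "batom", "bin")]
  sum(e$energy, na.rm = TRUE)
}

#' Score every enumerated k-mer threaded onto a curated complex
#'
#' Convenience driver for the core pipeline step: enumerate all 4^k
#' sequences, thread each with [swap_bases()] (optionally relaxing clashes),
#' and score with [score_interface()].
#'
#' @param cc a `curated_complex`.
#' @param pot a `pair_potential`.
#' @param relax run [relax_clashes()] on each threaded model (default FALSE).
#' @param relax_steps descent iterations when `relax = TRUE`.
#' @return A `score_table`: data.frame with columns `kmer` and `s_rv`,
#'   one row per enumerated sequence.
#' @export
score_all_kmers <- function(cc, pot, relax = FALSE, relax_steps = 100) {
  stopifnot(inherits(cc, "curated_complex"))
  kmers <- enumerate_kmers(cc$k)
  s_rv <- vapply(kmers, function(s) {
    m <- swap_bases(cc, s)
    if (relax) m <- relax_clashes(m, steps = relax_steps)
    score_interface(m, pot)
  }, numeric(1))
  structure(data.frame(kmer = kmers, s_rv = unname(s_rv),
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}

#' Serialize a pair potential to JSON
#'
#' @param pot a `pair_potential`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_potential <- function(pot, file) {
  stopifnot(inherits(pot, "pair_potential"))
  obj <- list(format = "structmotif_potential", version = 1L,
              sigma = pot$sigma, binning = unclass(pot$binning),
              meta = pot$meta, table = as.data.frame(pot$table))
  jsonlite::write_json(obj, file, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a pair potential serialized by [write_potential()]
#'
#' @param file JSON path.
#' @return A `pair_potential`.
#' @export
read_potential <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$format, "structmotif_potential"))
    stopf("'%s' is not a serialized potential", file)
  tab <- data.table::as.data.table(obj$table)
  tab$bin <- as.integer(tab$bin)
  new_pair_potential(tab, sigma = obj$sigma,
                     binning = do.call(distance_binning, as.list(obj$binning)),
                     meta = as.list(obj$meta))
}
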
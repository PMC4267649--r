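# Synthetic fixtures with known ground truth: toy TF-DNA complexes, planted
# potentials, random PWM sets and toy genomes. Everything is reproducible
# byte-for-byte from its seed and arguments.

PROBE_ATOMS <- data.frame(
  name = c("N", "CA", "C", "O", "CB"),
  element = c("N", "C", "C", "O", "C"),
  # offsets from the probe anchor point in the (radial, tangential, axial)
  # frame of the contacted nucleotide
  dr = c(0, 1.5, -1.5, 0, 0),
  dt = c(1.5, 0, 0, -1.5, 0),
  dz = c(0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

# rotation about z
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3)
}

# Compact synthetic sugar-phosphate layout shared by all four nucleotides,
# in the local nucleotide frame (x = radially outward from the helix axis,
# glycosidic N at the origin). The toy duplex only needs correct atom names
# and controlled distances, not covalent backbone geometry; keeping the
# backbone within ~5 A of the glycosidic nitrogen guarantees that a probe
# anchored over one position stays outside the 4.5 A contact shell of every
# other position.
TOY_BACKBONE <- data.frame(
  atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
           "C2'", "C1'"),
  element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C"),
  x = c(3.9, 4.9, 3.9, 3.6, 3.0, 2.9, 1.7, 3.0, 4.0, 1.8, 1.3),
  y = c(0.9, 1.5, 1.2, -0.6, -1.2, -0.4, -0.9, 1.0, 1.5, 1.4, 0.3),
  z = c(-0.9, -0.4, -1.6, -0.8, 0.3, 1.4, 1.9, 1.3, 2.0, 0.9, 0.2),
  stringsAsFactors = FALSE
)

# Express an ideal nucleotide in a standard local frame: glycosidic N at the
# origin, base centroid along -x, base plane normal along +z; the base
# moiety keeps its idealized planar geometry, the backbone uses the compact
# synthetic layout above.
nucleotide_template <- function(base) {
  geom <- ideal_nucleotide_geometry
  res <- c(A = "DA", C = "DC", G = "DG", T = "DT")[[base]]
  df <- geom[geom$residue == res & !(geom$atom %in% DNA_BACKBONE_ATOMS), ,
             drop = FALSE]
  xyz <- as.matrix(df[, c("x", "y", "z")])
  glyc <- ANCHOR_TRIADS[[base]][1]
  origin <- xyz[df$atom == glyc, ]
  xyz <- sweep(xyz, 2, origin)
  ring <- xyz[df$atom %in% BASE_RING_ATOMS[[base]], , drop = FALSE]
  centroid <- colMeans(ring)
  normal <- svd(sweep(ring, 2, colMeans(ring)))$v[, 3]
  ex <- -centroid / sqrt(sum(centroid^2))
  ez <- normal - sum(normal * ex) * ex
  ez <- ez / sqrt(sum(ez^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  frame <- cbind(ex, ey, ez)
  list(atoms = rbind(TOY_BACKBONE[, c("atom", "element")],
                     df[, c("atom", "element")]),
       xyz = rbind(as.matrix(TOY_BACKBONE[, c("x", "y", "z")]),
                   xyz %*% frame))
}

#' Generate a synthetic TF-DNA complex with controlled contacts
#'
#' Builds an idealized straight duplex (full heavy-atom planar bases on a
#' regular helix: 36 degree twist, glycosidic nitrogens at radius 9 A, and a
#' deliberately stretched 7 A rise so that the contact shell of each position
#' is cleanly separated from its neighbors; the complementary strand is a
#' radially displaced copy, which keeps strand pairing unambiguous without
#' modeling base-pairing geometry)
#' plus a pseudo-protein probe: one five-atom residue per requested contact
#' position, whose CB sits 2.6 A above that nucleotide's glycosidic nitrogen
#' -- inside the first potential bin of that position for every base
#' identity, outside 4.5 A of every other position. Probe residues take
#' distinct amino-acid types in contact order, which is what
#' [make_planted_potential()] keys its energies on. One interface water is
#' placed near the first contact.
#'
#' @param n_bp duplex length in base pairs (default 9).
#' @param contacts integer positions (1-based along the duplex) the probe
#'   touches.
#' @param seed RNG seed; fully determines the output.
#' @param native optional native duplex sequence (random under `seed` when
#'   NULL).
#' @param resolution nominal resolution recorded on the model (default 2.0).
#' @param water include the interface water (default TRUE).
#' @return A `structure_model` (PDB-writable via [write_pdb()]).
#' @export
#' @examples
#' cc <- curate_complex(make_toy_complex(contacts = 2:4, seed = 7))
#' cc$k  # 3
make_toy_complex <- function(n_bp = 9, contacts = 2:4, seed = 1,
                             native = NULL, resolution = 2.0, water = TRUE) {
  contacts <- sort(unique(as.integer(contacts)))
  if (length(contacts) == 0L || any(contacts < 1L | contacts > n_bp))
    stopf("contact positions must lie in 1..%d", n_bp)
  if (length(contacts) > length(AMINO_ACIDS))
    stopf("at most %d contact positions supported", length(AMINO_ACIDS))
  if (is.null(native))
    native <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), n_bp,
                                           replace = TRUE), collapse = ""))
  if (nchar(native) != n_bp || grepl("[^ACGT]", native))
    stopf("native sequence must be %d bases over A/C/G/T", n_bp)
  bases <- strsplit(native, "")[[1]]

  rise <- 7; twist <- 36 * pi / 180; radius <- 9
  rows <- list()
  add_residue <- function(tmpl_atoms, xyz, resname, resno, chain, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = tmpl_atoms$atom, element = tmpl_atoms$element,
      residue_name = resname, residue_index = resno, chain_id = chain,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], record_class = class,
      stringsAsFactors = FALSE)
  }

  place_nt <- function(base, i, radial_offset) {
    tm <- nucleotide_template(base)
    theta <- twist * (i - 1)
    xyz <- sweep(tm$xyz, 2, c(radius + radial_offset, 0, 0), `+`)
    xyz <- xyz %*% t(rot_z(theta))
    sweep(xyz, 2, c(0, 0, rise * (i - 1)), `+`)
  }

  probe_sites <- list()   # per contact: anchor frame info
  for (i in seq_len(n_bp)) {
    tm <- nucleotide_template(bases[i])
    add_residue(tm$atoms, place_nt(bases[i], i, 0), paste0("D", bases[i]),
                i, "B", "dna")
  }
  for (i in seq_len(n_bp)) {
    comp <- BASE_COMPLEMENT[[bases[i]]]
    tm <- nucleotide_template(comp)
    add_residue(tm$atoms, place_nt(comp, i, 20), paste0("D", comp),
                i, "C", "dna")
  }

  # probe residues: anchor above the glycosidic N of each contacted position
  for (j in seq_along(contacts)) {
    i <- contacts[j]
    theta <- twist * (i - 1)
    glyc <- as.numeric(rot_z(theta) %*% c(radius, 0, 0)) +
      c(0, 0, rise * (i - 1))
    r_hat <- as.numeric(rot_z(theta) %*% c(1, 0, 0))
    t_hat <- as.numeric(rot_z(theta) %*% c(0, 1, 0))
    z_hat <- c(0, 0, 1)
    anchor <- glyc + 2.6 * z_hat
    xyz <- t(vapply(seq_len(nrow(PROBE_ATOMS)), function(a)
      anchor + PROBE_ATOMS$dr[a] * r_hat + PROBE_ATOMS$dt[a] * t_hat +
        PROBE_ATOMS$dz[a] * z_hat, numeric(3)))
    add_residue(data.frame(atom = PROBE_ATOMS$name,
                           element = PROBE_ATOMS$element), xyz,
                AMINO_ACIDS[j], j, "A", "protein")
    probe_sites[[j]] <- list(anchor = anchor, z_hat = z_hat)
  }
  if (water) {
    w <- probe_sites[[1]]$anchor + 1.5 * probe_sites[[1]]$z_hat
    add_residue(data.frame(atom = "O", element = "O"),
                matrix(w, 1, 3), "HOH", 1L, "W", "water")
  }

  atoms <- do.call(rbind, rows)
  # protein first, then DNA strands, then water: parse/round-trip friendly
  ord <- order(match(atoms$chain_id, c("A", "B", "C", "W")))
  new_structure_model(atoms[ord, ], resolution = resolution,
                      identifier = sprintf("toy_%s_seed%d", native, seed))
}

#' Planted pair potential favoring a chosen k-mer
#'
#' Constructs a pair potential whose only non-zero energies reward, in the
#' first distance bin, contacts between the i-th probe residue type (the
#' amino-acid type [make_toy_complex()] assigns to the i-th contact) and the
#' base-moiety atoms of the i-th planted base. On a toy complex whose
#' contacts are a contiguous stretch, the planted k-mer is then the unique
#' global minimum of the raw score over all 4^k threaded sequences: every
#' probe has a guaranteed first-bin contact with the position it touches
#' (via the swap-invariant glycosidic nitrogen) and no first-bin contact
#' with any other position.
#'
#' @param planted_kmer the favored sequence (length k over A/C/G/T).
#' @param b a [distance_binning()] scheme.
#' @param energy energy of a favored contact (default -1).
#' @return A `pair_potential`.
#' @export
make_planted_potential <- function(planted_kmer, b = distance_binning(),
                                   energy = -1) {
  planted_kmer <- toupper(planted_kmer)
  if (grepl("[^ACGT]", planted_kmer)) stopf("planted k-mer must be A/C/G/T")
  k <- nchar(planted_kmer)
  if (k > length(AMINO_ACIDS)) stopf("planted k-mer too long")
  letters_k <- strsplit(planted_kmer, "")[[1]]
  tabs <- lapply(seq_len(k), function(i) {
    batoms <- base_moiety_atoms(letters_k[i])
    data.table::CJ(ptype = AMINO_ACIDS[i], patom = PROBE_ATOMS$name,
                   btype = letters_k[i], batom = batoms, bin = 0L)
  })
  tab <- data.table::rbindlist(tabs)
  tab$energy <- energy
  new_pair_potential(tab, sigma = 1, binning = b,
                     meta = list(planted_kmer = planted_kmer))
}

#' Random position weight matrices
#'
#' Columns are drawn Dirichlet-style: four gamma variates with shape
#' `1/sharpness`, normalized to sum to 1. Larger `sharpness` gives more
#' peaked (informative) columns; as `sharpness` grows without bound the
#' columns approach point masses, while `sharpness` near 0 gives
#' near-uniform columns.
#'
#' @param n number of PWMs.
#' @param k columns per PWM.
#' @param sharpness column peakedness (default 2, moderately informative
#'   columns).
#' @param seed RNG seed; fully determines the output.
#' @return List of `pwm` objects named `decoy1..n`.
#' @export
make_random_pwms <- function(n, k, sharpness = 2, seed = 1) {
  stopifnot(n >= 1, k >= 1, sharpness > 0)
  out <- with_seed(seed, lapply(seq_len(n), function(i) {
    mat <- matrix(stats::rgamma(4 * k, shape = 1 / sharpness), nrow = 4)
    # gamma variates underflow to zero at very small shapes; the Dirichlet
    # limit there is a point mass on a uniformly chosen base
    for (j in which(colSums(mat) <= 0))
      mat[sample.int(4, 1), j] <- 1
    new_pwm(sweep(mat, 2, colSums(mat), `/`), name = paste0("decoy", i))
  }))
  names(out) <- paste0("decoy", seq_len(n))
  out
}

#' Toy genome with planted motif sites
#'
#' Generates one random-background chromosome carrying `n_genes` evenly
#' spaced genes on alternating strands, plants the given words at recorded
#' promoter offsets and strands, and returns the genome, a BED6-style TSS
#' annotation and the ground-truth table of planted sites. With `dir` set,
#' the genome FASTA and BED file are also written to disk.
#'
#' @param n_genes number of genes (default 10).
#' @param planted data.frame with columns `gene` (1-based gene number),
#'   `offset` (0-based offset of the site in the promoter, gene
#'   orientation), `strand` (`"+"`/`"-"` relative to the promoter) and
#'   `word`; NULL plants nothing.
#' @param seed RNG seed; fully determines the output.
#' @param upstream,downstream promoter window around the TSS (defaults
#'   1500/500).
#' @param dir optional output directory for `genome.fa` and `tss.bed`.
#' @return List with `genome` (named `DNAStringSet`), `tss` (`GRanges`),
#'   `truth` (data.frame with gene ids), and, when `dir` is given,
#'   `genome_path`/`tss_path`.
#' @export
make_toy_genome <- function(n_genes = 10, planted = NULL, seed = 1,
                            upstream = 1500, downstream = 500, dir = NULL) {
  stopifnot(n_genes >= 1)
  spacing <- upstream + downstream + 3000
  margin <- upstream + downstream
  chrom_len <- margin + n_genes * spacing + margin
  win <- upstream + downstream

  out <- with_seed(seed, {
    chrom <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    tss <- margin + spacing * (seq_len(n_genes) - 1L) + upstream + 1L # 1-based
    strand <- rep(c("+", "-"), length.out = n_genes)
    gene_id <- sprintf("gene%02d", seq_len(n_genes))

    prom_window <- function(g) {    # 1-based inclusive genomic window
      if (strand[g] == "+") c(tss[g] - upstream, tss[g] + downstream - 1L)
      else c(tss[g] - downstream + 1L, tss[g] + upstream)
    }
    if (!is.null(planted)) {
      stopifnot(all(c("gene", "offset", "strand", "word") %in%
                      names(planted)))
      for (r in seq_len(nrow(planted))) {
        g <- planted$gene[r]; o <- planted$offset[r]
        w <- toupper(planted$word[r])
        if (o < 0 || o + nchar(w) > win)
          stopf("planted site at offset %d does not fit the %d bp promoter",
                o, win)
        word_fwd <- if (planted$strand[r] == "+") w else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
        wl <- strsplit(word_fwd, "")[[1]]
        wd <- prom_window(g)
        if (strand[g] == "+") {
          at <- wd[1] + o
          chrom[at:(at + nchar(w) - 1L)] <- wl
        } else {
          # promoter seq is the reverse complement of the genomic window, so
          # the genome's forward strand holds the reverse complement of the
          # planted text, ending at window_top - offset
          at <- wd[2] - o
          chrom[(at - nchar(w) + 1L):at] <-
            strsplit(as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(word_fwd))), "")[[1]]
        }
      }
    }
    genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
    names(genome) <- "chr1"
    gene_len <- 600L
    gr_start <- ifelse(strand == "+", tss, tss - gene_len + 1L)
    gr <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(start = gr_start, width = gene_len),
      strand = strand, name = gene_id)
    GenomeInfoDb::seqlengths(gr) <- chrom_len
    truth <- if (is.null(planted)) {
      data.frame(gene_id = character(0), offset = integer(0),
                 strand = character(0), word = character(0))
    } else {
      data.frame(gene_id = gene_id[planted$gene], offset = planted$offset,
                 strand = planted$strand, word = toupper(planted$word),
                 stringsAsFactors = FALSE)
    }
    list(genome = genome, tss = gr, truth = truth)
  })

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$genome_path <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(out$genome, out$genome_path)
    out$tss_path <- file.path(dir, "tss.bed")
    bed <- data.frame(
      chrom = "chr1",
      start = GenomicRanges::start(out$tss) - 1L,
      end = GenomicRanges::end(out$tss),
      name = out$tss$name, score = 0,
      strand = as.character(BiocGenerics::strand(out$tss)))
    write.table(bed, out$tss_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  out
}
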
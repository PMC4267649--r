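# Structure input, curation filters, DNA trimming and interface extraction.

#' Curation parameters for TF-DNA complex structures
#'
#' Bundles the filters applied when curating a TF-DNA co-crystal structure:
#' the maximum acceptable crystallographic resolution, the protein-DNA atomic
#' contact cutoff used to trim the DNA to its protein-contacting stretch, the
#' maximum motif length accepted for exhaustive threading, and whether
#' interface crystal waters are retained.
#'
#' @param resolution_max maximum resolution in Angstrom (default 2.5).
#' @param contact_cutoff protein-DNA heavy-atom contact distance in Angstrom
#'   (default 4.5, boundary inclusive).
#' @param k_max maximum number of contacting base pairs accepted (default 9;
#'   threading enumerates 4^k sequences, so larger k is impractical).
#' @param keep_interface_waters retain crystal waters within
#'   `contact_cutoff` of both protein and DNA (default TRUE).
#' @return An object of class `curation_params`.
#' @export
curation_params <- function(resolution_max = 2.5, contact_cutoff = 4.5,
                            k_max = 9, keep_interface_waters = TRUE) {
  stopifnot(resolution_max > 0, contact_cutoff > 0, k_max >= 1)
  structure(list(resolution_max = resolution_max,
                 contact_cutoff = contact_cutoff,
                 k_max = as.integer(k_max),
                 keep_interface_waters = isTRUE(keep_interface_waters)),
            class = "curation_params")
}

new_structure_model <- function(atoms, resolution = NA_real_, identifier = "") {
  req <- c("name", "element", "residue_name", "residue_index", "chain_id",
           "x", "y", "z", "record_class")
  stopifnot(all(req %in% names(atoms)))
  if (nrow(atoms) == 0L) stopf("structure contains no atoms")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stopf("non-finite atom coordinates")
  # a residue index must identify a single residue within its chain
  key <- paste(atoms$chain_id, atoms$residue_index)
  per_res <- tapply(atoms$residue_name, key, function(v) length(unique(v)))
  if (any(per_res > 1L))
    stopf("residue index reused for different residues within a chain")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, resolution = resolution,
                 identifier = identifier),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cls <- table(x$atoms$record_class)
  cat(sprintf("<structure_model> %s: %d atoms (%s), resolution %s\n",
              x$identifier, nrow(x$atoms),
              paste(names(cls), cls, sep = "=", collapse = ", "),
              ifelse(is.na(x$resolution), "unknown",
                     sprintf("%.2f A", x$resolution))))
  invisible(x)
}

#' Parse a PDB-format structure file
#'
#' Reads ATOM/HETATM records into an atom table and classifies every residue
#' as protein, DNA, water or other against the canonical residue tables.
#' Hydrogens are dropped on input: all downstream operations (contacts,
#' potential) are defined on heavy atoms only. The crystallographic
#' resolution is taken from the `REMARK   2 RESOLUTION` record when present.
#'
#' @param file path to a PDB-format file.
#' @return An object of class `structure_model` with fields `atoms`
#'   (data.frame: name, element, residue_name, residue_index, chain_id,
#'   x, y, z, record_class), `resolution` (Angstrom or NA) and `identifier`.
#' @export
#' @examples
#' cplx <- make_toy_complex(contacts = 2:4, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(cplx, f)
#' parse_structure(f)
parse_structure <- function(file) {
  lines <- readLines(file, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stopf("no ATOM/HETATM records in '%s'", file)
  short <- which(is_atom & nchar(lines) < 54L)
  if (length(short))
    stopf("truncated ATOM/HETATM record at line %d of '%s'", short[1], file)

  resolution <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
    if (length(m)) resolution <- as.numeric(m)
  }

  pdb <- suppressWarnings(bio3d::read.pdb(file, verbose = FALSE))
  at <- pdb$atom
  element <- at$elesy
  element[is.na(element) | element == ""] <-
    sub("^[0-9']*([A-Za-z]).*$", "\\1", at$elety[is.na(element) | element == ""])
  element <- toupper(element)
  atoms <- data.frame(
    name = at$elety,
    element = element,
    residue_name = at$resid,
    residue_index = at$resno,
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    x = at$x, y = at$y, z = at$z,
    record_class = classify_residue(at$resid),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  new_structure_model(atoms, resolution = resolution,
                      identifier = tools::file_path_sans_ext(basename(file)))
}

#' Write a structure to a PDB-format file
#'
#' @param x a `structure_model`, `curated_complex`, or bare atom data.frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(x, file) {
  resolution <- NA_real_
  if (inherits(x, "structure_model")) {
    atoms <- x$atoms; resolution <- x$resolution
  } else if (inherits(x, "curated_complex")) {
    m <- as_structure_model(x); atoms <- m$atoms; resolution <- m$resolution
  } else atoms <- x
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.na(resolution))
    writeLines(sprintf(
      "REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", resolution), con)
  rec <- ifelse(atoms$record_class %in% c("water", "other"), "HETATM", "ATOM  ")
  name <- ifelse(nchar(atoms$name) < 4L, paste0(" ", atoms$name), atoms$name)
  writeLines(sprintf(
    "%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(atoms)) %% 100000L, name, " ",
    atoms$residue_name, atoms$chain_id, atoms$residue_index,
    atoms$x, atoms$y, atoms$z, 1, 0, atoms$element), con)
  writeLines("END", con)
  invisible(file)
}

# Pair the reference DNA strand with its complementary strand by C1'
# proximity. The reference strand is the first DNA chain in file order;
# positions are numbered 1..n along it, 5'->3' in residue-index order.
pair_duplex <- function(atoms) {
  dna <- atoms[atoms$record_class == "dna", , drop = FALSE]
  if (nrow(dna) == 0L) stopf("structure contains no DNA atoms")
  chains <- unique(dna$chain_id)
  ref_chain <- chains[1]
  ref <- dna[dna$chain_id == ref_chain, , drop = FALSE]
  ref_res <- sort(unique(ref$residue_index))
  other <- dna[dna$chain_id != ref_chain, , drop = FALSE]

  get_c1 <- function(df, chain, resno) {
    r <- df[df$chain_id == chain & df$residue_index == resno &
              df$name == "C1'", c("x", "y", "z"), drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    as.numeric(r[1, ])
  }

  comp_chain <- comp_resno <- rep(NA, length(ref_res))
  if (nrow(other) > 0L) {
    okey <- unique(other[, c("chain_id", "residue_index")])
    oc1 <- t(vapply(seq_len(nrow(okey)), function(i) {
      v <- get_c1(other, okey$chain_id[i], okey$residue_index[i])
      if (is.null(v)) rep(NA_real_, 3) else v
    }, numeric(3)))
    for (i in seq_along(ref_res)) {
      c1 <- get_c1(ref, ref_chain, ref_res[i])
      if (is.null(c1) || all(is.na(oc1))) next
      d <- sqrt(rowSums((oc1 - matrix(c1, nrow(oc1), 3, byrow = TRUE))^2))
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] < 25) {
        comp_chain[i] <- okey$chain_id[j]
        comp_resno[i] <- okey$residue_index[j]
      }
    }
  }
  base_of <- function(chain, resno) {
    if (is.na(chain)) return(NA_character_)
    rn <- dna$residue_name[dna$chain_id == chain & dna$residue_index == resno][1]
    residue_base_letter(rn)
  }
  data.frame(
    pos = seq_along(ref_res),
    ref_chain = ref_chain, ref_resno = ref_res,
    ref_base = vapply(ref_res, function(r) base_of(ref_chain, r), ""),
    comp_chain = as.character(comp_chain),
    comp_resno = as.integer(comp_resno),
    comp_base = mapply(base_of, as.character(comp_chain),
                       as.integer(comp_resno), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

residue_atoms <- function(atoms, chain, resno) {
  atoms[atoms$chain_id == chain & atoms$residue_index == resno, ,
        drop = FALSE]
}

#' Base-pair positions of the DNA duplex in contact with the protein
#'
#' A duplex position is contacting when at least one heavy atom of its
#' reference-strand nucleotide, or of the paired nucleotide on the
#' complementary strand, lies within `cutoff` of at least one protein heavy
#' atom (boundary inclusive). Positions are returned 5'->3' along the
#' reference strand.
#'
#' @param s a `structure_model` containing protein and DNA.
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return Integer vector of contacting duplex positions (may be empty).
#' @export
contacting_positions <- function(s, cutoff = 4.5) {
  stopifnot(inherits(s, "structure_model"))
  atoms <- s$atoms
  prot <- atoms[atoms$record_class == "protein", , drop = FALSE]
  pairing <- pair_duplex(atoms)
  if (nrow(prot) == 0L) return(integer(0))
  pxyz <- prot[, c("x", "y", "z")]
  hit <- vapply(seq_len(nrow(pairing)), function(i) {
    res <- residue_atoms(atoms, pairing$ref_chain[i], pairing$ref_resno[i])
    if (!is.na(pairing$comp_chain[i]))
      res <- rbind(res, residue_atoms(atoms, pairing$comp_chain[i],
                                      pairing$comp_resno[i]))
    any(cross_dist(res[, c("x", "y", "z")], pxyz) <= cutoff)
  }, logical(1))
  pairing$pos[hit]
}

#' Curate a TF-DNA complex structure
#'
#' Applies the curation filters: rejects structures with resolution worse
#' than `p$resolution_max`, trims the DNA duplex to the contiguous stretch
#' of base pairs in contact with the protein (a contact on either strand
#' marks the pair; non-contacting pairs flanked by contacting ones are
#' retained so the stretch stays contiguous), rejects motifs longer than
#' `p$k_max`, rejects non-canonical or incomplete retained bases, retains
#' interface crystal waters (within the contact cutoff of both protein and
#' trimmed DNA), and records the protein interface residues.
#'
#' @param s a `structure_model` with at least one protein and one DNA atom.
#' @param p a [curation_params()] object.
#' @return An object of class `curated_complex` with fields `protein`, `dna`,
#'   `water` (atom tables), `positions` (per-position duplex bookkeeping),
#'   `contacting_positions` (positions, 1..k, with a direct contact),
#'   `interface_residue_ids`, `k`, `native_sequence`, `resolution`,
#'   `identifier` and `params`.
#' @export
curate_complex <- function(s, p = curation_params()) {
  stopifnot(inherits(s, "structure_model"), inherits(p, "curation_params"))
  atoms <- s$atoms
  if (!any(atoms$record_class == "protein")) stopf("no protein atoms")
  if (!any(atoms$record_class == "dna")) stopf("no DNA atoms")
  if (!is.na(s$resolution) && s$resolution > p$resolution_max)
    stopf("resolution %.2f A exceeds maximum %.2f A",
          s$resolution, p$resolution_max)

  pairing <- pair_duplex(atoms)
  contacts <- contacting_positions(s, p$contact_cutoff)
  if (length(contacts) == 0L)
    stopf("no interface: no protein-DNA atom pair within %.2f A",
          p$contact_cutoff)
  span <- seq(min(contacts), max(contacts))
  k <- length(span)
  if (k > p$k_max)
    stopf("motif too long: %d contacting base pairs exceed the maximum of %d",
          k, p$k_max)

  kept <- pairing[pairing$pos %in% span, , drop = FALSE]
  kept$pos <- seq_len(nrow(kept))

  # canonical, heavy-atom-complete bases only
  check_base <- function(chain, resno, base) {
    if (is.na(chain)) return(invisible(NULL))
    if (is.na(base) || !base %in% names(BASE_COMPLEMENT))
      stopf("non-canonical base '%s' at %s:%s", base, chain, resno)
    have <- residue_atoms(atoms, chain, resno)$name
    missing <- setdiff(base_moiety_atoms(base), have)
    if (length(missing))
      stopf("base at %s:%s is missing heavy atoms: %s", chain, resno,
            paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(kept))) {
    check_base(kept$ref_chain[i], kept$ref_resno[i], kept$ref_base[i])
    check_base(kept$comp_chain[i], kept$comp_resno[i], kept$comp_base[i])
  }

  keep_dna <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(kept))) {
    keep_dna <- keep_dna |
      (atoms$chain_id == kept$ref_chain[i] &
         atoms$residue_index == kept$ref_resno[i])
    if (!is.na(kept$comp_chain[i]))
      keep_dna <- keep_dna |
        (atoms$chain_id == kept$comp_chain[i] &
           atoms$residue_index == kept$comp_resno[i])
  }
  dna <- atoms[atoms$record_class == "dna" & keep_dna, , drop = FALSE]
  prot <- atoms[atoms$record_class == "protein", , drop = FALSE]

  water <- atoms[atoms$record_class == "water", , drop = FALSE]
  if (p$keep_interface_waters && nrow(water) > 0L) {
    wxyz <- water[, c("x", "y", "z")]
    near_p <- apply(cross_dist(wxyz, prot[, c("x", "y", "z")]) <=
                      p$contact_cutoff, 1, any)
    near_d <- apply(cross_dist(wxyz, dna[, c("x", "y", "z")]) <=
                      p$contact_cutoff, 1, any)
    water <- water[near_p & near_d, , drop = FALSE]
  } else {
    water <- water[0, , drop = FALSE]
  }

  cc <- structure(list(
    protein = prot, dna = dna, water = water,
    positions = kept,
    contacting_positions = which(kept$pos %in% (contacts - min(contacts) + 1L)),
    interface_residue_ids = character(0),
    k = k,
    native_sequence = paste(kept$ref_base, collapse = ""),
    resolution = s$resolution,
    identifier = s$identifier,
    params = p
  ), class = "curated_complex")
  cc$interface_residue_ids <- interface_residues(cc, p$contact_cutoff)
  cc
}

#' @export
print.curated_complex <- function(x, ...) {
  cat(sprintf(
    "<curated_complex> %s: k=%d (%s), %d protein / %d DNA / %d water atoms\n",
    x$identifier, x$k, x$native_sequence, nrow(x$protein), nrow(x$dna),
    nrow(x$water)))
  invisible(x)
}

#' Reassemble a curated complex into a structure model
#'
#' @param x a `curated_complex`.
#' @return A `structure_model` holding the protein, trimmed DNA and retained
#'   interface waters.
#' @export
as_structure_model <- function(x) {
  stopifnot(inherits(x, "curated_complex"))
  new_structure_model(rbind(x$protein, x$dna, x$water),
                      resolution = x$resolution, identifier = x$identifier)
}

#' Protein residues at the DNA interface
#'
#' @param c a `curated_complex`.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return Character vector of residue ids (`"chain:resno"`) with at least one
#'   heavy atom within `cutoff` of a (trimmed) DNA heavy atom.
#' @export
interface_residues <- function(c, cutoff = 4.5) {
  stopifnot(inherits(c, "curated_complex"))
  prot <- c$protein
  if (nrow(prot) == 0L || nrow(c$dna) == 0L) return(character(0))
  d <- cross_dist(prot[, c("x", "y", "z")], c$dna[, c("x", "y", "z")])
  near <- apply(d <= cutoff, 1, any)
  unique(paste0(prot$chain_id, ":", prot$residue_index)[near])
}

#' Greedy representative clustering of protein sequences
#'
#' Removes redundancy at a global-identity threshold with a greedy
#' longest-first scheme: sequences are visited longest first, each joins the
#' first existing cluster whose representative it matches at `identity` or
#' better (identity = aligned identical residues / length of the shorter
#' sequence), otherwise it founds a new cluster.
#'
#' @param seqs character vector of protein sequences.
#' @param identity global identity threshold as a fraction (default 0.90).
#' @return Character vector of cluster representatives (subset of `seqs`).
#' @export
greedy_cluster_sequences <- function(seqs, identity = 0.90) {
  if (length(seqs) == 0L) stopf("no sequences supplied")
  stopifnot(identity > 0, identity <= 1)
  ord <- order(-nchar(seqs))
  reps <- character(0)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- get("BLOSUM62", envir = data_env)
  for (s in seqs[ord]) {
    joined <- FALSE
    for (r in reps) {
      if (pairwise_identity(s, r, mat) >= identity) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, s)
  }
  reps
}

pairwise_identity <- function(a, b, mat) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Serialize a curated complex to JSON (with an optional trimmed PDB)
#'
#' @param x a `curated_complex`.
#' @param file output JSON path.
#' @param pdb optional path for a trimmed PDB copy of the complex.
#' @return `file`, invisibly.
#' @export
write_curated_complex <- function(x, file, pdb = NULL) {
  stopifnot(inherits(x, "curated_complex"))
  obj <- unclass(x)
  obj$params <- unclass(obj$params)
  jsonlite::write_json(obj, file, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(pdb)) write_pdb(x, pdb)
  invisible(file)
}

#' Read a curated complex serialized by [write_curated_complex()]
#'
#' @param file JSON path.
#' @return A `curated_complex`.
#' @export
read_curated_complex <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  obj$params <- do.call(curation_params, as.list(obj$params))
  for (f in c("protein", "dna", "water", "positions"))
    obj[[f]] <- as.data.frame(obj[[f]], stringsAsFactors = FALSE)
  if (nrow(obj$water) == 0L) obj$water <- obj$dna[0, , drop = FALSE]
  obj$k <- as.integer(obj$k)
  obj$contacting_positions <- as.integer(obj$contacting_positions)
  obj$resolution <- as.numeric(obj$resolution %||% NA_real_)
  structure(obj, class = "curated_complex")
}
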
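# Idealized nucleotide geometry and residue classification tables.
#
# Heavy-atom coordinates of the four deoxyribonucleotides in an arbitrary
# local frame, taken from standard chemical-component geometry tables and
# frozen here so the package needs no download. Base rings are planar to
# better than 0.01 A, which is what the threading step relies on.

ideal_nucleotide_geometry <- data.frame(
  residue = c("DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DA", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DC", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DG", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT"),
  atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4", "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6", "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4", "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
  element = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "N", "C", "C", "N", "N", "C", "N", "C", "P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "O", "N", "C", "N", "C", "C", "P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "N", "C", "C", "O", "N", "C", "N", "N", "C", "P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "O", "N", "C", "O", "C", "C", "C"),
  x = c(0.934, 1.781, -0.204, 0.241, -0.549, -1.239, -0.267, -2.105, -3.409, -2.173, -0.965, -0.078, 0.962, 1.535, 0.897, 1.069, 2.079, 0.236, -0.729, -0.925, -0.142, 0.987, 1.802, -0.119, 0.255, -0.571, -1.300, -0.363, -2.206, -3.488, -2.322, -1.106, -0.267, 0.270, 0.052, 1.037, 1.291, 2.085, 0.746, -0.035, -0.818, -1.774, 0.312, -0.126, 0.550, 1.233, 0.253, 1.976, 3.294, 2.026, 0.897, -0.068, -1.172, -1.804, -1.145, -1.361, -2.321, -0.473, 0.593, 1.474, 0.804, -0.027, -3.968, -4.406, -4.901, -2.493, -2.005, -0.611, 0.247, 0.008, 0.965, 0.710, 1.157, 1.164, 2.333, 3.410, 2.194, 1.047, 0.995, -0.143, -1.420, -0.013),
  y = c(-0.156, 0.996, 0.331, -0.771, 0.270, -0.251, -0.564, 0.859, 0.895, 0.398, -0.545, -0.047, 0.817, 1.044, 0.346, 0.196, 0.869, -0.603, -1.249, -1.144, -0.368, -0.017, 1.099, 0.560, -0.772, 0.196, -0.459, -0.863, 0.569, 0.649, -0.040, -0.981, -0.584, 0.648, 1.424, 1.035, 0.212, 0.622, -1.088, -1.465, -0.321, 0.766, 0.224, -0.826, 0.300, -0.113, -0.471, 1.091, 1.218, 0.692, -0.345, 0.111, 0.877, 1.094, 0.482, 0.377, 0.914, -0.327, -0.928, -1.643, -0.839, -0.152, -1.665, -2.599, -0.360, -1.028, -0.136, 0.328, -0.829, 1.286, 2.121, 0.360, -0.778, -2.047, -2.544, -1.945, -3.793, -4.570, -5.663, -3.980, -4.757, -2.784),
  z = c(-4.636, -4.255, -5.665, -3.320, -2.744, -1.482, -0.458, -0.835, -1.418, 0.640, 0.797, 1.852, 1.689, 2.835, 3.805, 5.191, 5.856, 5.850, 5.224, 3.927, 3.184, -3.894, -3.365, -4.910, -2.674, -2.027, -0.852, 0.171, -0.129, -0.756, 1.288, 1.395, 2.528, 2.563, 1.647, 3.581, 4.589, 5.635, 4.580, 3.541, 4.935, 4.630, 5.941, 3.572, 3.011, 1.706, 0.705, 1.073, 1.612, -0.421, -0.573, -1.575, -1.341, -2.458, -3.472, -4.866, -5.391, -5.601, -5.003, -5.774, -3.709, -2.917, 3.118, 4.208, 2.920, 3.315, 2.327, 2.728, 2.764, 1.720, 2.368, 0.754, 1.657, 0.989, 0.374, 0.363, -0.240, -0.300, -0.857, 0.369, 0.347, 0.958),
  stringsAsFactors = FALSE
)

# Canonical residue-name tables -----------------------------------------------

AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# DNA residue names plus single-letter aliases seen in older PDB files.
# U maps to the base letter "U", which downstream curation rejects as
# non-canonical for DNA.
DNA_RESIDUES <- c(
  DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
  A = "A", C = "C", G = "G", T = "T", U = "U"
)

WATER_RESIDUES <- c("HOH", "WAT")

BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

DNA_BACKBONE_ATOMS <- c(
  "P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'"
)

# Anchor triads: the glycosidic nitrogen and its two bonded ring carbons.
# Order matters: purine and pyrimidine triads correspond element-wise
# (N9<->N1, C8<->C6, C4<->C2) so that purine<->pyrimidine swaps preserve the
# glycosidic direction.
ANCHOR_TRIADS <- list(
  A = c("N9", "C8", "C4"),
  G = c("N9", "C8", "C4"),
  C = c("N1", "C6", "C2"),
  T = c("N1", "C6", "C2")
)

BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

residue_base_letter <- function(residue_name) {
  unname(DNA_RESIDUES[residue_name])
}

classify_residue <- function(residue_name) {
  out <- rep("other", length(residue_name))
  out[residue_name %in% AMINO_ACIDS] <- "protein"
  out[residue_name %in% names(DNA_RESIDUES)] <- "dna"
  out[residue_name %in% WATER_RESIDUES] <- "water"
  out
}

#' Idealized base geometry templates
#'
#' Returns, for each canonical base (A, C, G, T), the idealized planar
#' heavy-atom coordinates of the base moiety in a local frame, together with
#' the anchor-triad atom names used for superposition during base threading.
#' Backbone (sugar-phosphate) atoms are available through
#' `include_backbone = TRUE` and are used only by the fixture generator.
#'
#' @param include_backbone logical; include sugar-phosphate atoms.
#' @return A list with one entry per base letter; each entry has `atoms`
#'   (data.frame with `atom`, `element`, `x`, `y`, `z`) and `anchor_triad`
#'   (character vector of three atom names).
#' @export
#' @examples
#' geom <- base_geometry()
#' geom$A$anchor_triad
base_geometry <- function(include_backbone = FALSE) {
  out <- lapply(c(A = "DA", C = "DC", G = "DG", T = "DT"), function(res) {
    df <- ideal_nucleotide_geometry[ideal_nucleotide_geometry$residue == res, ]
    if (!include_backbone) df <- df[!(df$atom %in% DNA_BACKBONE_ATOMS), ]
    rownames(df) <- NULL
    base <- DNA_RESIDUES[[res]]
    list(atoms = df[, c("atom", "element", "x", "y", "z")],
         anchor_triad = ANCHOR_TRIADS[[base]])
  })
  names(out) <- c("A", "C", "G", "T")
  out
}

base_moiety_atoms <- function(base) {
  geom <- ideal_nucleotide_geometry
  res <- c(A = "DA", C = "DC", G = "DG", T = "DT")[[base]]
  atoms <- geom$atom[geom$residue == res]
  setdiff(atoms, DNA_BACKBONE_ATOMS)
}
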
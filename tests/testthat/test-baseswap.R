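# k-mer enumeration, rigid superposition and base threading.

test_that("enumerate_kmers covers the sequence space in lexicographic order", {
  expect_identical(enumerate_kmers(1), c("A", "C", "G", "T"))
  k2 <- enumerate_kmers(2)
  expect_length(k2, 16L)
  expect_identical(k2[1], "AA")
  expect_identical(k2[16], "TT")
  expect_identical(k2, sort(k2))
  expect_false(anyDuplicated(k2) > 0)
  expect_error(enumerate_kmers(0), "1..9")
  expect_error(enumerate_kmers(10), "1..9")
})

test_that("kabsch_fit recovers known transforms and refuses reflections", {
  tri <- matrix(c(0, 0, 0, 1.5, 0, 0, 0.3, 1.4, 0), 3, 3, byrow = TRUE)
  id <- kabsch_fit(tri, tri)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_lt(id$rmsd, 1e-12)

  theta <- pi / 2
  rot90 <- matrix(c(cos(theta), sin(theta), 0,
                    -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  target <- tri %*% t(rot90)
  target <- sweep(target, 2, c(3, -2, 5), `+`)
  fit <- kabsch_fit(tri, target)
  expect_equal(fit$rotation, rot90, tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # mirrored non-planar points: best proper rotation with nonzero residual
  # (three points are always coplanar, so their mirror image is reachable by
  # a proper rotation; four non-planar points expose the chirality)
  quad <- rbind(tri, c(0.4, 0.5, 1.3))
  fm <- kabsch_fit(quad, quad %*% diag(c(-1, 1, 1)))
  expect_equal(det(fm$rotation), 1, tolerance = 1e-10)
  expect_gt(fm$rmsd, 0.1)

  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  expect_error(kabsch_fit(collinear, collinear), "collinear")
})

test_that("threading the native sequence reconstructs the original bases", {
  cc <- curate_complex(make_toy_complex(n_bp = 9, contacts = 3:6, seed = 17))
  sw <- swap_bases(cc, cc$native_sequence)
  orig <- as_structure_model(cc)$atoms
  key <- function(a) paste(a$chain_id, a$residue_index, a$name)
  mm <- match(key(orig), key(sw$atoms))
  expect_false(anyNA(mm))
  dev <- sqrt(rowSums((as.matrix(orig[, c("x", "y", "z")]) -
                         as.matrix(sw$atoms[mm, c("x", "y", "z")]))^2))
  expect_lt(max(dev), 0.3)
})

test_that("protein and backbone atoms are bit-identical after threading", {
  cc <- curate_complex(make_toy_complex(n_bp = 9, contacts = 2:4, seed = 19))
  sw <- swap_bases(cc, "TTT")
  prot0 <- cc$protein
  prot1 <- sw$atoms[sw$atoms$record_class == "protein", ]
  expect_identical(prot0$x, prot1$x)
  expect_identical(prot0$y, prot1$y)
  expect_identical(prot0$z, prot1$z)
  backbone <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
                "C2'", "C1'")
  key <- function(a) paste(a$chain_id, a$residue_index, a$name)
  bb0 <- cc$dna[cc$dna$name %in% backbone, ]
  dna1 <- sw$atoms[sw$atoms$record_class == "dna", ]
  bb1 <- dna1[dna1$name %in% backbone, ]
  mm <- match(key(bb0), key(bb1))
  expect_identical(bb0$x, bb1$x[mm])
  expect_identical(bb0$z, bb1$z[mm])
})

test_that("purine-to-purine swaps keep the anchor triad coordinates exactly", {
  cc <- curate_complex(make_toy_complex(n_bp = 9, contacts = 2:4, seed = 23,
                                        native = "AAAAAAAAA"))
  sw <- swap_bases(cc, "GGG")
  d <- sw$atoms[sw$atoms$chain_id == "B" & sw$atoms$record_class == "dna", ]
  for (pos in cc$positions$ref_resno) {
    orig <- cc$dna[cc$dna$chain_id == "B" & cc$dna$residue_index == pos, ]
    new <- d[d$residue_index == pos, ]
    expect_identical(unique(new$residue_name), "DG")
    for (at in c("N9", "C8", "C4")) {
      expect_identical(
        as.numeric(orig[orig$name == at, c("x", "y", "z")][1, ]),
        as.numeric(new[new$name == at, c("x", "y", "z")][1, ]),
        label = paste("triad atom", at))
    }
  }
})

test_that("the paired strand carries the Watson-Crick complement", {
  cc <- curate_complex(make_toy_complex(n_bp = 9, contacts = 2:4, seed = 29))
  sw <- swap_bases(cc, "ACG")
  dna <- sw$atoms[sw$atoms$record_class == "dna", ]
  ref <- comp <- character(0)
  for (i in seq_len(nrow(cc$positions))) {
    p <- cc$positions[i, ]
    ref[i] <- unique(dna$residue_name[dna$chain_id == p$ref_chain &
                                        dna$residue_index == p$ref_resno])
    comp[i] <- unique(dna$residue_name[dna$chain_id == p$comp_chain &
                                         dna$residue_index == p$comp_resno])
  }
  expect_identical(ref, c("DA", "DC", "DG"))
  expect_identical(comp, c("DT", "DG", "DC"))
  # read 5'->3' on the opposite strand: CGT
  expect_identical(paste(rev(sub("D", "", comp)), collapse = ""), "CGT")
})

test_that("enumerating and threading k=2 yields models matching their labels", {
  cc <- curate_complex(make_toy_complex(n_bp = 6, contacts = 3:4, seed = 31))
  expect_equal(cc$k, 2L)
  for (s in enumerate_kmers(2)) {
    m <- swap_bases(cc, s)
    dna <- m$atoms[m$atoms$record_class == "dna", ]
    got <- vapply(seq_len(2), function(i) {
      p <- cc$positions[i, ]
      sub("D", "", unique(dna$residue_name[dna$chain_id == p$ref_chain &
                                             dna$residue_index == p$ref_resno]))
    }, character(1))
    expect_identical(paste(got, collapse = ""), s)
    # atom complement of each placed base is complete
    for (i in seq_len(2)) {
      p <- cc$positions[i, ]
      have <- dna$name[dna$chain_id == p$ref_chain &
                         dna$residue_index == p$ref_resno]
      need <- structmotif:::base_moiety_atoms(substr(s, i, i))
      expect_true(all(need %in% have))
    }
  }
})

test_that("placed bases stay planar", {
  cc <- curate_complex(make_toy_complex(n_bp = 9, contacts = 2:5, seed = 37))
  sw <- swap_bases(cc, "GTCA")
  dna <- sw$atoms[sw$atoms$record_class == "dna", ]
  for (i in seq_len(4)) {
    p <- cc$positions[i, ]
    base <- substr("GTCA", i, i)
    ring <- structmotif:::BASE_RING_ATOMS[[base]]
    res <- dna[dna$chain_id == p$ref_chain & dna$residue_index == p$ref_resno, ]
    xyz <- as.matrix(res[match(ring, res$name), c("x", "y", "z")])
    cen <- sweep(xyz, 2, colMeans(xyz))
    expect_lt(svd(cen)$d[3] / sqrt(nrow(cen)), 0.05)
  }
})

test_that("clash relaxation is monotone and leaves clash-free models alone", {
  cc <- curate_complex(make_toy_complex(n_bp = 9, contacts = 2:4, seed = 41))
  sw <- swap_bases(cc, cc$native_sequence)
  relaxed <- relax_clashes(sw)
  e <- attr(relaxed, "relax_energy")
  expect_lte(e[["after"]], e[["before"]])
  if (e[["before"]] == 0)
    expect_identical(relaxed$atoms$x, sw$atoms$x)

  # two atoms in different residues at 1.0 A: relaxation must separate them
  atoms <- rbind(
    atom_row("CB", "C", "ALA", 1L, "A", 0, 0, 0),
    atom_row("N9", "N", "DA", 1L, "B", 1, 0, 0))
  m <- toy_model(atoms)
  attr(m, "swapped_atoms") <- 2L
  out <- relax_clashes(m, steps = 100)
  d_after <- sqrt(sum((as.numeric(out$atoms[2, c("x", "y", "z")]) -
                         as.numeric(out$atoms[1, c("x", "y", "z")]))^2))
  expect_gt(d_after, 1.0)
  ea <- attr(out, "relax_energy")
  expect_lt(ea[["after"]], ea[["before"]])
  # protein (non-movable) atom did not move
  expect_identical(as.numeric(out$atoms[1, c("x", "y", "z")]), c(0, 0, 0))
})
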
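# Structure parsing, curation filters, DNA trimming and interface extraction.

test_that("PDB round-trip preserves atoms, classification and resolution", {
  m <- make_toy_complex(n_bp = 9, contacts = 2:4, seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- parse_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$resolution, 2.0)
  expect_equal(sort(unique(m2$atoms$chain_id)), c("A", "B", "C", "W"))
  expect_equal(table(m2$atoms$record_class)[["dna"]],
               table(m$atoms$record_class)[["dna"]])
  # coordinates survive to PDB precision
  key <- function(a) paste(a$chain_id, a$residue_index, a$name)
  mm <- match(key(m$atoms), key(m2$atoms))
  expect_false(anyNA(mm))
  expect_lt(max(abs(as.matrix(m$atoms[, c("x", "y", "z")]) -
                      as.matrix(m2$atoms[mm, c("x", "y", "z")]))), 1e-3 + 1e-9)
})

test_that("protein-only files parse with zero DNA atoms", {
  m <- make_toy_complex(contacts = 2:3, seed = 1)
  prot <- m$atoms[m$atoms$record_class == "protein", ]
  f <- tempfile(fileext = ".pdb")
  write_pdb(prot, f)
  m2 <- parse_structure(f)
  expect_equal(sum(m2$atoms$record_class == "dna"), 0L)
  expect_gt(sum(m2$atoms$record_class == "protein"), 0L)
})

test_that("truncated ATOM records raise an error naming the line", {
  m <- make_toy_complex(contacts = 2:3, seed = 1)
  f <- tempfile(fileext = ".pdb")
  write_pdb(m, f)
  lines <- readLines(f)
  atom_line <- grep("^ATOM", lines)[5]
  lines[atom_line] <- substr(lines[atom_line], 1, 40)
  writeLines(lines, f)
  expect_error(parse_structure(f), as.character(atom_line))
  f2 <- tempfile(fileext = ".pdb")
  writeLines("REMARK only", f2)
  expect_error(parse_structure(f2), "no ATOM/HETATM")
})

test_that("resolution filter rejects structures worse than the maximum", {
  m <- make_toy_complex(contacts = 2:4, seed = 1, resolution = 2.6)
  expect_error(curate_complex(m), "resolution")
  m2 <- make_toy_complex(contacts = 2:4, seed = 1, resolution = 2.5)
  expect_s3_class(curate_complex(m2), "curated_complex")
})

test_that("trimming keeps the contiguous contacting stretch and records k", {
  # protein contacting bp 4-8 of a 12 bp duplex -> k = 5
  m <- make_toy_complex(n_bp = 12, contacts = 4:8, seed = 2)
  cc <- curate_complex(m)
  expect_equal(cc$k, 5L)
  expect_equal(cc$contacting_positions, 1:5)
  expect_equal(nchar(cc$native_sequence), 5L)
  # interior gap: contacts {4, 8} still give a contiguous k = 5 stretch
  mg <- make_toy_complex(n_bp = 12, contacts = c(4, 8), seed = 2)
  ccg <- curate_complex(mg)
  expect_equal(ccg$k, 5L)
  expect_equal(ccg$contacting_positions, c(1L, 5L))
})

test_that("motifs longer than k_max are rejected", {
  m <- make_toy_complex(n_bp = 12, contacts = 1:10, seed = 1)
  expect_error(curate_complex(m), "too long")
  expect_s3_class(
    curate_complex(m, curation_params(k_max = 12)), "curated_complex")
})

test_that("contact boundary at 4.5 A is inclusive", {
  # one CA probe at an exact distance from the nearest atom of position 2:
  # approaching along +x from the maximal-x atom of the pair guarantees the
  # chosen atom is the closest one
  dna <- make_toy_complex(n_bp = 3, contacts = 1, seed = 1, water = FALSE)
  pos2 <- dna$atoms[dna$atoms$record_class == "dna" &
                      dna$atoms$residue_index == 2, ]
  base_atom <- pos2[which.max(pos2$x), ]
  probe_at <- function(d) {
    rbind(atom_row("CA", "C", "ALA", 1L, "Z",
                   base_atom$x + d, base_atom$y, base_atom$z),
          dna$atoms[dna$atoms$record_class == "dna", ])
  }
  near <- toy_model(probe_at(4.4))
  far <- toy_model(probe_at(4.6))
  expect_true(2 %in% contacting_positions(near, 4.5))
  expect_false(2 %in% contacting_positions(far, 4.5))
  # exact boundary counts (d <= cutoff)
  at <- toy_model(probe_at(4.5))
  expect_true(2 %in% contacting_positions(at, 4.5))
})

test_that("contacting_positions reports the designed pattern 5'->3'", {
  m <- make_toy_complex(n_bp = 9, contacts = c(2, 3, 4), seed = 5)
  expect_identical(contacting_positions(m, 4.5), c(2L, 3L, 4L))
  # brute-force oracle: recompute by looping over every atom pair
  atoms <- m$atoms
  prot <- atoms[atoms$record_class == "protein", ]
  hits <- integer(0)
  for (i in 1:9) {
    res <- atoms[atoms$record_class == "dna" & atoms$residue_index == i, ]
    mind <- Inf
    for (a in seq_len(nrow(res))) for (b in seq_len(nrow(prot)))
      mind <- min(mind, sqrt(sum((as.numeric(res[a, c("x", "y", "z")]) -
                          as.numeric(prot[b, c("x", "y", "z")]))^2)))
    if (mind <= 4.5) hits <- c(hits, i)
  }
  expect_identical(contacting_positions(m, 4.5), hits)
})

test_that("interface_residues finds exactly the designed contacts", {
  m <- make_toy_complex(n_bp = 9, contacts = c(3, 5, 7), seed = 11)
  cc <- curate_complex(m)
  expect_setequal(cc$interface_residue_ids, c("A:1", "A:2", "A:3"))
  expect_length(interface_residues(cc, 0.1), 0L)
  n_res <- length(unique(paste(cc$protein$chain_id, cc$protein$residue_index)))
  expect_length(interface_residues(cc, 1e6), n_res)
})

test_that("curation is idempotent", {
  cc <- curate_complex(make_toy_complex(n_bp = 10, contacts = 3:6, seed = 9))
  cc2 <- curate_complex(as_structure_model(cc))
  expect_equal(cc2$k, cc$k)
  expect_equal(cc2$native_sequence, cc$native_sequence)
  expect_equal(cc2$contacting_positions, cc$contacting_positions)
  expect_equal(nrow(cc2$dna), nrow(cc$dna))
  expect_equal(nrow(cc2$water), nrow(cc$water))
  expect_setequal(cc2$interface_residue_ids, cc$interface_residue_ids)
})

test_that("contact detection is invariant under rigid motion", {
  m <- make_toy_complex(n_bp = 9, contacts = 2:5, seed = 13)
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4)), 3, 3)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(rot)
  m2 <- m
  m2$atoms$x <- xyz[, 1] + 11.3
  m2$atoms$y <- xyz[, 2] - 4.2
  m2$atoms$z <- xyz[, 3] + 0.7
  expect_identical(contacting_positions(m2, 4.5), contacting_positions(m, 4.5))
})

test_that("interface waters are kept only when near both molecules", {
  m <- make_toy_complex(n_bp = 9, contacts = 2:4, seed = 1, water = TRUE)
  cc <- curate_complex(m)
  expect_equal(nrow(cc$water), 1L)
  cc2 <- curate_complex(m, curation_params(keep_interface_waters = FALSE))
  expect_equal(nrow(cc2$water), 0L)
  # a far-away water is dropped even when retention is on
  m3 <- m
  w <- m3$atoms$record_class == "water"
  m3$atoms$x[w] <- m3$atoms$x[w] + 500
  expect_equal(nrow(curate_complex(m3)$water), 0L)
})

test_that("non-canonical retained bases are rejected", {
  m <- make_toy_complex(n_bp = 9, contacts = 2:4, seed = 1)
  bad <- m
  sel <- bad$atoms$chain_id == "B" & bad$atoms$residue_index == 3
  bad$atoms$residue_name[sel] <- "DU"
  expect_error(curate_complex(bad), "non-canonical")
  # missing base heavy atoms are rejected too
  m2 <- make_toy_complex(n_bp = 9, contacts = 2:4, seed = 1)
  sel2 <- which(m2$atoms$chain_id == "B" & m2$atoms$residue_index == 3 &
                  !(m2$atoms$name %in%
                      c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                        "C3'", "O3'", "C2'", "C1'")))
  m2$atoms <- m2$atoms[-sel2[length(sel2)], ]
  expect_error(curate_complex(m2), "missing heavy atoms")
})

test_that("complexes without protein, DNA or interface are rejected", {
  m <- make_toy_complex(n_bp = 9, contacts = 2:4, seed = 1)
  prot_only <- toy_model(m$atoms[m$atoms$record_class == "protein", ])
  dna_only <- toy_model(m$atoms[m$atoms$record_class == "dna", ])
  expect_error(curate_complex(prot_only), "DNA")
  expect_error(curate_complex(dna_only), "protein")
  far <- m
  p <- far$atoms$record_class == "protein"
  far$atoms$z[p] <- far$atoms$z[p] + 300
  expect_error(curate_complex(far), "no interface")
})

test_that("greedy sequence clustering removes redundancy at the threshold", {
  s <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 1), collapse = "")
  expect_length(greedy_cluster_sequences(c(s, s)), 1L)
  # one mismatch in 20 -> 95% identity -> one representative at 0.90
  s2 <- sub("K", "W", s)
  expect_length(greedy_cluster_sequences(c(s, s2), 0.90), 1L)
  expect_length(greedy_cluster_sequences(c(s, s2), 0.99), 2L)
  # ~50% identity stays separate
  half <- paste0(substr(s, 1, 10), "GGGGGGGGGG")
  expect_length(greedy_cluster_sequences(c(s, half), 0.90), 2L)
  expect_error(greedy_cluster_sequences(character(0)), "no sequences")
})

test_that("curated complexes survive a JSON round-trip", {
  cc <- curate_complex(make_toy_complex(n_bp = 9, contacts = 2:4, seed = 21))
  f <- tempfile(fileext = ".json")
  write_curated_complex(cc, f)
  cc2 <- read_curated_complex(f)
  expect_equal(cc2$k, cc$k)
  expect_equal(cc2$native_sequence, cc$native_sequence)
  expect_equal(cc2$dna$x, cc$dna$x)
  expect_equal(cc2$positions$ref_base, cc$positions$ref_base)
  # and the round-tripped complex still threads
  sw <- swap_bases(cc2, cc2$native_sequence)
  expect_s3_class(sw, "structure_model")
})
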
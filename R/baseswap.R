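# Exhaustive k-mer enumeration and geometric base threading on a fixed
# sugar-phosphate backbone.

#' Enumerate all DNA k-mers
#'
#' @param k motif length, 1 to 9 (4^9 = 262,144 sequences is the practical
#'   ceiling for exhaustive threading).
#' @return Character vector of all 4^k sequences over A/C/G/T in
#'   lexicographic order.
#' @export
#' @examples
#' enumerate_kmers(2)[c(1, 16)]  # "AA" "TT"
enumerate_kmers <- function(k) {
  if (!is_count(k) || k < 1 || k > 9)
    stopf("k must be an integer in 1..9, got %s", format(k))
  k <- as.integer(k)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  do.call(paste0, rev(grid))
}

#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `target`. Reflections are never returned: when the optimal
#' orthogonal transform is improper, the best proper rotation is used.
#'
#' @param mobile n x 3 matrix of coordinates to move (n >= 3).
#' @param target n x 3 matrix of reference coordinates, row-matched.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3), and `rmsd` after superposition. Apply as
#'   `coords %*% t(rotation) + translation` (rows are points).
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); ct <- colMeans(target)
  a <- sweep(mobile, 2, cm); b <- sweep(target, 2, ct)
  # degenerate (collinear) point sets leave the rotation under-determined
  if (any(svd(a)$d[2] < 1e-8, svd(b)$d[2] < 1e-8))
    stopf("degenerate (collinear) points: rigid fit is under-determined")
  h <- crossprod(a, b)           # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- a %*% t(rot)
  structure(list(rotation = rot,
                 translation = as.numeric(ct) - as.numeric(cm %*% t(rot)),
                 rmsd = sqrt(mean(rowSums((moved - b)^2)))),
            class = "rigid_transform")
}

apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Thread a DNA sequence onto a curated complex
#'
#' Replaces the bases at every duplex position of the curated complex with
#' those of the requested k-mer (reference strand) and its Watson-Crick
#' complement (paired strand). At each nucleotide the anchor triad -- the
#' glycosidic nitrogen and its two bonded ring carbons (purines N9-C8-C4,
#' pyrimidines N1-C6-C2, matched in that order across purine/pyrimidine
#' swaps) -- is retained at its original coordinates to preserve the base's
#' direction and plane; all other base heavy atoms are rebuilt from the
#' idealized base geometry superposed onto the retained triad with
#' [kabsch_fit()]. Sugar-phosphate backbone, protein and water atoms are
#' untouched.
#'
#' @param c a `curated_complex`.
#' @param s character k-mer over A/C/G/T with `nchar(s) == c$k`
#'   (reference strand, 5'->3').
#' @param geom base geometry templates, as from [base_geometry()].
#' @return A `structure_model` of the threaded complex. The integer attribute
#'   `swapped_atoms` marks the rebuilt base atoms (row indices), which is the
#'   movable set for [relax_clashes()].
#' @export
swap_bases <- function(c, s, geom = base_geometry()) {
  stopifnot(inherits(c, "curated_complex"))
  s <- toupper(s)
  if (!is.character(s) || length(s) != 1L || nchar(s) != c$k ||
      grepl("[^ACGT]", s))
    stopf("sequence must be a length-%d string over A/C/G/T", c$k)
  targets <- strsplit(s, "")[[1]]

  dna <- c$dna
  swapped <- logical(nrow(dna))
  place <- function(dna, swapped, chain, resno, new_base) {
    idx <- which(dna$chain_id == chain & dna$residue_index == resno)
    res <- dna[idx, , drop = FALSE]
    old_base <- residue_base_letter(res$residue_name[1])
    old_triad <- ANCHOR_TRIADS[[old_base]]
    new_triad <- ANCHOR_TRIADS[[new_base]]
    tri_rows <- match(old_triad, res$name)
    if (any(is.na(tri_rows)))
      stopf("missing anchor atom %s in %s:%s",
            paste(old_triad[is.na(tri_rows)], collapse = ","), chain, resno)
    retained <- as.matrix(res[tri_rows, c("x", "y", "z")])

    tmpl <- geom[[new_base]]$atoms
    tmpl_tri <- match(new_triad, tmpl$atom)
    fit <- kabsch_fit(as.matrix(tmpl[tmpl_tri, c("x", "y", "z")]), retained)
    moved <- apply_transform(tmpl[, c("x", "y", "z")], fit)

    keep <- !(res$name %in% setdiff(base_moiety_atoms(old_base), old_triad))
    kept <- res[keep, , drop = FALSE]
    kept_swapped <- swapped[idx][keep]
    # rename retained triad atoms per the purine/pyrimidine correspondence
    tri_in_kept <- match(old_triad, kept$name)
    kept$name[tri_in_kept] <- new_triad
    kept$residue_name <- paste0("D", new_base)

    new_rows <- which(!(tmpl$atom %in% new_triad))
    add <- data.frame(
      name = tmpl$atom[new_rows], element = tmpl$element[new_rows],
      residue_name = paste0("D", new_base), residue_index = resno,
      chain_id = chain, x = moved[new_rows, 1], y = moved[new_rows, 2],
      z = moved[new_rows, 3], record_class = "dna",
      stringsAsFactors = FALSE)

    before <- if (min(idx) > 1L) dna[seq_len(min(idx) - 1L), , drop = FALSE]
              else dna[0, ]
    after <- if (max(idx) < nrow(dna)) dna[(max(idx) + 1L):nrow(dna), ,
                                           drop = FALSE] else dna[0, ]
    sw_before <- swapped[seq_len(nrow(before))]
    sw_after <- if (nrow(after)) swapped[(max(idx) + 1L):nrow(dna)]
                else logical(0)
    list(dna = rbind(before, kept, add, after),
         swapped = c(sw_before, kept_swapped | kept$name %in% new_triad,
                     rep(TRUE, nrow(add)), sw_after))
  }

  for (i in seq_len(nrow(c$positions))) {
    p <- c$positions[i, ]
    upd <- place(dna, swapped, p$ref_chain, p$ref_resno, targets[i])
    dna <- upd$dna; swapped <- upd$swapped
    if (!is.na(p$comp_chain)) {
      upd <- place(dna, swapped, p$comp_chain, p$comp_resno,
                   BASE_COMPLEMENT[[targets[i]]])
      dna <- upd$dna; swapped <- upd$swapped
    }
  }

  atoms <- rbind(c$protein, dna, c$water)
  m <- new_structure_model(atoms, resolution = c$resolution,
                           identifier = paste0(c$identifier, "_", s))
  attr(m, "swapped_atoms") <- nrow(c$protein) + which(swapped)
  m
}

# Element-based soft-sphere radii (Angstrom) for clash relaxation.
SOFT_SPHERE_RADII <- c(C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8)

soft_sphere_radius <- function(element) {
  r <- SOFT_SPHERE_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Clash energy sum(max(0, ri + rj - dij)^2) between movable atoms and all
# atoms of other residues, plus its gradient on the movable coordinates.
clash_energy <- function(xyz_mov, xyz_env, r_mov, r_env, gradient = FALSE) {
  d <- cross_dist(xyz_mov, xyz_env)
  rsum <- outer(r_mov, r_env, `+`)
  ov <- rsum - d
  ov[ov < 0] <- 0
  e <- sum(ov^2)
  if (!gradient) return(list(energy = e))
  g <- matrix(0, nrow(xyz_mov), 3)
  hit <- which(ov > 0, arr.ind = TRUE)
  if (nrow(hit)) {
    for (h in seq_len(nrow(hit))) {
      i <- hit[h, 1]; j <- hit[h, 2]
      dij <- max(d[i, j], 1e-6)
      dir <- (xyz_mov[i, ] - xyz_env[j, ]) / dij
      g[i, ] <- g[i, ] - 2 * ov[i, j] * dir   # d(e)/d(xi): -2*ov*unit(i-j)
    }
  }
  list(energy = e, gradient = g)
}

#' Relax steric clashes of threaded bases
#'
#' Minimizes a soft-sphere repulsion energy, `sum(max(0, ri + rj - dij)^2)`
#' over clashing atom pairs, by steepest descent with backtracking. Only the
#' rebuilt base atoms move (the movable set recorded by [swap_bases()]);
#' protein, backbone and water atoms are fixed. Pairs within the same residue
#' are excluded (covalently bonded atoms are not clashes). Energy is monotone
#' non-increasing across iterations; a clash-free model is returned unchanged.
#'
#' @param m a `structure_model` from [swap_bases()].
#' @param steps maximum descent iterations (default 100).
#' @param movable integer row indices of movable atoms; defaults to the
#'   `swapped_atoms` attribute set by [swap_bases()].
#' @return The relaxed `structure_model`; attribute `relax_energy` holds
#'   `c(before, after)`.
#' @export
relax_clashes <- function(m, steps = 100, movable = attr(m, "swapped_atoms")) {
  stopifnot(inherits(m, "structure_model"))
  if (is.null(movable) || length(movable) == 0L) return(m)
  atoms <- m$atoms
  mov <- atoms[movable, , drop = FALSE]
  env_idx <- setdiff(seq_len(nrow(atoms)), movable)
  # atoms of the same residue as a movable atom never count as clashes
  res_key <- paste(atoms$chain_id, atoms$residue_index)
  env_idx <- env_idx[!(res_key[env_idx] %in% unique(res_key[movable]))]
  if (length(env_idx) == 0L) return(m)
  env <- atoms[env_idx, , drop = FALSE]

  xyz <- as.matrix(mov[, c("x", "y", "z")])
  exyz <- as.matrix(env[, c("x", "y", "z")])
  r_mov <- soft_sphere_radius(mov$element)
  r_env <- soft_sphere_radius(env$element)

  e0 <- clash_energy(xyz, exyz, r_mov, r_env)$energy
  e <- e0
  if (e > 0) {
    step <- 0.05
    for (it in seq_len(steps)) {
      ce <- clash_energy(xyz, exyz, r_mov, r_env, gradient = TRUE)
      gn <- sqrt(sum(ce$gradient^2))
      if (ce$energy == 0 || gn < 1e-10) break
      dir <- -ce$gradient / gn
      accepted <- FALSE
      trial_step <- step
      for (bt in 1:20) {
        trial <- xyz + trial_step * dir
        et <- clash_energy(trial, exyz, r_mov, r_env)$energy
        if (et <= ce$energy) {
          xyz <- trial; e <- et
          step <- trial_step * 1.5
          accepted <- TRUE
          break
        }
        trial_step <- trial_step / 2
      }
      if (!accepted || e == 0) break
    }
  }
  atoms[movable, c("x", "y", "z")] <- xyz
  out <- new_structure_model(atoms, resolution = m$resolution,
                             identifier = m$identifier)
  attr(out, "swapped_atoms") <- movable
  attr(out, "relax_energy") <- c(before = e0, after = e)
  out
}
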
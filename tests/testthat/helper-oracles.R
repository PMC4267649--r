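# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: plain double loops, closed forms and exhaustive
# enumeration only.

# O(n^2) double-loop interface score: loop over every protein/DNA atom pair,
# bin the distance by interval arithmetic, and look the energy up in the
# potential table treated as a plain data.frame.
oracle_srv <- function(model, pot) {
  atoms <- model$atoms
  prot <- atoms[atoms$record_class == "protein", , drop = FALSE]
  dna <- atoms[atoms$record_class == "dna", , drop = FALSE]
  tab <- as.data.frame(pot$table)
  b <- pot$binning
  key <- paste(tab$ptype, tab$patom, tab$btype, tab$batom, tab$bin)
  total <- 0
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(dna))) {
      d <- sqrt((prot$x[i] - dna$x[j])^2 + (prot$y[i] - dna$y[j])^2 +
                  (prot$z[i] - dna$z[j])^2)
      if (d >= b$cutoff) next
      bin <- if (d < b$first_bin_width) 0L else
        1L + floor((d - b$first_bin_width) / b$other_bin_width)
      base <- c(DA = "A", DC = "C", DG = "G", DT = "T")[[dna$residue_name[j]]]
      hit <- match(paste(prot$residue_name[i], prot$name[i], base,
                         dna$name[j], bin), key)
      if (!is.na(hit)) total <- total + tab$energy[hit]
    }
  }
  total
}

# One-sided Fisher-Irwin p for the 2x2 table [m, L-m; r, L-r] by exhaustive
# enumeration of the hypergeometric pmf with choose().
oracle_fisher_p <- function(m, L) {
  r <- round(L / 4)
  k1 <- m + r               # first-column margin
  total <- 2 * L
  xs <- max(0, k1 - L):min(L, k1)
  pmf <- choose(k1, xs) * choose(total - k1, L - xs) / choose(total, L)
  sum(pmf[xs >= m])
}

# Naive O(n^3) UPGMA returning the cophenetic matrix (cluster distance at
# which each leaf pair first merges).
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  coph <- matrix(0, n, n)
  clusters <- as.list(seq_len(n))
  d <- D
  active <- seq_len(n)
  sizes <- rep(1, n)
  while (length(active) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      if (d[active[a], active[b]] < bestd) {
        bestd <- d[active[a], active[b]]; best <- c(a, b)
      }
    }
    ia <- active[best[1]]; ib <- active[best[2]]
    for (x in clusters[[ia]]) for (y in clusters[[ib]]) {
      coph[x, y] <- bestd; coph[y, x] <- bestd
    }
    # average linkage update into slot ia
    for (cidx in active) {
      if (cidx %in% c(ia, ib)) next
      d[ia, cidx] <- (sizes[ia] * d[ia, cidx] + sizes[ib] * d[ib, cidx]) /
        (sizes[ia] + sizes[ib])
      d[cidx, ia] <- d[ia, cidx]
    }
    clusters[[ia]] <- c(clusters[[ia]], clusters[[ib]])
    sizes[ia] <- sizes[ia] + sizes[ib]
    active <- setdiff(active, ib)
  }
  coph
}

# Point-mass PWM for a literal word (useful planted-site probe).
word_pwm <- function(word, name = word) {
  letters_w <- strsplit(word, "")[[1]]
  mat <- matrix(0, 4, length(letters_w),
                dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_along(letters_w)) mat[letters_w[j], j] <- 1
  pwm(mat, name = name)
}

# Near-point-mass PWM: consensus word with probability p, rest split evenly.
soft_word_pwm <- function(word, p = 0.85, name = word) {
  letters_w <- strsplit(word, "")[[1]]
  mat <- matrix((1 - p) / 3, 4, length(letters_w),
                dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_along(letters_w)) mat[letters_w[j], j] <- p
  pwm(mat, name = name)
}

# Minimal hand-built structure model from an atom spec data.frame.
toy_model <- function(atoms, resolution = NA_real_, id = "toy") {
  structmotif:::new_structure_model(atoms, resolution = resolution,
                                    identifier = id)
}

atom_row <- function(name, element, resname, resno, chain, x, y, z) {
  data.frame(name = name, element = element, residue_name = resname,
             residue_index = resno, chain_id = chain, x = x, y = y, z = z,
             record_class = structmotif:::classify_residue(resname),
             stringsAsFactors = FALSE)
}
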
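# PWM readers/writers for the two common motif dialects: JASPAR PFM and
# MEME minimal. Counts-format inputs are normalized to frequencies.

#' Read a JASPAR PFM motif file
#'
#' Accepts the bracketed four-row layout (`A [ 1 2 3 ]` ...) with an optional
#' `>name` header, and the bare four-row counts layout. Counts are
#' normalized to per-column frequencies.
#'
#' @param file path to a JASPAR PFM file.
#' @return A `pwm`.
#' @export
read_jaspar <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[lines != ""]
  name <- "motif"
  if (length(lines) && startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 4L) stopf("JASPAR file '%s': expected 4 matrix rows", file)
  lines <- lines[1:4]
  rows <- lapply(lines, function(l) {
    l <- sub("^[ACGTacgt]\\s*", "", l)
    l <- gsub("\\[|\\]", " ", l)
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (any(is.na(v)) || length(v) == 0L)
      stopf("JASPAR file '%s': malformed matrix row", file)
    v
  })
  if (length(unique(lengths(rows))) != 1L)
    stopf("JASPAR file '%s': rows have different lengths", file)
  mat <- do.call(rbind, rows)
  cs <- colSums(mat)
  if (any(cs <= 0)) stopf("JASPAR file '%s': column sums must be positive", file)
  new_pwm(sweep(mat, 2, cs, `/`), name = name)
}

#' Write a PWM as a JASPAR PFM file
#'
#' @param m a `pwm`.
#' @param file output path.
#' @param counts multiply frequencies by this total before writing
#'   (default 1: write frequencies).
#' @return `file`, invisibly.
#' @export
write_jaspar <- function(m, file, counts = 1) {
  stopifnot(inherits(m, "pwm"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0(">", attr(m, "name") %||% "motif"), con)
  for (b in c("A", "C", "G", "T"))
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(m[b, ] * counts, trim = TRUE),
                             collapse = " ")), con)
  invisible(file)
}

#' Read motifs from a MEME minimal-format file
#'
#' Requires the `ALPHABET=` line of the minimal format; each motif block is
#' a `MOTIF` line followed by a `letter-probability matrix:` header and
#' `w` rows of four frequencies.
#'
#' @param file path to a MEME minimal motif file.
#' @return A single `pwm` when the file holds one motif, otherwise a named
#'   list of `pwm`s.
#' @export
read_meme <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  if (!any(grepl("^ALPHABET\\s*=", lines)))
    stopf("MEME file '%s': missing ALPHABET line", file)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stopf("MEME file '%s': no MOTIF blocks", file)
  out <- list()
  for (s in starts) {
    name <- trimws(sub("^MOTIF\\s*", "", lines[s]))
    name <- strsplit(name, "\\s+")[[1]][1]
    h <- s + which(grepl("^letter-probability matrix:",
                         lines[(s + 1):length(lines)]))[1]
    if (is.na(h)) stopf("MEME file '%s': motif %s has no matrix header",
                        file, name)
    w <- suppressWarnings(as.integer(
      sub(".*w\\s*=\\s*([0-9]+).*", "\\1", lines[h])))
    if (is.na(w)) stopf("MEME file '%s': cannot parse matrix width", file)
    rows <- lines[(h + 1):(h + w)]
    mat <- t(vapply(rows, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
      if (length(v) != 4L || any(is.na(v)))
        stopf("MEME file '%s': malformed matrix row '%s'", file, l)
      v
    }, numeric(4)))
    cs <- rowSums(mat)   # mat is w x 4 here; rows are positions
    if (any(cs <= 0)) stopf("MEME file '%s': zero-sum matrix row", file)
    out[[name]] <- new_pwm(t(mat / cs), name = name)
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Write PWMs as a MEME minimal-format file
#'
#' @param m a `pwm` or list of `pwm`s.
#' @param file output path.
#' @param background background base frequencies written to the header
#'   (default uniform).
#' @return `file`, invisibly.
#' @export
write_meme <- function(m, file, background = rep(0.25, 4)) {
  if (inherits(m, "pwm")) m <- list(m)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3],
                       background[4]), ""), con)
  for (x in m) {
    writeLines(sprintf("MOTIF %s", attr(x, "name") %||% "motif"), con)
    writeLines(sprintf(
      "letter-probability matrix: alphabet= 4 w= %d nsites= 20 E= 0", ncol(x)),
      con)
    for (j in seq_len(ncol(x)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         x["A", j], x["C", j], x["G", j], x["T", j]), con)
    writeLines("", con)
  }
  invisible(file)
}

#' Read a motif file, dispatching on dialect
#'
#' @param file path; MEME minimal files are recognized by their
#'   `MEME version` header, everything else is treated as JASPAR PFM.
#' @return A `pwm` (or named list for multi-motif MEME files).
#' @export
read_motif <- function(file) {
  first <- readLines(file, n = 5L, warn = FALSE)
  if (any(grepl("^MEME version", first))) read_meme(file) else read_jaspar(file)
}
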
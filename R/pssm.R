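#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the log-odds block of the standard PSI-BLAST ASCII matrix dump:
#' header lines, then one row per sequence position holding the position
#' index, the query residue, 20 integer log-odds scores, 20 weighted
#' percentages and trailing per-position statistics. Only the position
#' index, residue and the 20 log-odds scores are used; columns are reordered
#' from the file's residue order (normally `ARNDCQEGHILKMFPSTWYV`, taken
#' from the column-header line when present) to the package's alphabetical
#' order.
#'
#' @param path Path to the PSSM file.
#' @return A [PSSM-class] object.
#' @export
parsePSSM <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rowPat <- "^\\s*\\d+\\s+[A-Z*]\\s"
  dataRows <- grepl(rowPat, lines)
  if (!any(dataRows)) stop("no PSSM rows found in ", path)
  first <- which(dataRows)[1]

  fileOrder <- PSIBLAST_ORDER
  if (first > 1L) {
    for (h in seq_len(first - 1L)) {
      toks <- strsplit(trimws(lines[h]), "\\s+")[[1]]
      if (length(toks) >= 20L && all(nchar(toks) == 1L) &&
          all(toks %in% LETTERS)) {
        fileOrder <- toks[1:20]
        break
      }
    }
  }
  if (!setequal(fileOrder, AA20))
    stop("PSSM column header does not list the 20 standard residues")

  residues <- character(0)
  scoreRows <- list()
  for (i in which(dataRows)[1]:length(lines)) {
    ln <- lines[i]
    if (!grepl(rowPat, ln)) break  # footer statistics reached
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    res <- toks[2]
    if (!res %in% AA20)
      stop("line ", i, ": residue '", res, "' is not a standard amino acid")
    num <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (anyNA(num) || length(num) < 40L)
      stop("line ", i, ": malformed PSSM row (expected 40 numeric fields, got ",
           sum(!is.na(num)), ")")
    residues <- c(residues, res)
    scoreRows[[length(scoreRows) + 1L]] <- num[1:20]
  }
  scores <- do.call(rbind, scoreRows)
  colnames(scores) <- fileOrder
  PSSM(paste(residues, collapse = ""), scores[, AA20, drop = FALSE])
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits the header, the two-block column header line (residues in
#' PSI-BLAST order), one row per position with the 20 integer log-odds
#' scores followed by a zero percentage block and trailing statistics, and a
#' footer — sufficient to round-trip through [parsePSSM()].
#'
#' @param pssm A [PSSM-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePSSM <- function(pssm, path) {
  stopifnot(is(pssm, "PSSM"))
  sc <- pssm@scores[, PSIBLAST_ORDER, drop = FALSE]
  res <- strsplit(pssm@sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ",
           paste(sprintf("%3s", c(PSIBLAST_ORDER, PSIBLAST_ORDER)),
                 collapse = " "))), con)
  for (i in seq_len(nrow(sc))) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", sc[i, ]), collapse = " "), " ",
                      paste(sprintf("%3d", rep(0L, 20L)), collapse = " "),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Min-max normalize one PSSM row
#'
#' Maps a vector of position scores to \[0, 1\] via
#' `(v - min) / (max - min)`, so the row minimum becomes 0 and the maximum
#' 1. A constant row (max == min) maps to all zeros, a documented convention
#' for the degenerate division.
#'
#' @param row Numeric vector of scores for one position (length 20 in
#'   normal use).
#' @return Numeric vector of the same length in \[0, 1\].
#' @examples
#' normalizeRow(c(-279, -515, 918))
#' @export
normalizeRow <- function(row) {
  row <- as.numeric(row)
  lo <- min(row); hi <- max(row)
  if (hi == lo) return(rep(0, length(row)))
  (row - lo) / (hi - lo)
}

#' Row-wise min-max normalization of a PSSM
#'
#' @param pssm A [PSSM-class] object.
#' @return Numeric L x 20 matrix with each row normalized by
#'   [normalizeRow()].
#' @export
normalizePSSM <- function(pssm) {
  stopifnot(is(pssm, "PSSM"))
  out <- t(apply(pssm@scores, 1L, normalizeRow))
  colnames(out) <- AA20
  out
}

#' 400-dimensional PSSM composition
#'
#' The standard PSSM-400 pooling of a normalized profile: a 20 x 20
#' accumulator in which cell (a, b) sums the normalized substitution score
#' toward residue b over all positions whose query residue is a, divided by
#' the sequence length L; flattened row-major (query residue a outer,
#' substitution residue b inner, both alphabetical) to 400 values named
#' `"A_A", "A_C", ..., "Y_Y"`.
#'
#' @param pssm A [PSSM-class] object (normalized internally), or an already
#'   normalized L x 20 matrix if `sequence` is supplied.
#' @param sequence Residue string matching the matrix rows; only needed when
#'   `pssm` is a plain matrix.
#' @return Named numeric vector of length 400.
#' @export
pssmComposition <- function(pssm, sequence = NULL) {
  if (is(pssm, "PSSM")) {
    X <- normalizePSSM(pssm)
    sequence <- pssm@sequence
  } else {
    X <- as.matrix(pssm)
    if (is.null(sequence)) stop("sequence required with a plain matrix")
  }
  res <- strsplit(sequence, "")[[1]]
  idx <- match(res, AA20)
  if (anyNA(idx)) stop("non-standard residue in PSSM sequence")
  L <- length(idx)
  stopifnot(nrow(X) == L, ncol(X) == 20L)
  acc <- matrix(0, 20L, 20L, dimnames = list(AA20, AA20))
  sums <- rowsum(X, group = idx)
  acc[as.integer(rownames(sums)), ] <- sums
  comp <- as.vector(t(acc)) / L
  names(comp) <- paste(rep(AA20, each = 20L), rep(AA20, 20L), sep = "_")
  comp
}

#' Truncate values to a fixed number of decimal places
#'
#' Compatibility formatter matching printed PSSM normalization tables, which
#' truncate (floor) rather than round: `truncateDecimals(0.16468, 4)` is
#' `0.1646`, not `0.1647`. Intended for non-negative values; full floating
#' precision is kept everywhere else in the package.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Truncated numeric vector.
#' @export
truncateDecimals <- function(x, digits = 4L) {
  f <- 10^digits
  floor(x * f) / f
}
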
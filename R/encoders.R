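#' Amino-acid composition (AC)
#'
#' The 20-dimensional fraction vector: component k is the count of the k-th
#' residue in alphabetical order `ACDEFGHIKLMNPQRSTVWY` divided by the
#' sequence length. Components are fractions in \[0, 1\] summing to 1.
#'
#' @param sequence A validated residue string (character scalar or
#'   `AAString`).
#' @return Named numeric vector of length 20.
#' @examples
#' aaComposition("AAG")
#' @export
aaComposition <- function(sequence) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 1L) stop("empty sequence")
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (anyNA(idx)) stop("non-standard residue in sequence; validate first")
  setNames(tabulate(idx, 20L) / L, AA20)
}

#' Dipeptide composition (DC)
#'
#' The 400-dimensional fraction vector over ordered residue pairs (AA, AC,
#' ..., YY; first residue varies slowest). Component (a, b) is the number of
#' overlapping occurrences of the dipeptide `ab` divided by L - 1, the total
#' number of overlapping dipeptide windows, so the vector sums to 1.
#'
#' @inheritParams aaComposition
#' @return Named numeric vector of length 400.
#' @examples
#' dipeptideComposition("ACA")[c("AC", "CA")]
#' @export
dipeptideComposition <- function(sequence) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 2L) stop("dipeptide composition undefined for sequences of length < 2")
  idx <- match(strsplit(sequence, "")[[1]], AA20)
  if (anyNA(idx)) stop("non-standard residue in sequence; validate first")
  pair <- (idx[-L] - 1L) * 20L + idx[-1L]
  setNames(tabulate(pair, 400L) / (L - 1L), .dipeptideNames())
}

.dipeptideNames <- function()
  paste0(rep(AA20, each = 20L), rep(AA20, times = 20L))

#' Max-to-min residue (MM) profile
#'
#' The amino-acid composition reordered along the fixed abundance order of
#' the average HbL sequence, from most to least abundant residue:
#' `ALEKIVGDPNFQRTMYSHWC`. A pure permutation of [aaComposition()].
#'
#' @inheritParams aaComposition
#' @return Named numeric vector of length 20 in MM order.
#' @examples
#' mmProfile("AA")[1]  # order starts with A
#' @export
mmProfile <- function(sequence) {
  ac <- aaComposition(sequence)
  ac[MM_ORDER]
}

#' Hybrid composition (AC + DC)
#'
#' Concatenation of the 20-dimensional amino-acid composition and the
#' 400-dimensional dipeptide composition into one 420-dimensional vector.
#'
#' @inheritParams aaComposition
#' @return Named numeric vector of length 420.
#' @export
hybridComposition <- function(sequence)
  c(aaComposition(sequence), dipeptideComposition(sequence))

#' Encode a set of sequences as a feature matrix
#'
#' @param x An `AAStringSet`, named character vector or [HbLDataset-class].
#' @param scheme One of `"AC"`, `"DC"`, `"MM"`, `"HYBRID"`, `"PSSM"`
#'   (case-insensitive).
#' @param pssms For `scheme = "PSSM"` only: a named list of [PSSM-class]
#'   objects covering every record id, or a directory containing
#'   `<id>.pssm` files in PSI-BLAST ASCII format.
#' @return Numeric matrix, one row per record (rownames = ids), with
#'   [schemeDims()]`[scheme]` columns.
#' @examples
#' encodeSequences(c(a = "MKVH", b = "MSTS"), "AC")[, c("M", "S")]
#' @export
encodeSequences <- function(x, scheme, pssms = NULL) {
  scheme <- .checkScheme(scheme)
  if (is(x, "HbLDataset")) x <- sequences(x)
  chars <- as.character(x)
  if (is.null(names(chars))) names(chars) <- names(x)
  ids <- names(chars)
  if (is.null(ids)) stop("sequences must be named by record id")
  if (scheme == "PSSM") {
    pssms <- .resolvePSSMs(ids, pssms)
    feat <- t(vapply(ids, function(id) {
      p <- pssms[[id]]
      if (p@sequence != chars[[id]])
        stop("PSSM sequence mismatch for record '", id, "'")
      pssmComposition(p)
    }, numeric(400L)))
  } else {
    enc <- switch(scheme,
                  AC = aaComposition, DC = dipeptideComposition,
                  MM = mmProfile, HYBRID = hybridComposition)
    feat <- t(vapply(chars, enc, numeric(SCHEME_DIMS[[scheme]])))
  }
  rownames(feat) <- ids
  feat
}

.resolvePSSMs <- function(ids, pssms) {
  if (is.null(pssms))
    stop("scheme 'PSSM' requires per-record PSSMs (list or directory)")
  if (is.character(pssms) && length(pssms) == 1L) {
    dir <- pssms
    paths <- file.path(dir, paste0(ids, ".pssm"))
    miss <- ids[!file.exists(paths)]
    if (length(miss))
      stop("missing PSSM file(s) for record(s): ", paste(miss, collapse = ", "))
    pssms <- lapply(paths, parsePSSM)
    names(pssms) <- ids
  }
  miss <- setdiff(ids, names(pssms))
  if (length(miss))
    stop("missing PSSM(s) for record(s): ", paste(miss, collapse = ", "))
  pssms
}

#' Write a feature matrix as TSV
#'
#' One row per record: id followed by the feature values, with a header of
#' feature names.
#'
#' @param features Numeric matrix with rownames (from [encodeSequences()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTSV <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read sparse feature files (SVMlight format)
#'
#' One line per example: the class label (`+1` / `-1`) followed by
#' space-separated `index:value` pairs for the non-zero features, indices
#' 1-based and ascending — the sparse convention used to feed SVM
#' command-line toolchains (positive sequences get the positive label,
#' negatives the negative label).
#'
#' @param features Numeric feature matrix, one row per example.
#' @param labels Vector of +1/-1 labels, one per row.
#' @param path File path.
#' @return `writeSVMlight`: `path` invisibly. `readSVMlight`: a list with
#'   elements `features` (dense matrix with `dim` columns) and `labels`.
#' @export
writeSVMlight <- function(features, labels, path) {
  stopifnot(nrow(features) == length(labels), all(labels %in% c(-1, 1)))
  lines <- vapply(seq_len(nrow(features)), function(i) {
    v <- features[i, ]
    nz <- which(v != 0)
    paste(c(sprintf("%+d", as.integer(labels[i])),
            sprintf("%d:%.12g", nz, v[nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSVMlight
#' @param dim Number of feature columns of the dense matrix to reconstruct.
#' @export
readSVMlight <- function(path, dim) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  feat <- matrix(0, nrow = length(lines), ncol = dim)
  labs <- numeric(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    labs[i] <- as.numeric(parts[1])
    if (length(parts) > 1L) {
      kv <- strsplit(parts[-1], ":", fixed = TRUE)
      idx <- as.integer(vapply(kv, `[`, character(1), 1L))
      val <- as.numeric(vapply(kv, `[`, character(1), 2L))
      if (any(is.na(idx)) || any(idx < 1L) || any(idx > dim))
        stop("bad feature index on line ", i)
      feat[i, idx] <- val
    }
  }
  list(features = feat, labels = labs)
}
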
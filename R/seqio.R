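#' Read protein sequences from a FASTA file
#'
#' Each header is split at the first whitespace into the record id and a
#' free-text description (kept in `mcols(x)$description`); sequences are
#' uppercased and stripped of whitespace. Duplicate ids are an error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return An [Biostrings::AAStringSet] named by record id.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 test protein", "MKVHAE"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(AAStringSet(character()))
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: sequence data before first header at line ",
         nonblank[1], " of ", path)
  seqs <- readAAStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chars <- toupper(gsub("\\s", "", as.character(seqs)))
  out <- AAStringSet(chars)
  names(out) <- ids
  mcols(out) <- DataFrame(description = unname(desc))
  out
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [readFasta()]: ids and descriptions are rejoined into headers.
#'
#' @param x An `AAStringSet` (optionally with `mcols(x)$description`) or an
#'   [HbLDataset-class].
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  if (is(x, "HbLDataset")) x <- sequences(x)
  desc <- if (!is.null(mcols(x)$description)) mcols(x)$description
          else rep("", length(x))
  out <- x
  names(out) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  writeXStringSet(out, path, width = width)
  invisible(path)
}

#' Validate or clean sequences against the 20-letter amino-acid alphabet
#'
#' @param x An `AAStringSet`, character vector or [HbLDataset-class].
#' @param policy `"reject"` (default) errors on any non-standard character
#'   (B, J, O, U, X, Z, `*`, gaps, ...), listing the offending records and
#'   positions; `"strip"` silently removes non-standard characters;
#'   `"remap"` maps the unambiguous codes B->D, Z->E, U->C and strips the
#'   rest.
#' @return Object of the same type with every sequence over
#'   `ACDEFGHIKLMNPQRSTVWY`; cleaning that empties a sequence is an error.
#' @examples
#' validateSequences(c(p = "MKVX"), policy = "strip")
#' @export
validateSequences <- function(x, policy = c("reject", "strip", "remap")) {
  policy <- match.arg(policy)
  if (is(x, "HbLDataset")) {
    x@sequences <- validateSequences(x@sequences, policy)
    validObject(x)
    return(x)
  }
  isSet <- is(x, "AAStringSet")
  nms <- names(x)
  chars <- as.character(x)
  ids <- if (!is.null(nms)) nms else as.character(seq_along(chars))
  badPat <- "[^ACDEFGHIKLMNPQRSTVWY]"
  if (policy == "reject") {
    for (i in seq_along(chars)) {
      hit <- gregexpr(badPat, chars[[i]])[[1]]
      if (hit[1] != -1L) {
        res <- strsplit(chars[[i]], "")[[1]][hit]
        stop("non-standard residue(s) in '", ids[i], "': ",
             paste(sprintf("%s at position %d", res, hit), collapse = ", "))
      }
    }
    cleaned <- chars
  } else {
    if (policy == "remap") chars <- chartr("BZU", "DEC", chars)
    cleaned <- gsub(badPat, "", chars)
  }
  if (any(!nzchar(cleaned)))
    stop("sequence(s) empty after cleaning: ",
         paste(ids[!nzchar(cleaned)], collapse = ", "))
  if (isSet) {
    out <- AAStringSet(cleaned)
    names(out) <- nms
    mcols(out) <- mcols(x)
    out
  } else setNames(cleaned, nms)
}

#' Remove records by annotation keywords
#'
#' Drops every record whose description contains any of the keywords
#' (case-insensitive substring match on the description only, never the id).
#' The default list removes entries annotated as fragments, isoforms,
#' potentials, similarity hits or probables; singular forms are used so
#' plurals also match.
#'
#' @param x An `AAStringSet` with `mcols(x)$description`, or an
#'   [HbLDataset-class].
#' @param keywords Character vector of keywords; an empty vector retains
#'   everything.
#' @return Filtered object of the same type. The numbers removed/retained
#'   are reported via [message()].
#' @export
filterAnnotations <- function(x,
    keywords = c("fragment", "isoform", "potential", "similarity", "probable")) {
  if (is(x, "HbLDataset")) {
    keep <- names(filterAnnotations(sequences(x), keywords))
    return(x[keep])
  }
  desc <- mcols(x)$description
  if (is.null(desc)) desc <- rep("", length(x))
  drop <- rep(FALSE, length(x))
  for (kw in keywords)
    drop <- drop | grepl(tolower(kw), tolower(desc), fixed = TRUE)
  message("filterAnnotations: removed ", sum(drop), ", retained ",
          sum(!drop), " of ", length(x), " records")
  x[!drop]
}

## match=1 / mismatch=0 substitution matrix over the 20-letter alphabet
.identityMatrix <- local({
  m <- diag(1, 20L)
  dimnames(m) <- list(AA20, AA20)
  storage.mode(m) <- "double"
  m
})

#' Pairwise sequence identity under global alignment
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and linear
#' gap penalty -1; identity is the number of exactly matching aligned
#' positions divided by the length of the shorter sequence.
#'
#' @param a,b Residue strings (character or `AAString`).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwiseIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  aln <- pairwiseAlignment(AAStringSet(a), AAStringSet(b),
                           substitutionMatrix = .identityMatrix,
                           gapOpening = 0, gapExtension = 1, type = "global")
  nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy redundancy reduction at an identity cutoff
#'
#' CD-HIT-style greedy clustering: records are visited by decreasing length
#' (ties by id, lexicographically) and a record is retained iff its pairwise
#' identity (see [pairwiseIdentity()]) to every already-retained record is at
#' most `cutoff`, so no two retained sequences exceed the cutoff.
#'
#' @param x An `AAStringSet` or [HbLDataset-class] of validated sequences.
#' @param cutoff Identity fraction in (0, 1\]; the conventional redundancy
#'   filter for this problem uses 0.9.
#' @return Filtered object of the same type, in original record order.
#' @export
reduceRedundancy <- function(x, cutoff = 0.9) {
  if (is(x, "HbLDataset"))
    return(x[names(reduceRedundancy(sequences(x), cutoff))])
  stopifnot(length(x) >= 1L, cutoff > 0, cutoff <= 1)
  ord <- order(-width(x), names(x))
  chars <- as.character(x)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (pairwiseIdentity(chars[[i]], chars[[j]]) > cutoff) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  message("reduceRedundancy: retained ", length(kept), " of ", length(x),
          " records at cutoff ", cutoff)
  x[sort(kept)]
}

#' Read / write a label table
#'
#' The label table is a tab-separated file with a header row and an `id`
#' column plus any of `class`, `subfamily`, `domain`; a headerless
#' two-column file is read as `id` + `class`.
#'
#' @param path File path.
#' @return `readLabelTable`: a `data.frame` with columns `id`, `class`,
#'   `subfamily`, `domain`.
#' @export
readLabelTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("(^|\t)id(\t|$)", first)
  tab <- read.delim(path, header = hasHeader, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!hasHeader) {
    if (ncol(tab) != 2L)
      stop("headerless label table must have exactly two columns (id, label)")
    colnames(tab) <- c("id", "class")
  }
  for (col in c("class", "subfamily", "domain"))
    if (!col %in% colnames(tab)) tab[[col]] <- NA_character_
  tab[, c("id", "class", "subfamily", "domain")]
}

#' @rdname readLabelTable
#' @param x A label `data.frame` or [HbLDataset-class].
#' @return `writeLabelTable`: `path`, invisibly.
#' @export
writeLabelTable <- function(x, path) {
  if (is(x, "HbLDataset")) x <- labelTable(x)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
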
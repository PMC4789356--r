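#' HbLDataset: labeled protein sequences
#'
#' Container pairing an [Biostrings::AAStringSet] of validated protein
#' sequences with a label table holding, per sequence, the binary class
#' (`HbL` / `nonHbL`), the globin subfamily (`sHb`, `flavoHb`, `trHb`; `NA`
#' for non-HbL) and the domain-architecture subgroup (one of
#' [domainTasks()]; `NA` for non-HbL).
#'
#' @slot sequences An `AAStringSet`; names are unique record ids and
#'   `mcols(sequences)$description` carries the free-text FASTA description.
#' @slot labels A `data.frame` with columns `id`, `class`, `subfamily`,
#'   `domain`, one row per sequence in the same order.
#' @export
setClass("HbLDataset",
  slots = c(sequences = "AAStringSet", labels = "data.frame"))

setValidity("HbLDataset", function(object) {
  seqs <- object@sequences
  lab <- object@labels
  msgs <- character()
  if (anyDuplicated(names(seqs)))
    msgs <- c(msgs, "sequence ids must be unique")
  need <- c("id", "class", "subfamily", "domain")
  if (!all(need %in% colnames(lab)))
    msgs <- c(msgs, paste("label table must have columns:",
                          paste(need, collapse = ", ")))
  else if (!identical(as.character(lab$id), as.character(names(seqs))))
    msgs <- c(msgs, "label table ids must match sequence names in order")
  if (length(seqs) && any(width(seqs) == 0L))
    msgs <- c(msgs, "sequences must be non-empty")
  if (length(msgs)) msgs else TRUE
})

#' Construct an HbLDataset
#'
#' @param sequences An `AAStringSet` (e.g. from [readFasta()]) or a named
#'   character vector of residue strings.
#' @param labels A `data.frame` with an `id` column and any of `class`,
#'   `subfamily`, `domain` (missing columns are filled with `NA`), or a
#'   two-column `id`/`label` table which is taken as the binary class.
#' @return An [HbLDataset-class] object.
#' @examples
#' ds <- HbLDataset(c(a = "MKVHAE", b = "MSTTSS"),
#'                  data.frame(id = c("a", "b"), class = c("HbL", "nonHbL")))
#' ds
#' @export
HbLDataset <- function(sequences, labels) {
  if (is.character(sequences)) sequences <- AAStringSet(sequences)
  if (is.null(names(sequences)))
    stop("sequences must be named by record id")
  if (is.null(mcols(sequences)))
    mcols(sequences) <- DataFrame(description = rep("", length(sequences)))
  if (is.null(mcols(sequences)$description))
    mcols(sequences)$description <- rep("", length(sequences))
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (!"id" %in% colnames(labels))
    stop("label table must have an 'id' column")
  if ("label" %in% colnames(labels) && !"class" %in% colnames(labels))
    colnames(labels)[colnames(labels) == "label"] <- "class"
  for (col in c("class", "subfamily", "domain"))
    if (!col %in% colnames(labels)) labels[[col]] <- NA_character_
  labels <- labels[, c("id", "class", "subfamily", "domain")]
  missing <- setdiff(names(sequences), labels$id)
  if (length(missing))
    stop("no label row for sequence id(s): ", paste(missing, collapse = ", "))
  labels <- labels[match(names(sequences), labels$id), , drop = FALSE]
  rownames(labels) <- NULL
  new("HbLDataset", sequences = sequences, labels = labels)
}

#' @describeIn HbLDataset-class The sequences as an `AAStringSet`.
#' @param x,object An `HbLDataset`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname HbLDataset-class
#' @export
setMethod("sequences", "HbLDataset", function(x) x@sequences)

#' @describeIn HbLDataset-class The label table
#'   (`id`, `class`, `subfamily`, `domain`).
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname HbLDataset-class
#' @export
setMethod("labelTable", "HbLDataset", function(x) x@labels)

#' @rdname HbLDataset-class
#' @param i Index, logical vector or character vector of ids.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "HbLDataset", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  lab <- x@labels[i, , drop = FALSE]
  rownames(lab) <- NULL
  new("HbLDataset", sequences = x@sequences[i], labels = lab)
})

#' @rdname HbLDataset-class
#' @export
setMethod("length", "HbLDataset", function(x) length(x@sequences))

setMethod("show", "HbLDataset", function(object) {
  cat("HbLDataset with", length(object), "sequences\n")
  cls <- table(object@labels$class, useNA = "ifany")
  cat("  class:    ", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
  sub <- object@labels$subfamily
  if (any(!is.na(sub))) {
    t2 <- table(sub)
    cat("  subfamily:", paste(names(t2), t2, sep = "=", collapse = " "), "\n")
  }
})

#' PSSM: position-specific scoring matrix
#'
#' An L x 20 integer matrix of substitution scores for one protein sequence,
#' as produced by iterative profile searches (PSI-BLAST). Rows are sequence
#' positions; columns are the 20 standard residues in alphabetical order
#' `ACDEFGHIKLMNPQRSTVWY` (files on disk use the PSI-BLAST column order and
#' are reordered on parsing).
#'
#' @slot sequence Character scalar, the residue string (length L).
#' @slot scores Integer matrix, L rows by 20 alphabetically ordered columns.
#' @export
setClass("PSSM", slots = c(sequence = "character", scores = "matrix"))

setValidity("PSSM", function(object) {
  msgs <- character()
  L <- nchar(object@sequence)
  if (length(object@sequence) != 1L || L < 1L)
    msgs <- c(msgs, "sequence must be a single non-empty string")
  if (nrow(object@scores) != L)
    msgs <- c(msgs, "score matrix must have one row per residue")
  if (ncol(object@scores) != 20L ||
      !identical(colnames(object@scores), AA20))
    msgs <- c(msgs, "score matrix needs 20 alphabetically named columns")
  bad <- setdiff(strsplit(object@sequence, "")[[1]], AA20)
  if (length(bad))
    msgs <- c(msgs, paste("non-standard residue(s):",
                          paste(unique(bad), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a PSSM object
#'
#' @param sequence Residue string over the 20-letter alphabet.
#' @param scores Numeric/integer L x 20 matrix; columns either already in
#'   alphabetical residue order, or named so they can be reordered.
#' @return A [PSSM-class] object.
#' @export
PSSM <- function(sequence, scores) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (!is.null(colnames(scores)) && !identical(colnames(scores), AA20)) {
    if (!setequal(colnames(scores), AA20))
      stop("score matrix columns must be the 20 standard residues")
    scores <- scores[, AA20, drop = FALSE]
  }
  colnames(scores) <- AA20
  new("PSSM", sequence = as.character(sequence), scores = scores)
}

#' @describeIn PSSM-class The raw integer score matrix.
#' @param x,object A `PSSM`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PSSM-class
#' @export
setMethod("scores", "PSSM", function(x) x@scores)

setMethod("show", "PSSM", function(object) {
  cat("PSSM for a", nchar(object@sequence), "residue sequence\n")
  cat("  score range:", paste(range(object@scores), collapse = " .. "), "\n")
})

#' SVMModel: a trained RBF-kernel support vector machine
#'
#' The decision function is the standard soft-margin SVM kernel expansion
#' `f(x) = sum_i coef_i K(sv_i, x) + bias` with the radial basis kernel
#' `K(u, v) = exp(-gamma * ||u - v||^2)`; an example is classified positive
#' iff `f(x) >= threshold` (default threshold 0, scores exactly on the
#' threshold count as positive).
#'
#' @slot scheme Encoding scheme tag the model was trained on (see
#'   [schemeDims()]).
#' @slot gamma RBF kernel width, positive.
#' @slot cost Soft-margin box constraint C, positive.
#' @slot SV Support-vector matrix (one row per support vector).
#' @slot coefs Signed dual coefficients `alpha_i * y_i`, one per support
#'   vector.
#' @slot bias Intercept of the decision function.
#' @slot threshold Decision threshold (default 0).
#' @export
setClass("SVMModel",
  slots = c(scheme = "character", gamma = "numeric", cost = "numeric",
            SV = "matrix", coefs = "numeric", bias = "numeric",
            threshold = "numeric"))

setValidity("SVMModel", function(object) {
  msgs <- character()
  if (object@gamma <= 0 || object@cost <= 0)
    msgs <- c(msgs, "gamma and cost must be positive")
  if (nrow(object@SV) != length(object@coefs))
    msgs <- c(msgs, "one dual coefficient per support vector required")
  if (!any(object@coefs > 0) || !any(object@coefs < 0))
    msgs <- c(msgs, "support vectors of both classes required")
  if (object@scheme %in% names(SCHEME_DIMS) &&
      ncol(object@SV) != SCHEME_DIMS[[object@scheme]])
    msgs <- c(msgs, "support-vector dimension does not match scheme")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SVMModel", function(object) {
  cat(sprintf(
    "RBF-SVM model [%s, %d features]: %d support vectors, gamma=%g, C=%g, threshold=%g\n",
    object@scheme, ncol(object@SV), nrow(object@SV),
    object@gamma, object@cost, object@threshold))
})

#' ModelRegistry: the trained model bank of the hierarchical predictor
#'
#' Maps each classification task of the three-stage hierarchy (see
#' [hblTasks()]) to a trained [SVMModel-class], all sharing one encoding
#' scheme. The single-domain and truncated-domain subgroup tasks share the
#' corresponding subfamily models (their positive sets are identical).
#'
#' @slot scheme The common encoding scheme.
#' @slot models Named list of `SVMModel` objects, one per task.
#' @export
setClass("ModelRegistry",
  slots = c(scheme = "character", models = "list"))

setValidity("ModelRegistry", function(object) {
  msgs <- character()
  if (!all(vapply(object@models, is, logical(1), "SVMModel")))
    msgs <- c(msgs, "all registry entries must be SVMModel objects")
  if (anyDuplicated(names(object@models)))
    msgs <- c(msgs, "task names must be unique")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ModelRegistry-class Retrieve the model for one task.
#' @param x,object A `ModelRegistry`.
#' @param task Task name, one of [hblTasks()].
#' @export
setGeneric("getModel", function(x, task) standardGeneric("getModel"))

#' @rdname ModelRegistry-class
#' @export
setMethod("getModel", "ModelRegistry", function(x, task) {
  if (!task %in% names(x@models))
    stop("no model for task '", task, "'; available: ",
         paste(names(x@models), collapse = ", "))
  x@models[[task]]
})

setMethod("show", "ModelRegistry", function(object) {
  cat("ModelRegistry [", object@scheme, "] with ",
      length(object@models), " task models:\n", sep = "")
  for (nm in names(object@models)) {
    m <- object@models[[nm]]
    cat(sprintf("  %-16s gamma=%-6g C=%-6g (%d SVs)\n",
                nm, m@gamma, m@cost, nrow(m@SV)))
  }
})
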
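#' RBF kernel matrix
#'
#' `K[i, j] = exp(-gamma * ||A[i, ] - B[j, ]||^2)`.
#'
#' @param A,B Numeric matrices with the same number of columns.
#' @param gamma Positive kernel width.
#' @return `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
rbfKernelMatrix <- function(A, B, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B), gamma > 0)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical noise
  exp(-gamma * d2)
}

#' Train a soft-margin RBF-kernel SVM
#'
#' Solves the standard soft-margin dual with kernel
#' `K(x, y) = exp(-gamma * ||x - y||^2)` and box constraint C (libsvm
#' backend via \pkg{e1071}, no feature scaling), and repackages the solution
#' as an [SVMModel-class] whose decision function
#' `f(x) = sum_i coef_i K(sv_i, x) + bias` is evaluated by this package's
#' own kernel expansion. Coefficients are oriented so that positive scores
#' mean the +1 class regardless of input ordering. Deterministic given the
#' seed and input order.
#'
#' @param features Numeric matrix, one row per training example.
#' @param labels Vector of +1/-1 class labels.
#' @param gamma,cost Positive RBF width and regularization parameters.
#' @param scheme Optional scheme tag recorded on the model (enforces the
#'   feature dimension when it is a known scheme).
#' @param threshold Decision threshold; scores `>= threshold` classify
#'   positive.
#' @param seed Integer RNG seed (the solver itself is deterministic; the
#'   seed pins any ancillary randomness).
#' @return An [SVMModel-class].
#' @examples
#' m <- trainSVM(matrix(c(0, 1)), c(-1, 1), gamma = 1, cost = 1000)
#' decisionScore(m, matrix(c(0, 1)))
#' @export
trainSVM <- function(features, labels, gamma, cost, scheme = "custom",
                     threshold = 0, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be +1/-1")
  if (length(unique(labels)) < 2L)
    stop("training requires at least one example of each class")
  if (nrow(features) != length(labels))
    stop("one label per feature row required")
  if (toupper(scheme) %in% names(SCHEME_DIMS) &&
      ncol(features) != SCHEME_DIMS[[toupper(scheme)]])
    stop("feature dimension ", ncol(features), " does not match scheme ",
         toupper(scheme))
  stopifnot(gamma > 0, cost > 0)
  scheme <- if (toupper(scheme) %in% names(SCHEME_DIMS)) toupper(scheme)
            else scheme
  fit <- .withSeed(seed,
    svm(features, factor(labels, levels = c("1", "-1")),
        type = "C-classification", kernel = "radial",
        gamma = gamma, cost = cost, scale = FALSE))
  coefs <- as.numeric(fit$coefs)
  bias <- -fit$rho
  ## libsvm orients the decision function toward the class seen first in the
  ## data; flip so that positive scores always mean the +1 class.
  if (fit$levels[fit$labels[1]] != "1") {
    coefs <- -coefs
    bias <- -bias
  }
  new("SVMModel", scheme = scheme, gamma = gamma, cost = cost,
      SV = unname(as.matrix(fit$SV)), coefs = coefs, bias = bias,
      threshold = threshold)
}

#' SVM decision scores and labels
#'
#' `decisionScore` evaluates the kernel expansion
#' `f(x) = sum_i coef_i K(sv_i, x) + bias` for each row of `x`;
#' `predictLabel` thresholds it, classifying positive iff
#' `f(x) >= threshold` (a score exactly on the threshold is positive).
#'
#' @param model An [SVMModel-class].
#' @param x Numeric matrix (rows are examples) or a single feature vector of
#'   the model's dimension.
#' @return `decisionScore`: numeric vector of signed scores (named by
#'   rownames of `x` when present). `predictLabel`: vector of +1/-1.
#' @export
decisionScore <- function(model, x) {
  stopifnot(is(model, "SVMModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model@SV))
    stop("feature dimension ", ncol(x), " does not match model (",
         ncol(model@SV), ", scheme ", model@scheme, ")")
  K <- rbfKernelMatrix(x, model@SV, model@gamma)
  setNames(as.numeric(K %*% model@coefs + model@bias), rownames(x))
}

#' @rdname decisionScore
#' @export
predictLabel <- function(model, x) {
  s <- decisionScore(model, x)
  setNames(ifelse(s >= model@threshold, 1, -1), names(s))
}

.MODEL_FORMAT <- "hblpred-svm"
.MODEL_VERSION <- 1L

#' Save / load a trained SVM model
#'
#' Versioned JSON text serialization of every [SVMModel-class] field
#' (support vectors at full floating precision), so a reloaded model
#' reproduces decision scores to numerical identity.
#'
#' @param model An [SVMModel-class].
#' @param path File path (conventionally `<task>.json`).
#' @return `saveModel`: `path` invisibly. `loadModel`: the restored
#'   [SVMModel-class].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "SVMModel"))
  obj <- list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
              scheme = model@scheme, gamma = model@gamma, cost = model@cost,
              threshold = model@threshold, bias = model@bias,
              coefs = model@coefs, dim = ncol(model@SV),
              sv = apply(model@SV, 1L, identity, simplify = FALSE))
  write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- tryCatch(read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted model file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(obj$format, .MODEL_FORMAT))
    stop("not an hblpred SVM model file: ", path)
  if (!identical(as.integer(obj$version), .MODEL_VERSION))
    stop("unsupported model file version ", obj$version,
         " (this package reads version ", .MODEL_VERSION, ")")
  sv <- obj$sv
  if (is.list(sv)) sv <- do.call(rbind, sv)
  sv <- matrix(as.numeric(sv), ncol = obj$dim)
  new("SVMModel", scheme = obj$scheme, gamma = as.numeric(obj$gamma),
      cost = as.numeric(obj$cost), SV = sv, coefs = as.numeric(obj$coefs),
      bias = as.numeric(obj$bias), threshold = as.numeric(obj$threshold))
}
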
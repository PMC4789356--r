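#' Classification tasks of the three-stage hierarchy
#'
#' Stage 1 discriminates HbL from non-HbL (`HbL_vs_non`). Stage 2 assigns a
#' predicted HbL sequence to one of the three globin subfamilies via
#' one-vs-rest models trained within the HbL set (`sHb`, `flavoHb`,
#' `trHb`). Stage 3 assigns one of five domain-architecture subgroups, again
#' one-vs-rest within the HbL set: the three flavohemoglobin architectures
#' (`fg_FAD_insig`: globin with only insignificant FAD similarity;
#' `fg_cyto_FAD_NAD`: globin + cytochrome-reductase + FAD/NAD-binding
#' domains; `fg_FAD`: globin + FAD/NAD-binding FR-type domain) plus
#' `single_domain` and `trunc_domain`, whose positive sets coincide with the
#' sHb and trHb subfamilies and which therefore share those models.
#'
#' @return `hblTasks()`: character vector of all nine task names.
#' @export
hblTasks <- function()
  c("HbL_vs_non", "sHb", "flavoHb", "trHb",
    "fg_FAD_insig", "fg_cyto_FAD_NAD", "fg_FAD",
    "single_domain", "trunc_domain")

#' @rdname hblTasks
#' @return `subfamilyTasks()` / `domainTasks()`: the stage-2 / stage-3 task
#'   names in their fixed (tie-breaking) order.
#' @export
subfamilyTasks <- function() c("sHb", "flavoHb", "trHb")

#' @rdname hblTasks
#' @export
domainTasks <- function()
  c("fg_FAD_insig", "fg_cyto_FAD_NAD", "fg_FAD",
    "single_domain", "trunc_domain")

## Published (gamma, C) working points per task and encoding scheme.
.DEFAULT_PARAMS <- local({
  rows <- list(
    ## task            scheme   gamma   C
    c("HbL_vs_non",      "AC",     25, 400),
    c("HbL_vs_non",      "DC",      1, 375),
    c("HbL_vs_non",      "PSSM",    1, 300),
    c("HbL_vs_non",      "MM",     25, 450),
    c("HbL_vs_non",      "HYBRID",  0.1, 375),
    c("sHb",             "AC",     15,   9),
    c("sHb",             "DC",      0.2, 250),
    c("sHb",             "PSSM",    5,   7),
    c("sHb",             "MM",      1, 150),
    c("sHb",             "HYBRID",  0.1, 350),
    c("flavoHb",         "AC",     10, 300),
    c("flavoHb",         "DC",      1, 350),
    c("flavoHb",         "PSSM",    1, 350),
    c("flavoHb",         "MM",     10, 300),
    c("flavoHb",         "HYBRID",  1, 150),
    c("trHb",            "AC",      5, 350),
    c("trHb",            "DC",      1, 275),
    c("trHb",            "PSSM",    1, 400),
    c("trHb",            "MM",      4, 500),
    c("trHb",            "HYBRID",  1, 150),
    c("fg_FAD_insig",    "AC",     50, 200),
    c("fg_FAD_insig",    "DC",      2, 250),
    c("fg_FAD_insig",    "PSSM",    2, 400),
    c("fg_FAD_insig",    "MM",     25, 450),
    c("fg_FAD_insig",    "HYBRID",  1, 450),
    c("fg_cyto_FAD_NAD", "AC",     10, 200),
    c("fg_cyto_FAD_NAD", "DC",      5, 200),
    c("fg_cyto_FAD_NAD", "PSSM",    2, 500),
    c("fg_cyto_FAD_NAD", "MM",     25, 400),
    c("fg_cyto_FAD_NAD", "HYBRID",  3, 350),
    c("fg_FAD",          "AC",     10, 275),
    c("fg_FAD",          "DC",      1, 275),
    c("fg_FAD",          "PSSM",    1, 500),
    c("fg_FAD",          "MM",     15, 500),
    c("fg_FAD",          "HYBRID",  1, 200),
    ## the single-domain and truncated-domain subgroup tasks reuse the
    ## subfamily working points (their positive sets are identical)
    c("single_domain",   "AC",     15,   9),
    c("single_domain",   "DC",      0.2, 250),
    c("single_domain",   "PSSM",    5,   7),
    c("single_domain",   "MM",      1, 150),
    c("single_domain",   "HYBRID",  0.1, 350),
    c("trunc_domain",    "AC",      5, 350),
    c("trunc_domain",    "DC",      1, 275),
    c("trunc_domain",    "PSSM",    1, 400),
    c("trunc_domain",    "MM",      4, 500),
    c("trunc_domain",    "HYBRID",  1, 150))
  df <- data.frame(task = vapply(rows, `[`, "", 1L),
                   scheme = vapply(rows, `[`, "", 2L),
                   gamma = as.numeric(vapply(rows, `[`, "", 3L)),
                   cost = as.numeric(vapply(rows, `[`, "", 4L)),
                   stringsAsFactors = FALSE)
  df
})

#' Default (gamma, C) working point for a task and scheme
#'
#' Returns the published RBF-SVM hyperparameters for each of the nine
#' hierarchy tasks under each encoding scheme, e.g. gamma = 25, C = 400 for
#' `HbL_vs_non` with `AC` and gamma = 5, C = 7 for `sHb` with `PSSM`.
#'
#' @param task One of [hblTasks()].
#' @param scheme One of the [schemeDims()] scheme names (case-insensitive).
#' @return List with elements `gamma` and `cost`.
#' @examples
#' defaultParams("HbL_vs_non", "AC")
#' @export
defaultParams <- function(task, scheme) {
  scheme <- .checkScheme(scheme)
  hit <- .DEFAULT_PARAMS$task == task & .DEFAULT_PARAMS$scheme == scheme
  if (!any(hit))
    stop("no default parameters for task '", task, "' with scheme '", scheme,
         "'; valid tasks: ", paste(hblTasks(), collapse = ", "))
  list(gamma = .DEFAULT_PARAMS$gamma[hit][1],
       cost = .DEFAULT_PARAMS$cost[hit][1])
}

#' Binary labels for one hierarchy task
#'
#' Converts a dataset's label table into +1/-1 labels for a task, restricted
#' to the rows the task is trained on: stage 1 uses every record (positive =
#' class HbL), subfamily and domain tasks use only the HbL records
#' (one-vs-rest within the HbL set).
#'
#' @param dataset An [HbLDataset-class].
#' @param task One of [hblTasks()].
#' @return Named numeric vector of +1/-1 over the participating record ids.
#' @export
taskLabels <- function(dataset, task) {
  lab <- labelTable(dataset)
  if (task == "HbL_vs_non") {
    if (anyNA(lab$class)) stop("class labels required for task HbL_vs_non")
    return(setNames(ifelse(lab$class == "HbL", 1, -1), lab$id))
  }
  hbl <- lab[!is.na(lab$class) & lab$class == "HbL", , drop = FALSE]
  if (task %in% subfamilyTasks()) {
    if (anyNA(hbl$subfamily)) stop("subfamily labels required for task ", task)
    return(setNames(ifelse(hbl$subfamily == task, 1, -1), hbl$id))
  }
  if (task %in% domainTasks()) {
    if (anyNA(hbl$domain)) stop("domain labels required for task ", task)
    return(setNames(ifelse(hbl$domain == task, 1, -1), hbl$id))
  }
  stop("unknown task '", task, "'; valid tasks: ",
       paste(hblTasks(), collapse = ", "))
}

#' Train the full hierarchical model bank
#'
#' Trains one binary RBF-SVM per hierarchy task: stage 1 on the whole
#' dataset, subfamily and domain tasks one-vs-rest within the HbL records.
#' The `single_domain` and `trunc_domain` entries share the `sHb` and `trHb`
#' model objects rather than being retrained, since their positive sets are
#' identical by construction.
#'
#' @param dataset A fully labeled [HbLDataset-class].
#' @param scheme Encoding scheme for every model.
#' @param params Optional named list `task -> list(gamma, cost)` overriding
#'   [defaultParams()].
#' @param seed Integer seed passed to each [trainSVM()] call.
#' @param pssms PSSMs for `scheme = "PSSM"`, see [encodeSequences()].
#' @return A [ModelRegistry-class] with nine task entries.
#' @export
trainHierarchy <- function(dataset, scheme, params = NULL, seed = 1L,
                           pssms = NULL) {
  scheme <- .checkScheme(scheme)
  feat <- encodeSequences(dataset, scheme, pssms = pssms)
  shared <- c(single_domain = "sHb", trunc_domain = "trHb")
  models <- list()
  for (task in setdiff(hblTasks(), names(shared))) {
    y <- taskLabels(dataset, task)
    if (length(unique(y)) < 2L)
      stop("task '", task, "' has a single class in the training data")
    p <- if (!is.null(params) && task %in% names(params)) params[[task]]
         else defaultParams(task, scheme)
    models[[task]] <- trainSVM(feat[names(y), , drop = FALSE], y,
                               gamma = p$gamma, cost = p$cost,
                               scheme = scheme, seed = seed)
  }
  for (task in names(shared)) models[[task]] <- models[[shared[[task]]]]
  new("ModelRegistry", scheme = scheme, models = models[hblTasks()])
}

#' Hierarchical prediction for protein sequences
#'
#' Stage 1 scores each sequence with the `HbL_vs_non` model; sequences with
#' scores below the model threshold (default 0, scores exactly on the
#' threshold count as positive) are called `nonHbL` and receive no further
#' labels. Positive sequences are scored by the three subfamily models and
#' assigned to the arg-max subfamily (ties broken by the fixed task order
#' sHb, flavoHb, trHb); if all three scores are negative the subfamily is
#' `NA` (unclassified HbL). The five domain models are applied the same way.
#'
#' @param x Sequences: an `AAStringSet`, named character vector or
#'   [HbLDataset-class].
#' @param registry A [ModelRegistry-class] from [trainHierarchy()].
#' @param pssms PSSMs when the registry scheme is `"PSSM"`.
#' @return A `data.frame` with one row per sequence: `id`, `stage1_score`,
#'   `stage1_label`, `subfamily`, one `<task>_score` column per subfamily
#'   task, `domain`, and one `<task>_score` column per domain task.
#'   Subfamily/domain columns are `NA` for sequences called `nonHbL`.
#' @export
predictHierarchy <- function(x, registry, pssms = NULL) {
  stopifnot(is(registry, "ModelRegistry"))
  feat <- encodeSequences(x, registry@scheme, pssms = pssms)
  ids <- rownames(feat)
  m1 <- getModel(registry, "HbL_vs_non")
  s1 <- decisionScore(m1, feat)
  pos <- s1 >= m1@threshold
  out <- data.frame(id = ids, stage1_score = unname(s1),
                    stage1_label = ifelse(pos, "HbL", "nonHbL"),
                    stringsAsFactors = FALSE)
  stageScores <- function(tasks) {
    sc <- matrix(NA_real_, length(ids), length(tasks),
                 dimnames = list(ids, tasks))
    if (any(pos))
      for (t in tasks)
        sc[pos, t] <- decisionScore(getModel(registry, t),
                                    feat[pos, , drop = FALSE])
    sc
  }
  argmaxCall <- function(sc) {
    apply(sc, 1L, function(v) {
      if (anyNA(v) || all(v < 0)) NA_character_ else names(v)[which.max(v)]
    })
  }
  sub <- stageScores(subfamilyTasks())
  dom <- stageScores(domainTasks())
  out$subfamily <- unname(argmaxCall(sub))
  for (t in subfamilyTasks()) out[[paste0(t, "_score")]] <- unname(sub[, t])
  out$domain <- unname(argmaxCall(dom))
  for (t in domainTasks()) out[[paste0(t, "_score")]] <- unname(dom[, t])
  rownames(out) <- NULL
  out
}

#' Save / load a model registry
#'
#' Writes one JSON model file per task into a directory (shared models are
#' written once per task name for simplicity of loading), plus a
#' `registry.json` manifest with the scheme and task list.
#'
#' @param registry A [ModelRegistry-class].
#' @param dir Directory path (created if needed).
#' @return `saveRegistry`: `dir` invisibly. `loadRegistry`: the restored
#'   [ModelRegistry-class].
#' @export
saveRegistry <- function(registry, dir) {
  stopifnot(is(registry, "ModelRegistry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_json(list(format = "hblpred-registry", version = 1L,
                  scheme = registry@scheme, tasks = names(registry@models)),
             file.path(dir, "registry.json"), auto_unbox = TRUE)
  for (task in names(registry@models))
    saveModel(registry@models[[task]], file.path(dir, paste0(task, ".json")))
  invisible(dir)
}

#' @rdname saveRegistry
#' @export
loadRegistry <- function(dir) {
  manifest <- file.path(dir, "registry.json")
  if (!file.exists(manifest))
    stop("not a model directory (no registry.json): ", dir)
  info <- read_json(manifest, simplifyVector = TRUE)
  if (!identical(info$format, "hblpred-registry"))
    stop("not an hblpred registry manifest: ", manifest)
  models <- lapply(info$tasks, function(task)
    loadModel(file.path(dir, paste0(task, ".json"))))
  names(models) <- info$tasks
  new("ModelRegistry", scheme = info$scheme, models = models)
}
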
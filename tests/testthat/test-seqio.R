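test_that("readFasta parses headers, sequences and edge cases", {
  f <- writeTempFasta("P1 test", "MKV")
  x <- readFasta(f)
  expect_length(x, 1L)
  expect_identical(names(x), "P1")
  expect_identical(S4Vectors::mcols(x)$description, "test")
  expect_identical(as.character(x), c(P1 = "MKV"))

  empty <- tempfile(); file.create(empty)
  expect_length(readFasta(empty), 0L)

  dup <- writeTempFasta(c("A", "A desc"), c("MK", "MV"))
  expect_error(readFasta(dup), "duplicate")

  bad <- tempfile()
  writeLines(c("MKV", ">A"), bad)
  expect_error(readFasta(bad), "line 1")

  ## wrapped lines and lowercase are normalized
  wrapped <- tempfile()
  writeLines(c(">W", "mkv", "HAE"), wrapped)
  expect_identical(as.character(readFasta(wrapped)), c(W = "MKVHAE"))
})

test_that("FASTA write/read round-trips validated records", {
  set.seed(41)
  headers <- c("A1 first protein", "B2", "C3 another one")
  seqs <- vapply(c(30L, 61L, 10L), randomSeq, "")
  f <- writeTempFasta(headers, seqs)
  x <- readFasta(f)
  g <- tempfile(fileext = ".fasta")
  writeFasta(x, g)
  y <- readFasta(g)
  expect_identical(as.character(y), as.character(x))
  expect_identical(S4Vectors::mcols(y)$description,
                   S4Vectors::mcols(x)$description)
})

test_that("validateSequences applies reject/strip/remap policies", {
  expect_identical(validateSequences(c(p = "MKVX"), "strip"), c(p = "MKV"))
  expect_identical(validateSequences(c(p = "MKV"), "reject"), c(p = "MKV"))
  expect_identical(validateSequences(c(p = "MBZ"), "remap"), c(p = "MDE"))
  expect_identical(validateSequences(c(p = "MUBJ"), "remap"), c(p = "MCD"))
  err <- tryCatch(validateSequences(c(bad = "MXKZ"), "reject"),
                  error = conditionMessage)
  expect_match(err, "bad")
  expect_match(err, "position 2")
  expect_match(err, "position 4")
  expect_error(validateSequences(c(p = "XX"), "strip"), "empty")
  ## default policy is reject
  expect_error(validateSequences(c(p = "MKX")), "non-standard")
})

test_that("filterAnnotations removes keyword-annotated records and is idempotent", {
  x <- Biostrings::AAStringSet(c(a = "MKV", b = "MHA", c = "MWC", d = "MEE"))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = c(
    "flavohemoglobin (Fragment)", "flavohemoglobin",
    "PROBABLE globin", "hemoglobin, isoforms 1/2"))
  suppressMessages({
    kept <- filterAnnotations(x)
    expect_identical(names(kept), "b")
    ## subset of input and idempotent
    again <- filterAnnotations(kept)
    expect_identical(names(again), names(kept))
    expect_true(all(names(kept) %in% names(x)))
    ## empty keyword list retains everything
    expect_length(filterAnnotations(x, character(0)), 4L)
  })
})

test_that("pairwiseIdentity matches a brute-force Needleman-Wunsch oracle", {
  expect_equal(pairwiseIdentity("MKVLAE", "MKQTWC"), 2 / 6)
  set.seed(7)
  for (i in 1:8) {
    a <- randomSeq(sample(5:14, 1))
    b <- randomSeq(sample(5:14, 1))
    expect_equal(pairwiseIdentity(a, b),
                 bruteForceNWMatches(a, b) / min(nchar(a), nchar(b)),
                 info = paste(a, b))
  }
})

test_that("reduceRedundancy keeps a cutoff-respecting longest-first subset", {
  suppressMessages({
    x <- Biostrings::AAStringSet(c(a = "MKVLAEHH", b = "MKVLAEHH"))
    expect_length(reduceRedundancy(x, 0.9), 1L)

    y <- Biostrings::AAStringSet(c(a = "MKVLAE", b = "MKQTWC"))
    expect_length(reduceRedundancy(y, 0.9), 2L)

    single <- Biostrings::AAStringSet(c(only = "MKV"))
    expect_length(reduceRedundancy(single, 0.9), 1L)

    ## property: retained set never contains a pair above the cutoff
    set.seed(11)
    base <- randomSeq(40)
    pool <- c(vapply(1:6, function(i) {
      s <- strsplit(base, "")[[1]]
      k <- sample(40, sample(1:20, 1))
      s[k] <- sample(AA, length(k), replace = TRUE)
      paste(s, collapse = "")
    }, ""), vapply(1:4, function(i) randomSeq(sample(30:50, 1)), ""))
    names(pool) <- sprintf("s%02d", seq_along(pool))
    kept <- reduceRedundancy(Biostrings::AAStringSet(pool), 0.8)
    ids <- names(kept)
    if (length(ids) > 1L)
      for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1L))
        expect_lte(pairwiseIdentity(pool[[ids[i]]], pool[[ids[j]]]), 0.8)
  })
})

test_that("label tables round-trip and accept the two-column form", {
  tab <- data.frame(id = c("a", "b"), class = c("HbL", "nonHbL"),
                    subfamily = c("sHb", NA), domain = c("single_domain", NA),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeLabelTable(tab, f)
  back <- readLabelTable(f)
  expect_identical(back$class, tab$class)
  expect_identical(back$subfamily, tab$subfamily)

  g <- tempfile()
  writeLines(c("a\tHbL", "b\tnonHbL"), g)
  two <- readLabelTable(g)
  expect_identical(two$class, c("HbL", "nonHbL"))
  expect_true(all(is.na(two$subfamily)))
})

test_that("HbLDataset validates, subsets and aligns labels to sequences", {
  ds <- HbLDataset(c(b = "MHA", a = "MKV"),
                   data.frame(id = c("a", "b"), class = c("HbL", "nonHbL")))
  expect_identical(labelTable(ds)$id, c("b", "a"))  # reordered to sequences
  expect_identical(labelTable(ds)$class, c("nonHbL", "HbL"))
  sub <- ds["a"]
  expect_length(sub, 1L)
  expect_identical(labelTable(sub)$class, "HbL")
  expect_error(HbLDataset(c(a = "MKV"), data.frame(id = "zz", class = "HbL")),
               "no label row")
})
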
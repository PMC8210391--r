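scale_set <- aa_scale_set()

test_that("worked micro-examples match their golden composition vectors", {
  wex <- worked_example_set()
  for (i in seq_len(nrow(wex))) {
    aa <- aa_composition(wex$sequence[i])
    golden <- wex$aa_golden[[i]]
    expect_equal(aa[names(golden)], golden, tolerance = 1e-12,
                 ignore_attr = FALSE)
    expect_equal(sum(aa[setdiff(names(aa), names(golden))]), 0)
    if (!is.null(wex$dp_golden[[i]])) {
      dp <- dipeptide_composition(wex$sequence[i])
      gdp <- wex$dp_golden[[i]]
      expect_equal(dp[names(gdp)], gdp, tolerance = 1e-12)
      expect_equal(sum(dp[setdiff(names(dp), names(gdp))]), 0)
    }
  }
})

test_that("scale set has the 11 documented scales, normalized to [0, 1]", {
  expect_equal(nrow(scale_set), 11)
  expect_equal(anyDuplicated(scale_set$scale), 0)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- as.matrix(scale_set[, aa])
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(unname(apply(m, 1, min)), rep(0, 11))
  expect_equal(unname(apply(m, 1, max)), rep(1, 11))
  arom <- as.numeric(scale_set[scale_set$scale == "aromaticity", aa])
  expect_equal(arom, as.numeric(aa %in% c("F", "W", "Y")))
})

test_that("min-max normalization maps extremes and rejects bad scales", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  raw <- stats::setNames(1:20, aa)
  norm <- normalize_scale(raw)
  expect_equal(unname(norm[c("A", "Y")]), c(0, 1))
  expect_equal(unname(norm["C"]), 1 / 19)
  expect_error(normalize_scale(stats::setNames(rep(3, 20), aa)), "constant")
  expect_error(normalize_scale(raw[1:19]), "20 canonical")
})

test_that("property averaging: constant-scale, single-residue and AV cases", {
  # constant scale: any sequence averages to the constant, exactly
  cs <- constant_scale_set(c(0.42, 0.0, 1.0))
  set.seed(4)
  for (s in c("ACDE", random_protein(100), "W")) {
    expect_equal(unname(pcp_features(s, cs)), c(0.42, 0, 1))
  }
  # single residue: the feature is that residue's normalized value
  w_vals <- as.numeric(as.matrix(scale_set[, "W"]))
  expect_equal(unname(pcp_features("W", scale_set)), w_vals)
  # two residues: exact mean, to 1e-12
  a_vals <- as.numeric(as.matrix(scale_set[, "A"]))
  v_vals <- as.numeric(as.matrix(scale_set[, "V"]))
  expect_equal(unname(pcp_features("AV", scale_set)), (a_vals + v_vals) / 2,
               tolerance = 1e-12)
})

test_that("encoders emit fixed dimensions and exact block concatenation", {
  set.seed(9)
  s <- random_protein(80)
  dims <- c(PCP = 11, AA = 20, DP = 400)
  for (sch in names(dims)) {
    expect_length(encode(s, sch, scale_set), dims[[sch]])
  }
  # combined schemes are exact concatenations of their blocks
  expect_identical(encode(s, "PCP_AA", scale_set),
                   c(pcp_features(s, scale_set), aa_composition(s)))
  expect_identical(encode(s, "PCP_AA_DP", scale_set),
                   c(pcp_features(s, scale_set), aa_composition(s),
                     dipeptide_composition(s)))
})

test_that("composition blocks are distributions; all features in [0, 1]", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_protein(sample(2:300, 1))
    v <- encode(s, "PCP_AA_DP", scale_set)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v[grepl("^AA_", names(v))]), 1, tolerance = 1e-9)
    expect_equal(sum(v[grepl("^DP_", names(v))]), 1, tolerance = 1e-9)
  }
})

test_that("AA and PCP are permutation-invariant, DP is not in general", {
  set.seed(33)
  s <- random_protein(60)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(aa_composition(s), aa_composition(perm))
  expect_equal(pcp_features(s, scale_set), pcp_features(perm, scale_set))
  expect_false(isTRUE(all.equal(dipeptide_composition(s),
                                dipeptide_composition(perm))))
})

test_that("dataset encoding keeps row order, stable names, and names failures", {
  recs <- records_from(c("ACDEFGHIK", "MMMMKLVVA", "WYWYWYWYW"))
  f1 <- encode_dataset(recs, "DP", scale_set)
  f2 <- encode_dataset(recs[3:1, ], "DP", scale_set)
  expect_equal(f1$id, recs$id)
  expect_equal(names(f1), names(f2))
  expect_equal(ncol(f1), 1 + 400)
  expect_equal(unlist(f1[1, -1]), dipeptide_composition(recs$sequence[1]))
  # mixed lengths still produce equal-length rows
  expect_true(all(rowSums(as.matrix(f1[, -1])) - 1 < 1e-9))
  bad <- records_from(c("ACDE", "W"), ids = c("ok", "tiny"))
  expect_error(encode_dataset(bad, "DP", scale_set), "tiny")
  dup <- records_from(c("ACDE", "MKLV"), ids = c("a", "a"))
  expect_error(encode_dataset(dup, "AA"), "duplicate")
})

test_that("feature tibbles round-trip through TSV unchanged", {
  wex <- worked_example_set()
  recs <- records_from(wex$sequence[wex$sequence != "W"],
                       ids = wex$id[wex$sequence != "W"])
  feats <- encode_dataset(recs, "PCP_AA_DP", scale_set)
  path <- tempfile(fileext = ".tsv")
  write_features(feats, path)
  back <- read_features(path)
  expect_equal(names(back), names(feats))
  expect_equal(as.matrix(back[, -1]), as.matrix(feats[, -1]),
               tolerance = 1e-12)
})

test_that("custom scale tables are normalized on read and preserve order", {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  raw <- data.frame(scale = c("s_one", "s_two"), source = "unit",
                    check.names = FALSE)
  set.seed(5)
  for (r in aa) raw[[r]] <- stats::runif(2, -3, 7)
  path <- tempfile(fileext = ".tsv")
  write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_scale_set(path)
  expect_equal(ss$scale, c("s_one", "s_two"))
  m <- as.matrix(ss[, aa])
  expect_equal(unname(apply(m, 1, range)), matrix(c(0, 1, 0, 1), 2))
  expect_equal(
    unname(pcp_features("AC", ss)),
    unname((m[, "A"] + m[, "C"]) / 2)
  )
})
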
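test_that("feature subsets enumerate by size then lexicographically", {
  all6 <- enumerate_feature_subsets()
  expect_length(all6, 63L)
  expect_length(enumerate_feature_subsets(c("H", "A", "C")), 7L)
  expect_identical(format(enumerate_feature_subsets("H")[[1]]), "H")
  sizes <- vapply(all6, length, integer(1))
  expect_true(!is.unsorted(sizes))
  strings <- vapply(all6, format, character(1))
  for (s in unique(sizes)) {
    expect_true(!is.unsorted(strings[sizes == s]))
  }
  expect_error(feature_set(character(0)), class = "mhcforest_config_error")
  expect_error(feature_set("HQ"), class = "mhcforest_config_error")
})

test_that("default feature combination is hydropathy/aromatic/sparse/mass", {
  expect_identical(format(default_feature_set()), "HASM")
  expect_false(identical(format(default_feature_set()), "HACMS"))
  expect_identical(ncol(encode_peptides("SIINFEKLV", default_feature_set())), 207L)
})

test_that("encodings have the documented dimension and block content", {
  p <- "SIINFEKLV"
  s <- encode_peptide(p, "S")
  expect_length(s, 180L)
  expect_equal(sum(s), 9)                 # exactly one hot coordinate per position
  expect_true(all(s %in% c(0, 1)))
  expect_length(encode_peptide(p, "HASM"), 207L)   # 3*9 + 180
  expect_equal(unname(encode_peptide("AAAAAAAAA", "H")), rep(1.8, 9))
  # B block carries the residue's substitution row at each position
  b <- encode_peptide(p, "B")
  b62 <- blosum62_matrix()
  res <- strsplit(p, "")[[1]]
  for (pos in 1:9) {
    expect_equal(unname(b[(pos - 1) * 20 + 1:20]), unname(b62[res[pos], ]))
  }
  # layout dimension formula across random subsets
  set.seed(11)
  for (i in 1:10) {
    fs <- feature_set(sample(c("H", "A", "C", "M", "S", "B"), sample(1:6, 1)))
    n_scalar <- sum(unclass(fs) %in% c("H", "A", "C", "M"))
    n_enc <- sum(unclass(fs) %in% c("S", "B"))
    expect_identical(nrow(feature_layout(fs)), 9L * n_scalar + 180L * n_enc)
  }
})

test_that("layout labels decode back to their source residue and property", {
  p <- validate_peptide("WCKDNFHTY")
  res <- strsplit(p, "")[[1]]
  props <- residue_properties()
  fs <- feature_set("HASMB")
  v <- encode_peptide(p, fs)
  lay <- feature_layout(fs)
  for (i in seq_len(nrow(lay))) {
    f <- lay$feature[i]; pos <- lay$position[i]
    expected <- if (f %in% c("H", "A", "M")) {
      prop <- c(H = "hydropathy", A = "aromatic", M = "mass")[[f]]
      props[[prop]][[res[pos]]]
    } else if (f == "S") {
      as.numeric(lay$sub[i] == res[pos])
    } else {
      blosum62_matrix()[res[pos], lay$sub[i]]
    }
    expect_equal(unname(v[i]), unname(expected))
  }
})

test_that("one-hot block makes the encoding injective and position-local", {
  set.seed(21)
  peps <- unique(replicate(40, paste(sample(AA_ALPHABET, 9, TRUE), collapse = "")))
  enc <- encode_peptides(peps, "HASM")
  expect_identical(nrow(unique(as.data.frame(enc))), length(peps))
  # swapping two peptide positions permutes exactly those blocks
  p1 <- "ACDEFGHIK"
  p2 <- "KCDEFGHIA"  # positions 1 and 9 swapped
  lay <- feature_layout("HASM")
  e1 <- encode_peptide(p1, "HASM"); e2 <- encode_peptide(p2, "HASM")
  inner <- lay$position %in% 2:8
  expect_equal(unname(e1[inner]), unname(e2[inner]))
  for (f in unique(lay$feature)) {
    i1 <- which(lay$feature == f & lay$position == 1)
    i9 <- which(lay$feature == f & lay$position == 9)
    expect_equal(unname(e1[i1]), unname(e2[i9]))
    expect_equal(unname(e1[i9]), unname(e2[i1]))
  }
  expect_error(encode_peptides("SIINFEKL", "S"), class = "mhcforest_length_error")
})
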
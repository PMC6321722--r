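test_that("motif construction is row-stochastic, anchored and seeded", {
  pwm <- make_motif(1L)
  expect_equal(unname(rowSums(pwm$matrix)), rep(1, 9), tolerance = 1e-9)
  expect_true(all(pwm$matrix >= 0))
  expect_identical(pwm$anchor_positions, c(2L, 9L))
  for (i in seq_along(pwm$anchor_positions)) {
    expect_equal(unname(pwm$matrix[pwm$anchor_positions[i], pwm$anchor_residues[i]]), 0.9)
  }
  expect_identical(make_motif(1L)$matrix, pwm$matrix)
  # weight 1/20 degenerates to a fully uniform motif
  flat <- make_motif(1L, anchor_weight = 0.05)
  expect_equal(unname(flat$matrix), matrix(1 / 20, 9, 20))
  expect_error(make_motif(1L, anchor_weight = 0.04), class = "mhcforest_config_error")
  expect_error(make_motif(1L, anchor_positions = 10), class = "mhcforest_config_error")
})

test_that("binder sampling follows the motif rows", {
  pwm <- make_motif(2L)
  b <- sample_binders(pwm, 200L, seed = 3L)
  expect_true(all(peptide_status(b) == "ok"))
  expect_identical(sample_binders(pwm, 200L, seed = 3L), b)
  # fully deterministic anchors at weight 1
  hard <- make_motif(4L, anchor_weight = 1)
  hb <- sample_binders(hard, 50L, seed = 5L)
  expect_true(all(substr(hb, 2, 2) == hard$anchor_residues[1]))
  expect_true(all(substr(hb, 9, 9) == hard$anchor_residues[2]))
  # anchor-position residue frequencies converge to the motif row
  big <- sample_binders(pwm, 10000L, seed = 6L)
  obs <- table(factor(substr(big, 2, 2), levels = AA_ALPHABET))
  p <- stats::chisq.test(obs, p = pwm$matrix[2, ])$p.value
  expect_gt(p, 1e-4)
})

test_that("synthetic proteomes have the declared window structure", {
  pr <- synth_proteome(25L, 120, seed = 8L)
  expect_length(pr$ids, 25L)
  expect_true(all(nchar(pr$sequences) >= 9))
  windows <- mhcforest:::eligible_window_starts(pr)
  expect_identical(sum(lengths(windows)), sum(nchar(pr$sequences) - 8L))
  # same seed reproduces the FASTA byte-for-byte
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_proteome(synth_proteome(25L, 120, seed = 8L), f1)
  write_proteome(synth_proteome(25L, 120, seed = 8L), f2)
  expect_identical(readLines(f1), readLines(f2))
  # swissprot-like composition is a valid distribution
  pr2 <- synth_proteome(5L, 200, seed = 9L, composition = "swissprot")
  expect_true(all(peptide_status(sample_decoys(pr2, 20L, seed = 1L)) == "ok"))
})

test_that("synthetic affinities are monotone in motif match", {
  pwm <- make_motif(10L)
  peps <- c(sample_binders(pwm, 250L, seed = 11L),
            sample_binders(make_motif(10L, anchor_weight = 0.05), 250L, seed = 12L))
  noiseless <- synth_affinity(peps, pwm, noise_sd = 0, seed = 13L)
  expect_true(all(noiseless$ic50 > 0))
  ll <- motif_loglik(peps, pwm)
  expect_equal(cor(ll, noiseless$ic50, method = "spearman"), -1)
  noisy <- synth_affinity(peps, pwm, noise_sd = 1, seed = 14L)
  expect_lt(cor(ll, noisy$ic50, method = "spearman"), -0.5)
  # the declared dynamic range covers typical assay values
  expect_lt(min(noiseless$ic50), 100)
  expect_gt(max(noiseless$ic50), 10000)
})

test_that("synthetic expression reproduces the closed-form effect size", {
  # location-shift normal model: d = 2 * pnorm(shift / sqrt(2)) - 1
  s <- synth_expression(5000L, 1000L, shift = 1.2, seed = 15L)
  d <- cliffs_d(unname(s$expression[s$presented_genes]),
                unname(s$expression[setdiff(names(s$expression), s$presented_genes)]))
  expect_equal(d, 2 * pnorm(1.2 / sqrt(2)) - 1, tolerance = 0.1)
  s0 <- synth_expression(3000L, 600L, shift = 0, seed = 16L)
  d0 <- cliffs_d(unname(s0$expression[s0$presented_genes]),
                 unname(s0$expression[setdiff(names(s0$expression), s0$presented_genes)]))
  expect_lt(abs(d0), 0.08)
  expect_error(synth_expression(10L, 10L), class = "mhcforest_config_error")
})

test_that("a simulated study is internally consistent", {
  study <- simulate_study(n_alleles = 2L, n_binders = 60L, n_proteins = 40L,
                          mean_length = 150, seed = 17L)
  expect_length(study$datasets, 2L)
  expect_true(all(peptide_status(study$mono$sequence) == "ok"))
  expect_true(all(study$poly$confidence >= 0.9 & study$poly$confidence <= 1))
  # mono + poly cover each allele's binder set
  pooled <- pool_by_allele(study$mono, study$poly, conf_threshold = 0,
                           min_peptides = 10L)
  for (a in study$alleles) {
    expect_setequal(pooled[[a]]$binders, study$datasets[[a]]$binders)
  }
  expect_true(all(study$affinity$ic50 > 0))
  expect_true(all(study$expression$presented_genes %in%
                    names(study$expression$expression)))
})
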
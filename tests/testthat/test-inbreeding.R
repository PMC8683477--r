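test_that("hard filter applies every criterion and attributes removals", {
  # 10 hand-set sites; expected survivors computed by per-site rule evaluation
  info <- data.frame(
    QD = c(1.9, 5, 5, 5, 5, 5, 5, NA, 5, 5),
    FS = c(10, 70, 10, 10, 10, 10, 10, 10, 10, 10),
    SOR = c(1, 1, 3.5, 1, 1, 1, 1, 1, 1, 1),
    MQ = c(50, 50, 50, 39, 50, 50, 50, 50, 50, 50),
    MQRankSum = c(0, 0, 0, 0, -13, 0, 0, 0, 0, 0),
    ReadPosRankSum = c(0, 0, 0, 0, 0, -9, 0, 0, 0, 0))
  # 8 individuals; site 7 gets MAF below 1%: all ref except nothing -> mono;
  # use one alt in 8 ind (MAF 1/16 = 0.0625 passes); make site 7 monomorphic
  dos <- matrix(1L, 8, 10)
  dos[, 7] <- 0L; dos[1, 7] <- 0L   # MAF 0 -> fails MAF
  tab <- make_geno(dos, info = info)
  res <- hard_filter(tab, default_config()$filters)
  # brute-force oracle
  viol <- with(info, QD < 2 | FS > 60 | SOR > 3 | MQ < 40 |
                 MQRankSum < -12.5 | ReadPosRankSum < -8)
  viol[is.na(viol)] <- FALSE
  maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  viol <- viol | maf < 0.01
  expect_equal(nrow(res$table$sites), sum(!viol))
  expect_equal(res$table$sites$pos, tab$sites$pos[!viol])
  rep <- setNames(res$report$n_removed, res$report$criterion)
  expect_equal(unname(rep[c("QD", "FS", "SOR", "MQ", "MQRankSum",
                            "ReadPosRankSum", "MAF")]),
               c(1, 1, 1, 1, 1, 1, 1))
  expect_true(any(grepl("QD", res$removed$criteria)))
})

test_that("MAF boundary is strict and empty tables are an error", {
  # 50 individuals, one alt allele at site 1 => MAF = 0.01 exactly: retained
  dos <- matrix(0L, 50, 2)
  dos[1, 1] <- 1L
  dos[, 2] <- rep(c(0L, 1L), 25)
  tab <- make_geno(dos)
  res <- hard_filter(tab)
  expect_true(1000L %in% res$table$sites$pos)  # site 1 retained at MAF == 0.01
  expect_error(hard_filter(genotype_table(character(0),
                                          data.frame(chrom = character(0),
                                                     pos = integer(0)),
                                          matrix(integer(0), 0, 0))), "empty")
})

test_that("mac filter drops singletons and private doubletons", {
  dos <- rbind(c(0L, 0L, 1L), c(0L, 2L, 1L), c(0L, 0L, 1L), c(1L, 0L, 0L))
  tab <- make_geno(dos)
  # alt counts: 1 (singleton), 2 (doubleton), 3 -> only site 3 kept
  kept <- mac_filter(tab, min_mac = 3L)
  expect_equal(kept$sites$pos, 3000L)
})

test_that("method-of-moments F has its closed-form limits", {
  # three individuals over 20 loci, pooled p = 0.5 everywhere
  tab <- make_geno(rbind(rep(c(0L, 2L), 10), rep(1L, 20), rep(c(2L, 0L), 10)))
  f <- f_moments(tab)
  expect_equal(unname(f["I01"]), 1)
  expect_equal(unname(f["I03"]), 1)
  # genotype counts at exact HWE proportions -> F = 0
  # p = 0.5: individuals with dosages 0,1,1,2 give each individual's F via
  # pooled p; instead check a heterozygote-everywhere individual: O_hom = 0,
  # E_hom = L/2 -> F = (0 - L/2) / (L - L/2) = -1
  expect_equal(unname(f["I02"]), -1)
})

test_that("a 3-locus worked example matches hand arithmetic", {
  # p = 0.5, 0.25, 0.1; genotypes 2, 1, 0
  # O_hom = 2; E_hom = 0.5 + 0.625 + 0.82 = 1.945
  # F = (2 - 1.945) / (3 - 1.945) = 0.0521327...
  dos <- matrix(c(2L, 1L, 0L), 1, 3)
  tab <- make_geno(dos)
  f <- f_moments(tab, p = c(0.5, 0.25, 0.1))
  expect_equal(unname(f), (2 - 1.945) / (3 - 1.945), tolerance = 1e-12)
})

test_that("HWE individuals have F near zero at many loci", {
  sim <- gen_genotypes(20, 10000, target_froh = 0, seed = 51)
  # corrected form is unbiased at a 20-individual panel; the plain form
  # carries the expected ~ -1/(2n) finite-panel bias but stays small
  f <- f_moments(sim$table, small_sample_correction = TRUE)
  expect_true(all(abs(f) < 0.05))
  expect_lt(max(abs(f_moments(sim$table))), 0.1)
})

test_that("ROH detection matches the exhaustive window oracle on fuzzed data", {
  params <- list(window_snps = 50L, window_het = 0L, window_missing = 2L,
                 hit_frac = 0.05, min_snps = 50L, min_length_kb = 100)
  set.seed(52)
  for (rep in 1:30) {
    m <- 500L
    pos <- sort(sample.int(5e6, m))
    g <- rep(0L, m)
    # plant heterozygotes and missing at random density
    g[sample.int(m, rpois(1, 30))] <- 1L
    g[sample.int(m, rpois(1, 10))] <- NA_integer_
    qual <- roh_qualifying_snps(g, params$window_snps, params$window_het,
                                params$window_missing, params$hit_frac)
    expect_identical(qual, roh_oracle_qualify(g, params$window_snps,
                                              params$window_het,
                                              params$window_missing,
                                              params$hit_frac))
    tab <- make_geno(matrix(g, 1), pos = pos)
    segs <- detect_roh(tab, params)
    oracle <- roh_oracle_segments(g, pos, params)
    if (is.null(oracle)) {
      expect_equal(nrow(segs), 0L)
    } else {
      expect_equal(nrow(segs), nrow(oracle))
      expect_equal(segs$start_bp, unname(oracle[, "start"]))
      expect_equal(segs$end_bp, unname(oracle[, "end"]))
      expect_equal(segs$n_snps, unname(oracle[, "n_snps"]))
    }
  }
})

test_that("ROH limits: all-homozygous spans report; short spans do not", {
  params <- default_config()$roh
  # 200 homozygous SNPs spanning 2.0 Mb -> one segment, 200 SNPs, 2.0 Mb
  pos <- as.integer(round(seq(1e6, 3e6, length.out = 200)))
  tab <- make_geno(matrix(0L, 1, 200), pos = pos)
  segs <- detect_roh(tab, params)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 200L)
  expect_equal(segs$length_bp, 2e6)
  # same SNPs compressed into 1.4 Mb: below the minimum length
  pos2 <- as.integer(round(seq(1e6, 2.4e6, length.out = 200)))
  tab2 <- make_geno(matrix(0L, 1, 200), pos = pos2)
  expect_equal(nrow(detect_roh(tab2, params)), 0L)
  # chromosome shorter than the window: no windows, no runs, no error
  tab3 <- make_geno(matrix(0L, 1, 100), pos = pos[1:100])
  expect_equal(nrow(detect_roh(tab3, params)), 0L)
})

test_that("F_ROH is total run length over screened length", {
  segs <- data.frame(ind = c("a", "a", "b"), chrom = "chr1",
                     start_bp = c(1, 100, 1), end_bp = c(51, 200, 11),
                     n_snps = c(10, 20, 5),
                     length_bp = c(370e6 / 2, 370e6 / 2, 10))
  fr <- froh(segs, 1e9, ids = c("a", "b", "c"))
  expect_equal(fr$froh, c(0.37, 1e-8, 0))
  expect_equal(fr$n_segments, c(2, 1, 0))
  expect_error(froh(segs, 0), "> 0")
})

test_that("F_ROH recovery and F/F_ROH correlation on planted panels", {
  sim <- gen_genotypes(12, 20000, target_froh = seq(0, 0.33, length.out = 12),
                       seed = 53)
  segs <- detect_roh(sim$table)
  fr <- froh(segs, sim$truth$screened_length_bp, ids = sim$table$ids)
  # recovery within detection edge losses
  expect_lt(max(abs(fr$froh - unname(sim$truth$target_froh))), 0.03)
  # monotone: planting more ROH never decreases the estimate (rank corr.)
  f <- f_moments(sim$table)
  expect_gt(cor(f, fr$froh), 0.7)
})

test_that("Mendelian errors follow biallelic transmission rules", {
  # trio loci: (sire, dam, child)
  cases <- rbind(
    c(0, 0, 1),  # impossible
    c(0, 0, 0),  # fine
    c(1, 1, 0), c(1, 1, 1), c(1, 1, 2),  # het x het: anything fine
    c(2, 0, 1),  # obligate het: fine
    c(2, 0, 0),  # impossible
    c(2, 2, 1),  # impossible
    c(0, 2, 2),  # impossible
    c(NA, 0, 2)) # not evaluable
  dos <- rbind(sire = cases[, 1], dam = cases[, 2], child = cases[, 3])
  tab <- genotype_table(c("sire", "dam", "child"),
                        data.frame(chrom = "chr1",
                                   pos = seq_len(nrow(cases)) * 100L),
                        dos)
  res <- mendelian_error_rate(tab, data.frame(child = "child", sire = "sire",
                                              dam = "dam"))
  expect_equal(res$per_locus,
               c(1, 0, 0, 0, 0, 0, 1, 1, 1, NA))
  expect_equal(res$mean_rate, 4 / 9)
  expect_error(mendelian_error_rate(tab, data.frame(child = "x", sire = "sire",
                                                    dam = "dam")), "unknown")
})

test_that("random trios match a brute-force transmission oracle", {
  set.seed(54)
  dos <- matrix(sample(c(0:2, NA), 300, replace = TRUE), 3, 100)
  tab <- genotype_table(c("c", "s", "d"),
                        data.frame(chrom = "chr1", pos = (1:100) * 10L), dos)
  res <- mendelian_error_rate(tab, data.frame(child = "c", sire = "s", dam = "d"))
  oracle <- vapply(1:100, function(l) {
    g <- dos[, l]
    if (any(is.na(g))) return(NA_real_)
    poss <- unique(outer(if (g[2] == 1) 0:1 else g[2] / 2,
                         if (g[3] == 1) 0:1 else g[3] / 2, `+`))
    as.numeric(!(g[1] %in% poss))
  }, numeric(1))
  expect_equal(res$per_locus, oracle)
})

test_that("imputation metrics: identity, dosage flip, constant input", {
  sim <- gen_genotypes(5, 200, target_froh = 0, seed = 55)
  truth <- sim$table
  m <- imputation_metrics(truth, truth$dosage)
  expect_equal(m$mean_concordance, 1)
  expect_equal(m$mean_dosage_r2, 1)
  flip <- 2L - truth$dosage
  mf <- imputation_metrics(truth, flip)
  expect_equal(mf$mean_dosage_r2, 1)
  het_frac <- mean(vapply(1:5, function(i) mean(truth$dosage[i, ] == 1L),
                          numeric(1)))
  expect_equal(mf$mean_concordance, het_frac)
  const <- matrix(1L, 5, 200)
  expect_message(mc <- imputation_metrics(truth, const), "constant")
  expect_true(is.na(mc$per_individual$dosage_r2[1]))
})
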
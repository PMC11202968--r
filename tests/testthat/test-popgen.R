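test_that("MAF counts alleles over non-missing genotypes", {
  expect_equal(compute_maf(c(1, 1)), 0.5)
  expect_equal(compute_maf(c(0, 0, 0)), 0)
  # 46 diploids, 40 alt alleles of 92
  d <- c(rep(2, 15), rep(1, 10), rep(0, 21))
  expect_equal(compute_maf(d), 40 / 92, tolerance = 1e-12)
  expect_equal(round(compute_maf(d), 4), 0.4348)
  expect_equal(compute_maf(c(2, NA, 0)), 0.5)  # missing excluded
  expect_error(compute_maf(c(NA, NA)), "all genotypes missing")
})

test_that("Fst limits: no divergence and fixed difference", {
  same <- c(rep(1, 10), rep(1, 10))
  lab <- rep(c("A", "B"), each = 10)
  expect_equal(compute_fst(same, lab, "hudson")$fst, 0)
  expect_lt(abs(compute_fst(same, lab, "weir_cockerham")$fst), 0.15)
  fixed <- c(rep(2, 10), rep(0, 10))
  expect_equal(compute_fst(fixed, lab, "hudson")$fst, 1)
  expect_equal(compute_fst(fixed, lab, "weir_cockerham")$fst, 1)
})

test_that("both Fst estimators match independently coded formulas", {
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    p1 <- runif(1, 0.05, 0.95); p2 <- runif(1, 0.05, 0.95)
    d <- c(rbinom(n1, 2, p1), rbinom(n2, 2, p2))
    lab <- rep(c("g1", "g2"), c(n1, n2))
    if (length(unique(d)) == 1) next
    wc <- compute_fst(d, lab, "weir_cockerham")
    expect_equal(wc$fst, oracle_wc_fst(d, lab), tolerance = 1e-12)
    hu <- compute_fst(d, lab, "hudson")
    expect_equal(hu$fst,
                 oracle_hudson_fst(hu$subpop_freqs[1],
                                   hu$subpop_freqs[2]),
                 tolerance = 1e-12)
    expect_lte(hu$fst, 1)
  }
})

test_that("negative Weir-Cockerham estimates are flagged, not clipped", {
  set.seed(3)
  found <- FALSE
  for (i in 1:50) {
    d <- rbinom(40, 2, 0.5)
    f <- compute_fst(d, rep(c("A", "B"), 20), "weir_cockerham")
    if (!is.na(f$fst) && f$fst < 0) {
      expect_true(f$negative)
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("Fst classification uses the 0.15/0.25 descriptive thresholds", {
  expect_equal(classify_fst(c(0.05, 0.19, 0.30, NA)),
               c("low", "moderately_high", "high", NA))
})

test_that("mean Weir-Cockerham Fst is ~0 without population structure", {
  set.seed(17)
  fst <- replicate(1000, {
    p <- runif(1, 0.1, 0.9)
    d <- rbinom(60, 2, p)
    compute_fst(d, rep(c("A", "B"), each = 30))$fst
  })
  fst <- fst[!is.na(fst)]
  expect_lt(abs(mean(fst)), 3 * sd(fst) / sqrt(length(fst)))
})

test_that("LD limits: perfect correlation and independence", {
  set.seed(9)
  d <- rbinom(200, 2, 0.4)
  ld <- compute_ld(d, d)
  expect_equal(ld$d_prime, 1, tolerance = 1e-9)
  expect_equal(ld$r2, 1, tolerance = 1e-9)

  a <- rbinom(5000, 2, 0.3); b <- rbinom(5000, 2, 0.6)
  ld2 <- compute_ld(a, b)
  expect_lt(ld2$r2, 0.01)
  expect_error(compute_ld(rep(0, 10), rbinom(10, 2, 0.5)),
               "monomorphic")
})

test_that("EM haplotype frequency maximises the likelihood", {
  # no double heterozygotes: phase is observable, EM must hit the
  # phased truth exactly
  da <- c(0, 2, 1, 0, 2, 1, 0, 2, 0, 1)
  db <- c(0, 2, 0, 1, 1, 2, 0, 2, 1, 0)
  stopifnot(!any(da == 1 & db == 1))
  ld <- compute_ld(da, db)
  # direct haplotype count: with at most one heterozygous locus per
  # individual the allele pairing is unambiguous
  count11 <- 0
  for (i in seq_along(da)) {
    if (da[i] == 2) count11 <- count11 + db[i]
    else if (da[i] == 1 && db[i] == 2) count11 <- count11 + 1
  }
  expect_equal(ld$p_ab, count11 / (2 * length(da)), tolerance = 1e-6)

  # with double heterozygotes: EM must agree with a grid-search
  # maximiser of the same likelihood
  set.seed(33)
  for (rep in 1:5) {
    repeat {
      a <- rbinom(20, 2, runif(1, 0.3, 0.7))
      b <- rbinom(20, 2, runif(1, 0.3, 0.7))
      if (var(a) > 0 && var(b) > 0 && any(a == 1 & b == 1)) break
    }
    ld <- compute_ld(a, b)
    expect_equal(ld$p_ab, oracle_ld_haplotype_freq(a, b),
                 tolerance = 1e-4)
  }
})

test_that("r2 never exceeds d_prime for biallelic loci", {
  set.seed(41)
  for (i in 1:30) {
    a <- rbinom(60, 2, runif(1, 0.2, 0.8))
    b <- rbinom(60, 2, runif(1, 0.2, 0.8))
    if (var(a) == 0 || var(b) == 0) next
    ld <- compute_ld(a, b)
    expect_lte(ld$r2, ld$d_prime + 1e-9)
    expect_gte(ld$d_prime, 0)
    expect_lte(ld$d_prime, 1)
  }
})

test_that("block detection recovers planted blocks and ignores weak LD", {
  # 5 mutually perfectly correlated SNPs -> one block of 5
  set.seed(55)
  d0 <- rbinom(80, 2, 0.5)
  dos <- matrix(rep(d0, 5), ncol = 5)  # identical dosages at all 5 SNPs
  gm <- genotype_matrix(
    dos, data.frame(chrom = "1", pos = 1:5 * 100, id = paste0("s", 1:5),
                    ref = "A", alt = "G"))
  blocks <- detect_blocks(gm)
  expect_length(blocks, 1)
  expect_length(blocks[[1]]$ids, 5)

  # all pairwise r2 below threshold -> empty list
  set.seed(56)
  dos2 <- sapply(1:4, function(j) rbinom(100, 2, 0.5))
  gm2 <- genotype_matrix(
    dos2, data.frame(chrom = "1", pos = 1:4 * 10, id = paste0("u", 1:4),
                     ref = "A", alt = "G"))
  expect_length(detect_blocks(gm2), 0)
})

test_that("planted two-class block is recovered among interleaved unlinked SNPs", {
  st <- generate_study(clean_panel_spec(seed = 101))
  blocks <- detect_blocks(st$genotypes)
  ids <- lapply(blocks, `[[`, "ids")
  expect_true(list(default_blocks()$H1$snp_ids) %in% ids ||
                any(vapply(ids, function(x)
                  setequal(x, default_blocks()$H1$snp_ids), logical(1))))
  expect_true(any(vapply(ids, function(x)
    setequal(x, default_blocks()$H2$snp_ids), logical(1))))
})

test_that("block detection is invariant to sample ordering", {
  st <- generate_study(clean_panel_spec(seed = 8))
  gm <- st$genotypes
  set.seed(1)
  perm <- sample(length(gm$samples))
  gm_perm <- genotype_matrix(gm$dosages[perm, ], gm$variants,
                             gm$samples[perm])
  b1 <- detect_blocks(gm)
  b2 <- detect_blocks(gm_perm)
  expect_equal(lapply(b1, `[[`, "ids"), lapply(b2, `[[`, "ids"))
})

test_that("block report is a header-carrying BED-like TSV", {
  st <- generate_study(clean_panel_spec(seed = 8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_block_report(detect_blocks(st$genotypes), path)
  lines <- readLines(path)
  expect_match(lines[1], "1-based inclusive")
  expect_match(lines[2], "chrom\tstart\tend\tn_snps\tsnp_ids")
  expect_gte(length(lines), 3)
})

test_that("Tajima components match hand counts on the printed toy sample", {
  # haplotypes AAA, AAT, GAT, GAT over 3 sites -> 0/1 coding
  hap <- rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 1), c(1, 0, 1))
  td <- tajimas_d(hap)
  expect_equal(td$s, 2)          # site 2 monomorphic
  # pairwise differences: 1,2,2,1,1,0 -> mean 7/6
  expect_equal(td$pi, 7 / 6, tolerance = 1e-12)
  orc <- oracle_tajima(hap)
  expect_equal(td$d, orc$d, tolerance = 1e-9)
})

test_that("Tajima's D signs: intermediate-frequency vs singleton excess", {
  bal <- generate_neutral_region(40, 20, "balanced_two_class")
  expect_gt(tajimas_d(bal)$d, 0)
  star <- generate_neutral_region(10, 10, "singleton_excess")
  expect_lt(tajimas_d(star)$d, 0)
})

test_that("Tajima's D is undefined (not zero) when S = 0", {
  td <- tajimas_d(matrix(0, 6, 4))
  expect_false(td$defined)
  expect_true(is.na(td$d))
})

test_that("genotype-input Tajima uses 2n sequences and frequency-based pi", {
  hap <- generate_neutral_region(20, 12, "binomial_neutral", seed = 2)
  # collapse into 10 diploids: dosage = sum of sequence pairs
  dos <- hap[seq(1, 19, 2), ] + hap[seq(2, 20, 2), ]
  td_g <- tajimas_d(dos, input = "genotype")
  td_h <- tajimas_d(hap)
  expect_equal(td_g$n, 20)
  expect_equal(td_g$pi, td_h$pi, tolerance = 1e-12)
  expect_equal(td_g$d, td_h$d, tolerance = 1e-12)
})

test_that("screen_variants tabulates per-SNP MAF and Fst", {
  st <- generate_study(clean_panel_spec(seed = 12))
  tab <- screen_variants(st$genotypes, st$subjects$ancestry)
  expect_equal(nrow(tab), nrow(st$genotypes$variants))
  expect_true(all(tab$maf >= 0 & tab$maf <= 0.5, na.rm = TRUE))
  # block tag SNPs diverge strongly between the two ancestries
  h2 <- tab[tab$id %in% default_blocks()$H2$snp_ids, ]
  expect_true(all(h2$fst > 0.25))
  expect_true(all(h2$fst_class == "high"))
})
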
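geno_from_counts <- function(n0, n1, n2) {
  m <- matrix(c(rep(0, n0), rep(1, n1), rep(2, n2)), ncol = 1)
  colnames(m) <- "rs1"
  m
}

test_that("HWE chi-squared test matches closed forms", {
  expect_equal(hwe_test(c(25, 50, 25)), 1.0)
  # counts (50, 0, 50): expected (25, 50, 25), chi2 = 25 + 50 + 25 = 100
  expect_equal(hwe_test(c(50, 0, 50)),
               stats::pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(c(50, 0, 50)), 1e-20)
  expect_equal(hwe_test(c(100, 0, 0)), 1.0)  # monomorphic convention
  expect_error(hwe_test(c(0, 0, 0)), ">= 1")
})

test_that("exact HWE test agrees with the chi-squared test for common SNPs", {
  counts <- c(360, 480, 160)
  expect_equal(hwe_test(counts, method = "exact"),
               hwe_test(counts, method = "chisq"), tolerance = 0.05)
  expect_lt(hwe_test(c(50, 0, 50), method = "exact"), 1e-10)
  expect_equal(hwe_test(c(10, 0, 0), method = "exact"), 1.0)
})

test_that("QC retains and excludes SNPs by the stated thresholds", {
  g_pass <- geno_from_counts(25, 50, 25)        # MAF 0.5, HWE p = 1
  g_hwe <- geno_from_counts(50, 0, 50)          # HWE chi2 = 100
  g_rare <- geno_from_counts(100, 0, 0)         # monomorphic, MAF 0
  g_miss <- g_pass
  g_miss[1:10] <- NA                            # call rate 0.90 <= 0.95
  # pad with clean SNPs so samples missing one call keep rate > 0.9
  pad <- matrix(rep(geno_from_counts(25, 50, 25), 10), nrow = 100)
  colnames(pad) <- paste0("pad", 1:10)
  G <- cbind(g_pass, g_hwe, g_rare, g_miss, pad)
  colnames(G)[1:4] <- c("pass", "hwe_fail", "maf_fail", "cr_fail")
  qc <- qc_filter_snps(G)
  expect_equal(qc$snps, c("pass", paste0("pad", 1:10)))
  rep <- qc$report[1:4, ]
  expect_equal(rep$status, c("pass", "fail", "fail", "fail"))
  expect_match(rep$reason[rep$snp == "hwe_fail"], "hwe")
  expect_match(rep$reason[rep$snp == "maf_fail"], "maf")
  expect_match(rep$reason[rep$snp == "cr_fail"], "call_rate")
  expect_equal(rep$maf[1], 0.5)
  expect_equal(rep$hwe_p[1], 1.0)
})

test_that("QC drops low-call-rate samples first and is idempotent", {
  set.seed(53)
  G <- matrix(rbinom(100 * 5, 2, 0.3), 100, 5,
              dimnames = list(sprintf("S%03d", 1:100), paste0("rs", 1:5)))
  G[1, 1:5] <- NA  # sample 1: call rate 0
  qc <- qc_filter_snps(G)
  expect_equal(qc$samples_dropped, "S001")
  qc2 <- qc_filter_snps(qc$genotypes)
  expect_identical(qc2$genotypes, qc$genotypes)
  expect_identical(qc2$snps, qc$snps)
  expect_error(qc_filter_snps(matrix(NA_real_, 3, 2)), "all samples")
})

test_that("replication keeps significant direction-consistent SNPs only", {
  set.seed(59)
  n <- 2000
  g_strong <- rbinom(n, 2, 0.3)
  g_null <- rbinom(n, 2, 0.3)
  g_flip <- rbinom(n, 2, 0.3)
  aam <- 15 - 0.3 * g_strong + 0.3 * g_flip + rnorm(n, 0, 1)
  G <- cbind(strong = g_strong, null = g_null, flipped = g_flip)
  panel <- tibble::tibble(
    snp = c("strong", "null", "flipped"),
    published_direction = c(-1L, -1L, -1L)  # all published as AAM-decreasing
  )
  dat <- tibble::tibble(aam = aam)
  kept <- replicate_snps(panel, dat, G)
  expect_equal(kept$snp, "strong")
  report <- attr(kept, "report")
  # the flipped SNP is significant but direction-inconsistent
  expect_lt(report$p[report$snp == "flipped"], 0.05)
  expect_false(report$replicated[report$snp == "flipped"])
  # exclusion list removes SNPs after replication
  expect_warning(
    out <- replicate_snps(panel, dat, G, exclude = "strong"),
    "no SNPs"
  )
  expect_equal(nrow(out), 0)
})

test_that("null SNPs are rejected at roughly the nominal rate", {
  set.seed(61)
  excluded <- vapply(1:300, function(i) {
    g <- rbinom(300, 2, 0.3)
    dat <- tibble::tibble(aam = rnorm(300, 15, 1.5))
    panel <- tibble::tibble(snp = "rs1", published_direction = -1L)
    out <- suppressWarnings(
      replicate_snps(panel, dat, matrix(g, dimnames = list(NULL, "rs1")))
    )
    nrow(out) == 0
  }, TRUE)
  # p < 0.05 AND matching sign keeps a null SNP w.p. alpha/2
  expect_gte(mean(excluded), 0.93)
})

test_that("GRS counts AAM-decreasing alleles with orientation flips", {
  G <- rbind(c(0, 0), c(2, 2), c(1, 2))
  colnames(G) <- c("dec", "inc")
  panel <- tibble::tibble(snp = c("dec", "inc"),
                          published_direction = c(-1L, 1L))
  grs <- build_grs(G, panel)
  # dec kept as dosage; inc flipped to 2 - dosage
  expect_equal(grs, c(0 + 2, 2 + 0, 1 + 0))
  expect_equal(build_grs(matrix(0, 3, 2, dimnames = list(NULL, c("dec", "inc"))),
                         panel[1, ]),
               rep(0, 3))
  # 14 SNPs all homozygous for the risk orientation -> ceiling 28
  G14 <- matrix(2, 2, 14, dimnames = list(NULL, paste0("rs", 1:14)))
  p14 <- tibble::tibble(snp = paste0("rs", 1:14),
                        published_direction = rep(-1L, 14))
  expect_equal(build_grs(G14, p14), c(28, 28))
  expect_error(build_grs(G, tibble::tibble(snp = "rs999",
                                           published_direction = -1L)),
               "rs999")
})

test_that("missing dosages are mean-imputed in the GRS", {
  G <- matrix(c(0, 2, NA, 2), ncol = 1, dimnames = list(NULL, "rs1"))
  panel <- tibble::tibble(snp = "rs1", published_direction = -1L)
  expect_equal(build_grs(G, panel), c(0, 2, 4 / 3, 2))
})

test_that("GRS orientation makes AAM decrease with the score", {
  cfg <- sim_config(n_individuals = 5000, seed = 67,
                    snp_effects_on_aam = seq(-0.1, -0.3, length.out = 14))
  sim <- simulate_cohort(cfg)
  grs <- build_grs(sim$genotypes, sim$panel)
  expect_lt(stats::coef(stats::lm(sim$phenotypes$aam ~ grs))[2], 0)
})

test_that("quartile coding is rank-based with ties to the lower quartile", {
  expect_equal(grs_quartiles(1:8), rep(1:4, each = 2))
  expect_error(grs_quartiles(c(1, 1, 1, 2)), "4 distinct")
  set.seed(71)
  x <- sample(0:28, 200, replace = TRUE)
  q <- grs_quartiles(x)
  expect_true(all(diff(q[order(x)]) >= 0))        # monotone in the score
  expect_equal(sort(unique(q)), 1:4)
  expect_true(all(q[x == min(x)] == 1))
  # ties share the lower quartile
  expect_true(all(tapply(q, x, function(v) length(unique(v))) == 1))
})

test_that("first-stage F matches the R-squared identity and brute force", {
  # exact R^2 = 0.5 at n = 12: F = (n - 2) R^2 / (1 - R^2) = 10
  x <- scale(1:12)[, 1]
  e <- scale(rep(c(1, -1), 6) - mean(rep(c(1, -1), 6)))[, 1]
  e <- e - x * sum(e * x) / sum(x^2)              # orthogonalize to x
  e <- e / sqrt(sum(e^2) / sum(x^2))              # equal explained/residual SS
  y <- x + e
  dat <- tibble::tibble(aam = y)
  fs <- first_stage_diagnostics(dat, grs = x)
  row <- fs[fs$coding == "per_unit", ]
  expect_equal(row$r.squared, 0.5, tolerance = 1e-10)
  expect_equal(row$F, 10, tolerance = 1e-8)
  bf <- brute_ols(y, cbind(1, x))
  expect_equal(row$estimate, unname(bf$coef[2]), tolerance = 1e-8)
})

test_that("first-stage diagnostics behave at the null and perfect extremes", {
  set.seed(73)
  grs <- rnorm(4000)
  fs_null <- first_stage_diagnostics(tibble::tibble(aam = rnorm(4000)), grs)
  expect_lt(fs_null$F[1], 6)
  expect_lt(fs_null$r.squared[1], 0.005)
  fs_perfect <- first_stage_diagnostics(tibble::tibble(aam = grs), grs)
  row <- fs_perfect[fs_perfect$coding == "per_unit", ]
  expect_equal(row$r.squared, 1)
  expect_equal(row$estimate, 1)
})

test_that("confounder balance finds self-association and independence", {
  set.seed(79)
  n <- 1500
  grs <- rnorm(n)
  dat <- tibble::tibble(copy = grs, indep = rnorm(n))
  tab <- confounder_balance(dat, grs, c("copy", "indep"))
  expect_equal(tab$estimate[tab$confounder == "copy"], 1.0, tolerance = 1e-10)
  expect_true(covers(tab[tab$confounder == "indep", ], 0) ||
                tab$p.value[tab$confounder == "indep"] > 0.001)
  expect_equal(nrow(confounder_balance(dat, grs, character())), 0)
})

test_that("confounder balance CIs cover zero at the nominal rate", {
  set.seed(83)
  hits <- vapply(1:400, function(i) {
    n <- 300
    grs <- rnorm(n)
    tab <- confounder_balance(tibble::tibble(x = rnorm(n)), grs, "x")
    covers(tab, 0)
  }, TRUE)
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})
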
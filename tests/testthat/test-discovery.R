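# Fabricate a scan_result over the markers of a sample with chosen
# significance calls.
fake_scan <- function(sample, sig, type = "univariate-1", loci = "neutral") {
  res <- data.frame(sample$map[, c("marker", "locus_id", "chr", "cM",
                                   "role", "maf")],
                    p = ifelse(sig, 1e-6, 0.9),
                    significant = sig, stringsAsFactors = FALSE)
  structure(res, class = c("scan_result", "data.frame"),
            scan_type = type, fdr = 0.1, loci = loci)
}

toy_sample <- function() {
  # 2 chromosomes, 3 markers each; QTL at 0.05 cM on each chromosome
  set.seed(71)
  hap <- random_hap(40, 6, p = rep(0.5, 6))
  phen <- cbind(rnorm(40), rnorm(40))
  ca <- cbind(sample(c("0:0", "1:1"), 80, TRUE),
              sample(c("0:0", "2:2"), 80, TRUE))
  colnames(ca) <- c("L101", "L102")
  truth <- data.frame(locus_id = c(101L, 102L), chr = 1:2,
                      cM = c(0.05, 0.05), role = "qtl_pleio",
                      pair = 1:2, segregating = TRUE)
  make_sample(hap, chr = rep(1:2, each = 3),
              cM = rep(c(0.01, 0.04, 0.11), 2),
              role = rep("neutral", 6), phen = phen,
              truth = truth, causal_alleles = ca)
}

test_that("discovery window arithmetic counts in-window hits only", {
  s <- toy_sample()
  # significant SNP at 0.04 cM from QTL1 only -> DR = 0.5
  scan <- fake_scan(s, sig = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
                    type = "multivariate")
  rep1 <- discovery_metrics(scan, s)
  expect_equal(rep1$DR, 0.5)
  expect_equal(rep1$SNPsig, 1)
  expect_equal(rep1$SNPpleio, 1)
  # SNP at 0.11 cM is 0.06 cM away: outside the 0.05 cM window
  scan2 <- fake_scan(s, sig = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                     type = "multivariate")
  expect_equal(discovery_metrics(scan2, s)$DR, 0)
  # a 0.05 cM offset is inclusive
  scan3 <- fake_scan(s, sig = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                     type = "multivariate")
  expect_equal(discovery_metrics(scan3, s)$DR, 0.5)
  # no significant markers at all
  rep0 <- discovery_metrics(fake_scan(s, rep(FALSE, 6),
                                      type = "multivariate"), s)
  expect_equal(rep0$DR, 0)
  expect_true(is.na(rep0$r2_mean))
})

test_that("univariate-pair metrics require both scans and are symmetric", {
  s <- toy_sample()
  s1 <- fake_scan(s, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  s2 <- fake_scan(s, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
                  type = "univariate-2")
  r <- discovery_metrics(list(s1, s2), s)
  expect_equal(r$DRpleio, 0.5)          # QTL1 hit in both, QTL2 in one
  expect_equal(r$DR_single, mean(c(1, 0.5)))
  expect_equal(r$SNPsig, 1.5)
  expect_equal(r$SNPpleio, 1)
  # invariant to relabeling the two traits
  r_swap <- discovery_metrics(list(s2, s1), s)
  expect_equal(r$DRpleio, r_swap$DRpleio)
  expect_equal(r$DR_single, r_swap$DR_single)
  expect_equal(r$SNPpleio, r_swap$SNPpleio)
})

test_that("discovery metrics are invariant to marker order", {
  s <- toy_sample()
  scan <- fake_scan(s, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
                    type = "multivariate")
  perm <- sample(nrow(scan))
  scan_perm <- scan[perm, ]
  attributes(scan_perm)$scan_type <- "multivariate"
  attr(scan_perm, "loci") <- "neutral"
  class(scan_perm) <- c("scan_result", "data.frame")
  a <- discovery_metrics(scan, s)
  b <- discovery_metrics(scan_perm, s)
  expect_equal(a$DR, b$DR)
  expect_equal(a$SNPsig, b$SNPsig)
})

test_that("QTN scans score spurious and missed pleiotropy", {
  set.seed(72)
  n <- 30
  hap <- random_hap(n, 4, p = rep(0.5, 4))
  phen <- cbind(rnorm(n), rnorm(n))
  ca <- apply(hap, 2, as.character)
  colnames(ca) <- sprintf("L%d", 1:4)
  truth <- data.frame(locus_id = 1:4, chr = c(1, 1, 2, 3),
                      cM = c(0.05, 0.05, 0.05, 0.05),
                      role = c("qtn_trait1", "qtn_trait2", "qtn_pleio",
                               "qtn_pleio"),
                      pair = c(1L, 1L, 2L, 3L),
                      segregating = TRUE)
  s <- make_sample(hap, chr = c(1, 1, 2, 3), cM = rep(0.05, 4),
                   role = truth$role, phen = phen, truth = truth,
                   causal_alleles = ca)
  # trait-1 scan: QTN 1, 2, 3 significant; trait-2 scan: QTN 2, 3
  q1 <- fake_scan(s, c(TRUE, TRUE, TRUE, FALSE), loci = "qtn")
  q2 <- fake_scan(s, c(FALSE, TRUE, TRUE, FALSE), type = "univariate-2",
                  loci = "qtn")
  r <- discovery_metrics(list(q1, q2), s)
  expect_equal(r$type, "qtn")
  expect_equal(r$FPR, 0.5)     # QTN2 of 2 nonpleiotropic hits both traits
  expect_equal(r$FNR, 0.5)     # QTN4 of 2 pleiotropic missed
  expect_equal(r$N_sign, 3)
  expect_equal(r$N_pleio, 2)
  expect_equal(r$N_segr, 4)
  # no significant markers: FPR 0, FNR 1
  r0 <- discovery_metrics(list(fake_scan(s, rep(FALSE, 4), loci = "qtn"),
                               fake_scan(s, rep(FALSE, 4),
                                         type = "univariate-2",
                                         loci = "qtn")), s)
  expect_equal(r0$FPR, 0)
  expect_equal(r0$FNR, 1)
})
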
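#' Truth-based discovery metrics for association scans
#'
#' Scores a scan (or a pair of univariate scans) against the simulator's
#' truth table of causal loci. A segregating causal locus counts as
#' discovered when at least one significant marker lies on the same
#' chromosome within `window_cM` on each side of the locus.
#'
#' For a single multivariate scan the report contains `DR` (fraction of
#' segregating QTL discovered), `SNPsig` (= `SNPpleio`: the joint test
#' associates a significant SNP with both traits), and the mean
#' multiallelic LD r-squared between each significant SNP and its nearest
#' segregating QTL.
#'
#' For a pair of univariate scans on neutral markers: `DRpleio` (fraction
#' of segregating QTL discovered in BOTH scans), `DR_single` (mean
#' per-scan discovery fraction), `SNPsig` (significant-marker count
#' averaged over the two scans), `SNPpleio` (markers significant in both)
#' and the mean r-squared of significant markers with their nearest
#' segregating QTL.
#'
#' For QTN scans (markers are the causal loci themselves, from
#' [qtn_scan()]): `FPR` is the fraction of segregating nonpleiotropic
#' QTNs whose own genotype is significant for BOTH traits (spurious
#' pleiotropy), `FNR` the fraction of segregating pleiotropic QTNs NOT
#' significant for both traits, `N_sign` QTNs significant for at least
#' one trait, `N_pleio` significant for both, `N_segr` segregating QTNs,
#' and (linkage architectures) the mean within-pair r-squared over pairs
#' bearing at least one significant QTN.
#'
#' @param scans A `scan_result` (multivariate) or a list of two
#'   univariate `scan_result`s.
#' @param sample The `genotype_sample` the scans were run on.
#' @param window_cM Discovery window on each side of a causal locus
#'   (default 0.05 cM); the window is inclusive (`<= window_cM`).
#' @param qtl_match How a significant SNP is paired with a QTL for the LD
#'   statistic: nearest segregating QTL in cM (`"nearest"`, default) or
#'   the segregating QTL with maximal r-squared (`"max_ld"`).
#' @return Object of class `discovery_report` (a named list).
#' @export
discovery_metrics <- function(scans, sample, window_cM = 0.05,
                              qtl_match = c("nearest", "max_ld")) {
  qtl_match <- match.arg(qtl_match)
  stopifnot(inherits(sample, "genotype_sample"))
  truth <- sample$truth
  if (nrow(truth) == 0) stop("empty truth table")
  seg <- truth[truth$segregating, , drop = FALSE]

  single <- inherits(scans, "scan_result")
  if (single) {
    qtn_mode <- attr(scans, "loci") == "qtn"
  } else {
    stopifnot(length(scans) == 2,
              all(vapply(scans, inherits, logical(1), "scan_result")))
    qtn_mode <- attr(scans[[1]], "loci") == "qtn"
  }

  discovered <- function(scan) {
    sig <- scan[scan$significant, , drop = FALSE]
    vapply(seq_len(nrow(seg)), function(i) {
      any(sig$chr == seg$chr[i] & abs(sig$cM - seg$cM[i]) <= window_cM)
    }, logical(1))
  }
  mean_r2 <- function(sig_markers) {
    if (nrow(sig_markers) == 0 || nrow(seg) == 0) return(NA_real_)
    r2s <- vapply(seq_len(nrow(sig_markers)), function(i) {
      on_chr <- which(seg$chr == sig_markers$chr[i])
      if (length(on_chr) == 0) return(NA_real_)
      hcol <- match(sig_markers$marker[i], sample$map$marker)
      snp_hap <- sample$hap[, hcol]
      ccols <- match(sprintf("L%d", seg$locus_id[on_chr]),
                     colnames(sample$causal_alleles))
      if (qtl_match == "nearest") {
        j <- on_chr[which.min(abs(seg$cM[on_chr] - sig_markers$cM[i]))]
        cc <- match(sprintf("L%d", seg$locus_id[j]),
                    colnames(sample$causal_alleles))
        as.numeric(multiallelic_r2(snp_hap, sample$causal_alleles[, cc]))
      } else {
        max(vapply(ccols, function(cc)
          as.numeric(multiallelic_r2(snp_hap,
                                     sample$causal_alleles[, cc])),
          numeric(1)))
      }
    }, numeric(1))
    if (all(is.na(r2s))) NA_real_ else mean(r2s, na.rm = TRUE)
  }

  if (qtn_mode) {
    s1 <- scans[[1]]; s2 <- scans[[2]]
    sig1 <- setNames(s1$significant, s1$locus_id)
    sig2 <- setNames(s2$significant, s2$locus_id)
    seg_m <- as.character(seg$locus_id)
    both <- sig1[seg_m] & sig2[seg_m]
    either <- sig1[seg_m] | sig2[seg_m]
    pleio <- seg$role == "qtn_pleio"
    npleio <- seg$role %in% c("qtn_trait1", "qtn_trait2")
    fpr <- if (any(npleio)) mean(both[npleio]) else NA_real_
    fnr <- if (any(pleio)) mean(!both[pleio]) else NA_real_
    # within-pair LD over nonpleiotropic pairs bearing >= 1 significant QTN
    r2_pairs <- NA_real_
    if (any(npleio)) {
      sig_pairs <- unique(seg$pair[npleio & either])
      r2s <- vapply(sig_pairs, function(pr) {
        members <- truth$locus_id[!is.na(truth$pair) & truth$pair == pr]
        if (length(members) != 2) return(NA_real_)
        cc <- match(sprintf("L%d", members),
                    colnames(sample$causal_alleles))
        as.numeric(multiallelic_r2(sample$causal_alleles[, cc[1]],
                                   sample$causal_alleles[, cc[2]]))
      }, numeric(1))
      if (length(r2s)) r2_pairs <- mean(r2s, na.rm = TRUE)
    }
    report <- list(type = "qtn",
                FPR = fpr, FNR = fnr,
                N_sign = sum(either, na.rm = TRUE),
                N_pleio = sum(both, na.rm = TRUE),
                N_segr = nrow(seg),
                r2_within_pair = r2_pairs,
                window_cM = window_cM)
  } else if (single) {
    disc <- discovered(scans)
    sig <- scans[scans$significant, , drop = FALSE]
    report <- list(type = "multivariate",
                DR = if (nrow(seg)) mean(disc) else NA_real_,
                SNPsig = nrow(sig), SNPpleio = nrow(sig),
                r2_mean = mean_r2(sig),
                n_qtl_segregating = nrow(seg),
                window_cM = window_cM)
  } else {
    d1 <- discovered(scans[[1]]); d2 <- discovered(scans[[2]])
    sig1 <- scans[[1]][scans[[1]]$significant, , drop = FALSE]
    sig2 <- scans[[2]][scans[[2]]$significant, , drop = FALSE]
    both_markers <- intersect(sig1$marker, sig2$marker)
    sig_union <- rbind(sig1[, c("marker", "chr", "cM")],
                       sig2[!sig2$marker %in% sig1$marker,
                            c("marker", "chr", "cM")])
    report <- list(type = "univariate-pair",
                DRpleio = if (nrow(seg)) mean(d1 & d2) else NA_real_,
                DR_single = if (nrow(seg)) mean(c(mean(d1), mean(d2)))
                            else NA_real_,
                SNPsig = mean(c(nrow(sig1), nrow(sig2))),
                SNPpleio = length(both_markers),
                r2_mean = mean_r2(sig_union),
                n_qtl_segregating = nrow(seg),
                window_cM = window_cM)
  }
  structure(report, class = "discovery_report")
}

#' @export
print.discovery_report <- function(x, ...) {
  cat(sprintf("<discovery_report> (%s scan)\n", x$type))
  for (nm in setdiff(names(x), "type"))
    cat(sprintf("  %-18s %s\n", nm,
                paste(format(x[[nm]], digits = 4), collapse = " ")))
  invisible(x)
}
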
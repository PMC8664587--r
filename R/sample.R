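#' Extract an association-mapping sample from a simulation
#'
#' Builds the genotype/phenotype data set consumed by the GWA stage:
#' phased haplotype states and minor-allele dosage for every biallelic
#' locus (neutral markers and, in QTN mode, the causal QTN), the marker
#' map, the phenotypes, and the truth table of causal loci with their
#' segregating status in the sample. Continuum-of-alleles QTL are not
#' representable as SNPs and are excluded from the genotype matrix but
#' retained in the truth table (and in `causal_alleles`, for LD with
#' significant markers).
#'
#' @param x A `wf_simulation` (uses its final population and stored sample
#'   indices) or a `wf_population`.
#' @param sample_idx Individuals to include (defaults to the simulation's
#'   stored sample, or all individuals for a bare population).
#' @return Object of class `genotype_sample`: `X` (`n x M` minor-allele
#'   dosage), `hap` (`2n x M` phased 0/1 states), `map` (marker id, chr,
#'   cM, role, maf, minor allele), `phen` (`n x 2`), `truth` (causal loci:
#'   id, chr, cM, role, pair, segregating), `causal_alleles` (`2n` x
#'   number-of-causal-loci allele identities for multiallelic LD), `n`.
#' @export
as_genotype_sample <- function(x, sample_idx = NULL) {
  if (inherits(x, "wf_simulation")) {
    if (is.null(sample_idx)) sample_idx <- x$sample_idx
    pop <- x$population
  } else {
    stopifnot(inherits(x, "wf_population"))
    pop <- x
    if (is.null(sample_idx)) sample_idx <- seq_len(ncol(pop$v1) / 2)
  }
  arch <- pop$arch
  loci <- arch$loci
  n <- length(sample_idx)
  hap_cols <- as.vector(rbind(2 * sample_idx - 1, 2 * sample_idx))

  biallelic <- which(loci$role %in%
                       c("neutral", "qtn_trait1", "qtn_trait2", "qtn_pleio"))
  # phased 0/1 allele states (2n x M): neutral = marker state,
  # QTN = sign of the allelic effect (positive allele coded 1)
  hap <- matrix(0L, 2 * n, length(biallelic))
  for (j in seq_along(biallelic)) {
    l <- biallelic[j]
    hap[, j] <- if (loci$role[l] == "neutral") {
      as.integer(pop$v1[l, hap_cols])
    } else if (loci$role[l] == "qtn_trait2") {
      as.integer(pop$v2[l, hap_cols] > 0)
    } else {
      as.integer(pop$v1[l, hap_cols] > 0)
    }
  }
  p1 <- colMeans(hap)
  minor <- ifelse(p1 <= 0.5, 1L, 0L)  # MAF ties go to allele "1"
  maf <- pmin(p1, 1 - p1)
  odd <- seq(1, 2 * n, by = 2)
  cnt1 <- hap[odd, , drop = FALSE] + hap[odd + 1, , drop = FALSE]
  X <- sweep(cnt1, 2, minor == 0L, function(a, flip) ifelse(flip, 2 - a, a))
  colnames(X) <- sprintf("L%d", loci$id[biallelic])

  map <- data.frame(marker = colnames(X),
                    locus_id = loci$id[biallelic],
                    chr = loci$chr[biallelic],
                    cM = loci$pos_cM[biallelic],
                    role = loci$role[biallelic],
                    maf = maf, minor_allele = minor,
                    stringsAsFactors = FALSE)

  causal <- which(loci$role != "neutral")
  causal_alleles <- matrix("", 2 * n, length(causal))
  for (j in seq_along(causal)) {
    l <- causal[j]
    causal_alleles[, j] <- paste(pop$v1[l, hap_cols], pop$v2[l, hap_cols],
                                 sep = ":")
  }
  colnames(causal_alleles) <- sprintf("L%d", loci$id[causal])
  seg <- vapply(seq_along(causal), function(j)
    length(unique(causal_alleles[, j])) > 1, logical(1))
  truth <- data.frame(locus_id = loci$id[causal],
                      chr = loci$chr[causal],
                      cM = loci$pos_cM[causal],
                      role = loci$role[causal],
                      pair = loci$pair[causal],
                      segregating = seg, stringsAsFactors = FALSE)

  structure(list(X = X, hap = hap, map = map,
                 phen = pop$phen[sample_idx, , drop = FALSE],
                 truth = truth, causal_alleles = causal_alleles,
                 arch = arch, n = n),
            class = "genotype_sample")
}

#' @export
print.genotype_sample <- function(x, ...) {
  cat(sprintf("<genotype_sample> n=%d individuals, %d biallelic markers (%d polymorphic), %d causal loci (%d segregating)\n",
              x$n, ncol(x$X), sum(x$map$maf > 0), nrow(x$truth),
              sum(x$truth$segregating)))
  invisible(x)
}

#' Export a genotype sample as PLINK .bed/.bim/.fam plus phenotype TSV
#'
#' Writes a PLINK 1.9 binary fileset: SNP-major `.bed` (magic bytes
#' 0x6c 0x1b 0x01; per SNP two bits per individual: 00 = two copies of the
#' A1/minor allele, 10 = heterozygote, 11 = zero copies), a `.bim` with
#' chromosome, marker id, cM position, dummy bp = round(cM * 1e4) and
#' allele labels (A1 = minor), a `.fam` with FID = IID = sample index, and
#' `<prefix>.phen` (FID, IID, trait1, trait2). Only biallelic markers are
#' written; continuum-of-alleles QTL are rejected with guidance (they are
#' exported separately via [write_qtl_values()]).
#'
#' @param sample A [as_genotype_sample()] result.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
export_plink <- function(sample, prefix) {
  stopifnot(inherits(sample, "genotype_sample"))
  X <- sample$X
  if (ncol(X) == 0)
    stop("no biallelic markers to export; continuum-of-alleles QTL cannot ",
         "be represented in PLINK (use write_qtl_values() for them)")
  n <- nrow(X); M <- ncol(X)
  # .bed, SNP-major: codes per 2 bits, individuals packed 4 per byte LSB first
  code <- matrix(0L, nrow = 4 * ceiling(n / 4), ncol = M)  # zero padding bits
  code[seq_len(n), ] <- matrix(c(3L, 2L, 0L)[X + 1L], n, M)  # 0->11, 1->10, 2->00
  i4 <- seq(1, nrow(code), by = 4)
  bytes <- code[i4, , drop = FALSE] + 4L * code[i4 + 1, , drop = FALSE] +
    16L * code[i4 + 2, , drop = FALSE] + 64L * code[i4 + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)

  map <- sample$map
  bim <- data.frame(chr = map$chr, id = map$marker, cM = map$cM,
                    bp = as.integer(round(map$cM * 1e4)),
                    a1 = as.character(map$minor_allele),
                    a2 = as.character(1L - map$minor_allele))
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = seq_len(n), iid = seq_len(n), pat = 0, mat = 0,
                    sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  phen <- data.frame(FID = seq_len(n), IID = seq_len(n),
                     trait1 = sample$phen[, 1], trait2 = sample$phen[, 2])
  write.table(phen, paste0(prefix, ".phen"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK 1.9 binary fileset
#'
#' Reads an SNP-major `.bed`/`.bim`/`.fam` triplet back into an A1-allele
#' dosage matrix. Missing genotypes (code 01) become `NA`.
#'
#' @param prefix Path prefix of the fileset.
#' @return List with `X` (`n x M` dosage of allele A1), `bim`, `fam`.
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), sep = "\t",
                    col.names = c("chr", "id", "cM", "bp", "a1", "a2"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"), sep = "\t",
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); M <- nrow(bim)
  bpS <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + bpS * M)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b || raw[3] != 0x01)
    stop("not an SNP-major PLINK 1.9 .bed file")
  body <- as.integer(raw[-(1:3)])
  codes <- matrix(0L, 4 * bpS, M)
  b <- matrix(body, bpS, M)
  codes[seq(1, 4 * bpS, 4), ] <- b %% 4L
  codes[seq(2, 4 * bpS, 4), ] <- (b %/% 4L) %% 4L
  codes[seq(3, 4 * bpS, 4), ] <- (b %/% 16L) %% 4L
  codes[seq(4, 4 * bpS, 4), ] <- (b %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  X <- matrix(NA_integer_, n, M)
  X[codes == 0L] <- 2L
  X[codes == 2L] <- 1L
  X[codes == 3L] <- 0L
  colnames(X) <- bim$id
  list(X = X, bim = bim, fam = fam)
}

#' Write continuum-of-alleles QTL values as TSV
#'
#' Continuum QTL cannot be represented in PLINK; their per-haplotype
#' allelic values are written as a long-format TSV (locus id, haplotype
#' index, effect on trait 1, effect on trait 2).
#'
#' @param sample A `genotype_sample`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qtl_values <- function(sample, path) {
  stopifnot(inherits(sample, "genotype_sample"))
  qtl <- which(sample$truth$role %in% c("qtl_trait1", "qtl_trait2",
                                        "qtl_pleio"))
  if (length(qtl) == 0) {
    writeLines("locus_id\thaplotype\teffect1\teffect2", path)
    return(invisible(path))
  }
  parts <- do.call(rbind, strsplit(
    as.vector(sample$causal_alleles[, qtl, drop = FALSE]), ":", fixed = TRUE))
  out <- data.frame(
    locus_id = rep(sample$truth$locus_id[qtl], each = 2 * sample$n),
    haplotype = rep(seq_len(2 * sample$n), length(qtl)),
    effect1 = as.numeric(parts[, 1]), effect2 = as.numeric(parts[, 2]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the truth table of causal loci as TSV
#'
#' @param sample A `genotype_sample`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sample, path) {
  stopifnot(inherits(sample, "genotype_sample"))
  write.table(sample$truth, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
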
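#' Map distance to recombination fraction (Haldane)
#'
#' Converts a map distance in centiMorgans to a recombination fraction using
#' Haldane's map function (crossovers form a Poisson process along the map,
#' no interference): `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Nonnegative map distance(s) in centiMorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`; `0` at `d_cM = 0`,
#'   approaching `1/2` for unlinked loci. In the small-distance limit
#'   `r ~ d_cM / 100`, so e.g. 0.0001 cM gives `r = 1e-6`.
#' @examples
#' recombination_fraction(c(0, 0.0001, 50))
#' @export
recombination_fraction <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distances must be nonnegative")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Specification of a neutral marker panel around each causal locus
#'
#' Describes the diallelic neutral marker loci placed on each chromosome
#' around its causal locus (or fully linked causal pair) for association
#' mapping. Markers are equidistant: chromosome map length `L` cM with `n`
#' markers gives an inter-marker spacing of `L/n` cM (markers sit at the
#' centers of `n` equal bins) and the causal position at the chromosome
#' center. The defaults (1000 markers on 0.1 cM) give a recombination
#' fraction of 1e-6 between adjacent markers.
#'
#' @param n_neutral_per_chromosome Number of neutral markers per chromosome.
#' @param chromosome_length_cM Map length of each chromosome (cM).
#' @param neutral_mu Per-allele mutation rate of the neutral markers
#'   (reversible 0/1 flips).
#' @return An object of class `neutral_panel_spec`.
#' @export
neutral_panel_spec <- function(n_neutral_per_chromosome = 1000,
                               chromosome_length_cM = 0.1,
                               neutral_mu = 1e-6) {
  stopifnot(n_neutral_per_chromosome >= 1, chromosome_length_cM > 0,
            neutral_mu >= 0, neutral_mu <= 1)
  structure(
    list(n_neutral_per_chromosome = as.integer(n_neutral_per_chromosome),
         chromosome_length_cM = chromosome_length_cM,
         adjacent_recomb = recombination_fraction(
           chromosome_length_cM / n_neutral_per_chromosome),
         neutral_mu = neutral_mu),
    class = "neutral_panel_spec")
}

.role_levels <- c("qtl_trait1", "qtl_trait2", "qtl_pleio",
                  "qtn_trait1", "qtn_trait2", "qtn_pleio", "neutral")

# integer codes used by the C++ engine
.role_code <- c(qtl_trait1 = 1L, qtl_trait2 = 2L, qtl_pleio = 3L,
                qtn_trait1 = 4L, qtn_trait2 = 5L, qtn_pleio = 6L,
                neutral = 0L)

#' Build a two-trait genetic architecture
#'
#' Lays out the causal loci of two additive polygenic traits on a genetic
#' map. Two architecture kinds are supported: `"pleiotropy"` (each causal
#' locus affects both traits) and `"linkage"` (pairs of nonpleiotropic loci,
#' one member affecting trait 1 and one affecting trait 2, separated by
#' `within_pair_cM`). By default each pair (or pleiotropic locus) sits on
#' its own chromosome, so pairs recombine freely with each other; when
#' `between_pair_cM` is given, all pairs are placed on a single chromosome
#' at that spacing. An optional neutral marker panel surrounds each causal
#' position symmetrically for association mapping.
#'
#' @param kind `"pleiotropy"` or `"linkage"`.
#' @param n_loci_per_trait Number of causal loci affecting each trait
#'   (default 120; the linkage kind then has `2 * n_loci_per_trait` loci).
#' @param within_pair_cM Map distance between the two members of a
#'   nonpleiotropic pair (cM). Must be 0 for the pleiotropy kind.
#' @param between_pair_cM Optional spacing between consecutive pairs (or
#'   pleiotropic loci) on a single shared chromosome; `NULL` (default)
#'   places each pair on its own chromosome (free recombination between
#'   pairs).
#' @param neutral_panel Optional [neutral_panel_spec()] adding equidistant
#'   diallelic neutral markers to each chromosome with the causal position
#'   at the chromosome center. Incompatible with `between_pair_cM`.
#' @param qtn If `TRUE`, causal loci are biallelic quantitative trait
#'   nucleotides (sign-flip mutation) instead of continuum-of-alleles QTL.
#' @return An object of class `architecture_spec`: a list with a `loci`
#'   data frame (`id`, `chr`, `pos_cM`, `role`, `trait1`, `trait2`),
#'   chromosome lengths, and the build parameters. Locus ids are
#'   consecutive integers in genome order and index genotype-matrix
#'   columns everywhere downstream.
#' @examples
#' arch <- build_architecture("linkage", 120, within_pair_cM = 0)
#' nrow(arch$loci)  # 240 QTL on 120 chromosomes
#' @export
build_architecture <- function(kind = c("pleiotropy", "linkage"),
                               n_loci_per_trait = 120,
                               within_pair_cM = 0,
                               between_pair_cM = NULL,
                               neutral_panel = NULL,
                               qtn = FALSE) {
  kind <- match.arg(kind)
  if (n_loci_per_trait < 1) stop("n_loci_per_trait must be >= 1")
  if (within_pair_cM < 0) stop("map distances must be nonnegative")
  if (!is.null(between_pair_cM) && between_pair_cM < 0)
    stop("map distances must be nonnegative")
  if (kind == "pleiotropy" && within_pair_cM > 0)
    stop("a pleiotropic locus has no within-pair distance; within_pair_cM must be 0")
  if (!is.null(between_pair_cM) && !is.null(neutral_panel))
    stop("between_pair_cM and neutral_panel cannot be combined")
  n <- as.integer(n_loci_per_trait)

  causal_roles <- if (kind == "pleiotropy") {
    if (qtn) "qtn_pleio" else "qtl_pleio"
  } else {
    if (qtn) c("qtn_trait1", "qtn_trait2") else c("qtl_trait1", "qtl_trait2")
  }

  if (!is.null(neutral_panel)) {
    stopifnot(inherits(neutral_panel, "neutral_panel_spec"))
    len <- neutral_panel$chromosome_length_cM
    nn <- neutral_panel$n_neutral_per_chromosome
    marker_pos <- (seq_len(nn) - 0.5) * (len / nn)
    centre <- len / 2
    causal_pos <- if (kind == "pleiotropy") centre else
      c(centre - within_pair_cM / 2, centre + within_pair_cM / 2)
    if (any(causal_pos < 0) || any(causal_pos > len))
      stop("within_pair_cM exceeds the neutral-panel chromosome length")
    per_chr <- data.frame(
      pos_cM = c(marker_pos, causal_pos),
      role = c(rep("neutral", nn), causal_roles),
      stringsAsFactors = FALSE)
    per_chr <- per_chr[order(per_chr$pos_cM, per_chr$role != "neutral"), ]
    loci <- do.call(rbind, lapply(seq_len(n), function(c_i) {
      cbind(chr = c_i, per_chr)
    }))
    chrom_len <- rep(len, n)
    n_chr <- n
  } else if (!is.null(between_pair_cM)) {
    starts <- (seq_len(n) - 1) * between_pair_cM
    if (kind == "pleiotropy") {
      loci <- data.frame(chr = 1L, pos_cM = starts,
                         role = causal_roles, stringsAsFactors = FALSE)
    } else {
      loci <- data.frame(
        chr = 1L,
        pos_cM = as.vector(rbind(starts, starts + within_pair_cM)),
        role = rep(causal_roles, n), stringsAsFactors = FALSE)
    }
    loci <- loci[order(loci$pos_cM), ]
    chrom_len <- max(loci$pos_cM)
    n_chr <- 1L
  } else {
    if (kind == "pleiotropy") {
      loci <- data.frame(chr = seq_len(n), pos_cM = 0,
                         role = causal_roles, stringsAsFactors = FALSE)
      chrom_len <- rep(0, n)
    } else {
      loci <- data.frame(
        chr = rep(seq_len(n), each = 2),
        pos_cM = rep(c(0, within_pair_cM), n),
        role = rep(causal_roles, n), stringsAsFactors = FALSE)
      chrom_len <- rep(within_pair_cM, n)
    }
    n_chr <- n
  }

  rownames(loci) <- NULL
  loci$trait1 <- loci$role %in% c("qtl_trait1", "qtl_pleio",
                                  "qtn_trait1", "qtn_pleio")
  loci$trait2 <- loci$role %in% c("qtl_trait2", "qtl_pleio",
                                  "qtn_trait2", "qtn_pleio")
  loci <- loci[order(loci$chr, loci$pos_cM,
                     loci$role != "neutral"), , drop = FALSE]
  loci <- data.frame(id = seq_len(nrow(loci)), loci, row.names = NULL)
  # pair index of causal loci in genome order (linkage: trait-1 member
  # first, then its trait-2 partner; pleiotropy: one locus per "pair")
  causal_rows <- which(loci$role != "neutral")
  loci$pair <- NA_integer_
  loci$pair[causal_rows] <- if (kind == "linkage")
    as.integer(ceiling(seq_along(causal_rows) / 2)) else
    seq_along(causal_rows)

  structure(
    list(loci = loci,
         n_chromosomes = as.integer(n_chr),
         chromosome_lengths_cM = chrom_len,
         within_pair_cM = within_pair_cM,
         between_pair_cM = between_pair_cM,
         architecture_kind = kind,
         n_loci_per_trait = n,
         qtn = qtn,
         neutral_panel = neutral_panel),
    class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> kind=%s, %d loci per trait, %d loci on %d chromosome(s)\n",
              x$architecture_kind, x$n_loci_per_trait, nrow(x$loci),
              x$n_chromosomes))
  cat(sprintf("  within-pair %.4g cM; between-pair %s; %s causal loci; %d neutral markers\n",
              x$within_pair_cM,
              if (is.null(x$between_pair_cM)) "free recombination"
              else sprintf("%.4g cM", x$between_pair_cM),
              if (x$qtn) "biallelic QTN" else "continuum-of-alleles QTL",
              sum(x$loci$role == "neutral")))
  invisible(x)
}

# Per-locus integer role codes, chromosome bounds and lengths for the engine.
.arch_engine_layout <- function(arch) {
  loci <- arch$loci
  role <- .role_code[loci$role]
  chr_ids <- sort(unique(loci$chr))
  chr_start <- vapply(chr_ids, function(c) min(which(loci$chr == c)) - 1L,
                      integer(1))
  chr_end <- vapply(chr_ids, function(c) max(which(loci$chr == c)),
                    integer(1))
  list(role = unname(role), pos = loci$pos_cM,
       chr_start = chr_start, chr_end = chr_end,
       chr_len = as.numeric(arch$chromosome_lengths_cM))
}

#' Recombination fractions between adjacent loci
#'
#' Haldane recombination fraction between each locus and the previous locus
#' in genome order; 0.5 at the start of each chromosome (free assortment
#' between chromosomes).
#'
#' @param arch An [build_architecture()] result.
#' @return Numeric vector of length `nrow(arch$loci)`; the first entry of
#'   each chromosome is 0.5.
#' @export
adjacent_recombination <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  loci <- arch$loci
  d <- c(Inf, diff(loci$pos_cM))
  d[c(TRUE, diff(loci$chr) != 0)] <- Inf
  ifelse(is.infinite(d), 0.5, recombination_fraction(d))
}

#' Export an architecture as PLINK .bim-compatible rows
#'
#' @param arch An `architecture_spec`.
#' @return Data frame with columns `chr`, `id`, `cM`, `bp` (dummy base-pair
#'   position `round(cM * 1e4)`), `a1`, `a2`.
#' @export
architecture_bim <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  loci <- arch$loci
  data.frame(chr = loci$chr,
             id = sprintf("L%d_%s", loci$id, loci$role),
             cM = loci$pos_cM,
             bp = as.integer(round(loci$pos_cM * 1e4)),
             a1 = "1", a2 = "0", stringsAsFactors = FALSE)
}

#' Write / read an architecture as a structured text config
#'
#' The file is a tab-separated locus table prefixed with `#key=value`
#' header lines carrying the build parameters, so an architecture
#' round-trips losslessly.
#'
#' @param arch An `architecture_spec`.
#' @param path File path.
#' @return `write_architecture` returns `path` invisibly;
#'   `read_architecture` returns an `architecture_spec`.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "architecture_spec"))
  hdr <- c(
    sprintf("#kind=%s", arch$architecture_kind),
    sprintf("#n_loci_per_trait=%d", arch$n_loci_per_trait),
    sprintf("#within_pair_cM=%.17g", arch$within_pair_cM),
    sprintf("#between_pair_cM=%s",
            if (is.null(arch$between_pair_cM)) "NA"
            else sprintf("%.17g", arch$between_pair_cM)),
    sprintf("#qtn=%s", arch$qtn),
    sprintf("#neutral_n=%s",
            if (is.null(arch$neutral_panel)) "NA"
            else arch$neutral_panel$n_neutral_per_chromosome),
    sprintf("#neutral_len=%s",
            if (is.null(arch$neutral_panel)) "NA"
            else sprintf("%.17g", arch$neutral_panel$chromosome_length_cM)),
    sprintf("#neutral_mu=%s",
            if (is.null(arch$neutral_panel)) "NA"
            else sprintf("%.17g", arch$neutral_panel$neutral_mu)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(arch$loci, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "=", fixed = TRUE))
  vals <- setNames(kv[, 2], kv[, 1])
  np <- if (vals["neutral_n"] == "NA") NULL else
    neutral_panel_spec(as.integer(vals["neutral_n"]),
                       as.numeric(vals["neutral_len"]),
                       as.numeric(vals["neutral_mu"]))
  build_architecture(
    kind = vals[["kind"]],
    n_loci_per_trait = as.integer(vals[["n_loci_per_trait"]]),
    within_pair_cM = as.numeric(vals[["within_pair_cM"]]),
    between_pair_cM = if (vals[["between_pair_cM"]] == "NA") NULL
                      else as.numeric(vals[["between_pair_cM"]]),
    neutral_panel = np,
    qtn = as.logical(vals[["qtn"]]))
}
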
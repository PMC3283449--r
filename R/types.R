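#' SNP locus table
#'
#' Builds and validates the ordered table of biallelic SNP loci that a
#' genotype matrix, haplotype or frequency table is defined over.
#'
#' @param id Character vector of marker identifiers (e.g. rsIDs).
#' @param chrom Chromosome labels.
#' @param pos 1-based positions (integer, >= 1).
#' @param ref,alt Reference and alternate bases; must differ per locus
#'   (biallelic markers only).
#'
#' @return A `data.frame` with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
snp_loci <- function(id, chrom, pos, ref, alt) {
  n <- length(id)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(ref) == 1L) ref <- rep(ref, n)
  if (length(alt) == 1L) alt <- rep(alt, n)
  stopifnot(length(chrom) == n, length(pos) == n,
            length(ref) == n, length(alt) == n)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (any(ref == alt)) stop("ref and alt alleles must differ (biallelic loci only)")
  if (anyDuplicated(id)) stop("duplicate locus ids")
  data.frame(id = as.character(id), chrom = as.character(chrom),
             pos = pos, ref = as.character(ref), alt = as.character(alt),
             stringsAsFactors = FALSE)
}

#' Unphased genotype matrix
#'
#' Wraps a subjects x loci matrix of genotype codes: 0 = homozygous
#' reference, 1 = heterozygous, 2 = homozygous alternate, `NA` = missing.
#'
#' @param codes Integer matrix (or coercible), subjects in rows, loci in
#'   columns. Row names are sample identifiers.
#' @param loci A locus table from [snp_loci()] with one row per column.
#'
#' @return An integer matrix of class `geno_matrix` with the locus table
#'   attached as attribute `"loci"`.
#' @export
geno_matrix <- function(codes, loci) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (ncol(codes) != nrow(loci))
    stop("number of genotype columns (", ncol(codes),
         ") does not match locus table (", nrow(loci), " loci)")
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(codes)) && nrow(codes) > 0)
    rownames(codes) <- paste0("S", seq_len(nrow(codes)))
  colnames(codes) <- loci$id
  structure(codes, loci = loci, class = c("geno_matrix", class(codes)))
}

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  loci <- attr(x, "loci")
  m <- unclass(x)
  sub <- if (missing(i) && missing(j)) m
         else if (missing(i)) m[, j, drop = FALSE]
         else if (missing(j)) m[i, , drop = FALSE]
         else m[i, j, drop = FALSE]
  lo <- loci[match(colnames(sub), loci$id), , drop = FALSE]
  rownames(lo) <- NULL
  geno_matrix(sub, lo)
}

#' @export
print.geno_matrix <- function(x, ...) {
  loci <- attr(x, "loci")
  cat("geno_matrix:", nrow(x), "subjects x", ncol(x), "biallelic loci\n")
  cat("missing rate:", signif(mean(is.na(x)), 3), "\n")
  invisible(x)
}

geno_loci <- function(G) {
  loci <- attr(G, "loci")
  if (is.null(loci)) stop("genotype matrix carries no locus table")
  loci
}

#' Haplotype (or gene-SNP haplotype) frequency table
#'
#' A normalized map from haplotype keys to population frequencies. Plain
#' haplotypes are encoded as strings of "0"/"1" allele codes over an ordered
#' locus list; joint gene-SNP haplotypes additionally carry a gene-allele
#' label, so that each entry represents one (gene allele, flanking SNP
#' haplotype) combination.
#'
#' @param hap Character vector of haplotype code strings (e.g. `"0101"`).
#' @param freq Numeric frequencies, non-negative and summing to 1 within
#'   `1e-9`.
#' @param loci Locus table the haplotype strings span (one character per
#'   row), or `NULL` for label-only tables.
#' @param allele Optional character vector of gene-allele labels, making
#'   this a joint gene-SNP table keyed by (allele, haplotype).
#'
#' @return An object of class `freq_table`: a data.frame with columns
#'   `hap`, `freq` and optionally `allele`, with the locus table attached.
#' @export
freq_table <- function(hap, freq, loci = NULL, allele = NULL) {
  hap <- as.character(hap)
  freq <- as.numeric(freq)
  stopifnot(length(hap) == length(freq))
  if (any(freq < 0)) stop("frequencies must be non-negative")
  if (length(freq) && abs(sum(freq) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", format(sum(freq)), ")")
  key <- if (is.null(allele)) hap else paste(allele, hap, sep = "|")
  if (anyDuplicated(key)) stop("duplicate haplotype keys")
  if (!is.null(loci)) {
    nc <- unique(nchar(hap))
    if (length(nc) > 1 || (length(nc) == 1 && nc != nrow(loci)))
      stop("haplotype strings must all span the locus table")
  }
  tab <- data.frame(hap = hap, freq = freq, stringsAsFactors = FALSE)
  if (!is.null(allele)) tab$allele <- as.character(allele)
  structure(tab, loci = loci, class = c("freq_table", "data.frame"))
}

#' @export
print.freq_table <- function(x, ...) {
  kind <- if (is.null(x$allele)) "haplotype" else "gene-SNP haplotype"
  cat("freq_table:", nrow(x), kind, "entries over",
      if (is.null(attr(x, "loci"))) 0L else nrow(attr(x, "loci")), "loci\n")
  ord <- order(-x$freq)
  show <- utils::head(ord, 8L)
  lab <- if (is.null(x$allele)) x$hap[show] else
    paste(x$allele[show], x$hap[show], sep = "|")
  for (i in seq_along(show))
    cat(sprintf("  %-24s %.6f\n", lab[i], x$freq[show[i]]))
  if (nrow(x) > 8L) cat("  ...\n")
  invisible(x)
}

ft_loci <- function(ft) attr(ft, "loci")

# frequencies below this are treated as exactly zero when enumerating
# compatible pairs, to bound the pair search
.FREQ_ZERO <- 1e-10

#' Tag-SNP prediction model for a multi-allelic gene
#'
#' Container built by [forward_backward_select()]: the gene's interval, the
#' selected flanking SNP loci, the fitted joint gene-SNP haplotype frequency
#' table, and the dictionary mapping gene-allele labels to their intragenic
#' SNP sequences.
#'
#' @param gene List with `name`, `chrom`, `start`, `end` (1-based inclusive).
#' @param snps Locus table of the selected SNPs, in selection order.
#' @param joint `freq_table` with an `allele` column over the selected loci.
#' @param alleles Named character vector: gene-allele label -> intragenic
#'   haplotype string.
#' @param flank_size Flanking window half-width in bp used for selection.
#' @param meta List of training metadata (sample count, objective value Q,
#'   configuration).
#'
#' @return Object of class `prediction_model`.
#' @export
prediction_model <- function(gene, snps, joint, alleles, flank_size = NA_real_,
                             meta = list()) {
  stopifnot(is.list(gene), !is.null(gene$name))
  if (!is.null(joint$allele) || nrow(joint) == 0) {
    unknown <- setdiff(unique(joint$allele), names(alleles))
    if (length(unknown))
      stop("joint table references gene alleles missing from the dictionary: ",
           paste(unknown, collapse = ", "))
  } else stop("joint table must carry gene-allele labels")
  if (abs(sum(joint$freq) - 1) > 1e-6)
    stop("joint frequencies must sum to 1")
  structure(list(gene = gene, snps = snps, joint = joint, alleles = alleles,
                 flank_size = flank_size, meta = meta),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat("prediction_model for gene", x$gene$name, "\n")
  cat("  interval: ", x$gene$chrom, ":", x$gene$start, "-", x$gene$end,
      " (flank ", x$flank_size, " bp)\n", sep = "")
  cat("  gene alleles:", length(x$alleles),
      " selected SNPs:", nrow(x$snps),
      " joint haplotypes:", nrow(x$joint), "\n")
  if (!is.null(x$meta$q)) cat("  objective Q:", format(x$meta$q), "\n")
  invisible(x)
}

# canonical unordered pair key for two allele labels / haplotype strings
pair_key <- function(a, b) {
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "/")
}
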
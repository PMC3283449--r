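#' Translate a gene allele to its amino-acid sequence
#'
#' Applies the allele's variant bases to a reference sequence, splices the
#' coding exons, and translates with the standard codon table. SNPs whose
#' position falls outside the coding exons (UTR/intronic) are ignored with
#' a warning; internal stop codons are retained as `*`.
#'
#' @param hap Allele code string over `loci` ("0" = reference base, "1" =
#'   alternate base).
#' @param loci [snp_loci()] table of the gene's intragenic SNPs; positions
#'   are 1-based coordinates on `ref_seq`.
#' @param exons Data.frame with `start`/`end` columns (1-based inclusive,
#'   on `ref_seq`), the coding exons in genomic order.
#' @param ref_seq Reference sequence: a character string, a
#'   `Biostrings::DNAString`, or a path to a single-sequence FASTA file.
#' @param strand `"+"` or `"-"`; minus-strand CDS are reverse-complemented
#'   before translation.
#'
#' @return Amino-acid sequence (character scalar, stops as `*`).
#' @export
translate_allele <- function(hap, loci, exons, ref_seq, strand = "+") {
  stopifnot(strand %in% c("+", "-"), nchar(hap) == nrow(loci))
  if (is.character(ref_seq) && length(ref_seq) == 1 && file.exists(ref_seq))
    ref_seq <- Biostrings::readDNAStringSet(ref_seq)[[1L]]
  s <- strsplit(toupper(as.character(ref_seq)), "", fixed = TRUE)[[1L]]
  codes <- as.integer(strsplit(hap, "", fixed = TRUE)[[1L]])

  in_cds <- function(pos) any(pos >= exons$start & pos <= exons$end)
  for (j in seq_len(nrow(loci))) {
    pos <- loci$pos[j]
    if (pos < 1 || pos > length(s))
      stop("SNP ", loci$id[j], " lies outside the reference sequence")
    if (s[pos] != toupper(loci$ref[j]))
      warning("reference base mismatch at ", loci$id[j], " (pos ", pos, "): ",
              s[pos], " vs declared ", loci$ref[j])
    if (!in_cds(pos)) {
      if (codes[j] == 1L)
        warning("variant at ", loci$id[j], " falls outside the coding exons; ignored")
      next
    }
    if (codes[j] == 1L) s[pos] <- toupper(loci$alt[j])
  }

  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- paste0(unlist(lapply(seq_len(nrow(exons)), function(i)
    s[exons$start[i]:exons$end[i]])), collapse = "")
  if (nchar(cds) %% 3 != 0)
    stop("frame violation: spliced CDS length ", nchar(cds),
         " is not a multiple of 3")
  d <- Biostrings::DNAString(cds)
  if (strand == "-") d <- Biostrings::reverseComplement(d)
  as.character(Biostrings::translate(d, no.init.codon = TRUE))
}

#' Translate every allele of a prediction model
#'
#' @param model A [prediction_model()].
#' @inheritParams translate_allele
#'
#' @return Named character vector: gene-allele label -> protein sequence.
#' @export
translate_model_alleles <- function(model, loci, exons, ref_seq, strand = "+") {
  vapply(model$alleles, translate_allele, character(1),
         loci = loci, exons = exons, ref_seq = ref_seq, strand = strand)
}

#' Collapse synonymous gene alleles into amino-acid alleles
#'
#' Groups gene (DNA) alleles whose translations are identical proteins,
#' sums their frequencies per phenotype group, and relabels the groups
#' `GeneName*aa*k` in order of decreasing control frequency. Because
#' redundant codon usage merges several DNA alleles into one protein
#' variant, the collapsed table has fewer levels and the multi-allelic test
#' on it gains power.
#'
#' @param allele_table Data.frame with `allele` plus frequency columns
#'   (`freq_control`/`freq_case`, or a single `freq`).
#' @param proteins Named character vector allele label -> protein sequence
#'   (e.g. from [translate_model_alleles()]).
#' @param gene_name Label prefix; default inferred from the first allele
#'   label (text before the first `*`).
#'
#' @return Data.frame: `aa_allele`, `protein`, `members` (comma-joined DNA
#'   allele labels), and the summed frequency columns; attribute
#'   `"mapping"` holds the named vector DNA allele -> aa allele.
#' @export
collapse_synonymous <- function(allele_table, proteins, gene_name = NULL) {
  stopifnot("allele" %in% names(allele_table))
  miss <- setdiff(allele_table$allele, names(proteins))
  if (length(miss)) stop("no translation for allele(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(gene_name))
    gene_name <- sub("\\*.*$", "", allele_table$allele[1L])
  prot <- unname(proteins[allele_table$allele])
  groups <- split(seq_len(nrow(allele_table)), prot)

  fcols <- intersect(c("freq_control", "freq_case", "freq"),
                     names(allele_table))
  if (!length(fcols)) stop("allele_table carries no frequency column")
  agg <- lapply(groups, function(i) {
    row <- list(protein = prot[i[1L]],
                members = paste(sort(allele_table$allele[i]), collapse = ","))
    for (fc in fcols) row[[fc]] <- sum(allele_table[[fc]][i])
    row
  })
  out <- do.call(rbind, lapply(agg, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rank_by <- if ("freq_control" %in% fcols) out$freq_control else out$freq
  out <- out[order(-rank_by, out$protein), , drop = FALSE]
  out <- cbind(aa_allele = paste0(gene_name, "*aa*", seq_len(nrow(out))), out)
  rownames(out) <- NULL

  mapping <- character(nrow(allele_table))
  names(mapping) <- allele_table$allele
  for (i in seq_len(nrow(out))) {
    members <- strsplit(out$members[i], ",", fixed = TRUE)[[1L]]
    mapping[members] <- out$aa_allele[i]
  }
  attr(out, "mapping") <- mapping
  out
}

#' Collapse a dosage matrix by an allele grouping
#'
#' Sums dosage columns that map to the same amino-acid allele, so per-
#' subject dosages still total 2.
#'
#' @param dosages Subjects x DNA-allele dosage matrix.
#' @param mapping Named character vector DNA allele -> group label (the
#'   `"mapping"` attribute of [collapse_synonymous()]).
#'
#' @return Subjects x group dosage matrix.
#' @export
collapse_dosages <- function(dosages, mapping) {
  miss <- setdiff(colnames(dosages), names(mapping))
  if (length(miss)) stop("mapping lacks allele(s): ", paste(miss, collapse = ", "))
  grp <- mapping[colnames(dosages)]
  out <- t(rowsum(t(dosages), grp))
  out[, sort(colnames(out)), drop = FALSE]
}
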
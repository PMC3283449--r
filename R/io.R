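# Readers and writers for the standard interchange formats: VCF genotypes,
# BED gene intervals, phenotype/call TSVs, and the JSON model schema.

MODEL_SCHEMA_VERSION <- 1L

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses GT fields into 0/1/2 genotype codes (alternate-allele counts);
#' phased separators are accepted but the phase is ignored on input.
#' Multi-allelic records are skipped with a warning.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param region Optional `"chrom:start-end"` filter (1-based inclusive).
#'
#' @return A [geno_matrix()] (subjects x loci) with the locus table
#'   attached; attribute `"n_skipped"` counts skipped non-biallelic
#'   records.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) & ref != alt
  n_skipped <- sum(!biallelic)
  if (n_skipped) warning(n_skipped, " non-biallelic record(s) skipped")
  keep <- which(biallelic)

  pos <- as.integer(fix[keep, "POS"])
  chrom <- fix[keep, "CHROM"]
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    inr <- chrom == m[2L] & pos >= as.integer(m[3L]) & pos <= as.integer(m[4L])
    keep <- keep[inr]; pos <- pos[inr]; chrom <- chrom[inr]
  }
  if (!length(keep)) stop("no usable biallelic records in ", path)

  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(chrom, ":", pos)[is.na(ids) | ids == "."]
  loci <- snp_loci(id = ids, chrom = chrom, pos = pos,
                   ref = fix[keep, "REF"], alt = fix[keep, "ALT"])

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  code <- function(x) {
    a <- strsplit(gsub("|", "/", x, fixed = TRUE), "/", fixed = TRUE)
    vapply(a, function(p) {
      if (length(p) != 2 || any(p == ".")) return(NA_integer_)
      sum(as.integer(p))
    }, integer(1))
  }
  codes <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) codes[, j] <- code(gt[j, ])
  G <- geno_matrix(codes, loci)
  rownames(G) <- colnames(gt)
  attr(G, "n_skipped") <- n_skipped
  G
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' @param G A [geno_matrix()].
#' @param path Output path (plain text).
#'
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  loci <- geno_loci(G)
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  body <- vapply(seq_len(nrow(loci)), function(j) {
    g <- unclass(G)[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(loci$chrom[j], loci$pos[j], loci$id[j], loci$ref[j], loci$alt[j],
            ".", "PASS", ".", "GT", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive
#' coordinates on input.
#'
#' @param path BED/TSV file with columns chrom, start, end and optionally
#'   name.
#'
#' @return Data.frame `chrom`, `start`, `end` (1-based inclusive), `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(b) < 3) stop("BED file needs at least 3 columns")
  data.frame(chrom = as.character(b[[1L]]),
             start = as.integer(b[[2L]]) + 1L,
             end = as.integer(b[[3L]]),
             name = if (ncol(b) >= 4) as.character(b[[4L]])
                    else paste0("region", seq_len(nrow(b))),
             stringsAsFactors = FALSE)
}

#' Read a phenotype table
#'
#' @param path TSV with header columns `sample` and `status` (0 = control,
#'   1 = case).
#'
#' @return Data.frame `sample`, `status`.
#' @export
read_phenotypes <- function(path) {
  p <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("sample", "status") %in% names(p)))
    stop("phenotype file needs 'sample' and 'status' columns")
  if (!all(p$status %in% 0:1)) stop("status must be 0 (control) or 1 (case)")
  p[, c("sample", "status")]
}

#' Write a prediction model to JSON
#'
#' The schema is versioned and human-diffable; frequencies are serialized
#' as decimal strings at full double precision, so a round trip through
#' [read_model()] is lossless.
#'
#' @param model A [prediction_model()].
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    gene = model$gene,
    flank_size = model$flank_size,
    snps = model$snps,
    alleles = as.list(model$alleles),
    joint = data.frame(allele = model$joint$allele,
                       snp_hap = model$joint$hap,
                       freq = sprintf("%.17g", model$joint$freq),
                       stringsAsFactors = FALSE),
    meta = list(n_train = model$meta$n_train,
                q = model$meta$q,
                q_trace = model$meta$q_trace,
                k = model$meta$k, m = model$meta$m))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a prediction model from JSON
#'
#' @param path Model file written by [write_model()].
#'
#' @return A [prediction_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed model file: ",
                                           conditionMessage(e)))
  if (is.null(obj$schema_version) ||
      obj$schema_version != MODEL_SCHEMA_VERSION)
    stop("unknown model schema version: ",
         if (is.null(obj$schema_version)) "<absent>" else obj$schema_version)
  snps <- as.data.frame(obj$snps, stringsAsFactors = FALSE)
  joint <- freq_table(hap = as.character(obj$joint$snp_hap),
                      freq = as.numeric(obj$joint$freq),
                      loci = if (nrow(snps)) snps else NULL,
                      allele = as.character(obj$joint$allele))
  prediction_model(gene = obj$gene, snps = snps, joint = joint,
                   alleles = unlist(obj$alleles),
                   flank_size = obj$flank_size,
                   meta = obj$meta)
}

#' Write diplotype calls or predictions as TSV
#'
#' @param calls Data.frame of calls/predictions.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
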
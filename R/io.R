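#' Read mQTL (or GWAS) summary statistics
#'
#' Expects a tab-delimited file with header
#' `probe chrom pos effect_allele other_allele beta se pval` (the dialect's
#' column names are configurable). Every record is validated: `se` must be
#' positive, `pval` in (0,1], and the two alleles distinct. Malformed rows
#' are dropped and reported with their line numbers in the `problems`
#' attribute of the result.
#'
#' @param path file path.
#' @param dialect named character vector mapping the canonical column names
#'   to the file's header names; defaults to the identity mapping.
#' @return data.frame of validated records with a `snp_id` column
#'   (`chrom:pos`) appended; attribute `problems` lists rejected rows.
#' @export
read_sumstats <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  canonical <- c("probe", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pval")
  dialect <- dialect %||% stats::setNames(canonical, canonical)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character"))
  missing_cols <- setdiff(unname(dialect[canonical]), names(x))
  if (length(missing_cols))
    stop_input("missing required column(s): ", paste(missing_cols, collapse = ", "))
  x <- x[unname(dialect[canonical])]
  names(x) <- canonical
  x$pos <- suppressWarnings(as.integer(x$pos))
  for (col in c("beta", "se", "pval"))
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  bad <- is.na(x$pos) | is.na(x$beta) | is.na(x$se) | is.na(x$pval) |
    x$se <= 0 | x$pval <= 0 | x$pval > 1 | x$effect_allele == x$other_allele
  problems <- data.frame(
    line = which(bad) + 1L,
    reason = rep_len("invalid numeric field, se<=0, pval outside (0,1], or identical alleles",
                     sum(bad)))
  x <- x[!bad, , drop = FALSE]
  x$snp_id <- paste(x$chrom, x$pos, sep = ":")
  rownames(x) <- NULL
  attr(x, "problems") <- problems
  x
}

#' Write summary statistics
#'
#' Emits the canonical tab-delimited layout
#' `probe chrom pos effect_allele other_allele beta se pval`.
#'
#' @param sumstats data.frame as produced by [simulate_mqtl_sumstats()] or
#'   [read_sumstats()].
#' @param path output path.
#' @export
write_sumstats <- function(sumstats, path) {
  cols <- c("probe", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "se", "pval")
  utils::write.table(sumstats[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotypes to VCF
#'
#' Writes a minimal VCF 4.2 file with GT (hard calls, rounded from dosage)
#' and DS (dosage) FORMAT fields.
#'
#' @param g a [genotype_matrix()].
#' @param path output path (plain text `.vcf`).
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  v <- g$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$sample_ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[pmin(pmax(round(d), 0), 2) + 1])
    ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 6))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT:DS", paste(gt, ds, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Parses a VCF 4.x file via `vcfR`. Dosages are taken from the DS FORMAT
#' field when present, otherwise from hard GT calls. Variants on chromosome
#' X or Y are excluded on read.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  keep <- !(fix$CHROM %in% c("X", "Y", "chrX", "chrY", "23", "24"))
  fmt <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    fmt <- matrix(sapply(strsplit(gt, "[/|]"), function(a)
      if (any(a == ".")) NA_real_ else sum(as.integer(a))),
      nrow = nrow(gt), dimnames = dimnames(gt))
  }
  dosage <- t(fmt[keep, , drop = FALSE])
  variants <- data.frame(id = fix$ID[keep], chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         stringsAsFactors = FALSE)
  blank <- is.na(variants$id) | variants$id == "."
  variants$id[blank] <- paste(variants$chrom, variants$pos, sep = ":")[blank]
  rownames(dosage) <- colnames(fmt)
  genotype_matrix(dosage, variants)
}

#' Write / read phenotype-covariate tables
#'
#' Tab-delimited with header; missing values encoded as `NA`.
#' @param phenotypes data.frame from [simulate_cohort()].
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "status")
  if (!all(req %in% names(x)))
    stop_input("phenotype table must contain columns: ", paste(req, collapse = ", "))
  tm <- intersect(c("os_time", "rfs_time"), names(x))
  if (length(tm) && any(unlist(x[tm]) < 0, na.rm = TRUE))
    stop_input("survival times must be non-negative")
  x
}

#' Read gene annotation
#'
#' Accepts a tab-delimited table with columns `gene chrom start end`
#' (1-based inclusive), a BED file (0-based half-open, converted to 1-based
#' inclusive) or a GFF3 file of gene features. BED/GFF parsing uses
#' `rtracklayer`.
#'
#' @param path annotation file; format inferred from the extension.
#' @return data.frame with columns `gene, chrom, start, end`.
#' @export
read_gene_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bed", "gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop_input("rtracklayer is required to read BED/GFF annotation")
    gr <- as.data.frame(rtracklayer::import(path))
    nm <- if (!is.null(gr$Name)) gr$Name else if (!is.null(gr$name)) gr$name
          else if (!is.null(gr$ID)) gr$ID else paste0("feature", seq_len(nrow(gr)))
    data.frame(gene = as.character(nm), chrom = as.character(gr$seqnames),
               start = gr$start, end = gr$end, stringsAsFactors = FALSE)
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene", "chrom", "start", "end")
    if (!all(req %in% names(x)))
      stop_input("gene annotation must contain columns: ", paste(req, collapse = ", "))
    x$chrom <- as.character(x$chrom)
    x[req]
  }
}

#' Write / read simulation ground truth
#'
#' Plain-text structured (YAML) serialisation of the ground-truth list so
#' parameter-recovery checks can consume planted effects without re-deriving
#' them.
#' @param truth ground-truth list.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) yaml::read_yaml(path)
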
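#' Region-partitioning configuration
#'
#' Thresholds for splitting one probe's trait-associated SNPs into genomic
#' regions: a region must contain at least one seed SNP with
#' `pval < p_seed`, includes every SNP with `pval < p_include`, and two
#' regions of the same probe are separated by at least `min_separation`
#' bases.
#'
#' @param p_seed seed p-value threshold (default 1e-6).
#' @param p_include membership p-value threshold (default 1e-5).
#' @param min_separation minimum inter-region gap in bases (default 1 Mb).
#' @return object of class `partition_config`.
#' @export
partition_config <- function(p_seed = 1e-6, p_include = 1e-5,
                             min_separation = 1e6) {
  if (p_seed > p_include) stop_input("p_seed must not exceed p_include")
  if (min_separation <= 0) stop_input("min_separation must be positive")
  structure(list(p_seed = p_seed, p_include = p_include,
                 min_separation = min_separation),
            class = "partition_config")
}

#' Partition one probe's summary statistics into trait-associated regions
#'
#' Retains SNPs with `pval < p_include`, single-linkage clusters them within
#' chromosome (consecutive retained SNPs join one cluster iff their gap is
#' smaller than `min_separation`), and discards clusters holding no SNP with
#' `pval < p_seed`. Region bounds are the min/max member positions.
#'
#' @param sumstats summary statistics for a single probe.
#' @param config a [partition_config()].
#' @return list of regions; each has `probe_id, chrom, start, end, snp_ids,
#'   seed_count, min_pval`.
#' @export
partition_regions <- function(sumstats, config = partition_config()) {
  if (length(unique(sumstats$probe)) > 1)
    stop_input("partition_regions expects records for a single probe")
  dup <- paste(sumstats$chrom, sumstats$pos)
  if (anyDuplicated(dup)) {
    d <- sumstats[dup %in% dup[duplicated(dup)], ]
    alleles <- paste(d$effect_allele, d$other_allele)
    if (length(unique(alleles)) > 1)
      stop_input("duplicate positions with conflicting alleles")
  }
  x <- sumstats[sumstats$pval < config$p_include, , drop = FALSE]
  if (!nrow(x)) return(list())
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  regions <- list()
  for (ch in unique(x$chrom)) {
    xc <- x[x$chrom == ch, , drop = FALSE]
    gap <- diff(xc$pos)
    cl <- cumsum(c(1L, as.integer(gap >= config$min_separation)))
    for (g in split(seq_len(nrow(xc)), cl)) {
      seeds <- sum(xc$pval[g] < config$p_seed)
      if (seeds < 1) next
      regions[[length(regions) + 1L]] <- list(
        probe_id = xc$probe[g[1]], chrom = ch,
        start = min(xc$pos[g]), end = max(xc$pos[g]),
        snp_ids = xc$snp_id[g], seed_count = seeds,
        min_pval = min(xc$pval[g]))
    }
  }
  regions
}

#' Tabulate regions
#'
#' Flattens a region list into the table layout
#' `probe chrom start end n_snps n_seed`.
#' @param regions list from [partition_regions()].
#' @return data.frame.
#' @export
regions_table <- function(regions) {
  if (!length(regions))
    return(data.frame(probe = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), n_seed = integer(0)))
  do.call(rbind, lapply(regions, function(r)
    data.frame(probe = r$probe_id, chrom = r$chrom, start = r$start,
               end = r$end, n_snps = length(r$snp_ids), n_seed = r$seed_count,
               stringsAsFactors = FALSE)))
}
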
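#' @name scoligene-io
#' @title Readers and writers for the pipeline's plain-text formats
#' @description Tab-separated tables for SNPs, LD pairs, eQTL records and
#'   burden/phenotype data; BED6 (+ TSS table) for gene models; BEDPE for
#'   chromatin interactions; minimal VCF 4.2 for annotated cohorts; CSV
#'   for traces and trajectories. Coordinates are 0-based half-open in
#'   BED/BEDPE, 1-based in VCF and SNP tables.
NULL

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, cols) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' @rdname scoligene-io
#' @param snps,ld,eqtls,phenotype,burden,results Data frames in the
#'   dialects produced by the generator and analysis functions.
#' @param path Output or input file path.
#' @export
write_snp_table <- function(snps, path) .write_tsv(snps, path)

#' @rdname scoligene-io
#' @export
read_snp_table <- function(path)
  .read_tsv(path, c("rsid", "chrom", "pos", "pvalue"))

#' @rdname scoligene-io
#' @export
write_ld_table <- function(ld, path) .write_tsv(ld, path)

#' @rdname scoligene-io
#' @export
read_ld_table <- function(path) .read_tsv(path, c("rsid1", "rsid2", "r2"))

#' @rdname scoligene-io
#' @export
write_eqtl_table <- function(eqtls, path) .write_tsv(eqtls, path)

#' @rdname scoligene-io
#' @export
read_eqtl_table <- function(path)
  .read_tsv(path, c("rsid", "gene_id", "tissue", "fdr"))

#' @rdname scoligene-io
#' @param genes Gene-model data.frame (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`).
#' @param bed_path,tss_path BED6 file and companion TSS table
#'   (`gene_id`, `tss`).
#' @export
write_gene_models <- function(genes, bed_path, tss_path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$name <- genes$gene_id
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, bed_path, format = "BED")
  .write_tsv(genes[, c("gene_id", "tss")], tss_path)
  invisible(bed_path)
}

#' @rdname scoligene-io
#' @export
read_gene_models <- function(bed_path, tss_path = NULL) {
  gr <- rtracklayer::import(bed_path, format = "BED")
  genes <- data.frame(gene_id = S4Vectors::mcols(gr)$name,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  if (!is.null(tss_path)) {
    tss <- .read_tsv(tss_path, c("gene_id", "tss"))
    genes$tss <- tss$tss[match(genes$gene_id, tss$gene_id)]
  } else {
    genes$tss <- ifelse(genes$strand == "+", genes$start + 1L, genes$end)
  }
  genes
}

#' @rdname scoligene-io
#' @param interactions Interaction data.frame (`chromA`, `startA`,
#'   `endA`, `chromB`, `startB`, `endB`, `fdr`).
#' @export
write_interactions_bedpe <- function(interactions, path) {
  bedpe <- data.frame(interactions$chromA, interactions$startA,
                      interactions$endA, interactions$chromB,
                      interactions$startB, interactions$endB,
                      name = sprintf("int%04d", seq_len(nrow(interactions))),
                      score = interactions$fdr)
  utils::write.table(bedpe, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname scoligene-io
#' @export
read_interactions_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 8)
    stop("BEDPE needs 8 columns (pair coordinates, name, score=FDR)",
         call. = FALSE)
  data.frame(chromA = df[[1]], startA = df[[2]], endA = df[[3]],
             chromB = df[[4]], startB = df[[5]], endB = df[[6]],
             fdr = df[[8]], stringsAsFactors = FALSE)
}

#' @rdname scoligene-io
#' @export
write_phenotype_table <- function(phenotype, path)
  .write_tsv(phenotype, path)

#' @rdname scoligene-io
#' @export
read_phenotype_table <- function(path)
  .read_tsv(path, c("sample", "status"))

#' @rdname scoligene-io
#' @export
write_burden_matrix <- function(burden, path) {
  df <- data.frame(sample = rownames(burden), burden,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname scoligene-io
#' @export
read_burden_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  m
}

#' @rdname scoligene-io
#' @param candidates Candidate-gene data.frame from
#'   [combine_candidates()].
#' @export
write_candidate_genes <- function(candidates, path)
  .write_tsv(candidates, path)

#' @rdname scoligene-io
#' @export
write_scan_results <- function(results, path) .write_tsv(results, path)

# ---- VCF ------------------------------------------------------------------

#' Write an annotated cohort as minimal VCF 4.2
#'
#' INFO carries `GENE`, `CSQ_CLASS`, `LOFTEE`, `SPLICEAI`, `REVEL`,
#' `CADD`, `GNOMAD_POPMAX_AF`; genotypes are unphased `GT`. Missing
#' scores are omitted from INFO. Records are single-alt, pre-split.
#'
#' @param variants Annotation data.frame (see [gen_cohort()]).
#' @param genotypes Samples x variants allele-count matrix (0/1/2).
#' @param path Output path (plain text, uncompressed).
#' @export
write_cohort_vcf <- function(variants, genotypes, path) {
  stopifnot(all(variants$variant_id %in% colnames(genotypes)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene identifier\">",
    paste0("##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=",
           "\"Consequence class\">"),
    paste0("##INFO=<ID=LOFTEE,Number=1,Type=String,Description=",
           "\"LOFTEE confidence (HC/LC)\">"),
    "##INFO=<ID=SPLICEAI,Number=1,Type=Float,Description=\"SpliceAI score\">",
    "##INFO=<ID=REVEL,Number=1,Type=Float,Description=\"REVEL score\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
    paste0("##INFO=<ID=GNOMAD_POPMAX_AF,Number=1,Type=Float,Description=",
           "\"gnomAD popmax allele frequency\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  info_field <- function(key, val, fmt = "%s") {
    ifelse(is.na(val), NA, paste0(key, "=", sprintf(fmt, val)))
  }
  info <- mapply(function(...) {
    parts <- c(...)
    parts <- parts[!is.na(parts)]
    if (!length(parts)) "." else paste(parts, collapse = ";")
  },
  info_field("GENE", variants$gene_id),
  info_field("CSQ_CLASS", variants$csq_class),
  info_field("LOFTEE", variants$loftee),
  info_field("SPLICEAI", variants$spliceai, "%.4g"),
  info_field("REVEL", variants$revel, "%.4g"),
  info_field("CADD", variants$cadd, "%.4g"),
  info_field("GNOMAD_POPMAX_AF", variants$popmax_af, "%.4g"))
  G <- as.matrix(genotypes[, variants$variant_id, drop = FALSE])
  gt <- matrix(c("0/0", "0/1", "1/1")[G + 1L], nrow(G), ncol(G))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an annotated cohort from VCF
#'
#' Parses the dialect written by [write_cohort_vcf()] (or any VCF with
#' the same INFO keys and GT genotypes) via the vcfR package.
#'
#' @param path VCF file path.
#' @return List with `variants` (annotation data.frame, `cohort_ac`
#'   recomputed from genotypes) and `genotypes` (sparse samples x
#'   variants allele-count matrix).
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_chr <- function(key) vcfR::extract.info(v, element = key)
  info_num <- function(key)
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ac <- matrix(0L, nrow(gt_raw), ncol(gt_raw))
  ac[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  ac[gt_raw %in% c("1/1", "1|1")] <- 2L
  genotypes <- Matrix::Matrix(t(ac), sparse = TRUE,
                              dimnames = list(colnames(gt_raw), fix$ID))
  variants <- data.frame(variant_id = fix$ID,
                         gene_id = info_chr("GENE"),
                         chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         csq_class = info_chr("CSQ_CLASS"),
                         loftee = info_chr("LOFTEE"),
                         spliceai = info_num("SPLICEAI"),
                         revel = info_num("REVEL"),
                         cadd = info_num("CADD"),
                         popmax_af = info_num("GNOMAD_POPMAX_AF"),
                         stringsAsFactors = FALSE)
  variants$popmax_af[is.na(variants$popmax_af)] <- 0
  variants$cohort_ac <- as.integer(Matrix::colSums(genotypes))
  list(variants = variants, genotypes = genotypes)
}

# ---- CSV traces / trajectories -------------------------------------------

#' @rdname scoligene-io
#' @param trace data.frame `time`, `left`, `right`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname scoligene-io
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "left", "right") %in% names(df)))
  df
}

#' @rdname scoligene-io
#' @param traj data.frame `time`, `x`, `y`.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname scoligene-io
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "x", "y") %in% names(df)))
  df
}

#' Write a complete synthetic-study bundle to a directory
#'
#' Runs every generator for `cfg` and serialises the results in the
#' pipeline's interchange formats: `snps.tsv`, `ld.tsv`, `genes.bed` +
#' `genes_tss.tsv`, `eqtls.tsv`, `interactions.bedpe`, `cohort.vcf`,
#' `phenotypes.tsv`, `trace.csv`, `trajectory.csv`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- gen_gene_models(cfg)
  gw <- gen_gwas_inputs(cfg, genes)
  cohort <- gen_cohort(cfg, genes)
  traces <- gen_bilateral_traces(cfg)
  traj <- gen_trajectory(cfg)
  write_snp_table(gw$snps, file.path(dir, "snps.tsv"))
  write_ld_table(gw$ld, file.path(dir, "ld.tsv"))
  write_gene_models(genes, file.path(dir, "genes.bed"),
                    file.path(dir, "genes_tss.tsv"))
  write_eqtl_table(gw$eqtls, file.path(dir, "eqtls.tsv"))
  write_interactions_bedpe(gw$interactions,
                           file.path(dir, "interactions.bedpe"))
  write_cohort_vcf(cohort$variants, cohort$genotypes,
                   file.path(dir, "cohort.vcf"))
  write_phenotype_table(cohort$phenotype, file.path(dir, "phenotypes.tsv"))
  write_trace_csv(traces$trace, file.path(dir, "trace.csv"))
  write_trajectory_csv(traj, file.path(dir, "trajectory.csv"))
  invisible(dir)
}
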
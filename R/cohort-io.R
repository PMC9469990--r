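#' Write a synthetic cohort bundle to disk
#'
#' Emits every file the pipeline stages consume — tumor VCFs in both
#' caller dialects, normal VCFs, germline-resource and withdrawn-sites
#' VCFs, regenotyping evidence TSVs, Manta-style SV VCFs, a centromere
#' BED, copy-ratio segment TSVs, coverage and chromosome-size TSVs, the
#' toy reference FASTA and GTF, genotype and breed-label TSVs — plus a
#' `manifest.json` listing each file with its truth cross-reference.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return named list of written paths (also stored in the manifest),
#'   invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  paths <- list()
  for (tn in names(cohort$tumors)) {
    paths[[paste0(tn, "_mutect2")]] <-
      write_vcf(cohort$tumors[[tn]]$mutect2, p(tn, ".mutect2.vcf"),
                contigs = cohort$contigs)
    pl <- cohort$tumors[[tn]]$platypus
    paths[[paste0(tn, "_platypus")]] <-
      .write_platypus_vcf(pl, p(tn, ".platypus.vcf"), cohort$contigs)
    paths[[paste0(tn, "_sv")]] <-
      write_sv_vcf(cohort$sv$tumors[[tn]], p(tn, ".sv.vcf"),
                   contigs = cohort$contigs)
    seg <- cohort$segments[[tn]]
    utils::write.table(
      data.frame(contig = seg$chrom, start = seg$start + 1, end = seg$end,
                 log2_ratio = seg$log2_ratio),
      paths[[paste0(tn, "_segments")]] <- p(tn, ".segments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    cov <- cohort$coverage[[tn]]$depths
    utils::write.table(data.frame(chrom = names(cov), mean_depth = cov),
                       paths[[paste0(tn, "_coverage")]] <- p(tn, ".coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nn in names(cohort$normals)) {
    paths[[paste0(nn, "_platypus")]] <-
      .write_platypus_vcf(cohort$normals[[nn]], p(nn, ".platypus.vcf"),
                          cohort$contigs)
  }
  for (nn in names(cohort$sv$normals)) {
    paths[[paste0(nn, "_sv")]] <-
      write_sv_vcf(cohort$sv$normals[[nn]], p(nn, ".sv.vcf"),
                   contigs = cohort$contigs)
  }
  for (rn in names(cohort$germline_resources)) {
    paths[[rn]] <- write_vcf(cohort$germline_resources[[rn]],
                             p("resource.", rn, ".vcf"),
                             contigs = cohort$contigs)
  }
  paths$removed_sites <- write_vcf(cohort$removed_sites, p("removed_sites.vcf"),
                                   contigs = cohort$contigs)
  utils::write.table(cohort$evidence, paths$evidence <- p("evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sv$evidence, paths$sv_evidence <- p("sv_evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$centromeres <- write_bed(cohort$sv$centromeres, p("centromeres.bed"))
  utils::write.table(data.frame(chrom = names(cohort$contigs),
                                length = as.integer(cohort$contigs)),
                     paths$chrom_sizes <- p("chrom_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(cohort$reference, paths$reference <- p("reference.fa"))
  paths$gtf <- .write_gtf(cohort$gene_model, p("genes.gtf"))
  geno <- cohort$ancestry$reference
  utils::write.table(
    cbind(data.frame(sample = rownames(geno$geno) %||%
                       paste0("ref", seq_len(nrow(geno$geno))),
                     breed = geno$labels), as.data.frame(geno$geno)),
    paths$reference_genotypes <- p("reference_genotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- p("truth.tsv")
  utils::write.table(cohort$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- truth_path
  manifest <- list(seed = cohort$seed,
                   n_tumors = length(cohort$tumors),
                   n_normals = length(cohort$normals),
                   files = lapply(paths, basename))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  paths$manifest <- p("manifest.json")
  invisible(paths)
}

# Platypus dialect writer: NR/NV FORMAT keys instead of AF/DP/AD.
.write_platypus_vcf <- function(records, path, contigs = NULL) {
  sample <- if (nrow(records) && !is.na(records$sample[1])) records$sample[1] else "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=NR,Number=A,Type=Integer,Description="Reads covering site">',
           '##FORMAT=<ID=NV,Number=A,Type=Integer,Description="Reads supporting variant">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)))
  }
  flt <- sort(unique(unlist(filter_tokens(records))))
  if (length(flt)) hdr <- c(hdr, sprintf('##FILTER=<ID=%s,Description="%s">', flt, flt))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- character(0)
  if (nrow(records)) {
    o <- order(records$chrom, records$pos, records$alt)
    r <- records[o, , drop = FALSE]
    body <- paste(r$chrom, r$pos, ".", r$ref, r$alt, ".",
                  ifelse(nzchar(r$filter), r$filter, "PASS"), ".",
                  "GT:NR:NV",
                  sprintf("0/1:%d:%d", as.integer(r$dp), as.integer(r$alt_depth)),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

.write_gtf <- function(gene_model, path) {
  row <- function(iv, type) {
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t+\t.\tgene_id \"%s\";",
            iv$chrom, type, iv$start + 1, iv$end, iv$gene_id)
  }
  writeLines(c(row(gene_model$genes, "gene"), row(gene_model$cds, "CDS")), path)
  invisible(path)
}

#' Read a per-chromosome coverage table
#'
#' @param path TSV with columns `chrom`, `mean_depth`.
#' @return named numeric vector of mean depths.
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$mean_depth, df$chrom)
}

#' Assemble an SNV pipeline configuration from a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @param tumor tumor sample name.
#' @return config list for [run_snv_pipeline()].
#' @export
snv_pipeline_config <- function(cohort, tumor) {
  list(mutect2 = cohort$tumors[[tumor]]$mutect2,
       platypus = cohort$tumors[[tumor]]$platypus,
       normals = cohort$normals,
       germline_resources = cohort$germline_resources,
       removed_sites = cohort$removed_sites,
       evidence = cohort$evidence,
       contigs = cohort$config$allow_contigs)
}

#' Assemble an SV pipeline configuration from a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @param tumor tumor sample name.
#' @return config list for [run_sv_pipeline()].
#' @export
sv_pipeline_config <- function(cohort, tumor) {
  list(tumor = cohort$sv$tumors[[tumor]],
       normals = cohort$sv$normals,
       centromeres = cohort$sv$centromeres,
       evidence = cohort$sv$evidence)
}
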
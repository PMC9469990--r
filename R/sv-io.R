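# Manta-style SV VCF I/O: INFO keys SVTYPE, END, SVLEN, IMPRECISE, MATEID;
# FORMAT keys PR and SR as "ref,alt" count pairs; BND partner breakpoints
# encoded in the ALT allele (e.g. N[chr2:12345[).

.info_field <- function(info, key) {
  vapply(regmatches(info, gregexpr(paste0("(^|;)", key, "=[^;]*"), info)),
         function(x) if (length(x)) sub(paste0(".*", key, "="), "", x[1]) else NA_character_,
         character(1))
}

.info_flag <- function(info, key) grepl(paste0("(^|;)", key, "(;|$)"), info)

#' Read a Manta-style structural-variant VCF
#'
#' Accepts both breakend-encoded and INV-converted inversion records.
#' PR/SR support is the alt count of the "ref,alt" FORMAT pair.
#'
#' @param path VCF path.
#' @param sample sample label; defaults to the genotype column name.
#' @return `sv_records`.
#' @export
read_sv_vcf <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(sv_records(character(0), character(0), character(0), integer(0)))
  }
  has_gt <- ncol(v@gt) >= 2
  if (is.null(sample)) sample <- if (has_gt) colnames(v@gt)[2] else NA_character_
  info <- fix[, "INFO"]
  svtype <- .info_field(info, "SVTYPE")
  endpos <- suppressWarnings(as.integer(.info_field(info, "END")))
  svlen <- suppressWarnings(as.numeric(.info_field(info, "SVLEN")))
  mate <- .info_field(info, "MATEID")
  imprecise <- .info_flag(info, "IMPRECISE")
  pr <- sr <- rep(0L, nrow(fix))
  if (has_gt) {
    fmt <- v@gt[, 1]; smp <- v@gt[, 2]
    alt2 <- function(x) suppressWarnings(as.integer(.nth_csv(x, rep(2L, length(x)))))
    prv <- alt2(.format_field(fmt, smp, "PR"))
    srv <- alt2(.format_field(fmt, smp, "SR"))
    pr <- ifelse(is.na(prv), 0L, prv)
    sr <- ifelse(is.na(srv), 0L, srv)
  }
  chrom1 <- fix[, "CHROM"]
  pos1 <- as.integer(fix[, "POS"])
  chrom2 <- chrom1
  pos2 <- ifelse(is.na(endpos), pos1, endpos)
  is_bnd <- svtype == "BND"
  if (any(is_bnd)) {
    alt <- fix[is_bnd, "ALT"]
    m <- regmatches(alt, regexpr("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]", alt,
                                 perl = TRUE))
    loc <- sub("^[][]", "", sub("[][]$", "", m))
    chrom2[is_bnd] <- sub(":.*", "", loc)
    pos2[is_bnd] <- as.integer(sub(".*:", "", loc))
  }
  sv_records(sv_id = fix[, "ID"], sv_type = svtype,
             chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
             svlen = svlen, pr = pr, sr = sr, imprecise = imprecise,
             filter = .normalize_filter(fix[, "FILTER"]),
             mate_id = mate, sample = sample)
}

#' Write structural variants as a Manta-style VCF
#'
#' @param svs `sv_records`.
#' @param path output path.
#' @param sample genotype column name.
#' @param contigs optional named vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, sample = NULL, contigs = NULL) {
  if (is.null(sample)) {
    sample <- if (nrow(svs) && !is.na(svs$sample[1])) svs$sample[1] else "SAMPLE"
  }
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
           '##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description="Imprecise breakpoints">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="Breakend mate id">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=PR,Number=2,Type=Integer,Description="Paired-read support (ref,alt)">',
           '##FORMAT=<ID=SR,Number=2,Type=Integer,Description="Split-read support (ref,alt)">')
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)))
  }
  flt <- sort(unique(unlist(strsplit(svs$filter[nzchar(svs$filter)], ";"))))
  if (length(flt)) hdr <- c(hdr, sprintf('##FILTER=<ID=%s,Description="%s">', flt, flt))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- character(0)
  if (nrow(svs)) {
    is_bnd <- svs$sv_type == "BND"
    alt <- ifelse(is_bnd,
                  sprintf("N[%s:%d[", svs$chrom2, svs$pos2),
                  paste0("<", svs$sv_type, ">"))
    info <- paste0("SVTYPE=", svs$sv_type,
                   ifelse(is_bnd, "", sprintf(";END=%d", svs$pos2)),
                   ifelse(is.na(svs$svlen), "", sprintf(";SVLEN=%d", as.integer(svs$svlen))),
                   ifelse(svs$imprecise, ";IMPRECISE", ""),
                   ifelse(is.na(svs$mate_id), "", paste0(";MATEID=", svs$mate_id)))
    fmt <- sprintf("0/1:%d,%d:%d,%d", pmax(0L, 30L - svs$pr), svs$pr,
                   pmax(0L, 30L - svs$sr), svs$sr)
    filt <- ifelse(nzchar(svs$filter), svs$filter, "PASS")
    body <- paste(svs$chrom1, svs$pos1, svs$sv_id, "N", alt, ".", filt, info,
                  "GT:PR:SR", fmt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
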
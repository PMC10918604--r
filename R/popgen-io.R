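#' Construct a GenotypeMatrix
#'
#' @param geno numeric/integer matrix individuals x loci, values 0/1/2/NA.
#' @param site character site label per individual.
#' @param chrom,pos optional per-locus chromosome and position.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
genotypeMatrix <- function(geno, site, chrom = character(), pos = integer()) {
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- paste0("loc", seq_len(ncol(geno)))
  new("GenotypeMatrix", geno = geno, site = as.character(site),
      chrom = as.character(chrom), pos = as.integer(pos))
}

#' Write genotypes to VCF
#'
#' Minimal VCF 4.2 with GT-only calls on the loci's contigs/positions;
#' written gzip-compressed when \code{path} ends in \code{.gz}.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param path output path (\code{.vcf} or \code{.vcf.gz}).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(g, path) {
  geno <- genotypeCalls(g)
  L <- ncol(geno)
  info <- lociInfo(g)
  chrom <- ifelse(is.na(info$chrom), "1", info$chrom)
  pos <- ifelse(is.na(info$pos), seq_len(L) * 100L, info$pos)
  gtStr <- matrix("./.", nrow(geno), L)
  gtStr[!is.na(geno) & geno == 0L] <- "0/0"
  gtStr[!is.na(geno) & geno == 1L] <- "0/1"
  gtStr[!is.na(geno) & geno == 2L] <- "1/1"
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_len(L), function(l) {
    paste(c(chrom[l], pos[l], colnames(geno)[l], "A", "C", ".", "PASS", ".",
            "GT", gtStr[, l]), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(c(lines, body), con)
  close(con)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' Keeps biallelic SNP rows only (multiallelic rows are dropped and counted);
#' phased and unphased calls are treated identically; \code{./.} becomes
#' \code{NA}.
#'
#' @param path a VCF file (optionally gzipped) with per-sample GT.
#' @param siteTable optional data.frame \code{(id, site)} mapping samples to
#'   sites; every sample must be present or an error lists the offenders.
#'   When \code{NULL}, the site is taken as the sample-name prefix before the
#'   last underscore.
#' @return a \linkS4class{GenotypeMatrix}; the number of dropped
#'   non-biallelic rows is attached as attribute \code{"droppedMultiallelic"}.
#' @export
readGenotypeVcf <- function(path, siteTable = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  dropped <- sum(!bi)
  if (dropped > 0) {
    message(dropped, " non-biallelic row(s) dropped")
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  num <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  num[gt %in% c("0/0")] <- 0L
  num[gt %in% c("0/1", "1/0")] <- 1L
  num[gt %in% c("1/1")] <- 2L
  geno <- t(num)
  samples <- rownames(geno)
  if (!is.null(siteTable)) {
    miss <- setdiff(samples, siteTable$id)
    if (length(miss))
      stop("samples missing from site table: ", paste(miss, collapse = ", "))
    site <- siteTable$site[match(samples, siteTable$id)]
  } else {
    site <- sub("_[^_]*$", "", samples)
  }
  fix <- vcfR::getFIX(vcf)
  out <- genotypeMatrix(geno, site, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]))
  attr(out, "droppedMultiallelic") <- dropped
  out
}
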
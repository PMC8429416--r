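#' Read a genotype reference panel from a VCF
#'
#' Parses hard genotype calls (GT) from a VCF 4.x file into an ALT-allele
#' dosage matrix. Multiallelic records are excluded, sites with more than
#' `maxMissing` missing genotypes are dropped, remaining missing calls are
#' imputed to the per-SNP mean dosage, and constant (monomorphic) sites are
#' removed so every retained SNP has minor allele frequency above zero.
#' The effect allele `a1` is the ALT allele.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @param maxMissing maximum tolerated fraction of missing genotypes per
#'   site, default 0.05.
#' @return A [GenotypePanel-class].
#' @export
readDosageVcf <- function(path, maxMissing = 0.05) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  alt <- VariantAnnotation::alt(vcf)
  biallelic <- S4Vectors::elementNROWS(alt) == 1L
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- names(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altc <- rep(NA_character_, length(biallelic))
  altc[biallelic] <- as.character(unlist(alt[biallelic]))

  # allele-count lookup covering phased and unphased diploid calls
  dose <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  lut <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
           "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  dose[] <- lut[gt]

  keep <- biallelic & rowMeans(is.na(dose)) <= maxMissing
  dose <- dose[keep, , drop = FALSE]
  if (!nrow(dose)) stop("no usable biallelic SNPs in ", path)
  for (j in which(rowSums(is.na(dose)) > 0)) {
    m <- mean(dose[j, ], na.rm = TRUE)
    dose[j, is.na(dose[j, ])] <- m
  }
  poly <- apply(dose, 1, function(x) max(x) - min(x) > 0)
  dose <- dose[poly, , drop = FALSE]
  if (!nrow(dose)) stop("no polymorphic SNPs in ", path)
  keepIdx <- which(keep)[poly]
  GenotypePanel(t(dose),
                data.frame(id = ids[keepIdx], chrom = chrom[keepIdx],
                           pos = pos[keepIdx], a1 = altc[keepIdx],
                           a2 = ref[keepIdx]),
                sampleIds = colnames(gt))
}

#' Write a GenotypePanel as a minimal GT-only VCF
#'
#' Emits a VCF 4.2 file with hard calls; dosages are rounded to the nearest
#' allele count. REF is the panel's `a2` allele and ALT its `a1` allele.
#'
#' @param panel a [GenotypePanel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDosageVcf <- function(panel, path) {
  s <- snpInfo(panel)
  d <- round(t(dosages(panel)))
  gtlut <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(panel)), collapse = "\t"))
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i], s$id[i], s$a2[i], s$a1[i], ".", "PASS",
            ".", "GT", gtlut[d[i, ] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Whitespace-delimited table with a header naming at least `SNP`, `A1`,
#' `A2`, `Z`; `CHR`, `POS` and `N` are used when present. Rows with
#' non-finite Z are dropped; duplicated SNP ids keep the first occurrence.
#'
#' @param path path to the summary-statistics file.
#' @param n GWAS sample size used when the file has no `N` column.
#' @return A [GwasSummary-class].
#' @export
readGwasSumstats <- function(path, n = NA_real_) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "Z")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("summary statistics missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  tab$Z <- suppressWarnings(as.numeric(tab$Z))
  tab <- tab[is.finite(tab$Z), , drop = FALSE]
  if (!nrow(tab)) stop("no rows with finite Z in ", path)
  dup <- duplicated(tab$SNP)
  if (any(dup)) {
    message(sum(dup), " duplicated SNP id(s) dropped (first kept)")
    tab <- tab[!dup, , drop = FALSE]
  }
  GwasSummary(
    data.frame(id = tab$SNP,
               chrom = if ("CHR" %in% names(tab)) as.character(tab$CHR) else NA_character_,
               pos = if ("POS" %in% names(tab)) as.integer(tab$POS) else NA_integer_,
               a1 = tab$A1, a2 = tab$A2),
    z = tab$Z,
    n = if ("N" %in% names(tab)) as.numeric(tab$N) else n)
}

#' Write GWAS summary statistics
#'
#' @param gwas a [GwasSummary-class].
#' @param path output path (tab-delimited, LDSC-style columns).
#' @return `path`, invisibly.
#' @export
writeGwasSumstats <- function(gwas, path) {
  s <- snpInfo(gwas)
  tab <- data.frame(SNP = s$id, CHR = s$chrom, POS = s$pos, A1 = s$a1,
                    A2 = s$a2, Z = sprintf("%.10g", zScores(gwas)),
                    N = gwasN(gwas))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3 interval file as an annotation feature
#'
#' BED coordinates are 0-based half-open; the returned [GenomicRanges::GRanges]
#' uses 1-based inclusive coordinates (`start+1 .. end`), so a 1-based SNP
#' position overlaps the interval exactly when BED would consider it covered.
#'
#' @param path path to a BED file with at least 3 columns.
#' @param featureName name of the feature (e.g. `"TFBS"`, `"DHS"`).
#' @return A `GRanges` with metadata attribute `featureName`.
#' @export
readAnnotationBed <- function(path, featureName) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns: ", path)
  bad <- which(tab[[2]] >= tab[[3]])
  if (length(bad))
    stop("BED interval with start >= end at line ", bad[1], " of ", path)
  gr <- GRanges(as.character(tab[[1]]),
                IRanges(start = tab[[2]] + 1L, end = tab[[3]]))
  S4Vectors::metadata(gr)$featureName <- featureName
  gr
}

#' Write an annotation feature as BED3
#'
#' @param gr a `GRanges` (1-based inclusive, converted to BED half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationBed <- function(gr, path) {
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene coordinate table
#'
#' Tab-delimited with header `gene_id chrom start end strand`; `start`/`end`
#' are the 1-based inclusive transcript span.
#'
#' @param path path to the gene table.
#' @return A `GRanges` with `gene_id` metadata column.
#' @export
readGeneTable <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$start > tab$end)) stop("gene with start > end in ", path)
  gr <- GRanges(as.character(tab$chrom),
                IRanges(tab$start, tab$end), strand = tab$strand)
  mcols(gr)$gene_id <- as.character(tab$gene_id)
  names(gr) <- tab$gene_id
  gr
}

#' Write a gene coordinate table
#'
#' @param genes a `GRanges` with `gene_id` metadata column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  tab <- data.frame(gene_id = mcols(genes)$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(genes)),
                    start = GenomicRanges::start(genes),
                    end = GenomicRanges::end(genes),
                    strand = as.character(GenomicRanges::strand(genes)))
  tab$strand[tab$strand == "*"] <- "+"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix
#'
#' Tab-delimited, genes in rows (first column `gene_id`), samples in columns.
#'
#' @param path file path.
#' @return `readExpression`: numeric matrix, genes x samples.
#' @export
readExpression <- function(path) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpression
#' @param expr genes x samples numeric matrix with rownames.
#' @export
writeExpression <- function(expr, path) {
  tab <- data.frame(gene_id = rownames(expr),
                    as.data.frame(signif(expr, 10), check.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

strandAmbiguous <- function(a1, a2) {
  p <- paste0(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  p %in% c("AT", "CG")
}

#' Harmonize GWAS z-scores onto a model's SNPs and alleles
#'
#' Matches by SNP id. When the GWAS effect/other alleles match the model's,
#' z is taken as is; when they are swapped the sign of z is flipped.
#' Strand-ambiguous SNPs (A/T, C/G) and allele mismatches are dropped.
#'
#' @param modelSnps DataFrame/data.frame of model SNPs (`id`, `a1`, `a2`).
#' @param gwas a [GwasSummary-class].
#' @return list with `z` (aligned z per retained model SNP), `kept`
#'   (indices into `modelSnps`), `flipped` (logical per retained SNP) and
#'   `nDropped`.
#' @export
harmonizeAlleles <- function(modelSnps, gwas) {
  modelSnps <- as.data.frame(modelSnps)
  if (!nrow(modelSnps)) stop("empty model SNP list")
  gs <- as.data.frame(snpInfo(gwas))
  hit <- match(modelSnps$id, gs$id)
  keep <- !is.na(hit)
  ma1 <- toupper(modelSnps$a1); ma2 <- toupper(modelSnps$a2)
  ga1 <- toupper(gs$a1[hit]);   ga2 <- toupper(gs$a2[hit])
  same <- keep & ma1 == ga1 & ma2 == ga2
  swap <- keep & ma1 == ga2 & ma2 == ga1
  ambig <- keep & (strandAmbiguous(ma1, ma2) | strandAmbiguous(ga1, ga2))
  ok <- (same | swap) & !ambig
  if (!any(ok)) stop("no model SNPs could be harmonized with the GWAS")
  z <- zScores(gwas)[hit[ok]]
  z[swap[ok]] <- -z[swap[ok]]
  list(z = z, kept = which(ok), flipped = swap[ok],
       nDropped = nrow(modelSnps) - sum(ok))
}

## ---- weight store: per-gene TSV + JSON sidecar -------------------------

modelStem <- function(m) paste0(m@geneId, ".", m@tissue)

#' Persist expression weight models
#'
#' Each model is stored as `<gene>.<tissue>.wgt.tsv` (columns snp, chrom,
#' pos, a1, a2, weight, full precision) plus a JSON sidecar with the
#' training metadata, and a `manifest.json` indexes the store.
#'
#' @param models list of [WeightModel-class] objects.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeWeights <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stems <- vapply(models, modelStem, character(1))
  for (i in seq_along(models)) {
    m <- models[[i]]
    s <- as.data.frame(modelSnps(m))
    tab <- data.frame(snp = s$id, chrom = s$chrom, pos = s$pos,
                      a1 = s$a1, a2 = s$a2,
                      weight = sprintf("%.17g", modelWeights(m)))
    write.table(tab, file.path(dir, paste0(stems[i], ".wgt.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(gene_id = m@geneId, tissue = m@tissue, method = m@method,
                 eqtl_p_threshold = m@eqtlPThreshold,
                 annotation_filter = m@annotationFilter,
                 cv_r2 = m@cvR2, cis_h2 = m@cisH2, cis_h2_se = m@cisH2Se)
    jsonlite::write_json(meta, file.path(dir, paste0(stems[i], ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  jsonlite::write_json(list(models = as.list(stems)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load expression weight models from a store
#'
#' @param dir directory written by [writeWeights()].
#' @return list of [WeightModel-class] objects.
#' @export
readWeights <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  lapply(man$models, function(stem) {
    meta <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                                simplifyVector = TRUE)
    num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    meta$cv_r2 <- num(meta$cv_r2)
    meta$cis_h2 <- num(meta$cis_h2)
    meta$cis_h2_se <- num(meta$cis_h2_se)
    tab <- read.table(file.path(dir, paste0(stem, ".wgt.tsv")),
                      header = TRUE, stringsAsFactors = FALSE,
                      colClasses = c(weight = "numeric"))
    if (!identical(paste0(meta$gene_id, ".", meta$tissue), stem))
      stop("weight store integrity error: metadata gene '", meta$gene_id,
           "' does not match file stem '", stem, "'")
    WeightModel(geneId = meta$gene_id, tissue = meta$tissue,
                snps = data.frame(id = tab$snp, chrom = as.character(tab$chrom),
                                  pos = tab$pos, a1 = tab$a1, a2 = tab$a2),
                weights = tab$weight, method = meta$method,
                eqtlPThreshold = meta$eqtl_p_threshold,
                annotationFilter = meta$annotation_filter,
                cvR2 = meta$cv_r2, cisH2 = meta$cis_h2,
                cisH2Se = meta$cis_h2_se)
  })
}
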
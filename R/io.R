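# Bundle I/O: variant evidence as a multi-sample VCF v4.2 (FORMAT
# GT:DP:AD:F1R2:F2R1, AD as ref,alt; INFO carries GENE/HGVSP/CSQ/CONTEXT),
# mCA calls and phenotypes as TSV, truth as JSON. Files round-trip
# losslessly through the paired readers.

DATE_COLS <- c("cancer_dx_date", "recruit_date", "incident_cvd_date",
               "incident_cad_date", "cv_death_date", "cad_death_date",
               "death_date", "hem_cancer_dx_date")

#' Write a cohort bundle to a directory
#'
#' @param bundle A `cohort_bundle` from [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named vector of the file paths written:
#'   `variant_evidence.vcf.gz`, `phenotypes.tsv`, `mca_calls.tsv`,
#'   `truth.json`.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- c(vcf = file.path(out_dir, "variant_evidence.vcf.gz"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"),
             mca = file.path(out_dir, "mca_calls.tsv"),
             truth = file.path(out_dir, "truth.json"))
  write_evidence_vcf(bundle$variant_evidence, paths["vcf"])
  write_phenotypes(bundle$participants, paths["phenotypes"])
  utils::write.table(bundle$mca_calls, paths["mca"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$end_date <- as.character(truth$end_date)
  truth$hazard <- unclass(truth$hazard)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

write_phenotypes <- function(participants, path) {
  out <- participants
  for (cl in intersect(DATE_COLS, names(out))) {
    out[[cl]] <- as.character(out[[cl]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Read a phenotype table
#'
#' @param path `phenotypes.tsv` written by [write_bundle()] (dates
#'   ISO-8601, empty string for missing).
#' @return Data frame with date columns parsed.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                          colClasses = c(participant_id = "character"))
  for (cl in intersect(DATE_COLS, names(df))) {
    df[[cl]] <- as.Date(df[[cl]])
  }
  if ("genotypic_sex_concordant" %in% names(df)) {
    df$genotypic_sex_concordant <- as.logical(df$genotypic_sex_concordant)
  }
  df
}

#' Read an mCA call table
#'
#' @param path `mca_calls.tsv` with columns `participant_id`, `chrom`,
#'   `event_type`, `cell_fraction`.
#' @return Data frame.
#' @export
read_mca_calls <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(participant_id = "character",
                                   chrom = "character"))
}

write_evidence_vcf <- function(evidence, path) {
  ord <- order(evidence$chrom, evidence$pos, evidence$ref, evidence$alt)
  evidence <- evidence[ord, , drop = FALSE]
  vkey <- paste(evidence$chrom, evidence$pos, evidence$ref, evidence$alt,
                sep = ":")
  uv <- !duplicated(vkey)
  vars <- evidence[uv, , drop = FALSE]
  samples <- sort(unique(evidence$participant_id))

  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=chcv synthetic cohort generator",
    sprintf("##contig=<ID=%s>", unique(vars$chrom)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein change\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CONTEXT,Number=1,Type=String,Description=\"Reference context, variant at centre\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt allele depths\">",
    "##FORMAT=<ID=F1R2,Number=1,Type=Integer,Description=\"Alt F1R2 read-pair depth\">",
    "##FORMAT=<ID=F2R1,Number=1,Type=Integer,Description=\"Alt F2R1 read-pair depth\">")

  fix <- cbind(CHROM = vars$chrom, POS = as.character(vars$pos),
               ID = rep(".", nrow(vars)), REF = vars$ref, ALT = vars$alt,
               QUAL = rep(".", nrow(vars)), FILTER = rep("PASS", nrow(vars)),
               INFO = sprintf("GENE=%s;HGVSP=%s;CSQ=%s;CONTEXT=%s",
                              vars$gene, vars$hgvs_p, vars$consequence,
                              vars$context))

  gt <- matrix("./.:.:.:.:.", nrow = nrow(vars), ncol = length(samples) + 1,
               dimnames = list(NULL, c("FORMAT", samples)))
  gt[, "FORMAT"] <- "GT:DP:AD:F1R2:F2R1"
  ri <- match(paste(evidence$chrom, evidence$pos, evidence$ref, evidence$alt,
                    sep = ":"), vkey[uv])
  ci <- match(evidence$participant_id, samples) + 1L
  gt[cbind(ri, ci)] <- sprintf("0/1:%d:%d,%d:%d:%d", evidence$dp,
                               evidence$dp - evidence$ad, evidence$ad,
                               evidence$f1r2, evidence$f2r1)

  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read variant evidence from a VCF
#'
#' Parses a (possibly multi-sample) VCF v4.2 with FORMAT
#' `GT:DP:AD:F1R2:F2R1` and INFO tags `GENE`, `HGVSP`, `CSQ`, `CONTEXT`
#' into the variant-evidence data frame consumed by [call_chip()]. One
#' row is emitted per non-missing sample-variant cell.
#'
#' @param path VCF path (plain or bgzip/gzip).
#' @return Variant-evidence data frame
#'   (see [validate_variant_evidence()]).
#' @export
read_variant_evidence <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- evidence_row(character(0), character(0), character(0),
                        character(0), integer(0), integer(0), integer(0),
                        integer(0), character(0))
  if (nrow(v@fix) == 0) return(empty)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- data.frame(
    gene = vcfR::extract.info(v, "GENE"),
    hgvs_p = vcfR::extract.info(v, "HGVSP"),
    consequence = vcfR::extract.info(v, "CSQ"),
    context = vcfR::extract.info(v, "CONTEXT"),
    stringsAsFactors = FALSE)
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad_alt <- vcfR::extract.gt(v, "AD")
  f1r2 <- vcfR::extract.gt(v, "F1R2", as.numeric = TRUE)
  f2r1 <- vcfR::extract.gt(v, "F2R1", as.numeric = TRUE)
  cells <- which(!is.na(dp), arr.ind = TRUE)
  if (nrow(cells) == 0) return(empty)
  ri <- cells[, 1]; ci <- cells[, 2]
  ad <- as.integer(vapply(strsplit(ad_alt[cells], ",", fixed = TRUE),
                          `[`, character(1), 2))
  out <- data.frame(
    participant_id = colnames(dp)[ci],
    gene = info$gene[ri], hgvs_p = info$hgvs_p[ri],
    chrom = fix$CHROM[ri], pos = as.integer(fix$POS[ri]),
    ref = fix$REF[ri], alt = fix$ALT[ri],
    dp = as.integer(dp[cells]), ad = ad,
    f1r2 = as.integer(f1r2[cells]), f2r1 = as.integer(f2r1[cells]),
    context = info$context[ri], consequence = info$consequence[ri],
    stringsAsFactors = FALSE)
  out$vaf <- out$ad / out$dp
  out <- out[order(out$participant_id, out$chrom, out$pos, out$ref,
                   out$alt), ]
  rownames(out) <- NULL
  out[, names(empty)]
}

#' Read a cohort bundle back from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return List with `participants`, `variant_evidence`, `mca_calls`,
#'   `truth`.
#' @export
read_bundle <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(participants = read_phenotypes(file.path(dir, "phenotypes.tsv")),
       variant_evidence = read_variant_evidence(
         file.path(dir, "variant_evidence.vcf.gz")),
       mca_calls = read_mca_calls(file.path(dir, "mca_calls.tsv")),
       truth = truth)
}
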
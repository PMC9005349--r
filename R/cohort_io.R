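# Plain-text interchange for simulated cohorts: a PLINK RAW-style dosage
# table, a FAM-style pedigree file, a phenotype table and the trait
# architecture. All files are tab-separated; missing genotypes are the "NA"
# token.

#' Write a cohort to a directory of plain-text files
#'
#' Emits `cohort.raw` (header `FID IID PAT MAT SEX PHENOTYPE` followed by one
#' `<snp>_<A1>` dosage column per SNP), `cohort.fam` (`FID IID PAT MAT SEX
#' PHENO`), `phenotypes.tsv` (per-individual phenotype, generation, roles) and
#' `architecture.tsv` (per-SNP truth: alleles, frequency, additive and
#' dominance effects, LD block). The files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param directory output directory (created if absent).
#' @param a1,a2 allele labels used for every SNP in the output dialect.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, directory, a1 = "A", a2 = "G") {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort$ped) > 0)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) stop("cannot create ", directory)
  }
  ped <- cohort$ped
  fid <- ifelse(is.na(ped$sibship_id), "FOUNDER", ped$sibship_id)
  sex_code <- ifelse(ped$sex == "M", 1L, 2L)
  pat <- ifelse(is.na(ped$father_id), "0", ped$father_id)
  mat <- ifelse(is.na(ped$mother_id), "0", ped$mother_id)

  raw <- data.frame(FID = fid, IID = ped$id, PAT = pat, MAT = mat,
                    SEX = sex_code, PHENOTYPE = ped$y,
                    check.names = FALSE, stringsAsFactors = FALSE)
  gm <- as.data.frame(cohort$geno)
  names(gm) <- paste0(colnames(cohort$geno), "_", a1)
  raw <- cbind(raw, gm)

  paths <- c(raw = file.path(directory, "cohort.raw"),
             fam = file.path(directory, "cohort.fam"),
             pheno = file.path(directory, "phenotypes.tsv"),
             arch = file.path(directory, "architecture.tsv"))

  utils::write.table(raw, paths["raw"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(
    data.frame(FID = fid, IID = ped$id, PAT = pat, MAT = mat, SEX = sex_code,
               PHENO = ped$y),
    paths["fam"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    ped[, c("id", "sex", "generation", "subpop", "F", "y", "gv_add",
            "gv_dom", "latent", "sibship_id")],
    paths["pheno"], sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  ar <- cohort$architecture
  utils::write.table(
    data.frame(SNP = ar$snp_id, A1 = a1, A2 = a2, FREQ = ar$freq,
               BETA_ADD = ar$beta_add, DELTA_DOM = ar$delta_dom,
               BLOCK = ar$block, ETA = ar$eta),
    paths["arch"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a PLINK RAW-style dosage table
#'
#' @param path path to a `.raw` file written by [write_cohort()] (or any
#'   RAW-dialect file with the `FID IID PAT MAT SEX PHENOTYPE` preamble).
#' @return List with `meta` (the six preamble columns) and `geno` (numeric
#'   dosage matrix, rownames = IID, colnames = SNP ids with the allele suffix
#'   stripped, attribute `effect_allele` holding the suffix alleles).
#' @export
read_raw <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  pre <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  stopifnot(identical(names(d)[1:6], pre))
  geno <- as.matrix(d[, -(1:6), drop = FALSE])
  snp_cols <- colnames(geno)
  a1 <- sub("^.*_", "", snp_cols)
  colnames(geno) <- sub("_[^_]*$", "", snp_cols)
  rownames(geno) <- d$IID
  attr(geno, "effect_allele") <- a1
  list(meta = d[, pre], geno = geno)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory the directory passed to [write_cohort()].
#' @return A list with `ped`, `geno` and `architecture` mirroring the
#'   corresponding fields of the simulated cohort.
#' @export
read_cohort <- function(directory) {
  raw <- read_raw(file.path(directory, "cohort.raw"))
  pheno <- utils::read.table(file.path(directory, "phenotypes.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  ar <- utils::read.table(file.path(directory, "architecture.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ped <- data.frame(
    id = raw$meta$IID,
    sex = ifelse(raw$meta$SEX == 1L, "M", "F"),
    father_id = ifelse(raw$meta$PAT == "0", NA_character_, raw$meta$PAT),
    mother_id = ifelse(raw$meta$MAT == "0", NA_character_, raw$meta$MAT),
    stringsAsFactors = FALSE)
  ped <- cbind(ped, pheno[match(ped$id, pheno$id),
                          setdiff(names(pheno), c("id", "sex"))])
  rownames(ped) <- NULL
  arch <- structure(
    list(beta_add = ar$BETA_ADD, delta_dom = ar$DELTA_DOM, eta = ar$ETA[1],
         freq = ar$FREQ, block = ar$BLOCK, snp_id = ar$SNP),
    class = "trait_architecture")
  list(ped = ped, geno = raw$geno, architecture = arch)
}
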
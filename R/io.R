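#' Read or write genotypes in a PLINK-RAW-style table
#'
#' The written layout matches PLINK's `--recode A` output: a header line
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one 0/1/2 column per marker,
#' space-delimited. `read_genotypes()` also accepts plain tables that start
#' directly with marker columns (the first non-meta columns are detected by
#' name).
#'
#' @param path File path.
#' @return `read_genotypes()` returns an integer matrix (animals x markers)
#'   with ids as row names, suitable for [build_grm()].
#' @export
read_genotypes <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(tab))
  ids <- if ("IID" %in% meta) as.character(tab$IID) else
    as.character(seq_len(nrow(tab)))
  geno <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  storage.mode(geno) <- "integer"
  if (anyNA(geno) || !all(geno %in% 0:2))
    stop("genotype file must contain complete 0/1/2 allele counts",
         call. = FALSE)
  rownames(geno) <- ids
  geno
}

#' @param x A `sim_population` or a 0/1/2 genotype matrix with ids as row
#'   names.
#' @rdname read_genotypes
#' @export
write_genotypes <- function(x, path) {
  if (inherits(x, "sim_population")) {
    geno <- x$genotypes
    a <- x$animals[match(rownames(geno), x$animals$id), ]
    meta <- data.frame(FID = 0L, IID = rownames(geno),
                       PAT = ifelse(is.na(a$sire), "0", a$sire),
                       MAT = ifelse(is.na(a$dam), "0", a$dam),
                       SEX = ifelse(is.na(a$sex), 0L,
                                    ifelse(a$sex == "M", 1L, 2L)),
                       PHENOTYPE = ifelse(is.na(a$phenotype), -9,
                                          a$phenotype))
  } else {
    geno <- as.matrix(x)
    ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
    meta <- data.frame(FID = 0L, IID = ids, PAT = "0", MAT = "0", SEX = 0L,
                       PHENOTYPE = -9)
  }
  write.table(cbind(meta, as.data.frame(geno)), path, quote = FALSE,
              row.names = FALSE, sep = " ")
  invisible(path)
}

#' Write a simulated population to delimited files
#'
#' Emits `genotypes.raw` (PLINK-RAW-style), `pedigree.tsv` (id, sire, dam,
#' generation), `phenotypes.tsv` (id, generation, role, tbv, phenotype) and
#' `map.tsv` (marker id, chromosome, position in cM) into a directory.
#'
#' @param pop A `sim_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(pop, file.path(dir, "genotypes.raw"))
  ped <- pop$animals[, c("id", "sire", "dam", "generation")]
  write.table(ped, file.path(dir, "pedigree.tsv"), quote = FALSE,
              row.names = FALSE, sep = "\t")
  phe <- pop$animals[, c("id", "generation", "role", "tbv", "phenotype")]
  write.table(phe, file.path(dir, "phenotypes.tsv"), quote = FALSE,
              row.names = FALSE, sep = "\t")
  write.table(pop$map, file.path(dir, "map.tsv"), quote = FALSE,
              row.names = FALSE, sep = "\t")
  invisible(dir)
}
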
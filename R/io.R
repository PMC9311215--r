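#' Read a VCF into a genotype matrix
#'
#' Biallelic SNP records are encoded as alternate-allele dosage (0/1/2);
#' multiallelic records are skipped with a message reporting the count.
#' Tag identifiers are taken from the CHROM field (de-novo SNP callers emit
#' one tag per pseudo-contig); when CHROM is constant and the ID field is
#' populated, the ID prefix before the last `_`, `:` or `.` separator is
#' used instead.
#'
#' @param path Path to a VCF (v4.x, plain text or bgzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF ", path, ": ", conditionMessage(e)))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1 & nchar(ref) == 1
  n_skip <- sum(!biallelic)
  if (n_skip > 0) {
    inform(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s).", n_skip))
  }
  if (!any(biallelic)) abort(paste0("no usable biallelic SNP records in ", path))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]

  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  # count alt alleles in the GT string; works for phased and unphased calls
  clean <- gsub("[^01.]", "", gt)
  dosage[clean == "00"] <- 0L
  dosage[clean %in% c("01", "10")] <- 1L
  dosage[clean == "11"] <- 2L

  locus_ids <- fix[, "ID"]
  no_id <- is.na(locus_ids) | locus_ids == "."
  locus_ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  if (anyDuplicated(locus_ids)) {
    locus_ids <- make.unique(locus_ids, sep = "_dup")
  }

  tag_ids <- fix[, "CHROM"]
  if (length(unique(tag_ids)) == 1 && !all(no_id)) {
    tag_ids <- sub("[_:.][^_:.]*$", "", fix[, "ID"])
  }

  genotype_matrix(
    t(dosage),
    locus_ids = locus_ids,
    tag_ids = tag_ids,
    individual_ids = colnames(gt)
  )
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits one biallelic record per locus with CHROM = tag id and placeholder
#' REF/ALT alleles; `read_vcf(write_vcf(g, f))` reproduces the dosage matrix.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  geno <- g$genotypes
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(geno)), function(j) {
    calls <- gt_code[as.character(geno[, j])]
    calls[is.na(calls)] <- "./."
    pos <- sum(g$tag_ids[seq_len(j)] == g$tag_ids[j]) # index within tag
    paste(c(g$tag_ids[j], pos, g$locus_ids[j], "A", "T", ".", "PASS", ".",
            "GT", calls), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$individual_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a population map
#'
#' Expects a 2- or 3-column tab-separated file: individual, population and
#' optionally group/clade (each population is its own group when absent).
#'
#' @param path Path to the TSV (a header is optional and auto-detected from
#'   the column names `individual_id`/`individual`).
#' @return A tibble as built by [population_map()].
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) abort(paste0("population map not found: ", path))
  first <- readLines(path, n = 1)
  has_header <- grepl("individual", strsplit(first, "\t")[[1]][1], ignore.case = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           colClasses = "character")
  if (ncol(tab) < 2) abort("population map needs at least 2 columns.")
  population_map(tab[[1]], tab[[2]], if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' Read an environment table
#'
#' CSV with a population key column (first column, or one named
#' `population_id`) and numeric variables.
#'
#' @param path Path to the CSV.
#' @return A tibble with `population_id` first and numeric variable columns.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path)) abort(paste0("environment table not found: ", path))
  env <- readr::read_csv(path, show_col_types = FALSE)
  key <- if ("population_id" %in% names(env)) "population_id" else names(env)[1]
  env <- dplyr::relocate(dplyr::rename(env, population_id = !!key),
                         "population_id")
  env$population_id <- as.character(env$population_id)
  not_num <- names(env)[-1][!vapply(env[-1], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0("non-numeric environment variable(s): ",
                 paste(not_num, collapse = ", ")))
  }
  env
}

#' Write a results table as TSV
#'
#' @param table A non-empty data frame (scan table, GEA table or candidate
#'   set). Written tab-separated with a header; numeric columns keep full
#'   precision (q-values round-trip to at least 1e-6).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("write_results: table is empty; nothing written.")
  }
  readr::write_tsv(table, path)
  invisible(path)
}
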
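#' @importFrom stats cor cor.test median sd quantile qnorm pnorm pchisq qchisq
#'   phyper p.adjust lm glm binomial anova rnorm rbinom runif shapiro.test
#'   wilcox.test t.test complete.cases coef resid fitted pt setNames na.omit
#' @importFrom utils read.delim write.table head
NULL

# ---- constructors and validators ------------------------------------------

#' Construct a genotype matrix object
#'
#' Holds biallelic SNP calls as alternate-allele counts (0/1/2, NA = missing)
#' for a set of samples, together with per-SNP metadata.
#'
#' @param calls numeric matrix, samples x SNPs, values in \{0,1,2,NA\};
#'   rownames are sample ids, colnames SNP ids.
#' @param snp_meta data.frame with one row per SNP: columns `snp_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, optional `gene`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp_meta = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("calls must have sample ids as rownames and SNP ids as colnames")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate SNP ids")
  bad <- which(!is.na(calls) & !(calls %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid genotype call %s at sample '%s', SNP '%s'",
                 format(calls[bad[1, , drop = FALSE]]),
                 rownames(calls)[bad[1, 1]], colnames(calls)[bad[1, 2]]))
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(snp_id = colnames(calls), chrom = NA_character_,
                           pos = NA_integer_, ref = NA_character_,
                           alt = NA_character_, gene = NA_character_,
                           stringsAsFactors = FALSE)
  } else {
    snp_meta <- as.data.frame(snp_meta)
    if (!"snp_id" %in% names(snp_meta)) stop("snp_meta needs a snp_id column")
    if (!setequal(snp_meta$snp_id, colnames(calls)))
      stop("snp_meta snp_ids do not match call matrix columns")
    snp_meta <- snp_meta[match(colnames(calls), snp_meta$snp_id), , drop = FALSE]
    if ("pos" %in% names(snp_meta) &&
        any(!is.na(snp_meta$pos) & snp_meta$pos < 1))
      stop("SNP positions must be >= 1")
    rownames(snp_meta) <- NULL
  }
  structure(list(calls = calls, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' Construct an expression matrix object
#'
#' @param values numeric matrix, probes x samples, log2 scale; rownames are
#'   probe ids, colnames sample ids. NA allowed before imputation.
#' @param probe_meta data.frame with `probe_id` and optional `gene`, `chrom`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_meta = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (is.null(probe_meta)) {
    probe_meta <- data.frame(probe_id = rownames(values),
                             gene = NA_character_, chrom = NA_character_,
                             stringsAsFactors = FALSE)
  } else {
    probe_meta <- as.data.frame(probe_meta)
    if (!"probe_id" %in% names(probe_meta)) stop("probe_meta needs probe_id")
    probe_meta <- probe_meta[match(rownames(values), probe_meta$probe_id), ,
                             drop = FALSE]
    probe_meta$probe_id <- rownames(values)
    rownames(probe_meta) <- NULL
  }
  structure(list(values = values, probe_meta = probe_meta),
            class = "expression_matrix")
}

#' Construct a phenotype table
#'
#' Derives the binary malignancy stage from the WHO grade: grade I tumors are
#' stage 0 (lowly malignant), grades II and III are stage 1 (malignant).
#'
#' @param df data.frame with `sample_id`, `who_grade` in \{1,2,3\} and any
#'   optional clinical trait columns.
#' @return data.frame of class `phenotype_table` with a `stage_binary` column.
#' @export
phenotype_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("sample_id", "who_grade") %in% names(df)))
    stop("phenotype table needs sample_id and who_grade columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (any(!df$who_grade %in% c(1, 2, 3)))
    stop("who_grade outside {1,2,3}: ",
         paste(df$sample_id[!df$who_grade %in% c(1, 2, 3)], collapse = ", "))
  df$stage_binary <- as.integer(df$who_grade != 1)
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%.2f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

# ---- readers ---------------------------------------------------------------

.read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
             na.strings = c("NA", "na", "Na", "nA", ""))
}

#' Read a genotype matrix from disk
#'
#' Two formats are supported: `tsv_dosage` (header row of SNP ids, first
#' column `sample_id`, cells 0/1/2/NA) and a minimal biallelic `vcf` (v4.x,
#' GT field; "0/0" -> 0, "0/1"/"1/0" -> 1, "1/1" -> 2, "./." -> missing).
#' Multi-allelic VCF records are rejected with their coordinates.
#'
#' @param path file path.
#' @param format "tsv_dosage" or "vcf".
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv_dosage", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv_dosage") {
    df <- .read_tsv(path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!is.na(m) & !(m %in% c(0, 1, 2)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("invalid dosage '%s' at sample '%s', SNP '%s'",
                   m[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                   colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "double"
    rownames(m) <- ids
    genotype_matrix(m)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      i <- which(multi)[1]
      stop(sprintf("multi-allelic VCF record at %s:%s (%s)",
                   fix$CHROM[i], fix$POS[i], fix$ID[i]))
    }
    gt <- vcfR::extract.gt(vcf, element = "GT")
    map <- c("0/0" = 0, "0|0" = 0, "0/1" = 1, "1/0" = 1, "0|1" = 1,
             "1|0" = 1, "1/1" = 2, "1|1" = 2)
    calls <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                    dimnames = list(colnames(gt), rownames(gt)))
    for (j in seq_len(nrow(gt))) {
      g <- gt[j, ]
      known <- g %in% names(map)
      calls[known, j] <- map[g[known]]
      odd <- !known & !is.na(g) & !g %in% c("./.", ".|.", ".")
      if (any(odd))
        stop(sprintf("unsupported GT '%s' at %s:%s", g[odd][1],
                     fix$CHROM[j], fix$POS[j]))
    }
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <-
      paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
    colnames(calls) <- ids
    meta <- data.frame(snp_id = ids, chrom = fix$CHROM,
                       pos = as.integer(fix$POS), ref = fix$REF,
                       alt = fix$ALT, gene = NA_character_,
                       stringsAsFactors = FALSE)
    genotype_matrix(calls, meta)
  }
}

#' Read an expression matrix (TSV, first column probe_id)
#'
#' @param path TSV file; header = sample ids, numeric or NA cells.
#' @param annot_path optional sidecar TSV of probe annotations (columns
#'   `probe_id` and e.g. `gene`, `chrom`), merged by probe id.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, annot_path = NULL) {
  df <- .read_tsv(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate probe_id: ", ids[duplicated(ids)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!is.na(m) & is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
    stop(sprintf("non-numeric expression cell at probe '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  meta <- NULL
  if (!is.null(annot_path)) {
    ann <- .read_tsv(annot_path)
    meta <- merge(data.frame(probe_id = ids, stringsAsFactors = FALSE),
                  ann, by = "probe_id", all.x = TRUE, sort = FALSE)
  }
  expression_matrix(m, meta)
}

#' Read a phenotype table (TSV with sample_id and who_grade)
#' @param path TSV file.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) phenotype_table(.read_tsv(path))

#' Read gene-set collections from a GMT file
#'
#' @param path GMT file: term, description, then tab-separated gene symbols.
#' @return named list of class `gene_set_collection`; each element has
#'   `description` and `genes`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (length(genes) == 0)
      stop("empty gene set in GMT: ", parts[1])
    if (parts[1] %in% names(sets)) stop("duplicate term id: ", parts[1])
    sets[[parts[1]]] <- list(description = parts[2], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' Read an undirected PPI edge list (two-column TSV)
#'
#' Deduplicates unordered pairs and drops self-loops.
#' @param path two-column TSV of gene symbols, no header required.
#' @return data.frame of class `ppi_edge_list` with columns `a`, `b`.
#' @export
read_ppi <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  ppi_edge_list(df[[1]], df[[2]])
}

#' Build a PPI edge list from two gene vectors
#' @param a,b character vectors of equal length (edge endpoints).
#' @return data.frame of class `ppi_edge_list`.
#' @export
ppi_edge_list <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  keep <- a != b
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  key <- paste(lo, hi, sep = "\r")
  d <- !duplicated(key)
  out <- data.frame(a = lo[d], b = hi[d], stringsAsFactors = FALSE)
  class(out) <- c("ppi_edge_list", "data.frame")
  out
}

# ---- writers (mirror the readers) -----------------------------------------

#' Write a genotype matrix as a TSV dosage file
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(sample_id = rownames(geno$calls), geno$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probe_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype table as TSV
#' @param pheno a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- cohort alignment ------------------------------------------------------

#' Restrict genotype, expression and phenotype data to shared samples
#'
#' Keeps the intersection of sample ids across the three layers and puts all
#' of them in the same sample order. Idempotent.
#'
#' @param geno [genotype_matrix()].
#' @param expr [expression_matrix()].
#' @param pheno [phenotype_table()].
#' @return list with elements `geno`, `expr`, `pheno`.
#' @export
align_cohort <- function(geno, expr, pheno) {
  common <- intersect(intersect(rownames(geno$calls), colnames(expr$values)),
                      pheno$sample_id)
  if (length(common) == 0) stop("no samples shared across the three layers")
  common <- sort(common)
  geno$calls <- geno$calls[common, , drop = FALSE]
  expr$values <- expr$values[, common, drop = FALSE]
  pheno <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  list(geno = geno, expr = expr, pheno = pheno)
}
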
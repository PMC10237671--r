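#' Dosage matrices with variant metadata
#'
#' A `dosage_set` couples an individuals-by-variants dosage matrix with the
#' variant records needed for scoring: variant ID, position and the allele
#' whose copies the dosage counts. Dosages are continuous in `[0, 2]`
#' (hard-called genotypes are the integer special case).
#'
#' @param dosages Numeric matrix, rows = samples, columns = variants;
#'   `colnames` are variant IDs and `rownames` sample IDs.
#' @param variants Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `counted_allele`.
#' @return Object of class `dosage_set`.
#' @export
dosage_set <- function(dosages, variants) {
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "counted_allele")
  if (!all(req %in% names(variants))) {
    stop("`variants` needs columns: ", paste(req, collapse = ", "))
  }
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$variant_id
  if (!identical(colnames(dosages), as.character(variants$variant_id))) {
    stop("dosage columns and variant records disagree")
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%05d", seq_len(nrow(dosages)))
  }
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants,
                                          stringsAsFactors = FALSE)),
            class = "dosage_set")
}

#' @export
print.dosage_set <- function(x, ...) {
  cat("<dosage_set>", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants\n")
  invisible(x)
}

#' Read and write tabular dosages
#'
#' The tabular layout is a pair of tab-separated files: `<stem>.dosage.tsv`
#' (a `sample_id` column followed by one numeric column per variant) and
#' `<stem>.variants.tsv` (the variant metadata).
#'
#' @param ds A [dosage_set()].
#' @param stem Output path stem.
#' @return `write_dosage_tsv` invisibly returns the two paths;
#'   `read_dosage_tsv` returns a [dosage_set()].
#' @export
write_dosage_tsv <- function(ds, stem) {
  stopifnot(inherits(ds, "dosage_set"))
  dpath <- paste0(stem, ".dosage.tsv")
  vpath <- paste0(stem, ".variants.tsv")
  df <- data.frame(sample_id = rownames(ds$dosages), ds$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, dpath, sep = "\t")
  data.table::fwrite(ds$variants, vpath, sep = "\t")
  invisible(c(dpath, vpath))
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(stem) {
  dpath <- paste0(stem, ".dosage.tsv")
  vpath <- paste0(stem, ".variants.tsv")
  df <- as.data.frame(data.table::fread(dpath, header = TRUE),
                      check.names = FALSE)
  variants <- as.data.frame(data.table::fread(vpath, header = TRUE))
  variants$chrom <- as.character(variants$chrom)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  dosage_set(m, variants)
}

#' Write a minimal VCF carrying dosages in the DS FORMAT field
#'
#' One sample column per individual, genotypes omitted (`GT` set to `./.`),
#' dosage of the ALT allele in `DS`. 1-based positions, VCFv4.2 header.
#'
#' @param ds A [dosage_set()]; `counted_allele` must equal `alt` (the VCF DS
#'   convention counts ALT copies).
#' @param path Output path (`.vcf`, uncompressed).
#' @return Invisibly, `path`.
#' @export
write_dosage_vcf <- function(ds, path) {
  stopifnot(inherits(ds, "dosage_set"))
  if (!all(ds$variants$counted_allele == ds$variants$alt)) {
    stop("VCF DS output requires counted_allele == alt")
  }
  v <- ds$variants
  samples <- rownames(ds$dosages)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,Description=",
           "\"Dosage of the ALT allele\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT:DS",
            paste0("./.:", format(ds$dosages[, i], trim = TRUE))),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Uses the vcfR parser; the counted allele is ALT.
#'
#' @param path VCF path.
#' @return A [dosage_set()].
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, counted_allele = fix$ALT,
                         stringsAsFactors = FALSE)
  m <- t(ds)
  colnames(m) <- variants$variant_id
  dosage_set(m, variants)
}

#' Write phenotype/covariate tables
#'
#' Tab-separated with a `sample_id` column.
#'
#' @param df Data frame with a `sample_id` column.
#' @param path Output path.
#' @export
write_sample_table <- function(df, path) {
  stopifnot("sample_id" %in% names(df))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!"sample_id" %in% names(df)) stop("missing sample_id column")
  df$sample_id <- as.character(df$sample_id)
  df
}
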
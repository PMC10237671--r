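#' Per-gene expression weight sets
#'
#' A `weight_set` holds the linear expression models ("local polygenic
#' scores") used to impute gene expression: for every gene, the variants
#' with non-zero weight, the allele whose dosage the weight multiplies, and
#' the gene's genomic coordinates (chromosome, midpoint and TSS, used by the
#' proximity filter and the SNP follow-up window).
#'
#' @param weights Data frame with columns `gene_id`, `variant_id`,
#'   `effect_allele`, `weight`.
#' @param coords Data frame with columns `gene_id`, `chrom`, and `midpoint`
#'   (or `start`/`end`, from which the midpoint is derived); an optional
#'   `tss` column is kept.
#' @return An object of class `weight_set`.
#' @export
weight_set <- function(weights, coords) {
  req <- c("gene_id", "variant_id", "effect_allele", "weight")
  if (!all(req %in% names(weights))) {
    stop("`weights` needs columns: ", paste(req, collapse = ", "))
  }
  coords <- normalize_coords(coords)
  nz <- weights$weight != 0
  n_dropped <- sum(!nz)
  if (n_dropped > 0) {
    message(n_dropped, " zero-weight entr",
            if (n_dropped == 1) "y" else "ies", " dropped")
  }
  weights <- weights[nz, , drop = FALSE]
  if (nrow(weights) == 0L) stop("no non-zero weight entries")
  dup <- duplicated(weights[, c("gene_id", "variant_id")])
  if (any(dup)) {
    stop("duplicate (gene, variant) weight entries: ",
         paste(utils::head(paste(weights$gene_id[dup],
                                 weights$variant_id[dup], sep = ":"), 3),
               collapse = ", "))
  }
  missing_genes <- setdiff(unique(weights$gene_id), coords$gene_id)
  if (length(missing_genes) > 0) {
    stop("genes absent from coordinate table: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  if (any(coords$midpoint <= 0)) stop("gene midpoints must be positive")
  rownames(weights) <- NULL
  structure(list(weights = weights,
                 coords = coords[coords$gene_id %in% weights$gene_id, ,
                                 drop = FALSE]),
            class = "weight_set")
}

normalize_coords <- function(coords) {
  if (!all(c("gene_id", "chrom") %in% names(coords))) {
    stop("`coords` needs columns gene_id and chrom")
  }
  coords <- as.data.frame(coords, stringsAsFactors = FALSE)
  if (!"midpoint" %in% names(coords)) {
    if (!all(c("start", "end") %in% names(coords))) {
      stop("`coords` needs either midpoint or start/end columns")
    }
    coords$midpoint <- (coords$start + coords$end) / 2
  }
  if (!"tss" %in% names(coords)) {
    coords$tss <- if ("start" %in% names(coords)) coords$start else
      coords$midpoint
  }
  if (anyDuplicated(coords$gene_id)) stop("duplicate gene IDs in `coords`")
  coords$chrom <- as.character(coords$chrom)
  coords
}

#' @export
print.weight_set <- function(x, ...) {
  cat("<weight_set>", length(unique(x$weights$gene_id)), "genes,",
      nrow(x$weights), "weighted variants\n")
  invisible(x)
}

#' Number of weighted variants per gene
#' @param ws A `weight_set`.
#' @return Named integer vector.
#' @export
variant_counts <- function(ws) {
  stopifnot(inherits(ws, "weight_set"))
  tab <- table(ws$weights$gene_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Read expression weights from PLINK-style score files
#'
#' Accepts either a directory of per-gene score files (`<gene>.score`, three
#' whitespace-separated columns: variant ID, effect allele, weight, no
#' header) or a single combined tab-separated file with header columns
#' `gene_id`, `variant_id`, `effect_allele`, `weight`. Zero-weight rows are
#' dropped; genes missing from the coordinate table are an error.
#'
#' @param path Directory of `.score` files or a combined weights TSV.
#' @param coords Gene coordinate table (see [weight_set()]).
#' @return A [weight_set()].
#' @export
read_weights <- function(path, coords) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.score$", full.names = TRUE)
    if (length(files) == 0L) stop("no .score files in ", path)
    parts <- lapply(files, function(f) {
      lines <- readLines(f)
      lines <- lines[nzchar(trimws(lines))]
      fields <- strsplit(trimws(lines), "[ \t]+")
      bad <- which(lengths(fields) != 3L)
      if (length(bad) > 0) {
        stop("malformed score line ", bad[1], " in ", basename(f))
      }
      m <- do.call(rbind, fields)
      w <- suppressWarnings(as.numeric(m[, 3]))
      if (any(is.na(w))) {
        stop("non-numeric weight at line ", which(is.na(w))[1], " in ",
             basename(f))
      }
      data.frame(gene_id = sub("\\.score$", "", basename(f)),
                 variant_id = m[, 1], effect_allele = m[, 2], weight = w,
                 stringsAsFactors = FALSE)
    })
    weights <- do.call(rbind, parts)
  } else {
    weights <- as.data.frame(data.table::fread(path, header = TRUE))
    req <- c("gene_id", "variant_id", "effect_allele", "weight")
    if (!all(req %in% names(weights))) {
      stop("combined weight file needs columns: ",
           paste(req, collapse = ", "))
    }
  }
  weight_set(weights, coords)
}

#' Write a weight set as per-gene PLINK score files
#'
#' @param ws A [weight_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths written.
#' @export
write_score_files <- function(ws, dir) {
  stopifnot(inherits(ws, "weight_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(ws$weights, ws$weights$gene_id), function(df) {
    f <- file.path(dir, paste0(df$gene_id[1], ".score"))
    data.table::fwrite(df[, c("variant_id", "effect_allele", "weight")],
                       f, sep = "\t", col.names = FALSE)
    f
  }, character(1))
  invisible(unname(paths))
}

#' Read a BED-like gene coordinate table
#'
#' Tab-separated with header; requires `gene_id` and `chrom` plus either
#' `midpoint` or `start`/`end`.
#'
#' @param path File path.
#' @return Data frame with `gene_id`, `chrom`, `midpoint`, `tss` (and any
#'   further columns present).
#' @export
read_gene_coords <- function(path) {
  normalize_coords(as.data.frame(data.table::fread(path, header = TRUE)))
}

#' @rdname read_gene_coords
#' @param coords Coordinate data frame.
#' @export
write_gene_coords <- function(coords, path) {
  data.table::fwrite(normalize_coords(coords), path, sep = "\t")
  invisible(path)
}
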
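#' Read an expression matrix from TSV/CSV
#'
#' Canonical layout is genes in rows: first column gene id, remaining columns
#' one per sample, values on the log2(2^-dCt) scale. Missing values are
#' encoded `NA`. Duplicate gene/sample ids, ragged rows and non-numeric cells
#' are parse errors naming the offending row or column.
#'
#' @param path TSV (default) or CSV file; the separator is inferred from the
#'   extension (`.csv` = comma) unless `sep` is given.
#' @param genes_in_rows if `FALSE`, the file is transposed on read.
#' @param sep field separator override.
#' @return numeric matrix, genes x samples, with gene ids as rownames.
#' @export
read_expression <- function(path, genes_in_rows = TRUE, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               colClasses = "character", quote = "\"", comment.char = ""),
    error = function(e) stopf("cannot parse %s: %s", path, conditionMessage(e)))
  if (ncol(df) < 2) stopf("%s: need a gene-id column plus >=1 sample", path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stopf("duplicate gene id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stopf("duplicate sample id(s): %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    cell <- df[[j + 1]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & !(is.na(cell) | cell %in% c("NA", "")))
    if (length(bad))
      stopf("non-numeric value '%s' at gene '%s', sample '%s'",
            cell[bad[1]], ids[bad[1]], samples[j])
    m[, j] <- val
  }
  if (any(is.infinite(m))) stopf("non-finite values in %s", path)
  if (!genes_in_rows) m <- t(m)
  m
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: genes in rows, first column `gene_id`,
#' missing values written as `NA`. `read_expression(write_expression(m))`
#' reproduces `m` bitwise.
#'
#' @param expr gene x sample numeric matrix with dimnames.
#' @param path output path; `.csv` extension switches to comma separation.
#' @export
write_expression <- function(expr, path) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stopf("expression matrix must have gene and sample ids as dimnames")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # %.17g keeps doubles bitwise across the write/read round trip
  chr <- matrix(sprintf("%.17g", expr), nrow(expr))
  chr[is.na(expr)] <- "NA"
  df <- data.frame(gene_id = rownames(expr), chr, check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' CSV with columns `sample_id, patient_id, group, timepoint, pred, cyc, tac,
#' aza, mmf`. Groups are `tolerant`, `stable`, `chronic_rejector`, `healthy`.
#' Drug flags are 0/1 or `NA` (unknown regimen). Records violating the drug
#' constraints (both CNIs, both antiproliferatives, or any drug in a
#' tolerant/healthy subject) are rejected with an error naming the sample.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  validate_metadata(md)
}

#' Write sample metadata to CSV
#' @param metadata validated metadata data frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' @param metadata data frame with the columns described in
#'   [read_metadata()].
#' @return the metadata, invisibly checked (flags coerced to integer).
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "patient_id", "group", "timepoint",
            "pred", "cyc", "tac", "aza", "mmf")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stopf("duplicate sample_id(s): %s",
          paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
                collapse = ", "))
  bad_grp <- setdiff(unique(metadata$group), GROUPS)
  if (length(bad_grp))
    stopf("unknown group(s): %s", paste(bad_grp, collapse = ", "))
  for (f in c("pred", "cyc", "tac", "aza", "mmf")) {
    v <- metadata[[f]]
    if (!all(is.na(v) | v %in% c(0, 1)))
      stopf("drug flag '%s' must be 0, 1 or NA", f)
    metadata[[f]] <- as.integer(v)
  }
  both_cni <- which(metadata$cyc %in% 1 & metadata$tac %in% 1)
  if (length(both_cni))
    stopf("sample(s) on both ciclosporin and tacrolimus: %s",
          paste(metadata$sample_id[both_cni], collapse = ", "))
  both_ap <- which(metadata$aza %in% 1 & metadata$mmf %in% 1)
  if (length(both_ap))
    stopf("sample(s) on both azathioprine and MMF: %s",
          paste(metadata$sample_id[both_ap], collapse = ", "))
  untreated <- metadata$group %in% c("tolerant", "healthy")
  flags <- as.matrix(metadata[, c("pred", "cyc", "tac", "aza", "mmf")])
  bad_unt <- which(untreated & rowSums(flags == 1, na.rm = TRUE) > 0)
  if (length(bad_unt))
    stopf("tolerant/healthy sample(s) with drug flags set: %s",
          paste(metadata$sample_id[bad_unt], collapse = ", "))
  metadata
}

#' Delta-Ct normalization of a qPCR Ct table
#'
#' Normalizes raw cycle-threshold values against a housekeeping reference
#' gene (classically HPRT): output is `-(Ct_gene - Ct_reference)` per sample,
#' i.e. expression on the log2(2^-dCt) scale. The reference row is removed
#' from the output.
#'
#' @param ct gene x sample numeric matrix of Ct values.
#' @param reference_gene rowname of the reference gene; its Ct must be
#'   present (non-missing) in every sample.
#' @return gene x sample matrix of log2(2^-dCt) values.
#' @export
dct_normalize <- function(ct, reference_gene) {
  if (!reference_gene %in% rownames(ct))
    stopf("reference gene '%s' not found", reference_gene)
  ref <- ct[reference_gene, ]
  if (any(is.na(ref)))
    stopf("reference Ct missing in sample(s): %s",
          paste(colnames(ct)[is.na(ref)], collapse = ", "))
  out <- -sweep(ct[setdiff(rownames(ct), reference_gene), , drop = FALSE],
                2, ref, "-")
  out
}

#' Detection calls from Ct values
#'
#' Convenience rule for qPCR data: a gene is called detected in a sample when
#' its Ct is below the limit-of-detection cycle (and not missing).
#'
#' @param ct gene x sample Ct matrix.
#' @param lod limit-of-detection cycle, default 40.
#' @return logical gene x sample matrix.
#' @export
detect_from_ct <- function(ct, lod = 40) {
  d <- !is.na(ct) & ct < lod
  d
}

#' Filter genes without reliable signal above background
#'
#' Retains genes detected above background in at least `min_frac` of samples
#' (equivalently, removes genes undetected in more than `1 - min_frac`).
#'
#' @param expr gene x sample expression matrix.
#' @param detected logical gene x sample matrix, conformable with `expr`
#'   (e.g. from [detect_from_ct()] or array detection p-values < 0.01).
#' @param min_frac minimum detection fraction in `(0, 1]`, default 0.80.
#' @return list with `expr` (retained genes) and `report` (data frame of
#'   removed genes and their detection fractions, plus the threshold).
#' @export
background_filter <- function(expr, detected, min_frac = 0.80) {
  if (!is.numeric(min_frac) || length(min_frac) != 1 ||
      is.na(min_frac) || min_frac <= 0 || min_frac > 1)
    stopf("min_frac must be in (0, 1]")
  if (!identical(dim(expr), dim(detected)))
    stopf("detected matrix must be conformable with expr")
  if (!is.null(rownames(detected)) &&
      !identical(rownames(expr), rownames(detected)))
    stopf("detected matrix gene ids do not match expr")
  frac <- rowMeans(detected)
  keep <- frac >= min_frac
  report <- list(
    min_frac = min_frac,
    n_input = nrow(expr), n_retained = sum(keep),
    removed = data.frame(gene_id = rownames(expr)[!keep],
                         detection_frac = unname(frac[!keep]),
                         stringsAsFactors = FALSE))
  list(expr = expr[keep, , drop = FALSE], report = report)
}

#' Encode drug regimens as a binary design matrix
#'
#' Builds the sample x drug indicator matrix (columns Pred, Cyc, Tac, Aza,
#' MMF) used by the drug-effect models, by default over the treated groups
#' (stable and chronic rejectors) — the fitting population. Samples with any
#' missing drug flag are excluded and listed in the `excluded` attribute,
#' mirroring the exclusion of patients with absent regimen information.
#'
#' @param metadata validated sample metadata.
#' @param groups groups to include; `NULL` keeps every sample.
#' @return binary matrix with sample ids as rownames and an `excluded`
#'   attribute (character vector of dropped sample ids).
#' @export
encode_drug_design <- function(metadata, groups = TREATED_GROUPS) {
  metadata <- validate_metadata(metadata)
  if (!is.null(groups)) metadata <- metadata[metadata$group %in% groups, ,
                                             drop = FALSE]
  flags <- as.matrix(metadata[, c("pred", "cyc", "tac", "aza", "mmf")])
  incomplete <- rowSums(is.na(flags)) > 0
  excluded <- metadata$sample_id[incomplete]
  X <- flags[!incomplete, , drop = FALSE]
  storage.mode(X) <- "double"
  colnames(X) <- DRUGS
  rownames(X) <- metadata$sample_id[!incomplete]
  attr(X, "excluded") <- excluded
  X
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, member gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line: %s", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stopf("duplicate gene-set names in %s", path)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, ds, s) paste(c(nm, ds, s), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
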
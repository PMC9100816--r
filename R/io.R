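#' Marker QC configuration
#'
#' @param maf_min minimum minor allele frequency; markers below it are
#'   dropped (default 0.05).
#' @param miss_max maximum missing fraction; markers above it are dropped
#'   (default 0.20).
#' @param drop_duplicates drop exact-duplicate marker columns, keeping the
#'   first (default TRUE).
#' @return a classed list of validated settings.
#' @export
qcConfig <- function(maf_min = 0.05, miss_max = 0.20, drop_duplicates = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  structure(list(maf_min = maf_min, miss_max = miss_max,
                 drop_duplicates = isTRUE(drop_duplicates)),
            class = "qcConfig")
}

#' Read a genotype matrix
#'
#' Two plain-text formats are supported, both with markers in genome
#' (column) order:
#' \describe{
#'   \item{`"dosage"`}{delimited table with a header of marker names,
#'     one row per individual, all cells dosages 0/1/2 or NA. A first
#'     column named `id`/`ID`/`IID` is treated as individual labels.}
#'   \item{`"raw"`}{PLINK `.raw` additive coding: columns FID IID PAT MAT
#'     SEX PHENOTYPE followed by one 0/1/2/NA column per marker (names like
#'     `rs123_A`).}
#' }
#' Any cell outside 0/1/2/NA raises an error naming the row and column.
#'
#' @param path file path.
#' @param format `"dosage"` or `"raw"`.
#' @return a [GenotypeMatrix-class] (missing entries preserved as NA).
#' @export
readGenotypes <- function(path, format = c("dosage", "raw")) {
  format <- match.arg(format)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "nan", ""))
  if (ncol(dt) == 0L) stop("malformed header: no columns found in ", path)
  ids <- NULL
  if (format == "raw") {
    need <- c("FID", "IID")
    if (!all(need %in% names(dt)[1:2]))
      stop("malformed PLINK .raw header: expected FID IID PAT MAT SEX ",
           "PHENOTYPE leading columns")
    ids <- as.character(dt$IID)
    drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(dt))
    dt <- dt[, setdiff(names(dt), drop), drop = FALSE]
    # strip the _<allele> suffix PLINK appends to marker names
    names(dt) <- sub("_[ACGT0-9]+$", "", names(dt))
  } else if (tolower(names(dt)[1]) %in% c("id", "iid")) {
    ids <- as.character(dt[[1]])
    dt <- dt[, -1, drop = FALSE]
  }
  Z <- as.matrix(dt)
  storage.mode(Z) <- "double"
  bad <- which(!is.na(Z) & !(Z %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(Z))
    stop(sprintf(
      "invalid dosage %g at row %d, marker '%s' (must be 0, 1, 2 or NA)",
      Z[bad[1]], rc[1], colnames(Z)[rc[2]]))
  }
  if (!is.null(ids)) rownames(Z) <- ids
  GenotypeMatrix(Z, markerIds = colnames(Z))
}

#' Write a genotype matrix
#'
#' Writes either the delimited dosage table or a PLINK `.raw`-style file;
#' reading the result back with [readGenotypes()] is lossless.
#'
#' @param Z a [GenotypeMatrix-class].
#' @param path output file path.
#' @param format `"dosage"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(Z, path, format = c("dosage", "raw")) {
  format <- match.arg(format)
  stopifnot(is(Z, "GenotypeMatrix"))
  M <- Z@dosages
  n <- nrow(M)
  ids <- if (!is.null(rownames(M))) rownames(M) else paste0("ind", seq_len(n))
  if (format == "dosage") {
    df <- data.frame(id = ids, M, check.names = FALSE)
  } else {
    df <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
                     PHENOTYPE = -9L, M, check.names = FALSE)
    names(df)[-(1:6)] <- paste0(Z@markerIds, "_A")
  }
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Marker quality control
#'
#' Drops markers with minor allele frequency below `maf_min`, missing
#' fraction above `miss_max`, and exact-duplicate columns (keeping the
#' first occurrence), then mean-imputes any remaining missing entries.
#' The exclusion report lists every dropped marker with its reason.
#' Applying the filter twice gives the same result as applying it once.
#'
#' Note: a common shorthand writes the MAF rule as "excluding MAF > x";
#' as in standard QC practice, markers *below* the threshold (rare alleles)
#' are the ones excluded here.
#'
#' @param Z a [GenotypeMatrix-class] (may contain NA).
#' @param qc a [qcConfig()].
#' @return list with `genotypes` (filtered, imputed [GenotypeMatrix-class])
#'   and `report` (data.frame of dropped markers and reasons).
#' @export
qcFilter <- function(Z, qc = qcConfig()) {
  stopifnot(is(Z, "GenotypeMatrix"), inherits(qc, "qcConfig"))
  M <- Z@dosages
  p <- ncol(M)
  miss_frac <- colMeans(is.na(M))
  pk <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(pk, 1 - pk)
  drop <- rep(NA_character_, p)
  drop[miss_frac > qc$miss_max] <- "missing fraction above threshold"
  sel <- is.na(drop) & maf < qc$maf_min
  drop[sel] <- "MAF below threshold"
  if (qc$drop_duplicates) {
    keepable <- which(is.na(drop))
    if (length(keepable) > 1L) {
      keys <- vapply(keepable, function(j)
        paste(M[, j], collapse = ","), character(1))
      dup <- keepable[duplicated(keys)]
      drop[dup] <- "duplicate of an earlier marker"
    }
  }
  keep <- which(is.na(drop))
  if (!length(keep)) stop("QC removed all markers")
  report <- data.frame(marker = Z@markerIds[!is.na(drop)],
                       reason = drop[!is.na(drop)])
  Mk <- M[, keep, drop = FALSE]
  for (j in which(colSums(is.na(Mk)) > 0L)) {
    mj <- mean(Mk[, j], na.rm = TRUE)
    Mk[is.na(Mk[, j]), j] <- mj
  }
  out <- new("GenotypeMatrix", dosages = Mk, markerIds = Z@markerIds[keep],
             positions = Z@positions[keep], chromosome = Z@chromosome[keep])
  list(genotypes = out, report = report)
}
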
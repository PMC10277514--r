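# Readers and writers for the package's plain-text interchange formats:
#   - wide TSV: samples x proteins, header row of protein ids, first column
#     `sample_id`; a parallel "<path>.lod.tsv" carries the below-LOD mask.
#   - long CSV (multiplex-assay style): sample_id, protein_id, npx,
#     below_lod columns, one measurement per row.
#   - metadata TSV: one row per sample.
# All files UTF-8; missing value token "NA".

GROUP_LEVELS <- c("HC", "NAFL", "NASH")

META_COLUMNS <- c("sample_id", "group", "fibrosis", "nas", "steatosis",
                  "lobular_inflammation", "ballooning", "t2d",
                  "hypertension", "bmi", "age", "sex")

#' Validate a sample metadata table
#'
#' Checks the per-sample clinical table consumed by the analysis stages:
#' disease group (HC = healthy control, NAFL = steatosis without
#' inflammation, NASH = steatohepatitis), Kleiner fibrosis stage F0-F4,
#' NAFLD activity score (NAS, 0-8) with its three subscores, comorbidities
#' and demographics.
#'
#' @param meta a data.frame with columns `sample_id`, `group`, `fibrosis`,
#'   `nas`, `steatosis`, `lobular_inflammation`, `ballooning`, `t2d`,
#'   `hypertension`, `bmi`, `age`, `sex`.
#' @return The validated data.frame (group and sex as factors), class
#'   `sample_metadata` prepended.
#' @export
sample_metadata <- function(meta) {
  abort_if(!is.data.frame(meta), "metadata must be a data.frame")
  missing_cols <- setdiff(META_COLUMNS, names(meta))
  abort_if(length(missing_cols) > 0,
           paste("metadata missing column(s):",
                 paste(missing_cols, collapse = ", ")))
  abort_if(anyDuplicated(meta$sample_id) > 0, "duplicated sample ids")
  abort_if(!all(meta$group %in% GROUP_LEVELS),
           "group labels must be HC, NAFL or NASH")
  meta$group <- factor(meta$group, levels = GROUP_LEVELS)
  abort_if(!all(is.na(meta$fibrosis) | meta$fibrosis %in% 0:4),
           "fibrosis stage must be 0..4")
  abort_if(!all(is.na(meta$nas) | meta$nas %in% 0:8), "NAS must be 0..8")
  abort_if(!all(meta$sex %in% c("F", "M")), "sex must be F or M")
  sub_ok <- is.na(meta$nas) | is.na(meta$steatosis) |
    is.na(meta$lobular_inflammation) | is.na(meta$ballooning) |
    meta$nas == meta$steatosis + meta$lobular_inflammation + meta$ballooning
  abort_if(!all(sub_ok), "NAS must equal the sum of its three subscores")
  meta$sex <- factor(meta$sex, levels = c("F", "M"))
  meta$t2d <- as.logical(meta$t2d)
  meta$hypertension <- as.logical(meta$hypertension)
  class(meta) <- unique(c("sample_metadata", class(meta)))
  meta
}

#' Read / write sample metadata TSV
#'
#' @param path file path.
#' @return `read_metadata` returns a validated `sample_metadata`;
#'   `write_metadata` returns `path` invisibly.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  sample_metadata(df)
}

#' @rdname read_metadata
#' @param meta a `sample_metadata` data.frame.
#' @export
write_metadata <- function(meta, path) {
  df <- as.data.frame(meta)
  df$group <- as.character(df$group)
  df$sex <- as.character(df$sex)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an NPX matrix from long-format CSV
#'
#' Long format has one measurement per row with columns `sample_id`,
#' `protein_id`, `npx` and `below_lod` (0/1 or TRUE/FALSE). Every
#' (sample, protein) pair must occur at most once; pairs absent from the
#' file are an error (the wide matrix must be complete).
#'
#' @param path CSV file path.
#' @return An `npx_matrix`. Sample and protein order follow first
#'   appearance in the file.
#' @export
read_long_npx <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("sample_id", "protein_id", "npx", "below_lod")
  missing_cols <- setdiff(need, names(df))
  abort_if(length(missing_cols) > 0,
           paste("long NPX file missing column(s):",
                 paste(missing_cols, collapse = ", ")))
  abort_if(!is.numeric(df$npx), "npx column must be numeric")
  key <- paste(df$sample_id, df$protein_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicated (sample, protein) pair: (%s, %s)",
                 df$sample_id[dup[1]], df$protein_id[dup[1]]), call. = FALSE)
  }
  samples <- unique(df$sample_id)
  proteins <- unique(df$protein_id)
  abort_if(nrow(df) != length(samples) * length(proteins),
           "long NPX file is not a complete sample x protein grid")
  i <- match(df$sample_id, samples)
  j <- match(df$protein_id, proteins)
  v <- matrix(NA_real_, length(samples), length(proteins),
              dimnames = list(samples, proteins))
  m <- matrix(FALSE, length(samples), length(proteins),
              dimnames = list(samples, proteins))
  v[cbind(i, j)] <- df$npx
  m[cbind(i, j)] <- as.logical(df$below_lod)
  npx_matrix(v, m)
}

#' Write an NPX matrix to long-format CSV
#'
#' @param x an `npx_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_long_npx <- function(x, path) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  df <- data.frame(
    sample_id = rep(sample_ids(x), times = ncol(x$values)),
    protein_id = rep(protein_ids(x), each = nrow(x$values)),
    npx = as.vector(x$values),
    below_lod = as.integer(as.vector(x$below_lod)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write an NPX matrix as wide TSV
#'
#' The wide file is samples x proteins with a `sample_id` first column. The
#' below-LOD mask travels in a sibling file `<path>.lod.tsv` of identical
#' layout with 0/1 entries; if absent on read, the mask is all-FALSE.
#'
#' @param path TSV file path.
#' @return `read_wide_npx` returns an `npx_matrix`; `write_wide_npx`
#'   returns `path` invisibly.
#' @export
read_wide_npx <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  abort_if(names(df)[1] != "sample_id",
           "wide NPX file must start with a sample_id column")
  v <- as.matrix(df[, -1, drop = FALSE])
  abort_if(!is.numeric(v), "NPX values must be numeric")
  rownames(v) <- df$sample_id
  lod_path <- paste0(path, ".lod.tsv")
  if (file.exists(lod_path)) {
    ldf <- utils::read.delim(lod_path, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE, fileEncoding = "UTF-8")
    m <- as.matrix(ldf[, -1, drop = FALSE]) != 0
    rownames(m) <- ldf$sample_id
    abort_if(!identical(dimnames(m), dimnames(v)),
             "below-LOD mask file does not match the value file layout")
  } else {
    m <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  }
  npx_matrix(v, m)
}

#' @rdname read_wide_npx
#' @param x an `npx_matrix`.
#' @export
write_wide_npx <- function(x, path) {
  abort_if(!inherits(x, "npx_matrix"), "x must be an npx_matrix")
  write_tab <- function(mat, p) {
    df <- data.frame(sample_id = rownames(mat), mat,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  write_tab(x$values, path)
  write_tab(matrix(as.integer(x$below_lod), nrow(x$values),
                   dimnames = dimnames(x$values)),
            paste0(path, ".lod.tsv"))
  invisible(path)
}
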
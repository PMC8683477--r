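#' Read a methylation beta matrix
#'
#' Beta values are fractions methylated, in \[0, 1\]. On disk the default
#' orientation is sites-as-rows (the common array-export layout); in memory
#' the canonical orientation is samples x sites, so the matrix is
#' transposed on read unless `sites_as_rows = FALSE`. Values outside
#' \[0, 1\] are a range error reporting coordinates; `NA` entries are kept
#' as missing and their count is reported.
#'
#' @param path CSV (or TSV, by `.tsv`/`.txt` extension) file; first column
#'   holds ids, remaining columns one id each.
#' @param sites_as_rows orientation of the file (default TRUE).
#' @return numeric matrix, samples in rows (rownames = sample ids),
#'   sites in columns (colnames = site ids).
#' @export
read_beta_matrix <- function(path, sites_as_rows = TRUE) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s) in beta matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in beta matrix")
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value out of [0,1] at row '%s', column '%s' (value %g)",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 m[bad[1L, , drop = FALSE]]))
  }
  n_missing <- sum(is.na(m))
  if (n_missing > 0L) {
    message(sprintf("beta matrix: %d missing value(s)", n_missing))
  }
  if (sites_as_rows) m <- t(m)
  m
}

#' Write a beta matrix
#'
#' @param beta samples x sites numeric matrix (canonical orientation).
#' @param path output path; `.tsv`/`.txt` gives tab separation.
#' @param sites_as_rows write sites as rows (on-disk default, TRUE).
#' @export
write_beta_matrix <- function(beta, path, sites_as_rows = TRUE) {
  m <- if (sites_as_rows) t(beta) else beta
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- if (sites_as_rows) "site_id" else "sample_id"
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop sites containing missing betas
#'
#' Sites with any missing value are removed before model fitting; the
#' number dropped is reported. No imputation is performed.
#'
#' @param beta samples x sites matrix.
#' @return the matrix restricted to complete sites.
#' @export
drop_incomplete_sites <- function(beta) {
  keep <- colSums(is.na(beta)) == 0L
  if (any(!keep)) {
    message(sprintf("dropping %d site(s) with missing betas", sum(!keep)))
  }
  beta[, keep, drop = FALSE]
}
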
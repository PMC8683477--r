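#' Read and validate a sample sheet
#'
#' The sample sheet is a CSV with one row per sample and the columns
#' `sample_id`, `species`, `tissue` (`blood` or `biopsy`), `sex`
#' (`F`, `M` or `unknown`) and `age` (chronological age in years,
#' non-negative). Rows with missing age are rejected with their row index
#' reported; duplicate ids and unknown tissue/sex tokens are validation
#' errors.
#'
#' @param path path to the CSV file.
#' @return a validated `data.frame` with the five columns above.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate an in-memory sample sheet
#'
#' @param df data.frame with columns sample_id, species, tissue, sex, age.
#' @return the validated data.frame (invisibly the same object).
#' @export
validate_sample_sheet <- function(df) {
  required <- c("sample_id", "species", "tissue", "sex", "age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("sample sheet missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$age <- suppressWarnings(as.numeric(df$age))

  bad_age <- which(is.na(df$age) | !is.finite(df$age))
  if (length(bad_age) > 0L) {
    stop("missing or non-numeric age in row(s): ",
         paste(bad_age, collapse = ", "))
  }
  neg_age <- which(df$age < 0)
  if (length(neg_age) > 0L) {
    stop("negative age in row(s): ", paste(neg_age, collapse = ", "))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  }
  bad_tissue <- setdiff(unique(df$tissue), c("blood", "biopsy"))
  if (length(bad_tissue) > 0L) {
    stop("unknown tissue token(s): ", paste(bad_tissue, collapse = ", "))
  }
  bad_sex <- setdiff(unique(df$sex), c("F", "M", "unknown"))
  if (length(bad_sex) > 0L) {
    stop("unknown sex token(s): ", paste(bad_sex, collapse = ", "))
  }
  df[, required]
}

#' Write a sample sheet to CSV
#'
#' @param df validated sample sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
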
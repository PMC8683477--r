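#' Construct a genotype table
#'
#' Holds biallelic SNP genotypes as alt-allele dosages in {0, 1, 2, NA}
#' with per-site metadata (chromosome, 1-based position, ref/alt alleles,
#' variant-quality INFO annotations).
#'
#' @param ids character vector of individual ids.
#' @param sites data.frame with columns `chrom`, `pos` and optionally
#'   `ref`, `alt`, and INFO columns (`QD`, `FS`, `SOR`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum`).
#' @param dosage individuals x sites integer matrix in {0, 1, 2, NA}.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(ids, sites, dosage) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(ids), ncol(dosage) == nrow(sites))
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(dosage) <- ids
  structure(list(ids = as.character(ids), sites = sites, dosage = dosage),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individual(s) x %d site(s) on %d chromosome(s)\n",
              length(x$ids), nrow(x$sites), length(unique(x$sites$chrom))))
  invisible(x)
}

.info_fields <- c("QD", "FS", "SOR", "MQ", "MQRankSum", "ReadPosRankSum")

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via `vcfR`), keeping only biallelic SNP records.
#' Genotypes are coded as alt-allele dosage 0/1/2 with `./.` preserved as
#' missing; multiallelic and indel records are skipped and their counts
#' reported. The INFO annotations QD, FS, SOR, MQ, MQRankSum and
#' ReadPosRankSum are carried along when present (absent values are NA).
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return a [genotype_table()] with attribute `skipped`
#'   (counts of multiallelic and indel records dropped).
#' @export
read_vcf_minimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L | alt == "." | ref == ".")
  keep <- !multi & !indel
  skipped <- c(multiallelic = sum(multi), indel = sum(indel))
  if (any(!keep)) {
    message(sprintf("read_vcf_minimal: skipped %d multiallelic and %d indel record(s)",
                    skipped[["multiallelic"]], skipped[["indel"]]))
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  alleles <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(alleles), ncol(alleles))
  dos[alleles %in% c("0/0")] <- 0L
  dos[alleles %in% c("0/1", "1/0")] <- 1L
  dos[alleles %in% c("1/1")] <- 2L
  known_missing <- is.na(alleles) | alleles %in% c("./.", ".")
  malformed <- which(is.na(dos) & !known_missing)
  if (length(malformed) > 0L) {
    rec <- ((malformed[1L] - 1L) %% nrow(alleles)) + 1L
    stop(sprintf("malformed GT '%s' at record %d", alleles[malformed[1L]], rec))
  }

  info <- sapply(.info_fields, function(f) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = f)))[keep]
  })
  info <- matrix(info, ncol = length(.info_fields),
                 dimnames = list(NULL, .info_fields))
  sites <- data.frame(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep], info,
    stringsAsFactors = FALSE
  )
  tab <- genotype_table(colnames(gt), sites, t(dos))
  attr(tab, "skipped") <- skipped
  tab
}

#' Write a genotype table as a minimal VCF 4.2 file
#'
#' Emits biallelic SNP records with GT fields and any INFO annotations
#' present in the site table. The output is plain text and round-trips
#' through [read_vcf_minimal()].
#'
#' @param tab a [genotype_table()].
#' @param path output path.
#' @export
write_vcf_minimal <- function(tab, path) {
  stopifnot(inherits(tab, "genotype_table"))
  s <- tab$sites
  if (is.null(s$ref)) s$ref <- "A"
  if (is.null(s$alt)) s$alt <- "G"
  info_cols <- intersect(.info_fields, names(s))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(s$chrom)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", info_cols, info_cols),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            tab$ids), collapse = "\t")
  )
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  nrec <- nrow(s)
  info_str <- rep(".", nrec)
  if (length(info_cols) > 0L) {
    parts <- lapply(info_cols, function(f) {
      ifelse(is.na(s[[f]]), NA_character_, paste0(f, "=", s[[f]]))
    })
    info_str <- apply(do.call(cbind, parts), 1L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) "." else paste(x, collapse = ";")
    })
  }
  gt_mat <- matrix("./.", nrec, length(tab$ids))
  dos <- t(tab$dosage)  # sites x individuals
  not_na <- !is.na(dos)
  gt_mat[not_na] <- gt_code[as.character(dos[not_na])]
  recs <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info_str, "GT",
                sep = "\t")
  recs <- paste(recs, apply(gt_mat, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}
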
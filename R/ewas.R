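#' Read a CpG annotation table
#'
#' CSV with columns `site_id`, `tss_class` (position relative to the
#' closest transcription start site: promoter, 5'UTR, exon, intron,
#' 3'UTR, downstream or intergenic) and `island_flag` (TRUE if the CpG
#' lies in a CpG island).
#'
#' @param path CSV path.
#' @return validated data.frame, one row per site.
#' @export
read_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "tss_class", "island_flag")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in annotation")
  legal <- c("promoter", "5'UTR", "exon", "intron", "3'UTR", "downstream",
             "intergenic")
  bad <- setdiff(unique(df$tss_class), legal)
  if (length(bad) > 0L) stop("unknown tss_class value(s): ", paste(bad, collapse = ", "))
  df$island_flag <- as.logical(df$island_flag)
  if (any(is.na(df$island_flag))) stop("island_flag must be logical")
  df[, required]
}

#' Per-site correlation screen of methylation against age
#'
#' For each site: Pearson `r` with age, `t = r * sqrt(n-2) / sqrt(1-r^2)`,
#' two-sided p from the Student-t distribution with n-2 df, and the
#' signed normal score `z = sign(r) * qnorm(1 - p/2)`. Perfectly
#' correlated sites underflow p toward 0; their z is capped at
#' `z_cap` (default 40) and flagged so extreme sites stay ordered and
#' finite. Zero-variance sites get missing statistics (reported).
#'
#' @param beta samples x sites matrix.
#' @param ages ages in years, length >= 4.
#' @param z_cap absolute cap applied to z.
#' @return data.frame: `site_id`, `n`, `r`, `t`, `p`, `z`, `capped`.
#' @export
site_age_screen <- function(beta, ages, z_cap = 40) {
  n <- length(ages)
  if (n < 4L) stop("screen requires at least 4 samples")
  if (nrow(beta) != n) stop("ages must match rows of beta")
  sds <- apply(beta, 2L, stats::sd)
  usable <- sds > 0
  if (any(!usable)) {
    message(sprintf("site_age_screen: %d zero-variance site(s) skipped", sum(!usable)))
  }
  r <- rep(NA_real_, ncol(beta))
  r[usable] <- as.numeric(stats::cor(beta[, usable, drop = FALSE], ages))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  underflow <- !is.na(p) & p < .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  z <- sign(r) * stats::qnorm(p / 2, lower.tail = FALSE)
  capped <- !is.na(z) & (abs(z) > z_cap | underflow)
  z[capped] <- sign(z[capped]) * z_cap
  data.frame(site_id = colnames(beta), n = n, r = r, t = tstat, p = p, z = z,
             capped = capped, row.names = NULL, stringsAsFactors = FALSE)
}

#' Stouffer meta-analysis of signed z-scores
#'
#' Combines per-tissue z-scores as
#' `z_meta = sum(w_k z_k) / sqrt(sum(w_k^2))` with weights
#' `w_k = sqrt(n_k)` by default, and a two-sided normal p. Sites with any
#' missing z get a missing meta value (the meta-analysis is computed only
#' on sites scored in every tissue).
#'
#' @param z sites x tissues matrix of signed z-scores (a vector is
#'   treated as one site).
#' @param weights per-tissue weights; default `sqrt(n)` when `n` given,
#'   else equal weights.
#' @param n per-tissue sample sizes (used for the default weights).
#' @return data.frame with `z_meta` and `p_meta` per site.
#' @export
stouffer_meta <- function(z, weights = NULL, n = NULL) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (is.null(weights)) {
    weights <- if (is.null(n)) rep(1, ncol(z)) else sqrt(n)
  }
  if (length(weights) != ncol(z)) stop("one weight per tissue required")
  denom <- sqrt(sum(weights^2))
  zm <- as.numeric(z %*% weights) / denom
  zm[rowSums(is.na(z)) > 0L] <- NA_real_
  data.frame(z_meta = zm, p_meta = 2 * stats::pnorm(abs(zm), lower.tail = FALSE))
}

#' Run the two-tissue EWAS with cross-tissue meta-analysis
#'
#' Screens every site against age in each tissue separately
#' ([site_age_screen()]) and combines the z-scores across tissues by
#' Stouffer's method with `sqrt(n)` weights.
#'
#' @param beta_blood,beta_biopsy samples x sites matrices sharing sites.
#' @param ages_blood,ages_biopsy per-tissue ages.
#' @param z_cap cap on |z| (see [site_age_screen()]).
#' @return data.frame with per-tissue statistics (suffixes `_blood`,
#'   `_biopsy`) and `z_meta`, `p_meta`.
#' @export
ewas_two_tissue <- function(beta_blood, ages_blood, beta_biopsy, ages_biopsy,
                            z_cap = 40) {
  shared <- intersect(colnames(beta_blood), colnames(beta_biopsy))
  if (length(shared) == 0L) stop("no shared sites between tissues")
  a <- site_age_screen(beta_blood[, shared, drop = FALSE], ages_blood, z_cap)
  b <- site_age_screen(beta_biopsy[, shared, drop = FALSE], ages_biopsy, z_cap)
  meta <- stouffer_meta(cbind(a$z, b$z), n = c(length(ages_blood), length(ages_biopsy)))
  out <- data.frame(site_id = shared, stringsAsFactors = FALSE)
  for (col in c("n", "r", "t", "p", "z")) {
    out[[paste0(col, "_blood")]] <- a[[col]]
    out[[paste0(col, "_biopsy")]] <- b[[col]]
  }
  out$z_meta <- meta$z_meta
  out$p_meta <- meta$p_meta
  out
}

#' Significance counts, tissue overlap and sector classes
#'
#' Per tissue, counts sites with p below `alpha` split by correlation
#' sign (hyper- vs hypomethylated with age); the cross-tissue overlap
#' (significant in both); and sector classes: `shared` (significant in
#' both tissues with the same sign), `divergent` (significant in both
#' with opposite signs), and tissue-specific (significant in one tissue
#' with p above `ns_p` in the other).
#'
#' @param results output of [ewas_two_tissue()].
#' @param alpha significance threshold (default 1e-4).
#' @param ns_p "clearly not significant" threshold for the specific
#'   classes (default 0.05).
#' @return list with `counts` (per tissue, by direction), `overlap`, and
#'   `sectors` (named counts), plus per-site `sector` labels.
#' @export
significant_sites <- function(results, alpha = 1e-4, ns_p = 0.05) {
  sig_bl <- !is.na(results$p_blood) & results$p_blood < alpha
  sig_bi <- !is.na(results$p_biopsy) & results$p_biopsy < alpha
  pos_bl <- results$z_blood > 0
  pos_bi <- results$z_biopsy > 0
  counts <- data.frame(
    tissue = c("blood", "blood", "biopsy", "biopsy"),
    direction = c("hyper", "hypo", "hyper", "hypo"),
    n = c(sum(sig_bl & pos_bl), sum(sig_bl & !pos_bl),
          sum(sig_bi & pos_bi), sum(sig_bi & !pos_bi)))
  sector <- rep("none", nrow(results))
  sector[sig_bl & sig_bi & (pos_bl == pos_bi)] <- "shared"
  sector[sig_bl & sig_bi & (pos_bl != pos_bi)] <- "divergent"
  sector[sig_bl & !sig_bi & results$p_biopsy > ns_p] <- "blood_specific"
  sector[sig_bi & !sig_bl & results$p_blood > ns_p] <- "biopsy_specific"
  list(counts = counts, overlap = sum(sig_bl & sig_bi),
       sectors = table(factor(sector, levels = c("shared", "divergent",
                                                 "blood_specific",
                                                 "biopsy_specific", "none"))),
       sector = sector)
}

#' Select the top-k sites by z-score in each direction
#'
#' Returns the `k` most positive and `k` most negative z-scores; ties are
#' broken by lexicographic site id so the selection is deterministic.
#' When fewer than `2k` scored sites exist, all are returned with a
#' warning.
#'
#' @param results data.frame with `site_id` and a z column.
#' @param k sites per direction (default 500).
#' @param z_col which z column to rank on (default `"z_meta"`).
#' @return data.frame `site_id`, `z`, `direction` (`"positive"`/`"negative"`).
#' @export
top_k_by_z <- function(results, k = 500L, z_col = "z_meta") {
  z <- results[[z_col]]
  ok <- !is.na(z)
  ids <- results$site_id[ok]
  z <- z[ok]
  if (length(z) < 2L * k) {
    warning(sprintf("only %d scored site(s) for 2k = %d requested; returning all",
                    length(z), 2L * k))
  }
  pos_ord <- order(-z, ids)
  neg_ord <- order(z, ids)
  kk <- min(k, length(z))
  pos <- pos_ord[seq_len(kk)]
  neg <- neg_ord[seq_len(kk)]
  neg <- setdiff(neg, pos)  # when k exceeds half the sites, avoid duplicates
  rbind(
    data.frame(site_id = ids[pos], z = z[pos],
               direction = rep("positive", length(pos)),
               stringsAsFactors = FALSE),
    data.frame(site_id = ids[neg], z = z[neg],
               direction = rep("negative", length(neg)),
               stringsAsFactors = FALSE))
}

#' Annotation summaries of selected age-related CpGs
#'
#' Counts selected sites per TSS position class split by z sign, and
#' compares z-scores of island vs non-island CpGs by a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param selected data.frame with `site_id` and `z` (e.g. from
#'   [top_k_by_z()]).
#' @param annotation annotation table ([read_annotation()]); should cover
#'   at least 95% of the selected sites (else a warning).
#' @return list with `tss_counts` (class x sign table), `island_test`
#'   (`statistic`, `p`, `median_diff` = median island z minus median
#'   non-island z), `n_annotated`.
#' @export
annotate_summary <- function(selected, annotation) {
  if (nrow(selected) == 0L) stop("empty selection")
  m <- merge(selected, annotation, by = "site_id")
  if (nrow(m) < 0.95 * nrow(selected)) {
    warning(sprintf("annotation covers only %d of %d selected site(s)",
                    nrow(m), nrow(selected)))
  }
  tss_counts <- table(m$tss_class, ifelse(m$z > 0, "positive", "negative"))
  isl <- m$z[m$island_flag]
  non <- m$z[!m$island_flag]
  island_test <- if (length(isl) > 0L && length(non) > 0L) {
    wt <- stats::wilcox.test(isl, non, alternative = "two.sided", exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value,
         median_diff = stats::median(isl) - stats::median(non))
  } else {
    list(statistic = NA_real_, p = NA_real_, median_diff = NA_real_)
  }
  list(tss_counts = tss_counts, island_test = island_test, n_annotated = nrow(m))
}

#' Export selected sites as a BED file
#'
#' Writes site coordinates (when provided) or site ids in BED format for
#' use with external enrichment tools.
#'
#' @param selected data.frame with `site_id` and optionally `chrom`,
#'   `pos` (1-based).
#' @param path output path.
#' @export
write_sites_bed <- function(selected, path) {
  if (all(c("chrom", "pos") %in% names(selected))) {
    bed <- data.frame(selected$chrom, selected$pos - 1L, selected$pos,
                      selected$site_id)
  } else {
    bed <- data.frame("unplaced", seq_len(nrow(selected)) - 1L,
                      seq_len(nrow(selected)), selected$site_id)
  }
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
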
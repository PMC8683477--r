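#' Alternate-allele frequencies from a genotype table
#'
#' @param tab a [genotype_table()].
#' @return numeric vector of per-site alt-allele frequencies computed
#'   from non-missing dosages.
#' @export
allele_freq <- function(tab) {
  colMeans(tab$dosage, na.rm = TRUE) / 2
}

#' Hard-filter variant sites
#'
#' Removes a site if it violates ANY of the variant-quality thresholds
#' (QD < 2, FS > 60, SOR > 3, MQ < 40, MQRankSum < -12.5,
#' ReadPosRankSum < -8 by default) or has minor allele frequency below
#' `maf_min` (strict `<`; MAF from non-missing dosages). A missing INFO
#' annotation passes that criterion (and is noted in the report).
#'
#' @param tab a [genotype_table()] whose `sites` carry INFO columns.
#' @param thresholds list as in `default_config()$filters`.
#' @return list with `table` (surviving sites), `report` (data.frame of
#'   per-criterion removal counts; a site violating several criteria is
#'   counted under each) and `removed` (per-site violated criteria).
#' @export
hard_filter <- function(tab, thresholds = default_config()$filters) {
  if (nrow(tab$sites) == 0L) stop("empty genotype table")
  s <- tab$sites
  th <- thresholds
  get_info <- function(field) {
    if (field %in% names(s)) s[[field]] else rep(NA_real_, nrow(s))
  }
  p <- allele_freq(tab)
  maf <- pmin(p, 1 - p)
  viol <- cbind(
    QD = get_info("QD") < th$qd_min,
    FS = get_info("FS") > th$fs_max,
    SOR = get_info("SOR") > th$sor_max,
    MQ = get_info("MQ") < th$mq_min,
    MQRankSum = get_info("MQRankSum") < th$mqranksum_min,
    ReadPosRankSum = get_info("ReadPosRankSum") < th$readposranksum_min,
    MAF = maf < th$maf_min
  )
  n_info_missing <- sum(is.na(viol[, 1:6]))
  viol[is.na(viol)] <- FALSE  # absent annotation passes that criterion
  if (n_info_missing > 0L) {
    message(sprintf("hard_filter: %d missing INFO value(s) passed their criterion",
                    n_info_missing))
  }
  drop <- rowSums(viol) > 0L
  report <- data.frame(criterion = colnames(viol), n_removed = colSums(viol),
                       row.names = NULL, stringsAsFactors = FALSE)
  removed <- apply(viol[drop, , drop = FALSE], 1L, function(x) {
    paste(colnames(viol)[x], collapse = ";")
  })
  message(sprintf("hard_filter: removed %d of %d site(s)", sum(drop), nrow(s)))
  kept <- genotype_table(tab$ids, s[!drop, , drop = FALSE],
                         tab$dosage[, !drop, drop = FALSE])
  list(table = kept, report = report,
       removed = data.frame(chrom = s$chrom[drop], pos = s$pos[drop],
                            criteria = removed, stringsAsFactors = FALSE))
}

#' Minor-allele-count filter
#'
#' Removes singletons and private doubletons as a minor-allele-count
#' rule: sites with minor allele count below `min_mac` are dropped.
#'
#' @param tab a [genotype_table()].
#' @param min_mac minimum minor-allele count to retain a site.
#' @return filtered [genotype_table()].
#' @export
mac_filter <- function(tab, min_mac = 3L) {
  ac <- colSums(tab$dosage, na.rm = TRUE)
  an <- 2L * colSums(!is.na(tab$dosage))
  mac <- pmin(ac, an - ac)
  keep <- mac >= min_mac
  message(sprintf("mac_filter: removed %d site(s) with minor allele count < %d",
                  sum(!keep), min_mac))
  genotype_table(tab$ids, tab$sites[keep, , drop = FALSE],
                 tab$dosage[, keep, drop = FALSE])
}

#' Method-of-moments inbreeding coefficient F
#'
#' Excess-homozygosity estimate
#' `F = (O_hom - E_hom) / (L - E_hom)` per individual, where `O_hom` is
#' the observed count of homozygous loci, `L` the individual's non-missing
#' polymorphic loci and `E_hom = sum(1 - 2 p q)` the expected homozygous
#' count under Hardy-Weinberg at the panel allele frequencies.
#' Monomorphic loci are excluded. With `small_sample_correction` the
#' expected heterozygosity uses the unbiased factor
#' `2 p q * n / (n - 1)` with `n` the non-missing allele count at the
#' locus.
#'
#' @param tab a [genotype_table()].
#' @param p optional externally supplied allele frequencies (default:
#'   estimated from the table itself).
#' @param small_sample_correction logical, default FALSE.
#' @return named numeric vector of F-hat per individual (NA, with a
#'   message, for individuals with no usable loci).
#' @export
f_moments <- function(tab, p = NULL, small_sample_correction = FALSE) {
  if (is.null(p)) p <- allele_freq(tab)
  if (length(p) != ncol(tab$dosage)) stop("one allele frequency per site required")
  n_al <- 2 * colSums(!is.na(tab$dosage))
  poly <- !is.na(p) & p > 0 & p < 1
  het_exp <- 2 * p * (1 - p)
  if (small_sample_correction) {
    het_exp <- het_exp * ifelse(n_al > 1, n_al / (n_al - 1), NA_real_)
  }
  out <- vapply(seq_along(tab$ids), function(i) {
    g <- tab$dosage[i, ]
    use <- poly & !is.na(g)
    L <- sum(use)
    if (L == 0L) {
      message("f_moments: no usable loci for individual ", tab$ids[i])
      return(NA_real_)
    }
    o_hom <- sum(g[use] != 1L)
    e_hom <- sum(1 - het_exp[use])
    (o_hom - e_hom) / (L - e_hom)
  }, numeric(1))
  stats::setNames(out, tab$ids)
}

#' Detect runs of homozygosity by sliding windows
#'
#' PLINK-style scanning: a window of `window_snps` consecutive SNPs is
#' called homozygous if it contains at most `window_het` heterozygotes
#' and at most `window_missing` missing calls. Each SNP's hit fraction is
#' the proportion of windows containing it that are homozygous; SNPs with
#' hit fraction >= `hit_frac` form candidate runs of consecutive
#' qualifying SNPs, and a candidate is reported iff it has at least
#' `min_snps` SNPs and spans at least `min_length_kb` kb (first to last
#' qualifying SNP). A chromosome with fewer SNPs than the window size
#' yields no windows and hence no runs.
#'
#' @param tab a [genotype_table()].
#' @param params list as in `default_config()$roh`.
#' @param ids individuals to scan (default all).
#' @return data.frame with columns `ind`, `chrom`, `start_bp`, `end_bp`
#'   (1-based positions of the first and last SNP in the run), `n_snps`,
#'   `length_bp` (= end - start).
#' @export
detect_roh <- function(tab, params = default_config()$roh, ids = tab$ids) {
  W <- as.integer(params$window_snps)
  segs <- list()
  for (id in ids) {
    i <- match(id, tab$ids)
    if (is.na(i)) stop("unknown individual id: ", id)
    for (ch in unique(tab$sites$chrom)) {
      on <- which(tab$sites$chrom == ch)
      g <- tab$dosage[i, on]
      pos <- tab$sites$pos[on]
      q <- roh_qualifying_snps(g, W, params$window_het, params$window_missing,
                               params$hit_frac)
      if (!any(q)) next
      rl <- rle(q)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (k in which(rl$values)) {
        idx <- starts[k]:ends[k]
        span <- pos[idx[length(idx)]] - pos[idx[1L]]
        if (length(idx) >= params$min_snps && span >= params$min_length_kb * 1000) {
          segs[[length(segs) + 1L]] <- data.frame(
            ind = id, chrom = ch, start_bp = pos[idx[1L]],
            end_bp = pos[idx[length(idx)]], n_snps = length(idx),
            length_bp = span, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(segs) == 0L) {
    return(data.frame(ind = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_bp = numeric(0)))
  }
  do.call(rbind, segs)
}

#' Per-SNP ROH qualification for one chromosome of one individual
#'
#' The window-scan core of [detect_roh()], exposed for testing: returns,
#' for each SNP, whether its hit fraction (homozygous windows containing
#' it / windows containing it) reaches `hit_frac`.
#'
#' @param g dosage vector (0/1/2/NA) in position order.
#' @param window_snps window size in SNPs.
#' @param window_het,window_missing maximum heterozygous / missing calls
#'   for a window to count as homozygous.
#' @param hit_frac hit-fraction threshold.
#' @return logical vector along `g` (all FALSE when no windows fit).
#' @export
roh_qualifying_snps <- function(g, window_snps, window_het, window_missing,
                                hit_frac) {
  m <- length(g)
  W <- as.integer(window_snps)
  if (m < W) return(rep(FALSE, m))
  het <- as.numeric(!is.na(g) & g == 1L)
  mis <- as.numeric(is.na(g))
  csh <- c(0, cumsum(het))
  csm <- c(0, cumsum(mis))
  nw <- m - W + 1L
  st <- seq_len(nw)
  win_ok <- (csh[st + W] - csh[st]) <= window_het &
    (csm[st + W] - csm[st]) <= window_missing
  cso <- c(0, cumsum(win_ok))
  i <- seq_len(m)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, nw)
  n_tot <- hi - lo + 1L
  n_ok <- cso[hi + 1L] - cso[lo]
  n_tot > 0L & (n_ok / n_tot) >= hit_frac
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Total ROH length per individual divided by the screened genome length.
#'
#' @param segments output of [detect_roh()].
#' @param screened_length_bp length of genome screened for ROH (bp).
#' @param ids individuals to report (default those in `segments`);
#'   individuals without segments get F_ROH = 0.
#' @return data.frame with `ind`, `froh`, `total_roh_bp`, `n_segments`.
#' @export
froh <- function(segments, screened_length_bp, ids = NULL) {
  if (screened_length_bp <= 0) stop("screened_length_bp must be > 0")
  if (is.null(ids)) ids <- unique(segments$ind)
  tot <- vapply(ids, function(id) {
    sum(segments$length_bp[segments$ind == id])
  }, numeric(1))
  nseg <- vapply(ids, function(id) sum(segments$ind == id), numeric(1))
  fr <- tot / screened_length_bp
  if (any(fr > 1)) warning("total ROH length exceeds screened length for some individual(s)")
  data.frame(ind = ids, froh = fr, total_roh_bp = tot, n_segments = nseg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write ROH segments as a BED file
#'
#' Coordinates are converted to 0-based half-open (BED convention); the
#' name column carries the individual id.
#'
#' @param segments output of [detect_roh()].
#' @param path output path.
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(segments$chrom, segments$start_bp - 1L, segments$end_bp,
                    segments$ind)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mendelian error rate from parent-offspring trios
#'
#' A trio-locus pair is an error iff the child's dosage is impossible
#' given the parents' dosages under biallelic transmission (a homozygous
#' parent must transmit its allele). Pairs with any missing genotype are
#' not evaluable.
#'
#' @param tab a [genotype_table()].
#' @param trios data.frame with columns `child`, `sire`, `dam` (ids).
#' @return list with `per_locus` (error rate per locus across trios),
#'   `mean_rate`, `sd_rate`.
#' @export
mendelian_error_rate <- function(tab, trios) {
  idx <- function(id) {
    i <- match(id, tab$ids)
    if (any(is.na(i))) stop("unknown id(s): ", paste(id[is.na(i)], collapse = ", "))
    i
  }
  ci <- idx(trios$child)
  si <- idx(trios$sire)
  di <- idx(trios$dam)
  # possible child dosages for each (sire, dam) dosage pair
  gametes <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  possible <- array(FALSE, c(3, 3, 3))  # sire+1, dam+1, child+1
  for (a in 0:2) for (b in 0:2) {
    kids <- unique(outer(gametes[[a + 1L]], gametes[[b + 1L]], `+`))
    possible[a + 1L, b + 1L, kids + 1L] <- TRUE
  }
  nloc <- ncol(tab$dosage)
  errs <- integer(nloc)
  evals <- integer(nloc)
  for (t in seq_len(nrow(trios))) {
    gc <- tab$dosage[ci[t], ]
    gs <- tab$dosage[si[t], ]
    gd <- tab$dosage[di[t], ]
    ok <- !is.na(gc) & !is.na(gs) & !is.na(gd)
    evals <- evals + ok
    bad <- ok & !possible[cbind(gs + 1L, gd + 1L, gc + 1L)]
    errs <- errs + (bad %in% TRUE)
  }
  per_locus <- ifelse(evals > 0L, errs / evals, NA_real_)
  list(per_locus = per_locus,
       mean_rate = mean(per_locus, na.rm = TRUE),
       sd_rate = stats::sd(per_locus, na.rm = TRUE))
}

#' Imputation evaluation metrics
#'
#' Per-individual concordance (fraction of sites, non-missing in both,
#' with identical hard genotype) and dosage r-squared (squared Pearson
#' correlation between true and imputed dosages).
#'
#' @param truth a [genotype_table()] with the true genotypes.
#' @param imputed matrix of imputed dosages with matching ids x sites.
#' @return list with `per_individual` data.frame (`ind`, `concordance`,
#'   `dosage_r2`) and `mean_concordance`, `mean_dosage_r2`.
#' @export
imputation_metrics <- function(truth, imputed) {
  if (!all(dim(imputed) == dim(truth$dosage))) {
    stop("imputed matrix dimensions do not match the truth table")
  }
  per <- lapply(seq_along(truth$ids), function(i) {
    g <- truth$dosage[i, ]
    h <- imputed[i, ]
    ok <- !is.na(g) & !is.na(h)
    if (!any(ok)) stop("no overlapping non-missing sites for individual ", truth$ids[i])
    conc <- mean(g[ok] == h[ok])
    r2 <- if (stats::sd(h[ok]) == 0 || stats::sd(g[ok]) == 0) {
      message("imputation_metrics: constant dosages, r2 undefined for ", truth$ids[i])
      NA_real_
    } else {
      stats::cor(g[ok], h[ok])^2
    }
    data.frame(ind = truth$ids[i], concordance = conc, dosage_r2 = r2,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_individual = per,
       mean_concordance = mean(per$concordance),
       mean_dosage_r2 = mean(per$dosage_r2, na.rm = TRUE))
}
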
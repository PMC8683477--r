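#' Default chromosome map for genotype simulation
#'
#' Ten autosomes of 100 Mb each (1 Gb screened genome).
#'
#' @return data.frame with columns `chrom` and `length_bp`.
#' @export
default_chrom_map <- function() {
  data.frame(chrom = sprintf("chr%d", 1:10), length_bp = 1e8,
             stringsAsFactors = FALSE)
}

# Draw non-overlapping run lengths in [1.5, 60] Mb summing exactly to
# target_len; the final run absorbs the remainder so the planted total is
# exact (and the F_ROH implied by the truth matches the target).
.draw_run_lengths <- function(target_len, min_len = 1.5e6, max_len = 6e7) {
  if (target_len == 0) return(numeric(0))
  if (target_len < min_len) {
    stop("target F_ROH implies less than one minimum-length (1.5 Mb) run")
  }
  lens <- numeric(0)
  remaining <- target_len
  while (remaining >= min_len) {
    if (remaining <= max_len) {
      lens <- c(lens, remaining)
      remaining <- 0
    } else {
      len <- stats::runif(1, min_len, min(max_len, remaining - min_len))
      lens <- c(lens, len)
      remaining <- remaining - len
    }
  }
  lens
}

#' Simulate a genotype panel with planted runs of homozygosity
#'
#' Outside planted runs genotypes are drawn under Hardy-Weinberg
#' equilibrium at per-SNP allele frequencies `p_l`; inside a planted run
#' the individual is homozygous (alt allele chosen with probability
#' `p_l`), with an optional per-SNP contamination rate at which an HWE
#' genotype is drawn instead. Planted run lengths are drawn in
#' \[1.5 Mb, 60 Mb\] and sum, per individual, to exactly
#' `target_froh * screened_length`.
#'
#' @param n_ind number of individuals.
#' @param n_snps total SNPs across the genome.
#' @param chrom_map data.frame(chrom, length_bp); default ten 100-Mb
#'   autosomes.
#' @param target_froh per-individual target F_ROH, each in \[0, 0.5\]
#'   (recycled to `n_ind`).
#' @param maf_range range of simulated allele frequencies.
#' @param contamination per-SNP probability of an HWE draw inside a run.
#' @param missing_rate per-call missing probability.
#' @param seed RNG seed.
#' @return list with `table` (a [genotype_table()]) and `truth` (planted
#'   run coordinates per individual, 0-based half-open; target F_ROH;
#'   allele frequencies; screened genome length).
#' @export
gen_genotypes <- function(n_ind, n_snps, chrom_map = default_chrom_map(),
                          target_froh = 0, maf_range = c(0.05, 0.5),
                          contamination = 0, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target_froh <- rep_len(target_froh, n_ind)
  if (any(target_froh < 0 | target_froh > 0.5)) stop("target_froh must be in [0, 0.5]")
  L <- sum(chrom_map$length_bp)

  # SNP positions, proportional to chromosome length
  n_per <- round(n_snps * chrom_map$length_bp / L)
  n_per[1L] <- n_per[1L] + (n_snps - sum(n_per))
  sites <- do.call(rbind, lapply(seq_len(nrow(chrom_map)), function(k) {
    data.frame(chrom = chrom_map$chrom[k],
               pos = sort(sample.int(chrom_map$length_bp[k], n_per[k])),
               stringsAsFactors = FALSE)
  }))
  p <- stats::runif(n_snps, maf_range[1L], maf_range[2L])

  ids <- sprintf("I%03d", seq_len(n_ind))
  dos <- matrix(stats::rbinom(n_ind * n_snps, 2L,
                              rep(p, each = n_ind)), n_ind, n_snps)

  runs <- list()
  for (i in seq_len(n_ind)) {
    lens <- .draw_run_lengths(target_froh[i] * L)
    occupied <- lapply(chrom_map$chrom, function(x) matrix(numeric(0), 0, 2))
    names(occupied) <- chrom_map$chrom
    for (len in lens) {
      placed <- FALSE
      for (attempt in seq_len(500L)) {
        k <- sample.int(nrow(chrom_map), 1L)
        cl <- chrom_map$length_bp[k]
        if (len > cl) next
        start <- floor(stats::runif(1, 0, cl - len))
        end <- start + len
        occ <- occupied[[chrom_map$chrom[k]]]
        if (nrow(occ) == 0L || all(end <= occ[, 1L] | start >= occ[, 2L])) {
          occupied[[chrom_map$chrom[k]]] <- rbind(occ, c(start, end))
          runs[[length(runs) + 1L]] <- data.frame(
            ind = ids[i], chrom = chrom_map$chrom[k],
            start = start, end = end, length = len,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place planted run (chromosomes too full)")
    }
    # make the individual homozygous inside its planted runs
    ind_runs <- occupied
    for (ch in names(ind_runs)) {
      occ <- ind_runs[[ch]]
      if (nrow(occ) == 0L) next
      on_chrom <- which(sites$chrom == ch)
      for (rr in seq_len(nrow(occ))) {
        in_run <- on_chrom[sites$pos[on_chrom] > occ[rr, 1L] &
                           sites$pos[on_chrom] <= occ[rr, 2L]]
        if (length(in_run) == 0L) next
        hom <- 2L * stats::rbinom(length(in_run), 1L, p[in_run])
        keep_hwe <- stats::runif(length(in_run)) < contamination
        dos[i, in_run] <- ifelse(keep_hwe, dos[i, in_run], hom)
      }
    }
  }
  if (missing_rate > 0) {
    dos[stats::runif(length(dos)) < missing_rate] <- NA_integer_
  }
  sites$ref <- "A"
  sites$alt <- "G"
  truth <- list(
    runs = if (length(runs) > 0L) do.call(rbind, runs) else
      data.frame(ind = character(0), chrom = character(0), start = numeric(0),
                 end = numeric(0), length = numeric(0)),
    target_froh = stats::setNames(target_froh, ids),
    p = p, screened_length_bp = L, chrom_map = chrom_map
  )
  list(table = genotype_table(ids, sites, dos), truth = truth)
}
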
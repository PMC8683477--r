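# Shared fixture builders (all programmatic; no data files)

make_sheet <- function(ages, tissue = "blood", sex = NULL,
                       ids = sprintf("S%03d", seq_along(ages))) {
  if (is.null(sex)) sex <- rep(c("F", "M"), length.out = length(ages))
  data.frame(sample_id = ids, species = "zebra",
             tissue = rep(tissue, length.out = length(ages)),
             sex = sex, age = ages, stringsAsFactors = FALSE)
}

# tiny genotype table built by hand
make_geno <- function(dosage, pos = NULL, chrom = "chr1", info = NULL) {
  dosage <- as.matrix(dosage)
  n_sites <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(n_sites) * 1000L
  sites <- data.frame(chrom = rep(chrom, n_sites), pos = pos,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (!is.null(info)) sites <- cbind(sites, info)
  genotype_table(sprintf("I%02d", seq_len(nrow(dosage))), sites, dosage)
}

# brute-force ROH oracle: enumerate every window and every candidate run
roh_oracle_qualify <- function(g, W, max_het, max_miss, hit_frac) {
  m <- length(g)
  if (m < W) return(rep(FALSE, m))
  nw <- m - W + 1L
  ok <- logical(nw)
  for (s in seq_len(nw)) {
    win <- g[s:(s + W - 1L)]
    ok[s] <- sum(win == 1L, na.rm = TRUE) <= max_het && sum(is.na(win)) <= max_miss
  }
  qual <- logical(m)
  for (i in seq_len(m)) {
    starts <- max(1L, i - W + 1L):min(i, nw)
    qual[i] <- mean(ok[starts]) >= hit_frac
  }
  qual
}

roh_oracle_segments <- function(g, pos, params) {
  qual <- roh_oracle_qualify(g, params$window_snps, params$window_het,
                             params$window_missing, params$hit_frac)
  segs <- list()
  i <- 1L
  m <- length(g)
  while (i <= m) {
    if (!qual[i]) { i <- i + 1L; next }
    j <- i
    while (j < m && qual[j + 1L]) j <- j + 1L
    n_snps <- j - i + 1L
    span <- pos[j] - pos[i]
    if (n_snps >= params$min_snps && span >= params$min_length_kb * 1000) {
      segs[[length(segs) + 1L]] <- c(start = pos[i], end = pos[j],
                                     n_snps = n_snps, length = span)
    }
    i <- j + 1L
  }
  if (length(segs) == 0L) return(NULL)
  do.call(rbind, segs)
}
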
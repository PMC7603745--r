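# Synthetic genotype-panel generator: a latent-haplotype mosaic with a
# tunable MAF spectrum and LD blocks, so every architecture (notably
# spurious pleiotropy) is testable without real data.

#' Generate a synthetic genotype panel
#'
#' Builds a diploid panel from simulated haplotypes. Markers outside LD
#' blocks are independent, with allele frequencies drawn from the requested
#' MAF spectrum. Each LD block shares one latent haplotype indicator
#' (frequency 0.5) per haplotype; every block marker is a noisy copy of the
#' indicator with flip probability `(1 - sqrt(|r|)) / 2`, which yields a
#' pairwise genotype correlation of about `r` between block members
#' (alternate markers are inverted when `r < 0`). Blocks are placed at
#' evenly spaced positions along the map, separated by runs of independent
#' markers, so positional neighbourhood scans see both block and background
#' markers.
#'
#' A fraction `inbred_fraction` of individuals is fully inbred (their two
#' haplotypes are identical, so they carry no heterozygous calls), emulating
#' diversity panels of inbred lines; the remainder pairs two independent
#' haplotypes, which exercises dominance and heterozygote-dependent paths.
#' Monomorphic columns are re-drawn so the panel is fully polymorphic.
#'
#' @param n_individuals number of individuals.
#' @param n_markers number of markers.
#' @param maf_range bounds of the allele-frequency spectrum for independent
#'   markers.
#' @param maf_distribution `"uniform"` or `"U_shaped"` (Beta(0.35, 0.35)
#'   rescaled into `maf_range`, mimicking the excess of rare and common
#'   variants in resequencing panels).
#' @param ld_blocks optional data frame (or list coercible to one) with
#'   columns `n_markers` and `r`: one row per block, `|r|` in (0, 1).
#' @param inbred_fraction fraction of individuals with no heterozygous
#'   calls (1 emulates an inbred diversity panel).
#' @param seed integer seed; the same spec and seed reproduce the panel
#'   exactly.
#' @return a [geno_matrix()] on one chromosome with positions in map order.
#' @export
make_fixture <- function(n_individuals, n_markers,
                         maf_range = c(0.05, 0.5),
                         maf_distribution = c("uniform", "U_shaped"),
                         ld_blocks = NULL, inbred_fraction = 1, seed = 1) {
  maf_distribution <- match.arg(maf_distribution)
  if (n_individuals < 2 || n_markers < 1) {
    pleio_stop("pleiosim_config_error",
               "need at least 2 individuals and 1 marker")
  }
  if (!(inbred_fraction >= 0 && inbred_fraction <= 1)) {
    pleio_stop("pleiosim_config_error", "inbred_fraction must be in [0, 1]")
  }
  if (!(maf_range[1] >= 0 && maf_range[1] < maf_range[2] &&
        maf_range[2] <= 0.5)) {
    pleio_stop("pleiosim_config_error",
               "maf_range must satisfy 0 <= lo < hi <= 0.5")
  }
  if (!is.null(ld_blocks)) {
    ld_blocks <- as.data.frame(ld_blocks)
    if (!all(c("n_markers", "r") %in% names(ld_blocks))) {
      pleio_stop("pleiosim_config_error",
                 "ld_blocks needs columns n_markers and r")
    }
    if (sum(ld_blocks$n_markers) > n_markers) {
      pleio_stop("pleiosim_config_error",
                 "LD blocks need %d markers but the panel has only %d",
                 sum(ld_blocks$n_markers), n_markers)
    }
    if (any(abs(ld_blocks$r) >= 1 | ld_blocks$r == 0)) {
      pleio_stop("pleiosim_config_error",
                 "block target r must have 0 < |r| < 1")
    }
  }
  n <- as.integer(n_individuals)
  m <- as.integer(n_markers)
  n_hap <- 2L * n

  # lay out the marker roles: blocks separated by equal runs of
  # independent markers, with runs at both ends
  block_of <- integer(m) # 0 = independent
  if (!is.null(ld_blocks) && nrow(ld_blocks)) {
    nb <- nrow(ld_blocks)
    free <- m - sum(ld_blocks$n_markers)
    gaps <- diff(floor(seq(0, free, length.out = nb + 2)))
    pos <- 0L
    for (b in seq_len(nb)) {
      pos <- pos + gaps[b]
      block_of[pos + seq_len(ld_blocks$n_markers[b])] <- b
      pos <- pos + ld_blocks$n_markers[b]
    }
  }

  with_seed(derive_seed(seed, 0L, 3L), {
    draw_maf <- function(k) {
      u <- if (maf_distribution == "uniform") stats::runif(k) else
        stats::rbeta(k, 0.35, 0.35)
      maf_range[1] + u * (maf_range[2] - maf_range[1])
    }
    hap <- matrix(0L, n_hap, m)
    if (!is.null(ld_blocks)) {
      for (b in seq_len(nrow(ld_blocks))) {
        cols <- which(block_of == b)
        latent <- stats::rbinom(n_hap, 1L, 0.5)
        eps <- (1 - sqrt(abs(ld_blocks$r[b]))) / 2
        for (kk in seq_along(cols)) {
          flip <- stats::rbinom(n_hap, 1L, eps)
          allele <- bitwXor(latent, flip)
          # negative target: invert every other block marker
          if (ld_blocks$r[b] < 0 && kk %% 2 == 0) allele <- 1L - allele
          hap[, cols[kk]] <- allele
        }
      }
    }
    indep <- which(block_of == 0L)
    if (length(indep)) {
      p <- draw_maf(length(indep))
      for (kk in seq_along(indep)) {
        hap[, indep[kk]] <- stats::rbinom(n_hap, 1L, p[kk])
      }
    }

    inbred <- rep(FALSE, n)
    n_inbred <- round(inbred_fraction * n)
    if (n_inbred > 0) inbred[sample.int(n, n_inbred)] <- TRUE
    h1 <- seq(1L, n_hap, by = 2L)
    h2 <- h1 + 1L
    hap[h2[inbred], ] <- hap[h1[inbred], ]

    geno <- hap[h1, , drop = FALSE] + hap[h2, , drop = FALSE] - 1L

    # re-draw monomorphic columns (rare; extreme allele frequencies)
    for (attempt in 1:25) {
      mono <- which(apply(geno, 2, function(col) length(unique(col)) < 2))
      if (!length(mono)) break
      for (j in mono) {
        p <- draw_maf(1)
        a1 <- stats::rbinom(n, 1L, p)
        a2 <- if (all(inbred)) a1 else ifelse(inbred, a1,
                                              stats::rbinom(n, 1L, p))
        geno[, j] <- a1 + a2 - 1L
      }
    }
    mono <- which(apply(geno, 2, function(col) length(unique(col)) < 2))
    if (length(mono)) {
      # deterministic fallback: flip one individual's genotype
      for (j in mono) geno[1, j] <- if (geno[1, j] == 1) -1 else 1
    }

    pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                    byrow = TRUE)
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    map <- data.frame(
      marker_id = sprintf("snp%05d", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * 64L,
      allele_minus = pairs[pick, 1], # alphabetically first => coded -1
      allele_plus = pairs[pick, 2],
      cm = NA_real_,
      stringsAsFactors = FALSE
    )
    g <- geno_matrix(geno, map, sprintf("ind%04d", seq_len(n)))
    g$block_of <- block_of
    g
  })
}
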
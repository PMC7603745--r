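# Shared in-code fixtures and tiny format writers used across the suite.

# A hand-sized genotype matrix with known MAFs and a heterozygote-bearing
# column.
tiny_geno <- function() {
  vals <- rbind(
    c(-1, -1,  1, 0),
    c(-1,  1,  1, 0),
    c(-1,  1, -1, 1),
    c( 0,  1, -1, -1)
  )
  map <- data.frame(
    marker_id = paste0("m", 1:4), chrom = "1", pos = c(10L, 20L, 30L, 40L),
    allele_minus = c("A", "A", "C", "A"), allele_plus = c("G", "T", "T", "C"),
    cm = NA_real_, stringsAsFactors = FALSE
  )
  geno_matrix(vals, map, paste0("ind", 1:4))
}

# Write a geno_matrix as a minimal VCF 4.2 text file (REF = allele_minus,
# ALT = allele_plus) so the VCF reader can be tested without binary data.
write_vcf_text <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$individual_ids),
                   collapse = "\t"), con)
  for (j in seq_len(ncol(geno$values))) {
    g <- geno$values[, j]
    gt <- ifelse(is.na(g), "./.",
                 ifelse(g == -1, "0/0", ifelse(g == 0, "0/1", "1/1")))
    writeLines(paste(c(geno$map$chrom[j], geno$map$pos[j],
                       geno$map$marker_id[j], geno$map$allele_minus[j],
                       geno$map$allele_plus[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# Write a geno_matrix as Plink ped/map text files; returns the ped path.
write_ped_map <- function(geno, prefix) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$marker_id, 0, map$pos),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  rows <- vapply(seq_len(nrow(geno$values)), function(i) {
    alleles <- unlist(lapply(seq_len(ncol(geno$values)), function(j) {
      g <- geno$values[i, j]
      a <- geno$map$allele_minus[j]
      b <- geno$map$allele_plus[j]
      if (is.na(g)) c("0", "0")
      else if (g == -1) c(a, a)
      else if (g == 0) c(a, b)
      else c(b, b)
    }))
    paste(c("FAM", geno$individual_ids[i], "0", "0", "0", "-9", alleles),
          collapse = " ")
  }, character(1))
  writeLines(rows, paste0(prefix, ".ped"))
  paste0(prefix, ".ped")
}

# Standard LD-block panel used by the spurious-pleiotropy tests.
block_fixture <- function(n = 300, m = 600, r = 0.6, n_blocks = 10,
                          block_len = 12, seed = 11) {
  make_fixture(n, m,
               ld_blocks = data.frame(n_markers = rep(block_len, n_blocks),
                                      r = rep(r, n_blocks)),
               seed = seed)
}
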
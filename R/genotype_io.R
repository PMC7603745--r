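# Marker data input/output and numericalization to the -1/0/1 coding the
# effect engine assumes.

#' Construct a genotype matrix object
#'
#' The central marker-data container: an individuals-by-markers matrix coded
#' -1/0/1 (homozygote / heterozygote / other homozygote; `NA` for missing)
#' together with a marker map. Markers are sorted by (chromosome, position)
#' and the value columns are reordered to match.
#'
#' @param values numeric matrix, individuals in rows, markers in columns,
#'   entries in \{-1, 0, 1, NA\}.
#' @param map data frame with columns `marker_id`, `chrom`, `pos`,
#'   `allele_minus`, `allele_plus` and optionally `cm`. `allele_minus` is the
#'   allele whose homozygote is coded -1, `allele_plus` the allele coded +1.
#' @param individual_ids character vector of unique individual identifiers.
#' @return an object of class `geno_matrix`: a list with elements `values`,
#'   `map`, `individual_ids`, `n_imputed` and `dropped`.
#' @export
geno_matrix <- function(values, map, individual_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind", seq_len(nrow(values)))
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("marker_id", "chrom", "pos", "allele_minus", "allele_plus")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols)) {
    pleio_stop("pleiosim_validation_error",
               "marker map is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  if (!"cm" %in% names(map)) map$cm <- NA_real_
  if (ncol(values) != nrow(map)) {
    pleio_stop("pleiosim_validation_error",
               "genotype matrix has %d columns but map has %d markers",
               ncol(values), nrow(map))
  }
  if (anyDuplicated(map$marker_id)) {
    pleio_stop("pleiosim_validation_error", "marker ids are not unique")
  }
  if (anyDuplicated(individual_ids)) {
    pleio_stop("pleiosim_validation_error", "individual ids are not unique")
  }
  if (any(map$pos < 1, na.rm = TRUE)) {
    pleio_stop("pleiosim_validation_error", "marker positions must be >= 1")
  }
  same <- !is.na(map$allele_minus) & map$allele_minus == map$allele_plus
  if (any(same)) {
    pleio_stop("pleiosim_validation_error",
               "marker %s has identical alleles", map$marker_id[which(same)[1]])
  }
  bad <- values[!is.na(values) & !(values %in% c(-1, 0, 1))]
  if (length(bad)) {
    pleio_stop("pleiosim_validation_error",
               "genotype values must be -1, 0, 1 or NA (found %s)",
               paste(utils::head(unique(bad), 3), collapse = ", "))
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  values <- values[, ord, drop = FALSE]
  rownames(map) <- NULL
  dimnames(values) <- list(individual_ids, map$marker_id)
  structure(
    list(values = values, map = map, individual_ids = individual_ids,
         n_imputed = 0L,
         dropped = list(multiallelic = 0L, monomorphic = 0L, all_missing = 0L)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d markers (%d chromosome%s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$map$chrom)),
              if (length(unique(x$map$chrom)) == 1) "" else "s"))
  if (x$n_imputed > 0) {
    cat(sprintf("  %d missing calls imputed to 0\n", x$n_imputed))
  }
  d <- unlist(x$dropped)
  if (any(d > 0)) {
    cat(sprintf("  dropped at read: %s\n",
                paste(sprintf("%s=%d", names(d[d > 0]), d[d > 0]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$values)

# --- numericalization -------------------------------------------------------

.iupac_het <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")
.missing_calls <- c("NN", "N", "--", "-", "00", "0", "./.", ".|.", ".", "NA")

# Split diploid calls ("AG", or IUPAC single letters) into a 2-column allele
# matrix; missing calls become NA rows.
split_calls <- function(calls) {
  calls <- toupper(as.character(calls))
  out <- matrix(NA_character_, length(calls), 2)
  miss <- calls %in% .missing_calls | is.na(calls)
  one <- !miss & nchar(calls) == 1
  hom1 <- one & calls %in% c("A", "C", "G", "T")
  out[hom1, 1] <- out[hom1, 2] <- calls[hom1]
  het1 <- one & calls %in% names(.iupac_het)
  if (any(het1)) {
    exp <- .iupac_het[calls[het1]]
    out[het1, 1] <- substr(exp, 1, 1)
    out[het1, 2] <- substr(exp, 2, 2)
  }
  two <- !miss & nchar(calls) == 2
  out[two, 1] <- substr(calls[two], 1, 1)
  out[two, 2] <- substr(calls[two], 2, 2)
  bad <- !miss & !one & !two
  if (any(bad)) {
    pleio_stop("pleiosim_format_error",
               "cannot parse genotype call '%s'", calls[which(bad)[1]])
  }
  out
}

#' Numericalize diploid allele calls for one marker
#'
#' Converts allele-call genotypes (e.g. `"AA"`, `"AG"`, IUPAC single letters)
#' to the numeric -1/0/+1 coding. The coding direction is deterministic:
#' +1 is the homozygote of the alphabetically-second observed allele (for
#' VCF input the ALT allele plays that role instead, see
#' [read_genotypes()]). Heterozygotes are 0, missing calls `NA`.
#'
#' @param calls character vector of diploid calls for one marker.
#' @return list with `code` (numeric vector over \{-1, 0, 1, NA\}),
#'   `allele_minus`, `allele_plus`, and `monomorphic` (logical).
#' @export
numericalize <- function(calls) {
  al <- split_calls(calls)
  obs <- sort(unique(stats::na.omit(c(al))))
  if (length(obs) > 2) {
    pleio_stop("pleiosim_validation_error",
               "marker is not biallelic: observed alleles %s",
               paste(obs, collapse = "/"))
  }
  if (length(obs) == 0) {
    return(list(code = rep(NA_real_, nrow(al)),
                allele_minus = NA_character_, allele_plus = NA_character_,
                monomorphic = TRUE))
  }
  minus <- obs[1]
  plus <- if (length(obs) == 2) obs[2] else NA_character_
  code <- rowSums(al == obs[length(obs)]) - 1 # count of "plus" alleles - 1
  if (length(obs) == 1) code <- rep(-1, nrow(al))
  code[is.na(al[, 1])] <- NA_real_
  list(code = as.numeric(code), allele_minus = minus, allele_plus = plus,
       monomorphic = length(obs) < 2 ||
         length(unique(stats::na.omit(code))) < 2)
}

# --- readers ----------------------------------------------------------------

#' Read biallelic marker data
#'
#' Reads marker data from one of four formats and numericalizes it to the
#' -1/0/+1 coding. Multiallelic, all-missing and monomorphic markers are
#' dropped (counts are kept in the returned object); remaining missing calls
#' are imputed to 0 (the heterozygote / column mean direction-free value) so
#' that genetic values are defined for every individual.
#'
#' Coding direction: for letter-based formats (HapMap, ped/map) the +1
#' homozygote is the alphabetically-second observed allele; for VCF it is
#' the ALT homozygote; numeric input is passed through unchanged. The
#' direction is recorded per marker in the map (`allele_minus`,
#' `allele_plus`).
#'
#' @param path path to the marker file. For `numeric`, a sidecar map file
#'   `<path>.map` (tab-separated, columns `marker_id`, `chrom`, `pos`,
#'   `allele_minus`, `allele_plus`, `cm`) is read when present. For
#'   `plink_ped`, `path` is the `.ped` file and the matching `.map` file must
#'   sit alongside it.
#' @param format one of `"numeric"`, `"hapmap"`, `"vcf"`, `"plink_ped"`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path,
                           format = c("numeric", "hapmap", "vcf", "plink_ped")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    pleio_stop("pleiosim_io_error", "file does not exist: %s", path)
  }
  g <- switch(format,
    numeric = read_numeric(path),
    hapmap = read_hapmap(path),
    vcf = read_vcf(path),
    plink_ped = read_plink_ped(path)
  )
  finalize_geno(g)
}

# Shared post-processing: drop monomorphic/all-missing columns, impute
# remaining NA to 0, record counts.
finalize_geno <- function(g) {
  v <- g$values
  n_nonmiss <- colSums(!is.na(v))
  all_missing <- n_nonmiss == 0
  n_distinct <- apply(v, 2, function(col) length(unique(col[!is.na(col)])))
  mono <- !all_missing & n_distinct < 2
  keep <- !all_missing & !mono
  g$dropped$all_missing <- g$dropped$all_missing + sum(all_missing)
  g$dropped$monomorphic <- g$dropped$monomorphic + sum(mono)
  if (!any(keep)) {
    pleio_stop("pleiosim_validation_error",
               "no polymorphic markers left after filtering")
  }
  g$values <- v[, keep, drop = FALSE]
  g$map <- g$map[keep, , drop = FALSE]
  rownames(g$map) <- NULL
  n_na <- sum(is.na(g$values))
  if (n_na > 0) {
    g$values[is.na(g$values)] <- 0
    g$n_imputed <- g$n_imputed + n_na
  }
  g
}

read_numeric <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) {
    pleio_stop("pleiosim_format_error",
               "numeric file %s needs a taxa column plus marker columns", path)
  }
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  bad <- which(!is.na(vals) & !(vals %in% c(-1, 0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    pleio_stop("pleiosim_validation_error",
               "numeric genotype file %s: marker '%s' has value outside {-1,0,1} at data line %d",
               path, colnames(vals)[bad[1, 2]], bad[1, 1])
  }
  map_path <- paste0(path, ".map")
  if (file.exists(map_path)) {
    map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
    if (!identical(as.character(map$marker_id), colnames(vals))) {
      pleio_stop("pleiosim_format_error",
                 "map sidecar %s does not match the marker columns of %s",
                 map_path, path)
    }
  } else {
    map <- data.frame(marker_id = colnames(vals), chrom = "1",
                      pos = seq_len(ncol(vals)), allele_minus = "A",
                      allele_plus = "B", cm = NA_real_,
                      stringsAsFactors = FALSE)
  }
  geno_matrix(vals, map, ids)
}

read_hapmap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (ncol(tab) < 12) {
    pleio_stop("pleiosim_format_error",
               "HapMap file %s must have 11 metadata columns plus genotypes",
               path)
  }
  ids <- colnames(tab)[-(1:11)]
  m <- nrow(tab)
  code <- matrix(NA_real_, length(ids), m)
  minus <- plus <- character(m)
  multi <- logical(m)
  for (j in seq_len(m)) {
    res <- tryCatch(numericalize(as.character(unlist(tab[j, -(1:11)]))),
                    error = function(e) e)
    if (inherits(res, "pleiosim_validation_error")) {
      multi[j] <- TRUE
      minus[j] <- "A"; plus[j] <- "B"
      next
    }
    if (inherits(res, "error")) stop(res)
    code[, j] <- res$code
    minus[j] <- res$allele_minus
    plus[j] <- if (is.na(res$allele_plus)) "B" else res$allele_plus
  }
  keep <- !multi
  map <- data.frame(
    marker_id = as.character(tab[[1]]), chrom = as.character(tab[[3]]),
    pos = as.integer(tab[[4]]), allele_minus = minus, allele_plus = plus,
    cm = NA_real_, stringsAsFactors = FALSE
  )
  g <- geno_matrix(code[, keep, drop = FALSE], map[keep, , drop = FALSE], ids)
  g$dropped$multiallelic <- sum(multi)
  g
}

read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL,
                                c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                  "FILTER")))
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1 | is.na(fix[, "ALT"])
  gt_clean <- gsub("\\|", "/", gt)
  code_one <- function(x) {
    out <- rep(NA_real_, length(x))
    out[x == "0/0"] <- -1
    out[x %in% c("0/1", "1/0")] <- 0
    out[x == "1/1"] <- 1
    out
  }
  code <- apply(gt_clean, 2, code_one)
  if (is.null(dim(code))) code <- matrix(code, nrow = nrow(gt_clean))
  ids <- colnames(gt)
  mid <- fix[, "ID"]
  no_id <- is.na(mid) | mid == "."
  mid[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  map <- data.frame(
    marker_id = mid, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    allele_minus = fix[, "REF"], allele_plus = fix[, "ALT"], cm = NA_real_,
    stringsAsFactors = FALSE
  )
  keep <- !multi
  g <- geno_matrix(t(code)[, keep, drop = FALSE], map[keep, , drop = FALSE],
                   ids)
  g$dropped$multiallelic <- sum(multi)
  g
}

read_plink_ped <- function(path) {
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path) || !file.exists(map_path)) {
    pleio_stop("pleiosim_io_error",
               "plink map file not found next to %s", path)
  }
  map_tab <- utils::read.table(map_path, header = FALSE,
                               stringsAsFactors = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  names(map_tab) <- c("chrom", "marker_id", "cm", "pos")
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map_tab)
  if (ncol(ped) != 6 + 2 * m) {
    pleio_stop("pleiosim_format_error",
               "ped file %s has %d genotype fields but map lists %d markers",
               path, ncol(ped) - 6, m)
  }
  ids <- ped[[2]]
  code <- matrix(NA_real_, length(ids), m)
  minus <- plus <- character(m)
  for (j in seq_len(m)) {
    a1 <- ped[[6 + 2 * j - 1]]
    a2 <- ped[[6 + 2 * j]]
    a1[a1 == "0"] <- NA
    a2[a2 == "0"] <- NA
    calls <- ifelse(is.na(a1) | is.na(a2), NA, paste0(a1, a2))
    res <- numericalize(calls)
    code[, j] <- res$code
    minus[j] <- if (is.na(res$allele_minus)) "A" else res$allele_minus
    plus[j] <- if (is.na(res$allele_plus)) "B" else res$allele_plus
  }
  map <- data.frame(
    marker_id = map_tab$marker_id, chrom = map_tab$chrom, pos = map_tab$pos,
    allele_minus = minus, allele_plus = plus, cm = map_tab$cm,
    stringsAsFactors = FALSE
  )
  geno_matrix(code, map, ids)
}

# --- writers ----------------------------------------------------------------

#' Write marker data, optionally excluding QTN columns
#'
#' Writes a [geno_matrix()] back out in numeric or HapMap format so that
#' reading the file with [read_genotypes()] reproduces the matrix minus the
#' excluded columns. Used by the simulation driver with `remove_QTN = TRUE`
#' to export marker data without the causal SNPs.
#'
#' @param geno a [geno_matrix()].
#' @param path output path. Numeric output also writes a `<path>.map`
#'   sidecar.
#' @param format `"numeric"` or `"hapmap"`.
#' @param exclude integer vector of marker column indices to drop.
#' @return `path`, invisibly.
#' @export
write_markers <- function(geno, path, format = c("numeric", "hapmap"),
                          exclude = integer(0)) {
  format <- match.arg(format)
  m <- ncol(geno$values)
  exclude <- unique(as.integer(exclude))
  if (length(exclude) && (min(exclude) < 1 || max(exclude) > m)) {
    pleio_stop("pleiosim_validation_error",
               "exclude indices must lie in 1..%d", m)
  }
  keep <- setdiff(seq_len(m), exclude)
  if (!length(keep)) {
    pleio_stop("pleiosim_validation_error",
               "cannot write an empty marker set (all %d columns excluded)", m)
  }
  vals <- geno$values[, keep, drop = FALSE]
  map <- geno$map[keep, , drop = FALSE]
  if (format == "numeric") {
    tab <- data.frame(taxa = geno$individual_ids, vals, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    calls <- matrix("NN", nrow(vals), ncol(vals))
    for (j in seq_len(ncol(vals))) {
      a <- map$allele_minus[j]
      b <- map$allele_plus[j]
      col <- vals[, j]
      calls[, j] <- ifelse(is.na(col), "NN",
                           ifelse(col == -1, paste0(a, a),
                                  ifelse(col == 0, paste0(a, b),
                                         paste0(b, b))))
    }
    head_cols <- data.frame(
      `rs#` = map$marker_id,
      alleles = paste0(map$allele_minus, "/", map$allele_plus),
      chrom = map$chrom, pos = map$pos, strand = "+", `assembly#` = "NA",
      center = "NA", protLSID = "NA", assayLSID = "NA", panelLSID = "NA",
      QCcode = "NA", check.names = FALSE, stringsAsFactors = FALSE
    )
    out <- cbind(head_cols,
                 as.data.frame(t(calls), stringsAsFactors = FALSE))
    names(out) <- c(names(head_cols), geno$individual_ids)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
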
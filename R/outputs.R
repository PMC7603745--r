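# Phenotype, provenance and log writers.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write a phenotype matrix for downstream GWAS/GS software
#'
#' Formats:
#' * `gemma`: whitespace-separated trait columns, no header, rows in the
#'   genotype file's individual order, `NA` for missing — GEMMA's `-p` file.
#' * `tassel`: TASSEL trait-format text: a `<Phenotype>` directive line, a
#'   `taxa`/`data` type line, a header naming the taxa column and traits,
#'   then one row per individual.
#' * `wide_table`: tab-separated `taxa`, `rep`, then one column per trait.
#' * `long_table`: tab-separated `taxa`, `rep`, `trait`, `value`.
#'
#' @param P individuals x traits numeric matrix with individual row names.
#' @param path output file path.
#' @param format one of `"gemma"`, `"tassel"`, `"wide_table"`,
#'   `"long_table"`.
#' @param rep_id replicate identifier written by the table formats.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(P, path,
                             format = c("gemma", "tassel", "wide_table",
                                        "long_table"),
                             rep_id = 1L) {
  format <- match.arg(format)
  if (any(!is.finite(P) & !is.na(P))) {
    pleio_stop("pleiosim_validation_error",
               "phenotypes contain non-finite values")
  }
  taxa <- rownames(P)
  if (is.null(taxa)) taxa <- paste0("ind", seq_len(nrow(P)))
  traits <- colnames(P)
  if (is.null(traits)) traits <- paste0("trait_", seq_len(ncol(P)))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "gemma") {
    apply_fmt <- apply(P, 1, function(r) paste(fmt_num(r), collapse = " "))
    writeLines(apply_fmt, con)
  } else if (format == "tassel") {
    writeLines("<Phenotype>", con)
    writeLines(paste(c("taxa", rep("data", ncol(P))), collapse = "\t"), con)
    writeLines(paste(c("Taxa", traits), collapse = "\t"), con)
    for (i in seq_len(nrow(P))) {
      writeLines(paste(c(taxa[i], fmt_num(P[i, ])), collapse = "\t"), con)
    }
  } else if (format == "wide_table") {
    writeLines(paste(c("taxa", "rep", traits), collapse = "\t"), con)
    for (i in seq_len(nrow(P))) {
      writeLines(paste(c(taxa[i], rep_id, fmt_num(P[i, ])), collapse = "\t"),
                 con)
    }
  } else {
    writeLines("taxa\trep\ttrait\tvalue", con)
    for (j in seq_len(ncol(P))) {
      for (i in seq_len(nrow(P))) {
        writeLines(paste(c(taxa[i], rep_id, traits[j], fmt_num(P[i, j])),
                         collapse = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read a phenotype file written by [write_phenotypes()]
#'
#' Round-trip reader used for validation; returns a numeric matrix
#' (individuals x traits). For the table formats only a single replicate's
#' rows are returned when `rep_id` is given.
#'
#' @param path file path.
#' @param format format the file was written in.
#' @param rep_id replicate to extract for `wide_table`/`long_table`.
#' @export
read_phenotypes <- function(path,
                            format = c("gemma", "tassel", "wide_table",
                                       "long_table"),
                            rep_id = 1L) {
  format <- match.arg(format)
  if (format == "gemma") {
    tab <- utils::read.table(path, header = FALSE)
    return(as.matrix(tab))
  }
  if (format == "tassel") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2,
                             check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    return(m)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  tab <- tab[tab$rep == rep_id, , drop = FALSE]
  if (format == "wide_table") {
    m <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(m) <- tab$taxa
    return(m)
  }
  traits <- unique(tab$trait)
  taxa <- unique(tab$taxa)
  m <- matrix(NA_real_, length(taxa), length(traits),
              dimnames = list(taxa, traits))
  m[cbind(match(tab$taxa, taxa), match(tab$trait, traits))] <- tab$value
  m
}

# QTN provenance rows for one replicate in the map-table schema:
# Replication, Marker_type, Marker, Allele, Chromosome, Position, cM, MAF
qtn_map_rows <- function(geno, assignment, rep_id) {
  mk_row <- function(idx, type) {
    if (!length(idx)) return(NULL)
    mp <- geno$map[idx, , drop = FALSE]
    data.frame(
      Replication = rep_id, Marker_type = type, Marker = mp$marker_id,
      Allele = paste0(mp$allele_minus, "/", mp$allele_plus),
      Chromosome = mp$chrom, Position = mp$pos, cM = mp$cm,
      MAF = vapply(idx, function(j) compute_maf(geno$values[, j]),
                   numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  spurious <- length(assignment$link) > 0
  rows <- list()
  if (spurious) {
    rows <- list(
      mk_row(assignment$link, "cause_of_LD"),
      mk_row(assignment$ld_table$qtn_trait1, "QTN_upstream"),
      mk_row(assignment$ld_table$qtn_trait2, "QTN_downstream")
    )
  } else {
    for (t in seq_along(assignment$traits)) {
      tr <- assignment$traits[[t]]
      rows <- c(rows, list(
        mk_row(tr$add, sprintf("additive_trait_%d", t)),
        mk_row(tr$dom, sprintf("dominance_trait_%d", t)),
        mk_row(as.vector(t(tr$epi)), sprintf("epistatic_trait_%d", t))
      ))
    }
  }
  do.call(rbind, Filter(Negate(is.null), rows))
}

# LD summary rows for one spurious replicate in the LD-table schema
ld_summary_rows <- function(geno, assignment, rep_id, ld_input) {
  lt <- assignment$ld_table
  if (is.null(lt) || !nrow(lt)) return(NULL)
  id_of <- function(i) ifelse(is.na(i), NA_character_, geno$map$marker_id[i])
  data.frame(
    Replication = rep_id,
    Marker_causing_LD = id_of(lt$link),
    input_LD = ld_input,
    Actual_LD_with_QTN_of_Trait_1 = lt$r_link_qtn1,
    Actual_LD_with_QTN_of_Trait_2 = lt$r_link_qtn2,
    QTN_for_Trait_1 = id_of(lt$qtn_trait1),
    QTN_for_Trait_2 = id_of(lt$qtn_trait2),
    LD_between_QTNs = lt$r_qtn_qtn,
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Human-readable log comparing targets with realized statistics.
write_log <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  cfg <- sim$config
  w("pleiosim simulation log")
  w("=======================")
  w("architecture      : %s", cfg$architecture)
  w("traits            : %d", cfg$ntraits)
  w("replicates        : %d", cfg$rep)
  w("root seed         : %d", cfg$seed)
  w("vary_QTN          : %s", cfg$vary_QTN)
  if (!is.null(cfg$maf_above)) {
    w("MAF window        : (%g, %g), exclusive", cfg$maf_above,
      cfg$maf_below)
  }
  if (cfg$architecture == "spurious_pleiotropy") {
    w("ld ceiling        : %g (%s)", cfg$ld, cfg$type_of_ld)
  }
  w("missing imputed   : %d", sim$geno_summary$n_imputed)
  w("markers dropped   : monomorphic=%d, multiallelic=%d, all_missing=%d",
    sim$geno_summary$dropped$monomorphic,
    sim$geno_summary$dropped$multiallelic,
    sim$geno_summary$dropped$all_missing)
  w("")
  w("heritability: target vs realized (mean over %d replicate%s)",
    cfg$rep, if (cfg$rep == 1) "" else "s")
  mean_h2 <- colMeans(sim$realized_h2, na.rm = TRUE)
  for (t in seq_len(cfg$ntraits)) {
    w("  trait_%d: target %.4f, realized %.6f", t, sim$h2[t], mean_h2[t])
  }
  if (!is.null(sim$cor_target)) {
    w("")
    w("genetic correlation: target vs realized (mean over replicates)")
    ct <- sim$cor_target
    cr <- sim$realized_genetic_cor_mean
    for (a in seq_len(nrow(ct))) for (b in seq_len(ncol(ct))) {
      if (b > a) w("  trait_%d ~ trait_%d: target %.4f, realized %.6f",
                   a, b, ct[a, b], cr[a, b])
    }
  }
  if (!is.null(sim$cor_res_target) && cfg$ntraits > 1) {
    w("")
    w("residual correlation: target vs realized (mean over replicates)")
    ct <- sim$cor_res_target
    cr <- sim$realized_residual_cor_mean
    for (a in seq_len(nrow(ct))) for (b in seq_len(ncol(ct))) {
      if (b > a) w("  trait_%d ~ trait_%d: target %.4f, realized %.6f",
                   a, b, ct[a, b], cr[a, b])
    }
  }
  w("")
  w("files written:")
  for (f in sim$files) w("  %s", basename(f)) # relative: the directory is
  # the user's choice, not part of the result
  invisible(path)
}
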
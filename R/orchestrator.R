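# The simulation driver: validates the full configuration, runs replicates
# through QTN selection -> genetic values -> optional whitening/coloring ->
# noise, and writes phenotypes, provenance and the log.

#' Simulate single- or multi-trait phenotypes from marker data
#'
#' The main entry point. For each of `rep` experiments (replicates) it
#' selects QTNs under the chosen architecture, computes genetic values from
#' the additive/dominance/epistatic effect models, optionally imposes a
#' target genetic correlation via the whitening/coloring transformation,
#' calibrates residual variance from the per-trait heritabilities, draws
#' (optionally correlated) normal errors, and assembles phenotypes.
#'
#' Parameter names mirror the field's conventional simulator interface:
#' `add_QTN_num`, `maf_above`/`maf_below`, `ld`, `type_of_ld`, `vary_QTN`,
#' `remove_QTN`, `cor`, `cor_res`, `rep`.
#'
#' All randomness derives from `seed`; the same configuration and seed
#' reproduce every output byte-for-byte. Per-replicate QTN-selection and
#' noise seeds are recorded in the returned object (and `seeds.txt` when
#' writing files).
#'
#' @param geno a [geno_matrix()] (from [read_genotypes()] or
#'   [make_fixture()]).
#' @param architecture `"single_trait"`, `"pleiotropy"`,
#'   `"partial_pleiotropy"` or `"spurious_pleiotropy"`.
#' @param ntraits number of traits.
#' @param add_QTN_num,dom_QTN_num,epi_QTN_num QTN counts; see
#'   [architecture_spec()] for the partial-pleiotropy list form.
#'   `epi_QTN_num` counts additive-by-additive pairs.
#' @param add_effect,dom_effect,epi_effect effect sizes per model class:
#'   either a numeric vector of per-trait geometric-series bases (effect i
#'   of trait t is `base[t]^i`), or a list of per-trait numeric vectors of
#'   explicit effects, ordered largest-first (for partial pleiotropy:
#'   shared QTNs first, then trait-specific).
#' @param h2 per-trait heritabilities in (0, 1] (recycled to `ntraits`).
#' @param cor optional target genetic correlation matrix (the
#'   whitening/coloring target).
#' @param cor_res optional residual correlation matrix; errors are
#'   independent when `NULL`.
#' @param ld,type_of_ld LD ceiling and mode for spurious pleiotropy.
#' @param maf_above,maf_below optional exclusive MAF window for QTN
#'   eligibility.
#' @param vary_QTN re-draw QTNs each replicate (`TRUE`) or reuse one draw
#'   (`FALSE`).
#' @param rep number of experiments.
#' @param seed root seed.
#' @param remove_QTN also write the marker data without the QTN columns
#'   (linking markers are kept: they are the discoverable signal).
#' @param out output directory (created if needed); `NULL` runs in memory
#'   only.
#' @param output_format any subset of `"wide_table"`, `"long_table"`,
#'   `"gemma"`, `"tassel"`. Table formats produce one file covering all
#'   replicates; `gemma`/`tassel` produce one file per replicate.
#' @param marker_format format for the `remove_QTN` marker file.
#' @param scan_window neighbourhood size for spurious LD searches.
#' @param verbose print a one-line summary.
#' @return an object of class `pleiosim` with elements `phenotypes` (list of
#'   per-replicate matrices), `genetic_values`, `assignments`,
#'   `realized_h2` (rep x trait matrix), `realized_genetic_cor_mean`,
#'   `realized_residual_cor_mean`, `qtn_map`, `ld_summary`,
#'   `variance_explained`, `seeds`, `files`, `config`.
#' @export
create_phenotypes <- function(geno,
                              architecture = c("pleiotropy",
                                               "partial_pleiotropy",
                                               "spurious_pleiotropy",
                                               "single_trait"),
                              ntraits = 2,
                              add_QTN_num = 0, dom_QTN_num = 0,
                              epi_QTN_num = 0,
                              add_effect = NULL, dom_effect = NULL,
                              epi_effect = NULL,
                              h2 = 0.5, cor = NULL, cor_res = NULL,
                              ld = 0.7,
                              type_of_ld = c("indirect", "direct"),
                              maf_above = NULL, maf_below = NULL,
                              vary_QTN = FALSE, rep = 1, seed = 165,
                              remove_QTN = FALSE, out = NULL,
                              output_format = "wide_table",
                              marker_format = c("numeric", "hapmap"),
                              scan_window = 50, verbose = FALSE) {
  architecture <- match.arg(architecture)
  type_of_ld <- match.arg(type_of_ld)
  marker_format <- match.arg(marker_format)
  if (!inherits(geno, "geno_matrix")) {
    pleio_stop("pleiosim_config_error",
               "geno must be a geno_matrix (see read_genotypes/make_fixture)")
  }
  bad_fmt <- setdiff(output_format,
                     c("wide_table", "long_table", "gemma", "tassel"))
  if (length(bad_fmt)) {
    pleio_stop("pleiosim_config_error", "unknown output format: %s",
               paste(bad_fmt, collapse = ", "))
  }
  spec <- architecture_spec(
    architecture = architecture, n_traits = ntraits,
    add_qtn_num = add_QTN_num, dom_qtn_num = dom_QTN_num,
    epi_qtn_num = epi_QTN_num, ld = ld, type_of_ld = type_of_ld,
    maf_above = maf_above, maf_below = maf_below, vary_qtn = vary_QTN,
    seed = seed, n_experiments = rep, scan_window = scan_window
  )
  ntraits <- spec$n_traits
  h2 <- rep_len(as.numeric(h2), ntraits)
  if (any(h2 <= 0 | h2 > 1)) {
    pleio_stop("pleiosim_config_error",
               "heritabilities must lie in (0, 1]")
  }
  if (!is.null(cor)) {
    cor <- as.matrix(cor)
    if (!all(dim(cor) == ntraits)) {
      pleio_stop("pleiosim_config_error", "cor must be %d x %d", ntraits,
                 ntraits)
    }
    check_correlation_matrix(cor, "cor")
  }
  if (!is.null(cor_res)) {
    cor_res <- as.matrix(cor_res)
    if (!all(dim(cor_res) == ntraits)) {
      pleio_stop("pleiosim_config_error", "cor_res must be %d x %d",
                 ntraits, ntraits)
    }
    check_correlation_matrix(cor_res, "cor_res")
  }
  effects <- list(add = add_effect, dom = dom_effect, epi = epi_effect)

  assignments <- select_qtns(spec, geno)

  n_ind <- nrow(geno$values)
  phenos <- vector("list", rep)
  gvals <- vector("list", rep)
  realized_h2 <- matrix(NA_real_, rep, ntraits,
                        dimnames = list(NULL,
                                        paste0("trait_", seq_len(ntraits))))
  gcor_sum <- matrix(0, ntraits, ntraits)
  rcor_sum <- matrix(0, ntraits, ntraits)
  rcor_n <- 0L
  qtn_map <- list()
  ld_summary <- list()
  var_expl <- list()
  seeds <- data.frame(rep = seq_len(rep), qtn_seed = NA_integer_,
                      noise_seed = NA_integer_)

  for (r in seq_len(rep)) {
    asg <- assignments[[r]]
    res <- tryCatch(
      run_replicate(geno, asg, effects, h2, cor, cor_res, spec, r),
      error = function(e) {
        # keep the condition class, attach the replicate index
        stop(structure(
          class = class(e),
          list(message = sprintf("replicate %d: %s", r,
                                 conditionMessage(e)),
               call = conditionCall(e))
        ))
      }
    )
    phenos[[r]] <- res$P
    gvals[[r]] <- res$G
    realized_h2[r, ] <- res$realized_h2
    if (ntraits > 1) {
      gcor_sum <- gcor_sum + stats::cor(res$G)
      if (any(res$var_e > 0)) {
        rcor_sum <- rcor_sum + stats::cor(res$E)
        rcor_n <- rcor_n + 1L
      }
    }
    qtn_map[[r]] <- qtn_map_rows(geno, asg, r)
    lsr <- ld_summary_rows(geno, asg, r, spec$ld)
    if (!is.null(lsr)) ld_summary[[r]] <- lsr
    ve <- res$var_expl
    if (!is.null(ve)) {
      ve <- cbind(rep = r, ve)
      var_expl[[r]] <- ve
    }
    seeds$qtn_seed[r] <- asg$seed
    seeds$noise_seed[r] <- res$noise_seed
  }

  sim <- structure(list(
    phenotypes = phenos,
    genetic_values = gvals,
    assignments = assignments,
    realized_h2 = realized_h2,
    realized_genetic_cor_mean = if (ntraits > 1) gcor_sum / rep else NULL,
    realized_residual_cor_mean = if (rcor_n > 0) rcor_sum / rcor_n else NULL,
    qtn_map = do.call(rbind, qtn_map),
    ld_summary = if (length(ld_summary)) do.call(rbind, ld_summary) else
      NULL,
    variance_explained = if (length(var_expl)) do.call(rbind, var_expl) else
      NULL,
    seeds = seeds,
    h2 = h2,
    cor_target = cor,
    cor_res_target = cor_res,
    geno_summary = list(n_imputed = geno$n_imputed, dropped = geno$dropped),
    files = character(0),
    config = list(architecture = architecture, ntraits = ntraits,
                  add_QTN_num = add_QTN_num, dom_QTN_num = dom_QTN_num,
                  epi_QTN_num = epi_QTN_num, h2 = h2, ld = ld,
                  type_of_ld = type_of_ld, maf_above = maf_above,
                  maf_below = maf_below, vary_QTN = vary_QTN, rep = rep,
                  seed = as.integer(seed), remove_QTN = remove_QTN,
                  output_format = output_format)
  ), class = "pleiosim")

  if (!is.null(out)) {
    sim <- write_simulation(sim, geno, out, output_format, marker_format,
                            remove_QTN)
  }
  if (verbose) print(sim)
  sim
}

# One replicate: genetic values -> correlation transform -> calibrated noise.
run_replicate <- function(geno, asg, effects, h2, cor, cor_res, spec, r) {
  agg <- aggregate_genetic_values(geno, asg, effects)
  G_pre <- agg$G
  # variance explained is decomposed on the pre-transform scale; the
  # phenotypic denominator is the genetic variance inflated to the target
  # heritability
  denom <- apply(G_pre, 2, stats::var) / h2
  ve <- variance_explained(agg$contributions, denom)
  G <- if (!is.null(cor) && ncol(G_pre) > 1) whiten_color(G_pre, cor) else
    G_pre
  var_g <- apply(G, 2, stats::var)
  var_e <- residual_variance(var_g, h2)
  noise_seed <- derive_seed(spec$seed, r, 2L)
  E <- simulate_errors(nrow(G), var_e, cor_res, noise_seed)
  asm <- assemble_phenotypes(G, E)
  list(P = asm$phenotypes, G = G, E = E, realized_h2 = asm$realized_h2,
       var_e = var_e, var_expl = ve, noise_seed = noise_seed)
}

# Write phenotypes, provenance tables, seeds, log and (optionally) the
# marker file without QTNs.
write_simulation <- function(sim, geno, out, output_format, marker_format,
                             remove_QTN) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add_file <- function(f) files <<- c(files, f)
  n_rep <- sim$config$rep

  for (fmt in output_format) {
    if (fmt %in% c("wide_table", "long_table")) {
      path <- file.path(out, sprintf("phenotypes_%s.txt",
                                     sub("_table", "", fmt)))
      con <- file(path, "w")
      for (r in seq_len(n_rep)) {
        tmp <- tempfile()
        write_phenotypes(sim$phenotypes[[r]], tmp, fmt, rep_id = r)
        lines <- readLines(tmp)
        unlink(tmp)
        if (r > 1) lines <- lines[-1] # drop repeated header
        writeLines(lines, con)
      }
      close(con)
      add_file(path)
    } else {
      for (r in seq_len(n_rep)) {
        path <- file.path(out, sprintf("phenotypes_rep%03d.%s.txt", r, fmt))
        write_phenotypes(sim$phenotypes[[r]], path, fmt, rep_id = r)
        add_file(path)
      }
    }
  }

  if (!is.null(sim$qtn_map)) {
    path <- file.path(out, "qtn_map.txt")
    write_tsv(sim$qtn_map, path)
    add_file(path)
  }
  if (!is.null(sim$ld_summary)) {
    path <- file.path(out, "ld_summary.txt")
    write_tsv(sim$ld_summary, path)
    add_file(path)
  }
  if (!is.null(sim$variance_explained)) {
    path <- file.path(out, "variance_explained.txt")
    write_tsv(sim$variance_explained, path)
    add_file(path)
  }
  path <- file.path(out, "seeds.txt")
  write_tsv(sim$seeds, path)
  add_file(path)
  path <- file.path(out, "realized_h2.txt")
  write_tsv(data.frame(rep = seq_len(n_rep), sim$realized_h2,
                       check.names = FALSE), path)
  add_file(path)

  if (remove_QTN) {
    qtn_idx <- sort(unique(unlist(lapply(sim$assignments,
                                         assignment_qtn_indices))))
    ext <- if (marker_format == "numeric") "numeric.txt" else "hapmap.txt"
    path <- file.path(out, paste0("markers_no_qtn.", ext))
    write_markers(geno, path, marker_format, exclude = qtn_idx)
    add_file(path)
    if (marker_format == "numeric") add_file(paste0(path, ".map"))
  }

  sim$files <- files
  log_path <- file.path(out, "simulation_log.txt")
  sim$files <- c(sim$files, log_path)
  write_log(sim, log_path)
  sim
}

#' @export
print.pleiosim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("pleiosim simulation: %s, %d trait%s, %d replicate%s\n",
              cfg$architecture, cfg$ntraits,
              if (cfg$ntraits == 1) "" else "s", cfg$rep,
              if (cfg$rep == 1) "" else "s"))
  mh <- colMeans(x$realized_h2, na.rm = TRUE)
  cat(sprintf("  realized h2 (mean): %s\n",
              paste(sprintf("%.3f", mh), collapse = ", ")))
  if (!is.null(x$realized_genetic_cor_mean) && cfg$ntraits > 1) {
    off <- x$realized_genetic_cor_mean[upper.tri(x$realized_genetic_cor_mean)]
    cat(sprintf("  realized genetic cor (mean, upper tri): %s\n",
                paste(sprintf("%.3f", off), collapse = ", ")))
  }
  if (length(x$files)) {
    cat(sprintf("  %d output file%s written\n", length(x$files),
                if (length(x$files) == 1) "" else "s"))
  }
  invisible(x)
}
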
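# Effect-size assignment and per-individual genetic values under the
# additive, dominance and additive-by-additive epistatic models.
#
# Effect coding on the -1/0/1 genotype scale:
#   additive : -a, 0, +a for genotypes -1, 0, +1
#   dominance:  0, d,  0 (heterozygote only)
#   epistasis: e * g1 * g2 for a QTN pair (g1, g2)

#' Geometric series of QTN effect sizes
#'
#' Effect i (1-based) equals `base^i`, so the largest effect goes to the
#' first-ranked QTN. `base = 0.4, n = 2` gives `(0.40, 0.16)`.
#'
#' @param base nonzero series base.
#' @param n number of effects (0 gives an empty vector).
#' @return numeric vector of length `n`.
#' @export
geometric_effects <- function(base, n) {
  if (!is_scalar_number(base) || base == 0) {
    pleio_stop("pleiosim_config_error",
               "geometric effect base must be a single nonzero number")
  }
  if (n < 0) pleio_stop("pleiosim_config_error", "n must be >= 0")
  if (n == 0) return(numeric(0))
  base^seq_len(n)
}

check_coded <- function(column) {
  if (any(!column %in% c(-1, 0, 1))) {
    pleio_stop("pleiosim_validation_error",
               "genotype column must be coded -1/0/1")
  }
  invisible(column)
}

#' Per-individual additive QTN contribution
#' @param column coded genotype column.
#' @param a additive effect size.
#' @return numeric vector `a * g`.
#' @export
additive_value <- function(column, a) {
  check_coded(column)
  a * column
}

#' Per-individual dominance QTN contribution
#'
#' Heterozygotes receive `d`; both homozygotes receive 0, so dominance is
#' inert in fully inbred panels.
#'
#' @param column coded genotype column.
#' @param d dominance effect size.
#' @export
dominance_value <- function(column, d) {
  check_coded(column)
  d * (1 - abs(column))
}

#' Per-individual additive-by-additive epistatic contribution
#'
#' A QTN pair (g1, g2) contributes `e * g1 * g2`: +e for matching
#' homozygotes, -e for opposite homozygotes, 0 whenever either locus is
#' heterozygous.
#'
#' @param col_1,col_2 coded genotype columns of the pair.
#' @param e epistatic effect size.
#' @export
epistatic_value <- function(col_1, col_2, e) {
  if (length(col_1) != length(col_2)) {
    pleio_stop("pleiosim_validation_error",
               "epistatic QTN pair columns have different lengths")
  }
  check_coded(col_1)
  check_coded(col_2)
  e * col_1 * col_2
}

# Resolve an effect specification for one trait and one model class.
# `spec_t` is either a numeric vector of explicit effects (length must equal
# n) or a single geometric base.
resolve_effects <- function(spec_t, n, what, trait) {
  if (n == 0) return(numeric(0))
  if (is.null(spec_t)) {
    pleio_stop("pleiosim_config_error",
               "trait %d has %d %s QTNs but no %s effects", trait, n, what,
               what)
  }
  if (length(spec_t) == 1 && n > 1) return(geometric_effects(spec_t, n))
  if (length(spec_t) == 1 && n == 1) return(as.numeric(spec_t))
  if (length(spec_t) != n) {
    pleio_stop("pleiosim_config_error",
               "trait %d: %d %s effects supplied for %d QTNs", trait,
               length(spec_t), what, n)
  }
  as.numeric(spec_t)
}

#' Genetic values for one replicate
#'
#' Sums additive, dominance and epistatic QTN contributions per individual
#' and trait. The per-QTN contribution matrices are retained for the
#' variance-explained decomposition.
#'
#' @param geno a [geno_matrix()].
#' @param assignment one replicate's QTN assignment (an element of the list
#'   returned by [select_qtns()]).
#' @param effects list with elements `add`, `dom`, `epi`; each is a list of
#'   per-trait numeric effect vectors, or a numeric vector of per-trait
#'   geometric bases.
#' @return list with `G` (individuals x traits matrix) and `contributions`
#'   (per trait, a matrix with one column per QTN unit).
#' @export
aggregate_genetic_values <- function(geno, assignment, effects) {
  n_traits <- length(assignment$traits)
  n_ind <- nrow(geno$values)
  G <- matrix(0, n_ind, n_traits)
  contributions <- vector("list", n_traits)
  trait_effect <- function(spec, t) {
    if (is.null(spec)) return(NULL)
    if (is.list(spec)) spec[[t]] else spec[t]
  }
  for (t in seq_len(n_traits)) {
    tr <- assignment$traits[[t]]
    a <- resolve_effects(trait_effect(effects$add, t), length(tr$add),
                         "additive", t)
    d <- resolve_effects(trait_effect(effects$dom, t), length(tr$dom),
                         "dominance", t)
    e <- resolve_effects(trait_effect(effects$epi, t), nrow(tr$epi),
                         "epistatic", t)
    cols <- list()
    nms <- character(0)
    for (k in seq_along(tr$add)) {
      cols[[length(cols) + 1]] <- additive_value(geno$values[, tr$add[k]],
                                                 a[k])
      nms <- c(nms, paste0("add_", geno$map$marker_id[tr$add[k]]))
    }
    for (k in seq_along(tr$dom)) {
      cols[[length(cols) + 1]] <- dominance_value(geno$values[, tr$dom[k]],
                                                  d[k])
      nms <- c(nms, paste0("dom_", geno$map$marker_id[tr$dom[k]]))
    }
    for (k in seq_len(nrow(tr$epi))) {
      cols[[length(cols) + 1]] <- epistatic_value(
        geno$values[, tr$epi[k, 1]], geno$values[, tr$epi[k, 2]], e[k]
      )
      nms <- c(nms, paste0("epi_", geno$map$marker_id[tr$epi[k, 1]], "x",
                           geno$map$marker_id[tr$epi[k, 2]]))
    }
    contrib <- if (length(cols)) {
      matrix(unlist(cols), nrow = n_ind, dimnames = list(NULL, nms))
    } else {
      matrix(0, n_ind, 0)
    }
    contributions[[t]] <- contrib
    if (ncol(contrib)) G[, t] <- rowSums(contrib)
  }
  rownames(G) <- geno$individual_ids
  colnames(G) <- paste0("trait_", seq_len(n_traits))
  list(G = G, contributions = contributions)
}

#' Fraction of trait variance explained by each QTN
#'
#' For each QTN unit (additive QTN, dominance QTN, or epistatic pair) the
#' fraction is `var(contribution) / denom_var`, where `denom_var` is the
#' phenotypic variance of the trait on the scale the contributions were
#' computed on (pre-whitening/coloring). A zero denominator yields `NA`.
#'
#' @param contributions per-trait list of contribution matrices (from
#'   [aggregate_genetic_values()]).
#' @param denom_var numeric vector of per-trait phenotypic variances.
#' @return data frame with columns `trait`, `qtn`, `variance_explained`.
#' @export
variance_explained <- function(contributions, denom_var) {
  out <- lapply(seq_along(contributions), function(t) {
    contrib <- contributions[[t]]
    if (!ncol(contrib)) return(NULL)
    v <- apply(contrib, 2, stats::var)
    frac <- if (denom_var[t] > 0) v / denom_var[t] else rep(NA_real_,
                                                            length(v))
    data.frame(trait = t, qtn = colnames(contrib),
               variance_explained = unname(frac),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
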
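# QTN selection under the pleiotropy, partial-pleiotropy and spurious-
# pleiotropy architectures, with MAF-window and LD-ceiling constraints.

#' Minor allele frequency of a coded genotype column
#'
#' The frequency of the "+1" allele is
#' `p = (2 * n(+1) + n(0)) / (2 * n_nonmissing)`; the MAF is `min(p, 1 - p)`.
#'
#' @param column numeric vector over \{-1, 0, 1, NA\}.
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(column) {
  ok <- !is.na(column)
  if (!any(ok)) {
    pleio_stop("pleiosim_validation_error",
               "cannot compute MAF of an all-missing column")
  }
  x <- column[ok]
  p <- (2 * sum(x == 1) + sum(x == 0)) / (2 * length(x))
  min(p, 1 - p)
}

#' Markers eligible under a MAF window
#'
#' Returns the indices of markers whose MAF lies strictly inside
#' `(maf_above, maf_below)`. Both bounds are exclusive: a marker whose MAF
#' equals a bound is rejected.
#'
#' @param geno a [geno_matrix()].
#' @param maf_above lower bound (exclusive), in \[0, 0.5).
#' @param maf_below upper bound (exclusive), in (0, 0.5\].
#' @return integer vector of eligible marker indices.
#' @export
maf_filter <- function(geno, maf_above = 0, maf_below = 0.5) {
  if (!(maf_above >= 0 && maf_above < maf_below && maf_below <= 0.5)) {
    pleio_stop("pleiosim_config_error",
               "need 0 <= maf_above < maf_below <= 0.5 (got %g, %g)",
               maf_above, maf_below)
  }
  mafs <- apply(geno$values, 2, compute_maf)
  idx <- which(unname(mafs > maf_above & mafs < maf_below))
  if (!length(idx)) {
    pleio_stop("pleiosim_config_error",
               "no markers have MAF strictly inside (%g, %g)",
               maf_above, maf_below)
  }
  idx
}

#' Linkage disequilibrium between two coded genotype columns
#'
#' Composite LD measured as the Pearson correlation of the -1/0/1 genotype
#' scores. Signed: r, not r-squared.
#'
#' @param col_a,col_b numeric genotype columns of equal length.
#' @return correlation in \[-1, 1\].
#' @export
ld_r <- function(col_a, col_b) {
  if (length(col_a) != length(col_b)) {
    pleio_stop("pleiosim_validation_error",
               "columns have different lengths (%d vs %d)",
               length(col_a), length(col_b))
  }
  if (stats::var(col_a, na.rm = TRUE) == 0 ||
      stats::var(col_b, na.rm = TRUE) == 0) {
    pleio_stop("pleiosim_validation_error",
               "LD is undefined for a zero-variance (monomorphic) column")
  }
  stats::cor(col_a, col_b, use = "pairwise.complete.obs")
}

# --- architecture spec ------------------------------------------------------

#' Describe a simulated genetic architecture
#'
#' Bundles the QTN configuration used by the selection routines. QTN counts
#' may be given per class as:
#' * a single integer (pleiotropy / single trait / spurious pleiotropy:
#'   the same count applies to every trait);
#' * for `partial_pleiotropy`, a list `list(shared = s, specific = c(...))`
#'   where `specific` has one entry per trait. Trait t is controlled by the
#'   `s` shared QTNs plus its own `specific[t]` QTNs.
#'
#' `epi_qtn_num` counts additive-by-additive QTN *pairs*; each pair consumes
#' two markers.
#'
#' @param architecture one of `"single_trait"`, `"pleiotropy"`,
#'   `"partial_pleiotropy"`, `"spurious_pleiotropy"`.
#' @param n_traits number of traits (>= 2 for multi-trait architectures).
#' @param add_qtn_num,dom_qtn_num,epi_qtn_num QTN counts (see above).
#' @param ld ceiling on |r| between a linking marker and its flanking QTNs
#'   (`type_of_ld = "indirect"`) or between the paired QTNs themselves
#'   (`"direct"`). Used only for spurious pleiotropy.
#' @param type_of_ld `"indirect"` or `"direct"`.
#' @param maf_above,maf_below optional MAF window (exclusive bounds); `NULL`
#'   means all polymorphic markers are eligible.
#' @param vary_qtn if `TRUE`, QTNs are re-drawn for every replicate
#'   (experiment); if `FALSE` the same QTNs are reused across replicates.
#' @param seed root seed for QTN selection.
#' @param n_experiments number of replicates.
#' @param scan_window how many map-adjacent markers on each side of a
#'   candidate linking marker are scanned for flanking QTNs in spurious
#'   mode.
#' @return an object of class `architecture_spec`.
#' @export
architecture_spec <- function(architecture = c("pleiotropy",
                                               "partial_pleiotropy",
                                               "spurious_pleiotropy",
                                               "single_trait"),
                              n_traits = 2,
                              add_qtn_num = 0, dom_qtn_num = 0,
                              epi_qtn_num = 0,
                              ld = 0.7, type_of_ld = c("indirect", "direct"),
                              maf_above = NULL, maf_below = NULL,
                              vary_qtn = FALSE, seed = 165,
                              n_experiments = 1, scan_window = 50) {
  architecture <- match.arg(architecture)
  type_of_ld <- match.arg(type_of_ld)
  if (architecture == "single_trait") n_traits <- 1L
  if (architecture != "single_trait" && n_traits < 2) {
    pleio_stop("pleiosim_config_error",
               "multi-trait architecture '%s' needs n_traits >= 2",
               architecture)
  }
  check_counts <- function(x, name) {
    if (architecture == "partial_pleiotropy") {
      if (is.list(x)) {
        if (!all(c("shared", "specific") %in% names(x)) ||
            length(x$specific) != n_traits) {
          pleio_stop("pleiosim_config_error",
                     "%s for partial pleiotropy must be list(shared=, specific=) with one specific count per trait",
                     name)
        }
        if (x$shared < 0 || any(x$specific < 0)) {
          pleio_stop("pleiosim_config_error", "%s counts must be >= 0", name)
        }
        return(x)
      }
      x <- list(shared = x, specific = rep(0L, n_traits))
      return(x)
    }
    if (!is_scalar_number(x) || x < 0) {
      pleio_stop("pleiosim_config_error",
                 "%s must be a single count >= 0", name)
    }
    x
  }
  add_qtn_num <- check_counts(add_qtn_num, "add_qtn_num")
  dom_qtn_num <- check_counts(dom_qtn_num, "dom_qtn_num")
  epi_qtn_num <- check_counts(epi_qtn_num, "epi_qtn_num")
  if (!is.null(maf_above) != !is.null(maf_below)) {
    pleio_stop("pleiosim_config_error",
               "maf_above and maf_below must be given together")
  }
  if (!(ld > 0 && ld <= 1)) {
    pleio_stop("pleiosim_config_error", "ld ceiling must lie in (0, 1]")
  }
  if (architecture == "spurious_pleiotropy") {
    if (n_traits != 2) {
      pleio_stop("pleiosim_config_error",
                 "spurious pleiotropy is defined for exactly 2 traits")
    }
    if (dom_count_total(dom_qtn_num) > 0 || dom_count_total(epi_qtn_num) > 0) {
      pleio_stop("pleiosim_config_error",
                 "spurious pleiotropy supports additive QTNs only")
    }
  }
  structure(
    list(architecture = architecture, n_traits = as.integer(n_traits),
         add_qtn_num = add_qtn_num, dom_qtn_num = dom_qtn_num,
         epi_qtn_num = epi_qtn_num, ld = ld, type_of_ld = type_of_ld,
         maf_above = maf_above, maf_below = maf_below,
         vary_qtn = isTRUE(vary_qtn), seed = as.integer(seed),
         n_experiments = as.integer(n_experiments),
         scan_window = as.integer(scan_window)),
    class = "architecture_spec"
  )
}

dom_count_total <- function(x) if (is.list(x)) x$shared + sum(x$specific) else x

# eligible marker indices for a spec: MAF window if set, else all polymorphic
eligible_markers <- function(geno, spec) {
  if (!is.null(spec$maf_above)) {
    maf_filter(geno, spec$maf_above, spec$maf_below)
  } else {
    vars <- apply(geno$values, 2, stats::var)
    which(vars > 0)
  }
}

# --- selection --------------------------------------------------------------

# A per-replicate assignment is a list:
#   traits: list per trait of list(add=idx, dom=idx, epi=2-col matrix of pairs)
#   link:   linking marker indices (spurious indirect only)
#   ld_table: data frame of realized LD (spurious only)
#   seed:   the seed used for this replicate
new_assignment <- function(spec, traits, seed, link = integer(0),
                           ld_table = NULL) {
  list(traits = traits, link = link, ld_table = ld_table, seed = seed)
}

require_eligible <- function(n_needed, eligible, what) {
  if (length(eligible) < n_needed) {
    pleio_stop("pleiosim_config_error",
               "%s needs %d eligible markers but only %d satisfy the constraints",
               what, n_needed, length(eligible))
  }
}

# draw one pleiotropic replicate: a single ordered sample partitioned into
# additive, dominance and epistatic-pair slots, shared by every trait
draw_pleiotropic_once <- function(spec, eligible, seed) {
  n_add <- spec$add_qtn_num
  n_dom <- spec$dom_qtn_num
  n_epi <- spec$epi_qtn_num
  total <- n_add + n_dom + 2 * n_epi
  require_eligible(total, eligible, "pleiotropic selection")
  picked <- with_seed(seed, sample_safe(eligible, total))
  add <- utils::head(picked, n_add)
  dom <- picked[seq_len(n_dom) + n_add]
  epi_flat <- utils::tail(picked, 2 * n_epi)
  epi <- if (n_epi > 0) matrix(epi_flat, ncol = 2, byrow = TRUE) else
    matrix(integer(0), ncol = 2)
  one <- list(add = add, dom = dom, epi = epi)
  new_assignment(spec, rep(list(one), spec$n_traits), seed)
}

#' Select QTNs under full pleiotropy
#'
#' One sample of markers (without replacement) controls every trait. With
#' `vary_qtn = FALSE` the replicate-1 assignment is reused for all
#' experiments; otherwise each replicate re-draws with its own derived seed.
#'
#' @param spec an [architecture_spec()].
#' @param eligible integer vector of eligible marker indices (see
#'   [maf_filter()]).
#' @return list of per-replicate assignments (class `qtn_assignment`).
#' @export
select_pleiotropic <- function(spec, eligible) {
  reps <- lapply(seq_len(spec$n_experiments), function(r) {
    seed_r <- derive_seed(spec$seed, if (spec$vary_qtn) r else 1L, 1L)
    draw_pleiotropic_once(spec, eligible, seed_r)
  })
  structure(reps, class = "qtn_assignment")
}

#' Select QTNs under partial pleiotropy
#'
#' Draws one shared QTN set controlling all traits plus a disjoint
#' trait-specific set per trait; trait t's QTNs are the union of the shared
#' set and its own set.
#'
#' @inheritParams select_pleiotropic
#' @export
select_partial <- function(spec, eligible) {
  na <- spec$add_qtn_num; nd <- spec$dom_qtn_num; ne <- spec$epi_qtn_num
  total <- (na$shared + sum(na$specific)) + (nd$shared + sum(nd$specific)) +
    2 * (ne$shared + sum(ne$specific))
  draw_once <- function(seed_r) {
    require_eligible(total, eligible, "partial-pleiotropy selection")
    picked <- with_seed(seed_r, sample_safe(eligible, total))
    take <- local({
      pos <- 0L
      function(k) {
        out <- picked[seq_len(k) + pos]
        pos <<- pos + k
        out
      }
    })
    shared <- list(add = take(na$shared), dom = take(nd$shared),
                   epi = pair_up(take(2 * ne$shared)))
    traits <- lapply(seq_len(spec$n_traits), function(t) {
      list(add = c(shared$add, take(na$specific[t])),
           dom = c(shared$dom, take(nd$specific[t])),
           epi = rbind(shared$epi, pair_up(take(2 * ne$specific[t]))))
    })
    new_assignment(spec, traits, seed_r)
  }
  reps <- lapply(seq_len(spec$n_experiments), function(r) {
    draw_once(derive_seed(spec$seed, if (spec$vary_qtn) r else 1L, 1L))
  })
  structure(reps, class = "qtn_assignment")
}

pair_up <- function(idx) {
  if (!length(idx)) return(matrix(integer(0), ncol = 2))
  matrix(idx, ncol = 2, byrow = TRUE)
}

#' Select QTNs under spurious pleiotropy
#'
#' Two traits are controlled by disjoint QTN sets that only appear
#' pleiotropic through linkage disequilibrium.
#'
#' In `indirect` mode, for each QTN slot a linking marker is drawn at
#' random; its map neighbourhood (`scan_window` markers each side) is then
#' scanned for one upstream and one downstream eligible marker whose |r|
#' with the linking marker does not exceed the `ld` ceiling. Among
#' qualifying candidates the one with |r| closest to the ceiling is taken,
#' so the realized LD is as informative as the constraint allows. The
#' upstream marker becomes a QTN of trait 1, the downstream one a QTN of
#' trait 2.
#'
#' In `direct` mode the ceiling applies between the two paired QTNs
#' themselves: a trait-1 QTN is drawn at random and its neighbourhood is
#' scanned for a trait-2 QTN with |r| <= ceiling, again taking the
#' qualifying candidate closest to the ceiling.
#'
#' Realized r values (link vs each QTN, and QTN vs QTN) are recorded in the
#' per-replicate `ld_table`.
#'
#' @inheritParams select_pleiotropic
#' @param geno the [geno_matrix()] the indices refer to (needed to compute
#'   r).
#' @export
select_spurious <- function(spec, geno, eligible) {
  reps <- lapply(seq_len(spec$n_experiments), function(r) {
    seed_r <- derive_seed(spec$seed, if (spec$vary_qtn) r else 1L, 1L)
    draw_spurious_once(spec, geno, eligible, seed_r)
  })
  structure(reps, class = "qtn_assignment")
}

draw_spurious_once <- function(spec, geno, eligible, seed) {
  n_slots <- spec$add_qtn_num
  v <- geno$values
  m <- ncol(v)
  elig <- logical(m)
  elig[eligible] <- TRUE
  with_seed(seed, {
    used <- logical(m)
    link <- integer(0)
    q1 <- integer(0)
    q2 <- integer(0)
    r_l1 <- r_l2 <- r_qq <- numeric(0)
    # best candidate in `cand` (scanned outward from anchor) with
    # |r(anchor, cand)| <= ceiling, maximizing |r|
    best_flank <- function(anchor, cand) {
      best <- NA_integer_
      best_r <- NA_real_
      for (j in cand) {
        if (!elig[j] || used[j]) next
        rj <- suppressWarnings(stats::cor(v[, anchor], v[, j]))
        if (is.na(rj)) next
        if (abs(rj) <= spec$ld && (is.na(best_r) || abs(rj) > abs(best_r))) {
          best <- j
          best_r <- rj
        }
      }
      list(idx = best, r = best_r)
    }
    for (slot in seq_len(n_slots)) {
      found <- FALSE
      anchors <- sample_safe(eligible[!used[eligible]])
      for (a in anchors) {
        up_cand <- if (a > 1) rev(seq(max(1, a - spec$scan_window), a - 1)) else integer(0)
        dn_cand <- if (a < m) seq(a + 1, min(m, a + spec$scan_window)) else integer(0)
        same_chr <- geno$map$chrom == geno$map$chrom[a]
        up_cand <- up_cand[same_chr[up_cand]]
        dn_cand <- dn_cand[same_chr[dn_cand]]
        if (spec$type_of_ld == "indirect") {
          up <- best_flank(a, up_cand)
          if (is.na(up$idx)) next
          dn <- best_flank(a, dn_cand)
          if (is.na(dn$idx)) next
          link <- c(link, a)
          q1 <- c(q1, up$idx)
          q2 <- c(q2, dn$idx)
          r_l1 <- c(r_l1, up$r)
          r_l2 <- c(r_l2, dn$r)
          r_qq <- c(r_qq, suppressWarnings(stats::cor(v[, up$idx],
                                                      v[, dn$idx])))
          used[c(a, up$idx, dn$idx)] <- TRUE
        } else {
          dn <- best_flank(a, c(dn_cand, up_cand))
          if (is.na(dn$idx)) next
          q1 <- c(q1, a)
          q2 <- c(q2, dn$idx)
          r_l1 <- c(r_l1, NA_real_)
          r_l2 <- c(r_l2, NA_real_)
          r_qq <- c(r_qq, dn$r)
          used[c(a, dn$idx)] <- TRUE
        }
        found <- TRUE
        break
      }
      if (!found) {
        pleio_stop("pleiosim_config_error",
                   "no qualifying %s LD pair/triple for QTN slot %d under ld ceiling %g; consider a larger ceiling or scan window",
                   spec$type_of_ld, slot, spec$ld)
      }
    }
    ld_table <- data.frame(
      link = if (spec$type_of_ld == "indirect") link else NA_integer_,
      qtn_trait1 = q1, qtn_trait2 = q2,
      r_link_qtn1 = r_l1, r_link_qtn2 = r_l2, r_qtn_qtn = r_qq
    )
    traits <- list(
      list(add = q1, dom = integer(0), epi = matrix(integer(0), ncol = 2)),
      list(add = q2, dom = integer(0), epi = matrix(integer(0), ncol = 2))
    )
    new_assignment(spec, traits, seed, link = link, ld_table = ld_table)
  })
}

#' Dispatch QTN selection for an architecture
#'
#' @inheritParams select_spurious
#' @return list of per-replicate assignments.
#' @export
select_qtns <- function(spec, geno) {
  eligible <- eligible_markers(geno, spec)
  switch(spec$architecture,
    single_trait = ,
    pleiotropy = select_pleiotropic(spec, eligible),
    partial_pleiotropy = select_partial(spec, eligible),
    spurious_pleiotropy = select_spurious(spec, geno, eligible)
  )
}

# all distinct QTN marker indices of one replicate (excluding linking markers)
assignment_qtn_indices <- function(rep_assignment) {
  idx <- unlist(lapply(rep_assignment$traits, function(tr) {
    c(tr$add, tr$dom, as.vector(tr$epi))
  }))
  sort(unique(as.integer(idx)))
}
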
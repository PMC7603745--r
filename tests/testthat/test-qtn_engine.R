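# MAF computation, LD, and QTN selection under the three architectures.

test_that("compute_maf matches hand allele counts", {
  cases <- list(
    list(col = c(-1, -1, 1, 1), maf = 0.5),      # balanced homozygotes
    list(col = c(-1, -1, -1, 0), maf = 0.125),   # 1 minor allele of 8
    list(col = c(0, 0, 0, 0), maf = 0.5),        # all heterozygous
    list(col = c(1, 1, 0, NA), maf = 1 / 6)      # missing excluded
  )
  for (cs in cases) expect_equal(compute_maf(cs$col), cs$maf)
  expect_error(compute_maf(c(NA, NA)), class = "pleiosim_validation_error")
})

test_that("maf_filter applies strict bounds on both sides", {
  # columns with known MAFs 0.1, 0.05, 0.45, 0.25 (n = 10 individuals)
  build_col <- function(n_plus_hom, n_het, n = 10) {
    c(rep(1, n_plus_hom), rep(0, n_het), rep(-1, n - n_plus_hom - n_het))
  }
  vals <- cbind(build_col(1, 0), build_col(0, 1), build_col(4, 1),
                build_col(2, 1))
  map <- data.frame(marker_id = paste0("m", 1:4), chrom = "1", pos = 1:4,
                    allele_minus = "A", allele_plus = "G",
                    stringsAsFactors = FALSE)
  g <- geno_matrix(vals, map, paste0("i", 1:10))
  expect_equal(apply(g$values, 2, compute_maf), c(m1 = 0.1, m2 = 0.05,
                                                  m3 = 0.45, m4 = 0.25))
  # both boundary MAFs are excluded under the exclusive window
  expect_equal(sort(g$map$marker_id[maf_filter(g, 0.05, 0.45)]),
               c("m1", "m4"))
  expect_equal(maf_filter(g, 0, 0.5), 1:4)
  expect_error(maf_filter(g, 0.46, 0.5), class = "pleiosim_config_error")
  expect_error(maf_filter(g, 0.3, 0.2), class = "pleiosim_config_error")
})

test_that("ld_r is signed Pearson correlation of coded genotypes", {
  x <- c(-1, -1, 1, 1, 0, 1)
  expect_equal(ld_r(x, x), 1)
  expect_equal(ld_r(x, -x), -1)
  expect_equal(ld_r(c(-1, -1, 1, 1), c(-1, 1, -1, 1)), 0)
  expect_error(ld_r(x, rep(1, 6)), class = "pleiosim_validation_error")
  expect_error(ld_r(x, x[-1]), class = "pleiosim_validation_error")
})

test_that("pleiotropic selection gives every trait the identical QTN set", {
  g <- make_fixture(80, 400, seed = 3)
  spec <- architecture_spec("pleiotropy", n_traits = 2, add_qtn_num = 20,
                            seed = 31, n_experiments = 3)
  asg <- select_qtns(spec, g)
  expect_length(asg, 3)
  for (r in 1:3) {
    expect_length(asg[[r]]$traits[[1]]$add, 20)
    expect_identical(asg[[r]]$traits[[1]], asg[[r]]$traits[[2]])
    expect_equal(anyDuplicated(asg[[r]]$traits[[1]]$add), 0)
  }
  # vary_qtn = FALSE: identical assignments across replicates
  expect_identical(asg[[1]]$traits, asg[[2]]$traits)

  # vary_qtn = TRUE: replicates differ (with overwhelming probability)
  spec_v <- architecture_spec("pleiotropy", n_traits = 2, add_qtn_num = 20,
                              seed = 31, n_experiments = 3, vary_qtn = TRUE)
  asg_v <- select_qtns(spec_v, g)
  expect_false(identical(asg_v[[1]]$traits[[1]]$add,
                         asg_v[[2]]$traits[[1]]$add))

  # determinism: same spec, same assignment
  asg2 <- select_qtns(spec, g)
  expect_identical(asg, asg2)
})

test_that("selection respects QTN class partitioning and MAF windows", {
  g <- make_fixture(100, 500, maf_range = c(0.02, 0.5), seed = 4)
  spec <- architecture_spec("pleiotropy", n_traits = 2, add_qtn_num = 4,
                            dom_qtn_num = 3, epi_qtn_num = 2,
                            maf_above = 0.05, maf_below = 0.45, seed = 8)
  asg <- select_qtns(spec, g)[[1]]
  tr <- asg$traits[[1]]
  expect_length(tr$add, 4)
  expect_length(tr$dom, 3)
  expect_equal(dim(tr$epi), c(2, 2))
  all_idx <- c(tr$add, tr$dom, as.vector(tr$epi))
  expect_equal(anyDuplicated(all_idx), 0)
  mafs <- vapply(all_idx, function(j) compute_maf(g$values[, j]), numeric(1))
  expect_true(all(mafs > 0.05 & mafs < 0.45))

  expect_error(
    select_qtns(architecture_spec("pleiotropy", n_traits = 2,
                                  add_qtn_num = 1000, seed = 8), g),
    class = "pleiosim_config_error"
  )
})

test_that("partial pleiotropy splits shared and trait-specific QTNs correctly", {
  g <- make_fixture(80, 400, seed = 5)
  spec <- architecture_spec("partial_pleiotropy", n_traits = 2,
                            add_qtn_num = list(shared = 4,
                                               specific = c(7, 9)),
                            seed = 12)
  asg <- select_qtns(spec, g)[[1]]
  a1 <- asg$traits[[1]]$add
  a2 <- asg$traits[[2]]$add
  expect_length(a1, 11)
  expect_length(a2, 13)
  expect_length(intersect(a1, a2), 4)

  # shared = 0 gives disjoint sets; specific = 0 reduces to pleiotropy
  asg0 <- select_qtns(architecture_spec("partial_pleiotropy", n_traits = 2,
                                        add_qtn_num = list(shared = 0,
                                                           specific = c(5, 5)),
                                        seed = 12), g)[[1]]
  expect_length(intersect(asg0$traits[[1]]$add, asg0$traits[[2]]$add), 0)
  asg_p <- select_qtns(architecture_spec("partial_pleiotropy", n_traits = 2,
                                         add_qtn_num = list(shared = 6,
                                                            specific = c(0, 0)),
                                         seed = 12), g)[[1]]
  expect_identical(asg_p$traits[[1]]$add, asg_p$traits[[2]]$add)
})

test_that("spurious-indirect selection respects the LD ceiling and disjointness", {
  g <- block_fixture(n = 300, m = 600, r = 0.6, seed = 21)
  spec <- architecture_spec("spurious_pleiotropy", n_traits = 2,
                            add_qtn_num = 5, ld = 0.7, seed = 33,
                            n_experiments = 5, vary_qtn = TRUE)
  asg <- select_qtns(spec, g)
  for (r in seq_along(asg)) {
    lt <- asg[[r]]$ld_table
    expect_equal(nrow(lt), 5)
    expect_true(all(abs(lt$r_link_qtn1) <= 0.7))
    expect_true(all(abs(lt$r_link_qtn2) <= 0.7))
    expect_length(intersect(asg[[r]]$traits[[1]]$add,
                            asg[[r]]$traits[[2]]$add), 0)
    # linking markers are not QTNs of either trait
    expect_length(intersect(asg[[r]]$link,
                            c(lt$qtn_trait1, lt$qtn_trait2)), 0)
    # recorded r values match direct recomputation
    for (k in seq_len(nrow(lt))) {
      expect_equal(lt$r_link_qtn1[k],
                   ld_r(g$values[, asg[[r]]$link[k]],
                        g$values[, lt$qtn_trait1[k]]))
    }
  }
})

test_that("spurious-direct selection bounds the LD between paired QTNs", {
  g <- block_fixture(n = 300, m = 600, r = 0.6, seed = 22)
  spec <- architecture_spec("spurious_pleiotropy", n_traits = 2,
                            add_qtn_num = 4, ld = 0.7,
                            type_of_ld = "direct", seed = 44)
  asg <- select_qtns(spec, g)[[1]]
  lt <- asg$ld_table
  expect_true(all(abs(lt$r_qtn_qtn) <= 0.7))
  expect_length(asg$link, 0)
  expect_length(intersect(asg$traits[[1]]$add, asg$traits[[2]]$add), 0)
})

test_that("a vacuous LD ceiling always succeeds", {
  g <- make_fixture(60, 200, seed = 9)
  spec <- architecture_spec("spurious_pleiotropy", n_traits = 2,
                            add_qtn_num = 3, ld = 1.0, seed = 7)
  expect_silent(asg <- select_qtns(spec, g))
  expect_equal(nrow(asg[[1]]$ld_table), 3)
})

test_that("linking triples concentrate in LD blocks when background r is near 0", {
  # one strong block; everything else independent. With ceiling 0.7 the
  # closest-to-ceiling rule must draw flanking QTNs from the block whenever
  # the linking marker sits inside it.
  g <- make_fixture(400, 120,
                    ld_blocks = data.frame(n_markers = 30, r = 0.6),
                    seed = 13)
  block_idx <- which(g$block_of == 1)
  spec <- architecture_spec("spurious_pleiotropy", n_traits = 2,
                            add_qtn_num = 3, ld = 0.7, seed = 5,
                            n_experiments = 10, vary_qtn = TRUE)
  asg <- select_qtns(spec, g)
  interior <- setdiff(block_idx, range(block_idx)) # block markers with
  # at least one block neighbour on each side
  in_block_link <- in_block_qtn <- 0L
  for (r in seq_along(asg)) {
    lt <- asg[[r]]$ld_table
    inside <- asg[[r]]$link %in% interior
    in_block_link <- in_block_link + sum(inside)
    in_block_qtn <- in_block_qtn +
      sum(lt$qtn_trait1[inside] %in% block_idx &
            lt$qtn_trait2[inside] %in% block_idx)
  }
  expect_gt(in_block_link, 0)
  expect_equal(in_block_qtn, in_block_link)
})
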